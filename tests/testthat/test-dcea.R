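# High-precision reference values for the EDE formulas (50-digit arithmetic,
# frozen): Atkinson and Kolm on (2, 3, 4, 5) with equal weights, and on
# (1, 7, 5) with weights (0.2, 0.5, 0.3).
ATK_E1_2345 <- 3.309750919646873105
ATK_E2_2345 <- 3.1168831168831168831 # harmonic mean 4 / (1/2 + 1/3 + 1/4 + 1/5)
ATK_E11_2345 <- 2.2932065683823066516
ATK_E05_175W <- 4.8123023544427776944
KOLM_A015_2345 <- 3.4065471257455428167
KOLM_A03_175W <- 4.2871873183947708021

test_that("Atkinson EDE matches closed forms and high-precision references", {
  v <- c(2, 3, 4, 5)
  expect_equal(atkinson_ede(v, epsilon = 0), 3.5)
  expect_equal(atkinson_ede(v, epsilon = 2), ATK_E2_2345, tolerance = 1e-12)
  expect_equal(atkinson_ede(v, epsilon = 1), ATK_E1_2345, tolerance = 1e-12)
  expect_equal(atkinson_ede(v, epsilon = 11), ATK_E11_2345, tolerance = 1e-12)
  expect_equal(atkinson_ede(c(1, 7, 5), c(0.2, 0.5, 0.3), epsilon = 0.5),
               ATK_E05_175W, tolerance = 1e-12)
  # equal distributions are their own EDE at any aversion
  for (e in c(0, 0.5, 1, 2, 11, 30))
    expect_equal(atkinson_ede(rep(4.2, 4), epsilon = e), 4.2, tolerance = 1e-12)
  expect_error(atkinson_ede(c(1, -1, 2, 3), epsilon = 2), "kolm_ede")
  expect_error(atkinson_ede(v, epsilon = -1), "epsilon")
  expect_error(atkinson_ede(v, weights = c(0.5, 0.5), epsilon = 1), "weights")
})

test_that("Kolm EDE matches references, its translation property and the mean limit", {
  v <- c(2, 3, 4, 5)
  expect_equal(kolm_ede(v, alpha = 0.15), KOLM_A015_2345, tolerance = 1e-12)
  expect_equal(kolm_ede(c(1, 7, 5), c(0.2, 0.5, 0.3), alpha = 0.3),
               KOLM_A03_175W, tolerance = 1e-12)
  expect_equal(kolm_ede(rep(1.5, 4), alpha = 0.15), 1.5)
  # translation: shifting all outcomes by c shifts the EDE by exactly c
  expect_equal(kolm_ede(v + 2.5, alpha = 0.15), KOLM_A015_2345 + 2.5,
               tolerance = 1e-10)
  # alpha -> 0 approaches the weighted mean
  expect_equal(kolm_ede(v, alpha = 1e-8), 3.5, tolerance = 1e-5)
  # negative outcomes are admissible
  expect_lt(kolm_ede(c(-1, 0, 1, 2), alpha = 0.5), 0.5)
  expect_error(kolm_ede(v, alpha = 0), "alpha")
})

test_that("EDE implementations agree with direct formula evaluation on random inputs", {
  set.seed(30)
  for (i in 1:250) {
    k <- sample(2:6, 1)
    v <- runif(k, 0.2, 20)
    w <- runif(k); w <- w / sum(w)
    for (e in c(0, 0.5, 1, 2, 5, 11, 30)) {
      direct <- if (e == 0) sum(w * v)
        else if (e == 1) prod(v^w)
        else sum(w * v^(1 - e))^(1 / (1 - e))
      expect_equal(atkinson_ede(v, w, e), direct, tolerance = 1e-10)
    }
    for (a in c(0.15, 1, 3)) {
      direct <- -log(sum(w * exp(-a * v))) / a
      expect_equal(kolm_ede(v, w, a), direct, tolerance = 1e-10)
    }
  }
})

test_that("Atkinson EDE is scale-covariant, bounded by the mean, and monotone in aversion", {
  set.seed(31)
  for (i in 1:50) {
    v <- runif(4, 0.5, 10)
    w <- rep(0.25, 4)
    eps <- c(0, 0.5, 1, 2, 5, 11, 20, 30)
    ede <- vapply(eps, function(e) atkinson_ede(v, w, e), numeric(1))
    expect_true(all(diff(ede) <= 1e-12)) # non-increasing in aversion
    if (diff(range(v)) > 1e-6) expect_true(all(ede[-1] < mean(v)))
    k <- runif(1, 0.1, 10)
    expect_equal(atkinson_ede(k * v, w, 11), k * atkinson_ede(v, w, 11),
                 tolerance = 1e-10)
    # Kolm never exceeds the mean; equality only for equal values
    expect_lt(kolm_ede(v, w, 0.5), mean(v) + 1e-12)
  }
})

test_that("per-capita NHB nets public opportunity cost off societal QALYs", {
  mk_summary <- function(qalys_pc, cost_pc, persons = 1000) {
    data.frame(strategy = "UC", group = c(paste0("Q", 1:4), "total"),
               persons = c(rep(persons, 4), 4 * persons),
               qalys = c(rep(qalys_pc * persons, 4), 4 * qalys_pc * persons),
               cost_public_allcause = c(rep(cost_pc * persons, 4),
                                        4 * cost_pc * persons),
               cost_public_fall = 0, oop_expenditure = 0, productivity_paid = 0,
               productivity_unpaid = 0, informal_care = 0, intervention_public = 0,
               intervention_copay = 0, intervention_participant_time = 0,
               intervention_caregiver_time = 0, stringsAsFactors = FALSE)
  }
  out <- per_capita_nhb_by_quartile(mk_summary(5, 28080), lambda_pub = 20000)
  expect_equal(out$nhb_per_capita, rep(5 - 28080 / 20000, 4)) # 3.596
  expect_equal(out$ses_quartile, 1:4)
  # zero costs: NHB equals per-capita QALYs
  out0 <- per_capita_nhb_by_quartile(mk_summary(5, 0), lambda_pub = 20000)
  expect_equal(out0$nhb_per_capita, rep(5, 4))
  # a higher public threshold raises NHB when public costs are positive
  out30 <- per_capita_nhb_by_quartile(mk_summary(5, 28080), lambda_pub = 30000)
  expect_true(all(out30$nhb_per_capita > out$nhb_per_capita))
  bad <- mk_summary(5, 100)
  bad$persons[2] <- 0
  expect_error(per_capita_nhb_by_quartile(bad, 20000), "quartile")
})

test_that("incremental EDE NHB is zero against itself and antisymmetric", {
  ede <- c(UC = 3.7127, R = 3.7183, RC = 3.7250)
  inc <- ede_inhb(ede, "UC")
  expect_equal(inc[["UC"]], 0)
  expect_equal(inc[["R"]], 3.7183 - 3.7127)
  expect_equal(ede_inhb(ede, "R")[["UC"]], -inc[["R"]])
  expect_error(ede_inhb(ede, "XX"), "comparator")
})

test_that("the optimal strategy can switch as inequality aversion rises", {
  # A is better on average; B is perfectly equal. Under enough relative
  # aversion the equal distribution wins.
  mk <- function(strategy, values) {
    do.call(rbind, lapply(c(0, 30), function(e)
      data.frame(strategy = strategy, lambda_pub = 30000,
                 index_family = "atkinson", index_value = e,
                 ede_nhb = atkinson_ede(values, epsilon = e), ede_inhb = NA,
                 optimal = NA, stringsAsFactors = FALSE)))
  }
  tab <- rbind(mk("A", c(0.5, 2, 6, 7.5)), mk("B", rep(3.6, 4)))
  opt <- optimal_strategy(tab)
  expect_identical(opt$optimal_strategy[opt$index_value == 0], "A")
  expect_identical(opt$optimal_strategy[opt$index_value == 30], "B")
  # the winner's incremental EDE NHB against every rival is non-negative
  at0 <- tab[tab$index_value == 0, ]
  winner <- at0$strategy[which.max(at0$ede_nhb)]
  expect_true(all(at0$ede_nhb[at0$strategy == winner] - at0$ede_nhb >= 0))
})

test_that("progressivity classification follows strict quartile ordering", {
  expect_identical(progressivity(c(0.01, 0.02, 0.03, 0.04)),
                   "unambiguously progressive")
  expect_identical(progressivity(c(0.04, 0.03, 0.02, 0.01)),
                   "unambiguously regressive")
  expect_identical(progressivity(c(0.01, 0.03, 0.02, 0.04)), "mixed")
  expect_error(progressivity(c(1, 2, 3)), "four")
})

test_that("the DCEA table reduces to weighted means at zero aversion", {
  p <- build_default_parameters()
  summ <- run_strategies(p, c("UC", "R"), list(n_baseline = 400, n_entry = 10),
                         master_seed = 2, horizon = 8)
  tab <- dcea_table(summ, lambda_pub = 20000, epsilon = c(0, 11), alpha = 0.15)
  for (s in c("UC", "R")) {
    nhb <- per_capita_nhb_by_quartile(summ[summ$strategy == s, ], 20000, 60000)
    at0 <- tab$ede_nhb[tab$strategy == s & tab$index_family == "atkinson" &
                       tab$index_value == 0]
    expect_equal(at0, mean(nhb$nhb_per_capita), tolerance = 1e-9)
    # any positive aversion weakly lowers the EDE below the mean
    at11 <- tab$ede_nhb[tab$strategy == s & tab$index_family == "atkinson" &
                        tab$index_value == 11]
    expect_lte(at11, at0)
  }
  # exactly one optimal strategy per (family, index, lambda) row
  split_keys <- split(tab$optimal,
                      paste(tab$lambda_pub, tab$index_family, tab$index_value))
  expect_true(all(vapply(split_keys, sum, numeric(1)) == 1))
  # comparator's incremental EDE NHB is zero
  expect_true(all(tab$ede_inhb[tab$strategy == "UC"] == 0))
})
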