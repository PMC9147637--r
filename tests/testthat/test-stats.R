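test_that("welch_t matches an independent evaluation on 1000 random inputs", {
  set.seed(101)
  worst_t <- worst_df <- 0
  for (i in 1:1000) {
    g <- random_groups()
    got <- welch_t(g$nc, g$blank, g$tc, g$tcb)
    want <- oracle_welch(g$nc, g$blank, g$tc, g$tcb)
    worst_t <- max(worst_t, abs(got[["t"]] - want[1]) / max(abs(want[1]), 1))
    worst_df <- max(worst_df, abs(got[["df"]] - want[2]) / want[2])
  }
  expect_lt(worst_t, 1e-12)
  expect_lt(worst_df, 1e-12)
})

test_that("welch_t symmetry, errors, and the two-sample limit", {
  eq <- gs(0.5, 0.01, 10)
  expect_equal(welch_t(eq, gs(0.1, 0.01, 10), gs(0.5, 0.01, 10),
                       gs(0.1, 0.01, 10))[["t"]], 0)
  expect_error(welch_t(gs(0.5, 0.01, 1), eq, eq, eq), "at least 2")
  expect_error(welch_t(gs(0.5, 0, 5), gs(0.1, 0, 5), gs(0.3, 0, 5),
                       gs(0.1, 0, 5)), "degenerate")
  # blank/TC-blank variance -> 0 with huge n: df approaches the classical
  # two-sample Welch df, cross-checked against stats::t.test
  set.seed(7)
  x <- rnorm(15, 1.0, 0.05)
  y <- rnorm(4, 0.6, 0.08)
  tt <- t.test(x, y)
  got <- welch_t(gs(mean(x), sd(x), 15), gs(0, 1e-12, 1e6),
                 gs(mean(y), sd(y), 4), gs(0, 1e-12, 1e6))
  expect_equal(got[["t"]], unname(tt$statistic), tolerance = 1e-6)
  expect_equal(got[["df"]], unname(tt$parameter), tolerance = 1e-4)
})

test_that("frequentist calls: strong depletion, null, and alpha monotonicity", {
  set.seed(21)
  g_strong <- groups_from_values(
    blank = rnorm(8, 0.10, 0.002), nc = rnorm(15, 1.10, 0.01),
    tc = rnorm(4, 0.55, 0.01), tcb = rnorm(3, 0.05, 0.002))
  for (a in c(0.05, 0.01, 0.005, 0.001)) {
    expect_equal(frequentist_call(g_strong, 1, inference_config(alpha = a))$call,
                 "binder")
  }
  g_null <- groups_from_values(
    blank = rnorm(8, 0.10, 0.002), nc = rnorm(15, 1.10, 0.01),
    tc = rnorm(4, 1.098, 0.01), tcb = rnorm(3, 0.1, 0.002))
  cl <- frequentist_call(g_null, 1, inference_config(alpha = 0.005))
  expect_equal(cl$call, "nonbinder")
  # decreasing alpha never increases binder calls on a fixed dataset
  set.seed(22)
  fixed <- replicate(120, {
    pct <- runif(1, 0, 25)
    groups_from_values(
      blank = rnorm(8, 0.10, 0.003), nc = rnorm(15, 1.10, 0.012),
      tc = rnorm(4, 0.10 + (1 - pct / 100), 0.02),
      tcb = rnorm(3, 0.10, 0.003))
  }, simplify = FALSE)
  n_binders <- vapply(c(0.05, 0.01, 0.005, 0.001), function(a) {
    cfg <- inference_config(alpha = a)
    sum(vapply(fixed, function(g) frequentist_call(g, 1, cfg)$call,
               character(1)) == "binder")
  }, numeric(1))
  expect_true(all(diff(n_binders) <= 0))
})

test_that("one-sided frequentist decision is monotone in depletion", {
  cfg <- inference_config(alpha = 0.005)
  sds <- list(blank = 0.003, nc = 0.012, tc = 0.02, tcb = 0.003)
  calls <- vapply(seq(0, 0.4, by = 0.02), function(dep) {
    g <- list(blank = gs(0.10, sds$blank, 8), nc = gs(1.10, sds$nc, 15),
              slots = list(list(name = "x", tc = gs(1.10 - dep, sds$tc, 4),
                                tc_blank = gs(0.10, sds$tcb, 3))),
              window = 1.0)
    class(g) <- "easa_groups"
    frequentist_call(g, 1, cfg)$call
  }, character(1))
  # once binder, always binder as depletion grows
  first <- match("binder", calls)
  expect_false(is.na(first))
  expect_true(all(calls[first:length(calls)] == "binder"))
})

test_that("type-I error matches nominal alpha 0.05 on null chemicals", {
  # At alpha = 0.005 the Satterthwaite approximation is measurably liberal
  # for this plate's group sizes (the dominant variance has ~3 df); the
  # far-tail behaviour is quantified in the acceptance suite.
  set.seed(31)
  n_sim <- 1500
  cfg <- inference_config(alpha = 0.05)
  hits <- 0
  for (i in seq_len(n_sim)) {
    g <- groups_from_values(
      blank = rnorm(8, 0.10, 0.003), nc = rnorm(15, 1.10, 0.012),
      tc = rnorm(4, 1.10, 0.012), tcb = rnorm(3, 0.10, 0.003))
    if (frequentist_call(g, 1, cfg)$call == "binder") hits <- hits + 1
  }
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(hits / n_sim - 0.05), 2 * se + 1e-12)
})

test_that("Bayesian route recovers parameters and handles the null", {
  set.seed(41)
  cfg <- fast_mcmc(alpha = 0.005)
  # well-separated: 50 % true depletion, ~1 % noise
  errs <- replicate(20, {
    g <- groups_from_values(
      blank = rnorm(8, 0.10, 0.001), nc = rnorm(15, 1.10, 0.011),
      tc = rnorm(4, 0.60, 0.006), tcb = rnorm(3, 0.10, 0.001))
    b <- bayesian_call(g, 1, cfg)
    expect_equal(b$call, "binder")
    expect_true(b$ci_low_abs > 0)
    b$pct_depletion - 50
  })
  expect_lt(abs(mean(errs)), 2)
  # identical group means: nonbinder, interval covers 0
  g0 <- groups_from_values(
    blank = rnorm(8, 0.10, 0.002), nc = rnorm(15, 1.10, 0.011),
    tc = rnorm(4, 1.10, 0.011), tcb = rnorm(3, 0.10, 0.002))
  b0 <- bayesian_call(g0, 1, cfg)
  expect_equal(b0$call, "nonbinder")
  expect_lt(b0$ci_low_abs, 0)
  expect_gt(b0$ci_high_abs, 0)
})

test_that("Bayesian call is reproducible under a fixed seed and scale-free", {
  set.seed(43)
  g <- groups_from_values(
    blank = rnorm(8, 0.10, 0.002), nc = rnorm(15, 1.10, 0.011),
    tc = rnorm(4, 0.80, 0.01), tcb = rnorm(3, 0.10, 0.002))
  b1 <- bayesian_call(g, 1, fast_mcmc(seed = 123))
  b2 <- bayesian_call(g, 1, fast_mcmc(seed = 123))
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$pct_depletion, b2$pct_depletion)
  # multiplying every well by a constant leaves the pct interval unchanged
  gscaled <- groups_from_values(
    blank = g$blank$values * 1000, nc = g$nc$values * 1000,
    tc = g$slots[[1]]$tc$values * 1000,
    tcb = g$slots[[1]]$tc_blank$values * 1000)
  b3 <- bayesian_call(gscaled, 1, fast_mcmc(seed = 123))
  expect_equal(b3$ci_low, b1$ci_low, tolerance = 1e-9)
  expect_equal(b3$ci_high_abs, 1000 * b1$ci_high_abs, tolerance = 1e-9)
})

test_that("k x SD rule uses a strict threshold", {
  cfg <- inference_config(ksd_factor = 5)
  expect_equal(ksd_call(10, 1.3, cfg)$call, "binder")     # 10 > 6.5
  expect_equal(ksd_call(0, 1.3, cfg)$call, "nonbinder")
  expect_equal(ksd_call(6.5, 1.3, cfg)$call, "nonbinder") # tie -> nonbinder
  expect_equal(ksd_call(6.5 + 1e-9, 1.3, cfg)$call, "binder")
})

test_that("borderline and anomaly flags", {
  cfg <- inference_config()
  mk <- function(call, pct) {
    x <- easa96:::assay_call(call, "frequentist", pct_depletion = pct)
    flag_borderline(x, cfg)
  }
  b7 <- mk("binder", 7)
  expect_true(b7$borderline_type1)
  expect_false(b7$borderline_type2)
  n5 <- mk("nonbinder", 5)
  expect_true(n5$borderline_type2)
  clean <- mk("binder", 45)
  expect_false(clean$borderline_type1 || clean$borderline_type2)
  anom <- mk("binder", -176)
  expect_equal(anom$call, "inconclusive")
  expect_true(anom$anomalous_negative)
})

test_that("run-level and chemical-level call rules", {
  b <- easa96:::assay_call("binder", "frequentist", 50)
  n <- easa96:::assay_call("nonbinder", "frequentist", 1)
  i <- easa96:::assay_call("inconclusive", "frequentist", -30)
  expect_equal(run_call(list(n, n, b)), "binder")
  expect_equal(run_call(list(n, n, n)), "nonbinder")
  expect_equal(run_call(list(n, i, n)), "inconclusive")
  expect_equal(run_call(list(b, i, "not_available")), "binder")
  expect_equal(run_call(list(n, "not_available", n)), "nonbinder")
  expect_error(run_call(list("not_available", "not_available",
                             "not_available")), "not evaluable")

  expect_equal(chemical_call("binder")$call, "binder")
  expect_equal(chemical_call(c("binder", "nonbinder", "binder",
                               "nonbinder"))$call, "inconclusive")
  expect_equal(chemical_call(c("binder", "binder", "nonbinder"))$call,
               "binder")
  expect_equal(chemical_call(c("inconclusive", "nonbinder"))$call,
               "nonbinder")
  expect_error(chemical_call(character()), "no runs")
  expect_error(chemical_call(c("inconclusive", "inconclusive")),
               "no evaluable")
})
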