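bubble_plate <- function(base = 0.066, hot = list()) {
  m <- matrix(base, 8, 12)
  for (w in names(hot)) {
    m[match(substr(w, 1, 1), LETTERS), as.integer(substring(w, 2))] <- hot[[w]]
  }
  plate_reading(m, "b680", "BUBBLE_680", 5)
}

test_that("bubble test excludes at the modality-appropriate threshold", {
  lay <- build_layout("x")
  spec <- qc_spec()
  p <- bubble_plate(hot = list(B3 = 0.085, C7 = 0.079))
  ex <- bubble_test(p, lay, spec, "NBT_ABS")
  expect_equal(as.character(ex), "B3")      # 0.085 out, 0.079 retained
  expect_equal(attr(ex, "reason"), "bubble")
  expect_length(bubble_test(bubble_plate(0.066), lay, spec, "NBT_ABS"), 0)
  # fluorescence uses the instrument-scale threshold
  pf <- bubble_plate(base = 4500, hot = list(D4 = 5400, E5 = 5200))
  expect_equal(as.character(bubble_test(pf, lay, spec, "PDA_FLUOR")), "D4")
  expect_error(bubble_test(NULL, lay, spec, "NBT_ABS"), "QC incomplete")
})

test_that("bubble exclusion is monotone in the threshold", {
  set.seed(5)
  m <- matrix(abs(rnorm(96, 0.07, 0.01)), 8, 12)
  p <- plate_reading(m, "b", "BUBBLE_680", 5)
  lay <- build_layout("x")
  counts <- vapply(c(0.06, 0.07, 0.081, 0.09, 0.12), function(thr) {
    length(bubble_test(p, lay, qc_spec(bubble_abs_threshold = thr), "NBT_ABS"))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("interference flags advisory offsets and dynamic-range violations", {
  fx <- noiseless_plate(tc_pct = c(20, 20, 20), interference = 0)
  vals <- fx$plate$values
  # slot 2 (row C): push its TC-blank wells up by 10 blank SDs worth
  vals[3, 10:12] <- vals[3, 10:12] + 0.05
  # add tiny blank noise so s_blank is defined and small
  set.seed(6)
  vals[1:8, 1] <- vals[1:8, 1] + rnorm(8, 0, 0.002)
  g <- summarize_groups(plate_reading(vals, "i", "NBT_ABS", 50), fx$layout)
  ic <- interference_check(g, qc_spec(), "NBT_ABS")
  expect_false(ic$flagged[1])
  expect_true(ic$flagged[2])
  expect_false(any(ic$assay_na))
  # saturating offset marks the slot not-available
  ic2 <- interference_check(g, qc_spec(dynamic_range_max = c(NBT_ABS = 0.12)),
                            "NBT_ABS")
  expect_true(ic2$assay_na[2])
  expect_false(ic2$assay_na[1])
})

test_that("interference decision is affine-consistent", {
  # adding a constant to every well shifts TC-blank and blank means alike,
  # so the flag must not change
  fx <- noiseless_plate(tc_pct = c(10, 10, 10), interference = 0.003)
  set.seed(8)
  vals <- fx$plate$values + matrix(rnorm(96, 0, 0.001), 8, 12)
  g1 <- summarize_groups(plate_reading(vals, "a", "NBT_ABS", 50), fx$layout)
  g2 <- summarize_groups(plate_reading(vals + 0.25, "b", "NBT_ABS", 50),
                         fx$layout)
  f1 <- interference_check(g1, qc_spec(), "NBT_ABS")$flagged
  f2 <- interference_check(g2, qc_spec(), "NBT_ABS")$flagged
  expect_equal(f1, f2)
})

test_that("pipetting QC: CVs and the column trend test", {
  fx <- noiseless_plate(nc = 1.0)
  qc0 <- pipetting_qc(fx$plate, fx$layout, qc_spec())
  expect_equal(qc0$within_step_cv, 0)
  expect_equal(qc0$between_step_cv, 0)
  expect_false(isTRUE(qc0$trend_warning))
  # strictly decreasing row-A values with tiny noise trips the trend test
  set.seed(9)
  vals <- fx$plate$values
  vals[1, 2:9] <- 1.0 - 0.01 * (0:7) + rnorm(8, 0, 1e-4)
  qc1 <- pipetting_qc(plate_reading(vals, "t", "NBT_ABS", 50), fx$layout,
                      qc_spec())
  expect_lt(qc1$trend_p, 0.05)
  expect_true(qc1$trend_warning)
  expect_lt(qc1$trend_slope, 0)
  # a ~1 % total decline is warned about but is not a rejection flag
  vals[1, 2:9] <- 1.0 * (1 - 0.01 * (0:7) / 7) + rnorm(8, 0, 1e-5)
  qc2 <- pipetting_qc(plate_reading(vals, "t2", "NBT_ABS", 50), fx$layout,
                      qc_spec())
  expect_true(qc2$trend_warning)
  expect_error(
    pipetting_qc(fx$plate, fx$layout, qc_spec(),
                 excluded = paste0("A", 3:9)),
    "QC incomplete")
})

test_that("control chart activates after the minimum history and trips at 3 SD", {
  spec <- qc_spec(chart_min_history = 5)
  st <- chart_state()
  base <- list(ss_mean = 0.10, nc_mean = 1.10, nc_cv = 1.0, pc_ic50 = 0.05)
  # insufficient history: runs accepted with a note, no limits applied
  for (i in 1:2) {
    up <- update_control_chart(st, base, spec)
    expect_true(up$accepted)
    st <- up$state
  }
  expect_match(update_control_chart(st, base, spec)$note, "insufficient")
  # build a 10-run history with small variation
  st <- chart_state()
  set.seed(10)
  for (i in 1:10) {
    rp <- lapply(base, function(v) v * (1 + rnorm(1, 0, 0.01)))
    st <- update_control_chart(st, rp, spec)$state
  }
  ok <- update_control_chart(st, base, spec)
  expect_true(ok$accepted)
  # NC CV at history mean + 4 SD -> plate outlier, not appended
  h <- st$history
  bad <- base
  bad$nc_cv <- mean(h$nc_cv) + 4 * sd(h$nc_cv)
  out <- update_control_chart(st, bad, spec)
  expect_false(out$accepted)
  expect_equal(out$outlier_params, "nc_cv")
  expect_equal(nrow(out$state$history), nrow(st$history))
  # identical history, identical run: accepted (zero deviation)
  st0 <- chart_state()
  for (i in 1:10) st0 <- update_control_chart(st0, base, spec)$state
  expect_true(update_control_chart(st0, base, spec)$accepted)
})

test_that("chart state persists through JSON", {
  st <- chart_state()
  for (i in 1:6) {
    st <- update_control_chart(st, list(ss_mean = 0.1 + i / 1000,
                                        nc_mean = 1.1, nc_cv = 1,
                                        pc_ic50 = 0.05))$state
  }
  f <- withr::local_tempfile(fileext = ".json")
  chart_to_json(st, f)
  st2 <- chart_from_json(f)
  expect_equal(st2$history, st$history)
})

test_that("false plate-outlier rate under 3-SD charting is small", {
  # clean runs, parameter noise ~1 %: expected trip rate < 5 % per parameter
  set.seed(12)
  n_hist <- 30; n_test <- 200
  spec <- qc_spec(chart_min_history = 5)
  st <- chart_state()
  draw <- function() list(ss_mean = rnorm(1, 0.10, 0.001),
                          nc_mean = rnorm(1, 1.10, 0.011),
                          nc_cv = rnorm(1, 1.0, 0.01),
                          pc_ic50 = rnorm(1, 0.05, 0.0005))
  for (i in seq_len(n_hist)) st <- update_control_chart(st, draw(), spec)$state
  trips <- 0
  for (i in seq_len(n_test)) {
    up <- update_control_chart(st, draw(), spec)
    if (!up$accepted) trips <- trips + 1 else st <- up$state
  }
  expect_lt(trips / n_test, 0.05)
})
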