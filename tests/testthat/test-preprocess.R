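test_that("compensation solves the spillover system", {
  panel <- toy_panel()
  cfg_id <- preprocess_config()
  em <- event_matrix(matrix(c(500, 500, 100, 10), 1), panel, "c1", "raw")
  expect_equal(compensate(em, cfg_id)$values, em$values,
               ignore_attr = TRUE)

  # spillover [[1, 0.1], [0, 1]]: observed (100, 10) -> true (99, 10)
  sp <- matrix(c(1, 0, 0.1, 1), 2)
  cfg <- preprocess_config(spillover = sp)
  out <- compensate(em, cfg)
  expect_equal(unname(out$values[1, 3:4]), c(99, 10))

  # a permutation spillover un-permutes the fluorescence columns
  perm <- matrix(c(0, 1, 1, 0), 2)
  em2 <- event_matrix(matrix(c(1, 1, 7, 13), 1), panel, "c2", "raw")
  out2 <- compensate(em2, preprocess_config(spillover = perm))
  expect_equal(unname(out2$values[1, 3:4]), c(13, 7))

  expect_error(preprocess_config(spillover = matrix(0, 2, 2)), "singular")
})

test_that("log transform floors and logs fluorescence, scales scatter", {
  panel <- toy_panel()
  cfg <- preprocess_config(log_floor = 1, scatter_scale = 100)
  em <- event_matrix(matrix(c(200, 300, 1000, 0.5), 1), panel, "l", "raw")
  out <- log_transform(compensate(em, cfg), cfg)
  expect_equal(unname(out$values[1, ]), c(2, 3, 3, 0))

  # monotone: sorted inputs give non-decreasing outputs
  x <- sort(runif(200, 0, 5000))
  em2 <- event_matrix(cbind(x, x, x, x), panel, "m", "raw")
  out2 <- log_transform(compensate(em2, cfg), cfg)
  expect_true(all(diff(out2$values[, 3]) >= 0))
})

test_that("high side-scatter exclusion removes the configured tail", {
  panel <- toy_panel()
  vals <- cbind(1:10, c(1, 3, 2, 8, 5, 9, 9, 4, 6, 7), 1:10, 1:10)
  em <- event_matrix(vals, panel, "s", "transformed")
  none <- exclude_high_ssc(em, preprocess_config(ssc_exclusion_quantile = 1))
  expect_equal(attr(none, "removed"), 0L)

  # 10 events, q = 0.9: exactly one removed, the SSC maximum; ties keep
  # earlier events (rows 6 and 7 tie at 9 -> row 7 goes)
  one <- exclude_high_ssc(em, preprocess_config(ssc_exclusion_quantile = 0.9))
  expect_equal(attr(one, "removed"), 1L)
  expect_equal(one$values[, 1], setdiff(1:10, 7), ignore_attr = TRUE)

  # removal count tracks (1 - q) * n within one event for continuous SSC
  set.seed(2)
  big <- event_matrix(matrix(runif(4000), 1000), panel, "b", "transformed")
  for (q in c(0.99, 0.95, 0.8, 0.5)) {
    r <- attr(exclude_high_ssc(big, preprocess_config(
      ssc_exclusion_quantile = q)), "removed")
    expect_lte(abs(r - round((1 - q) * 1000)), 1)
  }
})

test_that("range standardization maps the robust range onto [0, 6]", {
  panel <- toy_panel()
  cfg <- preprocess_config(robust_percentiles = c(0, 1))
  x <- c(10, 15, 20, 30, 40)   # lo 10, hi 40, midpoint 25
  em <- event_matrix(cbind(x, x, c(10, 25, 25, 25, 40), x), panel, "r",
                     "transformed")
  out <- standardize(em, cfg)
  expect_equal(unname(out$values[c(1, 5), 3]), c(0, 6))
  expect_equal(unname(out$values[2:4, 3]), c(3, 3, 3))
  expect_true(all(out$values >= 0 & out$values <= 6))

  const <- event_matrix(cbind(x, x, rep(5, 5), x), panel, "k",
                        "transformed")
  expect_warning(outc <- standardize(const, cfg), "constant")
  expect_equal(unname(outc$values[, 3]), rep(3, 5))
})

test_that("standardization is monotone per channel", {
  panel <- toy_panel()
  set.seed(9)
  v <- matrix(rnorm(400, 100, 30), 100)
  em <- event_matrix(v, panel, "mono", "transformed")
  out <- standardize(em, preprocess_config(robust_percentiles = c(0, 1)))
  for (j in 1:4) {
    expect_equal(order(out$values[, j]), order(v[, j]))
  }
})

test_that("subsampling is seeded, sized and identity at rate 1", {
  panel <- toy_panel()
  em <- event_matrix(matrix(runif(40000), 10000), panel, "ss",
                     "standardized")
  cfg <- preprocess_config(subsample_rate = 0.01, seed = 4)
  out <- subsample(em, cfg)
  expect_equal(nrow(out$values), 100)
  expect_identical(out$values, subsample(em, cfg)$values)
  all_of_it <- subsample(em, preprocess_config(subsample_rate = 1))
  expect_equal(all_of_it$values, em$values, ignore_attr = TRUE)
})

test_that("the chain preserves channel identity and enforces stage order", {
  cfg <- preprocess_config()
  coh <- small_cohort(2, 2, 800, output = "raw")
  em <- coh$samples[[1]]$events$T1
  out <- preprocess_sample(em, cfg, subsample_events = TRUE)
  expect_identical(colnames(out$values), colnames(em$values))
  expect_identical(out$stage, "subsampled")
  log <- attr(out, "stage_log")
  expect_equal(unname(log["raw"]), 800)
  expect_lt(log["after_ssc_exclusion"], 800 + 1)

  expect_error(log_transform(em, cfg), "expected stage")
  expect_error(subsample(em, cfg), "expected stage")
})
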