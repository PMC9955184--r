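test_that("a 1D-separable planted population is gated near the density gap", {
  # two modes on CD3: background at 1, planted population at 5; the
  # class-dependent fraction of the planted mode drives the split
  panel <- toy_panel()
  set.seed(31)
  events <- list()
  classes <- rep(c(1, 0), each = 10)
  for (i in 1:20) {
    frac <- if (classes[i] == 1) 0.35 else 0.10
    n <- 500
    k <- rbinom(1, n, frac)
    cd3 <- c(rnorm(k, 5, 0.3), rnorm(n - k, 1, 0.3))
    v <- cbind(runif(n, 2, 4), runif(n, 1, 3), pmin(pmax(cd3, 0), 6),
               runif(n, 0, 6))
    events[[paste0("s", i)]] <- v
  }
  tree <- build_gate_tree(events, classes, panel)
  expect_gt(length(tree$leaves), 1)
  root_gate <- tree$root$gate
  edge_near_gap <- function(g) {
    any(abs(c(g$x_lo, g$x_hi)[g$channel_x == "CD3"] - 3) < 1.2) ||
      any(abs(c(g$y_lo, g$y_hi)[g$channel_y == "CD3"] - 3) < 1.2)
  }
  expect_true("CD3" %in% c(root_gate$channel_x, root_gate$channel_y))
  expect_true(edge_near_gap(root_gate))
})

test_that("single-class input collapses to one warning leaf", {
  events <- list(a = matrix(runif(400, 0, 6), 100),
                 b = matrix(runif(400, 0, 6), 100))
  expect_warning(tree <- build_gate_tree(events, c(1, 1), toy_panel()),
                 "single-leaf")
  expect_length(tree$leaves, 1)
  lab <- assign_events(tree, matrix(runif(40, 0, 6), 10))
  expect_equal(unique(lab), tree$leaves[[1]]$pop_id)
})

test_that("empty input errors", {
  expect_error(build_gate_tree(list(a = matrix(0, 0, 4),
                                    b = matrix(0, 0, 4)),
                               c(0, 1), toy_panel()), "no training events")
})

test_that("planted CD4 effect produces a discriminative T-helper gate", {
  coh <- small_cohort(14, 24, 2500, seed = 41)
  res <- run_pipeline(coh, tubes = "T1")
  expect_true("T_CD4" %in% res$T1$lineage$label)
  cd4 <- res$T1$lineage$pop_id[res$T1$lineage$label == "T_CD4"][1]
  i <- match(cd4, res$T1$ranking$pop_id)
  # underrepresented in the inferior class, usefully discriminative
  expect_lt(res$T1$ranking$cohens_d[i], 0)
  expect_lt(res$T1$ranking$auc[i], 0.35)
  # the defining gates include a CD3/CD4-positive region
  pop <- res$T1$tree$leaves[[which(vapply(res$T1$tree$leaves, `[[`,
                                          character(1), "pop_id") == cd4)]]
  expect_equal(pop$direction, "underrepresented_in_ttf1")
})

test_that("frequency table group means track the generator calibration", {
  coh <- small_cohort(14, 24, 2500, seed = 41)
  res <- run_pipeline(coh, tubes = "T1")
  cd4 <- res$T1$lineage$pop_id[res$T1$lineage$label == "T_CD4"][1]
  i <- match(cd4, res$T1$ranking$pop_id)
  # class means within Monte-Carlo reach of 13.51% / 4.91% (n is small,
  # the gate captures most but not all of the population)
  expect_gt(res$T1$ranking$mean_ttf0[i], 7)
  expect_lt(res$T1$ranking$mean_ttf0[i], 20)
  expect_lt(res$T1$ranking$mean_ttf1[i], 9)
  expect_gt(res$T1$ranking$mean_ttf0[i], res$T1$ranking$mean_ttf1[i])
})

test_that("stability is perfect when every repeat sees identical data", {
  coh <- small_cohort(5, 7, 600, seed = 53)
  prep <- preprocess_cohort(coh, "T1",
                            preprocess_config(subsample_rate = 0.1))
  cfg <- discovery_config(max_depth = 3)
  tree <- build_gate_tree(prep$training, coh$metadata$ttf,
                          cll_panel("T1"), cfg)
  cv <- cross_validate(prep$training, coh$metadata$ttf, cll_panel("T1"),
                       tree, cfg, B = 3, rate = 1.0, seed = 5)
  expect_true(all(cv$stability == 1))
  expect_true(all(cv$retained))
})

test_that("a strong planted effect recurs across subsample repeats", {
  coh <- small_cohort(10, 14, 2500, seed = 61)
  prep <- preprocess_cohort(coh, "T1",
                            preprocess_config(subsample_rate = 0.02))
  tree <- build_gate_tree(prep$training, coh$metadata$ttf, cll_panel("T1"))
  cv <- cross_validate(prep$full, coh$metadata$ttf, cll_panel("T1"),
                       tree, B = 5, rate = 0.02, seed = 11)
  # the dominant populations (largest leaves) should recur in most
  # repeats; require at least one stable population
  expect_gt(max(cv$stability), 0.5)
})
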