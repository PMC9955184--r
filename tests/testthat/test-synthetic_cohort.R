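test_that("identical seeds give bit-identical samples, new seeds fresh data", {
  cfg <- cohort_config(n_ttf1 = 2, n_ttf0 = 2, events_per_sample = 500,
                       tubes = "T1")
  a <- generate_sample(cfg, 1, seed = 99)
  b <- generate_sample(cfg, 1, seed = 99)
  c <- generate_sample(cfg, 1, seed = 100)
  expect_identical(a$events$T1$values, b$events$T1$values)
  expect_identical(a$fractions, b$fractions)
  expect_false(identical(a$events$T1$values, c$events$T1$values))
  expect_identical(dim(a$events$T1$values), dim(c$events$T1$values))
})

test_that("cohort sizes follow the configured class split", {
  coh <- small_cohort(2, 2, 100)
  expect_length(coh$samples, 4)
  coh157 <- generate_cohort(cohort_config(events_per_sample = 20,
                                          tubes = "T1", seed = 3))
  expect_length(coh157$samples, 157)
  expect_equal(sum(coh157$metadata$ttf == 1), 42)
  expect_equal(sum(coh157$metadata$ttf == 0), 115)
})

test_that("true fractions sum to one and match the event multinomial", {
  cfg <- cohort_config(n_ttf1 = 2, n_ttf0 = 2, events_per_sample = 20000,
                       tubes = "T1")
  s <- generate_sample(cfg, 0, seed = 7)
  expect_equal(sum(s$fractions), 1)
  counts <- attr(s$events$T1, "population_counts")
  emp <- counts / sum(counts)
  # multinomial sampling: empirical fraction within 4 binomial SEs
  se <- sqrt(s$fractions * (1 - s$fractions) / 20000)
  expect_true(all(abs(emp - s$fractions) <= 4 * se + 1e-9))
})

test_that("class-conditional mean frequencies match their calibration", {
  cfg <- cohort_config(n_ttf1 = 2, n_ttf0 = 2, events_per_sample = 10,
                       tubes = "T1")
  draw_frac <- function(class, n) {
    vapply(seq_len(n), function(i)
      generate_sample(cfg, class, seed = 5000 + 7 * i +
                        class)$fractions[["T_CD4"]], numeric(1))
  }
  f0 <- draw_frac(0, 400)
  f1 <- draw_frac(1, 400)
  expect_lt(abs(mean(f0) - 0.1351), 3 * sd(f0) / sqrt(400))
  expect_lt(abs(mean(f1) - 0.0491), 3 * sd(f1) / sqrt(400))
})

test_that("analytic frequency AUC agrees with direct simulation", {
  cfg <- cohort_config(tubes = "T1", events_per_sample = 10)
  ana <- analytic_frequency_auc(cfg, "T_CD4")
  expect_gt(ana, 0.75)
  expect_lt(ana, 0.80)
  fp <- cfg$frequency_priors
  i <- match("T_CD4", fp$population)
  set.seed(42)
  f0 <- plogis(rnorm(4000, fp$mu_ttf0[i], fp$sigma[i]))
  f1 <- plogis(rnorm(4000, fp$mu_ttf1[i], fp$sigma[i]))
  emp <- roc_auc(c(-f1, -f0), rep(c(1, 0), each = 4000))$auc
  expect_lt(abs(emp - ana), 0.02)
})

test_that("null configuration removes every class difference", {
  cfg <- cohort_config(null = TRUE, tubes = "T1", events_per_sample = 10)
  fp <- cfg$frequency_priors
  expect_equal(fp$mean_ttf1, fp$mean_ttf0)
  expect_equal(analytic_frequency_auc(cfg, "T_CD4"), 0.5)
})

test_that("IPI component coupling behaves at both extremes", {
  pts <- function(class, coupling, n, base) {
    vapply(seq_len(n), function(i) {
      m <- generate_ipi_components(class, coupling, seed = base + i)
      ipi_score(cbind(data.frame(sample_id = "x"), m))$points
    }, numeric(1))
  }
  # coupling 1: clearly higher scores in class 1
  p1 <- pts(1, 1, 150, 100)
  p0 <- pts(0, 1, 150, 9000)
  expect_gt(mean(p1), mean(p0) + 1)
  # coupling 0: no dependence on class (same seeds give identical draws)
  expect_identical(pts(1, 0, 50, 500), pts(0, 0, 50, 500))
  # reproducible under a fixed seed
  expect_identical(generate_ipi_components(1, 0.5, 77),
                   generate_ipi_components(1, 0.5, 77))
})

test_that("raw output mode yields instrument-scale positive values", {
  cfg <- cohort_config(n_ttf1 = 2, n_ttf0 = 2, events_per_sample = 300,
                       tubes = "T1", output = "raw")
  em <- generate_sample(cfg, 0, seed = 3)$events$T1
  expect_identical(em$stage, "raw")
  expect_true(all(em$values >= 0))
  fl <- em$values[, 3:16]
  expect_gt(max(fl), 100)  # 4-decade fluorescence scale
})

test_that("invalid configurations are rejected", {
  bad <- default_frequency_priors()
  bad$mean_ttf0[1] <- 99
  expect_error(cohort_config(frequency_priors = bad), "exceed 100")
  expect_error(cohort_config(n_ttf1 = 1), "n_ttf1")
})
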