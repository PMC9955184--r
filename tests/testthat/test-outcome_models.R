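test_that("AUC equals the Mann-Whitney identity on random instances", {
  set.seed(101)
  for (rep in 1:200) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    labels <- sample(rep(c(1, 0), c(n1, n0)))
    scores <- if (rep %% 3 == 0) sample(1:5, n1 + n0, TRUE)  # with ties
              else rnorm(n1 + n0)
    r <- roc_auc(scores, labels)
    u <- suppressWarnings(stats::wilcox.test(
      scores[labels == 1], scores[labels == 0]))$statistic
    expect_equal(r$auc, unname(u) / (n1 * n0))
  }
})

test_that("AUC degenerate and symmetry properties hold", {
  labels <- rep(c(1, 0), c(5, 7))
  perfect <- c(rep(10, 5), rep(0, 7))
  expect_equal(roc_auc(perfect, labels)$auc, 1)
  set.seed(5)
  s <- rnorm(12)
  expect_equal(roc_auc(s, labels)$auc + roc_auc(-s, labels)$auc, 1)
  # monotone-transform invariance
  expect_equal(roc_auc(exp(s), labels)$auc, roc_auc(s, labels)$auc)
  r <- roc_auc(s, labels)
  expect_lte(r$ci95[1], r$auc)
  expect_gte(r$ci95[2], r$auc)
  expect_error(roc_auc(s, rep(1, 12)), "both outcome classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(33)
  labels <- rep(c(1, 0), c(30, 45))
  scores <- rnorm(75) + labels
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                           quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
})

test_that("paired AUC comparison degenerates and discriminates correctly", {
  set.seed(7)
  labels <- rep(c(1, 0), c(40, 60))
  s <- rnorm(100) + labels
  same <- compare_auc_paired(s, s, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  strong <- rnorm(100) + 3 * labels
  weak <- rnorm(100) + 0.3 * labels
  cmp <- compare_auc_paired(strong, weak, labels)
  expect_lt(cmp$p, 0.05)
  expect_gt(cmp$auc_a, cmp$auc_b)
})

test_that("paired AUC test is roughly calibrated under the null", {
  set.seed(19)
  ps <- replicate(200, {
    labels <- rep(c(1, 0), c(20, 30))
    compare_auc_paired(rnorm(50), rnorm(50), labels)$p
  })
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.13)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("logistic fits report odds ratios with the right signs", {
  set.seed(55)
  n <- 200
  x_adverse <- rnorm(n)
  x_protect <- rnorm(n)
  eta <- 1.2 * x_adverse - 1.2 * x_protect
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(cbind(adverse = x_adverse, protect = x_protect), y)
  expect_gt(fit$terms$odds_ratio[1], 1)
  expect_lt(fit$terms$odds_ratio[2], 1)
  expect_false(fit$separation)
  expect_gt(fit$model_auc$auc, 0.7)
  # OR > 1 exactly when the coefficient is positive
  expect_equal(fit$terms$odds_ratio > 1, fit$terms$estimate > 0)

  # perfect separation is flagged and still yields a finite fit
  sep <- fit_logistic(cbind(f = as.numeric(y)), y)
  expect_true(sep$separation)
  expect_true(all(is.finite(sep$coef)))

  expect_error(fit_logistic(cbind(k = rep(1, n)), y), "constant")
})

test_that("bootstrap validation has the prescribed shape and determinism", {
  set.seed(66)
  n <- 60
  x <- rnorm(n)
  y <- rep(c(1, 0), c(20, 40))
  bv <- bootstrap_validate(cbind(x = x), y, trials = 10,
                           leave_out_per_group = 3, seed = 2)
  expect_length(bv$per_trial_auc, 10)
  expect_equal(nrow(bv$held_out), 60)   # 10 trials x 6 held-out samples
  expect_equal(as.integer(table(bv$held_out$label)), c(30L, 30L))
  bv2 <- bootstrap_validate(cbind(x = x), y, trials = 10,
                            leave_out_per_group = 3, seed = 2)
  expect_identical(bv$held_out, bv2$held_out)
  # null feature: held-out AUC near chance
  expect_gt(bv$pooled_auc, 0.25)
  expect_lt(bv$pooled_auc, 0.75)
  expect_error(bootstrap_validate(cbind(x = x[1:8]), y[1:8],
                                  leave_out_per_group = 3), "too small")
})

test_that("CLL-IPI scoring follows the component weights and bands", {
  row <- function(...) cbind(data.frame(sample_id = "s"),
                             data.frame(...))
  worst <- ipi_score(row(age_years = 80, binet = "C", b2m_elevated = 1,
                         ighv_unmutated = 1, tp53_aberrant = 1))
  expect_equal(worst$points, 10)
  expect_equal(worst$category, "very_high")

  best <- ipi_score(row(age_years = 60, binet = "A", b2m_elevated = 0,
                        ighv_unmutated = 0, tp53_aberrant = 0))
  expect_equal(best$points, 0)
  expect_equal(best$category, "low")

  none <- ipi_score(row(age_years = NA, binet = NA, b2m_elevated = NA,
                        ighv_unmutated = NA, tp53_aberrant = NA))
  expect_equal(none$points, 5)
  expect_equal(none$n_missing_components, 5)

  # beta2-microglobulin accepted as a concentration
  conc <- ipi_score(row(age_years = 60, binet = "A", b2m_mg_l = 4.1,
                        ighv_unmutated = 0, tp53_aberrant = 0))
  expect_equal(conc$points, 2)
})

test_that("IPI score is integer without missingness and monotone", {
  grid <- expand.grid(age = c(60, 70), binet = c("A", "C"),
                      b2m = 0:1, ighv = 0:1, tp53 = 0:1,
                      stringsAsFactors = FALSE)
  pts <- function(g) ipi_score(cbind(
    data.frame(sample_id = "s"),
    data.frame(age_years = g$age, binet = g$binet, b2m_elevated = g$b2m,
               ighv_unmutated = g$ighv, tp53_aberrant = g$tp53)))$points
  for (i in seq_len(nrow(grid))) {
    p <- pts(grid[i, ])
    expect_equal(p, round(p))
    # worsening any single favourable component never decreases points
    worse <- grid[i, ]
    if (worse$age == 60) { worse$age <- 70
    } else if (worse$b2m == 0) { worse$b2m <- 1
    } else worse$tp53 <- 1
    expect_gte(pts(worse), p)
  }
})

test_that("cohort summaries count, percentage and quantile correctly", {
  meta <- data.frame(
    sample_id = paste0("s", 1:8),
    ttf = c(1, 1, 0, 0, 0, 0, 0, 0),
    died = c(1, 0, 0, 0, 0, 0, 0, 0),
    first_line_failure = c(1, 1, 0, 0, 0, 0, 0, 0),
    sex = c("F", "M", "F", "F", "M", "M", "M", "M"),
    age_years = c(70, 60, 50, 55, 65, 75, 80, 45),
    binet = c("A", "B", NA, "A", "A", "A", "C", "A"))
  s <- summarize_cohort(meta)
  g <- function(block, level, group)
    s[s$block == block & s$level == level & s$group == group, ]
  expect_equal(g("sex", "F", "total")$n, 3)
  expect_equal(g("sex", "F", "total")$pct, 37.5)
  expect_equal(g("death", "1", "total")$pct, 12.5)
  expect_equal(g("death", "1", "ttf1")$pct, 50)
  expect_equal(g("binet", "unknown", "total")$n, 1)
  expect_equal(g("age_years", "median", "total")$median, 62.5)
  # categorical block percentages close under rounding
  sex_total <- s[s$block == "sex" & s$group == "total", "pct"]
  expect_equal(sum(sex_total), 100)
  # empty category reports zero
  expect_equal(g("richter", "1", "total")$n, 0)
})
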