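#' ROC curve area with Hanley-McNeil confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation with midranks for ties:
#' the probability that a random positive (TTF 1) scores above a random
#' negative.  The standard error follows Hanley & McNeil's formula with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`; the 95% CI is the normal
#' approximation clipped to `[0,1]`, and `p_vs_chance` tests `A = 0.5`
#' two-sidedly.
#'
#' @param scores Numeric predictor, one value per sample.
#' @param labels Outcome class per sample (0/1); 1 is the positive class.
#' @return List: `auc`, `se`, `ci95` (length-2), `p_vs_chance`, `n1`,
#'   `n0`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(scores)                      # midranks handle ties
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  se <- hanley_se(auc, n1, n0)
  z <- if (se > 0) (auc - 0.5) / se else 0
  list(auc = auc, se = se,
       ci95 = c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se)),
       p_vs_chance = 2 * stats::pnorm(-abs(z)), n1 = n1, n0 = n0)
}

hanley_se <- function(a, n1, n0) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt(max(0, a * (1 - a) + (n1 - 1) * (q1 - a^2) +
             (n0 - 1) * (q2 - a^2)) / (n1 * n0))
}

#' Compare two correlated AUCs (Hanley-McNeil test)
#'
#' Both predictors are measured on the same samples, so their AUCs are
#' correlated.  The correlation of the AUC estimates is approximated by
#' the average of the Spearman rank correlations of the two score
#' vectors within the positives and within the negatives (the
#' rank-correlation entry point to Hanley & McNeil's correction), and
#' `z = (A1 - A2) / sqrt(SE1^2 + SE2^2 - 2 r SE1 SE2)`.
#'
#' @param scores_a,scores_b Two predictors on the same samples.
#' @param labels Outcome class per sample (0/1).
#' @return List: `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  ra <- roc_auc(scores_a, labels)
  rb <- roc_auc(scores_b, labels)
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b))))
    return(list(auc_a = ra$auc, auc_b = rb$auc, z = 0, p = 1))
  pos <- labels == 1; neg <- !pos
  r_pos <- suppressWarnings(stats::cor(scores_a[pos], scores_b[pos],
                                       method = "spearman"))
  r_neg <- suppressWarnings(stats::cor(scores_a[neg], scores_b[neg],
                                       method = "spearman"))
  r <- mean(c(r_pos, r_neg), na.rm = TRUE)
  if (!is.finite(r)) r <- 0
  denom <- sqrt(max(ra$se^2 + rb$se^2 - 2 * r * ra$se * rb$se, 1e-12))
  z <- (ra$auc - rb$auc) / denom
  list(auc_a = ra$auc, auc_b = rb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Multiple logistic regression with Wald inference
#'
#' Maximum-likelihood fit of `labels ~ features`; per-term odds ratios
#' with 95% Wald CIs and p-values, and the in-sample AUC of the fitted
#' probabilities.  Complete or quasi-complete separation (infinite MLE)
#' is detected and triggers a ridge-penalized refit, prominently
#' flagged, because at cohort sizes around 150 a strong planted effect
#' can separate.
#'
#' @param features Numeric matrix or data.frame of predictors (no
#'   constant columns).
#' @param labels Outcome class per sample (0/1).
#' @param ridge Penalty used on separation (L2 on coefficients,
#'   excluding the intercept).
#' @return List: `terms` (`data.frame`: `name`, `estimate`,
#'   `odds_ratio`, `ci_lo`, `ci_hi`, `p`), `model_auc` ([roc_auc()] of
#'   the linear predictor), `separation`, `fitted`, `coef`.
#' @export
fit_logistic <- function(features, labels, ridge = 0.01) {
  X <- as.matrix(as.data.frame(features))
  stopifnot(nrow(X) == length(labels), all(labels %in% c(0, 1)),
            nrow(X) >= 10)
  if (any(apply(X, 2, stats::sd) == 0))
    stop("constant feature column", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(labels)

  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- fit$coefficients
  if (!sep && any(abs(coefs[-1]) > 15 / apply(X, 2, stats::sd)))
    sep <- TRUE

  if (sep) {
    rf <- ridge_logistic(X, y, lambda = ridge)
    coefs <- rf$coef
    vc <- rf$vcov
  } else {
    w <- fit$weights
    XtWX <- crossprod(cbind(1, X) * sqrt(w))
    vc <- solve(XtWX)
  }
  se <- sqrt(diag(vc))
  est <- coefs[-1]
  se_t <- se[-1]
  zt <- est / se_t
  terms <- data.frame(
    name = colnames(X), estimate = unname(est),
    odds_ratio = unname(exp(est)),
    ci_lo = unname(exp(est - 1.96 * se_t)),
    ci_hi = unname(exp(est + 1.96 * se_t)),
    p = unname(2 * stats::pnorm(-abs(zt))),
    stringsAsFactors = FALSE)
  eta <- drop(cbind(1, X) %*% coefs)
  list(terms = terms, model_auc = roc_auc(eta, labels),
       separation = sep, fitted = stats::plogis(eta), coef = coefs)
}

# Newton-Raphson logistic fit with an L2 penalty on non-intercept terms
ridge_logistic <- function(X, y, lambda = 0.01, max_iter = 100) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd * sqrt(w)) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  names(beta) <- colnames(Xd)
  list(coef = beta, vcov = solve(H))
}

#' Bootstrap validation with leave-three-per-group trials
#'
#' In each of `trials` rounds, `leave_out_per_group` randomly chosen
#' samples from each outcome group are held out, the logistic model is
#' refit on the remainder, and the held-out samples are scored.
#' Reported are the per-trial held-out AUCs and the pooled AUC over all
#' held-out scores.
#'
#' @param features Predictor matrix/data.frame.
#' @param labels Outcome class per sample (0/1).
#' @param trials Number of bootstrap trials.
#' @param leave_out_per_group Samples held out from each group per trial.
#' @param seed Integer seed.
#' @return List: `per_trial_auc`, `pooled_auc`, `held_out` (data.frame
#'   of trial, score, label).
#' @export
bootstrap_validate <- function(features, labels, trials = 10,
                               leave_out_per_group = 3, seed = 1) {
  X <- as.matrix(as.data.frame(features))
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  if (length(i1) < leave_out_per_group + 2 ||
      length(i0) < leave_out_per_group + 2)
    stop("a group is too small for leave-", leave_out_per_group,
         "-out validation", call. = FALSE)
  set.seed(as.integer(seed))
  per_trial <- rep(NA_real_, trials)
  held <- list()
  for (t in seq_len(trials)) {
    out <- c(sample(i1, leave_out_per_group), sample(i0, leave_out_per_group))
    fit <- tryCatch(fit_logistic(X[-out, , drop = FALSE], labels[-out]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("bootstrap trial ", t, " skipped: model could not be fit",
              call. = FALSE)
      next
    }
    eta <- drop(cbind(1, X[out, , drop = FALSE]) %*% fit$coef)
    per_trial[t] <- roc_auc(eta, labels[out])$auc
    held[[t]] <- data.frame(trial = t, score = eta, label = labels[out])
  }
  if (!length(held)) stop("no bootstrap trial could be fit", call. = FALSE)
  held <- do.call(rbind, held)
  list(per_trial_auc = per_trial,
       pooled_auc = roc_auc(held$score, held$label)$auc,
       held_out = held)
}

# CLL-IPI component weights and category bands (single config table)
ipi_weights <- c(age_over_65 = 1, binet_bc = 1, b2m_elevated = 2,
                 ighv_unmutated = 2, tp53_aberrant = 4)
ipi_bands <- data.frame(category = c("low", "intermediate", "high",
                                     "very_high"),
                        lo = c(0, 2, 4, 7), hi = c(2, 4, 7, 10.5))

#' CLL-IPI score with half-point imputation
#'
#' Points: 1 for age > 65, 1 for Binet B/C, 2 for elevated
#' beta2-microglobulin (> 3.5 mg/L if given as a concentration), 2 for
#' unmutated IGHV, 4 for TP53 aberration.  A missing component
#' contributes half its points.  Categories: low 0-1, intermediate 2-3,
#' high 4-6, very high 7-10 (half-point totals fall into the band below
#' the next integer threshold).
#'
#' @param meta One-row metadata `data.frame` (see [metadata-format]); a
#'   `b2m_mg_l` column is accepted in place of `b2m_elevated`.
#' @return List: `points`, `category`, `n_missing_components`.
#' @export
ipi_score <- function(meta) {
  stopifnot(is.data.frame(meta), nrow(meta) == 1)
  g <- function(col) if (col %in% names(meta)) meta[[col]] else NA
  comp <- c(
    age_over_65 = if (is.na(g("age_years"))) NA else
      as.numeric(g("age_years") > 65),
    binet_bc = if (is.na(g("binet"))) NA else
      as.numeric(g("binet") %in% c("B", "C")),
    b2m_elevated = if (!is.na(g("b2m_elevated"))) as.numeric(g("b2m_elevated"))
      else if (!is.na(g("b2m_mg_l"))) as.numeric(g("b2m_mg_l") > 3.5)
      else NA,
    ighv_unmutated = if (is.na(g("ighv_unmutated"))) NA else
      as.numeric(g("ighv_unmutated")),
    tp53_aberrant = if (is.na(g("tp53_aberrant"))) NA else
      as.numeric(g("tp53_aberrant"))
  )
  miss <- is.na(comp)
  points <- sum(comp[!miss] * ipi_weights[!miss]) +
    sum(ipi_weights[miss] / 2)
  band <- ipi_bands$category[points >= ipi_bands$lo & points < ipi_bands$hi]
  list(points = points, category = band,
       n_missing_components = sum(miss))
}

#' Vectorized CLL-IPI scores for a metadata table
#'
#' @param meta Metadata `data.frame`, one row per sample.
#' @return `data.frame`: `sample_id`, `ipi_points`, `ipi_category`,
#'   `ipi_n_missing`.
#' @export
ipi_scores <- function(meta) {
  res <- lapply(seq_len(nrow(meta)), function(i) ipi_score(meta[i, ]))
  data.frame(sample_id = meta$sample_id,
             ipi_points = vapply(res, `[[`, numeric(1), "points"),
             ipi_category = vapply(res, `[[`, character(1), "category"),
             ipi_n_missing = vapply(res, `[[`, numeric(1),
                                    "n_missing_components"),
             stringsAsFactors = FALSE)
}

#' Cohort characteristics summary
#'
#' Counts and percentages (one decimal) by total cohort and by outcome
#' group for sex, Binet stage, IPI category, death, first-line
#' treatment failure, Richter transformation and first-line therapy
#' class, plus medians with range (age) and IQR (follow-up).
#'
#' @param meta Validated metadata `data.frame`.
#' @return `data.frame` in long form: `block`, `level`, `group`
#'   (`total`/`ttf1`/`ttf0`), `n`, `pct` (percent of the group, 1
#'   decimal; `NA` for the continuous rows, which instead fill
#'   `median`, `q_lo`, `q_hi`).
#' @export
summarize_cohort <- function(meta) {
  meta <- validate_metadata(meta)
  stopifnot(nrow(meta) >= 1)
  groups <- list(total = rep(TRUE, nrow(meta)),
                 ttf1 = meta$ttf == 1, ttf0 = meta$ttf == 0)
  ipi <- ipi_scores(meta)
  cat_block <- function(block, values, levels) {
    do.call(rbind, lapply(names(groups), function(gn) {
      v <- values[groups[[gn]]]
      denom <- sum(groups[[gn]])
      data.frame(block = block, level = levels,
                 group = gn,
                 n = vapply(levels, function(l)
                   sum(v == l, na.rm = TRUE), numeric(1)),
                 pct = if (denom > 0)
                   round(100 * vapply(levels, function(l)
                     sum(v == l, na.rm = TRUE), numeric(1)) / denom, 1)
                 else 0,
                 median = NA_real_, q_lo = NA_real_, q_hi = NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  num_block <- function(block, values, probs) {
    do.call(rbind, lapply(names(groups), function(gn) {
      v <- values[groups[[gn]]]
      q <- stats::quantile(v, probs, na.rm = TRUE, names = FALSE)
      data.frame(block = block, level = "median", group = gn,
                 n = sum(!is.na(v)), pct = NA_real_,
                 median = stats::median(v, na.rm = TRUE),
                 q_lo = q[1], q_hi = q[2], stringsAsFactors = FALSE)
    }))
  }
  binet_lv <- c("A", "B", "C", "unknown")
  binet_v <- ifelse(is.na(meta$binet), "unknown", meta$binet)
  therapy_v <- if (all(is.na(meta$therapy))) NULL else
    ifelse(is.na(meta$therapy), "Unknown", meta$therapy)
  out <- rbind(
    num_block("age_years", meta$age_years, c(0, 1)),
    cat_block("sex", meta$sex, c("F", "M")),
    cat_block("binet", binet_v, binet_lv),
    cat_block("ipi_category", ipi$ipi_category,
              c("low", "intermediate", "high", "very_high")),
    num_block("followup_months", meta$followup_months, c(0.25, 0.75)),
    cat_block("death", meta$died, c(1)),
    cat_block("first_line_failure", meta$first_line_failure, c(1)),
    cat_block("richter", meta$richter, c(1)),
    if (!is.null(therapy_v))
      cat_block("therapy", therapy_v, sort(unique(therapy_v)))
  )
  rownames(out) <- NULL
  out
}
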