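#' Default class-conditional frequency priors
#'
#' Class means (% of events) for the named populations, one row per
#' population, with the logit-scale dispersion of the per-sample
#' frequency draw.  The four effect populations are calibrated to the
#' group means observed for their real counterparts: the CD4+ T-cell
#' population (13.51% in superior-outcome TTF 0 vs 4.91% in inferior
#' TTF 1), an apoptotic CLL subset (1.39 vs 5.36), a prolymphocytoid CLL
#' subset (1.23 vs 9.64) and a CD8+ T-cell population (0.57 vs 2.25).
#' The residual after all draws goes to `other`.
#'
#' Dispersions (logit-scale SDs) of the effect populations are
#' calibrated so each population's per-sample frequency SD reproduces
#' its real counterpart's standard error of the group-mean difference
#' (SE_diff = s * sqrt(1/42 + 1/115), so s = SE_diff / 0.1805): 4.49%
#' for the apoptotic subset, 7.16% for the prolymphocytoid subset,
#' 2.72% for CD8 T cells.  This reproduces the observed effect-size
#' ranking (Cohen's d about 0.88, 1.18 and 0.62).  The CD4 population
#' uses sigma = 1.12, which both separates the classes at an analytic
#' AUC of about 0.78 (see [analytic_frequency_auc()]) and lands within
#' 7% of its SE-implied frequency SD of 10.1%.  The dominant CLL
#' fraction gets sigma = 0.8, spanning roughly 25-90% of events across
#' patients, the clinical range of leukemic burden.
#'
#' @return `data.frame` with columns `population`, `mean_ttf0`,
#'   `mean_ttf1` (percent) and `sigma` (logit-scale SD).
#' @export
default_frequency_priors <- function() {
  data.frame(
    population = c("CLL", "CLL_apoptotic", "CLL_prolymphocytoid",
                   "T_CD4", "T_CD8", "NK"),
    mean_ttf0 = c(60, 1.39, 1.23, 13.51, 0.57, 3.0),
    mean_ttf1 = c(60, 5.36, 9.64, 4.91, 2.25, 3.0),
    sigma = c(0.80, 1.35, 1.56, 1.12, 1.59, 0.6),
    stringsAsFactors = FALSE
  )
}

#' Configure a synthetic cohort
#'
#' @param n_ttf1,n_ttf0 Samples per outcome class; defaults mirror the
#'   157-patient study cohort (42 inferior / 115 superior).
#' @param events_per_sample Events acquired per sample and tube; the
#'   default matches routine acquisition of up to 1e5 cells.
#' @param frequency_priors See [default_frequency_priors()].
#' @param null If `TRUE`, both classes use the `mean_ttf0` frequencies
#'   (no planted effect), for null calibration of the pipeline.
#' @param tubes Which tubes to generate.
#' @param output `"standardized"` emits events directly on the `[0,6]`
#'   template scale; `"raw"` maps them back to instrument units
#'   (4-decade log for fluorescence, linear 0-1023 for scatter) so the
#'   full preprocessing chain can be exercised.
#' @param phenotype_jitter SD (scale units) of the per-sample,
#'   per-channel random shift applied to every population's template
#'   means: inter-patient variability of antigen brightness and scatter,
#'   which every real cohort shows (instrument drift, biological
#'   heterogeneity).  Set to 0 for identical phenotypes in all samples.
#' @param ipi_coupling Strength in `[0,1]` with which IPI components are
#'   coupled to the outcome class (see [generate_ipi_components()]).
#' @param seed Integer seed; all randomness derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_ttf1 = 42, n_ttf0 = 115,
                          events_per_sample = 100000,
                          frequency_priors = default_frequency_priors(),
                          null = FALSE,
                          tubes = c("T1", "T2"),
                          output = c("standardized", "raw"),
                          phenotype_jitter = 0.25,
                          ipi_coupling = 0.6,
                          seed = 1) {
  output <- match.arg(output)
  tubes <- match.arg(tubes, c("T1", "T2"), several.ok = TRUE)
  stopifnot(n_ttf1 >= 2, n_ttf0 >= 2, events_per_sample >= 10,
            ipi_coupling >= 0, ipi_coupling <= 1, phenotype_jitter >= 0)
  fp <- frequency_priors
  stopifnot(all(c("population", "mean_ttf0", "mean_ttf1", "sigma")
                %in% names(fp)), all(fp$sigma > 0))
  if (null) fp$mean_ttf1 <- fp$mean_ttf0
  for (col in c("mean_ttf0", "mean_ttf1"))
    if (sum(fp[[col]]) > 100)
      stop("frequency prior means exceed 100% for ", col, call. = FALSE)
  # pre-solve the logit-normal location so the *mean* frequency matches
  fp$mu_ttf0 <- mapply(logitnorm_mu, fp$mean_ttf0 / 100, fp$sigma)
  fp$mu_ttf1 <- mapply(logitnorm_mu, fp$mean_ttf1 / 100, fp$sigma)
  structure(list(n_ttf1 = n_ttf1, n_ttf0 = n_ttf0,
                 events_per_sample = events_per_sample,
                 frequency_priors = fp, null = null, tubes = tubes,
                 output = output, phenotype_jitter = phenotype_jitter,
                 ipi_coupling = ipi_coupling,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# location mu such that E[plogis(N(mu, sigma))] = target mean
logitnorm_mu <- function(mean_frac, sigma) {
  stopifnot(mean_frac > 0, mean_frac < 1)
  f <- function(mu)
    stats::integrate(function(z) stats::plogis(mu + sigma * z) *
                       stats::dnorm(z), -8, 8)$value - mean_frac
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

#' Analytic AUC of a planted frequency effect
#'
#' Per-sample frequencies are logit-normal with class-specific locations
#' and common dispersion; because the logit is monotone, the AUC of the
#' frequency as a classifier is the probability that a normal draw from
#' one class exceeds one from the other:
#' `Phi(|mu0 - mu1| / (sigma * sqrt(2)))`.
#'
#' @param config A [cohort_config()].
#' @param population Population name in the frequency priors.
#' @return AUC in `[0.5, 1)`.
#' @export
analytic_frequency_auc <- function(config, population) {
  fp <- config$frequency_priors
  i <- match(population, fp$population)
  if (is.na(i)) stop("unknown population: ", population, call. = FALSE)
  stats::pnorm(abs(fp$mu_ttf0[i] - fp$mu_ttf1[i]) / (fp$sigma[i] * sqrt(2)))
}

#' Generate one synthetic sample
#'
#' Draws the sample's true population fractions from the class-specific
#' logit-normal priors, assigns events to populations multinomially, and
#' draws each event's channel values from the population's truncated
#' Gaussian template (clamped to `[0,6]`).  Both tubes share the same
#' population fractions.  Kappa/lambda light-chain restriction of the CLL
#' clone is drawn per sample.
#'
#' @param config A [cohort_config()].
#' @param class Outcome class, 0 or 1.
#' @param seed Integer seed; identical seeds give identical samples.
#' @param sample_id Identifier stamped on the event matrices.
#' @return List with `events` (named list of [event_matrix()] per tube)
#'   and `fractions` (named true population fractions, summing to 1).
#' @export
generate_sample <- function(config, class, seed,
                            sample_id = sprintf("S%05d", seed %% 100000L)) {
  stopifnot(inherits(config, "cohort_config"), class %in% c(0, 1))
  set.seed(as.integer(seed))
  fp <- config$frequency_priors
  mu <- if (class == 1) fp$mu_ttf1 else fp$mu_ttf0
  frac <- stats::plogis(stats::rnorm(nrow(fp), mu, fp$sigma))
  # residual goes to "other"; in the rare draw where named populations
  # exceed the budget, rescale them and keep a sliver of other
  if (sum(frac) > 0.995) frac <- frac * (0.995 / sum(frac))
  fractions <- c(stats::setNames(frac, fp$population),
                 other = 1 - sum(frac))

  lambda_restricted <- stats::runif(1) < 0.5
  n <- config$events_per_sample
  counts <- as.vector(stats::rmultinom(1, n, fractions))
  names(counts) <- names(fractions)

  events <- list()
  for (tube in config$tubes) {
    tpls <- population_templates(tube)
    panel <- cll_panel(tube)
    markers <- panel$channels$marker
    blocks <- vector("list", length(fractions))
    for (k in seq_along(fractions)) {
      nk <- counts[k]
      tpl <- tpls[[names(fractions)[k]]]
      m <- tpl$mean
      if (lambda_restricted && tube == "T1" &&
          startsWith(names(fractions)[k], "CLL")) {
        kl <- m[c("kappa", "lambda")]
        m[c("kappa", "lambda")] <- kl[2:1]
      }
      if (config$phenotype_jitter > 0)
        m <- pmin(pmax(m + stats::rnorm(length(m), 0,
                                        config$phenotype_jitter), 0), 6)
      if (nk == 0) {
        blocks[[k]] <- matrix(0, 0, length(markers))
        next
      }
      x <- matrix(stats::rnorm(nk * length(markers),
                               mean = rep(m, each = nk),
                               sd = rep(tpl$sd, each = nk)),
                  nrow = nk)
      blocks[[k]] <- pmin(pmax(x, 0), 6)
    }
    v <- do.call(rbind, blocks)
    # shuffle acquisition order so population blocks are not contiguous
    v <- v[sample.int(nrow(v)), , drop = FALSE]
    if (config$output == "raw") {
      v <- destandardize(v, panel)
      stage <- "raw"
    } else stage <- "standardized"
    em <- event_matrix(v, panel, sample_id, stage = stage)
    attr(em, "population_counts") <- counts
    events[[tube]] <- em
  }
  list(events = events, fractions = fractions)
}

# map template-scale [0,6] values to plausible instrument units:
# fluorescence on a 4-decade log scale (1 .. 1e4), scatter linear 0..1023
destandardize <- function(v, panel) {
  fl <- fluor_idx(panel)
  sc <- scatter_idx(panel)
  v[, fl] <- 10^(v[, fl, drop = FALSE] * (4 / 6))
  v[, sc] <- v[, sc, drop = FALSE] / 6 * 1023
  v
}

#' Generate IPI components and demographics for one sample
#'
#' Draws the five CLL-IPI components (age > 65, Binet stage, elevated
#' beta2-microglobulin, unmutated IGHV, TP53 aberration) so that the
#' resulting IPI score is stochastically higher for class 1, with
#' strength controlled by `coupling`: at 0 the components are
#' independent of class, at 1 the adverse log-odds of each component are
#' shifted by a fixed increment for class 1.  Components may be masked
#' as missing at the given rates.
#'
#' @param class Outcome class, 0 or 1.
#' @param coupling Number in `[0,1]`.
#' @param seed Integer seed.
#' @param missing_rate Probability each of b2m/IGHV/TP53 is missing;
#'   Binet uses twice this rate (staging is the most often unknown).
#' @return One-row `data.frame` of metadata fields (without outcome
#'   columns).
#' @export
generate_ipi_components <- function(class, coupling, seed,
                                    missing_rate = 0.08) {
  stopifnot(class %in% c(0, 1), coupling >= 0, coupling <= 1)
  set.seed(as.integer(seed))
  shift <- 1.6 * coupling * class
  draw <- function(p0) stats::runif(1) < stats::plogis(stats::qlogis(p0) + shift)
  age_high <- draw(0.55)
  age_years <- if (age_high) stats::runif(1, 66, 91) else stats::runif(1, 26, 65)
  binet_bc <- draw(0.30)
  binet <- if (binet_bc) sample(c("B", "C"), 1) else "A"
  b2m <- as.integer(draw(0.35))
  ighv <- as.integer(draw(0.40))
  tp53 <- as.integer(draw(0.08))
  miss <- stats::runif(4) < c(2 * missing_rate, rep(missing_rate, 3))
  data.frame(
    age_years = round(age_years),
    binet = if (miss[1]) NA_character_ else binet,
    b2m_elevated = if (miss[2]) NA_integer_ else b2m,
    ighv_unmutated = if (miss[3]) NA_integer_ else ighv,
    tp53_aberrant = if (miss[4]) NA_integer_ else tp53,
    sex = sample(c("F", "M"), 1, prob = c(0.395, 0.605)),
    stringsAsFactors = FALSE
  )
}

#' Generate a full labelled synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: list with `samples` (per sample: `events`
#'   per tube and true `fractions`), `metadata` (validated table, see
#'   [metadata-format]), `truth` (samples x populations matrix of true
#'   fractions) and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_ttf1 + config$n_ttf0
  classes <- c(rep(1L, config$n_ttf1), rep(0L, config$n_ttf0))
  seeds <- sample.int(2^31 - 2, 3 * n)
  sample_seeds <- seeds[seq_len(n)]
  ipi_seeds <- seeds[n + seq_len(n)]
  clin_seeds <- seeds[2 * n + seq_len(n)]

  samples <- vector("list", n)
  meta_rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("S%03d", i)
    s <- generate_sample(config, classes[i], sample_seeds[i], sample_id = id)
    samples[[i]] <- s
    ipi <- generate_ipi_components(classes[i], config$ipi_coupling,
                                   ipi_seeds[i])
    meta_rows[[i]] <- cbind(
      data.frame(sample_id = id, ttf = classes[i],
                 stringsAsFactors = FALSE),
      ipi,
      clinical_course(classes[i], clin_seeds[i]),
      data.frame(cd38_positive_pct = cd38_fraction(classes[i], clin_seeds[i]))
    )
  }
  metadata <- validate_metadata(do.call(rbind, meta_rows))
  truth <- do.call(rbind, lapply(samples, `[[`, "fractions"))
  rownames(truth) <- metadata$sample_id
  structure(list(samples = samples, metadata = metadata, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

# death / first-line-failure / follow-up / therapy consistent with the
# outcome definition: ttf = 1 iff died or first-line failure
clinical_course <- function(class, seed) {
  set.seed(as.integer(seed))
  if (class == 1) {
    died <- stats::rbinom(1, 1, 16 / 42)
    failure <- if (died == 1) stats::rbinom(1, 1, 0.5) else 1L
    followup <- round(stats::runif(1, 38, 114))
    therapy <- sample(c("R-Bendamustin", "Ibrutinib", "Other", "Unknown"),
                      1, prob = c(17, 6, 15, 4))
  } else {
    died <- 0L
    failure <- 0L
    followup <- round(stats::runif(1, 7, 46))
    therapy <- sample(c("R-Bendamustin", "Ibrutinib", "Other",
                        "No therapy", "Unknown"), 1,
                      prob = c(8, 6, 9, 80, 12))
  }
  data.frame(died = died, first_line_failure = failure,
             followup_months = followup, therapy = therapy,
             richter = 0L, stringsAsFactors = FALSE)
}

# CD38+ CLL-cell fraction: logit-normal, class means 22.51% / 37.05%,
# dispersion set for the weak-classifier regime (AUC around 0.66)
cd38_fraction <- function(class, seed) {
  set.seed(as.integer(seed) + 7L)
  m <- if (class == 1) 0.3705 else 0.2251
  sigma <- 1.21
  round(100 * stats::plogis(stats::rnorm(1, logitnorm_mu(m, sigma), sigma)), 2)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(x$samples), "samples (",
      sum(x$metadata$ttf == 1), "TTF1 /", sum(x$metadata$ttf == 0),
      "TTF0 ),", x$config$events_per_sample, "events/sample, tubes",
      paste(x$config$tubes, collapse = "+"), "\n")
  invisible(x)
}
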