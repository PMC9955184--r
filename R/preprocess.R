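#' Configure the preprocessing chain
#'
#' The chain applied to each sample and tube, in fixed order:
#' compensation, log transform, high side-scatter exclusion, range
#' standardization to `[0,6]`, random subsampling.
#'
#' @param spillover Square spillover matrix over the tube's fluorescence
#'   channels (rows = true dyes, columns = detectors), or `NULL` for the
#'   identity (no bleed-through).  Compensation multiplies by its inverse.
#' @param log_floor Values below this are clamped before `log10`; 1
#'   instrument unit by default so the transform maps into `[0, decades]`.
#' @param scatter_scale Linear divisor applied to scatter channels in the
#'   transform step (scatter is scaled, not logged); default 1023/4 puts a
#'   full-range 10-bit scatter value on the same numeric footing as a
#'   4-decade log axis.
#' @param ssc_exclusion_quantile Events above this per-sample side-scatter
#'   quantile are excluded (mainly granulocytes); default 0.95.
#' @param robust_percentiles Lower/upper percentiles used as the range in
#'   standardization; default `c(0.001, 0.999)` resists outliers.  Use
#'   `c(0, 1)` for the plain min/max range form.
#' @param subsample_rate Fraction of events drawn for training; 1% by
#'   default.
#' @param seed Seed for the subsampling draw.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(spillover = NULL, log_floor = 1,
                              scatter_scale = 1023 / 4,
                              ssc_exclusion_quantile = 0.95,
                              robust_percentiles = c(0.001, 0.999),
                              subsample_rate = 0.01, seed = 1) {
  stopifnot(log_floor > 0, scatter_scale > 0,
            ssc_exclusion_quantile > 0, ssc_exclusion_quantile <= 1,
            length(robust_percentiles) == 2,
            robust_percentiles[1] < robust_percentiles[2],
            subsample_rate > 0, subsample_rate <= 1)
  if (!is.null(spillover)) {
    spillover <- as.matrix(spillover)
    stopifnot(nrow(spillover) == ncol(spillover))
    if (abs(det(spillover)) < .Machine$double.eps * 100)
      stop("spillover matrix is singular", call. = FALSE)
  }
  structure(list(spillover = spillover, log_floor = log_floor,
                 scatter_scale = scatter_scale,
                 ssc_exclusion_quantile = ssc_exclusion_quantile,
                 robust_percentiles = robust_percentiles,
                 subsample_rate = subsample_rate, seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Compensate fluorescence spillover
#'
#' Multiplies the fluorescence columns by the inverse of the spillover
#' matrix; scatter channels are untouched.  With the default identity
#' spillover the values pass through unchanged.
#'
#' @param em Raw [event_matrix()].
#' @param cfg A [preprocess_config()].
#' @return Compensated event matrix.
#' @export
compensate <- function(em, cfg = preprocess_config()) {
  require_stage(em, "raw")
  fl <- fluor_idx(em$panel)
  if (!is.null(cfg$spillover)) {
    if (nrow(cfg$spillover) != length(fl))
      stop("spillover matrix is ", nrow(cfg$spillover), "x",
           ncol(cfg$spillover), " but the tube has ", length(fl),
           " fluorescence channels", call. = FALSE)
    # observed = spillover %*% true (per event) => true = solve(spillover, observed)
    em$values[, fl] <- t(solve(cfg$spillover, t(em$values[, fl,
                                                          drop = FALSE])))
  }
  advance_stage(em, "compensated")
}

#' Log-transform fluorescence channels
#'
#' Fluorescence values are clamped at `log_floor` and log10-transformed;
#' scatter channels are divided by `scatter_scale` but kept linear, the
#' usual convention for size/granularity signals.
#'
#' @inheritParams compensate
#' @return Transformed event matrix.
#' @export
log_transform <- function(em, cfg = preprocess_config()) {
  require_stage(em, "compensated")
  fl <- fluor_idx(em$panel)
  sc <- scatter_idx(em$panel)
  em$values[, fl] <- log10(pmax(em$values[, fl, drop = FALSE], cfg$log_floor))
  em$values[, sc] <- em$values[, sc, drop = FALSE] / cfg$scatter_scale
  advance_stage(em, "transformed")
}

#' Exclude very-high side-scatter events
#'
#' Removes events whose side scatter exceeds the per-sample exclusion
#' quantile — mainly granulocytes, which add little information to a
#' B-cell panel.  Ties at the threshold are resolved by keeping
#' earlier-acquired events, so exactly `n - round(q * n)`-ish events go.
#'
#' @inheritParams compensate
#' @return The event matrix with high-SSC events removed; the number
#'   removed is in attribute `"removed"`.
#' @export
exclude_high_ssc <- function(em, cfg = preprocess_config()) {
  q <- cfg$ssc_exclusion_quantile
  ssc <- em$values[, ssc_idx(em$panel)]
  n <- length(ssc)
  keep_n <- max(1L, as.integer(round(q * n)))
  if (keep_n >= n) {
    attr(em, "removed") <- 0L
    return(em)
  }
  ord <- order(ssc, seq_len(n))   # stable: earlier events win ties
  keep <- sort(ord[seq_len(keep_n)])
  em$values <- em$values[keep, , drop = FALSE]
  if (nrow(em$values) == 0)
    stop("side-scatter exclusion removed every event", call. = FALSE)
  attr(em, "removed") <- n - keep_n
  em
}

#' Range-standardize each channel to [0, 6]
#'
#' The adapted range standardization: per channel, values are mapped by
#' `6 * (x - lo) / (hi - lo)` and clipped to `[0,6]`, where `lo`/`hi` are
#' the channel's robust percentiles within this sample.  A constant
#' channel cannot be ranged and is mapped to the midpoint 3 with a
#' warning.
#'
#' @inheritParams compensate
#' @return Standardized event matrix; all values in `[0,6]`.
#' @export
standardize <- function(em, cfg = preprocess_config()) {
  require_stage(em, "transformed")
  p <- cfg$robust_percentiles
  for (j in seq_len(ncol(em$values))) {
    x <- em$values[, j]
    lim <- stats::quantile(x, p, names = FALSE, type = 7)
    if (lim[2] - lim[1] <= .Machine$double.eps * max(1, abs(lim[2]))) {
      warning("channel '", colnames(em$values)[j],
              "' is constant in sample ", em$sample_id,
              "; standardized to midpoint 3", call. = FALSE)
      em$values[, j] <- 3
    } else {
      em$values[, j] <- pmin(pmax(6 * (x - lim[1]) / (lim[2] - lim[1]), 0), 6)
    }
  }
  advance_stage(em, "standardized")
}

#' Randomly subsample events
#'
#' Draws `max(1, round(rate * n))` events uniformly without replacement,
#' reproducibly under the config seed.
#'
#' @inheritParams compensate
#' @param seed Optional override of `cfg$seed`.
#' @return Subsampled event matrix.
#' @export
subsample <- function(em, cfg = preprocess_config(), seed = cfg$seed) {
  require_stage(em, "standardized")
  n <- n_events(em)
  k <- max(1L, as.integer(round(cfg$subsample_rate * n)))
  if (k < n) {
    set.seed(as.integer(seed))
    em$values <- em$values[sort(sample.int(n, k)), , drop = FALSE]
  }
  advance_stage(em, "subsampled")
}

#' Run the full preprocessing chain on one sample
#'
#' Order is fixed: compensate, log-transform, exclude high side scatter,
#' standardize, and (optionally) subsample.  Exclusion happens before
#' standardization so the robust range is computed on the retained
#' events.
#'
#' @inheritParams compensate
#' @param subsample_events If `FALSE`, stop after standardization (the
#'   full-event matrix used for frequency computation).
#' @param seed Seed for the subsampling draw.
#' @return Processed event matrix; per-stage event counts in attribute
#'   `"stage_log"`.
#' @export
preprocess_sample <- function(em, cfg = preprocess_config(),
                              subsample_events = TRUE, seed = cfg$seed) {
  log <- c(raw = n_events(em))
  em <- compensate(em, cfg)
  em <- log_transform(em, cfg)
  em <- exclude_high_ssc(em, cfg)
  log <- c(log, after_ssc_exclusion = n_events(em))
  em <- standardize(em, cfg)
  if (subsample_events) {
    em <- subsample(em, cfg, seed = seed)
    log <- c(log, after_subsample = n_events(em))
  }
  attr(em, "stage_log") <- log
  em
}
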