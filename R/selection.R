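#' Cohen's d effect size (pooled-SD form)
#'
#' `(mean(x) - mean(y)) / s_p` with the classic pooled standard
#' deviation `s_p = sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`.
#' Throughout the package `x` holds the inferior-outcome group (TTF 1)
#' and `y` the superior group, so positive d means overrepresented in
#' TTF 1.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @return Signed effect size.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) {
    if (mean(x) == mean(y)) return(0)
    stop("pooled standard deviation is zero; effect size undefined",
         call. = FALSE)
  }
  (mean(x) - mean(y)) / sp
}

#' Computed ABC analysis
#'
#' Partitions non-negative values into subset A ("the important few",
#' the largest values), B (break-even: yield comparable to effort) and
#' C (the trivial many).  Values are sorted in descending order and the
#' ABC curve is formed from (fraction of items, cumulative fraction of
#' total value).  The A/B boundary is the curve point closest (Euclidean
#' distance) to the ideal point (0, 1); the B/C boundary is the first
#' item past A whose marginal yield is no larger than the mean yield of
#' the items still remaining at that point.
#'
#' @param values Non-negative numeric vector, length >= 3, not all zero.
#' @return An `abc_partition`: `order` (indices into `values`,
#'   descending), `sorted_values`, index sets `A`, `B`, `C` (into the
#'   original vector) and `boundaries` (positions, in sorted order, of
#'   the last element of A and of B).
#' @export
abc_analysis <- function(values) {
  stopifnot(length(values) >= 3, all(values >= 0))
  if (all(values == 0)) stop("all values are zero", call. = FALSE)
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]
  n <- length(v)
  if (max(v) == min(v)) {
    warning("all values equal: no 'important few' exist; everything in B",
            call. = FALSE)
    return(structure(list(order = ord, sorted_values = v,
                          A = integer(0), B = ord, C = integer(0),
                          boundaries = c(a_b = 0L, b_c = n)),
                     class = "abc_partition"))
  }
  cum <- cumsum(v) / sum(v)
  xs <- seq_len(n) / n
  dist <- sqrt(xs^2 + (1 - cum)^2)
  i_ab <- which.min(dist)
  i_bc <- n
  if (i_ab < n) {
    for (i in (i_ab + 1):n) {
      if (v[i] <= mean(v[i:n]) + 1e-12) { i_bc <- i; break }
    }
  } else i_bc <- i_ab
  structure(list(order = ord, sorted_values = v,
                 A = ord[seq_len(i_ab)],
                 B = if (i_bc > i_ab) ord[(i_ab + 1):i_bc] else integer(0),
                 C = if (i_bc < n) ord[(i_bc + 1):n] else integer(0),
                 boundaries = c(a_b = i_ab, b_c = i_bc)),
            class = "abc_partition")
}

#' @export
print.abc_partition <- function(x, ...) {
  cat(sprintf("<abc_partition> |A|=%d |B|=%d |C|=%d of %d items\n",
              length(x$A), length(x$B), length(x$C),
              length(x$sorted_values)))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided test of identical distributions via `stats::wilcox.test`:
#' exact for small untied samples, normal approximation with tie
#' correction otherwise.  `U` is the number of (x, y) pairs with
#' `x > y` (+ half the ties), so `U(x, y) + U(y, x) = n1 * n2`.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Use the exact distribution when `n1 + n2` is at most
#'   this and there are no ties.
#' @return List with `U` and two-sided `p`.
#' @export
mwu_test <- function(x, y, exact_max = 20) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Rank populations by effect size and test group difference
#'
#' Builds the per-population evaluation block: class means, Cohen's d
#' (TTF 1 vs TTF 0, so positive = overrepresented in the inferior
#' group), standard error of the mean difference, and the two-sided
#' Mann-Whitney U p-value.
#'
#' @param freq A [frequency_table()] with a `ttf` column.
#' @return `data.frame` (one row per population): `pop_id`, `mean_ttf1`,
#'   `mean_ttf0`, `cohens_d`, `abs_d`, `se_difference`, `mwu_p`.
#' @export
effect_ranking <- function(freq) {
  stopifnot("ttf" %in% names(freq))
  pops <- setdiff(names(freq), c("sample_id", "ttf"))
  is1 <- freq$ttf == 1
  rows <- lapply(pops, function(p) {
    x <- freq[[p]][is1]; y <- freq[[p]][!is1]
    d <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
    data.frame(pop_id = p, mean_ttf1 = mean(x), mean_ttf0 = mean(y),
               cohens_d = d, abs_d = abs(d),
               se_difference = sqrt(stats::var(x) / length(x) +
                                      stats::var(y) / length(y)),
               mwu_p = mwu_test(x, y)$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the important populations by ABC analysis of |d|
#'
#' Applies [abc_analysis()] to the absolute Cohen's d values of the
#' ranking and keeps set A (optionally A and B).  Populations whose
#' `abs_d` falls below `min_effect` are dropped before the partition, so
#' a ranking with no real effects selects nothing.
#'
#' @param ranking Output of [effect_ranking()].
#' @param mode `"A"` (default) or `"AB"`.
#' @param min_effect Minimum `abs_d` to enter the partition.
#' @return Character vector of selected `pop_id`s (possibly empty).
#' @export
select_populations <- function(ranking, mode = c("A", "AB"),
                               min_effect = 0.5) {
  mode <- match.arg(mode)
  stopifnot(nrow(ranking) >= 1)
  ok <- !is.na(ranking$abs_d) & ranking$abs_d >= min_effect
  cand <- ranking[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  if (nrow(cand) <= 2 || max(cand$abs_d) == min(cand$abs_d)) {
    if (max(cand$abs_d) == min(cand$abs_d) && nrow(cand) > 1) {
      warning("all candidate effect sizes equal; selecting none",
              call. = FALSE)
      return(character(0))
    }
    return(cand$pop_id[order(cand$abs_d, decreasing = TRUE)])
  }
  part <- abc_analysis(cand$abs_d)
  idx <- if (mode == "A") part$A else c(part$A, part$B)
  cand$pop_id[idx]
}
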