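#' Configure gate-tree discovery
#'
#' The discovery surrogate is density-first, class-second: at each tree
#' node, candidate gate edges are the valleys of the per-channel event
#' density (cell populations are density modes on dot plots, so gate
#' boundaries belong in the low-density gaps between modes, never
#' through a mode), and the class-separation criterion then chooses
#' among the mode-aligned candidate rectangles.
#'
#' @param bin_width Histogram bin width (scale units) for valley
#'   detection.
#' @param smooth_bins Half-width (bins) of the running-mean smoother
#'   applied to the histogram before valley detection.
#' @param valley_ratio Required prominence: the smoothed density peaks
#'   on both sides of a valley must exceed `valley_ratio` times the
#'   valley density (plus one count) for the valley to count.
#' @param max_valleys Maximum valleys kept per channel (deepest first,
#'   at least 0.4 units apart).
#' @param max_depth Maximum number of gate levels.
#' @param min_leaf_events Minimum pooled training events on each side of
#'   a split.
#' @param min_split_d Minimum absolute Cohen's d of the candidate inside
#'   frequency (across samples, between classes) for a split to be made.
#' @param split_overdispersion A candidate rectangle is only a valid
#'   split if the between-sample variance of its share of the node's
#'   events exceeds this multiple of the binomial (counting) variance.
#'   In a homogeneous population every sub-rectangle holds a constant
#'   share of the node in every sample, so cutting it would only
#'   fragment one biological population; a genuine sub-population shows
#'   overdispersed shares.
#' @param min_effect Minimum absolute Cohen's d for a leaf to be treated
#'   as a reportable population downstream (leaves below it still exist,
#'   so the partition stays exhaustive).
#' @param seed Seed for any randomized tie handling (none by default;
#'   kept for config completeness).
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(bin_width = 0.1, smooth_bins = 2,
                             valley_ratio = 1.4, max_valleys = 3,
                             max_depth = 8, min_leaf_events = 50,
                             min_split_d = 0.3, split_overdispersion = 3,
                             min_effect = 0.5, seed = 1) {
  stopifnot(bin_width > 0, smooth_bins >= 0, valley_ratio >= 1,
            max_valleys >= 1, max_depth >= 1, min_leaf_events >= 1,
            min_split_d >= 0, split_overdispersion >= 0, min_effect >= 0)
  structure(list(bin_width = bin_width, smooth_bins = as.integer(smooth_bins),
                 valley_ratio = valley_ratio,
                 max_valleys = as.integer(max_valleys),
                 max_depth = as.integer(max_depth),
                 min_leaf_events = as.integer(min_leaf_events),
                 min_split_d = min_split_d,
                 split_overdispersion = split_overdispersion,
                 min_effect = min_effect,
                 seed = as.integer(seed)),
            class = "discovery_config")
}

# positions of prominent local density minima of x on [lo, hi].
# Standardization clamps values to the scale limits, piling density into
# the outermost bins; those piles are truncation artifacts, not modes,
# so the first/last few bins provide no peak evidence and valleys must
# sit away from the limits.
density_valleys <- function(x, cfg, lo = 0, hi = 6) {
  breaks <- seq(lo, hi, by = cfg$bin_width)
  n <- length(breaks) - 1
  x <- x[x > lo + cfg$bin_width & x < hi - cfg$bin_width]
  if (!length(x)) return(numeric(0))
  dens <- tabulate(pmin(pmax(findInterval(x, breaks), 1L), n), n)
  k <- cfg$smooth_bins
  sm <- if (k > 0) {
    cs <- cumsum(c(0, dens))
    i <- seq_len(n)
    (cs[pmin(i + k, n) + 1] - cs[pmax(i - k, 1)]) /
      (pmin(i + k, n) - pmax(i - k, 1) + 1)
  } else dens
  centers <- breaks[-length(breaks)] + cfg$bin_width / 2
  eb <- max(2L, ceiling(0.2 / cfg$bin_width))   # boundary-pile bins
  interior <- which(centers >= lo + 0.4 & centers <= hi - 0.4)
  interior <- interior[interior > 1 & interior < n]
  is_min <- interior[sm[interior] <= sm[interior - 1] &
                       sm[interior] <= sm[interior + 1]]
  if (!length(is_min)) return(numeric(0))
  keep <- vapply(is_min, function(i) {
    lmax <- if (i > eb) max(sm[(eb + 1):i]) else 0
    rmax <- if (i <= n - eb) max(sm[i:(n - eb)]) else 0
    min(lmax, rmax) >= cfg$valley_ratio * sm[i] + 1
  }, logical(1))
  cand <- is_min[keep]
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(sm[cand])]
  out <- numeric(0)
  for (i in cand) {
    if (all(abs(centers[i] - out) >= 0.4)) out <- c(out, centers[i])
    if (length(out) >= cfg$max_valleys) break
  }
  sort(out)
}

# per-sample counts on a gx x gy interval grid -> padded cumulative
# matrix, samples x (gx+1)(gy+1)
cumgrid <- function(ix, iy, s, n_samples, gx, gy) {
  key <- (s - 1L) * (gx * gy) + (iy - 1L) * gx + ix
  cnt <- tabulate(key, nbins = n_samples * gx * gy)
  a <- array(cnt, dim = c(gx, gy, n_samples))
  if (gx > 1) for (x in 2:gx) a[x, , ] <- a[x, , ] + a[x - 1, , ]
  if (gy > 1) for (y in 2:gy) a[, y, ] <- a[, y, ] + a[, y - 1, ]
  p <- array(0, dim = c(gx + 1, gy + 1, n_samples))
  p[2:(gx + 1), 2:(gy + 1), ] <- a
  t(matrix(p, nrow = (gx + 1) * (gy + 1)))
}

# Cohen's d for every column of the samples x rectangles frequency matrix
col_cohens_d <- function(freq, is1) {
  n1 <- sum(is1); n0 <- sum(!is1)
  m1 <- colMeans(freq[is1, , drop = FALSE])
  m0 <- colMeans(freq[!is1, , drop = FALSE])
  q1 <- colSums(freq[is1, , drop = FALSE]^2)
  q0 <- colSums(freq[!is1, , drop = FALSE]^2)
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v0 <- (q0 - n0 * m0^2) / (n0 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  d <- (m1 - m0) / sp
  d[!is.finite(d)] <- 0
  d
}

#' Discover a gate tree of outcome-associated populations
#'
#' A greedy binary gate tree over pooled, standardized training events.
#' At each node, the per-channel event density is scanned for prominent
#' valleys; the candidate splits are all rectangles, on all channel
#' pairs, whose edges are valley positions (or the scale limits).
#' Candidates are scored by the absolute Cohen's d, across samples and
#' between outcome classes, of the per-sample frequency of events
#' inside the rectangle (frequencies relative to each sample's total
#' retained events).  The best-scoring rectangle becomes the node's
#' gate (ties: larger pooled inside count, then first in
#' channel-pair/rectangle order); events inside and outside form the
#' two children.  Recursion stops at `max_depth`, when a side would
#' hold fewer than `min_leaf_events` pooled events, when no channel is
#' multimodal, or when no candidate reaches `min_split_d`.  Each leaf
#' becomes a population whose direction is the sign of the class
#' mean-frequency difference.
#'
#' Restricting gate edges to density valleys is what keeps the
#' discovered populations biologically coherent: a boundary through a
#' density mode would cut a cell population in half and make its
#' frequency hypersensitive to per-sample standardization jitter.
#'
#' @param events Named list of training event sets, one per sample:
#'   [event_matrix()] objects or plain matrices in panel channel order,
#'   standardized to `[0,6]`.
#' @param classes Outcome class (0/1) per sample, same order as `events`.
#' @param panel The tube's [panel_definition()].
#' @param cfg A [discovery_config()].
#' @return A `gate_tree` with fields `tube`, `panel`, `root`, `leaves`
#'   (list of [population_definition()]) and `training_config`.
#' @export
build_gate_tree <- function(events, classes, panel,
                            cfg = discovery_config()) {
  stopifnot(length(events) == length(classes),
            all(classes %in% c(0, 1)))
  mats <- lapply(events, function(e)
    if (inherits(e, "event_matrix")) e$values else as.matrix(e))
  n_ev <- vapply(mats, nrow, integer(1))
  if (sum(n_ev) == 0) stop("no training events", call. = FALSE)
  X <- do.call(rbind, mats)
  s <- rep(seq_along(mats), n_ev)
  ns <- length(mats)
  is1 <- classes == 1
  root_tot <- as.numeric(n_ev)

  single_class <- length(unique(classes)) < 2 ||
    sum(is1) < 2 || sum(!is1) < 2
  if (single_class)
    warning("fewer than two samples per class; returning a single-leaf tree",
            call. = FALSE)

  markers <- panel$channels$marker
  nch <- n_channels(panel)

  best_split <- function(idx) {
    si <- s[idx]
    node_cnt <- tabulate(si, nbins = ns)
    active <- node_cnt > 0
    edges <- lapply(seq_len(nch), function(ch)
      c(0, density_valleys(X[idx, ch], cfg), 6))
    n_int <- vapply(edges, length, integer(1)) - 1L
    ivl <- lapply(seq_len(nch), function(ch) {
      if (n_int[ch] == 1) rep(1L, length(idx))
      else findInterval(X[idx, ch], edges[[ch]], all.inside = TRUE)
    })
    multi <- which(n_int > 1)
    if (!length(multi)) return(NULL)
    best <- NULL
    for (ci in seq_len(nch - 1)) for (cj in (ci + 1):nch) {
      gx <- n_int[ci]; gy <- n_int[cj]
      if (gx == 1 && gy == 1) next
      P <- cumgrid(ivl[[ci]], ivl[[cj]], si, ns, gx, gy)
      # all interval-aligned rectangles via the padded integral image
      sp_x <- which(upper.tri(matrix(0, gx, gx), diag = TRUE),
                    arr.ind = TRUE)
      sp_y <- which(upper.tri(matrix(0, gy, gy), diag = TRUE),
                    arr.ind = TRUE)
      nx <- nrow(sp_x); ny <- nrow(sp_y)
      xi <- rep(seq_len(nx), times = ny)
      yi <- rep(seq_len(ny), each = nx)
      x1 <- sp_x[xi, 1]; x2 <- sp_x[xi, 2]
      y1 <- sp_y[yi, 1]; y2 <- sp_y[yi, 2]
      lin <- function(a, b) (b - 1) * (gx + 1) + a
      inside <- P[, lin(x2 + 1, y2 + 1), drop = FALSE] -
        P[, lin(x1, y2 + 1), drop = FALSE] -
        P[, lin(x2 + 1, y1), drop = FALSE] +
        P[, lin(x1, y1), drop = FALSE]
      tot_in <- colSums(inside)
      d <- col_cohens_d(inside / root_tot, is1)
      ok <- tot_in >= cfg$min_leaf_events &
        (length(idx) - tot_in) >= cfg$min_leaf_events
      if (cfg$split_overdispersion > 0) {
        # share of the node per sample must vary beyond counting noise,
        # else the rectangle merely slices one homogeneous population
        q <- inside[active, , drop = FALSE] / node_cnt[active]
        na <- sum(active)
        mq <- colMeans(q)
        vq <- (colSums(q^2) - na * mq^2) / max(na - 1, 1)
        bv <- colMeans(q * (1 - q) / node_cnt[active])
        ok <- ok & vq >= cfg$split_overdispersion * bv
      }
      score <- abs(d)
      score[!ok] <- -Inf
      if (all(score == -Inf)) next
      k <- which(score == max(score))
      k <- k[which.max(tot_in[k])]
      if (is.null(best) || score[k] > best$score ||
          (score[k] == best$score && tot_in[k] > best$tot_in)) {
        best <- list(score = score[k], d = d[k], tot_in = tot_in[k],
                     gate = gate2d(markers[ci], markers[cj],
                                   edges[[ci]][x1[k]],
                                   edges[[ci]][x2[k] + 1],
                                   edges[[cj]][y1[k]],
                                   edges[[cj]][y2[k] + 1]))
      }
    }
    best
  }

  leaf_paths <- list()
  grow <- function(idx, depth, path) {
    make_leaf <- function() {
      leaf_paths[[length(leaf_paths) + 1]] <<- list(path = path, idx = idx)
      list(type = "leaf", pop_id = length(leaf_paths))  # renamed later
    }
    if (single_class || depth >= cfg$max_depth ||
        length(idx) < 2 * cfg$min_leaf_events)
      return(make_leaf())
    bs <- best_split(idx)
    if (is.null(bs) || abs(bs$d) < cfg$min_split_d) return(make_leaf())
    m <- in_gate(bs$gate, X[idx, , drop = FALSE], panel)
    if (sum(m) < cfg$min_leaf_events ||
        sum(!m) < cfg$min_leaf_events) return(make_leaf())
    node <- list(type = "split", gate = bs$gate, d = bs$d)
    node$inside <- grow(idx[m], depth + 1,
                        c(path, list(list(gate = bs$gate, side = "inside"))))
    node$outside <- grow(idx[!m], depth + 1,
                         c(path, list(list(gate = bs$gate, side = "outside"))))
    node
  }
  root <- grow(seq_len(nrow(X)), 0, list())

  # name leaves in discovery order and attach direction + training d
  tube_num <- sub("^T", "", panel$tube_id)
  leaves <- vector("list", length(leaf_paths))
  relabel <- function(node) {
    if (node$type == "leaf") {
      k <- node$pop_id
      pid <- sprintf("T%sC%04d", tube_num, k)
      idx <- leaf_paths[[k]]$idx
      freq <- tabulate(s[idx], nbins = ns) / root_tot
      if (single_class) {
        dl <- NA_real_
        dir <- "overrepresented_in_ttf1"
      } else {
        dl <- tryCatch(cohens_d(freq[is1], freq[!is1]), error = function(e) 0)
        dir <- if (mean(freq[is1]) >= mean(freq[!is1]))
          "overrepresented_in_ttf1" else "underrepresented_in_ttf1"
      }
      path <- leaf_paths[[k]]$path
      if (!length(path)) {
        # degenerate single-leaf tree: the whole [0,6]^2 plane
        path <- list(list(gate = gate2d(markers[1], markers[2], 0, 6, 0, 6),
                          side = "inside"))
      }
      leaves[[k]] <<- population_definition(pid, panel$tube_id, path, dir,
                                            cohens_d = dl)
      node$pop_id <- pid
      return(node)
    }
    node$inside <- relabel(node$inside)
    node$outside <- relabel(node$outside)
    node
  }
  root <- relabel(root)

  structure(list(tube = panel$tube_id, panel = panel, root = root,
                 leaves = leaves, training_config = cfg),
            class = "gate_tree")
}

#' @export
print.gate_tree <- function(x, ...) {
  cat("<gate_tree> tube", x$tube, "-", length(x$leaves), "leaf populations\n")
  for (p in x$leaves)
    cat(sprintf("  %s  d=%+.2f  %s  (%d gates)\n", p$pop_id,
                p$cohens_d, p$direction, length(p$gates)))
  invisible(x)
}

#' Stability of discovered populations under repeated subsampling
#'
#' Repeats the subsample-and-train procedure `B` times with distinct
#' seeds and reports, per leaf of the reference tree, the fraction of
#' repeats in which a matched population recurs.  Two populations match
#' when their gated event sets on a common reference event pool overlap
#' with Jaccard index at least `jaccard` and they share the direction of
#' the class difference.
#'
#' @param events Named list of full standardized event sets per sample
#'   (matrices or [event_matrix()]).
#' @param classes Outcome class (0/1) per sample.
#' @param panel The tube's [panel_definition()].
#' @param reference Reference `gate_tree` whose populations are scored.
#' @param cfg A [discovery_config()].
#' @param B Number of repeats.
#' @param rate Subsample rate per repeat (the 1% training draw).
#' @param jaccard Overlap threshold for a match.
#' @param recurrence Fraction of repeats a population must recur in to
#'   be retained.
#' @param max_reference_events Size cap of the pooled reference event
#'   set used for overlap computation.
#' @param seed Integer seed.
#' @return `data.frame` with `pop_id`, `stability` (fraction of repeats
#'   matched) and `retained`.
#' @export
cross_validate <- function(events, classes, panel, reference,
                           cfg = discovery_config(), B = 10, rate = 0.01,
                           jaccard = 0.5, recurrence = 0.5,
                           max_reference_events = 20000, seed = 1) {
  stopifnot(B >= 2)
  mats <- lapply(events, function(e)
    if (inherits(e, "event_matrix")) e$values else as.matrix(e))
  set.seed(as.integer(seed))
  pool <- do.call(rbind, mats)
  if (nrow(pool) > max_reference_events)
    pool <- pool[sample.int(nrow(pool), max_reference_events), , drop = FALSE]
  ref_lab <- assign_events(reference, pool)
  ref_pops <- vapply(reference$leaves, `[[`, character(1), "pop_id")
  ref_dir <- vapply(reference$leaves, `[[`, character(1), "direction")
  hits <- stats::setNames(numeric(length(ref_pops)), ref_pops)

  rep_seeds <- sample.int(2^31 - 2, B)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    sub <- lapply(mats, function(m) {
      k <- max(1L, as.integer(round(rate * nrow(m))))
      m[sample.int(nrow(m), k), , drop = FALSE]
    })
    tr <- suppressWarnings(build_gate_tree(sub, classes, panel, cfg))
    lab <- assign_events(tr, pool)
    dir_b <- stats::setNames(
      vapply(tr$leaves, `[[`, character(1), "direction"),
      vapply(tr$leaves, `[[`, character(1), "pop_id"))
    for (i in seq_along(ref_pops)) {
      a <- ref_lab == ref_pops[i]
      matched <- FALSE
      for (pb in names(dir_b)) {
        if (dir_b[[pb]] != ref_dir[i]) next
        bset <- lab == pb
        j <- sum(a & bset) / sum(a | bset)
        if (is.finite(j) && j >= jaccard) { matched <- TRUE; break }
      }
      if (matched) hits[i] <- hits[i] + 1
    }
  }
  data.frame(pop_id = ref_pops, stability = unname(hits) / B,
             retained = unname(hits) / B >= recurrence,
             stringsAsFactors = FALSE)
}
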