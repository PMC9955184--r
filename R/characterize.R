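#' Reference CLL gate rule per tube
#'
#' The cohort-average CLL reference used for profiling is taken from a
#' rule-defined gate: CD19-positive, CD5-positive events in tube 1
#' (thresholds at the scale midpoint 3), and CD19-positive,
#' CD43-positive in tube 2, which lacks CD5.
#'
#' @param tube `"T1"` or `"T2"`.
#' @return Named numeric vector of channel thresholds (AND of
#'   `channel >= threshold`).
#' @export
default_cll_gate <- function(tube = c("T1", "T2")) {
  tube <- match.arg(tube)
  if (tube == "T1") c(CD19 = 3, CD5 = 3) else c(CD19 = 3, CD43 = 3)
}

#' Marker profiles of several populations in one pass
#'
#' Computes [population_profile()]-equivalent profiles for many
#' populations while assigning each sample's events to tree leaves only
#' once.
#'
#' @param tree A `gate_tree`.
#' @param events Named list of standardized event sets per sample.
#' @param pop_ids Populations to profile.
#' @param reference_rule Named thresholds of the reference CLL gate.
#' @param min_events Minimum cohort-wide event count per population;
#'   smaller populations yield `NULL`.
#' @return Named list of `population_profile` objects (or `NULL`).
#' @export
population_profiles <- function(tree, events, pop_ids,
                                reference_rule = default_cll_gate(tree$tube),
                                min_events = 50) {
  panel <- tree$panel
  markers <- panel$channels$marker
  pools <- stats::setNames(vector("list", length(pop_ids)), pop_ids)
  ref_medians <- list()
  ref_cols <- match_channels(panel, names(reference_rule))
  for (i in seq_along(events)) {
    v <- if (inherits(events[[i]], "event_matrix")) events[[i]]$values
         else as.matrix(events[[i]])
    lab <- assign_events(tree, v)
    for (p in pop_ids) {
      sel <- lab == p
      if (any(sel))
        pools[[p]][[length(pools[[p]]) + 1]] <- v[sel, , drop = FALSE]
    }
    keep <- rep(TRUE, nrow(v))
    for (k in seq_along(ref_cols))
      keep <- keep & v[, ref_cols[k]] >= reference_rule[[k]]
    if (sum(keep) >= 10)
      ref_medians[[length(ref_medians) + 1]] <-
        apply(v[keep, , drop = FALSE], 2, stats::median)
  }
  if (!length(ref_medians))
    stop("reference CLL gate is empty in every sample", call. = FALSE)
  ref <- colMeans(do.call(rbind, ref_medians))
  names(ref) <- markers
  fs <- markers[fsc_idx(panel)]
  lapply(pools, function(pl) {
    pool <- do.call(rbind, pl)
    if (is.null(pool) || nrow(pool) < min_events) return(NULL)
    med <- apply(pool, 2, stats::median)
    names(med) <- markers
    delta <- med - ref
    structure(list(pop_id = NULL, median = med, reference = ref,
                   delta = delta, n_events = nrow(pool),
                   low_fsc = delta[[fs]] < -0.5,
                   high_fsc = delta[[fs]] > 0.5),
              class = "population_profile")
  }) -> out
  for (p in pop_ids) if (!is.null(out[[p]])) out[[p]]$pop_id <- p
  out
}

#' Marker profile of a population relative to the average CLL patient
#'
#' The population's per-channel medians are pooled over the events all
#' samples contribute to it.  The reference profile is the median
#' profile of the rule-defined CLL gate computed per patient and then
#' averaged with equal patient weight, so samples with high leukocyte
#' counts do not dominate.  Deltas (population median minus reference)
#' below/above +-0.5 on the forward-scatter channel raise the
#' apoptotic-like / prolymphocytoid-like flags.
#'
#' @param tree A `gate_tree`.
#' @param events Named list of standardized event sets per sample.
#' @param pop_id Leaf population to profile.
#' @param reference_rule Named thresholds defining the reference CLL
#'   gate (see [default_cll_gate()]).
#' @param min_events Minimum cohort-wide event count for the population.
#' @return A `population_profile`: `pop_id`, `median` (per channel),
#'   `reference` (per channel), `delta`, `n_events`, flags `low_fsc`,
#'   `high_fsc`.
#' @export
population_profile <- function(tree, events, pop_id,
                               reference_rule = default_cll_gate(tree$tube),
                               min_events = 50) {
  panel <- tree$panel
  markers <- panel$channels$marker
  pop_pool <- list()
  ref_medians <- list()
  for (i in seq_along(events)) {
    v <- if (inherits(events[[i]], "event_matrix")) events[[i]]$values
         else as.matrix(events[[i]])
    lab <- assign_events(tree, v)
    pop_pool[[i]] <- v[lab == pop_id, , drop = FALSE]
    keep <- rep(TRUE, nrow(v))
    for (ch in names(reference_rule))
      keep <- keep & v[, match_channels(panel, ch)] >= reference_rule[[ch]]
    if (sum(keep) >= 10)
      ref_medians[[length(ref_medians) + 1]] <-
        apply(v[keep, , drop = FALSE], 2, stats::median)
  }
  pool <- do.call(rbind, pop_pool)
  if (is.null(pool) || nrow(pool) < min_events)
    stop("population ", pop_id, " holds fewer than ", min_events,
         " events cohort-wide", call. = FALSE)
  if (!length(ref_medians))
    stop("reference CLL gate is empty in every sample", call. = FALSE)
  med <- apply(pool, 2, stats::median)
  ref <- colMeans(do.call(rbind, ref_medians))
  names(med) <- names(ref) <- markers
  delta <- med - ref
  fs <- markers[fsc_idx(panel)]
  structure(list(pop_id = pop_id, median = med, reference = ref,
                 delta = delta, n_events = nrow(pool),
                 low_fsc = delta[[fs]] < -0.5,
                 high_fsc = delta[[fs]] > 0.5),
            class = "population_profile")
}

#' @export
print.population_profile <- function(x, ...) {
  cat("<population_profile>", x$pop_id, "-", x$n_events, "events",
      if (x$low_fsc) "[low FSC: apoptotic-like]",
      if (x$high_fsc) "[high FSC: prolymphocytoid-like]", "\n")
  print(round(rbind(median = x$median, delta = x$delta), 2))
  invisible(x)
}

#' Default lineage annotation rules
#'
#' A deterministic cascade on standardized medians, thresholds at the
#' midpoint of the `[0,6]` scale: CD3+CD4+CD19- calls a CD4 T cell,
#' CD3+CD8+CD19- a CD8 T cell, CD19+CD5+ a CLL subset, CD3-CD19- with
#' CD2 or CD7 positivity an NK/T mixture; anything else is `mixed`
#' (positive for something without a matching rule) or `other` (nothing
#' positive).
#'
#' @return `data.frame` of rules: `label` and per-channel thresholds.
#' @export
default_lineage_rules <- function() {
  data.frame(
    label = c("T_CD4", "T_CD8", "CLL_subset", "NK_or_T_mix"),
    rule = I(list(
      list(c("CD3", ">=", 3), c("CD4", ">=", 3), c("CD19", "<", 2)),
      list(c("CD3", ">=", 3), c("CD8", ">=", 3), c("CD19", "<", 2)),
      list(c("CD19", ">=", 3), c("CD5", ">=", 3)),
      list(c("CD3", "<", 2), c("CD19", "<", 2), c("CD7", ">=", 3)))),
    stringsAsFactors = FALSE
  )
}

#' Annotate the biological lineage of a population profile
#'
#' Applies the rule cascade to the profile's standardized medians; the
#' first rule whose clauses all hold gives the label.  If no rule fires
#' the call is `mixed` when any lineage channel is positive (>= 3) and
#' `other` otherwise.  The returned `rule_trace` lists every clause
#' evaluated for the winning rule (or, for `mixed`, the positive
#' channels that prevented a clean call).
#'
#' @param profile A [population_profile()].
#' @param rules Rule table, see [default_lineage_rules()].
#' @return A `lineage_call`: `pop_id`, `label`, `rule_trace`
#'   (`data.frame`: channel, relation, threshold, value).
#' @export
annotate_lineage <- function(profile, rules = default_lineage_rules()) {
  med <- profile$median
  lineage_channels <- unique(unlist(lapply(rules$rule, function(r)
    vapply(r, `[`, character(1), 1))))
  missing <- setdiff(lineage_channels, names(med))
  if (length(missing))
    stop("profile lacks lineage channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  eval_clause <- function(cl) {
    v <- med[[cl[1]]]
    ok <- switch(cl[2], ">=" = v >= as.numeric(cl[3]),
                 "<" = v < as.numeric(cl[3]),
                 stop("bad relation ", cl[2]))
    data.frame(channel = cl[1], relation = cl[2],
               threshold = as.numeric(cl[3]), value = v, holds = ok,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(rules))) {
    trace <- do.call(rbind, lapply(rules$rule[[i]], eval_clause))
    if (all(trace$holds))
      return(structure(list(pop_id = profile$pop_id,
                            label = rules$label[i], rule_trace = trace),
                       class = "lineage_call"))
  }
  pos <- med[lineage_channels][med[lineage_channels] >= 3]
  if (length(pos)) {
    trace <- do.call(rbind, lapply(names(pos), function(ch)
      eval_clause(c(ch, ">=", "3"))))
    structure(list(pop_id = profile$pop_id, label = "mixed",
                   rule_trace = trace), class = "lineage_call")
  } else {
    structure(list(pop_id = profile$pop_id, label = "other",
                   rule_trace = data.frame()), class = "lineage_call")
  }
}

#' @export
print.lineage_call <- function(x, ...) {
  cat("<lineage_call>", x$pop_id, "->", x$label, "\n")
  invisible(x)
}

#' Export dot plots with population overlays
#'
#' For each requested channel pair, draws the sample's events as a
#' scatter, colours the events belonging to the selected populations,
#' and overlays the rectangle of every gate of those populations that
#' lives on this channel pair.
#'
#' @param em A standardized [event_matrix()] for one sample.
#' @param tree The `gate_tree` defining the populations.
#' @param pop_ids Populations to highlight.
#' @param channel_pairs List of 2-element character vectors (marker
#'   names).
#' @param dir Output directory.
#' @param max_points Events plotted per panel (subsampled above this).
#' @param format `"png"` or `"svg"`.
#' @return Character vector of written file paths, invisibly.
#' @export
export_dotplots <- function(em, tree, pop_ids, channel_pairs,
                            dir = ".", max_points = 20000,
                            format = c("png", "svg")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- assign_events(tree, em)
  v <- em$values
  if (nrow(v) > max_points) {
    keep <- sort(sample.int(nrow(v), max_points))
    v <- v[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  paths <- character(0)
  for (cp in channel_pairs) {
    cx <- match_channels(em$panel, cp[1])
    cy <- match_channels(em$panel, cp[2])
    df <- data.frame(x = v[, cx], y = v[, cy],
                     population = ifelse(lab %in% pop_ids, lab, "rest"))
    counts <- table(factor(lab, levels = pop_ids))
    legend_lab <- sprintf("%s (%d events)", pop_ids, as.integer(counts))
    rects <- list()
    for (pid in pop_ids) {
      pop <- tree$leaves[[which(vapply(tree$leaves, `[[`, character(1),
                                       "pop_id") == pid)]]
      for (g in pop$gates) {
        gt <- g$gate
        if (setequal(c(gt$channel_x, gt$channel_y), cp)) {
          flip <- gt$channel_x != cp[1]
          rects[[length(rects) + 1]] <- data.frame(
            population = pid,
            xmin = if (flip) gt$y_lo else gt$x_lo,
            xmax = if (flip) gt$y_hi else gt$x_hi,
            ymin = if (flip) gt$x_lo else gt$y_lo,
            ymax = if (flip) gt$x_hi else gt$y_hi)
        }
      }
    }
    pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point(data = df[df$population == "rest", ],
                          colour = "grey70", size = 0.3, alpha = 0.4) +
      ggplot2::geom_point(data = df[df$population != "rest", ],
                          ggplot2::aes(colour = .data$population),
                          size = 0.4) +
      ggplot2::scale_colour_discrete(
        limits = pop_ids, labels = legend_lab, drop = FALSE) +
      ggplot2::labs(x = cp[1], y = cp[2],
                    title = paste(em$sample_id, "-", cp[1], "vs", cp[2])) +
      ggplot2::coord_cartesian(xlim = c(0, 6), ylim = c(0, 6)) +
      ggplot2::theme_minimal()
    if (length(rects)) {
      rdf <- do.call(rbind, rects)
      pl <- pl + ggplot2::geom_rect(
        data = rdf,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = .data$ymin, ymax = .data$ymax,
                     colour = .data$population),
        inherit.aes = FALSE, fill = NA, linewidth = 0.5)
    }
    f <- file.path(dir, sprintf("%s_%s_vs_%s.%s", em$sample_id,
                                cp[1], cp[2], format))
    ggplot2::ggsave(f, pl, width = 6, height = 5, dpi = 150)
    paths <- c(paths, f)
  }
  invisible(paths)
}
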