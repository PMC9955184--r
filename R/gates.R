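#' A rectangular 2D dot-plot gate
#'
#' @param channel_x,channel_y Marker names of the two plotted channels
#'   (distinct).
#' @param x_lo,x_hi,y_lo,y_hi Rectangle bounds on the standardized
#'   `[0,6]` scale, `lo < hi`.
#' @return A `gate2d` object.
#' @export
gate2d <- function(channel_x, channel_y, x_lo, x_hi, y_lo, y_hi) {
  stopifnot(is.character(channel_x), is.character(channel_y),
            channel_x != channel_y,
            x_lo < x_hi, y_lo < y_hi)
  structure(list(channel_x = channel_x, channel_y = channel_y,
                 x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi),
            class = "gate2d")
}

#' @export
print.gate2d <- function(x, ...) {
  cat(sprintf("<gate2d> %s in [%.2f, %.2f] x %s in [%.2f, %.2f]\n",
              x$channel_x, x$x_lo, x$x_hi, x$channel_y, x$y_lo, x$y_hi))
  invisible(x)
}

# membership is half-open [lo, hi) except at the top of the scale, so
# adjacent rectangles tile without double-claiming boundary events
in_gate <- function(gate, values, panel) {
  cx <- match_channels(panel, gate$channel_x)
  cy <- match_channels(panel, gate$channel_y)
  x <- values[, cx]
  y <- values[, cy]
  (x >= gate$x_lo & (x < gate$x_hi | (gate$x_hi >= 6 & x <= 6))) &
    (y >= gate$y_lo & (y < gate$y_hi | (gate$y_hi >= 6 & y <= 6)))
}

#' A discovered cell population
#'
#' A population is the set of events satisfying an ordered chain of 2D
#' gates, each taken on its `inside` or `outside` side.  The outside side
#' (a NOT gate, standard in cytometry software) is what lets the leaves
#' of a binary gate tree partition the event space.
#'
#' @param pop_id Identifier, `T{tube}C{index}` style.
#' @param tube `"T1"` or `"T2"`.
#' @param gates List of steps, each `list(gate = gate2d, side =
#'   "inside"|"outside")`.
#' @param direction `"overrepresented_in_ttf1"` or
#'   `"underrepresented_in_ttf1"`.
#' @param cohens_d Training-data effect size of the population frequency
#'   between outcome classes (optional).
#' @return A `population_definition`.
#' @export
population_definition <- function(pop_id, tube, gates, direction,
                                  cohens_d = NA_real_) {
  stopifnot(length(gates) >= 1,
            all(vapply(gates, function(g) inherits(g$gate, "gate2d") &&
                         g$side %in% c("inside", "outside"), logical(1))))
  direction <- match.arg(direction, c("overrepresented_in_ttf1",
                                      "underrepresented_in_ttf1"))
  structure(list(pop_id = pop_id, tube = tube, gates = gates,
                 direction = direction, cohens_d = cohens_d),
            class = "population_definition")
}

#' @export
print.population_definition <- function(x, ...) {
  cat("<population>", x$pop_id, paste0("(", x$direction, ")"),
      if (is.finite(x$cohens_d)) sprintf("d=%.2f", x$cohens_d), "\n")
  for (g in x$gates)
    cat(sprintf("  %s %s in [%.2f,%.2f] x %s in [%.2f,%.2f]\n",
                g$side, g$gate$channel_x, g$gate$x_lo, g$gate$x_hi,
                g$gate$channel_y, g$gate$y_lo, g$gate$y_hi))
  invisible(x)
}

in_population <- function(pop, values, panel) {
  keep <- rep(TRUE, nrow(values))
  for (g in pop$gates) {
    m <- in_gate(g$gate, values, panel)
    keep <- keep & (if (g$side == "inside") m else !m)
  }
  keep
}

#' Assign every event of a sample to exactly one tree leaf
#'
#' The gate tree's leaves partition the event space: each event descends
#' the tree by testing membership in each node's rectangle and lands in
#' exactly one leaf.
#'
#' @param tree A `gate_tree` from [build_gate_tree()].
#' @param em An [event_matrix()] (standardized) or a plain numeric
#'   matrix in the tree panel's channel order.
#' @return Character vector of leaf `pop_id`s, one per event.
#' @export
assign_events <- function(tree, em) {
  values <- if (inherits(em, "event_matrix")) {
    if (!identical(em$panel$channels$marker, tree$panel$channels$marker))
      stop("panel mismatch: event matrix channels do not match the tree",
           call. = FALSE)
    em$values
  } else as.matrix(em)
  if (ncol(values) != n_channels(tree$panel))
    stop("panel mismatch: expected ", n_channels(tree$panel), " channels",
         call. = FALSE)
  out <- character(nrow(values))
  descend <- function(node, idx) {
    if (node$type == "leaf") {
      out[idx] <<- node$pop_id
      return(invisible(NULL))
    }
    m <- in_gate(node$gate, values[idx, , drop = FALSE], tree$panel)
    if (any(m)) descend(node$inside, idx[m])
    if (any(!m)) descend(node$outside, idx[!m])
  }
  if (nrow(values)) descend(tree$root, seq_len(nrow(values)))
  out
}

#' Per-sample population frequency table
#'
#' For every sample, the percentage of retained events falling into each
#' leaf population of the tree.  Because the leaves partition the event
#' space, each row sums to 100.
#'
#' @param tree A `gate_tree`.
#' @param events Named list of standardized [event_matrix()] objects (or
#'   plain matrices), one per sample.
#' @param metadata Optional metadata table supplying the `ttf` group
#'   label per sample.
#' @return `data.frame` with `sample_id`, `ttf` (if available) and one
#'   column per leaf `pop_id`, values in percent.
#' @export
frequency_table <- function(tree, events, metadata = NULL) {
  ids <- names(events)
  if (is.null(ids)) ids <- paste0("S", seq_along(events))
  pops <- vapply(tree$leaves, `[[`, character(1), "pop_id")
  rows <- matrix(NA_real_, length(events), length(pops),
                 dimnames = list(ids, pops))
  keep <- rep(TRUE, length(events))
  for (i in seq_along(events)) {
    n <- if (inherits(events[[i]], "event_matrix")) n_events(events[[i]])
         else nrow(events[[i]])
    if (n == 0) {
      warning("sample ", ids[i], " has zero retained events; excluded",
              call. = FALSE)
      keep[i] <- FALSE
      next
    }
    lab <- assign_events(tree, events[[i]])
    cnt <- table(factor(lab, levels = pops))
    rows[i, ] <- 100 * as.numeric(cnt) / n
  }
  out <- data.frame(sample_id = ids[keep], rows[keep, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    out$ttf <- metadata$ttf[match(out$sample_id, metadata$sample_id)]
    out <- out[, c("sample_id", "ttf", pops)]
  }
  rownames(out) <- NULL
  out
}

#' Serialize a gate tree to JSON
#'
#' Emits the panel, the binary split structure and the leaf population
#' definitions; every population is a finite list of
#' `(channel_x, channel_y, rectangle, side)` steps — nothing else, which
#' is what keeps the model human-readable on dot plots.
#'
#' @param tree A `gate_tree`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly if `path` given).
#' @export
gate_tree_json <- function(tree, path = NULL) {
  ser_node <- function(node) {
    if (node$type == "leaf")
      return(list(type = "leaf", pop_id = node$pop_id))
    list(type = "split",
         gate = unclass(node$gate),
         inside = ser_node(node$inside),
         outside = ser_node(node$outside))
  }
  obj <- list(
    tube = tree$tube,
    channels = tree$panel$channels,
    root = ser_node(tree$root),
    populations = lapply(tree$leaves, function(p) list(
      pop_id = p$pop_id, tube = p$tube, direction = p$direction,
      cohens_d = p$cohens_d,
      gates = lapply(p$gates, function(g)
        c(unclass(g$gate), list(side = g$side)))))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
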