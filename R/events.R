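#' Construct an event matrix for one sample and tube
#'
#' The central per-sample container: an events x channels numeric matrix
#' plus the panel it conforms to and the preprocessing stage it has
#' reached.  Stages advance monotonically through
#' `raw -> compensated -> transformed -> standardized -> subsampled`.
#'
#' @param values Numeric matrix, events in rows, channels in columns
#'   (panel order).
#' @param panel A [panel_definition()].
#' @param sample_id Sample identifier.
#' @param stage Preprocessing stage the values are at.
#' @return An object of class `event_matrix`.
#' @export
event_matrix <- function(values, panel, sample_id,
                         stage = c("raw", "compensated", "transformed",
                                   "standardized", "subsampled")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != n_channels(panel))
    stop("event matrix has ", ncol(values), " columns but panel ",
         panel$tube_id, " declares ", n_channels(panel), " channels",
         call. = FALSE)
  if (anyNA(values))
    stop("event matrix contains missing values", call. = FALSE)
  colnames(values) <- panel$channels$marker
  structure(list(sample_id = as.character(sample_id), panel = panel,
                 values = values, stage = stage),
            class = "event_matrix")
}

.stages <- c("raw", "compensated", "transformed", "standardized", "subsampled")

stage_index <- function(stage) match(stage, .stages)

advance_stage <- function(em, to) {
  if (stage_index(to) < stage_index(em$stage))
    stop("stage may not move backwards: ", em$stage, " -> ", to,
         call. = FALSE)
  em$stage <- to
  em
}

require_stage <- function(em, stage) {
  if (em$stage != stage)
    stop("expected stage '", stage, "' but event matrix is at '",
         em$stage, "'", call. = FALSE)
  invisible(em)
}

#' @export
print.event_matrix <- function(x, ...) {
  cat("<event_matrix>", x$sample_id, "tube", x$panel$tube_id, "-",
      nrow(x$values), "events x", ncol(x$values), "channels, stage",
      x$stage, "\n")
  invisible(x)
}

#' @export
dim.event_matrix <- function(x) dim(x$values)

n_events <- function(em) nrow(em$values)
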