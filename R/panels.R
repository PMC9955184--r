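#' Define a flow cytometry tube panel
#'
#' A panel is the ordered list of channels acquired for one tube of a
#' staining panel: light-scatter channels plus fluorescence channels, each
#' identified by a short name (the detector, `$PnN` in FCS terms) and a
#' marker label (`$PnS`).
#'
#' @param tube_id Tube identifier, `"T1"` or `"T2"`.
#' @param channels `data.frame` with columns `name` (short name, unique
#'   within the tube), `marker` (antigen or scatter label) and `kind`
#'   (`"scatter"` or `"fluorescence"`).
#' @return An object of class `panel_definition`.
#' @details Every tube must carry at least one forward-scatter and one
#'   side-scatter channel; scatter channels are recognized by a marker or
#'   name starting with `FS`/`FSC` (forward) or `SS`/`SSC` (side).
#' @seealso [cll_panel()] for the two-tube B-cell panel used throughout.
#' @export
panel_definition <- function(tube_id, channels) {
  tube_id <- match.arg(tube_id, c("T1", "T2"))
  stopifnot(is.data.frame(channels),
            all(c("name", "marker", "kind") %in% names(channels)))
  channels$name <- as.character(channels$name)
  channels$marker <- as.character(channels$marker)
  channels$kind <- match.arg(channels$kind, c("scatter", "fluorescence"),
                             several.ok = TRUE)
  if (anyDuplicated(channels$name))
    stop("channel short names must be unique within a tube", call. = FALSE)
  sc <- channels$name[channels$kind == "scatter"]
  has_fs <- any(grepl("^FSC?([ -]|$)", sc)) || any(sc == "FS")
  has_ss <- any(grepl("^SSC?([ -]|$)", sc)) || any(sc == "SS")
  if (!has_fs || !has_ss)
    stop("panel needs at least one forward and one side scatter channel",
         call. = FALSE)
  structure(list(tube_id = tube_id, channels = channels),
            class = "panel_definition")
}

#' The two-tube CLL B-cell diagnostic panel
#'
#' Tube 1 carries B-cell antigens (CD19, CD20, FMC7, CD79b, CD23, kappa and
#' lambda light chains), T-cell antigens (CD3, CD5, CD2, CD7, CD4, CD8) and
#' the activation marker CD38.  Tube 2 carries B-cell antigens (CD19, CD20,
#' IgM), hairy-cell markers (CD103, CD11c, CD25), CD10, and the CLL
#' confirmation markers CD43 and CD200.  Both tubes open with forward and
#' side scatter.
#'
#' @param tube `"T1"` or `"T2"`.
#' @return A [panel_definition()].
#' @export
cll_panel <- function(tube = c("T1", "T2")) {
  tube <- match.arg(tube)
  markers <- if (tube == "T1") {
    c("CD19", "CD20", "FMC7", "CD79b", "CD23", "kappa", "lambda",
      "CD3", "CD5", "CD2", "CD7", "CD4", "CD8", "CD38")
  } else {
    c("CD19", "CD20", "IgM", "CD103", "CD11c", "CD25", "CD10",
      "CD43", "CD200")
  }
  channels <- data.frame(
    name = c("FS", "SS", paste0("FL", seq_along(markers))),
    marker = c("FS", "SS", markers),
    kind = c("scatter", "scatter", rep("fluorescence", length(markers))),
    stringsAsFactors = FALSE
  )
  panel_definition(tube, channels)
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("<panel_definition> tube", x$tube_id, "-", nrow(x$channels),
      "channels:", paste(x$channels$marker, collapse = ", "), "\n")
  invisible(x)
}

n_channels <- function(panel) nrow(panel$channels)

#' Locate panel channels by marker or short name
#'
#' Matching is case-insensitive and tries the marker label (`$PnS`) first,
#' then the short detector name (`$PnN`), mirroring how vendor FCS files
#' are reconciled.
#'
#' @param panel A [panel_definition()].
#' @param markers Character vector of markers or channel names.
#' @return Integer column indices.
#' @export
match_channels <- function(panel, markers) {
  lm <- tolower(panel$channels$marker)
  ln <- tolower(panel$channels$name)
  idx <- vapply(tolower(markers), function(m) {
    i <- match(m, lm)
    if (is.na(i)) i <- match(m, ln)
    if (is.na(i)) stop("channel not in panel: ", m, call. = FALSE)
    i
  }, integer(1))
  unname(idx)
}

scatter_idx <- function(panel) which(panel$channels$kind == "scatter")
fluor_idx <- function(panel) which(panel$channels$kind == "fluorescence")

ssc_idx <- function(panel) {
  sc <- scatter_idx(panel)
  i <- sc[grepl("^SSC?([ -]|$)|^SS$", panel$channels$name[sc])]
  if (!length(i)) stop("no side scatter channel in panel", call. = FALSE)
  i[1]
}

fsc_idx <- function(panel) {
  sc <- scatter_idx(panel)
  i <- sc[grepl("^FSC?([ -]|$)|^FS$", panel$channels$name[sc])]
  if (!length(i)) stop("no forward scatter channel in panel", call. = FALSE)
  i[1]
}
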