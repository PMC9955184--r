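#' Sample metadata columns
#'
#' The metadata table is a plain `data.frame`, one row per sample, with a
#' fixed header vocabulary.  Booleans are encoded 0/1; unknown values are
#' `NA` (empty fields in CSV), never silently imputed.
#'
#' Columns: `sample_id`; outcome `ttf` (1 = inferior outcome: death during
#' follow-up and/or failure of first-line systemic therapy, 0 = superior);
#' `died`, `first_line_failure` (0/1, required); CLL-IPI components
#' `age_years`, `binet` (A/B/C), `b2m_elevated`, `ighv_unmutated`,
#' `tp53_aberrant` (0/1, may be `NA`); `cd38_positive_pct` (percent of CLL
#' cells CD38+); `sex` (`"F"`/`"M"`); `followup_months`; optional
#' `therapy` (first-line therapy class) and `richter` (0/1).
#'
#' @name metadata-format
NULL

metadata_required <- c("sample_id", "ttf", "died", "first_line_failure")
metadata_optional <- c("age_years", "binet", "b2m_elevated",
                       "ighv_unmutated", "tp53_aberrant",
                       "cd38_positive_pct", "sex", "followup_months",
                       "therapy", "richter")

#' Validate a sample metadata table
#'
#' Checks the header vocabulary, value domains and the outcome-definition
#' invariant: `ttf == 1` exactly when the patient died during follow-up
#' and/or failed first-line therapy.
#'
#' @param meta A `data.frame` of per-sample metadata.
#' @return The table, with missing optional columns added as `NA`,
#'   invisibly usable downstream.
#' @export
validate_metadata <- function(meta) {
  stopifnot(is.data.frame(meta))
  missing_cols <- setdiff(metadata_required, names(meta))
  if (length(missing_cols))
    stop("metadata lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in setdiff(metadata_optional, names(meta))) meta[[col]] <- NA
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  for (col in c("ttf", "died", "first_line_failure")) {
    v <- meta[[col]]
    if (anyNA(v) || !all(v %in% c(0, 1)))
      stop("column '", col, "' must be 0/1 with no missing values",
           call. = FALSE)
  }
  bad_binet <- !is.na(meta$binet) & !meta$binet %in% c("A", "B", "C")
  if (any(bad_binet))
    stop("binet must be A, B, C or missing", call. = FALSE)
  derived <- as.integer(meta$died == 1 | meta$first_line_failure == 1)
  bad <- which(meta$ttf != derived)
  if (length(bad))
    stop("outcome invariant violated for sample(s) ",
         paste(meta$sample_id[bad], collapse = ", "),
         ": ttf must be 1 exactly when died == 1 or first_line_failure == 1",
         call. = FALSE)
  meta
}

#' Read a sample metadata CSV
#'
#' @param path Path to a comma-separated file with a header row following
#'   the vocabulary in [metadata-format].  Empty fields become `NA`.
#' @return Validated metadata `data.frame`.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  validate_metadata(meta)
}

#' Write a sample metadata CSV
#'
#' @param meta Metadata `data.frame` (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  meta <- validate_metadata(meta)
  utils::write.csv(meta, path, row.names = FALSE, na = "")
  invisible(path)
}
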