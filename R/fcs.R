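#' Read an FCS 3.0/3.1 event file
#'
#' Reads list-mode FCS files with float or integer data and reorders the
#' channels to the order of the supplied panel.  Channel identity is
#' resolved by the stain keyword `$PnS` (marker) first and the detector
#' name `$PnN` second, case-insensitively, because vendor files differ in
#' which of the two carries the antigen label.
#'
#' @param path Path to an FCS file.
#' @param panel [panel_definition()] the file must conform to.
#' @param stage Stage to stamp on the returned matrix (default `"raw"`).
#' @return An [event_matrix()] with channels in panel order.
#' @export
read_fcs <- function(path, panel, stage = "raw") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("not an FCS 3.0/3.1 file (header '", version, "')", call. = FALSE)
  off <- suppressWarnings(as.numeric(substring(
    header, 11 + 8 * (0:5), 18 + 8 * (0:5))))
  if (anyNA(off[1:2]) || off[1] <= 0 || off[2] <= off[1])
    stop("corrupt FCS header: bad TEXT segment offsets", call. = FALSE)

  seek(con, off[1])
  text_raw <- readBin(con, "raw", off[2] - off[1] + 1)
  kw <- parse_fcs_text(rawToChar(text_raw))
  need <- function(k) {
    v <- kw[[k]]
    if (is.null(v)) stop("FCS file lacks required keyword ", k, call. = FALSE)
    v
  }

  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (grepl("^4", byteord)) "big" else "little"
  if (toupper(need("$MODE")) != "L")
    stop("only list-mode ($MODE L) FCS data is supported", call. = FALSE)

  data_beg <- off[3]
  data_end <- off[4]
  if (is.na(data_beg) || data_beg == 0) data_beg <- as.numeric(need("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0) data_end <- as.numeric(need("$ENDDATA"))

  bits <- as.integer(kw[["$P1B"]])
  seek(con, data_beg)
  n_values <- n_par * n_tot
  values <- switch(dtype,
    F = readBin(con, "numeric", n_values, size = 4, endian = endian),
    D = readBin(con, "numeric", n_values, size = 8, endian = endian),
    I = readBin(con, "integer", n_values, size = bits %/% 8,
                endian = endian, signed = FALSE),
    stop("unsupported $DATATYPE '", dtype, "'", call. = FALSE))
  if (length(values) < n_values)
    stop("FCS data segment truncated: expected ", n_values,
         " values, read ", length(values), call. = FALSE)
  mat <- matrix(values, nrow = n_tot, ncol = n_par, byrow = TRUE)

  file_names <- vapply(seq_len(n_par), function(i)
    kw[[paste0("$P", i, "N")]] %||% "", character(1))
  file_stains <- vapply(seq_len(n_par), function(i)
    kw[[paste0("$P", i, "S")]] %||% "", character(1))

  want <- panel$channels
  col_idx <- integer(nrow(want))
  for (i in seq_len(nrow(want))) {
    j <- match(tolower(want$marker[i]), tolower(file_stains))
    if (is.na(j)) j <- match(tolower(want$marker[i]), tolower(file_names))
    if (is.na(j)) j <- match(tolower(want$name[i]), tolower(file_stains))
    if (is.na(j)) j <- match(tolower(want$name[i]), tolower(file_names))
    if (is.na(j))
      stop("panel mismatch: channel '", want$marker[i],
           "' not present in ", basename(path), call. = FALSE)
    col_idx[i] <- j
  }
  sample_id <- kw[["$SRC"]] %||% sub("\\.fcs$", "", basename(path),
                                     ignore.case = TRUE)
  event_matrix(mat[, col_idx, drop = FALSE], panel, sample_id, stage = stage)
}

#' Write an event matrix as an FCS 3.1 file
#'
#' Emits single-dataset, list-mode FCS 3.1 with 32-bit float data in
#' little-endian byte order; channel short names go to `$PnN` and marker
#' labels to `$PnS`.  Output bytes are deterministic for a given matrix.
#'
#' @param em An [event_matrix()] with at least one event.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(em, path) {
  stopifnot(inherits(em, "event_matrix"))
  if (n_events(em) == 0)
    stop("refusing to write an FCS file with zero events", call. = FALSE)
  v <- em$values
  n_par <- ncol(v)
  n_tot <- nrow(v)

  delim <- "/"
  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    # placeholders overwritten below; zero-padded so TEXT length is stable
    "$BEGINDATA" = "00000000", "$ENDDATA" = "00000000",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot),
    "$SRC" = em$sample_id,
    "$CYT" = "cytopops synthetic writer"
  )
  for (i in seq_len(n_par)) {
    kv[paste0("$P", i, "B")] <- "32"
    kv[paste0("$P", i, "E")] <- "0,0"
    kv[paste0("$P", i, "N")] <- em$panel$channels$name[i]
    kv[paste0("$P", i, "S")] <- em$panel$channels$marker[i]
    kv[paste0("$P", i, "R")] <- "262144"
  }
  text_of <- function(kv) paste0(delim, paste0(names(kv), delim, unname(kv),
                                               delim, collapse = ""))
  text <- text_of(kv)
  text_beg <- 58
  text_end <- text_beg + nchar(text) - 1
  data_beg <- text_end + 1
  data_end <- data_beg + 4 * n_par * n_tot - 1
  kv["$BEGINDATA"] <- formatC(data_beg, width = 8, flag = "0")
  kv["$ENDDATA"] <- formatC(data_end, width = 8, flag = "0")
  text <- text_of(kv)

  fmt_off <- function(x) {
    if (x > 99999999) "       0" else formatC(x, width = 8)
  }
  header <- paste0("FCS3.1    ",
                   fmt_off(text_beg), fmt_off(text_end),
                   fmt_off(data_beg), fmt_off(data_end),
                   formatC(0, width = 8), formatC(0, width = 8))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(v)), con, size = 4, endian = "little")
  invisible(path)
}

# TEXT segment: first byte is the delimiter; keys and values alternate.
# Doubled delimiters inside values (the FCS escape) are unescaped.
parse_fcs_text <- function(text) {
  delim <- substr(text, 1, 1)
  body <- substring(text, 2)
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # re-join empty parts produced by escaped (doubled) delimiters
  fields <- character(0)
  i <- 1
  while (i <= length(parts)) {
    cur <- parts[i]
    while (i + 1 <= length(parts) && parts[i + 1] == "" &&
           i + 2 <= length(parts)) {
      cur <- paste0(cur, delim, parts[i + 2])
      i <- i + 2
    }
    fields <- c(fields, cur)
    i <- i + 1
  }
  if (length(fields) %% 2 == 1) fields <- fields[-length(fields)]
  keys <- toupper(trimws(fields[seq(1, length(fields), 2)]))
  vals <- fields[seq(2, length(fields), 2)]
  stats::setNames(as.list(vals), keys)
}

`%||%` <- function(a, b) if (is.null(a) || !nzchar(a)) b else a
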