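#' Read event-level cytometry data
#'
#' Reads an FCS 3.0/3.1 file or the package CSV dialect into an
#' [event_matrix]. Channel names found in the file are resolved against the
#' panel through the alias table; an unmapped or ambiguous channel is an
#' error naming the offending channel. Event order is preserved from the
#' file and the result is always on the raw scale.
#'
#' The CSV dialect is: a header row of channel short names, one event per
#' row, UTF-8, `"."` decimal separator.
#'
#' @param path Path to an FCS or CSV file.
#' @param panel A [panel_definition]; defaults to [pidot_panel()].
#' @param meta A [sample_meta] describing the sample (age and WBC count are
#'   not carried by either file format).
#' @param aliases Alias table from [channel_aliases()].
#' @return A raw-scale [event_matrix].
#' @export
read_events <- function(path, panel = pidot_panel(), meta,
                        aliases = channel_aliases()) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 3L)
  is_fcs <- identical(rawToChar(magic), "FCS")
  if (is_fcs) {
    parsed <- .read_fcs(path)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
    parsed <- list(values = as.matrix(df), channels = names(df))
  }
  canon <- .resolve_channel_names(parsed$channels, panel, aliases)
  values <- parsed$values
  colnames(values) <- canon
  values <- values[, panel_channels(panel), drop = FALSE]
  event_matrix(values, panel, meta, scale = "raw")
}

#' Write event-level cytometry data
#'
#' Writes an [event_matrix] as FCS 3.1 (single-precision floating point data,
#' little-endian, `$PnN` set to the channel short names and `$TOT` to the
#' event count) or as the package CSV dialect. [read_events()] inverts it:
#' channel names round-trip exactly and values round-trip within
#' single-precision tolerance for FCS and printed-precision for CSV.
#'
#' @param events An [event_matrix].
#' @param path Output path; the format is chosen from the extension
#'   (`.csv` for CSV, anything else FCS) unless `format` is given.
#' @param format `"auto"`, `"fcs"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "fcs", "csv")) {
  stopifnot(inherits(events, "event_matrix"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fcs"
  if (format == "csv") {
    utils::write.csv(as.data.frame(events$values), path,
                     row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    .write_fcs(events$values, path)
  }
  invisible(path)
}

# -- minimal FCS 3.1 reader/writer -------------------------------------------
# Supports the subset of the standard needed here: list-mode data, datatype
# F (float32) or D (float64), little- or big-endian, one data set per file.

.read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", n = 58L))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version, "'", call. = FALSE)
  off <- function(i) {
    s <- substr(header, 11 + (i - 1) * 8, 10 + i * 8)
    s <- gsub(" ", "", s)
    if (s == "") 0 else as.numeric(s)
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)
  if (text_end <= text_beg)
    stop("truncated FCS file: bad TEXT segment offsets", call. = FALSE)
  seek(con, text_beg)
  txt <- rawToChar(readBin(con, "raw", n = text_end - text_beg + 1))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2)
    stop("truncated FCS file: empty TEXT segment", call. = FALSE)
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(trimws(parts[seq(1, length(parts), 2)])))
  need <- function(k) {
    if (is.na(kw[k])) stop("FCS file lacks required keyword ", k, call. = FALSE)
    kw[[k]]
  }
  par <- as.integer(need("$PAR"))
  tot <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"
  size <- switch(dtype, F = 4L, D = 8L,
                 stop("unsupported $DATATYPE '", dtype, "'", call. = FALSE))
  if (data_beg == 0) data_beg <- as.numeric(need("$BEGINDATA"))
  if (data_end == 0) data_end <- as.numeric(need("$ENDDATA"))
  n_values <- par * tot
  if (data_end - data_beg + 1 < n_values * size)
    stop("truncated FCS file: DATA segment smaller than $PAR * $TOT values",
         call. = FALSE)
  channels <- vapply(seq_len(par),
                     function(i) need(sprintf("$P%dN", i)), character(1))
  seek(con, data_beg)
  vals <- readBin(con, "numeric", n = n_values, size = size, endian = endian)
  if (length(vals) < n_values)
    stop("truncated FCS file: unexpected end of DATA segment", call. = FALSE)
  values <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  list(values = values, channels = channels)
}

.write_fcs <- function(values, path) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("values must carry channel names", call. = FALSE)
  tot <- nrow(values); par <- ncol(values)
  d <- "/"
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$NEXTDATA", "0", "$MODE", "L", "$DATATYPE", "F",
          "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(par), "$TOT", as.character(tot))
  for (i in seq_len(par)) {
    kv <- c(kv,
            sprintf("$P%dN", i), colnames(values)[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), as.character(RAW_SCALE_MAX))
  }
  # fixed-width data offsets so the TEXT length is known before writing
  text_body <- paste0(d, paste0(kv, collapse = d), d)
  text_beg <- 58L
  text_len <- nchar(gsub("%BD%|%ED%", "0000000000", text_body))
  data_beg <- text_beg + text_len
  data_end <- data_beg + 4L * tot * par - 1L
  text_body <- sub("%BD%", sprintf("%010d", data_beg), text_body, fixed = TRUE)
  text_body <- sub("%ED%", sprintf("%010d", data_end), text_body, fixed = TRUE)
  hdr_off <- function(x) {
    if (x > 99999999) "       0" else sprintf("%8d", x)
  }
  header <- paste0("FCS3.1    ",
                   hdr_off(text_beg), hdr_off(text_beg + text_len - 1L),
                   hdr_off(data_beg), hdr_off(data_end),
                   hdr_off(0), hdr_off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text_body), con)
  writeBin(as.vector(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}
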