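# Minimal FCS 3.1 I/O: float (single precision) data, list mode, one data
# set per file. Covers what the pipeline itself writes plus plain FCS
# 2.0/3.0/3.1 files with $DATATYPE F or D.

#' Default channel map
#'
#' Maps analysis marker names to FCS parameter names. Resolution tries the
#' stain name (`$PnS`) first, then the short name (`$PnN`), matching common
#' vendor practice. The default is the identity over [hspc_channels()],
#' which is what [write_events()] emits.
#'
#' @return named character vector: analysis name -> FCS parameter name.
#' @export
default_channel_map <- function() {
  stats::setNames(hspc_channels(), hspc_channels())
}

#' Write a CellEventTable as an FCS 3.1 file
#'
#' Channel columns are stored as single-precision floats in list mode.
#' Per-event metadata is preserved through keywords: `$SRC` carries the
#' patient id and the custom keyword `GROUP` the group label (both taken
#' from the table when present). Ground-truth side channels (dot-prefixed
#' columns) are deliberately not exported.
#'
#' @param table non-empty CellEventTable.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop_hspc("cannot write an empty event table", "hspcmap_argument_error")
  }
  ch <- event_channels(table)
  mat <- as.matrix(table[, ch, drop = FALSE])
  storage.mode(mat) <- "double"
  n <- nrow(mat); p <- ncol(mat)
  d <- "|"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "@B@@@@@@@@", "$ENDDATA", "@E@@@@@@@@",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p))
  for (i in seq_len(p)) {
    kw <- c(kw, sprintf("$P%dN", i), ch[i], sprintf("$P%dS", i), ch[i],
            sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "262144")
  }
  if ("patient_id" %in% names(table)) {
    kw <- c(kw, "$SRC", as.character(table$patient_id[1]))
  }
  if ("group" %in% names(table)) {
    kw <- c(kw, "GROUP", as.character(table$group[1]))
  }
  if (any(grepl(d, kw, fixed = TRUE))) {
    stop_hspc("keyword values must not contain the delimiter '|'",
              "hspcmap_format_error")
  }
  text <- paste0(d, paste(kw, collapse = d), d)
  header_len <- 58L
  data_begin <- header_len + nchar(text, type = "bytes")
  data_end <- data_begin + 4L * n * p - 1L
  text <- sub("@B@@@@@@@@", sprintf("%010d", data_begin), text, fixed = TRUE)
  text <- sub("@E@@@@@@@@", sprintf("%010d", data_end), text, fixed = TRUE)
  text_end <- header_len + nchar(text, type = "bytes") - 1L
  fmt8 <- function(x) if (x > 99999999) "       0" else sprintf("%8d", x)
  header <- paste0("FCS3.1    ", fmt8(header_len), fmt8(text_end),
                   fmt8(data_begin), fmt8(data_end), fmt8(0), fmt8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, text)), con)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

# Parse one FCS file into raw parts: keywords + data matrix ($PnN columns).
read_fcs_raw <- function(path) {
  if (!file.exists(path)) {
    stop_hspc(paste0("no such file: ", path), "hspcmap_format_error")
  }
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 58) stop_hspc("truncated FCS file", "hspcmap_format_error")
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1")) {
    stop_hspc(paste0("not an FCS 2.0/3.0/3.1 file (", version, ")"),
              "hspcmap_format_error")
  }
  off <- function(i) {
    s <- trimws(rawToChar(raw[(11 + 8 * (i - 1)):(10 + 8 * i)]))
    if (s == "") 0 else as.numeric(s)
  }
  text_begin <- off(1); text_end <- off(2)
  if (text_begin <= 0 || text_end <= text_begin) {
    stop_hspc("corrupt FCS header (TEXT offsets)", "hspcmap_format_error")
  }
  text <- rawToChar(raw[(text_begin + 1):(text_end + 1)])
  d <- substr(text, 1, 1)
  body <- substr(text, 2, nchar(text))
  parts <- strsplit(body, d, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(as.list(vals), toupper(keys))
  need <- c("$TOT", "$PAR", "$DATATYPE", "$BYTEORD", "$MODE")
  if (!all(need %in% names(kw))) {
    stop_hspc(paste0("missing required keywords: ",
                     paste(setdiff(need, names(kw)), collapse = ", ")),
              "hspcmap_format_error")
  }
  tot <- as.integer(kw$`$TOT`); par <- as.integer(kw$`$PAR`)
  data_begin <- off(3); data_end <- off(4)
  if (data_begin == 0 && !is.null(kw$`$BEGINDATA`)) {
    data_begin <- as.numeric(kw$`$BEGINDATA`)
    data_end <- as.numeric(kw$`$ENDDATA`)
  }
  if (toupper(kw$`$MODE`) != "L") {
    stop_hspc("only list-mode FCS files are supported", "hspcmap_format_error")
  }
  dtype <- toupper(kw$`$DATATYPE`)
  size <- switch(dtype, F = 4L, D = 8L,
                 stop_hspc("only $DATATYPE F or D supported",
                           "hspcmap_format_error"))
  endian <- if (startsWith(kw$`$BYTEORD`, "1")) "little" else "big"
  con <- rawConnection(raw[(data_begin + 1):(data_end + 1)])
  on.exit(close(con))
  vals <- readBin(con, "double", n = tot * par, size = size, endian = endian)
  mat <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  pnn <- vapply(seq_len(par),
                function(i) kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i),
                character(1))
  colnames(mat) <- pnn
  list(data = mat, keywords = kw, n_par = par)
}

#' Read events from an FCS file
#'
#' Restricts and renames the event matrix to the analysis channels of the
#' given channel map, preserving event order. Marker resolution tries the
#' stain keyword (`$PnS`) first, then the short name (`$PnN`).
#'
#' @param path FCS file path.
#' @param map named character vector mapping analysis names to FCS
#'   parameter names; default [default_channel_map()].
#' @return CellEventTable data.frame; `patient_id`/`group` restored from
#'   the `$SRC`/`GROUP` keywords when present.
#' @export
read_events <- function(path, map = default_channel_map()) {
  fcs <- read_fcs_raw(path)
  kw <- fcs$keywords
  pns <- vapply(seq_len(fcs$n_par),
                function(i) kw[[sprintf("$P%dS", i)]] %||% "", character(1))
  pnn <- colnames(fcs$data)
  idx <- integer(length(map))
  for (k in seq_along(map)) {
    i <- match(map[[k]], pns)
    if (is.na(i)) i <- match(map[[k]], pnn)
    if (is.na(i)) {
      stop_hspc(paste0("channel for marker '", names(map)[k],
                       "' (", map[[k]], ") not found in FCS file"),
                "hspcmap_channel_error")
    }
    idx[k] <- i
  }
  tab <- as.data.frame(fcs$data[, idx, drop = FALSE], check.names = FALSE)
  names(tab) <- names(map)
  if (!is.null(kw$`$SRC`)) tab$patient_id <- kw$`$SRC`
  if (!is.null(kw$GROUP)) tab$group <- kw$GROUP
  stopifnot(nrow(tab) == as.integer(kw$`$TOT`))
  tab
}
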