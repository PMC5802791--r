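# Standard-format I/O: event tables as CSV, raw signal as EDF.

EVENT_COLUMNS <- c("subject", "site", "session", "session_kind", "list_index",
                   "role", "serial_pos", "word", "onset_ms", "stimulated",
                   "flanking", "recalled", "classifier_prob",
                   "matched_control", "u_latent")

#' Read / write an event table as CSV
#'
#' Event tables serialize to UTF-8 CSV with '.' decimal separator and a
#' fixed, documented column order (see [simulate_recall()] for the fields).
#' Reading validates the schema and the boolean columns, reporting the first
#' offending row and column on failure; probabilities round-trip at full
#' precision.
#'
#' @param events an event table data.frame.
#' @param path file path.
#' @return `read_events` returns the event table; `write_events` its path,
#'   invisibly.
#' @export
write_events <- function(events, path) {
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols))
    stop_memloop("event table lacks column(s): %s",
                 paste(missing_cols, collapse = ", "),
                 class = "memloop_schema_error")
  utils::write.csv(events[, EVENT_COLUMNS], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(EVENT_COLUMNS, names(ev))
  if (length(missing_cols))
    stop_memloop("%s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", "),
                 class = "memloop_schema_error")
  for (col in c("stimulated", "flanking", "recalled", "matched_control")) {
    v <- ev[[col]]
    parsed <- suppressWarnings(as.logical(v))
    bad <- which(is.na(parsed) & !is.na(v))
    if (length(bad))
      stop_memloop("%s row %d: column %s value %s is not a boolean", path,
                   bad[1], col, v[bad[1]], class = "memloop_parse_error")
    ev[[col]] <- parsed
  }
  ev[, EVENT_COLUMNS]
}

#' Write / read a multichannel recording as EDF
#'
#' A minimal European Data Format (EDF, 16-bit) writer and reader for
#' `raw_signal` objects, using one-second data records. Recordings are
#' zero-padded to a whole number of seconds as the format requires; the true
#' sample count is carried in a reserved signal-header field so that sample
#' count and sampling rate round-trip exactly. Each channel is scaled to the
#' full digital range, so the amplitude quantization error is bounded by
#' half a digital step, `(phys_max - phys_min) / (2 * 65534)`.
#'
#' @param raw a `raw_signal`.
#' @param path file path.
#' @return `read_edf` returns a `raw_signal`; `write_edf` its path,
#'   invisibly.
#' @export
write_edf <- function(raw, path) {
  stopifnot(inherits(raw, "raw_signal"))
  ns <- ncol(raw$data)
  nch <- nrow(raw$data)
  fs <- raw$sampling_rate
  if (fs != round(fs))
    stop_memloop("EDF writer requires an integer sampling rate, got %g", fs,
                 class = "memloop_edf_error")
  spr <- as.integer(fs)
  n_rec <- as.integer(ceiling(ns / spr))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * nch
  writeChar(paste0(
    pad("0", 8), pad("synthetic", 80), pad("memloop raw_signal", 80),
    pad("01.01.00", 8), pad("00.00.00", 8), pad(hdr_bytes, 8), pad("", 44),
    pad(n_rec, 8), pad(1L, 8),
    pad(nch, 4)), con, eos = NULL)
  # integer physical range: parses back exactly, so digitization is lossless
  # up to the half-step bound
  phys_max <- pmax(ceiling(apply(abs(raw$data), 1, max)), 1L)
  fld <- function(vals, w) paste(vapply(vals, pad, "", w = w), collapse = "")
  reserved <- c(sprintf("NS=%d", ns), rep("", nch - 1L))
  writeChar(paste0(
    fld(substr(raw$labels, 1, 16), 16), fld(rep("", nch), 80),
    fld(rep("uV", nch), 8),
    fld(format(-phys_max, scientific = FALSE), 8),
    fld(format(phys_max, scientific = FALSE), 8),
    fld(rep(-32767L, nch), 8), fld(rep(32767L, nch), 8),
    fld(rep("", nch), 80), fld(rep(spr, nch), 8), fld(reserved, 32)),
    con, eos = NULL)
  dig <- matrix(0L, nch, spr * n_rec)
  for (ch in seq_len(nch))
    dig[ch, seq_len(ns)] <- as.integer(round(raw$data[ch, ] / phys_max[ch] * 32767))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nch))
      writeBin(dig[ch, cols], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  phys_min <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  reserved <- vapply(seq_len(nch), function(i) rd(32), "")
  data <- matrix(NA_real_, nch, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", spr[ch], size = 2L, endian = "little")
      scale <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      data[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        phys_min[ch] + (dig - dig_min[ch]) * scale
    }
  }
  ns_true <- sub("^NS=", "", reserved[grepl("^NS=", reserved)][1])
  if (!is.na(ns_true) && nzchar(ns_true))
    data <- data[, seq_len(as.integer(ns_true)), drop = FALSE]
  structure(list(data = data, sampling_rate = spr[1] / rec_dur,
                 labels = labels, montage = "monopolar", t0_ms = 0),
            class = "raw_signal")
}
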