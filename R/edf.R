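# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores an ASCII header (256 bytes + 256 per signal, field-major)
# followed by fixed-duration data records of little-endian 16-bit
# integers, linearly mapped between per-signal physical and digital
# ranges.  This implementation covers continuous single-session
# recordings with one second per record, which is what the simulator
# emits (recordings are padded to whole seconds).

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Signals are scaled per channel to the 16-bit digital range; the
#' physical range is the symmetric amplitude maximum, so the
#' round-trip quantization error is at most one step,
#' `(2 * max|x|) / 65535` uV.
#'
#' @param raw an [eeg_recording()] whose duration is a whole number
#'   of seconds.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(raw, path) {
  stopifnot(inherits(raw, "eeg_recording"))
  n <- ncol(raw$data)
  srate <- raw$srate
  if (abs(n / srate - round(n / srate)) > 1e-9) {
    stopf("recording length must be a whole number of seconds for EDF export")
  }
  n_rec <- as.integer(round(n / srate))
  ns <- nrow(raw$data)
  pmax_ <- apply(abs(raw$data), 1, max)
  pmax_[pmax_ == 0] <- 1
  pmin_ <- -pmax_
  dmin <- -32768L
  dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr(sprintf("Startdate 01-JAN-2000 X X ldaepr"), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in raw$channels$label) wr(lab, 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in signif(pmin_, 7)) wr(v, 8)
  for (v in signif(pmax_, 7)) wr(v, 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.integer(srate), 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  spr <- as.integer(srate)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- matrix(0L, spr, ns)
    for (s in seq_len(ns)) {
      d <- round((raw$data[s, idx] - pmin_[s]) * scale[s]) + dmin
      block[, s] <- as.integer(pmin(pmax(d, dmin), dmax))
    }
    writeBin(as.integer(as.vector(block)), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return list with `data` (channels x samples, physical units),
#'   `labels`, `srate`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  if (length(ver) != 1L || is.na(ver) || ver != "0") {
    stopf("malformed EDF: bad or missing version field")
  }
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns <= 0) stopf("malformed EDF: signal count")
  if (header_bytes != 256L * (ns + 1L)) {
    stopf("malformed EDF: header size %d inconsistent with %d signals",
          header_bytes, ns)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    stopf("mixed per-signal sampling rates are not supported")
  }
  expected <- n_rec * sum(spr)
  raw_int <- readBin(con, integer(), n = expected, size = 2L,
                     endian = "little")
  if (length(raw_int) != expected) {
    stopf("malformed EDF: data size does not match header (channel-count or record-count mismatch)")
  }
  n <- n_rec * spr[1]
  data <- matrix(0, ns, n)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- raw_int[(pos + 1L):(pos + spr[s])]
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        pmin_[s] + (seg - dmin[s]) * scale[s]
      pos <- pos + spr[s]
    }
  }
  list(data = data, labels = labels, srate = spr[1] / rec_dur)
}

events_path <- function(path) sub("\\.edf$", ".events.tsv", path)

#' Write a raw recording (EDF + events sidecar)
#'
#' @param raw an [eeg_recording()].
#' @param path target `.edf` path; the events table is written next to
#'   it as `<name>.events.tsv` with columns `onset_s`, `intensity_db`.
#' @return Invisibly, the EDF path.
#' @export
write_raw <- function(raw, path) {
  write_edf(raw, path)
  utils::write.table(raw$events, events_path(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw recording (EDF + events sidecar)
#'
#' @param path `.edf` path written by [write_raw()].
#' @param montage montage table used to restore channel metadata;
#'   labels must match the EDF header.
#' @return An [eeg_recording()].
#' @export
read_raw <- function(path, montage = standard_montage()) {
  e <- read_edf(path)
  ev_path <- events_path(path)
  if (!file.exists(ev_path)) {
    stopf("missing events sidecar: %s", ev_path)
  }
  events <- utils::read.table(ev_path, header = TRUE, sep = "\t")
  if (!all(c("onset_s", "intensity_db") %in% names(events))) {
    stopf("events sidecar lacks onset_s/intensity_db columns")
  }
  idx <- match(e$labels, montage$label)
  if (anyNA(idx)) {
    stopf("EDF channel(s) not in the montage: %s",
          paste(e$labels[is.na(idx)], collapse = ", "))
  }
  eeg_recording(e$data, e$srate, montage[idx, ], events)
}
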