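# Minimal EDF (European Data Format) writer/reader and event-table TSV IO.
# EDF: 256-byte ASCII main header, 256 bytes per signal, then data records
# of little-endian int16 samples scaled between physical and digital
# min/max.  One record per second.  Enough of the format for round-tripping
# continuous multichannel recordings; annotations (EDF+) are not used --
# events travel in a sidecar TSV.

.pad <- function(s, n) {
  s <- substr(as.character(s), 1L, n)
  sprintf(paste0("%-", n, "s"), s)
}

#' Write a recording to an EDF file
#'
#' @param rec an [eeg_recording()].
#' @param path output file path (`.edf`).  Events are written to
#'   `<path>.events.tsv` (columns `onset_seconds`, `condition`) when
#'   present.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- length(rec$channels)
  spr <- as.integer(rec$fs)           # samples per record (1 s records)
  n_rec <- floor(ncol(rec$signal) / spr)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  sig <- rec$signal[, seq_len(n_rec * spr), drop = FALSE]

  pmin <- apply(sig, 1L, min); pmax <- apply(sig, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(.pad("0", 8L), .pad("synthetic", 80L), .pad("recording", 80L),
                .pad(format(Sys.Date(), "%d.%m.%y"), 8L), .pad("00.00.00", 8L),
                .pad(256L * (ns + 1L), 8L), .pad("", 44L),
                .pad(n_rec, 8L), .pad("1", 8L), .pad(ns, 4L))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  fields <- c(vapply(rec$channels, .pad, "", n = 16L),
              rep(.pad("", 80L), ns),                    # transducer
              rep(.pad("uV", 8L), ns),                   # physical dim
              vapply(sprintf("%.8g", pmin), .pad, "", n = 8L),
              vapply(sprintf("%.8g", pmax), .pad, "", n = 8L),
              rep(.pad(dmin, 8L), ns), rep(.pad(dmax, 8L), ns),
              rep(.pad("", 80L), ns),                    # prefiltering
              rep(.pad(spr, 8L), ns), rep(.pad("", 32L), ns))
  writeChar(paste(fields, collapse = ""), con,
            nchars = sum(nchar(fields)), eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((sig[ch, cols] - pmin[ch]) * scale[ch]) + dmin)
      writeBin(pmin(pmax(dig, dmin), dmax), con, size = 2L,
               endian = "little")
    }
  }
  if (nrow(rec$events))
    write_events_tsv(rec$events, paste0(path, ".events.tsv"))
  invisible(path)
}

#' Read an EDF file into an [eeg_recording()]
#'
#' @param path EDF file path.  If `<path>.events.tsv` exists it is read as
#'   the event table.
#' @return an `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16L), ""))
  rd(80L * ns); rd(8L * ns)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  rd(80L * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), ""))
  rd(32L * ns)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  sig <- matrix(NA_real_, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little")
      cols <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      sig[ch, cols] <- pmin[ch] +
        (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
    }
  }
  ev_path <- paste0(path, ".events.tsv")
  events <- if (file.exists(ev_path)) read_events_tsv(ev_path) else
    data.frame(onset = numeric(), condition = character())
  eeg_recording(sig, fs = spr[1L] / rec_dur, channels = labels,
                events = events)
}

#' Write / read event tables as TSV
#'
#' Columns `onset_seconds` and `condition`.
#'
#' @param events data.frame with `onset` and `condition`.
#' @param path TSV path.
#' @return the path (write) or a data.frame with `onset`, `condition`
#'   (read).
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(
    data.frame(onset_seconds = events$onset, condition = events$condition),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  data.frame(onset = d$onset_seconds, condition = d$condition)
}

#' Read a delimited numeric matrix as a recording
#'
#' Expects samples in rows and channels in columns (with a header line of
#' channel labels), or the transpose; whichever dimension matches
#' `channels` is used.
#'
#' @param path delimited text file.
#' @param fs sampling rate in Hz.
#' @param sep field separator (default tab).
#' @param events optional event data.frame.
#' @return an `eeg_recording`.
#' @export
read_matrix_recording <- function(path, fs, sep = "\t",
                                  events = data.frame(onset = numeric(),
                                                      condition = character())) {
  d <- utils::read.table(path, sep = sep, header = TRUE)
  eeg_recording(t(as.matrix(d)), fs = fs, channels = colnames(d),
                events = events)
}
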