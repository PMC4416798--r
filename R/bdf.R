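# Minimal BDF (BioSemi 24-bit) recording I/O. The BDF format is the
# 24-bit variant of EDF: a 256-byte fixed header, one 256-byte header
# block per channel, then data records of little-endian 3-byte two's
# complement integers, channel-blocked within each record.

.pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as a 24-bit BDF file
#'
#' Each channel is scaled to the 24-bit digital range by a common
#' physical range chosen from the data extrema (symmetric, rounded up to
#' a whole microvolt), so quantisation is the only loss. The record
#' duration is 1 s; the recording is zero-padded to a whole number of
#' records (the true sample count is recoverable from the stored
#' duration).
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bdf <- function(rec, path) {
  X <- rec$data
  n_ch <- nrow(X)
  fs <- rec$fs
  if (fs != round(fs)) stop("BDF writer requires an integer sampling rate")
  n <- ncol(X)
  n_rec <- ceiling(n / fs)
  phys_max <- max(1, ceiling(max(abs(range(X)))))
  dig_max <- 8388607
  con <- file(path, "wb")
  on.exit(close(con))
  # fixed header
  writeBin(as.raw(255), con)
  writeChar(.pad("BIOSEMI", 7), con, eos = NULL)
  writeChar(.pad("synthetic treadmill EEG", 80), con, eos = NULL)
  writeChar(.pad(sprintf("session %s", rec$session_id), 80), con, eos = NULL)
  writeChar(.pad("01.01.26", 8), con, eos = NULL)
  writeChar(.pad("00.00.00", 8), con, eos = NULL)
  writeChar(.pad(256 * (1 + n_ch), 8), con, eos = NULL)
  writeChar(.pad("24BIT", 44), con, eos = NULL)
  writeChar(.pad(n_rec, 8), con, eos = NULL)
  writeChar(.pad("1", 8), con, eos = NULL)
  writeChar(.pad(n_ch, 4), con, eos = NULL)
  # per-channel fields, each field for all channels in turn
  for (lab in rec$labels) writeChar(.pad(lab, 16), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(.pad("active electrode", 80), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(.pad("uV", 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(.pad(-phys_max, 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(.pad(phys_max, 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(.pad(-dig_max, 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(.pad(dig_max, 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(.pad("", 80), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(.pad(fs, 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(.pad("", 32), con, eos = NULL)
  # digital data, one record (1 s) at a time
  scale <- dig_max / phys_max
  pad <- n_rec * fs - n
  if (pad > 0) X <- cbind(X, matrix(0, n_ch, pad))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    d <- round(X[, idx, drop = FALSE] * scale)
    d <- pmin(pmax(d, -dig_max), dig_max)
    v <- as.integer(t(d))              # channel-blocked
    v[v < 0] <- v[v < 0] + 16777216L   # two's complement in 24 bits
    b <- matrix(0L, 3, length(v))
    b[1, ] <- v %% 256L
    b[2, ] <- (v %/% 256L) %% 256L
    b[3, ] <- v %/% 65536L
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Read a BDF file written by [write_bdf()]
#'
#' @param path BDF file path.
#' @param events Optional event data.frame to attach (e.g. from
#'   [read_events_tsv()]).
#' @return An `eeg_recording`.
#' @export
read_bdf <- function(path, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 1)
  rd <- function(nc) {
    trimws(readChar(con, nc, useBytes = TRUE))
  }
  if (rd(7) != "BIOSEMI") stop("not a BDF file")
  rd(80); session_info <- rd(80); rd(8); rd(8)
  rd(8)                                # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), character(1))
  for (i in seq_len(n_ch)) rd(80)
  for (i in seq_len(n_ch)) rd(8)
  phys_min <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(n_ch)) rd(80)
  spr <- vapply(seq_len(n_ch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(n_ch)) rd(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  X <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    nb <- n_ch * spr[1] * 3L
    raw <- as.integer(readBin(con, "raw", nb))
    v <- raw[seq(1, nb, 3)] + 256L * raw[seq(2, nb, 3)] +
      65536L * raw[seq(3, nb, 3)]
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    X[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(matrix(v, spr[1], n_ch))
  }
  # undo the digital scaling (gain identical across channels by writer)
  gain <- (phys_max[1] - phys_min[1]) / (dig_max[1] - dig_min[1])
  X <- X * gain
  recording(X, fs, labels, events = events)
}
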