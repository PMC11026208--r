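# File formats: minimal EDF (16-bit, standard 256-byte headers) and
# tab-delimited channel x sample matrices, plus cohort tables as CSV.

#' Write an epoch to an EDF file
#'
#' Minimal EDF writer: standard 256-byte header plus one 256-byte header per
#' signal, 1-second data records, 16-bit little-endian samples scaled from
#' each channel's physical range. Sufficient for round-tripping epochs
#' between tools that speak EDF.
#'
#' @param epoch An [eeg_epoch()] whose sampling rate is an integer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(epoch, path) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  fs <- epoch$fs
  if (fs != round(fs)) stop("EDF writer needs an integer sampling rate", call. = FALSE)
  x <- epoch$data
  nch <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1) stop("epoch shorter than one EDF record (1 s)", call. = FALSE)
  x <- x[, seq_len(n_rec * fs), drop = FALSE]
  # quantise the physical range to what the 8-character header field can
  # carry, so the scaling the reader reconstructs matches the one used here
  phys_min <- floor(apply(x, 1, min) * 100) / 100
  phys_max <- ceiling(apply(x, 1, max) * 100) / 100
  if (any(abs(c(phys_min, phys_max)) >= 99999)) {
    stop("voltages too large for the EDF header fields", call. = FALSE)
  }
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  dig_min <- -32768; dig_max <- 32767
  pad <- function(s, n) {
    s <- substr(s, 1, n)
    sprintf(paste0("%-", n, "s"), s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeChar(pad(s, n), con, nchars = n, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (nch + 1)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(nch), 4)
  for (i in seq_len(nch)) wr(epoch$channel_names[i], 16)
  for (i in seq_len(nch)) wr("EEG", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(sprintf("%.2f", phys_min[i]), 8)
  for (i in seq_len(nch)) wr(sprintf("%.2f", phys_max[i]), 8)
  for (i in seq_len(nch)) wr(as.character(dig_min), 8)
  for (i in seq_len(nch)) wr(as.character(dig_max), 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(as.character(fs), 8)
  for (i in seq_len(nch)) wr("", 32)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(nch)) {
      d <- round((x[i, cols] - phys_min[i]) * gain[i] + dig_min)
      writeBin(as.integer(pmin(pmax(d, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an epoch
#'
#' Reads a standard 16-bit EDF file (as produced by [write_edf()] or common
#' acquisition software). Channel labels are matched case-insensitively
#' against the 9-channel neonatal montage when present.
#'
#' @param path EDF file path.
#' @return An [eeg_epoch()] with reference `"native"`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                               # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  for (i in seq_len(nch)) rd(80)      # transducer
  for (i in seq_len(nch)) rd(8)       # unit
  phys_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nch)) rd(80)      # prefiltering
  nsamp <- vapply(seq_len(nch), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(nsamp)) != 1L) {
    stop("channels with differing rates are not supported", call. = FALSE)
  }
  fs <- nsamp[1] / rec_dur
  x <- matrix(0, nch, n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      d <- readBin(con, integer(), n = nsamp[i], size = 2, endian = "little")
      cols <- ((r - 1) * nsamp[i] + 1):(r * nsamp[i])
      x[i, cols] <- phys_min[i] +
        (d - dig_min[i]) * (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    }
  }
  montage <- neonatal_montage()
  m <- match(tolower(labels), tolower(montage))
  if (!anyNA(m) && length(labels) == 9L) labels <- montage[m]
  eeg_epoch(x, fs, channel_names = labels, reference = "native")
}

#' Write an epoch as a tab-delimited channel x sample matrix
#'
#' One header line of channel names, then one row per channel.
#'
#' @param epoch An [eeg_epoch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_tsv <- function(epoch, path) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(epoch$channel_names, collapse = "\t"), con)
  utils::write.table(t(epoch$data), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited matrix as an epoch
#'
#' @param path Input path (header line of channel names, samples in rows).
#' @param fs Sampling rate in Hz (not stored in the file).
#' @return An [eeg_epoch()].
#' @export
read_epoch_tsv <- function(path, fs) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  eeg_epoch(t(as.matrix(d)), fs, channel_names = colnames(d))
}

#' Write a map set as CSV
#'
#' Rows are maps, columns channels, with a header of channel names.
#'
#' @param mapset A [ms_mapset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapset_csv <- function(mapset, path) {
  stopifnot(inherits(mapset, "ms_mapset"))
  utils::write.csv(as.data.frame(mapset$maps), path, row.names = FALSE)
  invisible(path)
}

#' Read a map set from CSV
#' @param path CSV path written by [write_mapset_csv()].
#' @return A [ms_mapset()].
#' @export
read_mapset_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  ms_mapset(as.matrix(d), channel_names = colnames(d))
}

#' Write the cohort table as CSV
#'
#' Drops the list-columns and writes the per-epoch records (subject, ages,
#' sleep state, ground-truth parameters) with an `epoch_path` column when
#' epoch files were written.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param path Output CSV path.
#' @param epoch_paths Optional character vector of per-epoch file paths.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, epoch_paths = NULL) {
  tab <- dplyr::select(cohort, -dplyr::any_of(c("epoch", "gt_labels")))
  if (!is.null(epoch_paths)) tab$epoch_path <- epoch_paths
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
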