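#' EEG epoch objects
#'
#' An `eeg_epoch` holds one multichannel EEG segment: a channels x samples
#' voltage matrix (microvolts), its sampling rate, channel labels, the
#' reference scheme and an optional sleep-state tag. It is the unit of
#' analysis throughout the package (a 5-minute artefact-free segment in the
#' default configuration).
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of channel labels; defaults to the
#'   9-channel neonatal montage Fp1, Fp2, C3, C4, T3, T4, O1, O2, Cz when the
#'   epoch has nine channels, else `ch1..chC`.
#' @param reference `"native"` or `"common_average"`.
#' @param sleep_state Optional `"QS"` or `"NQS"` tag.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, fs, channel_names = NULL,
                      reference = c("native", "common_average"),
                      sleep_state = NULL) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("epoch data must be a finite numeric matrix", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- if (nrow(data) == 9L) neonatal_montage() else
      paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("channel_names length must match the number of rows", call. = FALSE)
  }
  if (!is.null(sleep_state)) sleep_state <- match.arg(sleep_state, c("QS", "NQS"))
  structure(
    list(data = data, fs = as.numeric(fs), channel_names = channel_names,
         reference = reference, sleep_state = sleep_state),
    class = "eeg_epoch"
  )
}

#' The standard 9-channel neonatal 10-20 montage
#' @return Character vector of the nine channel labels.
#' @export
neonatal_montage <- function() {
  c("Fp1", "Fp2", "C3", "C4", "T3", "T4", "O1", "O2", "Cz")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz (%.1f s), ref=%s%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference,
              if (is.null(x$sleep_state)) "" else paste0(", ", x$sleep_state)))
  invisible(x)
}

#' @export
dim.eeg_epoch <- function(x) dim(x$data)

n_samples <- function(epoch) ncol(epoch$data)
n_channels <- function(epoch) nrow(epoch$data)

is_average_referenced <- function(epoch, tol = 1e-9) {
  if (identical(epoch$reference, "common_average")) return(TRUE)
  cm <- colMeans(epoch$data)
  scale <- max(abs(epoch$data), 1e-300)
  all(abs(cm) <= tol * scale)
}

#' Extract a contiguous epoch from a longer recording
#'
#' Slices `duration_s` seconds starting at `start_s` from a recording and
#' tags the result with the caller-provided sleep state. Sleep labels and
#' artefact-free windows are inputs here (from an external sleep stager or
#' the synthetic generator); no staging is performed.
#'
#' @param recording An `eeg_epoch` (possibly long) to slice from.
#' @param start_s Start time in seconds (0 = first sample).
#' @param duration_s Window length in seconds.
#' @param sleep_state `"QS"` or `"NQS"`.
#' @return An `eeg_epoch` of `round(duration_s * fs)` samples.
#' @export
extract_epoch <- function(recording, start_s, duration_s, sleep_state) {
  stopifnot(inherits(recording, "eeg_epoch"))
  fs <- recording$fs
  i0 <- round(start_s * fs) + 1L
  n <- round(duration_s * fs)
  if (start_s < 0 || i0 + n - 1L > n_samples(recording)) {
    stop("requested window [", start_s, ", ", start_s + duration_s,
         "] s lies outside the recording", call. = FALSE)
  }
  eeg_epoch(recording$data[, i0:(i0 + n - 1L), drop = FALSE], fs,
            recording$channel_names, recording$reference,
            sleep_state = sleep_state)
}
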