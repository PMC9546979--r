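#' Construct a multichannel recording
#'
#' A channels-by-samples matrix of simultaneously recorded time series (EEG
#' electrodes, fMRI ROIs, ...) with its sampling rate, from which windowed
#' connectivity matrices are reconstructed.
#'
#' @param data Numeric matrix, one row per channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Optional character vector of channel names; defaults
#'   to `ch1`, `ch2`, ...
#' @return An object of class `recording`.
#' @export
recording <- function(data, sampling_rate, channel_labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (nrow(data) < 2L) stop("a recording needs at least 2 channels",
                            call. = FALSE)
  if (ncol(data) < 2L) stop("a recording needs at least 2 samples",
                            call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive number (Hz)", call. = FALSE)
  }
  labels <- channel_labels %||% paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    stop("`channel_labels` length must equal the number of channels",
         call. = FALSE)
  }
  structure(list(data = unname(data), sampling_rate = sampling_rate,
                 channel_labels = as.character(labels)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %d channels x %d samples @ %g Hz>\n",
              nrow(x$data), ncol(x$data), x$sampling_rate))
  invisible(x)
}

#' Split a recording into non-overlapping windows
#'
#' Cuts the recording into `floor(samples / tau)` consecutive windows of
#' exactly `tau` samples; the trailing remainder is discarded. Each window is
#' typically turned into one connectivity matrix and treated as an
#' independent group member.
#'
#' @param rec A [recording()].
#' @param tau Window length in samples (default 128).
#' @return List of `recording` objects (possibly empty, with a warning, when
#'   the recording is shorter than `tau`).
#' @export
split_windows <- function(rec, tau = 128L) {
  stopifnot(inherits(rec, "recording"))
  if (!is_count(tau, min = 2L)) stop("`tau` must be an integer >= 2",
                                     call. = FALSE)
  n <- ncol(rec$data)
  k <- n %/% tau
  if (k == 0L) {
    warning(sprintf("recording has %d samples, shorter than tau = %d: %s",
                    n, tau, "no windows produced"), call. = FALSE)
    return(list())
  }
  lapply(seq_len(k), function(i) {
    recording(rec$data[, ((i - 1L) * tau + 1L):(i * tau), drop = FALSE],
              rec$sampling_rate, rec$channel_labels)
  })
}

#' Conventional EEG frequency bands
#'
#' Band edges in Hz used by [bandpass_filter()] when a band is given by
#' name. The paper's analyses sweep such bands; the edges follow the
#' conventional EEG nomenclature and are freely overridable by passing
#' numeric edges instead.
#' @export
eeg_bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 45))

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth filter applied forward and backward
#' ([signal::filtfilt()]), so the output has no phase distortion — phase
#' shifts would bias time-lagged connectivity estimates.
#'
#' @param rec A [recording()].
#' @param band Either a band name from [eeg_bands] (`"alpha"`, ...) or a
#'   numeric `c(low, high)` in Hz; must lie inside (0, Nyquist).
#' @return A filtered `recording` of the same shape and sampling rate.
#' @export
bandpass_filter <- function(rec, band) {
  stopifnot(inherits(rec, "recording"))
  if (is.character(band)) {
    if (!band %in% names(eeg_bands)) {
      stop(sprintf("unknown band '%s'; known bands: %s", band,
                   paste(names(eeg_bands), collapse = ", ")), call. = FALSE)
    }
    band <- eeg_bands[[band]]
  }
  if (length(band) != 2L || !is.numeric(band)) {
    stop("`band` must be a band name or c(low, high) in Hz", call. = FALSE)
  }
  nyq <- rec$sampling_rate / 2
  if (!(band[1L] > 0 && band[1L] < band[2L] && band[2L] < nyq)) {
    stop(sprintf("band edges (%g, %g) Hz must satisfy 0 < low < high < %g",
                 band[1L], band[2L], nyq), call. = FALSE)
  }
  bf <- signal::butter(4L, band / nyq, type = "pass")
  filtered <- t(apply(rec$data, 1L, function(x) {
    signal::filtfilt(bf, x)
  }))
  recording(filtered, rec$sampling_rate, rec$channel_labels)
}

#' Decimate a recording by literal stride
#'
#' Keeps one sample every `stride` (samples 1, 1 + stride, 1 + 2*stride,
#' ...), dividing the sampling rate accordingly. Deliberately applies no
#' anti-alias filtering: the operation emulates acquiring the signal at a
#' lower temporal resolution by literal value-taking.
#'
#' @param rec A [recording()].
#' @param stride Positive integer, at most the number of samples.
#' @return A decimated `recording`.
#' @export
decimate_by_stride <- function(rec, stride) {
  stopifnot(inherits(rec, "recording"))
  if (!is_count(stride)) stop("`stride` must be a positive integer",
                              call. = FALSE)
  n <- ncol(rec$data)
  if (stride > n) stop(sprintf("stride %d exceeds the %d available samples",
                               stride, n), call. = FALSE)
  recording(rec$data[, seq(1L, n, by = stride), drop = FALSE],
            rec$sampling_rate / stride, rec$channel_labels)
}
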