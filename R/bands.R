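#' Define a frequency band
#'
#' @param name Band name (unique within a bank).
#' @param lo_hz,hi_hz Band edges in Hz, `0 < lo_hz < hi_hz`.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, lo_hz, hi_hz) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("band name must be a non-empty string")
  if (!(lo_hz > 0 && hi_hz > lo_hz))
    stop(sprintf("invalid band edges for '%s': need 0 < lo < hi, got [%g, %g]",
                 name, lo_hz, hi_hz))
  structure(list(name = name, lo_hz = as.numeric(lo_hz),
                 hi_hz = as.numeric(hi_hz)), class = "band_spec")
}

#' The canonical five-band EEG bank
#'
#' Delta 1--3, theta 4--7, alpha 8--13, beta 14--30 and gamma 31--50 Hz.
#' The printed gaps between adjacent bands (3--4 Hz, 7--8 Hz, ...) are kept
#' as-is rather than stretched into contiguous edges.
#'
#' @return A named list of [band_spec()] objects in canonical order.
#' @export
default_band_bank <- function() {
  band_bank(list(
    band_spec("delta", 1, 3),
    band_spec("theta", 4, 7),
    band_spec("alpha", 8, 13),
    band_spec("beta", 14, 30),
    band_spec("gamma", 31, 50)))
}

#' Validate and name an ordered collection of bands
#'
#' @param bands List of [band_spec()] objects.
#' @return The same list, named by band, class `band_bank`.
#' @export
band_bank <- function(bands) {
  if (!is.list(bands) || length(bands) < 1L)
    stop("a band bank needs at least one band")
  if (!all(vapply(bands, inherits, logical(1), "band_spec")))
    stop("all elements must be band_spec objects")
  nm <- vapply(bands, function(b) b$name, "")
  if (anyDuplicated(nm)) stop("band names must be unique")
  names(bands) <- nm
  structure(bands, class = "band_bank")
}

# cache of squared-magnitude responses keyed by (order, lo, hi, fs, nfft)
.response_cache <- new.env(parent = emptyenv())

# Amplitude response applied by the zero-phase filter at the nfft FFT bin
# frequencies: |H(w)|^2 for the digital Butterworth band-pass H, i.e. the
# net response of running H forward then backward (filtfilt). Evaluated in
# closed form: a digital Butterworth designed by the bilinear transform with
# pre-warped edges W1, W2 (W = tan(pi f / fs)) has
#   |H(e^{iw})|^2 = 1 / (1 + ((W^2 - W1 W2) / ((W2 - W1) W))^(2 order)),
# with W = tan(w / 2). Direct polynomial evaluation of the 2*order-degree
# transfer function is catastrophically ill-conditioned for the narrow
# low-frequency bands; the closed form is exact and stable.
butter_zero_phase_response <- function(band, sampling_rate_hz, nfft,
                                       order = 5L) {
  key <- sprintf("%d|%g|%g|%g|%d", order, band$lo_hz, band$hi_hz,
                 sampling_rate_hz, nfft)
  hit <- .response_cache[[key]]
  if (!is.null(hit)) return(hit)
  nyq <- sampling_rate_hz / 2
  if (band$hi_hz >= nyq)
    stop(sprintf("band '%s' upper edge %g Hz >= Nyquist %g Hz",
                 band$name, band$hi_hz, nyq))
  w <- 2 * pi * (seq_len(nfft) - 1L) / nfft
  W <- tan(w / 2)
  W1 <- tan(pi * band$lo_hz / sampling_rate_hz)
  W2 <- tan(pi * band$hi_hz / sampling_rate_hz)
  x <- (W^2 - W1 * W2) / ((W2 - W1) * W)
  h2 <- 1 / (1 + x^(2L * order))
  h2[W == 0] <- 0   # DC: the band-pass has a zero at z = 1
  .response_cache[[key]] <- h2
  h2
}

# settling span (samples) used for padding and the minimum-length rule:
# three cycles of the low band edge
band_settle_samples <- function(band, sampling_rate_hz) {
  ceiling(3 * sampling_rate_hz / band$lo_hz)
}

# zero-phase band-pass of a channels x samples matrix via FFT with
# reflect padding; vectorized over channels
bandpass_matrix <- function(x, band, sampling_rate_hz, order = 5L) {
  n <- ncol(x)
  pad <- min(n - 1L, band_settle_samples(band, sampling_rate_hz))
  idx <- c(seq(pad + 1L, 2L, by = -1L), seq_len(n),
           seq(n - 1L, n - pad, by = -1L))
  xp <- x[, idx, drop = FALSE]
  np <- ncol(xp)
  h2 <- butter_zero_phase_response(band, sampling_rate_hz, np, order)
  sp <- stats::mvfft(t(xp))
  y <- Re(stats::mvfft(sp * h2, inverse = TRUE)) / np
  t(y)[, pad + seq_len(n), drop = FALSE]
}

#' Zero-phase band-pass filter of one trial
#'
#' Applies a 5th-order digital Butterworth band-pass with zero net phase:
#' the spectrum is multiplied by the squared magnitude response `|H(w)|^2`
#' (the response of running the filter forward then backward), with
#' reflect padding of one settling span at each end to suppress edge
#' transients. Shape, sampling rate and label are preserved; a sinusoid in
#' the passband comes out with no group delay.
#'
#' @param trial An [eeg_trial()].
#' @param band A [band_spec()].
#' @param order Butterworth order (default 5).
#' @return A filtered `eeg_trial`.
#' @export
bandpass <- function(trial, band, order = 5L) {
  stopifnot(inherits(trial, "eeg_trial"), inherits(band, "band_spec"))
  fs <- trial$sampling_rate_hz
  if (band$hi_hz >= fs / 2)
    stop(sprintf("band '%s' upper edge %g Hz >= Nyquist %g Hz",
                 band$name, band$hi_hz, fs / 2))
  need <- band_settle_samples(band, fs)
  if (ncol(trial$data) < need)
    stop(sprintf(
      "trial %s too short for stable '%s' filtering: %d samples < %d (three cycles of the %g Hz low edge)",
      trial$trial_id, band$name, ncol(trial$data), need, band$lo_hz))
  out <- trial
  out$data <- bandpass_matrix(trial$data, band, fs, order)
  out
}

#' Decompose a trial set into per-band trial sets
#'
#' Runs [bandpass()] for every trial and band; the result is one trial set
#' per band with identical trial order, labels and metadata.
#'
#' @param trials A `trial_set`.
#' @param bank A [band_bank()] (default: the canonical five bands).
#' @param order Butterworth order.
#' @return Named list of `trial_set`, one per band, in bank order.
#' @export
decompose_bands <- function(trials, bank = default_band_bank(), order = 5L) {
  stopifnot(inherits(trials, "trial_set"))
  if (!inherits(bank, "band_bank")) stop("`bank` must be a band_bank")
  out <- lapply(bank, function(b) {
    filtered <- lapply(trials$trials, bandpass, band = b, order = order)
    trial_set(filtered, trials$class_names)
  })
  names(out) <- names(bank)
  out
}
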