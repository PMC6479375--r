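#' Configuration of the synthetic emotion-EEG generator
#'
#' Generates labelled pseudo-EEG with the statistical structure the DE+LDA
#' method assumes: each trial is a sum over bands of band-limited Gaussian
#' noise whose per-channel standard deviation is
#' `exp(base + class effect + subject jitter)`, plus a broadband noise
#' floor. Class information therefore lives purely in band power, which
#' ties the generator's ground truth analytically to the differential
#' entropy the pipeline extracts. The defaults emulate the standard
#' three-class corpus geometry: 15 subjects x 3 sessions x (5 clips x 3
#' classes) = 675 trials of 62 channels at 200 Hz.
#'
#' @param n_subjects,n_sessions,n_clips_per_class Trial-count geometry
#'   (defaults 15, 3, 5 — i.e. 675 trials over 3 classes).
#' @param n_channels Channels per trial (default 62).
#' @param sampling_rate_hz Sampling rate (default 200).
#' @param clip_seconds Trial length in seconds (default 60).
#' @param bands A [band_bank()] (default: the canonical five bands).
#' @param effect K x n_bands matrix of per-class log-SD offsets; row `j`,
#'   column `b` is added to the log standard deviation of band `b` on
#'   loaded channels for class `j - 1`. See [effect_presets()].
#' @param channel_loading Fraction of channels carrying the class effect
#'   (default 0.3); the loaded subset is drawn once from the seed.
#' @param subject_sigma SD of the per-(subject, band, channel) log-SD
#'   jitter — between-subject nuisance variation (default 0.15).
#' @param noise_floor_variance Variance of the broadband white noise floor
#'   (default 0.01).
#' @param base_log_sd Baseline log standard deviation of every band signal
#'   (default 0, i.e. unit SD).
#' @param seed Generator seed; the full dataset is a deterministic
#'   function of the configuration.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 15L, n_sessions = 3L,
                         n_clips_per_class = 5L, n_channels = 62L,
                         sampling_rate_hz = 200, clip_seconds = 60,
                         bands = default_band_bank(),
                         effect = effect_presets()$null,
                         channel_loading = 0.3, subject_sigma = 0.15,
                         noise_floor_variance = 0.01, base_log_sd = 0,
                         seed = 1L) {
  stopifnot(n_subjects >= 1L, n_sessions >= 1L, n_clips_per_class >= 1L,
            n_channels >= 1L, sampling_rate_hz > 0, clip_seconds >= 2,
            channel_loading > 0, channel_loading <= 1,
            subject_sigma >= 0, noise_floor_variance >= 0)
  if (!inherits(bands, "band_bank")) stop("`bands` must be a band_bank")
  effect <- as.matrix(effect)
  if (any(!is.finite(effect))) stop("`effect` must be finite")
  if (ncol(effect) != length(bands))
    stop("`effect` must have one column per band")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 n_clips_per_class = as.integer(n_clips_per_class),
                 n_channels = as.integer(n_channels),
                 sampling_rate_hz = sampling_rate_hz,
                 clip_seconds = clip_seconds, bands = bands,
                 effect = effect, channel_loading = channel_loading,
                 subject_sigma = subject_sigma,
                 noise_floor_variance = noise_floor_variance,
                 base_log_sd = base_log_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Named class-effect presets
#'
#' Per-class log-SD offset matrices (rows = negative/neutral/positive,
#' columns = delta/theta/alpha/beta/gamma):
#' \describe{
#'   \item{null}{all zeros — band power carries no class information, so
#'     downstream accuracy should sit at chance.}
#'   \item{strong}{offsets 0, 0.55 and 1.10 in the beta and gamma columns —
#'     the higher bands carry the emotion signal, with adjacent-class
#'     differential-entropy separation of 0.55 nats on loaded channels
#'     (slightly reduced by the noise floor, staying above 0.5).}
#'   \item{weak}{0.2 x strong.}
#' }
#'
#' @return Named list of 3 x 5 numeric matrices.
#' @export
effect_presets <- function() {
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  classes <- c("negative", "neutral", "positive")
  strong <- matrix(0, 3, 5, dimnames = list(classes, bands))
  strong[, c("beta", "gamma")] <- c(0, 0.55, 1.10)
  list(null = strong * 0, weak = strong * 0.2, strong = strong)
}

# variance gain of the zero-phase band filter on white noise (first pass)
# and on its own output (refiltering), from the applied response H2 = |H|^2:
# first pass multiplies the spectrum by H2 -> variance gain mean(H2^2);
# refiltering the band signal multiplies its spectrum (prop. H2^2) by H2^2
# again -> variance ratio mean(H2^4)/mean(H2^2).
band_filter_gains <- function(band, sampling_rate_hz, n) {
  pad <- min(n - 1L, band_settle_samples(band, sampling_rate_hz))
  h2 <- butter_zero_phase_response(band, sampling_rate_hz, n + 2L * pad)
  list(noise_gain = mean(h2^2),
       refilter_ratio = mean(h2^4) / mean(h2^2))
}

#' Generate a labelled synthetic EEG trial set with ground truth
#'
#' Each trial is built as `sum_b s_b + floor`, where `s_b` is white
#' Gaussian noise band-passed to band `b` (the same zero-phase filter the
#' decomposition stage uses) and rescaled per channel so its variance is
#' exactly the configured `sd^2`, and `floor` is broadband white noise.
#' Labels are balanced across the three classes; the whole dataset is a
#' deterministic function of `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return List with `trials` (a `trial_set`) and `truth`: the true
#'   per-(class, band, channel, subject) standard deviations (`true_sd`),
#'   the loaded channel indices, per-band filter gains (`noise_gain` and
#'   `refilter_ratio`, for predicting what the decomposition stage sees),
#'   and the expected post-decomposition band variances
#'   (`decomposed_variance`, same shape as `true_sd`:
#'   `sd^2 * refilter_ratio + floor * noise_gain`).
#' @export
generate_eeg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  K <- nrow(cfg$effect)
  nb <- length(cfg$bands)
  nch <- cfg$n_channels
  fs <- cfg$sampling_rate_hz
  n <- round(cfg$clip_seconds * fs)
  gains <- lapply(cfg$bands, band_filter_gains, sampling_rate_hz = fs, n = n)
  noise_gain <- vapply(gains, `[[`, 0, "noise_gain")
  refilter <- vapply(gains, `[[`, 0, "refilter_ratio")
  with_seed(cfg$seed, {
    n_loaded <- max(1L, ceiling(cfg$channel_loading * nch))
    loaded <- sort(sample.int(nch, n_loaded))
    load_vec <- as.numeric(seq_len(nch) %in% loaded)
    jitter <- array(stats::rnorm(cfg$n_subjects * nb * nch,
                                 sd = cfg$subject_sigma),
                    dim = c(cfg$n_subjects, nb, nch))
    true_sd <- array(0, dim = c(K, nb, nch, cfg$n_subjects))
    for (j in seq_len(K))
      for (b in seq_len(nb))
        for (s in seq_len(cfg$n_subjects))
          true_sd[j, b, , s] <- exp(cfg$base_log_sd +
                                      cfg$effect[j, b] * load_vec +
                                      jitter[s, b, ])
    trials <- vector("list",
                     cfg$n_subjects * cfg$n_sessions * K * cfg$n_clips_per_class)
    i <- 0L
    for (s in seq_len(cfg$n_subjects)) {
      for (e in seq_len(cfg$n_sessions)) {
        for (j in seq_len(K)) {
          for (c in seq_len(cfg$n_clips_per_class)) {
            x <- matrix(stats::rnorm(nch * n, sd = sqrt(cfg$noise_floor_variance)),
                        nch, n)
            for (b in seq_len(nb)) {
              w <- matrix(stats::rnorm(nch * n), nch, n)
              sb <- bandpass_matrix(w, cfg$bands[[b]], fs)
              x <- x + sb * (true_sd[j, b, , s] / sqrt(noise_gain[b]))
            }
            i <- i + 1L
            trials[[i]] <- eeg_trial(
              x, j - 1L, fs,
              trial_id = sprintf("s%02d_e%d_%s%d", s, e,
                                 substr(DEFAULT_CLASSES[j], 1, 3), c),
              subject_id = sprintf("s%02d", s),
              session_id = sprintf("e%d", e))
          }
        }
      }
    }
    list(trials = trial_set(trials, DEFAULT_CLASSES[seq_len(K)]),
         truth = list(true_sd = true_sd, loaded_channels = loaded,
                      noise_gain = noise_gain, refilter_ratio = refilter,
                      decomposed_variance = sweep(
                        sweep(true_sd^2, 2, refilter, `*`),
                        2, cfg$noise_floor_variance * noise_gain, `+`),
                      config = cfg))
  })
}
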