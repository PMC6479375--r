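# Small in-code fixtures shared across test files.

# one white-noise trial
noise_trial <- function(channels = 2, seconds = 10, fs = 200, sd = 1,
                        label = 0L, seed = 1, trial_id = "t001") {
  set.seed(seed)
  eeg_trial(matrix(rnorm(channels * seconds * fs, sd = sd), channels),
            label, fs, trial_id = trial_id)
}

# a sinusoid trial at a given frequency
sine_trial <- function(freq, seconds = 10, fs = 200, channels = 1) {
  t <- (0:(seconds * fs - 1)) / fs
  eeg_trial(matrix(rep(sin(2 * pi * freq * t), channels), channels,
                   byrow = TRUE), 0L, fs)
}

# the six-point three-class planar configuration with hand-computed scatter
six_point_table <- function() {
  x <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1), c(4, 0), c(4, 1))
  y <- c(0L, 0L, 1L, 1L, 2L, 2L)
  list(x = x, y = y,
       Sw = matrix(c(0, 0, 0, 1.5), 2),    # hand-summed outer products
       Sb = matrix(c(16, 0, 0, 0), 2))
}

# random 2-D three-class instance with nonsingular within-class scatter
random_lda_instance <- function(seed, n_per_class = 20) {
  set.seed(seed)
  mus <- matrix(rnorm(6, sd = 3), 3)
  x <- do.call(rbind, lapply(1:3, function(j)
    sweep(matrix(rnorm(n_per_class * 2), ncol = 2), 2, mus[j, ], `+`)))
  list(x = x, y = rep(0:2, each = n_per_class))
}

# brute-force 1-degree grid of single-direction Fisher quotients
grid_max_quotient <- function(Sw, Sb, step_deg = 1) {
  theta <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  max(vapply(theta, function(a) {
    w <- c(cos(a), sin(a))
    (w %*% Sb %*% w) / (w %*% Sw %*% w)
  }, numeric(1)))
}

# small synthetic dataset for pipeline-level tests
small_synth <- function(effect = effect_presets()$strong, seed = 42,
                        clip_seconds = 6, n_channels = 8, n_subjects = 3,
                        n_sessions = 1, n_clips = 3) {
  generate_eeg(synth_config(
    n_subjects = n_subjects, n_sessions = n_sessions,
    n_clips_per_class = n_clips, n_channels = n_channels,
    clip_seconds = clip_seconds, effect = effect, seed = seed))
}

random_feature_table <- function(n, p, K = 3, seed = 1) {
  set.seed(seed)
  feature_table(matrix(rnorm(n * p), n),
                sample(0:(K - 1), n, replace = TRUE),
                data.frame(channel = paste0("c", seq_len(p)), band = "all",
                           kind = "de", stringsAsFactors = FALSE),
                "random fixture")
}
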