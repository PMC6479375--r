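test_that("default geometry yields 675 balanced trials of 62 x 12000", {
  # geometry check only: counts are forced by the configuration arithmetic
  cfg <- synth_config()
  expect_identical(cfg$n_subjects * cfg$n_sessions * 3L *
                     cfg$n_clips_per_class, 675L)
  gen <- small_synth(n_channels = 5, clip_seconds = 3)
  expect_length(gen$trials, 27)
  expect_equal(unname(table(trial_labels(gen$trials))), rep(9, 3),
               ignore_attr = TRUE)
  expect_identical(dim(gen$trials$trials[[1]]$data), c(5L, 600L))
})

test_that("generation is a deterministic function of the seed", {
  g1 <- small_synth(seed = 7, n_channels = 3, clip_seconds = 3)
  g2 <- small_synth(seed = 7, n_channels = 3, clip_seconds = 3)
  expect_identical(g1$trials$trials[[10]]$data, g2$trials$trials[[10]]$data)
  expect_identical(g1$truth$true_sd, g2$truth$true_sd)
  g3 <- small_synth(seed = 8, n_channels = 3, clip_seconds = 3)
  expect_false(identical(g1$trials$trials[[10]]$data,
                         g3$trials$trials[[10]]$data))
})

test_that("effect presets scale as documented and nulls carry no signal", {
  pr <- effect_presets()
  expect_equal(pr$weak, 0.2 * pr$strong)
  expect_true(all(pr$null == 0))
  expect_true(all(pr$strong[, c("delta", "theta", "alpha")] == 0))
  # null preset: per-band true variances identical across classes
  gen <- small_synth(effect = pr$null, n_channels = 4, clip_seconds = 3)
  v <- gen$truth$true_sd
  expect_equal(v[1, , , ], v[2, , , ])
  expect_equal(v[1, , , ], v[3, , , ])
})

test_that("strong preset separates class DE means by >= 0.5 nats on loaded gamma channels", {
  # oracle: the Gaussian entropy formula applied to the generator's own
  # post-decomposition variances
  gen <- small_synth(effect = effect_presets()$strong, n_channels = 8,
                     clip_seconds = 4, seed = 31)
  v <- gen$truth$decomposed_variance   # class x band x channel x subject
  loaded <- gen$truth$loaded_channels
  g <- which(names(default_band_bank()) == "gamma")
  de <- 0.5 * log(2 * pi * exp(1) * v[, g, , , drop = FALSE])
  for (ch in loaded) {
    mean_by_class <- apply(de[, 1, ch, ], 1, mean)
    expect_gte(min(diff(mean_by_class)), 0.5)
  }
  # null preset: zero separation by construction
  gen0 <- small_synth(effect = effect_presets()$null, n_channels = 4,
                      clip_seconds = 3)
  v0 <- gen0$truth$decomposed_variance
  expect_equal(max(abs(v0[1, , , ] - v0[3, , , ])), 0)
})

test_that("empirical band variance matches ground truth within Monte-Carlo error", {
  gen <- generate_eeg(synth_config(
    n_subjects = 1, n_sessions = 1, n_clips_per_class = 2, n_channels = 4,
    clip_seconds = 30, effect = effect_presets()$strong, seed = 17))
  bank <- default_band_bank()
  bands <- decompose_bands(gen$trials)
  n <- 30 * 200
  devs <- c()
  for (b in seq_along(bank)) {
    # Monte-Carlo SE of the variance of a Gaussian process with spectrum S:
    # relative SE = sqrt(2 mean(S^2) / (n mean(S)^2)); the decomposed band
    # signal has S proportional to |H|^4 (filter applied in generation and
    # again in decomposition)
    h2 <- delda:::butter_zero_phase_response(bank[[b]], 200, n)
    S <- h2^4
    rel_se <- sqrt(2 * mean(S^2) / (n * mean(S)^2))
    for (i in seq_along(gen$trials$trials)) {
      tr <- bands[[b]]$trials[[i]]
      j <- tr$label + 1L
      emp <- apply(tr$data, 1, function(ch) mean(ch^2) - mean(ch)^2)
      truth <- gen$truth$decomposed_variance[j, b, , 1]
      devs <- c(devs, (emp / truth - 1) / rel_se)
    }
  }
  # per-channel deviations are ~N(0, 1): essentially all inside 3 SE, and
  # the max over the 120 draws stays inside 4 SE
  expect_gte(mean(abs(devs) <= 3), 0.95)
  expect_lt(max(abs(devs)), 4)
})

test_that("band-limited signals remain Gaussian (skewness/kurtosis bounds)", {
  gen <- generate_eeg(synth_config(
    n_subjects = 1, n_sessions = 1, n_clips_per_class = 1, n_channels = 2,
    clip_seconds = 60, effect = effect_presets()$null, seed = 5))
  bands <- decompose_bands(gen$trials)
  for (nm in c("alpha", "gamma")) {
    x <- bands[[nm]]$trials[[1]]$data[1, ]
    z <- (x - mean(x)) / sd(x)
    skew <- mean(z^3)
    kurt <- mean(z^4) - 3
    # autocorrelation-widened bounds at n = 12000
    expect_lt(abs(skew), 0.25)
    expect_lt(abs(kurt), 0.6)
  }
})

test_that("extracted DE features recover the generator's entropy ground truth", {
  # closes the front half of the pipeline: generator -> bands -> DE
  gen <- generate_eeg(synth_config(
    n_subjects = 2, n_sessions = 1, n_clips_per_class = 3, n_channels = 4,
    clip_seconds = 20, effect = effect_presets()$strong, seed = 23))
  feats <- extract_features(gen$trials)$de
  bank <- default_band_bank()
  labs <- trial_labels(gen$trials)
  subj <- as.integer(factor(vapply(gen$trials$trials, `[[`, "", "subject_id")))
  wlen <- 200L    # 1-s windows
  nwin <- 20L     # windows per 20-s clip
  devs <- c()
  for (b in seq_along(bank)) {
    tab <- feats$per_band[[names(bank)[b]]]
    # windowed variance of the band signal is ~ chi-square with effective
    # dof k = 2 / relSE^2 (Satterthwaite); the log makes the plug-in DE
    # biased by (digamma(k/2) - log(k/2)) / 2 per window
    h2 <- delda:::butter_zero_phase_response(bank[[b]], 200, wlen)
    S <- h2^4
    rel_se_w <- sqrt(2 * mean(S^2) / (wlen * mean(S)^2))
    k <- 2 / rel_se_w^2
    bias <- 0.5 * (digamma(k / 2) - log(k / 2))
    se_feat <- 0.5 * rel_se_w / sqrt(nwin)
    for (i in seq_len(nrow(tab$values))) {
      truth <- 0.5 * log(2 * pi * exp(1) *
                           gen$truth$decomposed_variance[labs[i] + 1L, b, ,
                                                         subj[i]])
      devs <- c(devs, (tab$values[i, ] - truth - bias) / se_feat)
    }
  }
  expect_gte(mean(abs(devs) <= 3), 0.9)
  expect_lt(max(abs(devs)), 5)
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synth_config(n_channels = 0), "n_channels")
  expect_error(synth_config(effect = matrix(0, 3, 2)), "one column per band")
  expect_error(synth_config(effect = matrix(NA_real_, 3, 5)), "finite")
  expect_error(synth_config(channel_loading = 0), "channel_loading")
})
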