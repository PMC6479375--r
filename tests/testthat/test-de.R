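test_that("gaussian differential entropy matches its closed form", {
  # high-precision evaluation of 1/2 * ln(2*pi*e)
  expect_equal(gaussian_de(1), 0.5 * (log(2 * pi) + 1), tolerance = 1e-14)
  expect_equal(gaussian_de(1), 1.4189385332046727, tolerance = 1e-12)
  expect_equal(gaussian_de(1 / (2 * pi * exp(1))), 0, tolerance = 1e-14)
  # log identity: variance ratio e^2 shifts DE by exactly 1
  v <- c(0.1, 1, 42)
  expect_equal(gaussian_de(exp(2) * v) - gaussian_de(v), rep(1, 3),
               tolerance = 1e-12)
  expect_error(gaussian_de(-1), "non-negative")
})

test_that("windowed DE of white Gaussian noise recovers the closed form", {
  tr <- noise_trial(channels = 2, seconds = 60, sd = 2, seed = 2026)
  de <- trial_de(tr, de_config())
  expect_equal(unname(de[1]), 0.5 * log(2 * pi * exp(1) * 4),
               tolerance = 0.02)
  # two identical channels give identical features
  tr2 <- eeg_trial(rbind(tr$data[1, ], tr$data[1, ]), 0L, 200)
  de2 <- trial_de(tr2)
  expect_identical(de2[[1]], de2[[2]])
})

test_that("degenerate windows hit the variance floor with a warning", {
  tr <- eeg_trial(matrix(0, 1, 1000), 0L, 200)
  expect_warning(de <- trial_de(tr), "floored")
  expect_true(is.finite(de))
  expect_equal(unname(de), gaussian_de(1e-12), tolerance = 1e-12)
})

test_that("DE is scale-equivariant: scaling samples by c shifts DE by ln|c|", {
  tr <- noise_trial(channels = 3, seconds = 10, seed = 4)
  base <- trial_de(tr)
  for (c in c(0.5, 3, 10)) {
    scaled <- tr
    scaled$data <- tr$data * c
    expect_equal(trial_de(scaled) - base, rep(log(c), 3),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("DE estimator error shrinks roughly as 1/sqrt(window count)", {
  # plug-in consistency: longer trials estimate the same DE more tightly
  err_for <- function(seconds, n_rep) {
    vapply(seq_len(n_rep), function(i) {
      tr <- noise_trial(channels = 1, seconds = seconds, sd = 2,
                        seed = 1000 + i)
      trial_de(tr)[[1]] - 0.5 * log(2 * pi * exp(1) * 4)
    }, numeric(1))
  }
  e_short <- sd(err_for(5, 30))
  e_long <- sd(err_for(45, 30))
  expect_lt(e_long, e_short / 2)   # 9x windows -> 3x shrink expected
})

test_that("trial_de rejects trials shorter than one window", {
  tr <- noise_trial(seconds = 3)
  expect_error(trial_de(tr, de_config(window_seconds = 5)), "shorter than")
  expect_error(de_config(window_overlap = 1), "window_overlap")
})

test_that("DE tables have one column per channel per band, plus combined", {
  gen <- small_synth(n_channels = 4, clip_seconds = 4)
  bands <- decompose_bands(gen$trials)
  tabs <- build_de_table(bands)
  expect_length(tabs$per_band, 5)
  expect_identical(dim(tabs$per_band$alpha), c(27L, 4L))
  expect_identical(dim(tabs$combined), c(27L, 20L))
  expect_identical(tabs$combined$labels, trial_labels(gen$trials))
  expect_identical(unique(tabs$combined$meta$kind), "de")
  # band order in the combined table follows bank order
  expect_identical(unique(tabs$combined$meta$band),
                   c("delta", "theta", "alpha", "beta", "gamma"))

  # single band, single channel
  one <- decompose_bands(gen$trials, band_bank(list(band_spec("beta", 14, 30))))
  sub <- trial_set(lapply(one$beta$trials, function(tr) {
    tr$data <- tr$data[1, , drop = FALSE]
    tr$channel_names <- tr$channel_names[1]
    tr
  }), one$beta$class_names)
  t1 <- build_de_table(list(beta = sub))
  expect_identical(dim(t1$combined), c(27L, 1L))

  # shuffled trial order between bands is a misalignment error
  shuffled <- bands
  shuffled$gamma <- trial_set(rev(shuffled$gamma$trials),
                              shuffled$gamma$class_names)
  expect_error(build_de_table(shuffled), "misaligned")
})

test_that("one-pass extraction equals decompose + build tables", {
  gen <- small_synth(n_channels = 3, clip_seconds = 4)
  via_sets <- build_de_table(decompose_bands(gen$trials))
  one_pass <- extract_features(gen$trials, raw_samples_per_channel = 6)
  expect_equal(one_pass$de$combined$values, via_sets$combined$values)
  raw_via <- build_raw_table(decompose_bands(gen$trials),
                             samples_per_channel = 6)
  expect_equal(one_pass$raw$combined$values, raw_via$combined$values)
  expect_identical(unique(one_pass$raw$combined$meta$kind), "raw")
})
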