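#' Configuration for differential-entropy feature extraction
#'
#' Controls how per-channel variances are estimated before the Gaussian
#' differential-entropy formula is applied: the trial is cut into windows,
#' the maximum-likelihood variance (mean-removed, divide by N) is taken per
#' window, each window yields a DE value, and the values are aggregated into
#' one feature per channel.
#'
#' @param window_seconds Window length in seconds (default 1).
#' @param window_overlap Fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0, i.e. non-overlapping).
#' @param variance_floor Variance substituted for degenerate (near-constant)
#'   windows so the logarithm stays finite (default 1e-12).
#' @param aggregate `"mean"` (default) or `"median"` across windows.
#' @return An object of class `de_config`. Entropy is always in nats
#'   (natural logarithm), which makes the `2*pi*e` constant exact.
#' @export
de_config <- function(window_seconds = 1, window_overlap = 0,
                      variance_floor = 1e-12, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(window_seconds > 0, window_overlap >= 0, window_overlap < 1,
            variance_floor > 0)
  structure(list(window_seconds = window_seconds,
                 window_overlap = window_overlap,
                 variance_floor = variance_floor,
                 aggregate = aggregate),
            class = "de_config")
}

#' Differential entropy of a Gaussian variable
#'
#' For `X ~ N(mu, sigma^2)` the differential entropy is
#' `h(X) = 1/2 * ln(2 * pi * e * sigma^2)` nats. Variances below
#' `variance_floor` are floored so the result stays finite.
#'
#' @param variance Non-negative variance(s); vectorized.
#' @param variance_floor Lower floor applied to `variance`.
#' @return Differential entropy in nats, same length as `variance`.
#' @examples
#' gaussian_de(1)              # 1.418939
#' gaussian_de(1 / (2 * pi * exp(1)))  # 0
#' @export
gaussian_de <- function(variance, variance_floor = 1e-12) {
  if (anyNA(variance) || any(variance < 0))
    stop("`variance` must be non-negative")
  0.5 * log(2 * pi * exp(1) * pmax(variance, variance_floor))
}

#' Per-channel differential-entropy features of one band-filtered trial
#'
#' The trial is partitioned into windows per `cfg`; within each window the
#' per-channel maximum-likelihood variance is computed (mean removed,
#' divided by the window length) and converted to differential entropy; the
#' window values are then aggregated (mean by default) into one feature per
#' channel. The trial is expected to be band-filtered already — the feature
#' is the fixed-band differential entropy of that band's signal.
#'
#' @param trial An [eeg_trial()], already band-filtered.
#' @param cfg A [de_config()].
#' @return Named numeric vector of length `channels` (nats).
#' @export
trial_de <- function(trial, cfg = de_config()) {
  stopifnot(inherits(trial, "eeg_trial"), inherits(cfg, "de_config"))
  fs <- trial$sampling_rate_hz
  wlen <- round(cfg$window_seconds * fs)
  if (wlen < 2L)
    stop("window too short: need window_seconds * sampling_rate >= 2 samples")
  n <- ncol(trial$data)
  if (n < wlen)
    stop(sprintf("trial %s shorter than one %g s window (%d < %d samples)",
                 trial$trial_id, cfg$window_seconds, n, wlen))
  step <- max(1L, round(wlen * (1 - cfg$window_overlap)))
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  de <- matrix(0, nrow(trial$data), length(starts))
  floored <- FALSE
  for (k in seq_along(starts)) {
    w <- trial$data[, starts[k] + 0:(wlen - 1L), drop = FALSE]
    v <- rowMeans(w * w) - rowMeans(w)^2   # ML variance, mean removed
    if (any(v < cfg$variance_floor)) floored <- TRUE
    de[, k] <- gaussian_de(pmax(v, 0), cfg$variance_floor)
  }
  if (floored)
    warning(sprintf("trial %s: degenerate window variance floored at %g",
                    trial$trial_id, cfg$variance_floor))
  out <- if (cfg$aggregate == "mean") rowMeans(de)
         else apply(de, 1, stats::median)
  names(out) <- trial$channel_names
  out
}

# alignment check shared by the table builders
check_band_alignment <- function(band_sets) {
  if (!is.list(band_sets) || length(band_sets) < 1L || is.null(names(band_sets)))
    stop("`band_sets` must be a named list of trial_set objects")
  ref <- band_sets[[1]]
  ref_ids <- trial_ids(ref)
  ref_labs <- trial_labels(ref)
  for (nm in names(band_sets)) {
    s <- band_sets[[nm]]
    if (!inherits(s, "trial_set")) stop("band '", nm, "' is not a trial_set")
    if (!identical(trial_ids(s), ref_ids) ||
        !identical(trial_labels(s), ref_labs))
      stop("band sets are misaligned: trial order/labels differ for band '",
           nm, "'")
  }
  invisible(TRUE)
}

#' Build per-band and combined differential-entropy feature tables
#'
#' One row per trial, one column per channel within each band; the combined
#' table concatenates the per-band tables in bank order (62 channels x 5
#' bands = 310 columns for the standard geometry).
#'
#' @param band_sets Named list of aligned `trial_set`s, as produced by
#'   [decompose_bands()].
#' @param cfg A [de_config()].
#' @return List with `per_band` (named list of `feature_table`) and
#'   `combined` (one `feature_table`).
#' @export
build_de_table <- function(band_sets, cfg = de_config()) {
  check_band_alignment(band_sets)
  labs <- trial_labels(band_sets[[1]])
  per_band <- lapply(names(band_sets), function(nm) {
    s <- band_sets[[nm]]
    vals <- vapply(s$trials, trial_de, cfg = cfg,
                   numeric(nrow(s$trials[[1]]$data)))
    vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1)
    feature_table(vals, labs,
                  data.frame(channel = s$trials[[1]]$channel_names,
                             band = nm, kind = "de",
                             stringsAsFactors = FALSE),
                  provenance = sprintf("de features, band %s", nm))
  })
  names(per_band) <- names(band_sets)
  list(per_band = per_band,
       combined = combine_feature_tables(per_band,
                                         "de features, combined bands"))
}

#' Build per-band and combined raw-signal feature tables
#'
#' The "raw" baseline condition uses the band-filtered time samples
#' themselves as features. To keep the feature count tractable the samples
#' are decimated to `samples_per_channel` evenly spaced time points per
#' channel per band; class information carried by band power is unaffected
#' by the decimation.
#'
#' @param band_sets Named list of aligned `trial_set`s.
#' @param samples_per_channel Time points kept per channel per band.
#' @return List with `per_band` and `combined`, as [build_de_table()].
#' @export
build_raw_table <- function(band_sets, samples_per_channel = 16L) {
  check_band_alignment(band_sets)
  labs <- trial_labels(band_sets[[1]])
  per_band <- lapply(names(band_sets), function(nm) {
    s <- band_sets[[nm]]
    n <- ncol(s$trials[[1]]$data)
    keep <- unique(round(seq(1, n, length.out = samples_per_channel)))
    chn <- s$trials[[1]]$channel_names
    vals <- vapply(s$trials,
                   function(tr) as.vector(t(tr$data[, keep, drop = FALSE])),
                   numeric(nrow(s$trials[[1]]$data) * length(keep)))
    vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1)
    feature_table(vals, labs,
                  data.frame(channel = paste0(rep(chn, each = length(keep)),
                                              "#", rep(keep, length(chn))),
                             band = nm, kind = "raw",
                             stringsAsFactors = FALSE),
                  provenance = sprintf("raw band samples, band %s", nm))
  })
  names(per_band) <- names(band_sets)
  list(per_band = per_band,
       combined = combine_feature_tables(per_band,
                                         "raw band samples, combined bands"))
}

#' One-pass feature extraction without storing filtered trial sets
#'
#' Equivalent to [decompose_bands()] followed by [build_de_table()] (and
#' optionally [build_raw_table()]), but filters one trial at a time so only
#' the feature tables are kept in memory — the practical route for
#' full-size runs.
#'
#' @param trials A `trial_set`.
#' @param bank A [band_bank()].
#' @param cfg A [de_config()].
#' @param raw_samples_per_channel If non-`NULL`, also build the decimated
#'   raw tables with this many time points per channel.
#' @return List with `de` and (optionally) `raw`, each a list of
#'   `per_band` + `combined` tables.
#' @export
extract_features <- function(trials, bank = default_band_bank(),
                             cfg = de_config(),
                             raw_samples_per_channel = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  labs <- trial_labels(trials)
  chn <- trials$trials[[1]]$channel_names
  fs <- trials$trials[[1]]$sampling_rate_hz
  n <- ncol(trials$trials[[1]]$data)
  keep <- if (!is.null(raw_samples_per_channel))
    unique(round(seq(1, n, length.out = raw_samples_per_channel)))
  de_bands <- list()
  raw_bands <- list()
  for (nm in names(bank)) {
    b <- bank[[nm]]
    de_vals <- matrix(0, length(trials$trials), length(chn))
    raw_vals <- if (!is.null(keep))
      matrix(0, length(trials$trials), length(chn) * length(keep))
    for (i in seq_along(trials$trials)) {
      ftr <- bandpass(trials$trials[[i]], b)
      de_vals[i, ] <- trial_de(ftr, cfg)
      if (!is.null(keep))
        raw_vals[i, ] <- as.vector(t(ftr$data[, keep, drop = FALSE]))
    }
    de_bands[[nm]] <- feature_table(
      de_vals, labs,
      data.frame(channel = chn, band = nm, kind = "de",
                 stringsAsFactors = FALSE),
      sprintf("de features, band %s", nm))
    if (!is.null(keep))
      raw_bands[[nm]] <- feature_table(
        raw_vals, labs,
        data.frame(channel = paste0(rep(chn, each = length(keep)), "#",
                                    rep(keep, length(chn))),
                   band = nm, kind = "raw", stringsAsFactors = FALSE),
        sprintf("raw band samples, band %s", nm))
  }
  out <- list(de = list(
    per_band = de_bands,
    combined = combine_feature_tables(de_bands, "de features, combined bands")))
  if (!is.null(keep))
    out$raw <- list(
      per_band = raw_bands,
      combined = combine_feature_tables(raw_bands,
                                        "raw band samples, combined bands"))
  out
}
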