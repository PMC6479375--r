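#' Emotion classes and their default integer encoding
#'
#' The three-class emotion labelling used throughout the package:
#' negative = 0, neutral = 1, positive = 2. The order is configurable in
#' most constructors but this vector is the documented default.
#'
#' @format Character vector of length 3.
#' @export
DEFAULT_CLASSES <- c("negative", "neutral", "positive")

#' Construct a single labelled EEG trial
#'
#' A trial is one full movie-clip recording: a channels-by-samples matrix of
#' preprocessed EEG (typically 200 Hz, 0.5--70 Hz band-limited) with one
#' categorical emotion label. Windowing for feature extraction happens later;
#' the trial is the sample unit of the whole pipeline.
#'
#' @param data Numeric matrix, channels x samples.
#' @param label Integer class code in `0:(K-1)` (default encoding:
#'   negative = 0, neutral = 1, positive = 2).
#' @param sampling_rate_hz Sampling rate in Hz (positive).
#' @param trial_id,subject_id,session_id Identifier strings.
#' @param channel_names Character vector, one name per row of `data`.
#'   Defaults to `"ch01"`, `"ch02"`, ...
#' @return An object of class `eeg_trial`.
#' @examples
#' tr <- eeg_trial(matrix(rnorm(2 * 400), 2), label = 0, sampling_rate_hz = 200)
#' tr
#' @export
eeg_trial <- function(data, label, sampling_rate_hz,
                      trial_id = "t001", subject_id = "s01", session_id = "e1",
                      channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (anyNA(data) || any(!is.finite(data)))
    stop("trial data contains non-finite values")
  if (nrow(data) < 1L) stop("a trial needs at least one channel")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be a single positive number")
  if (ncol(data) < 2 * sampling_rate_hz)
    stop(sprintf(
      "trial too short: %d samples < 2 s at %g Hz (need >= %d)",
      ncol(data), sampling_rate_hz, ceiling(2 * sampling_rate_hz)))
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label < 0L)
    stop("`label` must be a single non-negative integer class code")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("`channel_names` length must equal the number of channels")
  structure(
    list(trial_id = as.character(trial_id),
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         label = label,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         data = data,
         channel_names = as.character(channel_names)),
    class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial %s> subject %s, session %s, label %d\n",
              x$trial_id, x$subject_id, x$session_id, x$label))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              ncol(x$data) / x$sampling_rate_hz))
  invisible(x)
}

#' Construct a set of EEG trials
#'
#' Bundles trials that share a sampling rate and channel layout, together
#' with the ordered class names that define the integer label encoding.
#'
#' @param trials List of [eeg_trial()] objects.
#' @param class_names Ordered class names; position `k` is label code `k - 1`.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, class_names = DEFAULT_CLASSES) {
  if (!is.list(trials) || length(trials) < 1L)
    stop("`trials` must be a non-empty list of eeg_trial objects")
  if (!all(vapply(trials, inherits, logical(1), "eeg_trial")))
    stop("all elements of `trials` must be eeg_trial objects")
  fs <- unique(vapply(trials, function(t) t$sampling_rate_hz, numeric(1)))
  if (length(fs) != 1L)
    stop("all trials in a set must share one sampling rate; found: ",
         paste(fs, collapse = ", "))
  nch <- unique(vapply(trials, function(t) nrow(t$data), integer(1)))
  if (length(nch) != 1L)
    stop("all trials in a set must share one channel count; found: ",
         paste(nch, collapse = ", "))
  labs <- vapply(trials, function(t) t$label, integer(1))
  if (any(labs >= length(class_names)))
    stop("trial labels exceed the number of class names")
  structure(list(trials = trials, class_names = as.character(class_names)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  labs <- trial_labels(x)
  tab <- table(factor(labs, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  cat(sprintf("<trial_set> %d trials, %d channels @ %g Hz\n",
              length(x$trials), nrow(x$trials[[1]]$data),
              x$trials[[1]]$sampling_rate_hz))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' Integer labels of a trial set
#' @param x A `trial_set`.
#' @return Integer vector of class codes, one per trial.
#' @export
trial_labels <- function(x) {
  stopifnot(inherits(x, "trial_set"))
  vapply(x$trials, function(t) t$label, integer(1))
}

#' Trial identifiers of a trial set
#' @param x A `trial_set`.
#' @return Character vector of trial ids.
#' @export
trial_ids <- function(x) {
  stopifnot(inherits(x, "trial_set"))
  vapply(x$trials, function(t) t$trial_id, character(1))
}
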