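# Minimal EDF (European Data Format) I/O: continuous recordings, identical
# sampling rate across signals, 16-bit samples with per-signal physical
# scaling. Covers the interchange needs of this pipeline, not EDF+ annotations.

# ascii header field, right-padded with spaces to `n` bytes
edf_field <- function(x, n) {
  s <- as.character(x)
  if (nchar(s) > n) s <- substr(s, 1, n)
  formatC(s, width = -n, flag = " ")
}

# shortest decimal representation of a number fitting an 8-char ascii field
edf_num <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot represent ", x, " in an 8-character EDF field")
}

#' Write one multichannel recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric physical range
#' `[-m, m]` with `m = max(|data|)` per channel, so the worst-case
#' round-trip error per channel is `m / 32767` (half a quantization step
#' below that bound).
#'
#' @param data Numeric matrix, channels x samples.
#' @param path Output path.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param channel_names One name per channel (<= 16 ascii characters used).
#' @param patient,recording Free-text EDF header fields (80 characters).
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, path, sampling_rate_hz,
                      channel_names = NULL,
                      patient = "X", recording = "X") {
  stopifnot(is.matrix(data), is.numeric(data))
  ns <- nrow(data)
  n <- ncol(data)
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(ns))
  # 1-second records when the length allows, otherwise one whole-trial record
  if (n %% sampling_rate_hz == 0 && sampling_rate_hz == round(sampling_rate_hz)) {
    spr <- as.integer(sampling_rate_hz)
    nrec <- n %/% spr
    dur <- 1
  } else {
    spr <- n
    nrec <- 1L
    dur <- n / sampling_rate_hz
  }
  phys_max <- apply(abs(data), 1, max)
  phys_max[phys_max == 0] <- 1
  dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(patient, 80),
    edf_field(recording, 80),
    edf_field("01.01.20", 8),
    edf_field("00.00.00", 8),
    edf_field(256L * (ns + 1L), 8),
    edf_field("", 44),
    edf_field(nrec, 8),
    edf_field(edf_num(dur), 8),
    edf_field(ns, 4))
  sig <- paste0(
    paste(vapply(channel_names, edf_field, "", n = 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(-phys_max, function(x) edf_field(edf_num(x), 8), ""),
          collapse = ""),
    paste(vapply(phys_max, function(x) edf_field(edf_num(x), 8), ""),
          collapse = ""),
    paste(rep(edf_field(-dig_max, 8), ns), collapse = ""),
    paste(rep(edf_field(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(spr, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  # digital samples, record-major then signal-major inside each record
  dig <- round(sweep(data, 1, dig_max / phys_max, `*`))
  storage.mode(dig) <- "integer"
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain continuous EDF)
#'
#' Requires all signals to share one samples-per-record value; EDF+
#' annotation signals are not supported.
#'
#' @param path EDF file path.
#' @return List with `data` (channels x samples matrix), `sampling_rate_hz`,
#'   `channel_names`, `patient`, `recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    if (length(raw) < n) stop("truncated EDF header in ", path)
    trimws(rawToChar(raw))
  }
  rd(8)                       # version
  patient <- rd(80)
  recording <- rd(80)
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  rd(44)                      # reserved
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header (signal count) in ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")   # transducer
  vapply(seq_len(ns), function(i) rd(8), "")    # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")   # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF with heterogeneous samples-per-record is not supported: ", path)
  spr1 <- spr[1]
  n <- nrec * spr1
  data <- matrix(0, ns, n)
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = ns * spr1, size = 2L, signed = TRUE,
                     endian = "little")
    if (length(block) < ns * spr1) stop("truncated EDF data in ", path)
    data[, ((r - 1L) * spr1 + 1L):(r * spr1)] <-
      matrix(block, nrow = ns, byrow = TRUE)
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- sweep(sweep(data, 1, dmin, `-`), 1, scale, `*`) + pmin
  list(data = data, sampling_rate_hz = spr1 / dur, channel_names = labels,
       patient = patient, recording = recording)
}

#' Write a trial set as one EDF file per trial plus a label sidecar
#'
#' The sidecar is a tab-separated table with columns `file`, `subject`,
#' `session`, `label` (label as class name), readable back with
#' [read_edf_trials()].
#'
#' @param trials A `trial_set`.
#' @param dir Output directory (created if needed).
#' @param sidecar Sidecar file name within `dir`.
#' @return Character vector of written EDF paths, invisibly.
#' @export
write_edf_trials <- function(trials, dir, sidecar = "labels.tsv") {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(trials$trials))
  rows <- vector("list", length(trials$trials))
  for (i in seq_along(trials$trials)) {
    tr <- trials$trials[[i]]
    files[i] <- paste0(tr$trial_id, ".edf")
    write_edf(tr$data, file.path(dir, files[i]), tr$sampling_rate_hz,
              tr$channel_names, patient = tr$subject_id,
              recording = tr$trial_id)
    rows[[i]] <- data.frame(file = files[i], subject = tr$subject_id,
                            session = tr$session_id,
                            label = trials$class_names[tr$label + 1L],
                            stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), file.path(dir, sidecar),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, files))
}

#' Read labelled EEG trials from EDF files and a label sidecar
#'
#' @param edf_paths Character vector of EDF file paths, one trial each.
#' @param label_sidecar Path to a tab-separated sidecar with columns `file`,
#'   `subject`, `session`, `label`; `file` entries are matched against
#'   `basename(edf_paths)` and labels must be members of `class_names`.
#' @param class_names Ordered class names defining the integer encoding.
#' @return A `trial_set`. Channel order is taken from the first file and
#'   enforced on the rest (files with the same channels in a different order
#'   are reordered; different channel sets are an error).
#' @export
read_edf_trials <- function(edf_paths, label_sidecar,
                            class_names = DEFAULT_CLASSES) {
  side <- utils::read.table(label_sidecar, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("file", "subject", "session", "label")
  if (!all(need %in% names(side)))
    stop("label sidecar must have columns: ", paste(need, collapse = ", "))
  bad_lab <- setdiff(unique(side$label), class_names)
  if (length(bad_lab))
    stop("sidecar labels not in class_names: ", paste(bad_lab, collapse = ", "))
  trials <- vector("list", length(edf_paths))
  ref_names <- NULL
  ref_fs <- NULL
  for (i in seq_along(edf_paths)) {
    p <- edf_paths[i]
    row <- side[side$file == basename(p), , drop = FALSE]
    if (nrow(row) == 0L)
      stop("no label in sidecar for file: ", basename(p))
    e <- read_edf(p)
    if (is.null(ref_names)) {
      ref_names <- e$channel_names
      ref_fs <- e$sampling_rate_hz
    } else {
      if (e$sampling_rate_hz != ref_fs)
        stop(sprintf("mixed sampling rates: %s has %g Hz, expected %g Hz",
                     basename(p), e$sampling_rate_hz, ref_fs))
      if (length(e$channel_names) != length(ref_names))
        stop(sprintf("channel count mismatch: %s has %d channels, expected %d",
                     basename(p), length(e$channel_names), length(ref_names)))
      if (!identical(e$channel_names, ref_names)) {
        if (!setequal(e$channel_names, ref_names))
          stop("channel names of ", basename(p),
               " do not match the first file")
        e$data <- e$data[match(ref_names, e$channel_names), , drop = FALSE]
      }
    }
    trials[[i]] <- eeg_trial(
      e$data, match(row$label[1], class_names) - 1L, ref_fs,
      trial_id = sub("\\.edf$", "", basename(p), ignore.case = TRUE),
      subject_id = row$subject[1], session_id = row$session[1],
      channel_names = ref_names)
  }
  trial_set(trials, class_names)
}
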