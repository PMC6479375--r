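#' Define the resampling protocol of the benchmark
#'
#' The default mirrors the benchmark protocol: repeated stratified holdout
#' with 70% training / 30% validation, 200 repeats. Stratified k-fold
#' cross-validation (5 folds) is available as an alternative mode.
#'
#' @param mode `"repeated_holdout"` (default) or `"kfold"`.
#' @param train_fraction Training fraction for holdout mode (default 0.7).
#' @param repeats Number of holdout repeats (default 200).
#' @param folds Number of folds for k-fold mode (default 5).
#' @param stratified Preserve class proportions per split (default TRUE).
#' @param seed Base seed; together with the repeat index it fully
#'   determines every split.
#' @return An object of class `split_protocol`.
#' @export
split_protocol <- function(mode = c("repeated_holdout", "kfold"),
                           train_fraction = 0.7, repeats = 200L,
                           folds = 5L, stratified = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(train_fraction > 0, train_fraction < 1, repeats >= 1L,
            folds >= 2L)
  structure(list(mode = mode, train_fraction = train_fraction,
                 repeats = as.integer(repeats), folds = as.integer(folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_protocol")
}

n_splits <- function(protocol) {
  if (protocol$mode == "kfold") protocol$folds else protocol$repeats
}

#' One reproducible train/validation split
#'
#' Holdout mode draws a stratified 70/30 (by default) split; per-class
#' training quotas are `floor(f * N_j)` with the remainder up to
#' `floor(f * n)` distributed by largest fractional part, so class
#' proportions are preserved within one sample. K-fold mode deals each
#' class round-robin into folds (shuffled once from the base seed) and
#' `repeat_index` selects the validation fold. Identical
#' `(seed, repeat_index)` always reproduce the same split.
#'
#' @param labels Integer class labels for all samples.
#' @param protocol A [split_protocol()].
#' @param repeat_index Which repeat (holdout) or fold (k-fold), 1-based.
#' @return List with integer index vectors `train` and `valid` (disjoint;
#'   exhaustive in k-fold mode).
#' @export
make_split <- function(labels, protocol, repeat_index = 1L) {
  stopifnot(inherits(protocol, "split_protocol"))
  labels <- as.integer(labels)
  n <- length(labels)
  classes <- sort(unique(labels))
  if (n == 0L || n < length(classes)) stop("fewer samples than classes")
  cnt <- table(factor(labels, levels = classes))
  if (any(cnt < 2L))
    stop("every class needs at least 2 samples to split; counts: ",
         paste(cnt, collapse = ", "))
  if (protocol$mode == "kfold") {
    if (repeat_index < 1L || repeat_index > protocol$folds)
      stop("repeat_index out of 1..folds")
    fold_of <- integer(n)
    with_seed(derive_seed(protocol$seed, 0L), {
      for (cl in classes) {
        idx <- sample(which(labels == cl))
        fold_of[idx] <- rep_len(seq_len(protocol$folds), length(idx))
      }
    })
    valid <- which(fold_of == repeat_index)
    return(list(train = setdiff(seq_len(n), valid), valid = valid))
  }
  f <- protocol$train_fraction
  quota <- floor(f * as.numeric(cnt))
  total <- floor(f * n + 1e-9)
  extra <- total - sum(quota)
  if (extra > 0) {
    frac <- f * as.numeric(cnt) - quota
    give <- order(-frac, seq_along(frac))[seq_len(extra)]
    quota[give] <- quota[give] + 1L
  }
  train <- integer(0)
  with_seed(derive_seed(protocol$seed, repeat_index), {
    if (protocol$stratified) {
      for (k in seq_along(classes)) {
        idx <- which(labels == classes[k])
        train <- c(train, sample(idx, quota[k]))
      }
    } else {
      train <- sample(seq_len(n), total)
    }
  })
  train <- sort(train)
  list(train = train, valid = setdiff(seq_len(n), train))
}

#' Run one experimental condition of the benchmark
#'
#' The four conditions correspond to the four feature-extraction arms:
#' `raw` (band-filtered samples as-is), `lda` (raw + discriminant
#' projection), `de` (differential-entropy features) and `de_lda`
#' (differential entropy + discriminant projection — the fused method).
#' For the `lda`/`de_lda` arms the projection is fitted on each training
#' split only and applied to its validation split. Every
#' (band + combined) x classifier x split cell records accuracy, macro
#' precision/recall/F1, Cohen's kappa and classifier fit+predict seconds.
#'
#' @param tables Named list of `feature_table`s, one per band; a
#'   `"combined"` entry is added from the rest if absent. For `raw`/`lda`
#'   pass raw tables, for `de`/`de_lda` pass DE tables.
#' @param condition One of `"raw"`, `"lda"`, `"de"`, `"de_lda"`.
#' @param classifiers List of [classifier_spec()]s
#'   (default: all five).
#' @param protocol A [split_protocol()].
#' @param d,gamma Discriminant projection dimension and shrinkage for the
#'   `lda`/`de_lda` arms.
#' @param bands Optional subset of band names to run.
#' @return An object of class `eval_report`: `per_split` data frame,
#'   `aggregates` (mean and sd per cell), `confusion` (summed K x K
#'   matrices per cell) and the protocol.
#' @export
run_condition <- function(tables, condition = c("raw", "lda", "de", "de_lda"),
                          classifiers = default_classifiers(),
                          protocol = split_protocol(), d = 2L, gamma = 1e-6,
                          bands = NULL) {
  if (length(condition) != 1L || !condition %in% c("raw", "lda", "de", "de_lda"))
    stop("unknown condition: ", paste(condition, collapse = ","),
         " (expected raw, lda, de or de_lda)")
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (inherits(classifiers, "classifier_spec"))
    classifiers <- stats::setNames(list(classifiers), classifiers$name)
  if (!"combined" %in% names(tables) && length(tables) > 1L)
    tables$combined <- combine_feature_tables(tables)
  lab0 <- tables[[1]]$labels
  for (nm in names(tables))
    if (!identical(tables[[nm]]$labels, lab0))
      stop("feature tables are misaligned across bands: labels differ for '",
           nm, "'")
  if (!is.null(bands)) tables <- tables[intersect(bands, names(tables))]
  K <- length(unique(lab0))
  use_lda <- condition %in% c("lda", "de_lda")
  rows <- list()
  confusion <- list()
  for (band in names(tables)) {
    tab <- tables[[band]]
    for (r in seq_len(n_splits(protocol))) {
      sp <- make_split(tab$labels, protocol, r)
      xtr <- tab$values[sp$train, , drop = FALSE]
      xva <- tab$values[sp$valid, , drop = FALSE]
      ytr <- tab$labels[sp$train]
      yva <- tab$labels[sp$valid]
      feat_sec <- 0
      if (use_lda) {
        t0 <- proc.time()[["elapsed"]]
        proj <- fisher_lda(xtr, ytr, d = d, gamma = gamma)
        xtr <- predict(proj, xtr)
        xva <- predict(proj, xva)
        feat_sec <- proc.time()[["elapsed"]] - t0
      }
      for (cl in names(classifiers)) {
        res <- fit_predict(classifiers[[cl]], xtr, ytr, xva, K,
                           seed = derive_seed(protocol$seed, r * 131L +
                                                match(cl, names(classifiers))))
        m <- compute_metrics(yva, res$pred, K)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = condition, band = band, classifier = cl, split = r,
          accuracy = m$accuracy, precision = m$precision, recall = m$recall,
          f1 = m$f1, kappa = m$kappa, seconds = res$seconds,
          feature_seconds = feat_sec, stringsAsFactors = FALSE)
        key <- paste(band, cl, sep = "|")
        confusion[[key]] <- if (is.null(confusion[[key]])) m$confusion
                            else confusion[[key]] + m$confusion
      }
    }
  }
  per_split <- do.call(rbind, rows)
  structure(list(condition = condition, per_split = per_split,
                 aggregates = aggregate_splits(per_split),
                 confusion = confusion, protocol = protocol,
                 n_classes = K),
            class = "eval_report")
}

aggregate_splits <- function(per_split) {
  metrics <- c("accuracy", "precision", "recall", "f1", "kappa",
               "seconds", "feature_seconds")
  key <- interaction(per_split$condition, per_split$band,
                     per_split$classifier, drop = TRUE, lex.order = TRUE)
  out <- lapply(levels(key), function(k) {
    sub <- per_split[key == k, , drop = FALSE]
    row <- sub[1, c("condition", "band", "classifier")]
    row$n_splits <- nrow(sub)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]])
      row[[paste0(m, "_sd")]] <- if (nrow(sub) > 1) stats::sd(sub[[m]]) else 0
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$band, out$classifier), ]
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> condition '%s', %d splits (%s)\n",
              x$condition, n_splits(x$protocol), x$protocol$mode))
  agg <- x$aggregates
  cat(sprintf("  %-9s %-5s acc %.3f±%.3f  kappa %.3f±%.3f  f1 %.3f\n",
              agg$band, agg$classifier, agg$accuracy_mean, agg$accuracy_sd,
              agg$kappa_mean, agg$kappa_sd, agg$f1_mean), sep = "")
  invisible(x)
}

#' Merge evaluation reports from several conditions
#' @param reports List of `eval_report`s.
#' @return A combined `eval_report` (condition `"all"`).
#' @export
merge_reports <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "eval_report")))
  per_split <- do.call(rbind, lapply(reports, `[[`, "per_split"))
  confusion <- list()
  for (rep in reports)
    for (key in names(rep$confusion))
      confusion[[paste(rep$condition, key, sep = "|")]] <- rep$confusion[[key]]
  structure(list(condition = "all", per_split = per_split,
                 aggregates = aggregate_splits(per_split),
                 confusion = confusion, protocol = reports[[1]]$protocol,
                 n_classes = reports[[1]]$n_classes),
            class = "eval_report")
}

#' Export an evaluation report as tab-separated tables
#'
#' Writes `metrics.tsv` (per-cell mean and sd of every metric),
#' `per_split_accuracy.tsv` (the long table box plots are drawn from),
#' `confusion.tsv` (summed confusion matrices in long form) and
#' `timing.tsv`. Ordering is deterministic, so re-exporting the same
#' report reproduces byte-identical files.
#'
#' @param report An `eval_report`.
#' @param out_dir Output directory (created if needed).
#' @param plots If `TRUE`, also render an accuracy box plot per condition
#'   (`accuracy_boxplot.png`).
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(report, out_dir, plots = FALSE) {
  stopifnot(inherits(report, "eval_report"))
  if (is.null(report$per_split) || nrow(report$per_split) == 0L)
    stop("empty report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  wt <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character(0)
  # metric tables are deterministic given the seed; wall-clock timing is
  # not, so it is exported separately (timing.tsv)
  metric_cols <- setdiff(names(report$aggregates),
                         c("seconds_mean", "seconds_sd",
                           "feature_seconds_mean", "feature_seconds_sd"))
  files <- c(files, wt(report$aggregates[, metric_cols], "metrics.tsv"))
  ps <- report$per_split[order(report$per_split$condition,
                               report$per_split$band,
                               report$per_split$classifier,
                               report$per_split$split), ]
  files <- c(files, wt(ps[, c("condition", "band", "classifier", "split",
                              "accuracy")],
                       "per_split_accuracy.tsv"))
  cm_rows <- list()
  for (key in sort(names(report$confusion))) {
    cm <- report$confusion[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(cm)))
      for (j in seq_len(ncol(cm)))
        cm_rows[[length(cm_rows) + 1L]] <- data.frame(
          cell = key, true = i - 1L, pred = j - 1L, count = cm[i, j],
          stringsAsFactors = FALSE)
  }
  files <- c(files, wt(do.call(rbind, cm_rows), "confusion.tsv"))
  files <- c(files, wt(report$aggregates[, c("condition", "band", "classifier",
                                             "seconds_mean", "seconds_sd",
                                             "feature_seconds_mean")],
                       "timing.tsv"))
  if (plots) {
    png_path <- file.path(out_dir, "accuracy_boxplot.png")
    grDevices::png(png_path, width = 900, height = 500)
    graphics::boxplot(accuracy ~ classifier + band, data = report$per_split,
                      las = 2, ylab = "validation accuracy",
                      main = paste("condition:", report$condition))
    grDevices::dev.off()
    files <- c(files, png_path)
  }
  invisible(files)
}
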