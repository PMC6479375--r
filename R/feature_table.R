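#' Construct a feature table
#'
#' The tabular interchange object between feature extraction and
#' classification: one row per trial, one column per feature, with per-column
#' provenance (channel, band, feature kind) and the integer class labels.
#'
#' @param values Numeric matrix, trials x features; all entries finite.
#' @param labels Integer vector of class codes, length `nrow(values)`.
#' @param meta Data frame with one row per feature column and columns
#'   `channel`, `band`, `kind` (kind in `"raw"`, `"de"`, `"lda_component"`).
#' @param provenance Free-text description of the producing pipeline stage.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, labels, meta, provenance = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite feature value at row %d, column %d",
                 bad[1], bad[2]))
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("`labels` length must equal the number of rows of `values`")
  if (!is.data.frame(meta) ||
      !all(c("channel", "band", "kind") %in% names(meta)))
    stop("`meta` must be a data frame with columns channel, band, kind")
  if (nrow(meta) != ncol(values))
    stop("`meta` must have one row per feature column")
  if (!all(meta$kind %in% c("raw", "de", "lda_component")))
    stop("feature kind must be one of raw, de, lda_component")
  meta <- data.frame(channel = as.character(meta$channel),
                     band = as.character(meta$band),
                     kind = as.character(meta$kind),
                     stringsAsFactors = FALSE)
  colnames(values) <- paste(meta$channel, meta$band, meta$kind, sep = "|")
  structure(list(values = values, labels = labels, meta = meta,
                 provenance = as.character(provenance)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d trials x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$meta$kind), collapse = "+")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Column-wise concatenation of aligned feature tables
#'
#' Used to build the combined-band table: the per-band tables are joined
#' column-wise in band order, so each trial's feature vector is the
#' concatenation of its per-band vectors (62 channels x 5 bands = 310
#' features for the standard geometry).
#'
#' @param tables Named list of `feature_table`s with identical labels and
#'   row order.
#' @param provenance Provenance string for the result.
#' @return A `feature_table`.
#' @export
combine_feature_tables <- function(tables, provenance = "combined bands") {
  stopifnot(is.list(tables), length(tables) >= 1L)
  lab0 <- tables[[1]]$labels
  for (t in tables) {
    if (!inherits(t, "feature_table")) stop("all elements must be feature_tables")
    if (!identical(t$labels, lab0))
      stop("feature tables are misaligned: labels differ between bands")
  }
  feature_table(do.call(cbind, lapply(tables, function(t) t$values)),
                lab0,
                do.call(rbind, lapply(tables, function(t) t$meta)),
                provenance)
}

#' Write a feature table to tab-separated text
#'
#' Format: comment lines `# provenance: ...` and `# classes: ...` followed by
#' a header row of `channel|band|kind` column names plus a final `label`
#' column, then one row per trial. Values are written with full double
#' precision so a round-trip reproduces them to better than 1e-12 relative.
#'
#' @param table A `feature_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", table$provenance), con)
  df <- as.data.frame(format(table$values, digits = 17, trim = TRUE,
                             scientific = TRUE),
                      stringsAsFactors = FALSE)
  names(df) <- colnames(table$values)
  df$label <- table$labels
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input file path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty feature table file: ", path)
  prov <- ""
  head_i <- 1L
  while (head_i <= length(lines) && startsWith(lines[head_i], "#")) {
    if (startsWith(lines[head_i], "# provenance: "))
      prov <- sub("^# provenance: ", "", lines[head_i])
    head_i <- head_i + 1L
  }
  if (head_i > length(lines))
    stop("malformed feature table (no header row) at line ", head_i,
         " in ", path)
  header <- strsplit(lines[head_i], "\t", fixed = TRUE)[[1]]
  if (header[length(header)] != "label")
    stop("malformed header (no trailing 'label' column) at line ", head_i,
         " in ", path)
  feat_cols <- header[-length(header)]
  parts <- strsplit(feat_cols, "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed feature column name(s) at line ", head_i,
         ": expected channel|band|kind")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, feat_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value in %s at data row %d, column %d (%s)",
                 path, bad[1], bad[2], feat_cols[bad[2]]))
  }
  meta <- data.frame(channel = vapply(parts, `[`, "", 1L),
                     band = vapply(parts, `[`, "", 2L),
                     kind = vapply(parts, `[`, "", 3L),
                     stringsAsFactors = FALSE)
  feature_table(vals, as.integer(df$label), meta, prov)
}
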