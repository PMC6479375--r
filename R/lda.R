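#' Within-, between- and total-scatter matrices
#'
#' For classes `j = 1..K` with samples `x` in class set `X_j`, class counts
#' `N_j`, class means `mu_j` and global mean `mu`:
#' \deqn{S_w = \sum_j \sum_{x \in X_j} (x - \mu_j)(x - \mu_j)^T}
#' \deqn{S_b = \sum_j N_j (\mu_j - \mu)(\mu_j - \mu)^T}
#' and the total scatter `S_t` about the global mean satisfies
#' `S_t = S_w + S_b`.
#'
#' @param x Numeric matrix (samples x features) or a `feature_table`.
#' @param y Integer class labels (ignored when `x` is a `feature_table`).
#' @return List with `Sw`, `Sb`, `St`, `class_means` (K x n matrix),
#'   `global_mean`, `counts`, `classes`.
#' @export
scatter_matrices <- function(x, y = NULL) {
  if (inherits(x, "feature_table")) {
    y <- x$labels
    x <- x$values
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) == 0L) stop("empty feature table")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite feature values")
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("label length must match row count")
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("scatter matrices need at least 2 classes; got ", length(classes))
  n <- ncol(x)
  mu <- colMeans(x)
  counts <- integer(length(classes))
  mus <- matrix(0, length(classes), n)
  Sw <- matrix(0, n, n)
  Sb <- matrix(0, n, n)
  for (k in seq_along(classes)) {
    xk <- x[y == classes[k], , drop = FALSE]
    counts[k] <- nrow(xk)
    mus[k, ] <- colMeans(xk)
    ck <- sweep(xk, 2, mus[k, ])
    Sw <- Sw + crossprod(ck)
    dk <- mus[k, ] - mu
    Sb <- Sb + counts[k] * tcrossprod(dk)
  }
  xc <- sweep(x, 2, mu)
  list(Sw = Sw, Sb = Sb, St = crossprod(xc),
       class_means = mus, global_mean = mu, counts = counts,
       classes = classes)
}

#' Fit a multi-class Fisher linear discriminant projection
#'
#' Finds the `d` directions `w` maximizing the Fisher quotient
#' `w' Sb w / w' Sw w` by solving the generalized eigenproblem
#' `Sb w = lambda Sw w` (via Cholesky whitening of the — optionally
#' shrunk — within-class scatter). Projecting onto the top `d <= K - 1`
#' eigenvectors maximizes every factor of the product-form Fisher
#' objective simultaneously.
#'
#' Determinism conventions: eigenvector columns are unit-normalized with the
#' largest-magnitude entry made positive; equal eigenvalues are ordered by
#' the index of that entry.
#'
#' @param x Numeric matrix (samples x features) or `feature_table`.
#' @param y Integer labels (ignored for a `feature_table`).
#' @param d Projection dimension, at most `K - 1` (default `K - 1`).
#' @param gamma Shrinkage: `gamma * (trace(Sw)/n)` is added to the diagonal
#'   of `Sw` before inversion (default 1e-6). With `gamma = 0` a singular
#'   `Sw` is an error suggesting shrinkage.
#' @param ... Unused.
#' @return An object of class `fisher_lda` with elements `W` (n x d
#'   projection, unit columns), `eigenvalues` (achieved Fisher quotients
#'   `w' Sb w / w' Sw w`, descending), `class_means`, `global_mean`,
#'   `counts`, `Sw`, `Sb`, `gamma`, `d`, `classes`, `feature_names`.
#' @examples
#' x <- rbind(matrix(rnorm(100, -3), 50), matrix(rnorm(100, 3), 50))
#' fit <- fisher_lda(x, rep(0:1, each = 50), d = 1)
#' fit
#' @export
fisher_lda <- function(x, y = NULL, d = NULL, gamma = 1e-6, ...) {
  meta <- NULL
  if (inherits(x, "feature_table")) {
    y <- x$labels
    meta <- x$meta
    x <- x$values
  }
  stopifnot(is.matrix(x))
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite feature values")
  sc <- scatter_matrices(x, y)
  K <- length(sc$classes)
  n <- ncol(x)
  if (is.null(d)) d <- K - 1L
  d <- as.integer(d)
  if (d < 1L) stop("`d` must be a positive integer")
  if (d > K - 1L)
    stop(sprintf(
      "d = %d exceeds the K - 1 = %d informative discriminant directions for K = %d classes",
      d, K - 1L, K))
  if (gamma < 0) stop("`gamma` must be non-negative")
  Sw_reg <- sc$Sw
  if (gamma > 0)
    Sw_reg <- Sw_reg + diag(gamma * sum(diag(sc$Sw)) / n, n)
  R <- tryCatch(chol(Sw_reg), error = function(e) NULL)
  if (is.null(R))
    stop("within-class scatter is singular; refit with shrinkage gamma > 0")
  # whiten: M = R^-T Sb R^-1, symmetric; eigvecs u map back as w = R^-1 u
  tmp <- backsolve(R, sc$Sb, transpose = TRUE)
  M <- backsolve(R, t(tmp), transpose = TRUE)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  W <- backsolve(R, eig$vectors[, seq_len(d), drop = FALSE])
  # unit norm, sign fixed by the largest-magnitude entry
  peak <- integer(d)
  for (j in seq_len(d)) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    peak[j] <- which.max(abs(W[, j]))
    if (W[peak[j], j] < 0) W[, j] <- -W[, j]
  }
  vals <- eig$values[seq_len(d)]
  # stable order for (near-)tied eigenvalues: by peak-entry index
  tol <- 1e-10 * max(abs(vals), 1)
  ord <- order(-round(vals / tol), peak)
  W <- W[, ord, drop = FALSE]
  # achieved Fisher quotients on the unshrunk scatters
  num <- diag(crossprod(W, sc$Sb %*% W))
  den <- diag(crossprod(W, sc$Sw %*% W))
  structure(
    list(W = W, eigenvalues = num / pmax(den, .Machine$double.xmin),
         class_means = sc$class_means, global_mean = sc$global_mean,
         counts = sc$counts, Sw = sc$Sw, Sb = sc$Sb,
         gamma = gamma, d = d, classes = sc$classes,
         feature_names = colnames(x), feature_meta = meta),
    class = "fisher_lda")
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat(sprintf("<fisher_lda> %d features -> %d discriminant component%s, %d classes\n",
              length(x$global_mean), x$d, if (x$d > 1) "s" else "", length(x$classes)))
  cat("  Fisher quotients:", paste(signif(x$eigenvalues, 5), collapse = ", "),
      "\n")
  cat(sprintf("  shrinkage gamma = %g\n", x$gamma))
  invisible(x)
}

#' @export
summary.fisher_lda <- function(object, ...) {
  ev <- object$eigenvalues
  out <- list(
    n_features = length(object$global_mean),
    d = object$d,
    classes = object$classes,
    counts = object$counts,
    eigenvalues = ev,
    explained = ev / sum(ev),
    fisher_product = prod(ev),
    gamma = object$gamma)
  class(out) <- "summary.fisher_lda"
  out
}

#' @export
print.summary.fisher_lda <- function(x, ...) {
  cat(sprintf("Fisher LDA: %d features, %d classes (n = %s), d = %d\n",
              x$n_features, length(x$classes),
              paste(x$counts, collapse = "/"), x$d))
  cat("Per-direction Fisher quotients (between/within):\n")
  print(data.frame(component = seq_along(x$eigenvalues),
                   quotient = x$eigenvalues,
                   share = x$explained))
  cat(sprintf("Product-form objective J(W) = %g, shrinkage gamma = %g\n",
              x$fisher_product, x$gamma))
  invisible(x)
}

#' @export
coef.fisher_lda <- function(object, ...) object$W

#' Project feature vectors onto the fitted discriminant components
#'
#' Centers rows by the training global mean and multiplies by the fitted
#' projection `W`. No statistic is re-estimated from `newdata`, so applying
#' the model to held-out data cannot leak its labels.
#'
#' @param object A `fisher_lda` fit.
#' @param newdata Matrix or `feature_table` with the training column count.
#' @param ... Unused.
#' @return A matrix of scores (samples x d), or a `feature_table` with
#'   feature kind `lda_component` when `newdata` is a `feature_table`.
#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  is_table <- inherits(newdata, "feature_table")
  x <- if (is_table) newdata$values else newdata
  stopifnot(is.matrix(x))
  if (ncol(x) != length(object$global_mean))
    stop(sprintf("feature count mismatch: model has %d features, data has %d",
                 length(object$global_mean), ncol(x)))
  scores <- sweep(x, 2, object$global_mean) %*% object$W
  colnames(scores) <- paste0("LD", seq_len(object$d))
  if (!is_table) return(scores)
  feature_table(scores, newdata$labels,
                data.frame(channel = colnames(scores), band = "all",
                           kind = "lda_component", stringsAsFactors = FALSE),
                provenance = paste0(newdata$provenance, " -> fisher_lda"))
}

#' Scatter plot of discriminant scores by class
#'
#' @param x A `fisher_lda` fit.
#' @param newdata Matrix or `feature_table` to project and plot.
#' @param class_names Optional class names for the legend.
#' @param ... Passed to [graphics::plot()].
#' @return The score matrix, invisibly.
#' @export
plot.fisher_lda <- function(x, newdata, class_names = NULL, ...) {
  scores <- predict(x, newdata)
  if (inherits(scores, "feature_table")) {
    labs <- scores$labels
    scores <- scores$values
  } else if (inherits(newdata, "feature_table")) {
    labs <- newdata$labels
  } else {
    labs <- rep(0L, nrow(scores))
  }
  cls <- sort(unique(labs))
  col <- grDevices::hcl.colors(max(length(cls), 3L), "Dark 3")
  if (ncol(scores) >= 2) {
    graphics::plot(scores[, 1], scores[, 2], col = col[match(labs, cls)],
                   pch = 19, xlab = "LD1", ylab = "LD2", ...)
  } else {
    graphics::stripchart(split(scores[, 1], labs), method = "jitter",
                         pch = 19, col = col, xlab = "LD1", ...)
  }
  if (!is.null(class_names))
    graphics::legend("topright", legend = class_names, col = col[seq_along(class_names)],
                     pch = 19, bty = "n")
  invisible(scores)
}

#' Serialize a fitted discriminant model to JSON
#'
#' Stores the projection, means, Fisher quotients and shrinkage so a model
#' can be reused across runs; [read_fisher_lda()] restores it.
#'
#' @param model A `fisher_lda` fit.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fisher_lda <- function(model, path) {
  stopifnot(inherits(model, "fisher_lda"))
  obj <- list(W = model$W, eigenvalues = model$eigenvalues,
              class_means = model$class_means,
              global_mean = model$global_mean, counts = model$counts,
              gamma = model$gamma, d = model$d, classes = model$classes,
              feature_names = model$feature_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a fitted discriminant model written by [write_fisher_lda()]
#'
#' @param path JSON path.
#' @return A `fisher_lda` object (scatter matrices are not stored and come
#'   back `NULL`).
#' @export
read_fisher_lda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(W = as.matrix(obj$W), eigenvalues = as.numeric(obj$eigenvalues),
         class_means = as.matrix(obj$class_means),
         global_mean = as.numeric(obj$global_mean),
         counts = as.integer(obj$counts), Sw = NULL, Sb = NULL,
         gamma = obj$gamma, d = as.integer(obj$d),
         classes = as.integer(obj$classes),
         feature_names = obj$feature_names, feature_meta = NULL),
    class = "fisher_lda")
}
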