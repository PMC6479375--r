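#' Specify one benchmark classifier
#'
#' The five reference classifiers with their tuned defaults:
#' \describe{
#'   \item{knn}{k-nearest neighbours, `neighbors = 20`.}
#'   \item{lr}{multinomial logistic regression, L2 penalty with inverse
#'     regularization strength `C = 1` (fit with weight decay `1/C`).}
#'   \item{mlp}{two hidden layers of 64 and 32 ReLU units, Adam optimizer,
#'     batch size 32, learning rate 1e-4, 200 epochs.}
#'   \item{rf}{random forest, 120 trees, maximum depth 10, minimum node
#'     size 8.}
#'   \item{svm}{support vector machine, RBF kernel, cost `C = 1`, kernel
#'     width `gamma = 1 / (p * var(x))`.}
#' }
#'
#' @param name One of `"knn"`, `"lr"`, `"mlp"`, `"rf"`, `"svm"`.
#' @param ... Named hyperparameter overrides (see the defaults above).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("knn", "lr", "mlp", "rf", "svm"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    knn = list(neighbors = 20L),
    lr  = list(penalty = "l2", C = 1.0, maxit = 200L),
    mlp = list(hidden = c(64L, 32L), activation = "relu", optimizer = "adam",
               batch_size = 32L, learning_rate = 1e-4, epochs = 200L),
    rf  = list(trees = 120L, max_depth = 10L, min_node = 8L),
    svm = list(kernel = "radial", C = 1.0))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(list(name = name, params = defaults), class = "classifier_spec")
}

#' The default five-classifier bank
#' @param names Subset of classifier names to include.
#' @return Named list of [classifier_spec()]s.
#' @export
default_classifiers <- function(names = c("knn", "lr", "mlp", "rf", "svm")) {
  out <- lapply(names, classifier_spec)
  names(out) <- names
  out
}

# minimal two-hidden-layer ReLU/softmax network trained with Adam.
# x: samples x features, y: integer labels 0..K-1
mlp_train <- function(x, y, K, hidden, epochs, batch_size, lr, seed) {
  n <- nrow(x); p <- ncol(x)
  sizes <- c(p, hidden, K)
  L <- length(sizes) - 1L
  with_seed(seed, {
    Ws <- vector("list", L)
    bs <- vector("list", L)
    for (l in seq_len(L)) {
      # Glorot-uniform initialization
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      Ws[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                        sizes[l], sizes[l + 1])
      bs[[l]] <- numeric(sizes[l + 1])
    }
    mW <- lapply(Ws, function(w) w * 0); vW <- mW
    mb <- lapply(bs, function(b) b * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    yk <- y + 1L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        m <- length(idx)
        # forward
        acts <- vector("list", L + 1L)
        acts[[1]] <- xb
        for (l in seq_len(L)) {
          z <- sweep(acts[[l]] %*% Ws[[l]], 2, bs[[l]], `+`)
          acts[[l + 1L]] <- if (l < L) pmax(z, 0) else z
        }
        z <- acts[[L + 1L]]
        z <- z - apply(z, 1, max)
        ez <- exp(z)
        probs <- ez / rowSums(ez)
        # backward (softmax cross-entropy)
        delta <- probs
        delta[cbind(seq_len(m), yk[idx])] <-
          delta[cbind(seq_len(m), yk[idx])] - 1
        delta <- delta / m
        step <- step + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(Ws[[l]])) * (acts[[l]] > 0)
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
          corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
          Ws[[l]] <- Ws[[l]] - lr * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps)
          bs[[l]] <- bs[[l]] - lr * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
    }
    list(Ws = Ws, bs = bs, L = L)
  })
}

mlp_predict <- function(fit, x) {
  a <- x
  for (l in seq_len(fit$L)) {
    z <- sweep(a %*% fit$Ws[[l]], 2, fit$bs[[l]], `+`)
    a <- if (l < fit$L) pmax(z, 0) else z
  }
  max.col(a, ties.method = "first") - 1L
}

#' Fit one classifier on a training split and predict a validation split
#'
#' @param spec A [classifier_spec()].
#' @param x_train,x_valid Numeric matrices with matching columns.
#' @param y_train Integer labels in `0:(K-1)` for the training rows.
#' @param K Number of classes.
#' @param seed Seed for the classifier's own randomness (forest bootstrap,
#'   network initialization, k-NN tie-breaking).
#' @return List with `pred` (integer labels for `x_valid`) and `seconds`
#'   (fit + predict wall time from a monotonic process clock).
#' @export
fit_predict <- function(spec, x_train, y_train, x_valid, K, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  p <- spec$params
  yf <- factor(y_train, levels = 0:(K - 1))
  t0 <- proc.time()[["elapsed"]]
  pred <- switch(spec$name,
    knn = with_seed(seed, {
      as.integer(as.character(
        class::knn(x_train, x_valid, cl = yf,
                   k = min(p$neighbors, nrow(x_train)))))
    }),
    lr = with_seed(seed, {
      df <- as.data.frame(x_train)
      names(df) <- paste0("f", seq_len(ncol(x_train)))
      df$.y <- yf
      capture <- utils::capture.output(
        fit <- nnet::multinom(.y ~ ., data = df, decay = 1 / p$C,
                              maxit = p$maxit, MaxNWts = 1e6, trace = FALSE))
      dv <- as.data.frame(x_valid)
      names(dv) <- paste0("f", seq_len(ncol(x_valid)))
      as.integer(as.character(predict(fit, dv)))
    }),
    mlp = {
      fit <- mlp_train(x_train, y_train, K, p$hidden, p$epochs,
                       p$batch_size, p$learning_rate, seed)
      mlp_predict(fit, x_valid)
    },
    rf = {
      df <- as.data.frame(x_train)
      names(df) <- paste0("f", seq_len(ncol(x_train)))
      fit <- ranger::ranger(x = df, y = yf, num.trees = p$trees,
                            max.depth = p$max_depth,
                            min.node.size = p$min_node,
                            seed = seed, num.threads = 1L)
      dv <- as.data.frame(x_valid)
      names(dv) <- paste0("f", seq_len(ncol(x_valid)))
      as.integer(as.character(predict(fit, data = dv,
                                      num.threads = 1L)$predictions))
    },
    svm = with_seed(seed, {
      v <- stats::var(as.vector(x_train))
      g <- if (v > 0) 1 / (ncol(x_train) * v) else 1 / ncol(x_train)
      fit <- e1071::svm(x_train, yf, kernel = p$kernel, cost = p$C,
                        gamma = g, scale = FALSE)
      as.integer(as.character(predict(fit, x_valid)))
    }),
    stop("unknown classifier: ", spec$name))
  list(pred = pred, seconds = proc.time()[["elapsed"]] - t0)
}
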