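test_that("scatter matrices match hand-summed outer products on the six-point set", {
  sp <- six_point_table()
  sc <- scatter_matrices(sp$x, sp$y)
  expect_equal(sc$Sw, sp$Sw)
  expect_equal(sc$Sb, sp$Sb)
  expect_equal(sc$St, sp$Sw + sp$Sb)
  expect_equal(sc$class_means,
               rbind(c(0, 0.5), c(2, 0.5), c(4, 0.5)))
  expect_identical(sc$counts, c(2L, 2L, 2L))
})

test_that("total scatter decomposes as St = Sw + Sb on random tables", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:120, 1)
    p <- sample(2:40, 1)
    x <- matrix(rnorm(n * p), n)
    y <- sample(0:2, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    sc <- scatter_matrices(x, y)
    rel <- max(abs(sc$St - (sc$Sw + sc$Sb))) / max(abs(sc$St))
    expect_lt(rel, 1e-8)
    expect_lt(max(abs(sc$Sw - t(sc$Sw))), 1e-10)
    expect_lt(max(abs(sc$Sb - t(sc$Sb))), 1e-10)
  }
})

test_that("degenerate scatter inputs behave as the definitions force", {
  # one sample per class: centered sums vanish
  x <- rbind(c(1, 2), c(3, 4), c(5, 6))
  sc <- scatter_matrices(x, 0:2)
  expect_equal(sc$Sw, matrix(0, 2, 2))
  # all samples identical: both scatters vanish
  sc0 <- scatter_matrices(matrix(1, 6, 2), rep(0:2, 2))
  expect_equal(sc0$Sw, matrix(0, 2, 2))
  expect_equal(sc0$Sb, matrix(0, 2, 2))
  expect_error(scatter_matrices(x, c(0L, 0L, 0L)), "2 classes")
  expect_error(scatter_matrices(matrix(numeric(0), 0, 2), integer(0)),
               "empty")
})

test_that("eigen-solution quotient beats a 1-degree brute-force grid", {
  for (seed in c(3, 14, 159, 2653)) {
    inst <- random_lda_instance(seed)
    fit <- fisher_lda(inst$x, inst$y, d = 2, gamma = 0)
    sc <- scatter_matrices(inst$x, inst$y)
    grid_best <- grid_max_quotient(sc$Sw, sc$Sb)
    expect_gte(fit$eigenvalues[1], grid_best * (1 - 1e-6))
  }
})

test_that("well-separated classes recover the mean-difference axis", {
  set.seed(77)
  x <- rbind(sweep(matrix(rnorm(400), ncol = 2), 2, c(-5, 0), `+`),
             sweep(matrix(rnorm(400), ncol = 2), 2, c(5, 0), `+`))
  fit <- fisher_lda(x, rep(0:1, each = 200), d = 1)
  angle <- acos(abs(fit$W[1, 1])) * 180 / pi
  expect_lt(angle, 5)
})

test_that("shrinkage handles singular within-class scatter, gamma = 0 refuses", {
  sp <- six_point_table()   # Sw singular along x
  expect_error(fisher_lda(sp$x, sp$y, d = 2, gamma = 0), "shrinkage")
  fit <- fisher_lda(sp$x, sp$y, d = 2, gamma = 1e-6)
  # discriminant axis is x (all between-class scatter lies there)
  expect_gt(abs(fit$W[1, 1]), 0.999)
  # p > n also works under shrinkage
  tab <- random_feature_table(12, 30, seed = 3)
  fit2 <- fisher_lda(tab, d = 2)
  expect_identical(dim(fit2$W), c(30L, 2L))
})

test_that("dimension bound d <= K - 1 is enforced", {
  inst <- random_lda_instance(5)
  expect_error(fisher_lda(inst$x, inst$y, d = 3), "K - 1")
  expect_error(fisher_lda(inst$x, inst$y, d = 0), "positive")
  fit <- fisher_lda(inst$x, inst$y)
  expect_identical(fit$d, 2L)   # default d = K - 1
  expect_lte(qr(fit$Sb)$rank, 2)
})

test_that("scatters and projection span are translation invariant", {
  inst <- random_lda_instance(21)
  shift <- c(13.7, -4.2)
  x2 <- sweep(inst$x, 2, shift, `+`)
  sc1 <- scatter_matrices(inst$x, inst$y)
  sc2 <- scatter_matrices(x2, inst$y)
  expect_equal(sc1$Sw, sc2$Sw, tolerance = 1e-8)
  expect_equal(sc1$Sb, sc2$Sb, tolerance = 1e-8)
  f1 <- fisher_lda(inst$x, inst$y, d = 2)
  f2 <- fisher_lda(x2, inst$y, d = 2)
  expect_equal(abs(crossprod(f1$W[, 1], f2$W[, 1]))[1, 1], 1,
               tolerance = 1e-8)
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-6)
})

test_that("projection centers by the training mean and never re-estimates", {
  inst <- random_lda_instance(8, n_per_class = 30)
  fit <- fisher_lda(inst$x, inst$y, d = 2)
  scores <- predict(fit, inst$x)
  expect_equal(scores, sweep(inst$x, 2, fit$global_mean) %*% fit$W,
               ignore_attr = TRUE)
  # transforming new data uses the stored mean, not the new data's own
  xnew <- matrix(rnorm(20), ncol = 2) + 100
  s1 <- predict(fit, xnew)
  expect_equal(s1, sweep(xnew, 2, fit$global_mean) %*% fit$W,
               ignore_attr = TRUE)
  expect_error(predict(fit, matrix(rnorm(9), 3)), "mismatch")
})

test_that("projected component concentrates class separation", {
  # between/within variance ratio along LD1 beats every original feature
  gen <- small_synth(n_channels = 6, clip_seconds = 6)
  tab <- extract_features(gen$trials)$de$combined
  fit <- fisher_lda(tab, d = 2)
  proj <- predict(fit, tab)
  ratio <- function(v, y) {
    sc <- scatter_matrices(matrix(v, ncol = 1), y)
    sc$Sb[1, 1] / sc$Sw[1, 1]
  }
  r_ld1 <- ratio(proj$values[, 1], tab$labels)
  r_best_orig <- max(vapply(seq_len(ncol(tab$values)), function(j)
    ratio(tab$values[, j], tab$labels), numeric(1)))
  expect_gte(r_ld1, r_best_orig)
  expect_identical(unique(proj$meta$kind), "lda_component")
})

test_that("near-identity limit: large gamma with d = K - 1 recenters input", {
  # with overwhelming shrinkage Sw is effectively spherical, so the
  # projection becomes an orthonormal basis of the class-mean subspace:
  # projecting the centered data is then a rotation of that subspace
  inst <- random_lda_instance(4)
  fit <- fisher_lda(inst$x, inst$y, d = 2, gamma = 1e9)
  expect_equal(crossprod(fit$W), diag(2), tolerance = 1e-4)
  sc <- predict(fit, inst$x)
  centered <- sweep(inst$x, 2, colMeans(inst$x))
  expect_equal(sc %*% t(fit$W), centered, tolerance = 1e-4,
               ignore_attr = TRUE)
})
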