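test_that("stratified 70/30 holdout gives the forced counts on 675 samples", {
  labels <- rep(0:2, each = 225)
  prot <- split_protocol(seed = 5)
  sp <- make_split(labels, prot, 1)
  expect_length(sp$train, 472)
  expect_length(sp$valid, 203)
  expect_length(intersect(sp$train, sp$valid), 0)
  tr_counts <- table(labels[sp$train])
  expect_true(all(abs(tr_counts - 472 / 3) <= 1))
})

test_that("splits are reproducible and distinct across repeats", {
  labels <- rep(0:2, each = 30)
  prot <- split_protocol(seed = 11, repeats = 5)
  s1 <- make_split(labels, prot, 3)
  s2 <- make_split(labels, prot, 3)
  expect_identical(s1, s2)
  s3 <- make_split(labels, prot, 4)
  expect_false(identical(s1$train, s3$train))
})

test_that("k-fold mode partitions the data exhaustively and stratified", {
  labels <- rep(0:2, each = 25)
  prot <- split_protocol(mode = "kfold", folds = 5, seed = 2)
  seen <- integer(0)
  for (k in 1:5) {
    sp <- make_split(labels, prot, k)
    expect_length(intersect(sp$train, sp$valid), 0)
    counts <- table(labels[sp$valid])
    expect_true(all(abs(counts - 5) <= 1))
    seen <- c(seen, sp$valid)
  }
  expect_identical(sort(seen), seq_along(labels))
  expect_error(make_split(labels, prot, 6), "folds")
})

test_that("degenerate split requests error out", {
  expect_error(make_split(c(0L, 1L, 2L), split_protocol(), 1),
               "at least 2 samples")
  expect_error(make_split(integer(0), split_protocol(), 1), "fewer samples")
})

test_that("every classifier learns a linearly separated toy problem", {
  set.seed(99)
  n <- 60
  mus <- rbind(c(-6, 0), c(0, 6), c(6, 0))
  x <- do.call(rbind, lapply(1:3, function(j)
    sweep(matrix(rnorm(2 * n), ncol = 2), 2, mus[j, ], `+`)))
  y <- rep(0:2, each = n)
  idx <- sample(length(y))
  tr <- idx[1:120]; va <- idx[121:180]
  specs <- list(
    classifier_spec("knn"),
    classifier_spec("lr"),
    classifier_spec("rf"),
    classifier_spec("svm"),
    # the benchmark's default learning rate is tuned for hundreds of
    # 310-dimensional samples; the toy check uses a faster schedule
    classifier_spec("mlp", learning_rate = 0.01, epochs = 100))
  for (spec in specs) {
    res <- fit_predict(spec, x[tr, ], y[tr], x[va, ], 3, seed = 1)
    acc <- mean(res$pred == y[va])
    expect_gte(acc, 0.9)
    expect_true(res$seconds >= 0)
  }
  expect_error(classifier_spec("svm", bogus = 1), "unknown hyperparameter")
})

test_that("the harness is reproducible, aligned and validates conditions", {
  gen <- small_synth(n_channels = 4, clip_seconds = 4)
  tabs <- extract_features(gen$trials)$de
  tables <- c(tabs$per_band["gamma"], list(combined = tabs$combined))
  prot <- split_protocol(repeats = 3, seed = 13)
  cls <- default_classifiers("svm")
  r1 <- run_condition(tables, "de", cls, prot)
  r2 <- run_condition(tables, "de", cls, prot)
  keep <- setdiff(names(r1$per_split), c("seconds", "feature_seconds"))
  expect_identical(r1$per_split[keep], r2$per_split[keep])
  expect_identical(r1$confusion, r2$confusion)
  expect_s3_class(r1, "eval_report")
  expect_setequal(unique(r1$per_split$band), c("gamma", "combined"))

  expect_error(run_condition(tables, "nonsense", cls, prot),
               "unknown condition")
  misaligned <- tables
  misaligned$combined$labels <- rev(misaligned$combined$labels)
  expect_error(run_condition(misaligned, "de", cls, prot), "misaligned")
})

test_that("confusion marginals in reports match validation class counts", {
  gen <- small_synth(n_channels = 4, clip_seconds = 4)
  tabs <- extract_features(gen$trials)$de
  prot <- split_protocol(repeats = 4, seed = 3)
  rep1 <- run_condition(list(combined = tabs$combined), "de_lda",
                        default_classifiers("knn"), prot)
  cm <- rep1$confusion[["combined|knn"]]
  # 27 trials: 70/30 stratified -> 9 validation samples per split, 3/class
  expect_equal(unname(rowSums(cm)), rep(3 * 4, 3))
  # kappa identity per split against the recorded accuracy
  ps <- rep1$per_split
  expect_true(all(ps$kappa <= 1 & ps$kappa >= -1))
})

test_that("single-repeat protocols aggregate without crashing", {
  gen <- small_synth(n_channels = 4, clip_seconds = 4)
  tabs <- extract_features(gen$trials)$de
  prot <- split_protocol(repeats = 1, seed = 1)
  rep1 <- run_condition(list(combined = tabs$combined), "de",
                        default_classifiers("svm"), prot)
  expect_identical(nrow(rep1$per_split), 1L)
  expect_identical(rep1$aggregates$accuracy_sd, 0)
})

test_that("reports export deterministically to TSV", {
  gen <- small_synth(n_channels = 4, clip_seconds = 4)
  tabs <- extract_features(gen$trials)$de
  prot <- split_protocol(repeats = 2, seed = 4)
  rep1 <- run_condition(list(combined = tabs$combined), "de",
                        default_classifiers(c("svm", "knn")), prot)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- export_report(rep1, d1)
  f2 <- export_report(rep1, d2)
  expect_true(all(file.exists(f1)))
  expect_setequal(basename(f1),
                  c("metrics.tsv", "per_split_accuracy.tsv",
                    "confusion.tsv", "timing.tsv"))
  for (f in basename(f1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  empty <- rep1
  empty$per_split <- empty$per_split[0, ]
  expect_error(export_report(empty, d1), "empty")
})
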