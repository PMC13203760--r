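test_that("confusion matrix counts by (true, predicted) pair", {
  cm <- confusion(c("N", "N", "V"), c("N", "V", "V"))
  expect_identical(unclass(cm)[1, ], c(N = 1L, V = 1L, S = 0L))
  expect_identical(unclass(cm)[2, ], c(N = 0L, V = 1L, S = 0L))
  expect_identical(sum(cm), 3L)

  perfect <- confusion(c("N", "V", "S"), c("N", "V", "S"))
  expect_identical(sum(diag(perfect)), 3L)
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)

  expect_error(confusion(character(0), character(0)),
               class = "tinybeat_domain_error")
  expect_error(confusion("N", "X"), class = "tinybeat_data_error")
})

test_that("metrics follow the one-vs-rest closed forms", {
  # class N: TP=3, FN=2, FP=1 -> precision .75, recall .6, F1 .6667
  m <- matrix(0L, 3, 3, dimnames = list(c("N", "V", "S"), c("N", "V", "S")))
  m["N", "N"] <- 3L; m["N", "V"] <- 2L; m["V", "N"] <- 1L
  m["V", "V"] <- 4L; m["S", "S"] <- 5L
  class(m) <- c("confusion_counts", class(m))
  rep <- metrics_from_confusion(m)
  pc <- rep$per_class
  expect_equal(pc$precision[pc$class == "N"], 0.75)
  expect_equal(pc$recall[pc$class == "N"], 0.6)
  expect_equal(pc$f1[pc$class == "N"], 2 * 0.75 * 0.6 / 1.35)
  expect_equal(rep$accuracy, 12 / 15)
  # weighted average = sum(n_i * M_i) / sum(n_i)
  sup <- pc$support
  expect_equal(rep$weighted[["recall"]], sum(sup * pc$recall) / sum(sup))

  idm <- confusion(rep(c("N", "V", "S"), 4), rep(c("N", "V", "S"), 4))
  repi <- metrics_from_confusion(idm)
  expect_equal(repi$accuracy, 1)
  expect_equal(unname(repi$weighted), c(1, 1, 1))
  # equal supports: weighted equals macro
  expect_equal(repi$weighted, repi$macro)
})

test_that("zero-denominator metrics are flagged as zero", {
  m <- confusion(c("N", "N", "V", "S"), c("V", "V", "V", "S"))
  expect_warning(rep <- metrics_from_confusion(m), NA)
  pc <- rep$per_class
  expect_equal(pc$precision[pc$class == "N"], 0)   # no N predictions
  expect_true(any(grepl("precision", rep$flags)))
})

test_that("metrics engine matches a brute-force recount on random cases", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    yt <- sample(c("N", "V", "S"), n, replace = TRUE)
    yp <- sample(c("N", "V", "S"), n, replace = TRUE)
    rep <- suppressWarnings(metrics_from_confusion(confusion(yt, yp)))
    ref <- brute_metrics(yt, yp)
    for (cl in c("N", "V", "S")) {
      row <- rep$per_class[rep$per_class$class == cl, ]
      expect_equal(row$precision, ref[[cl]][["precision"]])
      expect_equal(row$recall, ref[[cl]][["recall"]])
      expect_equal(row$f1, ref[[cl]][["f1"]])
    }
    expect_equal(rep$accuracy, mean(yt == yp))
  }
})

test_that("one-vs-rest AUC equals the pairwise-comparison oracle", {
  # perfectly separated
  yt <- c("N", "N", "V", "V", "S", "S")
  P <- rbind(c(.9, .05, .05), c(.8, .1, .1), c(.1, .8, .1),
             c(.05, .9, .05), c(.1, .1, .8), c(.05, .05, .9))
  expect_equal(auc_ovr(yt, P), 1.0)
  # scores independent of labels (all tied) -> 0.5
  expect_equal(auc_ovr(yt, matrix(1 / 3, 6, 3)), 0.5)
  # random small cases vs brute force
  set.seed(11)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    yt <- sample(c("N", "V", "S"), n, replace = TRUE)
    if (length(unique(yt)) < 3) next
    P <- matrix(runif(3 * n), n, 3)
    P <- P / rowSums(P)
    expect_equal(auc_ovr(yt, P), brute_auc_ovr(yt, P), tolerance = 1e-12)
  }
  # absent class excluded with warning
  expect_warning(auc_ovr(rep(c("N", "V"), 3), matrix(runif(18), 6, 3)),
                 "absent")
})

test_that("stratified split preserves proportions and partitions the data", {
  ds <- synth_beat_dataset(320, seed = 14)
  # trim to exactly 100 per class
  idx <- unlist(lapply(c("N", "V", "S"),
                       function(cl) which(ds$labels == cl)[1:100]))
  ds <- dataset_subset(ds, idx)
  sp <- stratified_split(ds, c(0.6, 0.2, 0.2), seed = 7)
  expect_identical(as.vector(class_counts(sp$train)), rep(60L, 3))
  expect_identical(as.vector(class_counts(sp$validation)), rep(20L, 3))
  expect_identical(as.vector(class_counts(sp$test)), rep(20L, 3))
  # same seed -> identical partition
  sp2 <- stratified_split(ds, c(0.6, 0.2, 0.2), seed = 7)
  expect_identical(sp$train$x, sp2$train$x)
  # disjoint union equals the input (multiset equality via sorted rows)
  key <- function(d) sort(apply(d$x, 1, function(r) paste(r[1:8], collapse = ",")))
  expect_identical(sort(c(key(sp$train), key(sp$validation), key(sp$test))),
                   key(ds))
  expect_identical(nrow(sp$train$x) + nrow(sp$validation$x) +
                     nrow(sp$test$x), nrow(ds$x))
  # class too small
  tiny <- dataset_subset(ds, c(which(ds$labels == "N")[1:4],
                               which(ds$labels == "V")[1:10],
                               which(ds$labels == "S")[1:10]))
  expect_error(stratified_split(tiny), class = "tinybeat_split_error")
})

test_that("cross-validation folds are stratified partitions", {
  ds <- synth_beat_dataset(150, seed = 15)
  fold <- tinybeat:::stratified_folds(ds$labels, 5L, seed = 3)
  expect_identical(sort(unique(fold)), 1:5)
  expect_identical(length(fold), nrow(ds$x))
  tab <- table(ds$labels, fold)
  for (cl in rownames(tab))
    expect_lte(diff(range(tab[cl, ])), 1)

  cv <- crossval_beat_cnn(ds, folds = 3,
                          control = beat_cnn_control(epochs = 2,
                                                     early_stopping_patience = 1),
                          seed = 3)
  expect_identical(length(cv$reports), 3L)
  expect_true(all(c("accuracy", "precision", "recall", "f1", "auc") %in%
                    cv$summary$metric))
  expect_true(all(cv$summary$mean >= 0 & cv$summary$mean <= 1))
})

test_that("agreement of a model with itself is exact", {
  fit <- small_fit()
  ag <- agreement_report(fit$model, fit$model, fit$split$test)
  expect_equal(ag$r_squared, 1)
  expect_equal(ag$argmax_agreement, 1)
  expect_equal(ag$delta_pp, 0)
})
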