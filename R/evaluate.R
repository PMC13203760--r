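#' Confusion matrix over the three-class alphabet
#'
#' @param y_true,y_pred character vectors over `c("N","V","S")`, equal
#'   length, nonempty.
#' @return 3x3 integer matrix (rows = true, cols = predicted), class
#'   `confusion_counts`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0L)
    tb_stop("empty input", class = "tinybeat_domain_error")
  if (length(y_true) != length(y_pred))
    tb_stop("y_true and y_pred lengths differ", class = "tinybeat_data_error")
  if (!all(y_true %in% BEAT_CLASSES) || !all(y_pred %in% BEAT_CLASSES))
    tb_stop("labels outside {N, V, S}", class = "tinybeat_data_error")
  cm <- table(factor(y_true, BEAT_CLASSES), factor(y_pred, BEAT_CLASSES))
  m <- matrix(as.integer(cm), 3L, 3L,
              dimnames = list(true = BEAT_CLASSES, predicted = BEAT_CLASSES))
  class(m) <- c("confusion_counts", class(m))
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest precision, recall and F1, overall accuracy
#' (trace/total), and both support-weighted and macro averages.  A
#' per-class metric with zero denominator is reported as 0 and flagged;
#' classes with zero support are excluded from the weighted average with
#' a warning.
#'
#' @param cm a [confusion()] matrix.
#' @return list of class `metric_report` (without AUC).
#' @export
metrics_from_confusion <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total <= 0) tb_stop("empty confusion matrix",
                          class = "tinybeat_domain_error")
  tp <- diag(m)
  support <- rowSums(m)
  pred_n <- colSums(m)
  flags <- character(0)
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      flags <<- c(flags, sprintf("%s undefined (zero denominator) for %s",
                                 what, paste(BEAT_CLASSES[den == 0],
                                             collapse = ",")))
    out
  }
  precision <- safe_div(tp, pred_n, "precision")
  recall <- safe_div(tp, support, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  present <- support > 0
  if (!all(present))
    tb_warn("classes with zero support excluded from weighted averages: %s",
            paste(BEAT_CLASSES[!present], collapse = ", "))
  wavg <- function(v) sum(support[present] * v[present]) / sum(support[present])
  structure(list(
    confusion = cm, accuracy = sum(tp) / total,
    per_class = data.frame(class = BEAT_CLASSES, support = as.integer(support),
                           precision = precision, recall = recall, f1 = f1),
    weighted = c(precision = wavg(precision), recall = wavg(recall),
                 f1 = wavg(f1)),
    macro = c(precision = mean(precision[present]),
              recall = mean(recall[present]), f1 = mean(f1[present])),
    flags = flags), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | weighted P %.4f R %.4f F1 %.4f",
              x$accuracy, x$weighted[["precision"]], x$weighted[["recall"]],
              x$weighted[["f1"]]))
  if (!is.null(x$auc)) cat(sprintf(" | AUC %.4f", x$auc))
  cat("\n")
  invisible(x)
}

#' Support-weighted one-vs-rest AUC
#'
#' Per-class AUC via the rank statistic (ties handled by midranks),
#' averaged with per-class support weights.  Classes absent from `y_true`
#' are excluded with a warning.
#'
#' @param y_true labels over `c("N","V","S")`.
#' @param probabilities matrix of class probabilities (columns in class
#'   order, rows on the simplex).
#' @return weighted AUC in \[0, 1\].
#' @export
auc_ovr <- function(y_true, probabilities) {
  probabilities <- as.matrix(probabilities)
  stopifnot(nrow(probabilities) == length(y_true),
            ncol(probabilities) == length(BEAT_CLASSES))
  aucs <- numeric(0)
  supports <- numeric(0)
  for (k in seq_along(BEAT_CLASSES)) {
    pos <- y_true == BEAT_CLASSES[[k]]
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0L) {
      tb_warn("class %s absent from y_true; excluded from AUC",
              BEAT_CLASSES[[k]])
      next
    }
    if (n0 == 0L) next
    r <- rank(probabilities[, k])
    aucs <- c(aucs, (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
    supports <- c(supports, n1)
  }
  sum(aucs * supports) / sum(supports)
}

#' Full metric report for predictions
#'
#' @param y_true true labels.
#' @param y_pred predicted labels.
#' @param probabilities optional probability matrix for AUC.
#' @return a `metric_report` (with `auc` when probabilities are given).
#' @export
metric_report <- function(y_true, y_pred, probabilities = NULL) {
  rep <- metrics_from_confusion(confusion(y_true, y_pred))
  if (!is.null(probabilities)) rep$auc <- auc_ovr(y_true, probabilities)
  rep
}

#' Stratified train/validation/test split
#'
#' Beat-wise stratified partition preserving per-class proportions within
#' rounding (the benchmark protocol; no inter-patient separation is
#' enforced).
#'
#' @param ds a labeled [beat_dataset()].
#' @param fractions length-3 proportions summing to 1 (default 60/20/20).
#' @param seed integer seed.
#' @return named list of [beat_dataset()]s: `train`, `validation`, `test`.
#' @export
stratified_split <- function(ds, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(inherits(ds, "beat_dataset"), length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-9)
  cc <- class_counts(ds)
  if (any(cc < 5L))
    tb_stop("every class needs >= 5 beats for a stratified split (have %s)",
            paste(cc, collapse = "/"), class = "tinybeat_split_error")
  set.seed(seed)
  parts <- list(integer(0), integer(0), integer(0))
  for (cl in BEAT_CLASSES) {
    idx <- sample(which(ds$labels == cl))
    n <- length(idx)
    take <- floor(fractions * n)
    rem <- n - sum(take)
    if (rem > 0) {
      fr <- fractions * n - take
      ord <- order(fr, decreasing = TRUE)[seq_len(rem)]
      take[ord] <- take[ord] + 1L
    }
    bounds <- cumsum(c(0L, take))
    for (j in 1:3)
      if (take[[j]] > 0L)
        parts[[j]] <- c(parts[[j]], idx[(bounds[[j]] + 1L):bounds[[j + 1L]]])
  }
  list(train = dataset_subset(ds, sort(parts[[1L]])),
       validation = dataset_subset(ds, sort(parts[[2L]])),
       test = dataset_subset(ds, sort(parts[[3L]])))
}

# Stratified fold assignment: per class, shuffled indices dealt round-robin.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified five-fold cross-validation
#'
#' Trains the model on four folds and evaluates on the held-out fold,
#' repeating over all folds; optionally also quantizes each fold's model
#' and reports INT8 metrics.  A stratified 20% slice of each training set
#' serves as the early-stopping validation set.  Folds are beat-wise
#' (no patient separation), matching benchmark practice.
#'
#' @param ds labeled [beat_dataset()] (every class >= 5 beats).
#' @param folds number of folds.
#' @param architecture a [beat_cnn_architecture()].
#' @param control a [beat_cnn_control()].
#' @param quantize_folds also evaluate INT8 models per fold.
#' @param seed integer seed.
#' @return object of class `beat_cnn_cv`: per-fold `metric_report`s and a
#'   `summary` table of mean and SD per metric.
#' @export
crossval_beat_cnn <- function(ds, folds = 5L,
                              architecture = beat_cnn_architecture(),
                              control = beat_cnn_control(),
                              quantize_folds = FALSE, seed = 1L) {
  stopifnot(inherits(ds, "beat_dataset"))
  cc <- class_counts(ds)
  if (any(cc < folds))
    tb_stop("every class needs >= %d beats for %d-fold CV", folds, folds,
            class = "tinybeat_split_error")
  fold <- stratified_folds(ds$labels, folds, seed)
  reports <- vector("list", folds)
  int8_reports <- if (quantize_folds) vector("list", folds) else NULL
  for (f in seq_len(folds)) {
    test <- dataset_subset(ds, which(fold == f))
    rest <- dataset_subset(ds, which(fold != f))
    sp <- stratified_split(rest, c(0.8, 0.2, 0), seed = seed + f)
    model <- beat_cnn(sp$train, validation = sp$validation,
                      architecture = architecture, control = control,
                      seed = seed + 100L * f)
    P <- predict(model, test, type = "prob")
    pred <- model$classes[max.col(P)]
    reports[[f]] <- metric_report(test$labels, pred, P)
    if (quantize_folds) {
      qm <- quantize(model, representative = sp$train, seed = seed + f)
      predq <- predict(qm, test, type = "class")
      Pq <- predict(qm, test, type = "prob")
      int8_reports[[f]] <- metric_report(test$labels, predq, Pq)
    }
  }
  summarize <- function(reps) {
    vals <- t(vapply(reps, function(r)
      c(accuracy = r$accuracy, r$weighted, auc = r$auc %||% NA_real_),
      numeric(5)))
    data.frame(metric = colnames(vals), mean = colMeans(vals),
               sd = apply(vals, 2L, sd), row.names = NULL)
  }
  structure(list(folds = folds, reports = reports,
                 summary = summarize(reports),
                 int8_reports = int8_reports,
                 int8_summary = if (quantize_folds) summarize(int8_reports),
                 seed = seed),
            class = "beat_cnn_cv")
}

#' @export
print.beat_cnn_cv <- function(x, ...) {
  cat(sprintf("<beat_cnn_cv> %d-fold stratified cross-validation\n", x$folds))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %.4f (+/- %.4f)\n", s$metric[[i]], s$mean[[i]],
                s$sd[[i]]))
  if (!is.null(x$int8_summary)) {
    cat("  INT8:\n")
    s <- x$int8_summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-10s %.4f (+/- %.4f)\n", s$metric[[i]], s$mean[[i]],
                  s$sd[[i]]))
  }
  invisible(x)
}

#' Float vs INT8 agreement report
#'
#' Compares a float model and its quantized version on a test set:
#' accuracies, their difference in percentage points, the coefficient of
#' determination between pooled class probabilities, and the argmax
#' agreement fraction.
#'
#' @param float_model a fitted [beat_cnn()].
#' @param qm the [quantize()]d model derived from it.
#' @param test_ds labeled [beat_dataset()].
#' @return list of class `agreement_report`.
#' @export
agreement_report <- function(float_model, qm, test_ds) {
  stopifnot(inherits(float_model, "beat_cnn"), inherits(test_ds, "beat_dataset"))
  if (!identical(float_model$classes, qm$classes))
    tb_stop("class alphabets differ", class = "tinybeat_contract_error")
  Pf <- predict(float_model, test_ds, type = "prob")
  Pq <- predict(qm, test_ds, type = "prob")
  pred_f <- float_model$classes[max.col(Pf)]
  pred_q <- predict(qm, test_ds, type = "class")
  acc_f <- mean(pred_f == test_ds$labels)
  acc_q <- mean(pred_q == test_ds$labels)
  ss_res <- sum((Pq - Pf)^2)
  ss_tot <- sum((Pf - mean(Pf))^2)
  structure(list(accuracy_float = acc_f, accuracy_int8 = acc_q,
                 delta_pp = (acc_f - acc_q) * 100,
                 r_squared = 1 - ss_res / ss_tot,
                 argmax_agreement = mean(pred_f == pred_q),
                 n = nrow(test_ds$x)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> n=%d\n",
                     "  accuracy: float %.4f, int8 %.4f (delta %.2f pp)\n",
                     "  probability R^2 %.4f, argmax agreement %.4f\n"),
              x$n, x$accuracy_float, x$accuracy_int8, x$delta_pp,
              x$r_squared, x$argmax_agreement))
  invisible(x)
}
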