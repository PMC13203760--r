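#' Training control parameters
#'
#' Defaults follow the standard recipe for this model family: Adam with
#' learning rate 0.001, batch size 32, up to 100 epochs, categorical
#' cross-entropy, early stopping with patience 10 on validation loss
#' (best-validation weights restored), dropout 0.2 before the output
#' layer.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping; must be smaller than `epochs`.  Ignored when no
#'   validation set is supplied.
#' @param min_delta smallest validation-loss decrease counted as an
#'   improvement; changes below this are treated as noise.
#' @param dropout dropout rate before the final dense layer.
#' @param verbose print per-epoch progress.
#' @return an object of class `beat_cnn_control`.
#' @export
beat_cnn_control <- function(learning_rate = 0.001, batch_size = 32L,
                             epochs = 100L, early_stopping_patience = 10L,
                             min_delta = 1e-4, dropout = 0.2,
                             verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L,
            early_stopping_patience >= 1L, min_delta >= 0,
            dropout >= 0, dropout < 1)
  if (early_stopping_patience >= epochs && epochs > 1L)
    tb_warn("early stopping patience >= epochs; early stopping cannot trigger")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 min_delta = min_delta, dropout = dropout, verbose = verbose),
            class = "beat_cnn_control")
}

#' Fit the compact 1D-CNN beat classifier
#'
#' Trains the float (real-arithmetic) convolutional network on normalized
#' 250-sample beat windows.  Weight initialization is uniform
#' (Glorot-style bounds), optimization is Adam on categorical
#' cross-entropy, and when a validation set is given training stops early
#' after `early_stopping_patience` epochs without validation-loss
#' improvement, restoring the best-validation weights.  Training is
#' deterministic for a fixed `seed` (single random stream drives
#' initialization, shuffling and dropout).
#'
#' @param x a [beat_dataset()], or a numeric matrix of beat windows (one
#'   row per beat, 250 columns, values in \[0, 1\]).
#' @param y beat labels over `c("N","V","S")`; taken from the dataset when
#'   `x` is a [beat_dataset()].
#' @param validation optional validation data: a [beat_dataset()] or
#'   `list(x, y)`.
#' @param architecture a [beat_cnn_architecture()].
#' @param control a [beat_cnn_control()].
#' @param seed integer seed.
#' @return an object of class `beat_cnn` with elements `weights`,
#'   `architecture`, `control`, `history` (per-epoch loss/accuracy, train
#'   and validation), `classes`, `seed`.
#' @export
beat_cnn <- function(x, y = NULL, validation = NULL,
                     architecture = beat_cnn_architecture(),
                     control = beat_cnn_control(), seed = 1L) {
  if (inherits(x, "beat_dataset")) {
    y <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  if (ncol(x) != architecture$input_len)
    tb_stop("beat windows have %d samples; architecture expects %d",
            ncol(x), architecture$input_len, class = "tinybeat_shape_error")
  if (is.null(y) || length(y) != nrow(x))
    tb_stop("labels are required for training", class = "tinybeat_data_error")
  Y <- labels_to_onehot(y)
  if (any(colSums(Y) == 0))
    tb_stop("every class must be present in the training set",
            class = "tinybeat_data_error")
  val <- NULL
  if (!is.null(validation)) {
    if (inherits(validation, "beat_dataset"))
      val <- list(x = validation$x, y = labels_to_onehot(validation$labels))
    else val <- list(x = as.matrix(validation$x),
                     y = labels_to_onehot(validation$y))
  }

  set.seed(seed)
  w <- init_weights(architecture)
  state <- adam_init(w)
  n <- nrow(x)
  nb <- ceiling(n / control$batch_size)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0), val_loss = numeric(0),
                     val_accuracy = numeric(0))
  best <- list(loss = Inf, weights = w, epoch = 0L)
  wait <- 0L
  t_step <- 0L

  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_hits <- 0L
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * control$batch_size + 1L):min(bi * control$batch_size, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      fwd <- nn_forward(w, architecture, xb, training = TRUE,
                        dropout = control$dropout)
      w <- fwd$weights                       # batch-norm running stats
      grads <- nn_backward(w, architecture, fwd, yb)
      t_step <- t_step + 1L
      upd <- adam_step(w, grads, state, t_step, lr = control$learning_rate)
      w <- upd$weights
      state <- upd$state
      ep_loss <- ep_loss + cross_entropy(fwd$out, yb) * nrow(xb)
      ep_hits <- ep_hits + sum(max.col(fwd$out) == max.col(yb))
    }
    # re-estimate batch-norm statistics exactly on a fixed training subset
    # so inference-mode evaluation tracks the current weights
    if (any(vapply(architecture$layers,
                   function(l) isTRUE(l$batch_norm), TRUE))) {
      stats_idx <- seq_len(min(512L, n))
      w <- nn_forward(w, architecture, x[stats_idx, , drop = FALSE],
                      training = TRUE, dropout = 0, bn_momentum = 0)$weights
    }
    row <- data.frame(epoch = ep, loss = ep_loss / n, accuracy = ep_hits / n,
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (!is.null(val)) {
      pv <- nn_forward(w, architecture, val$x)$out
      row$val_loss <- cross_entropy(pv, val$y)
      row$val_accuracy <- mean(max.col(pv) == max.col(val$y))
      if (row$val_loss < best$loss - control$min_delta) {
        best <- list(loss = row$val_loss, weights = w, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist <- rbind(hist, row)
    if (control$verbose)
      message(sprintf("epoch %3d  loss %.4f acc %.4f  val_loss %s", ep,
                      row$loss, row$accuracy,
                      if (is.na(row$val_loss)) "-" else sprintf("%.4f", row$val_loss)))
    if (!is.null(val) && wait >= control$early_stopping_patience) break
  }
  if (!is.null(val)) w <- best$weights

  structure(list(weights = w, architecture = architecture, control = control,
                 history = hist, classes = BEAT_CLASSES, seed = seed,
                 best_epoch = if (is.null(val)) nrow(hist) else best$epoch),
            class = "beat_cnn")
}

#' Predict from a fitted float model
#'
#' @param object a [beat_cnn()].
#' @param newdata a [beat_dataset()] or matrix of 250-sample normalized
#'   windows (a single beat may be given as a vector).
#' @param type `"prob"` (softmax probabilities), `"class"` (labels) or
#'   `"logits"` (pre-softmax).
#' @param ... unused.
#' @return matrix of probabilities/logits or a character vector of labels.
#' @export
predict.beat_cnn <- function(object, newdata,
                             type = c("prob", "class", "logits"), ...) {
  type <- match.arg(type)
  x <- prepare_segments(newdata, object$architecture$input_len)
  arch <- object$architecture
  if (type == "logits") {
    fwd <- nn_forward(object$weights, arch, x)
    lg <- fwd$caches[[length(arch$layers)]]$pre
    colnames(lg) <- object$classes
    return(lg)
  }
  P <- nn_forward(object$weights, arch, x)$out
  colnames(P) <- object$classes
  if (type == "prob") P else object$classes[max.col(P)]
}

prepare_segments <- function(newdata, input_len) {
  x <- if (inherits(newdata, "beat_dataset")) newdata$x else newdata
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != input_len)
    tb_stop("segments have %d samples; model expects %d", ncol(x), input_len,
            class = "tinybeat_shape_error")
  x
}

#' @export
print.beat_cnn <- function(x, ...) {
  cat(sprintf("<beat_cnn> %s architecture, %d parameters, trained %d epochs (best %d)\n",
              x$architecture$preset, count_parameters(x), nrow(x$history),
              x$best_epoch))
  invisible(x)
}

#' @export
summary.beat_cnn <- function(object, ...) {
  print(object$architecture)
  h <- object$history
  last <- h[nrow(h), ]
  cat(sprintf("training: %d epochs, final loss %.4f, accuracy %.4f\n",
              nrow(h), last$loss, last$accuracy))
  if (!is.na(last$val_loss))
    cat(sprintf("validation: best loss %.4f at epoch %d\n",
                min(h$val_loss, na.rm = TRUE), object$best_epoch))
  invisible(object)
}

#' @export
coef.beat_cnn <- function(object, ...) {
  w <- object$weights
  names(w) <- vapply(seq_along(object$architecture$layers), function(i) {
    ly <- object$architecture$layers[[i]]
    sprintf("%d_%s", i, ly$type)
  }, character(1))
  w[!vapply(w, is.null, TRUE)]
}

#' @export
plot.beat_cnn <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "training history", ...)
  if (!all(is.na(h$val_loss))) {
    lines(h$epoch, h$val_loss, lty = 2)
    legend("topright", legend = c("train", "validation"), lty = c(1, 2),
           bty = "n")
  }
  invisible(x)
}

#' Export training history as CSV
#' @param model a fitted [beat_cnn()].
#' @param path output path.
#' @export
export_history_csv <- function(model, path) {
  stopifnot(inherits(model, "beat_cnn"))
  write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
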