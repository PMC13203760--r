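# Shared fixtures (built once per test run) and independent reference
# implementations used as oracles.

.tb_cache <- new.env(parent = emptyenv())

tb_fixture <- function(name, expr) {
  if (!exists(name, .tb_cache)) assign(name, force(expr), .tb_cache)
  get(name, .tb_cache)
}

# Small trained model + split used by several module tests.
small_fit <- function() tb_fixture("small_fit", {
  ds <- synth_beat_dataset(600, seed = 1)
  sp <- stratified_split(ds, seed = 2)
  model <- beat_cnn(sp$train, validation = sp$validation,
                    control = beat_cnn_control(epochs = 12), seed = 3)
  qm <- quantize(model, representative = sp$train, seed = 4)
  list(ds = ds, split = sp, model = model, qm = qm)
})

# Study-conditions fixture: 3,000 training beats (seed 1), 600 test beats
# (seed 9), Table-2 hyperparameters with early stopping, 200-segment
# calibration subsample (seed 2).
study_fit <- function() tb_fixture("study_fit", {
  train_ds <- synth_beat_dataset(3000, seed = 1)
  test_ds <- synth_beat_dataset(600, seed = 9)
  sp <- stratified_split(train_ds, c(0.8, 0.2, 0), seed = 1)
  model <- beat_cnn(sp$train, validation = sp$validation, seed = 1)
  qm <- quantize(model, representative = sp$train, seed = 2)
  list(train = train_ds, test = test_ds, model = model, qm = qm)
})

# --- pure-R reference integer engine -------------------------------------
# Independent of the compiled kernels; every intermediate is checked to be
# an exact integer (an arithmetic trace of the FPU-less path).

r_requantize <- function(acc, m0, n) {
  stopifnot(acc == round(acc), abs(acc * m0) < 2^53)
  v <- (acc * m0) / 2^(31 + n)
  sign(v) * floor(abs(v) + 0.5)
}

r_int8_clamp <- function(q, lo = -128) pmin(127, pmax(lo, q))

r_conv1d_int8 <- function(input, layer) {
  k <- layer$kernel
  cin <- ncol(input)
  t_out <- nrow(input) - k + 1L
  out <- matrix(0L, t_out, layer$filters)
  lo <- if (identical(layer$activation, "relu")) layer$zp_out else -128
  for (o in seq_len(layer$filters)) {
    for (t in seq_len(t_out)) {
      acc <- layer$b[[o]]
      for (c in seq_len(cin))
        for (kk in seq_len(k))
          acc <- acc + (input[t + kk - 1L, c] - layer$zp_in) *
            layer$W[kk, c, o]
      stopifnot(acc == round(acc), abs(acc) < 2^31)
      q <- r_requantize(acc, layer$m0, layer$n) + layer$zp_out
      out[t, o] <- r_int8_clamp(q, lo)
    }
  }
  storage.mode(out) <- "integer"
  out
}

r_dense_int8 <- function(input, layer) {
  lo <- if (identical(layer$activation, "relu")) layer$zp_out else -128
  out <- integer(ncol(layer$W))
  for (j in seq_along(out)) {
    acc <- layer$b[[j]] + sum((input - layer$zp_in) * layer$W[, j])
    stopifnot(acc == round(acc), abs(acc) < 2^31)
    out[[j]] <- r_int8_clamp(r_requantize(acc, layer$m0, layer$n) +
                               layer$zp_out, lo)
  }
  out
}

# Build a quantized conv/dense layer directly from float tensors and
# explicit activation ranges (bypassing model calibration) for kernel
# tests.
make_qlayer <- function(type, W, b, in_range, out_range, activation = "relu") {
  qp_in <- choose_qparams(in_range, "activations")
  qp_w <- choose_qparams(range(W), "weights")
  qp_out <- choose_qparams(out_range, "activations")
  mult <- tinybeat:::quantize_multiplier(qp_in$scale * qp_w$scale /
                                           qp_out$scale)
  list(type = type, activation = activation,
       W = quantize_value(W, qp_w),
       b = as.integer(round(b / (qp_in$scale * qp_w$scale))),
       kernel = if (type == "conv") dim(W)[[1L]] else NA_integer_,
       filters = if (type == "conv") dim(W)[[3L]] else ncol(W),
       s_in = qp_in$scale, zp_in = qp_in$zero_point,
       s_w = qp_w$scale, s_out = qp_out$scale,
       zp_out = qp_out$zero_point, m0 = mult$m0, n = mult$n,
       qp_in = qp_in, qp_w = qp_w, qp_out = qp_out)
}

# Brute-force per-class metric recount (independent of the metrics
# engine).
brute_metrics <- function(y_true, y_pred) {
  classes <- c("N", "V", "S")
  out <- list()
  for (cl in classes) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out[[cl]] <- c(precision = prec, recall = rec, f1 = f1,
                   support = sum(y_true == cl))
  }
  out
}

# Brute-force one-vs-rest AUC by pairwise comparison counts.
brute_auc_ovr <- function(y_true, prob) {
  classes <- c("N", "V", "S")
  aucs <- numeric(0)
  supports <- numeric(0)
  for (k in seq_along(classes)) {
    pos <- which(y_true == classes[[k]])
    neg <- which(y_true != classes[[k]])
    if (!length(pos) || !length(neg)) next
    wins <- 0
    for (i in pos)
      for (j in neg)
        wins <- wins + (prob[i, k] > prob[j, k]) + 0.5 * (prob[i, k] == prob[j, k])
    aucs <- c(aucs, wins / (length(pos) * length(neg)))
    supports <- c(supports, length(pos))
  }
  sum(aucs * supports) / sum(supports)
}
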