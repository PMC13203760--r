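# Post-training full-integer INT8 quantization: per-tensor symmetric
# weights, asymmetric activations, int32 biases at s_in*s_w, and
# fixed-point requantization multipliers m0 * 2^-31 * 2^-n.  Batch-norm
# layers are folded into the preceding convolution (exact for inference
# mode) before weights are quantized.

#' Calibrate activation ranges on representative data
#'
#' Runs the float model in inference mode over a representative set of
#' segments and records the min/max of every quantized tensor (network
#' input, each post-activation feature map, and the output logits).  Each
#' range is widened so that zero is representable; an all-constant tensor
#' widens to a nonzero interval containing zero.
#'
#' @param model a fitted [beat_cnn()].
#' @param representative matrix or [beat_dataset()] of segments
#'   (nonempty).
#' @return named list of `c(min, max)` ranges keyed `"input"` and
#'   `"L<i>"` for each compute layer `i`.
#' @export
calibrate <- function(model, representative) {
  stopifnot(inherits(model, "beat_cnn"))
  x <- prepare_segments(representative, model$architecture$input_len)
  if (nrow(x) == 0L)
    tb_stop("representative set is empty", class = "tinybeat_calibration_error")
  fwd <- nn_forward(model$weights, model$architecture, x)
  widen <- function(r) {
    lo <- min(0, r[[1L]])
    hi <- max(0, r[[2L]])
    if (hi == lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
    c(lo, hi)
  }
  ranges <- list(input = widen(range(x)))
  layers <- model$architecture$layers
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      act <- pmax(fwd$caches[[i]]$pre, 0)
      ranges[[sprintf("L%d", i)]] <- widen(range(act))
    } else if (ly$type == "dense") {
      pre <- fwd$caches[[i]]$pre
      act <- if (ly$activation == "softmax") pre else pmax(pre, 0)
      ranges[[sprintf("L%d", i)]] <- widen(range(act))
    }
  }
  ranges
}

#' Choose affine quantization parameters for a range
#'
#' Weights use symmetric per-tensor quantization
#' (`scale = max(|min|, |max|) / 127`, zero point 0); activations use the
#' asymmetric scheme (`scale = (max - min) / 255`,
#' `zero_point = round(-128 - min/scale)` clamped to the int8 domain).
#'
#' @param range numeric `c(min, max)` with `max >= min`.
#' @param kind `"weights"` or `"activations"`.
#' @return list with `scale` (> 0) and `zero_point` (int in \[-128, 127\]).
#' @export
choose_qparams <- function(range, kind = c("weights", "activations")) {
  kind <- match.arg(kind)
  lo <- range[[1L]]; hi <- range[[2L]]
  if (hi < lo) tb_stop("max < min", class = "tinybeat_parameter_error")
  if (kind == "weights") {
    # an all-zero tensor carries no scale information; use a unit range
    amax <- max(abs(lo), abs(hi))
    if (amax == 0) amax <- 1
    list(scale = amax / 127, zero_point = 0L)
  } else {
    if (hi == lo)
      tb_stop("degenerate range after widening",
              class = "tinybeat_parameter_error")
    scale <- (hi - lo) / 255
    zp <- round(-128 - lo / scale)
    list(scale = scale,
         zero_point = as.integer(max(-128, min(127, zp))))
  }
}

# round half away from zero (R's round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Quantize real values to int8
#'
#' `q = clamp(round(x / scale) + zero_point, -128, 127)` with rounding
#' half away from zero; saturating, never erroring.
#'
#' @param x numeric vector/array.
#' @param qp a [choose_qparams()] result.
#' @return integer vector/array of int8 values.
#' @export
quantize_value <- function(x, qp) {
  q <- round_half_away(x / qp$scale) + qp$zero_point
  q <- pmax(-128, pmin(127, q))
  out <- as.integer(q)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Dequantize int8 values
#' @param q int8 values.
#' @param qp quantization parameters.
#' @return numeric values `(q - zero_point) * scale`.
#' @export
dequantize_value <- function(q, qp) (q - qp$zero_point) * qp$scale

# Decompose a positive real multiplier M as m0 * 2^-31 * 2^-n with
# m0 in [2^30, 2^31); relative error bounded by 2^-31.
quantize_multiplier <- function(M) {
  stopifnot(M > 0)
  n <- 0L
  m <- M * 2^31
  while (m < 2^30) { m <- m * 2; n <- n + 1L }
  while (m >= 2^31) { m <- m / 2; n <- n - 1L }
  m0 <- round(m)
  if (m0 >= 2^31) { m0 <- 2^30; n <- n - 1L }
  list(m0 = m0, n = n)
}

# Fold batch normalization (inference mode, eps matching training) into
# conv weights/biases; returns the effective float tensors.
fold_conv_bn <- function(w, has_bn, eps = 1e-3) {
  if (!has_bn) return(list(W = w$W, b = w$b))
  inv <- w$gamma / sqrt(w$running_var + eps)
  W <- sweep(w$W, 3L, inv, "*")
  b <- w$beta + (w$b - w$running_mean) * inv
  list(W = W, b = b)
}

#' Convert a float model to a full-integer INT8 model
#'
#' Post-training quantization of a fitted [beat_cnn()]: batch norm is
#' folded into the convolutions, weights are quantized per-tensor
#' symmetric to int8, biases to int32 at `s_in * s_w`, and each compute
#' layer gets a fixed-point requantization constant.  Weight tensor
#' payloads shrink to exactly 25% of their float32 bytes.
#'
#' @param object a fitted [beat_cnn()].
#' @param representative representative segments for calibration; by
#'   default a seeded 200-segment subsample of `calibration_data`.
#' @param calibration optionally, precomputed [calibrate()] ranges.
#' @param n_representative subsample size when `representative` is a
#'   larger dataset.
#' @param seed seed for the calibration subsample.
#' @param ... unused.
#' @return an object of class `quant_beat_cnn`.
#' @export
quantize <- function(object, ...) UseMethod("quantize")

#' @rdname quantize
#' @export
quantize.beat_cnn <- function(object, representative, calibration = NULL,
                              n_representative = 200L, seed = 1L, ...) {
  arch <- object$architecture
  if (is.null(calibration)) {
    x <- prepare_segments(representative, arch$input_len)
    if (nrow(x) > n_representative) {
      old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      set.seed(seed)
      x <- x[sample.int(nrow(x), n_representative), , drop = FALSE]
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
    }
    calibration <- calibrate(object, x)
  }
  qp_in <- choose_qparams(calibration$input, "activations")
  layers <- vector("list", length(arch$layers))
  s_in <- qp_in$scale
  zp_in <- qp_in$zero_point
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$type %in% c("maxpool", "flatten")) {
      layers[[i]] <- list(type = ly$type, pool = ly$pool %||% NA_integer_)
      next
    }
    key <- sprintf("L%d", i)
    if (is.null(calibration[[key]]))
      tb_stop("missing calibration range for layer %d", i,
              class = "tinybeat_conversion_error")
    eff <- if (ly$type == "conv")
      fold_conv_bn(object$weights[[i]], isTRUE(ly$batch_norm))
    else object$weights[[i]]
    qp_w <- choose_qparams(range(eff$W), "weights")
    qp_out <- choose_qparams(calibration[[key]], "activations")
    W_q <- quantize_value(eff$W, qp_w)
    b_q <- as.integer(round_half_away(eff$b / (s_in * qp_w$scale)))
    mult <- quantize_multiplier(s_in * qp_w$scale / qp_out$scale)
    layers[[i]] <- list(type = ly$type, activation = ly$activation,
                        W = W_q, b = b_q,
                        kernel = ly$kernel %||% NA_integer_,
                        filters = ly$filters %||% ly$units,
                        s_in = s_in, zp_in = zp_in,
                        s_w = qp_w$scale,
                        s_out = qp_out$scale, zp_out = qp_out$zero_point,
                        m0 = mult$m0, n = mult$n)
    s_in <- qp_out$scale
    zp_in <- qp_out$zero_point
  }
  structure(list(layers = layers, input_qp = qp_in, classes = object$classes,
                 architecture = arch, calibration = calibration),
            class = "quant_beat_cnn")
}

#' @export
print.quant_beat_cnn <- function(x, ...) {
  payload <- weight_payload_bytes(x)
  cat(sprintf("<quant_beat_cnn> %s architecture, INT8 weights (%d bytes; float32 would be %d)\n",
              x$architecture$preset, payload, payload * 4L))
  invisible(x)
}

#' Weight tensor payload size in bytes
#'
#' Int8 weight tensors occupy 1 byte per element, exactly 25% of their
#' float32 storage.
#'
#' @param qm a [quantize()]d model.
#' @param dtype `"int8"` or `"float32"`.
#' @return integer byte count.
#' @export
weight_payload_bytes <- function(qm, dtype = c("int8", "float32")) {
  dtype <- match.arg(dtype)
  n <- sum(vapply(qm$layers, function(l) length(l$W %||% integer(0)),
                  integer(1)))
  as.integer(n * if (dtype == "int8") 1L else 4L)
}

# ---- portable container -------------------------------------------------

QUANT_MAGIC <- charToRaw("TBQ1")

#' Serialize / save / load a quantized model
#'
#' Portable single-file layout: magic, format version, JSON metadata
#' (shapes, zero points, requantization constants, class alphabet)
#' followed by the binary tensor sections (int8 weights, int32 biases,
#' float64 scales).  The serialized byte count is the Flash payload used
#' by [footprint()].  `serialize_quant_model` returns the raw bytes;
#' `save_quant_model`/`load_quant_model` round-trip losslessly.
#'
#' @param qm a [quantize()]d model.
#' @param path file path.
#' @return raw vector (`serialize_quant_model`) or the model
#'   (`load_quant_model`).
#' @export
serialize_quant_model <- function(qm) {
  stopifnot(inherits(qm, "quant_beat_cnn"))
  meta <- list(
    version = 1L,
    preset = qm$architecture$preset,
    input_len = qm$architecture$input_len,
    n_classes = qm$architecture$n_classes,
    classes = qm$classes,
    input_zp = qm$input_qp$zero_point,
    layers = lapply(qm$layers, function(l) {
      out <- list(type = l$type)
      if (l$type == "maxpool") out$pool <- l$pool
      if (!is.null(l$W)) {
        out$dims <- dim(l$W) %||% length(l$W)
        out$n_bias <- length(l$b)
        out$zp_in <- l$zp_in
        out$zp_out <- l$zp_out
        out$m0 <- l$m0
        out$n <- l$n
        out$activation <- l$activation
        out$kernel <- l$kernel
        out$filters <- l$filters
      }
      out
    }))
  meta_raw <- charToRaw(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)))
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(QUANT_MAGIC, con)
  writeBin(as.integer(length(meta_raw)), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  scales <- qm$input_qp$scale
  for (l in qm$layers) {
    if (is.null(l$W)) next
    writeBin(as.integer(l$W), con, size = 1L)
    writeBin(as.integer(l$b), con, size = 4L, endian = "little")
    scales <- c(scales, l$s_in, l$s_w, l$s_out)
  }
  writeBin(as.numeric(scales), con, size = 8L, endian = "little")
  rawConnectionValue(con)
}

#' @rdname serialize_quant_model
#' @export
save_quant_model <- function(qm, path) {
  writeBin(serialize_quant_model(qm), path)
  invisible(path)
}

#' @rdname serialize_quant_model
#' @export
load_quant_model <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  parse_quant_model(bytes)
}

parse_quant_model <- function(bytes) {
  if (length(bytes) < 8L || !identical(bytes[1:4], QUANT_MAGIC))
    tb_stop("not a tinybeat quantized-model container",
            class = "tinybeat_format_error")
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  readBin(con, "raw", 4L)
  meta_len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", meta_len)),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!isTRUE(meta$version == 1))
    tb_stop("quantized-model container version %s not supported",
            meta$version, class = "tinybeat_format_error")
  arch <- beat_cnn_architecture(meta$preset, input_len = meta$input_len,
                                n_classes = meta$n_classes)
  layers <- vector("list", length(meta$layers))
  tensors <- list()
  for (i in seq_along(meta$layers)) {
    ml <- meta$layers[[i]]
    if (is.null(ml$dims)) {
      layers[[i]] <- list(type = ml$type, pool = ml$pool %||% NA_integer_)
      next
    }
    dims <- as.integer(unlist(ml$dims))
    W <- readBin(con, "integer", prod(dims), size = 1L, signed = TRUE)
    if (length(dims) > 1L) dim(W) <- dims
    b <- readBin(con, "integer", ml$n_bias, size = 4L, endian = "little")
    layers[[i]] <- list(type = ml$type, activation = ml$activation,
                        W = W, b = b,
                        kernel = ml$kernel %||% NA_integer_,
                        filters = ml$filters,
                        zp_in = as.integer(ml$zp_in),
                        zp_out = as.integer(ml$zp_out),
                        m0 = ml$m0, n = as.integer(ml$n))
  }
  scale_in <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  for (i in seq_along(layers)) {
    if (is.null(layers[[i]]$W)) next
    s <- readBin(con, "numeric", 3L, size = 8L, endian = "little")
    layers[[i]]$s_in <- s[[1L]]
    layers[[i]]$s_w <- s[[2L]]
    layers[[i]]$s_out <- s[[3L]]
  }
  structure(list(layers = layers,
                 input_qp = list(scale = scale_in,
                                 zero_point = as.integer(meta$input_zp)),
                 classes = unlist(meta$classes), architecture = arch,
                 calibration = NULL),
            class = "quant_beat_cnn")
}

#' Export the serialized model as a C header
#'
#' xxd-style array suitable for embedding in microcontroller firmware:
#' one `unsigned char` array holding the serialized model plus a length
#' constant.
#'
#' @param qm a [quantize()]d model.
#' @param path optional output path; when `NULL` the header text is
#'   returned.
#' @param name C identifier for the array.
#' @return header text (invisibly when written to `path`).
#' @export
export_c_header <- function(qm, path = NULL, name = "model") {
  bytes <- serialize_quant_model(qm)
  hex <- sprintf("0x%02x", as.integer(bytes))
  rows <- tapply(hex, (seq_along(hex) - 1L) %/% 12L, paste, collapse = ", ")
  body <- paste0("  ", rows, collapse = ",\n")
  text <- paste0("unsigned char ", name, "[] = {\n", body, "\n};\n",
                 "unsigned int ", name, "_len = ", length(bytes), ";\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}
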