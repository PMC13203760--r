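# Integer-only inference engine.  The classification path uses int8
# tensors, int32 accumulators and fixed-point requantization only (no
# floating-point operation from quantized input to argmax), emulating
# execution on a microcontroller without an FPU.  Probabilities, when
# requested, are a display feature computed by dequantizing the logits
# and applying softmax in floating point.

#' Fixed-point requantization
#'
#' Rescales an int32 accumulator by the real multiplier
#' `M = m0 * 2^-31 * 2^-n` using integer arithmetic only, rounding half
#' away from zero; results saturate at the int32 bounds.
#'
#' @param acc int32 accumulator value(s).
#' @param m0 fixed-point mantissa in `[2^30, 2^31)`.
#' @param n right-shift exponent.
#' @return rescaled integer(s).
#' @export
requantize <- function(acc, m0, n) {
  stopifnot(m0 >= 2^30, m0 < 2^31)
  vapply(acc, function(a) requantize_core(a, m0, as.integer(n)), integer(1))
}

#' Int8 convolution / pooling / dense layers
#'
#' Reference entry points to the integer-only layer kernels: valid
#' stride-1 convolution and full connection with int32 accumulation
#' (`acc = sum (q_in - zp_in) * q_w + bias`), fixed-point requantization,
#' output zero-point shift and saturation to int8 (ReLU fused as a clamp
#' at the output zero point), and non-overlapping temporal max pooling
#' (quantization parameters pass through unchanged).
#'
#' @param input int8 matrix (time x channels) for `conv1d_int8` /
#'   `maxpool_int8`, int8 vector for `dense_int8`.
#' @param layer quantized layer descriptor (a `quant_beat_cnn` layer).
#' @param pool pooling width.
#' @return int8 matrix or vector.
#' @export
conv1d_int8 <- function(input, layer) {
  check_qlayer(layer, "conv")
  conv1d_int8_core(input, as.integer(layer$W), layer$b,
                   as.integer(layer$kernel), as.integer(layer$filters),
                   layer$zp_in, layer$zp_out, layer$m0, layer$n,
                   identical(layer$activation, "relu"))
}

#' @rdname conv1d_int8
#' @export
dense_int8 <- function(input, layer) {
  check_qlayer(layer, "dense")
  dense_int8_core(as.integer(input), layer$W, layer$b, layer$zp_in,
                  layer$zp_out, layer$m0, layer$n,
                  identical(layer$activation, "relu"))
}

#' @rdname conv1d_int8
#' @export
maxpool_int8 <- function(input, pool = 2L) {
  maxpool_int8_core(input, as.integer(pool))
}

check_qlayer <- function(layer, type) {
  if (!identical(layer$type, type))
    tb_stop("expected a quantized %s layer", type,
            class = "tinybeat_contract_error")
  invisible(TRUE)
}

# Integer forward pass for one segment already quantized to int8.
quant_forward_int8 <- function(qm, q_in) {
  A <- matrix(as.integer(q_in), ncol = 1L)    # time x channels
  for (l in qm$layers) {
    if (l$type == "conv") {
      A <- conv1d_int8(A, l)
    } else if (l$type == "maxpool") {
      A <- maxpool_int8(A, l$pool)
    } else if (l$type == "flatten") {
      A <- as.integer(A)                      # time fastest within channel
    } else if (l$type == "dense") {
      A <- dense_int8(A, l)
    }
  }
  A                                           # int8 logits
}

#' Classify a beat with the integer-only engine
#'
#' Quantizes a normalized 250-sample segment with the model's input
#' parameters and runs the whole network in integer arithmetic; the label
#' is the argmax over the final int8 logits (softmax is monotone, so it is
#' excluded from the integer path).
#'
#' @param qm a [quantize()]d model.
#' @param segment numeric vector of 250 samples in \[0, 1\].
#' @param probs also return display probabilities (computed in floating
#'   point from the dequantized logits).
#' @return list with `label`, `logits_int8`, and optionally `probabilities`.
#' @export
classify <- function(qm, segment, probs = FALSE) {
  stopifnot(inherits(qm, "quant_beat_cnn"))
  if (length(segment) != qm$architecture$input_len)
    tb_stop("segment has %d samples; model expects %d", length(segment),
            qm$architecture$input_len, class = "tinybeat_shape_error")
  q_in <- quantize_value(segment, qm$input_qp)
  logits <- quant_forward_int8(qm, q_in)
  out <- list(label = qm$classes[which.max(logits)], logits_int8 = logits)
  if (probs) {
    last <- qm$layers[[length(qm$layers)]]
    lg <- dequantize_value(logits, list(scale = last$s_out,
                                        zero_point = last$zp_out))
    e <- exp(lg - max(lg))
    out$probabilities <- stats::setNames(e / sum(e), qm$classes)
  }
  out
}

#' Predict from a quantized model
#'
#' @param object a [quantize()]d model.
#' @param newdata a [beat_dataset()] or matrix of normalized segments.
#' @param type `"class"` (integer-only path), `"prob"` (display
#'   probabilities from dequantized logits) or `"logits"` (raw int8
#'   logits).
#' @param ... unused.
#' @export
predict.quant_beat_cnn <- function(object, newdata,
                                   type = c("class", "prob", "logits"),
                                   ...) {
  type <- match.arg(type)
  x <- prepare_segments(newdata, object$architecture$input_len)
  n <- nrow(x)
  logits <- matrix(0L, n, object$architecture$n_classes)
  for (i in seq_len(n))
    logits[i, ] <- quant_forward_int8(object,
                                      quantize_value(x[i, ], object$input_qp))
  colnames(logits) <- object$classes
  if (type == "logits") return(logits)
  if (type == "class") return(object$classes[max.col(logits, ties.method = "first")])
  last <- object$layers[[length(object$layers)]]
  lg <- dequantize_value(logits, list(scale = last$s_out,
                                      zero_point = last$zp_out))
  P <- softmax_rows(lg)
  colnames(P) <- object$classes
  P
}

#' Flash / SRAM footprint accounting
#'
#' Flash is the serialized model payload ([serialize_quant_model()]
#' bytes).  SRAM is the peak, over a two-buffer ping-pong execution
#' schedule, of live input buffer + live output buffer + the int32
#' scratch accumulators for one output tile (one time step of output
#' channels for convolutions, the full unit vector for dense layers), all
#' at native widths (int8 activations, int32 scratch).
#'
#' @param qm a [quantize()]d model.
#' @return object of class `memory_footprint` with `flash_bytes`,
#'   `sram_bytes` and a per-layer table.
#' @export
footprint <- function(qm) {
  stopifnot(inherits(qm, "quant_beat_cnn"))
  arch <- qm$architecture
  shapes <- arch_shapes(arch)
  in_elems <- arch$input_len
  rows <- list()
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    sh <- shapes[[i]]
    out_elems <- as.integer(prod(sh))
    if (ly$type %in% c("conv", "dense")) {
      scratch <- 4L * if (ly$type == "conv") ly$filters else ly$units
      rows[[length(rows) + 1L]] <-
        data.frame(layer = i, type = ly$type, in_bytes = in_elems,
                   out_bytes = out_elems, scratch_bytes = scratch,
                   total = in_elems + out_elems + scratch)
    } else if (ly$type == "maxpool") {
      rows[[length(rows) + 1L]] <-
        data.frame(layer = i, type = ly$type, in_bytes = in_elems,
                   out_bytes = out_elems, scratch_bytes = 0L,
                   total = in_elems + out_elems)
    }
    in_elems <- out_elems
  }
  tab <- do.call(rbind, rows)
  structure(list(flash_bytes = length(serialize_quant_model(qm)),
                 sram_bytes = max(tab$total), per_layer = tab),
            class = "memory_footprint")
}

#' @export
print.memory_footprint <- function(x, ...) {
  cat(sprintf("<memory_footprint> flash %.1f KB, sram peak %.2f KB\n",
              x$flash_bytes / 1024, x$sram_bytes / 1024))
  print(x$per_layer, row.names = FALSE)
  invisible(x)
}
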