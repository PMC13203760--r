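#' Describe the compact 1D-CNN architecture
#'
#' The canonical (`"table1"`) topology is
#' Conv1D(16, k=3, ReLU) -> MaxPool(2) -> Conv1D(32, k=3, ReLU) ->
#' Flatten -> Dense(64, ReLU) -> Dense(3, softmax), operating on
#' 250-sample single-channel beat windows with valid (no-padding)
#' convolutions, so shapes propagate as
#' (250,1) -> (248,16) -> (124,16) -> (122,32) -> 3904 -> 64 -> 3.
#' Batch normalization after each convolution and dropout before the final
#' dense layer are on by default.
#'
#' The `"reduced"` preset adds a second MaxPool(2) after the second
#' convolution and shrinks the hidden dense layer to 9 units, bringing the
#' parameter count down to the ~18.5k regime; it is provided as an
#' explicit configuration preset, never silently.
#'
#' @param preset `"table1"` (canonical) or `"reduced"`.
#' @param batch_norm apply batch normalization after each convolution.
#' @param input_len beat window length in samples.
#' @param n_classes number of output classes.
#' @return an object of class `beat_cnn_architecture`.
#' @export
beat_cnn_architecture <- function(preset = c("table1", "reduced"),
                                  batch_norm = TRUE, input_len = 250L,
                                  n_classes = 3L) {
  preset <- match.arg(preset)
  conv <- function(f) list(type = "conv", filters = f, kernel = 3L,
                           activation = "relu", batch_norm = batch_norm)
  layers <- if (preset == "table1") list(
    conv(16L), list(type = "maxpool", pool = 2L), conv(32L),
    list(type = "flatten"),
    list(type = "dense", units = 64L, activation = "relu"),
    list(type = "dense", units = n_classes, activation = "softmax",
         dropout_before = TRUE))
  else list(
    conv(16L), list(type = "maxpool", pool = 2L), conv(32L),
    list(type = "maxpool", pool = 2L), list(type = "flatten"),
    list(type = "dense", units = 9L, activation = "relu"),
    list(type = "dense", units = n_classes, activation = "softmax",
         dropout_before = TRUE))
  arch <- structure(list(preset = preset, input_len = as.integer(input_len),
                         n_classes = as.integer(n_classes), layers = layers),
                    class = "beat_cnn_architecture")
  arch_shapes(arch)  # validates propagation
  arch
}

#' Shape propagation through the architecture
#'
#' @param arch a [beat_cnn_architecture()].
#' @return list of per-layer output shapes, each `c(time, channels)` for
#'   convolutional stages or a single width for flat stages.
#' @export
arch_shapes <- function(arch) {
  stopifnot(inherits(arch, "beat_cnn_architecture"))
  shape <- c(arch$input_len, 1L)
  out <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    shape <- switch(ly$type,
      conv = {
        t_out <- shape[[1L]] - ly$kernel + 1L
        if (t_out < 1L)
          tb_stop("layer %d: input length %d shorter than kernel %d", i,
                  shape[[1L]], ly$kernel, class = "tinybeat_architecture_error")
        c(t_out, ly$filters)
      },
      maxpool = c(shape[[1L]] %/% ly$pool, shape[[2L]]),
      flatten = shape[[1L]] * shape[[2L]],
      dense = {
        if (length(shape) != 1L)
          tb_stop("dense layer %d requires flat input", i,
                  class = "tinybeat_architecture_error")
        ly$units
      },
      tb_stop("unknown layer type '%s'", ly$type,
              class = "tinybeat_architecture_error"))
    out[[i]] <- shape
  }
  last <- out[[length(out)]]
  if (last != arch$n_classes)
    tb_stop("final layer width %d != number of classes %d", last,
            arch$n_classes, class = "tinybeat_architecture_error")
  out
}

#' @export
print.beat_cnn_architecture <- function(x, ...) {
  shapes <- arch_shapes(x)
  cat(sprintf("<beat_cnn_architecture> preset '%s', input (%d, 1)\n",
              x$preset, x$input_len))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    desc <- switch(ly$type,
      conv = sprintf("Conv1D(%d, k=%d, %s%s)", ly$filters, ly$kernel,
                     ly$activation, if (isTRUE(ly$batch_norm)) " + BN" else ""),
      maxpool = sprintf("MaxPool(%d)", ly$pool),
      flatten = "Flatten",
      dense = sprintf("Dense(%d, %s)%s", ly$units, ly$activation,
                      if (isTRUE(ly$dropout_before)) " [dropout before]" else ""))
    sh <- shapes[[i]]
    cat(sprintf("  %-34s -> %s\n", desc,
                if (length(sh) == 2L) sprintf("(%d, %d)", sh[[1L]], sh[[2L]])
                else as.character(sh)))
  }
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sum over layers of weight and bias element counts (batch-norm gain and
#' shift included; running statistics excluded as non-trainable).
#'
#' @param object a [beat_cnn_architecture()] or fitted [beat_cnn()].
#' @return integer parameter count.
#' @export
count_parameters <- function(object) UseMethod("count_parameters")

#' @export
count_parameters.beat_cnn_architecture <- function(object) {
  shapes <- arch_shapes(object)
  shape <- c(object$input_len, 1L)
  total <- 0L
  for (i in seq_along(object$layers)) {
    ly <- object$layers[[i]]
    if (ly$type == "conv") {
      total <- total + ly$kernel * shape[[2L]] * ly$filters + ly$filters
      if (isTRUE(ly$batch_norm)) total <- total + 2L * ly$filters
    } else if (ly$type == "dense") {
      total <- total + shape[[1L]] * ly$units + ly$units
    }
    shape <- shapes[[i]]
  }
  as.integer(total)
}

#' @export
count_parameters.beat_cnn <- function(object) {
  total <- 0L
  for (w in object$weights) {
    if (is.null(w)) next
    for (nm in intersect(c("W", "b", "gamma", "beta"), names(w)))
      total <- total + length(w[[nm]])
  }
  as.integer(total)
}
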