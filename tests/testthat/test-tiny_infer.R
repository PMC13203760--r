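test_that("requantize follows the fixed-point rounding rule", {
  # M = 0.25 -> m0 = 2^30, n = 1
  expect_identical(requantize(128, 2^30, 1L), 32L)
  # M = 0.5 -> m0 = 2^30, n = 0; 3 * 0.5 = 1.5 rounds away from zero
  expect_identical(requantize(3, 2^30, 0L), 2L)
  expect_identical(requantize(-3, 2^30, 0L), -2L)
  expect_identical(requantize(0, 2^30 + 12345, 3L), 0L)
  # agrees with the R reference on random accumulators
  set.seed(5)
  for (i in 1:50) {
    acc <- sample(-10^6:10^6, 1)
    M <- 10^runif(1, -4, 0)
    d <- tinybeat:::quantize_multiplier(M)
    expect_identical(as.numeric(requantize(acc, d$m0, d$n)),
                     r_requantize(acc, d$m0, d$n))
  }
})

test_that("int8 max pooling matches its definition", {
  m <- matrix(c(1L, 5L, 3L, 2L), 4, 1)
  expect_identical(as.vector(maxpool_int8(m, 2L)), c(5L, 3L))
  cst <- matrix(7L, 6, 3)
  expect_true(all(maxpool_int8(cst, 2L) == 7L))
  expect_identical(nrow(maxpool_int8(matrix(0L, 248, 16), 2L)), 124L)
  expect_identical(nrow(maxpool_int8(matrix(0L, 7, 2), 2L)), 3L)
})

test_that("int8 convolution propagates an identity kernel", {
  W <- array(1.0, c(1, 1, 1))
  l <- make_qlayer("conv", W, 0, in_range = c(0, 1), out_range = c(0, 1))
  x <- seq(0, 1, length.out = 12)
  q_in <- quantize_value(x, l$qp_in)
  out <- conv1d_int8(matrix(q_in, ncol = 1), l)
  deq <- dequantize_value(as.vector(out), l$qp_out)
  expect_true(all(abs(deq - x) <= l$s_out + 1e-12))
})

test_that("int8 conv and dense agree with the float oracle and R reference", {
  set.seed(3)
  for (trial in 1:20) {
    # conv: 12-sample input, 2 input channels, 2 filters
    W <- array(rnorm(3 * 2 * 2, sd = 0.4), c(3, 2, 2))
    b <- rnorm(2, sd = 0.1)
    x <- matrix(runif(24, -1, 1), 12, 2)
    l <- make_qlayer("conv", W, b, in_range = c(-1, 1),
                     out_range = c(0, 3), activation = "relu")
    q_in <- quantize_value(x, l$qp_in)
    out_c <- conv1d_int8(q_in, l)
    expect_identical(unname(as.matrix(out_c)), unname(r_conv1d_int8(q_in, l)))
    # float oracle on dequantized tensors
    xd <- dequantize_value(q_in, l$qp_in)
    wd <- l$W * l$s_w
    bd <- l$b * (l$s_in * l$s_w)
    ref <- matrix(0, 10, 2)
    for (o in 1:2)
      for (t in 1:10)
        ref[t, o] <- max(0, sum(xd[t:(t + 2), ] * wd[, , o]) + bd[[o]])
    ref <- pmin(ref, (127 - l$zp_out) * l$s_out)   # int8 saturation
    deq <- dequantize_value(as.matrix(out_c), l$qp_out)
    expect_true(all(abs(deq - ref) <= l$s_out + 1e-9))
  }

  set.seed(5)
  for (trial in 1:20) {
    W <- matrix(rnorm(8 * 3, sd = 0.5), 8, 3)
    b <- rnorm(3, sd = 0.2)
    x <- runif(8, -1, 1)
    l <- make_qlayer("dense", W, b, in_range = c(-1, 1),
                     out_range = c(-2, 2), activation = "linear")
    q_in <- quantize_value(x, l$qp_in)
    out <- dense_int8(q_in, l)
    expect_identical(as.integer(out), as.integer(r_dense_int8(q_in, l)))
    xd <- dequantize_value(q_in, l$qp_in)
    ref <- as.vector(xd %*% (l$W * l$s_w)) + l$b * (l$s_in * l$s_w)
    ref <- pmin(pmax(ref, (-128 - l$zp_out) * l$s_out),
                (127 - l$zp_out) * l$s_out)
    deq <- dequantize_value(as.vector(out), l$qp_out)
    expect_true(all(abs(deq - ref) <= l$s_out + 1e-9))
  }
})

test_that("fused ReLU clamps all-negative pre-activations at the zero point", {
  W <- array(-1.0, c(1, 1, 1))
  l <- make_qlayer("conv", W, -0.5, in_range = c(0, 1), out_range = c(0, 1))
  q_in <- quantize_value(seq(0.1, 1, length.out = 8), l$qp_in)
  out <- conv1d_int8(matrix(q_in, ncol = 1), l)
  expect_true(all(out == l$zp_out))
})

test_that("dense zero weights pass the bias through; unit permutation is a symmetry", {
  l <- make_qlayer("dense", matrix(0, 6, 2), c(0.7, -0.3),
                   in_range = c(-1, 1), out_range = c(-1, 1),
                   activation = "linear")
  q_in <- quantize_value(runif(6, -1, 1), l$qp_in)
  deq <- dequantize_value(as.vector(dense_int8(q_in, l)), l$qp_out)
  expect_true(all(abs(deq - c(0.7, -0.3)) <= l$s_out))

  set.seed(8)
  W <- matrix(rnorm(12), 4, 3)
  l2 <- make_qlayer("dense", W, numeric(3), in_range = c(-1, 1),
                    out_range = c(-2, 2), activation = "linear")
  q_in <- quantize_value(runif(4, -1, 1), l2$qp_in)
  perm <- c(3, 1, 4, 2)
  l2p <- l2
  l2p$W <- l2$W[perm, ]
  expect_identical(as.integer(dense_int8(q_in[perm], l2p)),
                   as.integer(dense_int8(q_in, l2)))
})

test_that("classify runs integer-only to a deterministic label", {
  fit <- small_fit()
  seg <- fit$split$test$x[1, ]
  r1 <- classify(fit$qm, seg)
  r2 <- classify(fit$qm, seg, probs = TRUE)
  expect_identical(r1$label, r2$label)
  expect_identical(r1$logits_int8, r2$logits_int8)
  expect_true(all(r1$logits_int8 == round(r1$logits_int8)))
  expect_equal(sum(r2$probabilities), 1, tolerance = 1e-9)
  expect_true(all(r2$probabilities >= 0))
  expect_error(classify(fit$qm, seg[1:100]), class = "tinybeat_shape_error")
  # layer kernels reject mismatched layer types
  expect_error(conv1d_int8(matrix(0L, 4, 1), fit$qm$layers[[5]]),
               class = "tinybeat_contract_error")
})

test_that("whole-network integer path matches the R reference engine", {
  fit <- small_fit()
  qm <- fit$qm
  for (i in 1:3) {
    seg <- fit$split$test$x[i, ]
    A <- matrix(quantize_value(seg, qm$input_qp), ncol = 1)
    for (l in qm$layers) {
      if (l$type == "conv") A <- r_conv1d_int8(A, l)
      else if (l$type == "maxpool") {
        t_out <- nrow(A) %/% l$pool
        A <- apply(A, 2, function(col)
          vapply(seq_len(t_out), function(t)
            max(col[((t - 1) * l$pool + 1):(t * l$pool)]), numeric(1)))
      } else if (l$type == "flatten") A <- as.vector(A)
      else if (l$type == "dense") A <- r_dense_int8(A, l)
    }
    expect_identical(as.integer(A), classify(qm, seg)$logits_int8)
  }
})

test_that("memory footprint accounting is consistent", {
  fit <- small_fit()
  fp <- footprint(fit$qm)
  expect_identical(fp$flash_bytes, length(serialize_quant_model(fit$qm)))
  buffers <- c(250, 248 * 16, 124 * 16, 122 * 32, 64, 3)
  expect_gte(fp$sram_bytes, max(buffers))
  # conv1 row: input 250 int8 + output 248*16 int8 + 16 int32 scratch
  r1 <- fp$per_layer[fp$per_layer$layer == 1, ]
  expect_identical(r1$total, 250L + 248L * 16L + 64L)
  # doubling conv1 filters doubles its activation-buffer contribution
  arch2 <- beat_cnn_architecture()
  arch2$layers[[1]]$filters <- 32L
  set.seed(1)
  fake <- structure(list(weights = tinybeat:::init_weights(arch2),
                         architecture = arch2, classes = c("N", "V", "S")),
                    class = "beat_cnn")
  qm2 <- quantize(fake, representative = fit$split$train$x[1:40, ], seed = 1)
  fp2 <- footprint(qm2)
  r2 <- fp2$per_layer[fp2$per_layer$layer == 1, ]
  expect_identical(r2$out_bytes, 2L * r1$out_bytes)
})
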