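test_that("quantization parameter formulas", {
  qp <- choose_qparams(c(-0.5, 0.25), "weights")
  expect_equal(qp$scale, 0.5 / 127)
  expect_identical(qp$zero_point, 0L)

  qp <- choose_qparams(c(0, 2.55), "activations")
  expect_equal(qp$scale, 0.01)
  expect_identical(qp$zero_point, -128L)

  qp <- choose_qparams(c(-1, 1), "activations")
  expect_identical(qp$zero_point, 0L)

  # constant nonzero weight tensors still quantize (symmetric scheme)
  expect_equal(choose_qparams(c(1, 1), "weights")$scale, 1 / 127)
  expect_error(choose_qparams(c(1, 1), "activations"),
               class = "tinybeat_parameter_error")
  expect_error(choose_qparams(c(2, 1), "weights"),
               class = "tinybeat_parameter_error")
})

test_that("value quantization rounds half away from zero and saturates", {
  qp <- list(scale = 0.5, zero_point = 0L)
  expect_identical(quantize_value(0, qp), 0L)
  expect_identical(quantize_value(1.0, qp), 2L)
  expect_identical(quantize_value(100, qp), 127L)
  expect_identical(quantize_value(-100, qp), -128L)
  expect_identical(quantize_value(0.75, qp), 2L)    # 1.5 away from zero
  expect_identical(quantize_value(-0.75, qp), -2L)
  # dequantize inverts up to scale/2
  set.seed(3)
  x <- runif(100, -10, 10)
  qp2 <- choose_qparams(c(-10, 10), "activations")
  err <- abs(dequantize_value(quantize_value(x, qp2), qp2) - x)
  expect_true(all(err <= qp2$scale / 2 + 1e-12))
})

test_that("fixed-point multiplier decomposition is accurate to 2^-24", {
  set.seed(4)
  for (M in c(10^runif(50, -6, 2))) {
    d <- tinybeat:::quantize_multiplier(M)
    expect_gte(d$m0, 2^30)
    expect_lt(d$m0, 2^31)
    expect_lt(abs(d$m0 * 2^-31 * 2^-d$n - M) / M, 2^-24)
  }
})

test_that("calibration widens ranges around zero and grows monotonically", {
  fit <- small_fit()
  zeros <- matrix(0, 5, 250)
  r0 <- calibrate(fit$model, zeros)
  for (r in r0) {
    expect_lte(r[[1]], 0)
    expect_gte(r[[2]], 0)
    expect_gt(r[[2]], r[[1]])
  }
  x <- fit$split$train$x
  r10 <- calibrate(fit$model, x[1:10, ])
  r50 <- calibrate(fit$model, x[1:50, ])
  for (k in names(r10)) {
    expect_lte(r50[[k]][[1]], r10[[k]][[1]])
    expect_gte(r50[[k]][[2]], r10[[k]][[2]])
  }
  expect_error(calibrate(fit$model, matrix(numeric(0), 0, 250)),
               class = "tinybeat_calibration_error")
})

test_that("conversion yields exact 75% weight-payload reduction and bounded error", {
  fit <- small_fit()
  qm <- fit$qm
  expect_identical(weight_payload_bytes(qm, "int8") /
                     weight_payload_bytes(qm, "float32"), 0.25)
  for (l in qm$layers) {
    if (is.null(l$W)) next
    expect_true(all(l$W >= -128 & l$W <= 127))
    # bias scale = s_in * s_w by construction; dequantized weights stay in
    # the symmetric calibrated range +/- one scale step
    wd <- l$W * l$s_w
    expect_lte(max(abs(wd)), 127 * l$s_w + l$s_w)
  }
  # dequantize(quantize(w)) within scale/2 elementwise for the first conv
  eff <- tinybeat:::fold_conv_bn(fit$model$weights[[1]], TRUE)
  l1 <- qm$layers[[1]]
  expect_true(all(abs(l1$W * l1$s_w - eff$W) <= l1$s_w / 2 + 1e-12))
})

test_that("portable container and C header are self-consistent", {
  fit <- small_fit()
  qm <- fit$qm
  bytes <- serialize_quant_model(qm)
  f <- withr::local_tempfile()
  save_quant_model(qm, f)
  expect_identical(file.info(f)$size, as.numeric(length(bytes)))
  qm2 <- load_quant_model(f)
  expect_identical(serialize_quant_model(qm2), bytes)
  # loaded model predicts identically
  xs <- fit$split$test$x[1:20, ]
  expect_identical(predict(qm, xs, type = "logits"),
                   predict(qm2, xs, type = "logits"))
  # foreign file rejected
  f2 <- withr::local_tempfile()
  writeBin(as.raw(1:32), f2)
  expect_error(load_quant_model(f2), class = "tinybeat_format_error")

  hdr <- export_c_header(qm)
  n_hex <- lengths(regmatches(hdr, gregexpr("0x[0-9a-f]{2}", hdr)))
  expect_identical(n_hex, length(bytes))
  expect_identical(lengths(regmatches(hdr, gregexpr("\\{", hdr))),
                   lengths(regmatches(hdr, gregexpr("\\}", hdr))))
  expect_match(hdr, sprintf("unsigned int model_len = %d;", length(bytes)))
})

test_that("serialized size is one byte per weight plus fixed overhead", {
  fit <- small_fit()
  qm <- fit$qm
  n_w <- weight_payload_bytes(qm)
  n_b <- sum(vapply(qm$layers, function(l) length(l$b %||% integer(0)),
                    integer(1)))
  n_scales <- 1L + 3L * sum(vapply(qm$layers,
                                   function(l) !is.null(l$W), logical(1)))
  overhead <- length(serialize_quant_model(qm)) -
    (n_w + 4L * n_b + 8L * n_scales)
  expect_gt(overhead, 0L)
  expect_lt(overhead, 2048L)    # magic + JSON metadata only
})
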