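spec360 <- design_bandpass()

filtered_gen <- function(cfg) {
  gen <- generate_record(cfg)
  gen$filtered <- filter_zero_phase(gen$record$signal, spec360)
  gen
}

match_stats <- function(det, truth_idx, tol = 18L) {
  if (!length(det)) return(c(sens = 0, ppv = 0))
  d <- outer(det, truth_idx, function(a, b) abs(a - b))
  c(sens = mean(apply(d, 2, min) <= tol),
    ppv = mean(apply(d, 1, min) <= tol))
}

test_that("detector finds noiseless beats within 50 ms of truth", {
  gen <- filtered_gen(synth_config(n_beats = 10, mean_hr = 72, seed = 7,
                                   baseline_wander_amp = 0,
                                   powerline_amp = 0, white_sd = 0))
  det <- pan_tompkins_detect(gen$filtered, 360)
  expect_identical(length(det), 10L)
  expect_true(all(abs(det - gen$truth$r_index) <= 18))
})

test_that("detector returns nothing on flat or too-short signals", {
  expect_identical(pan_tompkins_detect(numeric(5000), 360), integer(0))
  expect_warning(out <- pan_tompkins_detect(numeric(10), 360),
                 "integration window")
  expect_identical(out, integer(0))
})

test_that("detector reaches sensitivity and PPV >= 0.99 at 20 dB SNR", {
  cfg <- synth_config(n_beats = 60, seed = 11)
  cfg$white_sd <- synth_white_sd(cfg, 20)
  gen <- filtered_gen(cfg)
  st <- match_stats(pan_tompkins_detect(gen$filtered, 360),
                    gen$truth$r_index)
  expect_gte(st[["sens"]], 0.99)
  expect_gte(st[["ppv"]], 0.99)
})

test_that("refractory spacing holds for every input", {
  for (seed in c(1, 2, 3)) {
    cfg <- synth_config(n_beats = 40, seed = seed, mean_hr = 90)
    gen <- filtered_gen(cfg)
    det <- pan_tompkins_detect(gen$filtered, 360)
    expect_true(all(diff(det) >= round(200 / 1000 * 360)))
  }
})

test_that("noiseless detections coincide with truth apices", {
  cfg <- synth_config(n_beats = 15, seed = 5, baseline_wander_amp = 0,
                      powerline_amp = 0, white_sd = 0,
                      class_mix = c(N = 1, V = 0, S = 0))
  gen <- filtered_gen(cfg)
  det <- pan_tompkins_detect(gen$filtered, 360)
  expect_identical(det, gen$truth$r_index)
  # mixed morphologies: filtering can shift wide-beat apices by a sample
  cfgm <- synth_config(n_beats = 15, seed = 5, baseline_wander_amp = 0,
                       powerline_amp = 0, white_sd = 0)
  genm <- filtered_gen(cfgm)
  detm <- pan_tompkins_detect(genm$filtered, 360)
  expect_identical(length(detm), 15L)
  expect_true(all(abs(detm - genm$truth$r_index) <= 1))
})

test_that("segment windows are 250 samples centred on the R index", {
  rec <- ecg_record(sin(seq(0, 6 * pi, length.out = 250)), fs = 360,
                    record_id = "edge")
  ds <- segment_beats(rec, 125L, labels = "N")
  expect_identical(nrow(ds$x), 1L)
  expect_identical(ncol(ds$x), 250L)
  # the whole record is the window, so its extremes hit 0 and 1
  expect_equal(range(ds$x), c(0, 1))

  ds2 <- segment_beats(rec, 50L, labels = "N")
  expect_identical(nrow(ds2$x), 0L)
  expect_identical(attr(ds2, "dropped")[["boundary"]], 1L)
})

test_that("segmentation conserves beats and drops excluded/degenerate windows", {
  gen <- filtered_gen(synth_config(n_beats = 25, seed = 9))
  rec <- gen$record
  rec$signal <- gen$filtered
  labels <- c(gen$truth$label[-1], "EXCLUDED")
  ds <- segment_beats(rec, gen$truth$r_index, labels = labels)
  dropped <- attr(ds, "dropped")
  expect_identical(nrow(ds$x) + sum(dropped), 25L)
  expect_identical(dropped[["excluded"]], 1L)
  expect_true(all(ds$x >= 0 & ds$x <= 1))
  # R apex at local index 125 (0-based) for noiseless narrow beats
  expect_true(all(ds$r_index %in% gen$truth$r_index))
})

test_that("build_dataset wires annotation and detection paths", {
  gen <- filtered_gen(synth_config(n_beats = 20, seed = 13))
  rec <- gen$record
  rec$signal <- gen$filtered
  ds_ann <- build_dataset(list(rec), mode = "annotations")
  expect_identical(nrow(ds_ann$x) + attr(ds_ann, "dropped")[["boundary"]],
                   20L)
  expect_true(all(ds_ann$labels %in% c("N", "V", "S")))

  ds_det <- build_dataset(list(rec), mode = "detected")
  expect_null(ds_det$labels)
  expect_gt(nrow(ds_det$x), 0L)

  rec_na <- rec
  rec_na$annotations <- NULL
  expect_error(build_dataset(list(rec_na), mode = "annotations"),
               class = "tinybeat_input_error")

  rec_ex <- rec
  rec_ex$annotations$symbol <- rep("Q", nrow(rec_ex$annotations))
  expect_warning(ds_ex <- build_dataset(list(rec_ex), mode = "annotations"),
                 "no usable beats")
  expect_identical(nrow(ds_ex$x), 0L)
})
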