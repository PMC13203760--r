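test_that("WFDB round trip preserves sample count, annotations and amplitudes", {
  gen <- generate_record(synth_config(n_beats = 12, seed = 5), "rt01")
  dir <- withr::local_tempdir()
  base <- write_wfdb_record(gen$record, dir)
  back <- read_wfdb_record(base)
  expect_identical(length(back$signal), length(gen$record$signal))
  expect_identical(back$annotations$sample, gen$record$annotations$sample)
  expect_identical(back$annotations$symbol, gen$record$annotations$symbol)
  # format-16 quantization at gain 200 ADC units/mV
  expect_lt(max(abs(back$signal - gen$record$signal)), 1 / 400 + 1e-12)
})

test_that("lead preference selects the matching channel, falls back with warning", {
  dir <- withr::local_tempdir()
  adc <- cbind(1:20 * 10L, -(1:20) * 10L)
  writeBin(as.integer(t(adc)), file.path(dir, "two.dat"), size = 2L,
           endian = "little")
  writeLines(c("two 2 360 20",
               "two.dat 16 200 16 0 0 0 0 MLII",
               "two.dat 16 200 16 0 0 0 0 V5"),
             file.path(dir, "two.hea"))
  rec <- read_wfdb_record(file.path(dir, "two"))
  expect_identical(rec$lead, "MLII")
  expect_equal(rec$signal, adc[, 1] / 200)

  writeLines(c("one 1 360 20", "one.dat 16 200 16 0 0 0 0 V5"),
             file.path(dir, "one.hea"))
  writeBin(as.integer(adc[, 2]), file.path(dir, "one.dat"), size = 2L,
           endian = "little")
  expect_warning(rec1 <- read_wfdb_record(file.path(dir, "one")),
                 "no channel matching")
  expect_identical(rec1$lead, "V5")
})

test_that("format 212 unpacking matches independent packing", {
  set.seed(42)
  s <- as.integer(sample(-2048:2047, 20))
  # independent packer: 12-bit pairs in 3 bytes
  pack <- function(s1, s2) {
    u1 <- ifelse(s1 < 0, s1 + 4096L, s1)
    u2 <- ifelse(s2 < 0, s2 + 4096L, s2)
    as.raw(c(bitwAnd(u1, 255L),
             bitwOr(bitwShiftL(bitwShiftR(u2, 8L), 4L), bitwShiftR(u1, 8L)),
             bitwAnd(u2, 255L)))
  }
  bytes <- do.call(c, lapply(seq(1, 20, 2), function(i) pack(s[i], s[i + 1])))
  f <- withr::local_tempfile()
  writeBin(bytes, f)
  mat <- tinybeat:::read_dat_212(f, nsig = 2L, nsamp = 10)
  expect_identical(as.vector(t(mat)), s)
})

test_that("missing or malformed headers raise format errors", {
  expect_error(read_wfdb_record(tempfile()), class = "tinybeat_format_error")
  dir <- withr::local_tempdir()
  writeLines("bad", file.path(dir, "bad.hea"))
  expect_error(read_wfdb_record(file.path(dir, "bad")),
               class = "tinybeat_format_error")
  writeLines("zero 0 360 10", file.path(dir, "zero.hea"))
  expect_error(read_wfdb_record(file.path(dir, "zero")),
               class = "tinybeat_format_error")
})

test_that("annotation symbols map to the AAMI three-class scheme, totally and idempotently", {
  expect_identical(map_annotation_symbol(c("N", "L", "R", "e", "j")),
                   rep("N", 5))
  expect_identical(map_annotation_symbol(c("A", "a", "J", "S")), rep("S", 4))
  expect_identical(map_annotation_symbol(c("V", "E")), rep("V", 2))
  expect_identical(map_annotation_symbol(c("F", "Q", "/", "~", "?", "z")),
                   rep("EXCLUDED", 6))
  # total over any character, idempotent over its own output alphabet
  all_syms <- c(LETTERS, letters, "/", "~", "+", "|")
  out <- map_annotation_symbol(all_syms)
  expect_true(all(out %in% c("N", "V", "S", "EXCLUDED")))
  expect_identical(map_annotation_symbol(setdiff(out, "EXCLUDED")),
                   setdiff(out, "EXCLUDED"))
  # config override
  expect_identical(map_annotation_symbol("F", table = c(F = "V")), "V")
})

test_that("beat dataset container round-trips losslessly and rejects bad files", {
  ds <- synth_beat_dataset(30, seed = 11)
  f <- withr::local_tempfile()
  save_dataset(ds, f)
  back <- load_dataset(f)
  expect_identical(back$x, ds$x)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$provenance, ds$provenance)
  expect_identical(back$seed, ds$seed)

  # truncated file
  bytes <- readBin(f, "raw", file.info(f)$size)
  f2 <- withr::local_tempfile()
  writeBin(bytes[1:20], f2)
  expect_error(load_dataset(f2), class = "tinybeat_format_error")

  # foreign RDS
  f3 <- withr::local_tempfile()
  saveRDS(list(a = 1), f3)
  expect_error(load_dataset(f3), class = "tinybeat_format_error")

  # empty dataset round trip
  e <- beat_dataset(matrix(numeric(0), 0, 250))
  f4 <- withr::local_tempfile()
  save_dataset(e, f4)
  expect_identical(nrow(load_dataset(f4)$x), 0L)
})

test_that("record and dataset constructors enforce their invariants", {
  expect_error(ecg_record(numeric(0)), "at least one sample")
  expect_error(ecg_record(1:10, fs = 0), "positive")
  expect_error(ecg_record(1:10, annotations = data.frame(sample = c(3, 3),
                                                         symbol = c("N", "N"))),
               "strictly increasing")
  expect_error(ecg_record(1:10, annotations = data.frame(sample = 10,
                                                         symbol = "N")),
               "lie in")
  expect_error(beat_dataset(matrix(0, 2, 100)), "250")
  expect_error(beat_dataset(matrix(0, 2, 250), labels = c("N", "X")),
               "must be in")
})
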