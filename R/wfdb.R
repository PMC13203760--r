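# Minimal WFDB support: header parsing, signal formats 16 and 212, and the
# MIT annotation codec.  Covers the MIT-BIH Arrhythmia Database layout
# (.hea/.dat/.atr) and the records this package writes itself; it is not a
# general WFDB implementation (no multi-segment records, no EDF).

# MIT annotation code <-> mnemonic table (subset of the standard codes).
WFDB_ANN_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L, "~" = 14L,
  "|" = 16L, "s" = 18L, "T" = 19L, "*" = 20L, "D" = 21L, "\"" = 22L,
  "=" = 23L, "p" = 24L, "B" = 25L, "^" = 26L, "t" = 27L, "+" = 28L,
  "u" = 29L, "?" = 30L, "!" = 31L, "[" = 32L, "]" = 33L, "e" = 34L,
  "n" = 35L, "@" = 36L, "x" = 37L, "f" = 38L, "(" = 39L, ")" = 40L)

wfdb_code_for_symbol <- function(symbol) {
  code <- WFDB_ANN_CODES[symbol]
  code[is.na(code)] <- WFDB_ANN_CODES[["Q"]]
  unname(code)
}

wfdb_symbol_for_code <- function(code) {
  sym <- names(WFDB_ANN_CODES)[match(code, WFDB_ANN_CODES)]
  sym[is.na(sym)] <- "Q"
  sym
}

parse_hea <- function(hea_path) {
  if (!file.exists(hea_path)) tb_stop("WFDB header not found: %s",
                                      hea_path, class = "tinybeat_format_error")
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) tb_stop("empty WFDB header: %s", hea_path,
                                  class = "tinybeat_format_error")
  top <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(top) < 2L) tb_stop("malformed WFDB header line: %s", lines[[1L]],
                                class = "tinybeat_format_error")
  nsig <- suppressWarnings(as.integer(top[[2L]]))
  if (is.na(nsig)) tb_stop("malformed signal count in header",
                           class = "tinybeat_format_error")
  if (nsig < 1L) tb_stop("record declares zero signal channels",
                         class = "tinybeat_format_error")
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*$", "", top[[3L]])) else 250
  nsamp <- if (length(top) >= 4L) as.numeric(top[[4L]]) else NA_real_
  if (length(lines) < 1L + nsig) tb_stop("header declares %d signals but lists %d",
                                         nsig, length(lines) - 1L,
                                         class = "tinybeat_format_error")
  sig <- lapply(lines[2L:(1L + nsig)], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) < 2L) tb_stop("malformed signal specification: %s", ln,
                                  class = "tinybeat_format_error")
    gain_tok <- if (length(tok) >= 3L) tok[[3L]] else "200"
    gain_num <- sub("/.*$", "", gain_tok)
    baseline <- NA_real_
    if (grepl("\\(", gain_num)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_num))
      gain_num <- sub("\\(.*$", "", gain_num)
    }
    gain <- as.numeric(gain_num)
    if (is.na(gain) || gain == 0) gain <- 200
    adczero <- if (length(tok) >= 5L) suppressWarnings(as.numeric(tok[[5L]])) else 0
    if (is.na(adczero)) adczero <- 0
    desc <- if (length(tok) >= 9L) paste(tok[9L:length(tok)], collapse = " ") else ""
    list(file = tok[[1L]], format = as.integer(sub("x.*$", "", tok[[2L]])),
         gain = gain, baseline = if (is.na(baseline)) adczero else baseline,
         adczero = adczero, description = desc)
  })
  list(record = top[[1L]], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_16 <- function(path, nsig, nsamp) {
  raw <- readBin(path, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = file.info(path)$size / 2L)
  matrix(raw, ncol = nsig, byrow = TRUE)
}

read_dat_212 <- function(path, nsig, nsamp) {
  bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  b <- as.integer(bytes)
  ntrip <- length(b) %/% 3L
  b1 <- b[seq(1L, by = 3L, length.out = ntrip)]
  b2 <- b[seq(2L, by = 3L, length.out = ntrip)]
  b3 <- b[seq(3L, by = 3L, length.out = ntrip)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  samples <- as.vector(rbind(s1, s2))
  matrix(samples[seq_len((length(samples) %/% nsig) * nsig)],
         ncol = nsig, byrow = TRUE)
}

# Reads a MIT-format annotation file into (sample, symbol).
read_atr <- function(path) {
  words <- readBin(path, what = "integer", size = 2L, signed = FALSE,
                   endian = "little", n = file.info(path)$size / 2L)
  time <- 0
  i <- 1L
  out_t <- numeric(0)
  out_s <- character(0)
  while (i <= length(words)) {
    w <- words[[i]]
    code <- bitwShiftR(w, 10L)
    data <- bitwAnd(w, 1023L)
    if (code == 0L && data == 0L) break
    if (code == 59L) {            # SKIP: 4-byte interval, high word first
      if (i + 2L > length(words)) break
      hi <- words[[i + 1L]]
      lo <- words[[i + 2L]]
      time <- time + hi * 65536 + lo
      i <- i + 3L
      next
    }
    if (code == 63L) {            # AUX: data = byte count, padded to even
      i <- i + 1L + (data + data %% 2L) %/% 2L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { # NUM / SUB / CHN modifiers
      i <- i + 1L
      next
    }
    time <- time + data
    out_t <- c(out_t, time)
    out_s <- c(out_s, wfdb_symbol_for_code(code))
    i <- i + 1L
  }
  data.frame(sample = out_t, symbol = out_s, stringsAsFactors = FALSE)
}

write_atr <- function(path, samples, symbols) {
  # samples are 0-based; MIT format stores first annotation time as a delta
  # from 0.
  words <- integer(0)
  prev <- 0
  for (k in seq_along(samples)) {
    delta <- samples[[k]] - prev
    code <- wfdb_code_for_symbol(symbols[[k]])
    if (delta > 1023) {
      hi <- delta %/% 65536
      lo <- delta %% 65536
      words <- c(words, bitwShiftL(59L, 10L), as.integer(hi), as.integer(lo))
      delta <- 0
    }
    words <- c(words, bitwShiftL(code, 10L) + as.integer(delta))
    prev <- samples[[k]]
  }
  words <- c(words, 0L)           # EOF
  # writeBin size = 2 takes signed shorts; re-wrap the unsigned words
  words <- ifelse(words > 32767L, words - 65536L, words)
  writeBin(as.integer(words), path, size = 2L, endian = "little")
  invisible(NULL)
}
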