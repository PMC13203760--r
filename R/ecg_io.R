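#' Construct a single-lead ECG record
#'
#' The central container for a sampled single-lead ECG: amplitudes in
#' millivolts, the sampling rate, and an optional beat-annotation stream
#' of 0-based sample indices (taken as R-peak samples) with single-character
#' symbols.
#'
#' @param signal numeric vector of amplitudes (mV).
#' @param fs sampling rate in Hz (the MIT-BIH rate, 360 Hz, by default).
#' @param record_id record identifier.
#' @param lead lead name (MIT-BIH Lead II is `"MLII"`).
#' @param annotations `NULL` or a data frame with columns `sample`
#'   (0-based integer, strictly increasing, `< length(signal)`) and
#'   `symbol` (single character).
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs = 360, record_id = "rec", lead = "MLII",
                       annotations = NULL) {
  signal <- as.numeric(signal)
  if (length(signal) < 1L) tb_stop("signal must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    tb_stop("fs must be a positive scalar")
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("sample", "symbol") %in% names(annotations)))
    s <- annotations$sample
    if (length(s) && (any(s < 0) || any(s >= length(signal))))
      tb_stop("annotation sample indices must lie in [0, length(signal))")
    if (length(s) > 1L && any(diff(s) <= 0))
      tb_stop("annotation sample indices must be strictly increasing")
    annotations <- data.frame(sample = as.integer(s),
                              symbol = as.character(annotations$symbol),
                              stringsAsFactors = FALSE)
  }
  structure(list(record_id = as.character(record_id), signal = signal,
                 fs = fs, lead = as.character(lead),
                 annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> lead %s, %d samples @ %g Hz (%.1f s), %d annotations\n",
              x$record_id, x$lead, length(x$signal), x$fs,
              length(x$signal) / x$fs,
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

#' Read a WFDB record (.hea/.dat, optionally .atr)
#'
#' Reads a WFDB-format record, selects the channel whose description
#' matches `lead_preference` (Lead II by default, the lead used for
#' single-channel beat classification), converts amplitudes to physical
#' units (mV), and attaches beat annotations when an annotation file is
#' present.  If no channel matches the preferred lead, channel 1 is used
#' with a warning.
#'
#' Supported signal formats: 16 (16-bit little-endian) and 212 (the
#' MIT-BIH packed 12-bit format).
#'
#' @param path record path without extension (e.g. `"data/100"`).
#' @param lead_preference character vector of acceptable lead names, in
#'   order of preference.
#' @param annotator annotation file extension (default `"atr"`).
#' @return an [ecg_record()].
#' @export
read_wfdb_record <- function(path, lead_preference = c("MLII", "II"),
                             annotator = "atr") {
  hdr <- parse_hea(paste0(path, ".hea"))
  dat_path <- file.path(dirname(path), hdr$signals[[1L]]$file)
  if (!file.exists(dat_path))
    tb_stop("signal file not found: %s", dat_path,
            class = "tinybeat_format_error")
  fmt <- hdr$signals[[1L]]$format
  mat <- switch(as.character(fmt),
                "16" = read_dat_16(dat_path, hdr$nsig, hdr$nsamp),
                "212" = read_dat_212(dat_path, hdr$nsig, hdr$nsamp),
                tb_stop("unsupported WFDB signal format %s", fmt,
                        class = "tinybeat_format_error"))
  if (!is.na(hdr$nsamp) && nrow(mat) > hdr$nsamp)
    mat <- mat[seq_len(hdr$nsamp), , drop = FALSE]
  descs <- vapply(hdr$signals, `[[`, "", "description")
  ch <- which(toupper(descs) %in% toupper(lead_preference))[1L]
  if (is.na(ch)) {
    ch <- 1L
    tb_warn("record '%s' has no channel matching %s (channels: %s); using channel 1",
            hdr$record, paste(lead_preference, collapse = "/"),
            paste(descs, collapse = ", "))
  }
  sig <- (mat[, ch] - hdr$signals[[ch]]$baseline) / hdr$signals[[ch]]$gain
  ann <- NULL
  atr_path <- paste0(path, ".", annotator)
  if (file.exists(atr_path)) {
    ann <- read_atr(atr_path)
    ann <- ann[ann$sample < length(sig), , drop = FALSE]
  }
  ecg_record(sig, fs = hdr$fs, record_id = hdr$record,
             lead = descs[[ch]], annotations = ann)
}

#' Write an [ecg_record()] in WFDB format
#'
#' Writes `<dir>/<record_id>.hea` and `.dat` (format 16, gain 200 ADC
#' units/mV) plus `.atr` when the record carries annotations.  Round-trip
#' amplitude error is bounded by the ADC step, 1/(2*200) mV.
#'
#' @param record an [ecg_record()].
#' @param dir output directory (created if missing).
#' @return the record path (without extension), invisibly.
#' @export
write_wfdb_record <- function(record, dir) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gain <- 200
  base <- file.path(dir, record$record_id)
  adc <- as.integer(round(record$signal * gain))
  adc[adc > 32767L] <- 32767L
  adc[adc < -32768L] <- -32768L
  writeBin(adc, paste0(base, ".dat"), size = 2L, endian = "little")
  hea <- c(sprintf("%s 1 %g %d", record$record_id, record$fs,
                   length(record$signal)),
           sprintf("%s.dat 16 %d 16 0 %d 0 0 %s", record$record_id, gain,
                   adc[[1L]], record$lead))
  writeLines(hea, paste0(base, ".hea"))
  if (!is.null(record$annotations) && nrow(record$annotations) > 0L)
    write_atr(paste0(base, ".atr"), record$annotations$sample,
              record$annotations$symbol)
  invisible(base)
}

#' Map a beat-annotation symbol to the three-class scheme
#'
#' Deterministic, total mapping of MIT/AAMI annotation mnemonics to the
#' reduced three-class scheme: normal-like beats (`N`, `L`, `R`, `e`, `j`)
#' to `"N"`, supraventricular ectopics (`A`, `a`, `J`, `S`) to `"S"`,
#' ventricular ectopics (`V`, `E`) to `"V"`; every other symbol (fusion,
#' paced, unknown, non-beat marks) maps to `"EXCLUDED"` and never enters
#' training or evaluation.
#'
#' @param symbol character vector of single-character annotation symbols.
#' @param table optional named character vector overriding the grouping
#'   (names = symbols, values in `c("N","V","S","EXCLUDED")`).
#' @return character vector over `c("N","V","S","EXCLUDED")`.
#' @export
map_annotation_symbol <- function(symbol, table = NULL) {
  default <- c(N = "N", L = "N", R = "N", e = "N", j = "N",
               A = "S", a = "S", J = "S", S = "S",
               V = "V", E = "V")
  if (!is.null(table)) {
    stopifnot(all(table %in% c(BEAT_CLASSES, "EXCLUDED")))
    default[names(table)] <- table
  }
  out <- default[as.character(symbol)]
  out[is.na(out)] <- "EXCLUDED"
  unname(out)
}

#' Construct a beat dataset
#'
#' A labeled collection of normalized 250-sample beat windows, the unit of
#' analysis throughout training and evaluation.
#'
#' @param x numeric matrix, one row per beat, 250 columns, values in
#'   \[0, 1\].
#' @param labels `NULL` (inference path) or character vector over
#'   `c("N","V","S")`, one per row.
#' @param r_index integer vector of source R-peak sample indices (0-based).
#' @param record_id character vector of source record ids.
#' @param provenance `"real"` or `"synthetic"`.
#' @param seed generator seed, if the data is synthetic.
#' @return an object of class `beat_dataset`.
#' @export
beat_dataset <- function(x, labels = NULL, r_index = NULL, record_id = NULL,
                         provenance = "synthetic", seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n > 0L && ncol(x) != 250L)
    tb_stop("beat windows must have exactly 250 samples (got %d)", ncol(x))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) tb_stop("labels length must match rows")
    if (n > 0L && !all(labels %in% BEAT_CLASSES))
      tb_stop("labels must be in {N, V, S}")
  }
  structure(list(x = x, labels = labels,
                 r_index = as.integer(r_index %||% rep(NA_integer_, n)),
                 record_id = as.character(record_id %||% rep("rec", n)),
                 provenance = provenance, seed = seed),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats x 250 samples (%s)\n", nrow(x$x),
              x$provenance))
  if (!is.null(x$labels) && nrow(x$x) > 0L)
    print(class_counts(x))
  invisible(x)
}

#' @export
length.beat_dataset <- function(x) nrow(x$x)

#' Per-class beat counts of a dataset
#' @param ds a [beat_dataset()].
#' @return named integer vector over the class alphabet.
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "beat_dataset"))
  if (is.null(ds$labels)) tb_stop("dataset has no labels")
  table(factor(ds$labels, levels = BEAT_CLASSES))
}

#' Subset a beat dataset by row index
#' @param ds a [beat_dataset()].
#' @param i integer row indices.
#' @return a [beat_dataset()].
#' @export
dataset_subset <- function(ds, i) {
  beat_dataset(ds$x[i, , drop = FALSE],
               labels = if (is.null(ds$labels)) NULL else ds$labels[i],
               r_index = ds$r_index[i], record_id = ds$record_id[i],
               provenance = ds$provenance, seed = ds$seed)
}

#' Combine beat datasets
#' @param ... [beat_dataset()] objects.
#' @return a [beat_dataset()].
#' @export
dataset_rbind <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "beat_dataset")))
  labs <- if (all(vapply(parts, function(p) !is.null(p$labels), TRUE)))
    unlist(lapply(parts, `[[`, "labels")) else NULL
  beat_dataset(do.call(rbind, lapply(parts, `[[`, "x")), labels = labs,
               r_index = unlist(lapply(parts, `[[`, "r_index")),
               record_id = unlist(lapply(parts, `[[`, "record_id")),
               provenance = parts[[1L]]$provenance, seed = parts[[1L]]$seed)
}

DATASET_CONTAINER_VERSION <- 1L

#' Save / load a beat dataset
#'
#' Lossless single-file container (versioned R serialization).  Loading a
#' file with a different container version, or a truncated/foreign file,
#' raises a format error.
#'
#' @param ds a [beat_dataset()].
#' @param path file path.
#' @return `load_dataset` returns the [beat_dataset()].
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "beat_dataset"))
  obj <- list(magic = "tinybeat-dataset",
              version = DATASET_CONTAINER_VERSION, payload = unclass(ds))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    tb_stop("unreadable dataset container '%s': %s", path, conditionMessage(e),
            class = "tinybeat_format_error"))
  if (!is.list(obj) || !identical(obj$magic, "tinybeat-dataset"))
    tb_stop("'%s' is not a tinybeat dataset container", path,
            class = "tinybeat_format_error")
  if (!identical(obj$version, DATASET_CONTAINER_VERSION))
    tb_stop("dataset container version %s not supported (expected %d)",
            obj$version, DATASET_CONTAINER_VERSION,
            class = "tinybeat_format_error")
  do.call(beat_dataset, c(list(x = obj$payload$x),
                          obj$payload[c("labels", "r_index", "record_id",
                                        "provenance", "seed")]))
}

#' Export dataset labels for audit
#'
#' Writes one row per beat (record id, 0-based R index, label) as CSV.
#'
#' @param ds a [beat_dataset()].
#' @param path output CSV path.
#' @export
export_labels_csv <- function(ds, path) {
  stopifnot(inherits(ds, "beat_dataset"))
  write.csv(data.frame(record_id = ds$record_id, r_index = ds$r_index,
                       label = ds$labels %||% NA_character_),
            path, row.names = FALSE)
  invisible(path)
}
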