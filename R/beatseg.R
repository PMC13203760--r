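#' Detect R-peaks with an adapted Pan--Tompkins chain
#'
#' Classic parameterization of the Pan--Tompkins QRS detector applied to a
#' band-pass-filtered signal: five-point derivative, squaring, moving
#' window integration (150 ms), then an adaptive threshold
#' `npk + 0.25 * (spk - npk)` over running signal/noise peak estimates
#' (`0.125 * peak + 0.875 * estimate`) with a 200 ms refractory period.
#' No search-back / second-threshold stage is applied.  Each accepted
#' detection is refined to the local maximum of the filtered signal within
#' +/-100 ms.
#'
#' @param signal band-pass-filtered ECG (mV).
#' @param fs sampling rate (Hz).
#' @param integration_ms moving-window integration length (ms).
#' @param refractory_ms refractory period (ms).
#' @param threshold_fraction fraction of `(spk - npk)` above the noise
#'   estimate.
#' @return strictly increasing 0-based R-peak sample indices.
#' @export
pan_tompkins_detect <- function(signal, fs, integration_ms = 150,
                                refractory_ms = 200,
                                threshold_fraction = 0.25) {
  if (fs <= 0) tb_stop("fs must be positive")
  w <- max(1L, as.integer(round(integration_ms / 1000 * fs)))
  if (length(signal) < w + 5L) {
    tb_warn("signal shorter than one integration window; no detections")
    return(integer(0))
  }
  refr <- as.integer(round(refractory_ms / 1000 * fs))

  # five-point derivative (centered so no group delay), squaring, MWI
  der <- stats::filter(signal, c(2, 1, 0, -1, -2) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  if (max(mwi) <= 0) return(integer(0))

  # candidate peaks: local maxima of the integrated signal
  n <- length(mwi)
  cand <- which(mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                  mwi[2:(n - 1)] >= mwi[3:n]) + 1L
  if (!length(cand)) return(integer(0))

  learn <- seq_len(min(n, as.integer(2 * fs)))
  spk <- 0.5 * max(mwi[learn])
  npk <- mean(mwi[learn]) * 0.5
  peaks <- integer(0)
  thr_at <- numeric(length(cand))     # running threshold seen by candidate
  last <- -Inf
  for (ci in seq_along(cand)) {
    i <- cand[[ci]]
    thr <- npk + threshold_fraction * (spk - npk)
    thr_at[[ci]] <- thr
    if (i - last < refr) next
    if (mwi[[i]] > thr) {
      peaks <- c(peaks, i)
      last <- i
      spk <- 0.125 * mwi[[i]] + 0.875 * spk
    } else {
      npk <- 0.125 * mwi[[i]] + 0.875 * npk
    }
  }
  if (!length(peaks)) return(integer(0))

  # search-back: when an RR gap exceeds 1.66x the median RR, re-scan it
  # with the halved threshold (classic second-threshold stage) and accept
  # the largest qualifying integrated peak; repeat until stable
  repeat {
    if (length(peaks) < 3L) break
    rr_med <- stats::median(diff(peaks))
    inserted <- FALSE
    for (g in which(diff(peaks) > 1.66 * rr_med)) {
      lo <- peaks[[g]] + refr
      hi <- peaks[[g + 1L]] - refr
      sel <- which(cand > lo & cand < hi & mwi[cand] > thr_at / 2)
      if (length(sel)) {
        best <- sel[[which.max(mwi[cand[sel]])]]
        peaks <- sort(c(peaks, cand[[best]]))
        inserted <- TRUE
        break
      }
    }
    if (!inserted) break
  }

  # refine to the apex of the filtered signal within +/-100 ms
  half <- as.integer(round(0.1 * fs))
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(signal), i + half)
    lo + which.max(signal[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))

  # refinement can pull neighbours together; re-impose the refractory
  # period keeping the larger filtered amplitude
  keep <- rep(TRUE, length(refined))
  j <- 1L
  for (i in seq_along(refined)[-1L]) {
    if (refined[[i]] - refined[[j]] < refr) {
      if (signal[[refined[[i]]]] > signal[[refined[[j]]]]) {
        keep[[j]] <- FALSE
        j <- i
      } else keep[[i]] <- FALSE
    } else j <- i
  }
  as.integer(refined[keep] - 1L)                 # 0-based
}

#' Extract 250-sample beat windows around R-peaks
#'
#' Cuts one half-open window `[r - 125, r + 125)` (250 samples, about
#' 0.7 s at 360 Hz) around each R index, min--max normalizes each window
#' individually, and drops beats with insufficient context at the record
#' edges, constant (flat) windows, and beats labeled `EXCLUDED`.
#'
#' @param record a band-pass-filtered [ecg_record()].
#' @param r_indices sorted 0-based R-peak sample indices.
#' @param labels optional per-beat labels over `c("N","V","S","EXCLUDED")`.
#' @return a [beat_dataset()]; attribute `dropped` holds the counts of
#'   dropped beats by reason (`boundary`, `excluded`, `degenerate`).
#' @export
segment_beats <- function(record, r_indices, labels = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  half <- 125L
  r <- as.integer(r_indices)
  if (is.unsorted(r, strictly = FALSE)) tb_stop("r_indices must be sorted")
  n_sig <- length(record$signal)
  dropped <- c(boundary = 0L, excluded = 0L, degenerate = 0L)

  keep_lab <- rep(TRUE, length(r))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(r))
    keep_lab <- labels %in% BEAT_CLASSES
    dropped[["excluded"]] <- sum(!keep_lab)
  }
  in_bounds <- r >= half & r + half <= n_sig
  dropped[["boundary"]] <- sum(!in_bounds & keep_lab)
  sel <- which(in_bounds & keep_lab)

  rows <- vector("list", length(sel))
  ok <- logical(length(sel))
  for (i in seq_along(sel)) {
    ri <- r[[sel[[i]]]]
    win <- record$signal[(ri - half + 1L):(ri + half)]
    norm <- tryCatch(minmax_normalize(win)$normalized,
                     tinybeat_degenerate_error = function(e) NULL)
    if (is.null(norm)) next
    rows[[i]] <- norm
    ok[[i]] <- TRUE
  }
  dropped[["degenerate"]] <- sum(!ok)
  sel <- sel[ok]
  x <- if (length(sel)) do.call(rbind, rows[ok]) else
    matrix(numeric(0), 0L, 250L)
  ds <- beat_dataset(x,
                     labels = if (is.null(labels) || !length(sel)) NULL
                              else labels[sel],
                     r_index = r[sel],
                     record_id = rep(record$record_id, length(sel)),
                     provenance = "real")
  attr(ds, "dropped") <- dropped
  ds
}

#' Build a beat dataset from ECG records
#'
#' In `"annotations"` mode (the training path) windows are centered on the
#' annotated R samples and labels come from [map_annotation_symbol()]; in
#' `"detected"` mode (the inference path) windows are centered on
#' [pan_tompkins_detect()] output and carry no labels.  Records are
#' expected to be band-pass filtered already.
#'
#' @param records list of filtered [ecg_record()] objects.
#' @param mode `"annotations"` or `"detected"`.
#' @param label_map optional symbol-grouping override passed to
#'   [map_annotation_symbol()].
#' @return a [beat_dataset()] with a `dropped` count attribute.
#' @export
build_dataset <- function(records, mode = c("annotations", "detected"),
                          label_map = NULL) {
  mode <- match.arg(mode)
  if (inherits(records, "ecg_record")) records <- list(records)
  parts <- lapply(records, function(rec) {
    if (mode == "annotations") {
      if (is.null(rec$annotations) || nrow(rec$annotations) == 0L)
        tb_stop("record '%s' has no annotations (annotations mode)",
                rec$record_id, class = "tinybeat_input_error")
      labs <- map_annotation_symbol(rec$annotations$symbol, table = label_map)
      segment_beats(rec, rec$annotations$sample, labels = labs)
    } else {
      segment_beats(rec, pan_tompkins_detect(rec$signal, rec$fs))
    }
  })
  ds <- if (length(parts) == 1L) parts[[1L]] else do.call(dataset_rbind, parts)
  dropped <- Reduce(`+`, lapply(parts, attr, "dropped"))
  if (nrow(ds$x) == 0L)
    tb_warn("no usable beats (%d dropped: %s)", sum(dropped),
            paste(names(dropped), dropped, sep = "=", collapse = ", "))
  attr(ds, "dropped") <- dropped
  ds
}
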