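#' Design the Butterworth band-pass filter
#'
#' Designs the digital Butterworth band-pass used to clean raw ECG
#' (default: fourth order overall, 0.5--40 Hz).  The transfer function is
#' obtained from [signal::butter()] and realized as cascaded second-order
#' sections (biquads) for numerical stability at the 0.5 Hz corner.
#'
#' @param order overall filter order (even, >= 2); the band-pass prototype
#'   order is `order/2`.
#' @param low_cut,high_cut band edges in Hz; `0 < low_cut < high_cut <
#'   fs/2`.
#' @param fs sampling rate in Hz.
#' @return an object of class `filter_spec` with the section matrix `sos`
#'   (one row per biquad: b0 b1 b2 a0 a1 a2).
#' @export
design_bandpass <- function(order = 4L, low_cut = 0.5, high_cut = 40,
                            fs = 360) {
  if (order < 2L || order %% 2L != 0L)
    tb_stop("order must be even and >= 2", class = "tinybeat_design_error")
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2))
    tb_stop("need 0 < low_cut < high_cut < fs/2",
            class = "tinybeat_design_error")
  bt <- signal::butter(order / 2L, c(low_cut, high_cut) / (fs / 2),
                       type = "pass")
  sos <- tf_to_sos(bt$b, bt$a)
  structure(list(order = as.integer(order), low_cut = low_cut,
                 high_cut = high_cut, fs = fs, b = bt$b, a = bt$a,
                 sos = sos),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> Butterworth band-pass, order %d, %g-%g Hz @ %g Hz (%d biquads)\n",
              x$order, x$low_cut, x$high_cut, x$fs, nrow(x$sos)))
  invisible(x)
}

# Split a transfer function into second-order sections by pairing
# conjugate poles (largest magnitude first) with their nearest zeros; the
# overall gain is spread evenly across sections.
tf_to_sos <- function(b, a) {
  z <- polyroot(rev(b / b[[1L]]))
  p <- polyroot(rev(a / a[[1L]]))
  k <- b[[1L]] / a[[1L]]
  nsec <- ceiling(max(length(z), length(p)) / 2)
  # pad to even counts
  if (length(z) < 2L * nsec) z <- c(z, rep(0i, 2L * nsec - length(z)))
  if (length(p) < 2L * nsec) p <- c(p, rep(0i, 2L * nsec - length(p)))
  sos <- matrix(0, nsec, 6L)
  kp <- k^(1 / nsec)
  for (s in seq_len(nsec)) {
    i1 <- which.max(Mod(p))
    p1 <- p[[i1]]; p <- p[-i1]
    i2 <- which.min(Mod(p - Conj(p1)))
    p2 <- p[[i2]]; p <- p[-i2]
    j1 <- which.min(Mod(z - p1))
    z1 <- z[[j1]]; z <- z[-j1]
    j2 <- which.min(Mod(z - Conj(z1)))
    z2 <- z[[j2]]; z <- z[-j2]
    bs <- Re(c(1, -(z1 + z2), z1 * z2)) * kp
    as_ <- Re(c(1, -(p1 + p2), p1 * p2))
    sos[s, ] <- c(bs, as_)
  }
  sos
}

# Steady-state filter state (direct form II transposed) for a unit-step
# input, one row per section; used to suppress start-up transients.
sos_step_zi <- function(sos) {
  t(apply(sos, 1L, function(s) {
    b <- s[1:3] / s[[4L]]
    a <- s[4:6] / s[[4L]]
    A <- rbind(c(-a[[2L]], 1), c(-a[[3L]], 0))
    B <- b[2:3] - a[2:3] * b[[1L]]
    solve(diag(2) - A, B)
  }))
}

sos_dc_gain <- function(sos) {
  apply(sos, 1L, function(s) sum(s[1:3]) / sum(s[4:6]))
}

# One forward pass through the biquad cascade with per-section initial
# conditions scaled for input level x0.
sos_forward <- function(x, sos, zi, x0) {
  gains <- sos_dc_gain(sos)
  scale <- x0
  for (s in seq_len(nrow(sos))) {
    x <- biquad_df2t(x, sos[s, 1:3] / sos[s, 4L], sos[s, 5:6] / sos[s, 4L],
                     zi[s, ] * scale)
    scale <- scale * gains[[s]]
  }
  x
}

#' Zero-phase forward--backward filtering
#'
#' Applies the band-pass forward and then backward so the net phase shift
#' is zero and waveform landmarks (in particular the QRS apex) are not
#' displaced; the effective magnitude response is the squared single-pass
#' response.  The signal is edge-padded by even extension of length
#' `3 * (order + 1)` and each pass starts from step-matched initial
#' conditions.
#'
#' @param x numeric signal.
#' @param spec a [design_bandpass()] filter spec.
#' @return filtered signal, same length as `x`.
#' @export
filter_zero_phase <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  pad <- 3L * (spec$order + 1L)
  if (length(x) <= 3L * spec$order)
    tb_stop("signal too short to filter (need > %d samples)", 3L * spec$order,
            class = "tinybeat_length_error")
  pad <- min(pad, length(x) - 1L)
  xe <- c(rev(x[2:(pad + 1L)]), x, rev(x[(length(x) - pad):(length(x) - 1L)]))
  zi <- sos_step_zi(spec$sos)
  y <- sos_forward(xe, spec$sos, zi, xe[[1L]])
  y <- rev(y)
  y <- sos_forward(y, spec$sos, zi, y[[1L]])
  y <- rev(y)
  y[(pad + 1L):(pad + length(x))]
}

#' Magnitude response of a filter spec
#'
#' Evaluates the single-pass magnitude response of the biquad cascade at
#' the requested frequencies (the zero-phase pipeline applies its square).
#'
#' @param spec a [design_bandpass()] spec.
#' @param f frequencies in Hz.
#' @return numeric vector of single-pass gains.
#' @export
filter_gain <- function(spec, f) {
  w <- 2 * pi * f / spec$fs
  zinv <- exp(-1i * w)
  g <- rep(1 + 0i, length(w))
  for (s in seq_len(nrow(spec$sos))) {
    bs <- spec$sos[s, 1:3]
    as_ <- spec$sos[s, 4:6]
    g <- g * (bs[[1L]] + bs[[2L]] * zinv + bs[[3L]] * zinv^2) /
      (as_[[1L]] + as_[[2L]] * zinv + as_[[3L]] * zinv^2)
  }
  Mod(g)
}

#' Min--max normalize one heartbeat segment
#'
#' Rescales a segment to \[0, 1\] using the minimum and maximum computed
#' within that individual segment, preserving relative morphology.  A
#' constant segment carries no morphology and raises a degenerate-segment
#' error (callers drop and count such windows).
#'
#' @param segment numeric vector (nonempty).
#' @return list with `normalized` (values in \[0, 1\]) and `params`
#'   (`x_min`, `x_max`).
#' @export
minmax_normalize <- function(segment) {
  if (length(segment) < 1L) tb_stop("segment must be nonempty")
  x_min <- min(segment)
  x_max <- max(segment)
  if (x_max == x_min)
    tb_stop("constant segment cannot be min-max normalized",
            class = "tinybeat_degenerate_error")
  list(normalized = (segment - x_min) / (x_max - x_min),
       params = list(x_min = x_min, x_max = x_max))
}
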