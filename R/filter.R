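# Butterworth band-pass design in second-order sections and zero-phase
# application. Coefficients are derived analytically (analog prototype ->
# lowpass-to-bandpass transform -> bilinear transform per biquad); the SOS
# cascade stays numerically stable where a single transfer-function
# realization of the same order fails (narrow low-frequency bands).

#' Butterworth band-pass filter in second-order sections
#'
#' Designs a band-pass Butterworth filter of the given overall order as a
#' cascade of biquad sections. `order` counts the poles of the band-pass
#' filter itself, so `order = 10` corresponds to a 5th-order low-pass
#' prototype and rolls off at 60 dB/octave on each side.
#'
#' @param low,high Pass-band edges in Hz.
#' @param fs Sampling rate in Hz; `high` must be below `fs / 2`.
#' @param order Overall band-pass order (even, default 10).
#' @return A `butter_sos` object: list with `sos` (n_sections x 6 matrix of
#'   b0, b1, b2, 1, a1, a2) and the design parameters.
#' @export
butter_bandpass <- function(low, high, fs, order = 10L) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= fs / 2) {
    stop("upper band edge ", high, " Hz is not below the Nyquist frequency ",
         fs / 2, " Hz")
  }
  if (order %% 2L != 0L) stop("band-pass order must be even")
  n <- order %/% 2L                      # low-pass prototype order

  # prototype poles on the unit circle, left half-plane
  kk <- seq_len(n)
  theta <- pi * (2 * kk - 1) / (2 * n)
  p <- complex(real = -sin(theta), imaginary = cos(theta))

  # bilinear pre-warp of the band edges
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1

  # each prototype pole maps to two band-pass poles; conjugate pairs are
  # grouped into one biquad each, a real prototype pole yields one biquad
  pole_pairs <- list()
  for (i in kk) {
    pp <- p[i]
    half <- bw * pp / 2
    disc <- sqrt(half^2 - w0^2 + 0i)
    q1 <- half + disc
    q2 <- half - disc
    if (abs(Im(pp)) < 1e-12) {
      pole_pairs[[length(pole_pairs) + 1L]] <- c(q1, q2)
    } else if (Im(pp) > 0) {
      pole_pairs[[length(pole_pairs) + 1L]] <- c(q1, Conj(q1))
      pole_pairs[[length(pole_pairs) + 1L]] <- c(q2, Conj(q2))
    }
  }

  # bilinear transform of each pole pair; every section takes one zero at
  # z = 1 and one at z = -1 (numerator z^2 - 1)
  nsec <- length(pole_pairs)
  sos <- matrix(0, nsec, 6L)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  for (s in seq_len(nsec)) {
    z <- (fs2 + pole_pairs[[s]]) / (fs2 - pole_pairs[[s]])
    a1 <- -Re(z[1] + z[2])
    a2 <- Re(z[1] * z[2])
    sos[s, ] <- c(1, 0, -1, 1, a1, a2)
  }

  # normalise to unit gain at the (digital) centre frequency, spreading the
  # scale evenly across sections
  fc <- atan(w0 / fs2) * fs / pi
  zc <- exp(2i * pi * fc / fs)
  h <- prod(vapply(seq_len(nsec), function(s) {
    num <- sos[s, 1] + sos[s, 2] / zc + sos[s, 3] / zc^2
    den <- 1 + sos[s, 5] / zc + sos[s, 6] / zc^2
    Mod(num / den)
  }, numeric(1)))
  g <- (1 / h)^(1 / nsec)
  sos[, 1:3] <- sos[, 1:3] * g

  structure(list(sos = sos, low = low, high = high, fs = fs, order = order),
            class = "butter_sos")
}

# one biquad, zero initial state; AR part runs through stats::filter's
# C recursion
biquad_filter <- function(b, a1, a2, x) {
  n <- length(x)
  w <- b[1] * x
  if (n > 1L) w[-1L] <- w[-1L] + b[2] * x[-n]
  if (n > 2L) w[-(1:2)] <- w[-(1:2)] + b[3] * x[seq_len(n - 2L)]
  as.numeric(stats::filter(w, c(-a1, -a2), method = "recursive"))
}

sosfilt_vec <- function(sos, x) {
  for (s in seq_len(nrow(sos))) {
    x <- biquad_filter(sos[s, 1:3], sos[s, 5], sos[s, 6], x)
  }
  x
}

#' Zero-phase filtering through a second-order-section cascade
#'
#' Applies the filter forward and backward (squaring the magnitude response
#' and cancelling the phase), with odd-reflection padding at both ends to
#' suppress startup transients. Group delay is zero, so post-onset latencies
#' of filtered features are preserved.
#'
#' @param filt A `butter_sos` object from [butter_bandpass()].
#' @param x Numeric vector, or matrix with time in rows (one column per
#'   channel).
#' @param padlen Reflection pad length in samples; defaults to the signal
#'   length minus one (maximal padding, appropriate for short epochs and
#'   low-frequency bands).
#' @param direction `"zero-phase"` (default, forward-backward) or
#'   `"forward"` (single causal pass, order as designed but with group
#'   delay).
#' @return Filtered data with the shape of `x`.
#' @export
sos_filtfilt <- function(filt, x, padlen = NULL,
                         direction = c("zero-phase", "forward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(filt, "butter_sos"))
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) {
      out[, j] <- sos_filtfilt(filt, x[, j], padlen = padlen,
                               direction = direction)
    }
    return(out)
  }
  n <- length(x)
  if (n < 4L) stop("signal too short to filter (need >= 4 samples)")
  if (all(x == 0)) return(x)
  if (is.null(padlen)) padlen <- n - 1L
  padlen <- min(padlen, n - 1L)
  xp <- c(2 * x[1L] - x[(padlen + 1L):2L],
          x,
          2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- sosfilt_vec(filt$sos, xp)
  if (direction == "zero-phase") {
    y <- rev(sosfilt_vec(filt$sos, rev(y)))
  }
  y[(padlen + 1L):(padlen + n)]
}

#' Band-pass filter a recording, trial set, or matrix
#'
#' Applies the band's 10th-order Butterworth band-pass, zero-phase, per
#' channel. This is the first of the five TFSL steps (band definition and
#' filtering).
#'
#' @param x A [recording][as_recording()], a `trialset`, or a numeric matrix
#'   with time in rows.
#' @param band A [band_spec()].
#' @param fs Sampling rate in Hz (taken from `x` when it carries one).
#' @param ... Passed to [sos_filtfilt()].
#' @return Object of the same shape with each channel filtered.
#' @export
bandpass <- function(x, band, fs = NULL, ...) UseMethod("bandpass")

#' @export
bandpass.matrix <- function(x, band, fs, ...) {
  stopifnot(inherits(band, "band_spec"))
  sos_filtfilt(butter_bandpass(band$low, band$high, fs), x, ...)
}

#' @export
bandpass.recording <- function(x, band, fs = NULL, ...) {
  x$data <- t(bandpass.matrix(t(x$data), band, fs = x$fs, ...))
  x
}

#' @export
bandpass.trialset <- function(x, band, fs = NULL, ...) {
  filt <- butter_bandpass(band$low, band$high, x$fs)
  for (i in seq_len(dim(x$trials)[1L])) {
    x$trials[i, , ] <- t(sos_filtfilt(filt, t(x$trials[i, , , drop = TRUE]), ...))
  }
  x
}
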