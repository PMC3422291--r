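#' Frequency band specification
#'
#' A band couples a pass-band in Hz with the time-delay embedding parameters
#' used for synchronization-likelihood estimation in that band: the embedding
#' lag `L` (in samples) and the embedding dimension `m`. An embedded state
#' vector spans `(m - 1) * L` samples.
#'
#' @param name Band name (e.g. `"alpha"`).
#' @param low,high Pass-band edges in Hz, `0 < low < high`.
#' @param L Embedding lag in samples, `L >= 1`.
#' @param m Embedding dimension, `m >= 2`.
#' @return An object of class `band_spec`.
#' @seealso [default_bands()]
#' @export
band_spec <- function(name, low, high, L, m) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && high > low)) {
    stop("band edges must satisfy 0 < low < high (got ", low, ", ", high, ")")
  }
  L <- as.integer(L); m <- as.integer(m)
  if (L < 1L) stop("embedding lag L must be >= 1")
  if (m < 2L) stop("embedding dimension m must be >= 2")
  structure(list(name = name, low = low, high = high, L = L, m = m),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz, L = %d, m = %d, span = %d samples>\n",
              x$name, x$low, x$high, x$L, x$m, (x$m - 1L) * x$L))
  invisible(x)
}

#' Default six-band analysis grid
#'
#' The canonical EEG band partition used throughout the pipeline, each with
#' its synchronization-likelihood embedding parameters: delta (1-4 Hz,
#' L = 25, m = 8), theta (4-8 Hz, L = 21, m = 7), alpha (8-12 Hz, L = 14,
#' m = 6), beta (12-30 Hz, L = 6, m = 8), gamma1 (30-40 Hz, L = 5, m = 5)
#' and gamma2 (40-60 Hz, L = 3, m = 6). Lags shorten as frequency rises so
#' that an embedded vector covers roughly comparable oscillatory phase in
#' every band.
#'
#' @return A named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  b <- list(
    band_spec("delta",  1,  4, 25, 8),
    band_spec("theta",  4,  8, 21, 7),
    band_spec("alpha",  8, 12, 14, 6),
    band_spec("beta",  12, 30,  6, 8),
    band_spec("gamma1", 30, 40, 5, 5),
    band_spec("gamma2", 40, 60, 3, 6)
  )
  names(b) <- vapply(b, `[[`, "", "name")
  b
}

#' Embedding tail length for a set of bands
#'
#' Epochs carry `(m - 1) * L` extra samples (maximised over bands) beyond the
#' nominal analysis second, so that embedding vectors anchored anywhere inside
#' the analysis second are complete even in the slowest band.
#'
#' @param bands A list of [band_spec()] objects.
#' @return Tail length in samples.
#' @export
embedding_tail <- function(bands = default_bands()) {
  max(vapply(bands, function(b) (b$m - 1L) * b$L, integer(1)))
}

#' 50 ms window grid over the analysis second
#'
#' Returns the boundaries of `n_windows` equal 50 ms windows tiling the first
#' second after stimulus onset. Boundaries are `round(k * 0.05 * fs)` with
#' half-open intervals, so at 512 Hz the windows alternate between 25 and 26
#' samples and tile samples 0..511 exactly.
#'
#' @param fs Sampling rate in Hz.
#' @param n_windows Number of windows (default 20).
#' @return Integer matrix with columns `start`, `end`: 0-based half-open
#'   sample ranges `[start, end)`.
#' @export
window_grid <- function(fs, n_windows = 20L) {
  k <- 0:n_windows
  edges <- as.integer(round(k * 0.05 * fs))
  cbind(start = edges[-(n_windows + 1L)], end = edges[-1L])
}
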