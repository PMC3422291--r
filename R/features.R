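#' F-ratio discriminability score
#'
#' Ratio of the variance of the two class means to the average within-class
#' variance. With class means `m1, m2`, grand mean of means `mb`, and
#' unbiased within-class variances `s1^2, s2^2`:
#' `FR = ((m1 - mb)^2 + (m2 - mb)^2) / 1  /  ((s1^2 + s2^2) / 2)`,
#' equivalently `(m1 - m2)^2 / 2` over the mean within-class variance.
#' The score is invariant to adding a constant and to common rescaling.
#'
#' @param x Numeric vector (one feature) or trials x features matrix.
#' @param labels Two-level factor of class labels, one per trial.
#' @param between `"sample"` (default; divides the between-class sum of
#'   squares by K - 1 = 1) or `"population"` (divides by K = 2, halving all
#'   scores but leaving ranks unchanged).
#' @return Numeric vector of F-ratios (one per feature). Features with zero
#'   within-class variance but differing means return `Inf` with a warning;
#'   identical degenerate classes return 0.
#' @export
f_ratio <- function(x, labels, between = c("sample", "population")) {
  between <- match.arg(between)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) {
    stop("f_ratio needs exactly two classes, got ", nlevels(labels))
  }
  n_per <- table(labels)
  if (any(n_per < 2L)) {
    stop("class '", names(n_per)[which.min(n_per)],
         "' has fewer than 2 trials")
  }
  g1 <- labels == levels(labels)[1L]
  x1 <- x[g1, , drop = FALSE]; x2 <- x[!g1, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2L, stats::var); v2 <- apply(x2, 2L, stats::var)
  mb <- (m1 + m2) / 2
  denom_k <- if (between == "sample") 1 else 2
  bss <- ((m1 - mb)^2 + (m2 - mb)^2) / denom_k
  wss <- (v1 + v2) / 2
  fr <- bss / wss
  degenerate <- wss == 0
  if (any(degenerate)) {
    fr[degenerate & bss > 0] <- Inf
    fr[degenerate & bss == 0] <- 0
    if (any(degenerate & bss > 0)) {
      warning(sum(degenerate & bss > 0),
              " feature(s) have zero within-class variance and differing ",
              "means; F-ratio set to Inf")
    }
  }
  fr
}

feature_matrix_of <- function(x, labels = NULL, windows = NULL) {
  if (inherits(x, "feature_tensor")) {
    lab <- if (is.null(labels)) attr(x, "labels") else labels
    list(mat = tensor_to_matrix(x, windows = windows), labels = lab)
  } else {
    stopifnot(is.matrix(x))
    if (is.null(labels)) stop("labels must be supplied with a plain matrix")
    idx <- attr(x, "feature_index")
    if (!is.null(windows) && !is.null(idx)) {
      keep <- idx$window %in% windows
      x2 <- x[, keep, drop = FALSE]
      attr(x2, "feature_index") <- idx[keep, , drop = FALSE]
      x <- x2
    }
    list(mat = x, labels = labels)
  }
}

# deterministic descending order: F-ratio, ties by (band, electrode, window)
fr_order <- function(fr, idx) {
  if (is.null(idx)) order(-fr, seq_along(fr))
  else order(-fr, idx$band, idx$electrode, idx$window)
}

#' Rank all features by F-ratio
#'
#' @param x A `feature_tensor` or trials x features matrix (with an optional
#'   `feature_index` attribute).
#' @param labels Two-level factor; taken from the tensor when omitted.
#' @param ... Passed to [f_ratio()].
#' @return Data frame (class `fratio_table`) with one row per feature:
#'   `id`, `band`, `electrode`, `window`, `f_ratio`, `rank` (1 = most
#'   discriminative; ties broken by feature id order).
#' @export
rank_features <- function(x, labels = NULL, ...) {
  fm <- feature_matrix_of(x, labels)
  fr <- f_ratio(fm$mat, fm$labels, ...)
  idx <- attr(fm$mat, "feature_index")
  ord <- fr_order(fr, idx)
  rk <- integer(length(fr)); rk[ord] <- seq_along(fr)
  out <- if (is.null(idx)) {
    data.frame(id = colnames(fm$mat) %||% paste0("f", seq_along(fr)))
  } else idx
  out$f_ratio <- fr
  out$rank <- rk
  class(out) <- c("fratio_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Temporal profile of feature-space discriminability
#'
#' Mean F-ratio of the top `k` features as a function of time. In
#' `"cumulative"` mode step `k'` uses all features from windows `1..k'`
#' (384 features per window step at the default 64-channel, 6-band grid);
#' in `"windowed"` mode step `k'` uses only window `k'`'s features.
#'
#' @param x A `feature_tensor` (or matrix with `feature_index`).
#' @param labels Two-level factor; taken from the tensor when omitted.
#' @param mode `"cumulative"` or `"windowed"`.
#' @param k Number of top-ranked features to average (default 300). When
#'   fewer features are available than `k`, all are averaged (with a
#'   warning at the first such step).
#' @return Data frame (class `fratio_profile`): `step`, `time_ms` (window
#'   end), `n_features`, `n_averaged`, `mean_top_k`.
#' @export
fratio_profile <- function(x, labels = NULL,
                           mode = c("cumulative", "windowed"), k = 300L) {
  mode <- match.arg(mode)
  fm <- feature_matrix_of(x, labels)
  idx <- attr(fm$mat, "feature_index")
  if (is.null(idx)) stop("a feature index with windows is required")
  nw <- max(idx$window)
  fs_ms <- 50                                    # window grid pitch in ms
  warned <- FALSE
  rows <- lapply(seq_len(nw), function(kp) {
    wins <- if (mode == "cumulative") seq_len(kp) else kp
    keep <- idx$window %in% wins
    fr <- f_ratio(fm$mat[, keep, drop = FALSE], fm$labels)
    ord <- fr_order(fr, idx[keep, , drop = FALSE])
    n_avg <- min(k, length(fr))
    if (n_avg < k && !warned) {
      warning("fewer than k = ", k, " features at step ", kp,
              "; averaging all ", length(fr))
      warned <<- TRUE
    }
    data.frame(step = kp, time_ms = kp * fs_ms, n_features = length(fr),
               n_averaged = n_avg,
               mean_top_k = mean(fr[ord[seq_len(n_avg)]]))
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  class(out) <- c("fratio_profile", "data.frame")
  out
}

#' Spatial map of discriminability
#'
#' Per-electrode mean F-ratio over all bands and a selected range of 50 ms
#' windows, for scalp topography of where class information lives.
#'
#' @param x A `feature_tensor`.
#' @param labels Two-level factor; taken from the tensor when omitted.
#' @param windows Non-empty vector of window indices to average over.
#' @param positions Optional n_electrodes x 2 coordinates (default
#'   [radial_layout()]).
#' @return A `scalp_map`: list with `values` (one per electrode),
#'   `positions`, `windows`.
#' @export
scalp_map <- function(x, labels = NULL, windows, positions = NULL) {
  if (length(windows) == 0L) stop("window subset must be non-empty")
  fm <- feature_matrix_of(x, labels, windows = windows)
  idx <- attr(fm$mat, "feature_index")
  fr <- f_ratio(fm$mat, fm$labels)
  vals <- tapply(fr, idx$electrode, mean)
  electrodes <- as.integer(names(vals))
  if (is.null(positions)) positions <- radial_layout(max(electrodes))
  structure(list(values = as.numeric(vals), electrodes = electrodes,
                 positions = positions[electrodes, , drop = FALSE],
                 windows = windows),
            class = "scalp_map")
}

#' Plot a scalp map
#'
#' Inverse-distance-weighted interpolation of per-electrode values over the
#' head disc, with electrode markers. Requires ggplot2.
#'
#' @param map A [scalp_map()].
#' @param grid_n Interpolation grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_scalp_map <- function(map, grid_n = 80L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_scalp_map requires the ggplot2 package")
  }
  stopifnot(inherits(map, "scalp_map"))
  g <- expand.grid(x = seq(-1.1, 1.1, length.out = grid_n),
                   y = seq(-1.1, 1.1, length.out = grid_n))
  inside <- g$x^2 + g$y^2 <= 1.1^2
  interp <- rep(NA_real_, nrow(g))
  px <- map$positions[, 1L]; py <- map$positions[, 2L]
  interp[inside] <- vapply(which(inside), function(i) {
    d2 <- (g$x[i] - px)^2 + (g$y[i] - py)^2
    if (any(d2 < 1e-12)) return(map$values[which.min(d2)])
    w <- 1 / d2
    sum(w * map$values) / sum(w)
  }, numeric(1))
  g$value <- interp
  pts <- data.frame(x = px, y = py, value = map$values)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value), na.rm = TRUE) +
    ggplot2::geom_point(data = pts, shape = 21, colour = "black",
                        ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(name = "mean F-ratio", na.value = NA) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
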