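#' Synchronization likelihood parameters
#'
#' Parameters shared by all bands when computing time-frequency resolved
#' synchronization likelihood (TFSL).
#'
#' @param p_ref Reference recurrence probability; each anchor's critical
#'   distance is chosen so this fraction of candidate vectors counts as a
#'   recurrence. `p_ref` is also the expected SL between independent
#'   signals. Default 0.1.
#' @param candidate_shift Spacing in samples between successive candidate
#'   (state) vectors. Default 1.
#' @param anchor_shift Spacing in samples between successive reference
#'   (anchor) vectors. Default 25.
#' @param n_anchors Number of reference vectors per epoch. Default 20, one
#'   per 50 ms window of the analysis second.
#' @param theiler Temporal exclusion half-width in samples around each
#'   anchor; candidates closer than this never count as recurrences, which
#'   guards against trivially autocorrelated neighbours. `NULL` (default)
#'   uses the embedding span `(m - 1) * L` of the band being analysed.
#' @return An `sl_params` object.
#' @export
sl_params <- function(p_ref = 0.1, candidate_shift = 1L, anchor_shift = 25L,
                      n_anchors = 20L, theiler = NULL) {
  if (!(p_ref > 0 && p_ref < 1)) stop("p_ref must lie in (0, 1)")
  if (candidate_shift < 1L) stop("candidate_shift must be >= 1")
  if (anchor_shift < 1L) stop("anchor_shift must be >= 1")
  if (n_anchors < 1L) stop("n_anchors must be >= 1")
  if (!is.null(theiler) && theiler < 0L) stop("theiler must be >= 0")
  structure(list(p_ref = p_ref,
                 candidate_shift = as.integer(candidate_shift),
                 anchor_shift = as.integer(anchor_shift),
                 n_anchors = as.integer(n_anchors),
                 theiler = if (is.null(theiler)) NULL else as.integer(theiler)),
            class = "sl_params")
}

theiler_for <- function(params, band) {
  if (is.null(params$theiler)) (band$m - 1L) * band$L else params$theiler
}

#' Time-delay embedding of a scalar series
#'
#' The embedded state at (1-based) index `t` is
#' `(x[t], x[t + L], ..., x[t + (m - 1) * L])`; the series yields
#' `length(x) - (m - 1) * L` such states.
#'
#' @param x Numeric vector.
#' @param L Lag in samples.
#' @param m Embedding dimension.
#' @return Matrix with one embedded state per row.
#' @export
embed_delay <- function(x, L, m) {
  L <- as.integer(L); m <- as.integer(m)
  span <- (m - 1L) * L
  n <- length(x) - span
  if (n < 1L) {
    stop("series of length ", length(x), " too short to embed with L = ", L,
         ", m = ", m, "; need at least ", span + 1L, " samples")
  }
  out <- matrix(0, n, m)
  for (d in seq_len(m)) out[, d] <- x[(1L + (d - 1L) * L):(n + (d - 1L) * L)]
  out
}

# squared Euclidean distances from one embedded state to many;
# colSums accumulates in extended precision, matching the C++ core
dist2_to <- function(anchor, candidates) {
  colSums((t(candidates) - anchor)^2)
}

#' Critical (recurrence) distance at an anchor
#'
#' The smallest distance `eps` such that at least a fraction `p_ref` of the
#' non-excluded candidate states lie within `eps` of the anchor state:
#' the `ceiling(p_ref * N)`-th order statistic of the candidate distances.
#'
#' @param anchor Numeric vector: one embedded state.
#' @param candidates Matrix of candidate states (one per row).
#' @param p_ref Recurrence probability in (0, 1).
#' @param excluded Integer row indices of candidates to ignore (e.g. the
#'   Theiler neighbourhood of the anchor).
#' @return The critical Euclidean distance.
#' @export
critical_distance <- function(anchor, candidates, p_ref = 0.1,
                              excluded = integer(0)) {
  if (!(p_ref > 0 && p_ref < 1)) stop("p_ref must lie in (0, 1)")
  if (!is.matrix(candidates)) candidates <- matrix(candidates, ncol = length(anchor))
  keep <- setdiff(seq_len(nrow(candidates)), excluded)
  N <- length(keep)
  if (N < ceiling(1 / p_ref)) {
    stop("only ", N, " non-excluded candidates; need at least ",
         ceiling(1 / p_ref), " for p_ref = ", p_ref)
  }
  d2 <- dist2_to(anchor, candidates[keep, , drop = FALSE])
  k <- ceiling(p_ref * N)
  sqrt(sort(d2, partial = k)[k])
}

#' Synchronization likelihood at one anchor
#'
#' With `Rx` the recurrence set of channel `x` at the anchor (non-excluded
#' candidates within `x`'s critical distance) and `Ry` likewise for channel
#' `y`, the directed SL is `|Rx n Ry| / |Rx|`: the conditional probability
#' that a recurrence in `x` is accompanied by a recurrence in `y`.
#'
#' @param anchor_idx 1-based row index of the anchor in both embedding
#'   matrices.
#' @param X,Y Embedding matrices (states in rows) of the two channels,
#'   aligned in time.
#' @param params [sl_params()]; `theiler` of `NULL` here means no exclusion
#'   beyond the anchor itself.
#' @param symmetric If `TRUE`, return the mean of the two directed values
#'   (the undirected pair SL); otherwise the x-to-y directed value.
#' @return SL value in \[0, 1\].
#' @export
sl_at_anchor <- function(anchor_idx, X, Y, params = sl_params(),
                         symmetric = FALSE) {
  stopifnot(nrow(X) == nrow(Y))
  theiler <- if (is.null(params$theiler)) 0L else params$theiler
  cand <- seq(1L, nrow(X), by = params$candidate_shift)
  excl <- which(abs(cand - anchor_idx) <= theiler)
  rec_set <- function(E) {
    d2 <- dist2_to(E[anchor_idx, ], E[cand, , drop = FALSE])
    d2[excl] <- NA_real_
    kept <- d2[!is.na(d2)]
    N <- length(kept)
    if (N < ceiling(1 / params$p_ref)) {
      stop("only ", N, " non-excluded candidates; need at least ",
           ceiling(1 / params$p_ref))
    }
    k <- ceiling(params$p_ref * N)
    eps2 <- sort(kept, partial = k)[k]
    which(!is.na(d2) & d2 <= eps2)
  }
  rx <- rec_set(X)
  ry <- rec_set(Y)
  cnt <- length(intersect(rx, ry))
  if (symmetric) (cnt / length(rx) + cnt / length(ry)) / 2
  else cnt / length(rx)
}

anchor_positions <- function(params) {
  (seq_len(params$n_anchors) - 1L) * params$anchor_shift
}

# map 0-based anchor sample positions onto the window grid; returns a list
# of anchor index vectors, one per window
anchors_to_windows <- function(anchors0, windows) {
  nw <- nrow(windows)
  if (length(anchors0) == nw) {
    # the defaults' one-to-one correspondence: k-th anchor <-> k-th window
    return(as.list(seq_len(nw)))
  }
  out <- lapply(seq_len(nw), function(k) {
    which(anchors0 >= windows[k, "start"] & anchors0 < windows[k, "end"])
  })
  empty <- which(lengths(out) == 0L)
  if (length(empty) > 0L) {
    stop("no anchor falls inside window(s) ", paste(empty, collapse = ", "),
         "; adjust anchor_shift / n_anchors")
  }
  out
}

#' Pairwise TFSL for one band-filtered epoch
#'
#' Evaluates the synchronization likelihood of every channel pair at each
#' anchor and maps anchors onto the 50 ms window grid. At the default
#' parameters (20 anchors spaced 25 samples, 20 windows) the k-th anchor is
#' assigned to the k-th window; in other configurations anchors map to the
#' window containing them and windows holding several anchors average them.
#' Candidate vectors span the full epoch including the embedding tail.
#'
#' @param trial Channels x samples matrix, already band-pass filtered, of
#'   length at least the analysis second plus the band's embedding span.
#' @param band A [band_spec()] supplying the embedding lag and dimension.
#' @param params [sl_params()].
#' @param fs Sampling rate in Hz.
#' @param windows Window grid from [window_grid()].
#' @param engine `"cpp"` (optimized) or `"reference"` (plain-R brute force
#'   with explicit distance matrices; bit-identical results).
#' @return `n_pairs x n_windows` matrix of SL values in \[0, 1\], rows in
#'   `combn(n_channels, 2)` order.
#' @export
tfsl_pairwise <- function(trial, band, params = sl_params(), fs,
                          windows = window_grid(fs),
                          engine = c("cpp", "reference")) {
  engine <- match.arg(engine)
  stopifnot(is.matrix(trial), inherits(band, "band_spec"))
  anchors0 <- anchor_positions(params)
  theiler <- theiler_for(params, band)
  x <- t(trial)                          # samples x channels
  per_anchor <- if (engine == "cpp") {
    sl_pairwise_core(x, band$L, band$m, params$p_ref, params$candidate_shift,
                     anchors0, theiler)
  } else {
    sl_pairwise_ref(x, band$L, band$m, params$p_ref, params$candidate_shift,
                    anchors0, theiler)
  }
  amap <- anchors_to_windows(anchors0, windows)
  out <- matrix(NA_real_, nrow(per_anchor), nrow(windows))
  for (k in seq_len(nrow(windows))) {
    out[, k] <- rowMeans(per_anchor[, amap[[k]], drop = FALSE])
  }
  out
}

# Reference implementation: explicit distance matrices and recurrence sets.
# Deliberately naive (O(N^2) per channel); the optimized core is tested for
# bit-for-bit agreement against this path.
sl_pairwise_ref <- function(x, L, m, p_ref, candidate_shift, anchors0,
                            theiler) {
  ns <- nrow(x); nc <- ncol(x)
  span <- (m - 1L) * L
  nvec <- ns - span
  if (nvec < 1L) stop("epoch too short for embedding")
  cand <- seq(0L, nvec - 1L, by = candidate_shift)   # 0-based starts
  min_cand <- ceiling(1 / p_ref)
  rec_sets <- vector("list", nc)
  for (c in seq_len(nc)) {
    E <- embed_delay(x[, c], L, m)                    # nvec x m
    Ec <- E[cand + 1L, , drop = FALSE]
    rec_sets[[c]] <- lapply(seq_along(anchors0), function(a) {
      ap <- anchors0[a]
      if (ap < 0L || ap > nvec - 1L) stop("anchor outside embeddable range")
      d2 <- dist2_to(E[ap + 1L, ], Ec)
      excl <- abs(cand - ap) <= theiler
      kept <- d2[!excl]
      N <- length(kept)
      if (N < min_cand) {
        stop("only ", N, " non-excluded candidates at anchor ", ap)
      }
      k <- ceiling(p_ref * N)
      eps2 <- sort(kept)[k]
      which(!excl & d2 <= eps2)
    })
  }
  pairs <- utils::combn(nc, 2L)
  out <- matrix(NA_real_, ncol(pairs), length(anchors0))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    for (a in seq_along(anchors0)) {
      A <- rec_sets[[i]][[a]]; B <- rec_sets[[j]][[a]]
      cnt <- length(intersect(A, B))
      out[p, a] <- (cnt / length(A) + cnt / length(B)) / 2
    }
  }
  out
}

#' Aggregate pairwise SL to per-electrode values
#'
#' SL is defined per channel pair but features are indexed per electrode;
#' electrode `j`'s value at a window is the mean SL over the
#' `n_channels - 1` pairs that contain `j`.
#'
#' @param pairwise `n_pairs x n_windows` matrix from [tfsl_pairwise()].
#' @param n_channels Number of channels the pairs were formed from.
#' @return `n_channels x n_windows` matrix.
#' @export
channel_tfsl <- function(pairwise, n_channels) {
  pairs <- utils::combn(n_channels, 2L)
  if (ncol(pairs) != nrow(pairwise)) {
    stop("pairwise matrix has ", nrow(pairwise), " rows but ", n_channels,
         " channels give ", ncol(pairs), " pairs")
  }
  out <- matrix(0, n_channels, ncol(pairwise))
  for (j in seq_len(n_channels)) {
    sel <- pairs[1L, ] == j | pairs[2L, ] == j
    out[j, ] <- colMeans(pairwise[sel, , drop = FALSE])
  }
  out
}

#' Compute the TFSL feature tensor of a trial set
#'
#' For every trial and band: band-pass filter the epoch (including its
#' embedding tail), evaluate pairwise SL at the anchors with the band's
#' embedding parameters, and aggregate to electrodes. The result is the
#' `trial x band x electrode x window` tensor of features `B_i E_j T_k`;
#' at the default configuration (6 bands, 64 electrodes, 20 windows) each
#' trial carries 6 x 64 x 20 = 7680 features.
#'
#' @param trialset A `trialset` (see [generate_trialset()] or
#'   [epoch_and_label()]).
#' @param bands List of [band_spec()] objects (default [default_bands()]).
#' @param params [sl_params()].
#' @param engine Passed to [tfsl_pairwise()].
#' @param verbose Print progress every 25 trials.
#' @return A `feature_tensor`: 4-d array with a `feature_index` attribute
#'   (data frame of band / electrode / window / id per flattened feature)
#'   and the trial labels carried along as attributes.
#' @export
compute_feature_tensor <- function(trialset, bands = default_bands(),
                                   params = sl_params(), engine = "cpp",
                                   verbose = FALSE) {
  stopifnot(inherits(trialset, "trialset"))
  dims <- dim(trialset$trials)
  n_trial <- dims[1L]; n_chan <- dims[2L]; n_samp <- dims[3L]
  fs <- trialset$fs
  windows <- trialset$windows
  nw <- nrow(windows)
  filters <- lapply(bands, function(b) butter_bandpass(b$low, b$high, fs))
  vals <- array(NA_real_,
                c(n_trial, length(bands), n_chan, nw),
                dimnames = list(NULL, names(bands), NULL, NULL))
  for (i in seq_len(n_trial)) {
    raw <- matrix(trialset$trials[i, , ], n_chan, n_samp)
    for (b in seq_along(bands)) {
      filt <- t(sos_filtfilt(filters[[b]], t(raw)))
      pw <- tfsl_pairwise(filt, bands[[b]], params, fs, windows,
                          engine = engine)
      vals[i, b, , ] <- channel_tfsl(pw, n_chan)
    }
    if (verbose && i %% 25L == 0L) {
      message("  TFSL: trial ", i, " / ", n_trial)
    }
  }
  structure(vals,
            feature_index = feature_index(names(bands), n_chan, nw),
            labels = trialset$labels,
            participant = trialset$participant,
            fs = fs,
            class = c("feature_tensor", "array"))
}

#' Flattened feature index of a tensor
#'
#' Feature `B_i E_j T_k` denotes band `i`, electrode `j`, window `k`. The
#' flattened order runs window fastest, then electrode, then band.
#'
#' @param band_names Character vector of band names.
#' @param n_channels,n_windows Grid sizes.
#' @return Data frame with columns `band`, `electrode`, `window`, `id`.
#' @export
feature_index <- function(band_names, n_channels, n_windows) {
  g <- expand.grid(window = seq_len(n_windows),
                   electrode = seq_len(n_channels),
                   band = seq_along(band_names))
  g <- g[, c("band", "electrode", "window")]
  g$id <- sprintf("B%dE%dT%d", g$band, g$electrode, g$window)
  rownames(g) <- NULL
  g
}

#' Flatten a feature tensor to a trial-by-feature matrix
#'
#' @param tensor A `feature_tensor`.
#' @param windows Optional window subset (1-based indices) to keep.
#' @param features Optional row indices into the (already window-subset)
#'   feature index.
#' @return Numeric matrix, one row per trial; the matching feature index is
#'   attached as attribute `feature_index`.
#' @export
tensor_to_matrix <- function(tensor, windows = NULL, features = NULL) {
  stopifnot(inherits(tensor, "feature_tensor"))
  idx <- attr(tensor, "feature_index")
  d <- dim(tensor)
  if (is.null(windows)) windows <- seq_len(d[4L])
  keep <- idx$window %in% windows
  idx <- idx[keep, , drop = FALSE]
  n_trial <- d[1L]
  mat <- matrix(NA_real_, n_trial, nrow(idx))
  for (r in seq_len(nrow(idx))) {
    mat[, r] <- tensor[, idx$band[r], idx$electrode[r], idx$window[r]]
  }
  colnames(mat) <- idx$id
  if (!is.null(features)) {
    mat <- mat[, features, drop = FALSE]
    idx <- idx[features, , drop = FALSE]
  }
  attr(mat, "feature_index") <- idx
  mat
}
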