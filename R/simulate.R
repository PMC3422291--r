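#' Configuration of the synthetic coupled-EEG generator
#'
#' Describes a two-class epoched dataset in which class membership is carried
#' solely by inter-channel synchronization: trials of class `"chosen"` have a
#' shared narrow-band driver mixed into a subset of electrodes during a
#' subset of 50 ms windows, while `"not_chosen"` trials receive none (or a
#' reduced mixing coefficient). Everything else is independent 1/f background
#' noise, so the ground-truth discriminative features are exactly the
#' (effect band, effect electrode, effect window) triples.
#'
#' @param n_participants Number of simulated participants (default 17).
#' @param trials_per_participant Trials per participant (default 39).
#' @param n_channels Number of channels (default 64).
#' @param sampling_rate Sampling rate in Hz (default 512).
#' @param epoch_seconds Nominal analysis epoch in seconds (default 1);
#'   epochs additionally carry `tail_samples` for complete embeddings.
#' @param tail_samples Embedding tail beyond the analysis second, default
#'   [embedding_tail()] over `bands`.
#' @param bands Band list; the default six-band grid.
#' @param effect_band Name of the band carrying the class effect.
#' @param effect_windows 1-based indices (in 1..n_windows) of the 50 ms
#'   windows in which the driver is active.
#' @param effect_electrodes Electrode indices receiving the driver. `NULL`
#'   draws `n_effect_electrodes` at random (once, shared across
#'   participants, unless `per_participant_effects`).
#' @param n_effect_electrodes Size of a randomly drawn electrode set.
#' @param per_participant_effects If `TRUE`, each participant gets an
#'   independent random electrode set (the idiosyncratic regime that favours
#'   per-participant models); if `FALSE` all participants share one set.
#' @param coupling_strength Mixing coefficient `kappa >= 0`: driver RMS
#'   relative to the background RMS in `"chosen"` trials. At
#'   `coupling_strength = 1` the driver amplitude matches the background.
#' @param coupling_strength_nc Mixing coefficient of a *shared* driver in
#'   `"not_chosen"` trials (default 0), used when `matched_power = FALSE`.
#' @param matched_power If `TRUE` (default), every effect electrode in every
#'   trial carries a full-epoch band-limited driver at `coupling_strength`,
#'   and the class effect is injected purely as *synchronization*: in
#'   `"chosen"` trials the drivers of all effect electrodes crossfade to one
#'   shared realization inside the effect windows
#'   (`d_e(t) = m(t) c(t) + sqrt(1 - m(t)^2) o_e(t)` with `m` the ramped
#'   window mask, `c` shared, `o_e` electrode-specific), while in
#'   `"not_chosen"` trials each electrode keeps its own realization
#'   throughout. Band power is then identical across classes, electrodes
#'   and time, so the class contrast is confined to the ground-truth
#'   triples. With `FALSE`, the driver is simply switched on inside the
#'   effect windows of `"chosen"` trials (shared, scaled
#'   `coupling_strength`) and of `"not_chosen"` trials (shared, scaled
#'   `coupling_strength_nc`, none when 0); the on/off amplitude envelope
#'   then also discriminates the classes and bleeds into neighbouring
#'   windows.
#' @param class_balance Expected fraction of `"chosen"` trials, in (0, 1).
#' @param noise_exponent Spectral slope of the 1/f background (power ~
#'   1/f^exponent), default 1.
#' @param ramp_seconds Cosine on/off ramp applied at effect-window edges to
#'   keep the effect confined after filtering (default 0.01 s).
#' @param amplitude_uv Background RMS in microvolts (default 10); SL is
#'   amplitude-scale-free, this only sets a plausible numeric scale.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_participants = 17L, trials_per_participant = 39L,
                       n_channels = 64L, sampling_rate = 512,
                       epoch_seconds = 1, tail_samples = NULL,
                       bands = default_bands(),
                       effect_band = "alpha", effect_windows = 5:8,
                       effect_electrodes = NULL, n_effect_electrodes = 4L,
                       per_participant_effects = FALSE,
                       coupling_strength = 1, coupling_strength_nc = 0,
                       matched_power = TRUE,
                       class_balance = 0.5, noise_exponent = 1,
                       ramp_seconds = 0.01, amplitude_uv = 10) {
  if (is.null(tail_samples)) tail_samples <- embedding_tail(bands)
  nw <- 20L
  if (!all(effect_windows %in% seq_len(nw))) {
    stop("effect_windows must be a subset of 1..", nw)
  }
  if (!is.null(effect_electrodes) &&
      !all(effect_electrodes %in% seq_len(n_channels))) {
    stop("effect_electrodes must be a subset of 1..", n_channels)
  }
  if (coupling_strength < 0 || coupling_strength_nc < 0) {
    stop("coupling strengths must be >= 0")
  }
  if (!(class_balance > 0 && class_balance < 1)) {
    stop("class_balance must lie strictly between 0 and 1")
  }
  if (!effect_band %in% names(bands)) {
    stop("effect_band '", effect_band, "' is not one of: ",
         paste(names(bands), collapse = ", "))
  }
  structure(list(
    n_participants = as.integer(n_participants),
    trials_per_participant = as.integer(trials_per_participant),
    n_channels = as.integer(n_channels),
    sampling_rate = sampling_rate,
    epoch_seconds = epoch_seconds,
    tail_samples = as.integer(tail_samples),
    bands = bands,
    effect_band = effect_band,
    effect_windows = as.integer(effect_windows),
    effect_electrodes = if (is.null(effect_electrodes)) NULL
                        else as.integer(effect_electrodes),
    n_effect_electrodes = as.integer(n_effect_electrodes),
    per_participant_effects = isTRUE(per_participant_effects),
    coupling_strength = coupling_strength,
    coupling_strength_nc = coupling_strength_nc,
    matched_power = isTRUE(matched_power),
    class_balance = class_balance,
    noise_exponent = noise_exponent,
    ramp_seconds = ramp_seconds,
    amplitude_uv = amplitude_uv
  ), class = "sim_config")
}

# Gaussian noise with power spectral density ~ 1/f^exponent, unit RMS
one_over_f_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w / stats::sd(w))
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                       # avoid dividing DC by 0
  f <- pmin(f, n - f)                             # two-sided frequency index
  shape <- f^(-exponent / 2)
  shape[1L] <- 0                                  # remove DC
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# 0/1 mask over the epoch covering the effect windows, with raised-cosine
# ramps at the edges of each contiguous run of windows
effect_mask <- function(n_samples, windows, effect_windows, ramp_samples) {
  mask <- numeric(n_samples)
  for (k in effect_windows) {
    mask[(windows[k, "start"] + 1L):windows[k, "end"]] <- 1
  }
  if (ramp_samples >= 2L) {
    r <- (1 - cos(pi * seq(0, 1, length.out = ramp_samples))) / 2
    runs <- rle(mask > 0)
    pos <- cumsum(c(1L, runs$lengths))
    for (i in seq_along(runs$values)) {
      if (!runs$values[i]) next
      a <- pos[i]; b <- pos[i + 1L] - 1L
      len <- b - a + 1L
      nr <- min(ramp_samples, len %/% 2L)
      if (nr >= 2L) {
        up <- r[seq_len(nr)]
        mask[a:(a + nr - 1L)] <- mask[a:(a + nr - 1L)] * up
        mask[b:(b - nr + 1L)] <- mask[b:(b - nr + 1L)] * up
      }
    }
  }
  mask
}

#' Generate a synthetic epoched trial set with known coupling
#'
#' Every channel is independent spectrally shaped (1/f) Gaussian noise.
#' In `"chosen"` trials one band-limited driver realization per trial is
#' additively mixed, with coefficient `coupling_strength` relative to the
#' background RMS, into each effect electrode during the effect windows
#' (cosine-ramped at the edges). `"not_chosen"` trials use
#' `coupling_strength_nc` (default: no driver). The shared driver induces
#' generalized synchronization between effect electrodes that the SL
#' estimator detects, so the ground truth of every downstream stage is
#' known by construction.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical `(config, seed)` yield bit-identical
#'   output.
#' @return List with `trialset` (class `trialset`) and `ground_truth`
#'   (class `ground_truth`: data frame of signal-carrying
#'   band/electrode/window triples, plus the per-participant electrode map
#'   when `per_participant_effects`).
#' @export
generate_trialset <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  fs <- config$sampling_rate
  n1s <- round(fs * config$epoch_seconds)
  n_samp <- n1s + config$tail_samples
  windows <- window_grid(fs)
  n_trials <- config$n_participants * config$trials_per_participant
  nch <- config$n_channels
  band <- config$bands[[config$effect_band]]
  filt <- butter_bandpass(band$low, band$high, fs)
  ramp <- round(config$ramp_seconds * fs)
  mask <- effect_mask(n_samp, windows, config$effect_windows, ramp)
  support <- mask > 0

  # electrode sets
  if (config$per_participant_effects) {
    emap <- lapply(seq_len(config$n_participants), function(p) {
      sort(sample.int(nch, config$n_effect_electrodes))
    })
  } else {
    shared <- if (is.null(config$effect_electrodes)) {
      sort(sample.int(nch, config$n_effect_electrodes))
    } else config$effect_electrodes
    emap <- rep(list(shared), config$n_participants)
  }

  labels <- factor(ifelse(stats::rbinom(n_trials, 1L, config$class_balance) == 1L,
                          "chosen", "not_chosen"),
                   levels = c("chosen", "not_chosen"))
  participant <- rep(seq_len(config$n_participants),
                     each = config$trials_per_participant)

  trials <- array(0, c(n_trials, nch, n_samp))
  for (i in seq_len(n_trials)) {
    for (c in seq_len(nch)) {
      trials[i, c, ] <- config$amplitude_uv *
        one_over_f_noise(n_samp, config$noise_exponent)
    }
    band_noise <- function() {
      drv <- sos_filtfilt(filt, stats::rnorm(n_samp))
      drv / sqrt(mean(drv^2))
    }
    if (config$matched_power) {
      if (config$coupling_strength > 0) {
        amp <- config$coupling_strength * config$amplitude_uv
        shared <- if (labels[i] == "chosen") band_noise() else NULL
        for (e in emap[[participant[i]]]) {
          own <- band_noise()
          drv <- if (is.null(shared)) own
                 else mask * shared + sqrt(1 - mask^2) * own
          trials[i, e, ] <- trials[i, e, ] + amp * drv
        }
      }
    } else {
      kappa <- if (labels[i] == "chosen") config$coupling_strength
               else config$coupling_strength_nc
      if (kappa > 0) {
        drv <- band_noise() * mask          # one realization, shared
        rms <- sqrt(mean(drv[support]^2))
        if (rms > 0) drv <- drv / rms
        for (e in emap[[participant[i]]]) {
          trials[i, e, ] <- trials[i, e, ] +
            kappa * config$amplitude_uv * drv
        }
      }
    }
  }

  ts <- new_trialset(trials, labels, participant, fs, windows,
                     face = "F2", n_analysis = n1s)

  band_i <- match(config$effect_band, names(config$bands))
  truth_for <- function(electrodes) {
    expand.grid(band = band_i, electrode = electrodes,
                window = config$effect_windows)
  }
  gt <- if (config$per_participant_effects) {
    triples <- unique(do.call(rbind, lapply(emap, truth_for)))
    structure(list(triples = triples, per_participant_map = emap,
                   effect_band = config$effect_band),
              class = "ground_truth")
  } else {
    structure(list(triples = truth_for(emap[[1L]]), per_participant_map = NULL,
                   effect_band = config$effect_band),
              class = "ground_truth")
  }
  list(trialset = ts, ground_truth = gt)
}

new_trialset <- function(trials, labels, participant, fs, windows,
                         face = "F2", n_analysis = NULL) {
  stopifnot(length(labels) == dim(trials)[1L],
            length(participant) == dim(trials)[1L])
  if (is.null(n_analysis)) n_analysis <- max(windows[, "end"])
  structure(list(trials = trials, labels = labels,
                 participant = participant, face = face, fs = fs,
                 windows = windows, n_analysis = n_analysis),
            class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf(paste0("<trialset: %d trials x %d channels x %d samples @ %g Hz",
                     " (%d analysis + %d tail), %s epochs>\n"),
              d[1L], d[2L], d[3L], x$fs, x$n_analysis, d[3L] - x$n_analysis,
              x$face))
  print(table(x$labels))
  invisible(x)
}

#' Write / read a trial set in the package's plain-text trial format
#'
#' A directory holding `meta.json` (sampling rate, labels, participants,
#' window grid) and `signals.tsv` (one row per trial x channel, samples in
#' columns).
#'
#' @param ts A `trialset`.
#' @param dir Output directory (created if needed).
#' @param ground_truth Optional `ground_truth` written as a JSON sidecar.
#' @return `dir`, invisibly (`write_trialset`); a `trialset`
#'   (`read_trialset`).
#' @export
write_trialset <- function(ts, dir, ground_truth = NULL) {
  stopifnot(inherits(ts, "trialset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ts$trials)
  meta <- list(n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
               fs = ts$fs, labels = as.character(ts$labels),
               participant = ts$participant, face = ts$face,
               n_analysis = ts$n_analysis,
               window_start = ts$windows[, "start"],
               window_end = ts$windows[, "end"])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- matrix(aperm(ts$trials, c(3L, 2L, 1L)), nrow = d[1L] * d[2L],
                 byrow = TRUE)
  utils::write.table(flat, file.path(dir, "signals.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(ground_truth)) {
    jsonlite::write_json(list(triples = ground_truth$triples,
                              per_participant_map = ground_truth$per_participant_map,
                              effect_band = ground_truth$effect_band),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "signals.tsv"),
                                      sep = "\t", header = FALSE))
  trials <- aperm(array(t(flat), c(meta$n_samples, meta$n_channels,
                                   meta$n_trials)), c(3L, 2L, 1L))
  windows <- cbind(start = as.integer(meta$window_start),
                   end = as.integer(meta$window_end))
  new_trialset(trials,
               factor(meta$labels, levels = c("chosen", "not_chosen")),
               as.integer(meta$participant), meta$fs, windows,
               face = meta$face, n_analysis = meta$n_analysis)
}
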