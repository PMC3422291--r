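# Shared fixtures, built once per test run and memoized. All synthetic data
# come from the package's own generator under fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

two_bands <- function() default_bands()[c("alpha", "beta")]
alpha_band <- function() default_bands()["alpha"]

# strong-coupling study condition used across recovery / decoding tests:
# 8 channels, alpha effect at 4 electrodes over windows 3..12 (100-600 ms),
# driver amplitude 4x the background RMS, 200 trials
strong_config <- function() {
  sim_config(n_participants = 1, trials_per_participant = 200,
             n_channels = 8, bands = two_bands(), effect_band = "alpha",
             effect_windows = 3:12, effect_electrodes = c(1, 3, 5, 7),
             coupling_strength = 4)
}

strong_data <- function() memo("strong_data", function() {
  generate_trialset(strong_config(), seed = 42)
})

strong_tensor <- function() memo("strong_tensor", function() {
  compute_feature_tensor(strong_data()$trialset, two_bands())
})

# ground-truth ids as "band electrode window" strings
gt_ids_of <- function(gt) paste(gt$triples$band, gt$triples$electrode,
                                gt$triples$window)
all_ids_of <- function(tensor) {
  idx <- attr(tensor, "feature_index")
  paste(idx$band, idx$electrode, idx$window)
}

# two well-separated Gaussian blobs in 2-D (linearly separable toy set)
blob_data <- function(n_per = 30, sep = 10, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(2 * n_per), ncol = 2),
             matrix(stats::rnorm(2 * n_per, mean = sep), ncol = 2))
  labels <- factor(rep(c("a", "b"), each = n_per))
  list(x = x, labels = labels)
}

# feature matrix with exactly n_signal informative columns (shifted in class
# "chosen") and n_noise pure-noise columns
planted_features <- function(n_trials = 120, n_signal = 3, n_noise = 37,
                             shift = 2, seed = 9) {
  set.seed(seed)
  labels <- factor(rep(c("chosen", "not_chosen"), length.out = n_trials),
                   levels = c("chosen", "not_chosen"))
  x <- matrix(stats::rnorm(n_trials * (n_signal + n_noise)), n_trials)
  x[labels == "chosen", seq_len(n_signal)] <-
    x[labels == "chosen", seq_len(n_signal)] + shift
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = x, labels = labels, signal = seq_len(n_signal))
}

# synthetic event-coded recording for epoching tests: n_trials complete
# trials; odd trials choose face 1 (left response), even choose face 2
synthetic_recording <- function(n_trials = 4, n_channels = 6, fs = 512,
                                seed = 3, gap = 3000) {
  set.seed(seed)
  n <- gap * (n_trials + 1L)
  dat <- matrix(stats::rnorm(n_channels * n, sd = 10), n_channels, n)
  codes <- event_codes()
  ev <- do.call(rbind, lapply(seq_len(n_trials), function(t) {
    s <- t * gap
    data.frame(sample = c(s, s + 800, s + 1100, s + 2200),
               code = c(codes$f1_onset, codes$f1_keypress, codes$f2_onset,
                        if (t %% 2 == 1) codes$resp_left else codes$resp_right))
  }))
  as_recording(dat, fs, events = ev)
}
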