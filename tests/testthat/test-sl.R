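test_that("time-delay embedding follows the definition", {
  E <- embed_delay(1:5, L = 1, m = 3)
  expect_equal(E, rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(nrow(embed_delay(1:6, L = 2, m = 2)), 4)
  Ec <- embed_delay(rep(2, 10), L = 3, m = 3)
  expect_true(all(Ec == 2))
  expect_error(embed_delay(1:5, L = 3, m = 3), "too short")
})

test_that("critical distance is the ceil(p_ref N)-th order statistic", {
  # candidates at distances 1..10 from the anchor along one axis
  anchor <- c(0, 0)
  cands <- cbind(1:10, 0)
  expect_equal(critical_distance(anchor, cands, p_ref = 0.1), 1)
  expect_equal(critical_distance(anchor, cands, p_ref = 0.25), 3)
  # all candidates identical to the anchor
  expect_equal(critical_distance(c(1, 2), matrix(c(1, 2), 10, 2,
                                                 byrow = TRUE)), 0)
  # random case against an exhaustive sort-based oracle
  set.seed(6)
  for (rep in 1:5) {
    cands <- matrix(stats::rnorm(60), 20, 3)
    anchor <- stats::rnorm(3)
    excl <- sample(20, 3)
    got <- critical_distance(anchor, cands, p_ref = 0.2, excluded = excl)
    d <- sqrt(colSums((t(cands[-excl, ]) - anchor)^2))
    k <- ceiling(0.2 * length(d))
    expect_equal(got, sort(d)[k])
  }
  expect_error(critical_distance(c(0, 0), cands[1:5, ], p_ref = 0.1),
               "non-excluded candidates")
})

test_that("SL of a channel with its own copy is 1 at every anchor", {
  set.seed(8)
  x <- stats::rnorm(300)
  E <- embed_delay(x, 5, 4)
  p <- sl_params(theiler = 15)
  for (a in c(1, 50, 150)) {
    expect_equal(sl_at_anchor(a, E, E, p), 1)
    expect_equal(sl_at_anchor(a, E, E, p, symmetric = TRUE), 1)
  }
})

test_that("mean SL between independent white-noise channels converges to p_ref", {
  set.seed(9)
  p <- sl_params(theiler = 15)
  vals <- replicate(150, {
    X <- embed_delay(stats::rnorm(300), 5, 4)
    Y <- embed_delay(stats::rnorm(300), 5, 4)
    sl_at_anchor(sample(280, 1), X, Y, p, symmetric = TRUE)
  })
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.1), 3 * se)
})

test_that("directed SL is nearly symmetric on random inputs", {
  set.seed(10)
  p <- sl_params(theiler = 15)
  asym <- replicate(40, {
    X <- embed_delay(stats::rnorm(300), 5, 4)
    Y <- embed_delay(stats::rnorm(300), 5, 4)
    a <- sample(280, 1)
    abs(sl_at_anchor(a, X, Y, p) - sl_at_anchor(a, Y, X, p))
  })
  expect_lt(mean(asym), 0.05)
})

test_that("default anchors sit at multiples of 25 samples, one per 50 ms window", {
  p <- sl_params()
  a <- tfsldecode:::anchor_positions(p)
  expect_equal(a, seq(0, 475, by = 25))
  expect_length(a, 20)
  amap <- tfsldecode:::anchors_to_windows(a, window_grid(512))
  expect_equal(unlist(amap), 1:20)
})

test_that("reconfigured anchors map to containing windows and average within them", {
  w <- window_grid(512)
  anchors <- seq(0, 503, by = 12)
  amap <- tfsldecode:::anchors_to_windows(anchors, w)
  expect_length(amap, 20)
  expect_true(all(lengths(amap) >= 1))
  expect_equal(sum(lengths(amap)), length(anchors))
  expect_error(tfsldecode:::anchors_to_windows(c(0, 25), w), "no anchor")
})

test_that("pairwise TFSL forms C(n,2) pairs and detects a perfectly coupled pair", {
  set.seed(13)
  n <- 687
  x1 <- stats::rnorm(n)
  trial <- rbind(x1, x1, stats::rnorm(n))   # channels 1,2 identical
  band <- band_spec("broad", 1, 100, 5, 4)
  pw <- tfsl_pairwise(trial, band, sl_params(), fs = 512)
  expect_equal(dim(pw), c(3, 20))
  expect_true(all(pw[1, ] == 1))                  # coupled pair
  base <- mean(pw[2:3, ])
  expect_lt(abs(base - 0.1), 0.03)                # independent pairs near p_ref
})

test_that("optimized SL path equals the brute-force reference bit for bit", {
  set.seed(14)
  band <- band_spec("alpha", 8, 12, 14, 6)
  p <- sl_params(anchor_shift = 10, n_anchors = 5)
  w <- cbind(start = seq(0, 160, 40), end = seq(40, 200, 40))
  for (rep in 1:5) {
    trial <- matrix(stats::rnorm(4 * 200), 4, 200)
    a <- tfsl_pairwise(trial, band, p, fs = 512, windows = w, engine = "cpp")
    b <- tfsl_pairwise(trial, band, p, fs = 512, windows = w,
                       engine = "reference")
    expect_identical(a, b)
  }
  # also at the full default geometry on a filtered epoch
  filt <- butter_bandpass(8, 12, 512)
  trial <- t(sos_filtfilt(filt, matrix(stats::rnorm(687 * 3), 687, 3)))
  expect_identical(
    tfsl_pairwise(trial, band, sl_params(), fs = 512, engine = "cpp"),
    tfsl_pairwise(trial, band, sl_params(), fs = 512, engine = "reference"))
})

test_that("channel aggregation averages the pairs containing each electrode", {
  # all pairwise values equal c -> every electrode value c
  pw <- matrix(0.42, 6, 4)                        # 4 channels, 6 pairs
  expect_true(all(channel_tfsl(pw, 4) == 0.42))
  # hand-computed 3-channel example
  pw3 <- matrix(c(0.9, 0.1, 0.1), 3, 1)           # pairs (12), (13), (23)
  expect_equal(channel_tfsl(pw3, 3)[, 1], c(0.5, 0.5, 0.1))
  expect_error(channel_tfsl(pw3, 4), "pairs")
})

test_that("feature tensor has band x electrode x window features per trial", {
  cfg <- sim_config(n_participants = 1, trials_per_participant = 2,
                    n_channels = 4, bands = two_bands(),
                    effect_band = "alpha", effect_electrodes = c(1, 2),
                    coupling_strength = 1)
  gen <- generate_trialset(cfg, seed = 5)
  ft <- compute_feature_tensor(gen$trialset, two_bands())
  expect_equal(dim(ft), c(2, 2, 4, 20))
  expect_equal(prod(dim(ft)[-1]), 160)
  expect_true(all(ft >= 0 & ft <= 1))
  idx <- attr(ft, "feature_index")
  expect_equal(nrow(idx), 160)
  expect_equal(idx$id[1], "B1E1T1")
  # determinism: same input computed twice gives identical tensors
  ft2 <- compute_feature_tensor(gen$trialset, two_bands())
  expect_identical(ft, ft2)
})

test_that("epochs without the embedding tail are rejected for slow bands", {
  band <- band_spec("delta", 1, 4, 25, 8)         # span 175 samples
  trial <- matrix(stats::rnorm(2 * 512), 2, 512)
  expect_error(tfsl_pairwise(trial, band, sl_params(), fs = 512),
               "anchor|embeddable|short")
})
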