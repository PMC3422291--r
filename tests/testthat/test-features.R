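test_that("F-ratio matches the two-class definition on the worked example", {
  x <- c(0, 2, 4, 6)
  lab <- factor(c("FC", "FC", "FNC", "FNC"))
  expect_equal(f_ratio(x, lab), 4)
  # population between-class variance halves the score, ranks unchanged
  expect_equal(f_ratio(x, lab, between = "population"), 2)
  # identical class distributions give 0
  expect_equal(f_ratio(c(1, 5, 1, 5), factor(c("a", "a", "b", "b"))), 0)
})

test_that("F-ratio equals a brute-force computation from raw definitions", {
  set.seed(15)
  brute <- function(v, g) {
    m <- tapply(v, g, mean); s2 <- tapply(v, g, stats::var)
    mb <- mean(m)
    sum((m - mb)^2) / (2 - 1) / mean(s2)
  }
  lab <- factor(rep(c("a", "b"), times = c(9, 11)))
  x <- matrix(stats::rnorm(20 * 6), 20, 6)
  expect_equal(unname(f_ratio(x, lab)),
               apply(x, 2, brute, g = lab))
})

test_that("F-ratio is shift-invariant and scale-invariant", {
  set.seed(16)
  x <- stats::rnorm(30)
  lab <- factor(rep(c("a", "b"), 15))
  f0 <- f_ratio(x, lab)
  expect_equal(f_ratio(x + 100, lab), f0)
  expect_equal(f_ratio(x * 7.5, lab), f0)
})

test_that("degenerate inputs are handled per contract", {
  lab <- factor(c("a", "a", "b", "b"))
  expect_warning(fr <- f_ratio(c(1, 1, 2, 2), lab), "Inf")
  expect_identical(fr, Inf)
  expect_equal(suppressWarnings(f_ratio(c(1, 1, 1, 1), lab)), 0)
  expect_error(f_ratio(c(1, 2, 3), factor(c("a", "b", "b"))), "fewer than 2")
  expect_error(f_ratio(1:6, factor(rep("a", 6))), "two classes")
})

test_that("ranking orders by descending F-ratio with deterministic tie-breaks", {
  pl <- planted_features()
  tab <- rank_features(pl$x, pl$labels)
  expect_setequal(tab$rank, seq_len(ncol(pl$x)))
  ord <- order(tab$rank)
  expect_true(all(diff(tab$f_ratio[ord]) <= 0))
  # the planted signal features dominate the top ranks
  expect_true(all(pl$signal %in% ord[1:5]))
  # exact ties resolve by feature order, reproducibly
  xx <- cbind(a = c(0, 2, 4, 6), b = c(0, 2, 4, 6))
  tt <- rank_features(xx, factor(c("x", "x", "y", "y")))
  expect_equal(tt$rank, c(1L, 2L))
})

test_that("permuted labels destroy the ranking signal", {
  pl <- planted_features()
  set.seed(17)
  perm <- sample(pl$labels)
  tab <- rank_features(pl$x, perm)
  top5 <- order(tab$rank)[1:5]
  # the planted features hold no privileged position after permutation;
  # their F-ratios fall in the bulk of the permuted distribution
  fr <- f_ratio(pl$x, perm)
  expect_lt(max(fr[pl$signal]), max(fr[-pl$signal]) * 2)
  expect_false(all(pl$signal %in% top5))
})

test_that("cumulative profile grows by one window's features per step", {
  ft <- strong_tensor()
  prof <- fratio_profile(ft, mode = "cumulative", k = 8)
  nb <- dim(ft)[2]; ne <- dim(ft)[3]
  expect_equal(prof$n_features, nb * ne * (1:20))
  expect_equal(prof$time_ms, 50 * (1:20))
  expect_equal(nrow(prof), 20)
})

test_that("top-k mean is non-increasing in k for a fixed ranking", {
  pl <- planted_features()
  fr <- sort(f_ratio(pl$x, pl$labels), decreasing = TRUE)
  means <- cumsum(fr) / seq_along(fr)
  expect_true(all(diff(means) <= 1e-12))
})

test_that("profile averages all features, with warning, when k exceeds availability", {
  cfg <- sim_config(n_participants = 1, trials_per_participant = 20,
                    n_channels = 3, bands = alpha_band(),
                    effect_band = "alpha", effect_electrodes = c(1, 2),
                    coupling_strength = 0)
  ft <- compute_feature_tensor(generate_trialset(cfg, 31)$trialset,
                               alpha_band())
  expect_warning(prof <- fratio_profile(ft, mode = "windowed", k = 300),
                 "fewer than k")
  expect_true(all(prof$n_averaged == 3))
})

test_that("windowed profile localizes an injected effect in time", {
  ft <- strong_tensor()
  prof <- fratio_profile(ft, mode = "windowed", k = 8)
  eff <- strong_config()$effect_windows
  expect_true(which.max(prof$mean_top_k) %in% eff)
  expect_gt(mean(prof$mean_top_k[eff]), 2 * mean(prof$mean_top_k[-eff]))
})

test_that("scalp map localizes the injected electrodes and matches the windowed profile", {
  ft <- strong_tensor()
  eff_w <- strong_config()$effect_windows
  eff_e <- strong_config()$effect_electrodes
  sm <- scalp_map(ft, windows = eff_w)
  expect_length(sm$values, dim(ft)[3])
  expect_setequal(order(sm$values, decreasing = TRUE)[seq_along(eff_e)],
                  eff_e)
  # single-window subset agrees with per-electrode averaging done by hand
  sm1 <- scalp_map(ft, windows = 5)
  idx <- attr(ft, "feature_index")
  keep <- idx$window == 5
  fr <- f_ratio(tensor_to_matrix(ft, windows = 5), attr(ft, "labels"))
  byhand <- tapply(fr, idx$electrode[keep], mean)
  expect_equal(sm1$values, unname(as.numeric(byhand)))
  expect_error(scalp_map(ft, windows = integer(0)), "non-empty")
})

test_that("scalp map is flat on uniform random data", {
  set.seed(18)
  cfg <- sim_config(n_participants = 1, trials_per_participant = 80,
                    n_channels = 6, bands = alpha_band(),
                    effect_band = "alpha", effect_electrodes = c(1, 2),
                    coupling_strength = 0)
  ft <- compute_feature_tensor(generate_trialset(cfg, 41)$trialset,
                               alpha_band())
  sm <- scalp_map(ft, windows = 1:20)
  # flat up to sampling noise: the observed electrode spread must not
  # exceed the spread seen under label permutation (which is pure noise)
  lab <- attr(ft, "labels")
  perm_spread <- replicate(30, {
    v <- scalp_map(ft, labels = sample(lab), windows = 1:20)$values
    diff(range(v))
  })
  expect_lte(diff(range(sm$values)), max(perm_spread))
})
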