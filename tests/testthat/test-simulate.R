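test_that("generation is bit-identical for identical config and seed", {
  cfg <- sim_config(n_participants = 1, trials_per_participant = 4,
                    n_channels = 4, bands = alpha_band(),
                    effect_band = "alpha", effect_electrodes = c(1, 2),
                    coupling_strength = 1)
  a <- generate_trialset(cfg, seed = 7)
  b <- generate_trialset(cfg, seed = 7)
  expect_identical(a$trialset$trials, b$trialset$trials)
  expect_identical(a$trialset$labels, b$trialset$labels)
  expect_identical(a$ground_truth$triples, b$ground_truth$triples)
  c <- generate_trialset(cfg, seed = 8)
  expect_false(identical(a$trialset$trials, c$trialset$trials))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(effect_windows = c(1, 21)), "subset of 1..20")
  expect_error(sim_config(n_channels = 8, effect_electrodes = c(1, 9)),
               "subset of 1..8")
  expect_error(sim_config(coupling_strength = -1), ">= 0")
  expect_error(sim_config(class_balance = 1), "strictly between")
  expect_error(sim_config(effect_band = "mu"), "not one of")
})

test_that("realized class balance falls in the binomial 99% interval", {
  cfg <- sim_config(n_participants = 1, trials_per_participant = 400,
                    n_channels = 2, bands = alpha_band(),
                    effect_band = "alpha", effect_electrodes = 1:2,
                    coupling_strength = 0, class_balance = 0.5)
  gen <- generate_trialset(cfg, seed = 3)
  n_chosen <- sum(gen$trialset$labels == "chosen")
  ci <- stats::qbinom(c(0.005, 0.995), 400, 0.5)
  expect_gte(n_chosen, ci[1])
  expect_lte(n_chosen, ci[2])
})

test_that("epochs carry the embedding tail beyond the analysis second", {
  cfg <- sim_config(n_participants = 1, trials_per_participant = 2,
                    n_channels = 2, effect_electrodes = 1:2)
  gen <- generate_trialset(cfg, seed = 1)
  expect_equal(dim(gen$trialset$trials)[3],
               512 + embedding_tail(default_bands()))
  expect_equal(gen$trialset$n_analysis, 512)
})

test_that("with no coupling the two classes' TFSL features are indistinguishable", {
  cfg <- sim_config(n_participants = 1, trials_per_participant = 200,
                    n_channels = 3, bands = alpha_band(),
                    effect_band = "alpha", effect_electrodes = c(1, 2),
                    effect_windows = 5:8, coupling_strength = 0)
  gen <- generate_trialset(cfg, seed = 19)
  ft <- compute_feature_tensor(gen$trialset, alpha_band())
  lab <- attr(ft, "labels")
  # two-sample test on every ground-truth feature at alpha = 0.01
  gt <- gen$ground_truth$triples
  pvals <- vapply(seq_len(nrow(gt)), function(i) {
    v <- ft[, gt$band[i], gt$electrode[i], gt$window[i]]
    stats::t.test(v[lab == "chosen"], v[lab == "not_chosen"])$p.value
  }, numeric(1))
  # at alpha = 0.01 over 8 features, any rejection is rare under the null;
  # require the minimum p above the Bonferroni-corrected threshold
  expect_gt(min(pvals), 0.01 / length(pvals))
})

test_that("strong coupling raises mean TFSL on ground-truth triples for the chosen class", {
  ft <- strong_tensor()
  gt <- strong_data()$ground_truth
  lab <- attr(ft, "labels")
  diffs <- vapply(seq_len(nrow(gt$triples)), function(i) {
    v <- ft[, gt$triples$band[i], gt$triples$electrode[i],
            gt$triples$window[i]]
    mean(v[lab == "chosen"]) - mean(v[lab == "not_chosen"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)      # nearly every truth triple elevated
})

test_that("class contrast is localized: non-ground-truth triples show no mean difference", {
  # 500 trials, small montage; off-truth class differences must vanish
  cfg <- sim_config(n_participants = 1, trials_per_participant = 500,
                    n_channels = 4, bands = alpha_band(),
                    effect_band = "alpha", effect_electrodes = c(1, 2),
                    effect_windows = 5:10, coupling_strength = 4)
  gen <- generate_trialset(cfg, seed = 23)
  ft <- compute_feature_tensor(gen$trialset, alpha_band())
  lab <- attr(ft, "labels")
  mat <- tensor_to_matrix(ft)
  idx <- attr(ft, "feature_index")
  on_truth <- all_ids_of(ft) %in% gt_ids_of(gen$ground_truth)
  # embedded vectors span (m-1)L samples (~3 windows), so windows adjacent
  # to the effect span on effect electrodes legitimately carry bleed;
  # exclude that halo from the null set
  halo <- idx$electrode %in% c(1, 2) & idx$window %in% 2:13 & !on_truth
  d <- colMeans(mat[lab == "chosen", ]) - colMeans(mat[lab == "not_chosen", ])
  null_d <- d[!on_truth & !halo]
  # pooled mean off-truth difference within 3 standard errors of zero
  se <- stats::sd(null_d) / sqrt(length(null_d))
  expect_lt(abs(mean(null_d)), 3 * se)
  # and clearly smaller than the on-truth contrast
  p <- stats::t.test(d[on_truth], null_d, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("per-participant effect maps give each participant its own electrode set", {
  cfg <- sim_config(n_participants = 4, trials_per_participant = 2,
                    n_channels = 16, bands = alpha_band(),
                    effect_band = "alpha", n_effect_electrodes = 3,
                    per_participant_effects = TRUE, coupling_strength = 1)
  gen <- generate_trialset(cfg, seed = 2)
  emap <- gen$ground_truth$per_participant_map
  expect_length(emap, 4)
  expect_true(all(lengths(emap) == 3))
  expect_gt(length(unique(lapply(emap, paste, collapse = ","))), 1)
})

test_that("trialsets round-trip through the plain-text trial format", {
  cfg <- sim_config(n_participants = 2, trials_per_participant = 3,
                    n_channels = 3, bands = alpha_band(),
                    effect_band = "alpha", effect_electrodes = c(1, 2),
                    coupling_strength = 1)
  gen <- generate_trialset(cfg, seed = 4)
  d <- withr::local_tempdir()
  write_trialset(gen$trialset, d, ground_truth = gen$ground_truth)
  ts2 <- read_trialset(d)
  expect_equal(ts2$trials, gen$trialset$trials, tolerance = 1e-12)
  expect_identical(ts2$labels, gen$trialset$labels)
  expect_identical(ts2$participant, as.integer(gen$trialset$participant))
  expect_identical(ts2$windows, gen$trialset$windows)
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(gt$triples), nrow(gen$ground_truth$triples))
})
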