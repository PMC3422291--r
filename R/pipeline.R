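#' Sequential forward selection over F-ratio-ranked features
#'
#' Makes one stratified train/validation/test split, ranks all features by
#' F-ratio on the training partition only, then adds features in rank order,
#' retraining the network after each addition. Selection stops once the
#' score fails to improve for `patience` consecutive additions (or at
#' `max_features`) and the best-scoring prefix is returned. By default the
#' score driving selection is validation accuracy; `score_on = "test"`
#' reproduces the protocol that scores selection on the test partition
#' directly (optimistically biased, retained for comparability).
#'
#' @param x A `feature_tensor` or trials x features matrix.
#' @param labels Two-level factor; taken from the tensor when omitted.
#' @param config [ann_config()].
#' @param patience Consecutive non-improving additions tolerated before
#'   stopping (default 1: stop at the first non-improvement). Use `Inf`
#'   with `max_features = ncol(x)` for an exhaustive trajectory.
#' @param max_features Cap on the number of additions tried (default 25).
#' @param split Train/validation/test fractions.
#' @param score_on `"validation"` (default) or `"test"`.
#' @param seed Seed for the split and weight initializations.
#' @param windows Optional window subset to restrict the tensor to.
#' @return An `sfs_result`: `trajectory` (score after each addition),
#'   `selected` (column indices of the best prefix, in rank order),
#'   `n_selected`, `test_accuracy` of the selected model, `ranking`.
#' @export
sfs_select <- function(x, labels = NULL, config = ann_config(),
                       patience = 1L, max_features = 25L,
                       split = c(0.6, 0.2, 0.2),
                       score_on = c("validation", "test"), seed = 1L,
                       windows = NULL) {
  score_on <- match.arg(score_on)
  fm <- feature_matrix_of(x, labels, windows = windows)
  mat <- fm$mat; labels <- as.factor(fm$labels)
  set.seed(as.integer(seed))
  parts <- stratified_split(labels, c(train = split[1L],
                                      validation = split[2L],
                                      test = split[3L]))
  init_seeds <- sample.int(.Machine$integer.max, max_features + 1L)

  fr <- f_ratio(mat[parts$train, , drop = FALSE], labels[parts$train])
  ord <- fr_order(fr, attr(mat, "feature_index"))

  score_idx <- if (score_on == "validation") parts$validation else parts$test
  trajectory <- numeric(0)
  best <- -Inf; best_k <- 0L; fails <- 0L
  max_features <- min(max_features, ncol(mat))
  for (k in seq_len(max_features)) {
    feats <- ord[seq_len(k)]
    model <- train_ann(mat[parts$train, feats, drop = FALSE],
                       labels[parts$train], config,
                       validation = list(
                         x = mat[parts$validation, feats, drop = FALSE],
                         labels = labels[parts$validation]),
                       init_seed = init_seeds[k])
    sc <- accuracy_pct(predict_ann(model, mat[score_idx, feats, drop = FALSE]),
                       labels[score_idx])
    trajectory <- c(trajectory, sc)
    if (sc > best) {
      best <- sc; best_k <- k; fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= patience) break
    }
  }
  if (best_k == 0L) best_k <- 1L
  feats <- ord[seq_len(best_k)]
  final <- train_ann(mat[parts$train, feats, drop = FALSE],
                     labels[parts$train], config,
                     validation = list(
                       x = mat[parts$validation, feats, drop = FALSE],
                       labels = labels[parts$validation]),
                     init_seed = init_seeds[max_features + 1L])
  test_acc <- accuracy_pct(predict_ann(final,
                                       mat[parts$test, feats, drop = FALSE]),
                           labels[parts$test])
  structure(list(trajectory = trajectory, selected = feats,
                 n_selected = best_k, score = best, score_on = score_on,
                 test_accuracy = test_acc, ranking = ord),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("<sfs_result: %d feature(s) selected, %s score %.1f%%, test accuracy %.1f%%>\n",
              x$n_selected, x$score_on, x$score, x$test_accuracy))
  invisible(x)
}

#' Evaluate a model scope: pooled (CGM) or per participant (PAM)
#'
#' CGM (combined global model) pools all trials into one classifier and
#' repeats the full SFS + evaluation cycle `n_reps` times (SD across
#' repetitions). PAM (personalized average model) runs the same cycle
#' separately per participant and summarizes the per-participant mean
#' accuracies (SD across participants).
#'
#' @param x A `feature_tensor` (labels and participants taken from its
#'   attributes unless supplied).
#' @param scope `"CGM"` or `"PAM"`.
#' @param labels,participants Override the tensor attributes.
#' @param config [ann_config()].
#' @param n_reps Repetitions of the split + SFS + test cycle.
#' @param seed Master seed.
#' @param min_per_class Minimum trials per class for a participant to enter
#'   the PAM loop; smaller participants are skipped with a warning.
#' @param ... Passed to [sfs_select()] (`patience`, `max_features`,
#'   `score_on`, `windows`, `split`).
#' @return A `run_report`: `scope`, `eval` (an `eval_result`),
#'   `per_participant` (PAM: data frame of participant means),
#'   `n_selected` (median selected feature counts), `seed`.
#' @export
run_scope <- function(x, scope = c("CGM", "PAM"), labels = NULL,
                      participants = NULL, config = ann_config(),
                      n_reps = 10L, seed = 1L, min_per_class = 5L, ...) {
  scope <- match.arg(scope)
  fm <- feature_matrix_of(x, labels)
  mat <- fm$mat; labels <- as.factor(fm$labels)
  if (is.null(participants)) participants <- attr(x, "participant")
  if (is.null(participants)) participants <- rep(1L, nrow(mat))
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)

  run_reps <- function(rows) {
    res <- lapply(seq_len(n_reps), function(r) {
      m <- mat[rows, , drop = FALSE]
      attr(m, "feature_index") <- attr(mat, "feature_index")
      sfs_select(m, labels[rows], config = config,
                 seed = rep_seeds[r], ...)
    })
    list(acc = vapply(res, `[[`, numeric(1), "test_accuracy"),
         n_sel = vapply(res, `[[`, numeric(1), "n_selected"))
  }

  if (scope == "CGM") {
    out <- run_reps(seq_len(nrow(mat)))
    report <- list(scope = scope,
                   eval = eval_result(out$acc, sprintf("CGM x%d", n_reps)),
                   per_participant = NULL,
                   n_selected = stats::median(out$n_sel), seed = seed)
  } else {
    ids <- sort(unique(participants))
    rows_ok <- list(); means <- numeric(0); kept <- integer(0)
    nsel <- numeric(0)
    for (p in ids) {
      rows <- which(participants == p)
      if (any(table(factor(labels[rows])) < min_per_class)) {
        warning("participant ", p, " skipped: fewer than ", min_per_class,
                " trials in a class")
        next
      }
      out <- run_reps(rows)
      means <- c(means, mean(out$acc))
      nsel <- c(nsel, stats::median(out$n_sel))
      kept <- c(kept, p)
    }
    if (length(kept) == 0L) stop("no participant has enough trials per class")
    report <- list(scope = scope,
                   eval = eval_result(means, sprintf("PAM x%d", n_reps)),
                   per_participant = data.frame(participant = kept,
                                                accuracy = means,
                                                n_selected = nsel),
                   n_selected = stats::median(nsel), seed = seed)
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report [%s]: accuracy %.1f%% +/- %.2f%%, median %g features>\n",
              x$scope, x$eval$accuracy_mean, x$eval$accuracy_sd,
              x$n_selected))
  invisible(x)
}

#' Temporal decoding profile over cumulative windows
#'
#' For each step `k'` the full selection + evaluation cycle is re-run using
#' only the features of windows `1..k'`, tracing how decodable the classes
#' are as post-onset information accumulates.
#'
#' @param x A `feature_tensor`.
#' @param scope `"CGM"` or `"PAM"`.
#' @param labels,participants,config,n_reps,seed As in [run_scope()].
#' @param ... Passed on to [run_scope()] / [sfs_select()].
#' @return Data frame: `step`, `time_ms`, `accuracy_mean`, `accuracy_sd`.
#' @export
temporal_decoding_profile <- function(x, scope = "CGM", labels = NULL,
                                      participants = NULL,
                                      config = ann_config(), n_reps = 3L,
                                      seed = 1L, ...) {
  stopifnot(inherits(x, "feature_tensor"))
  nw <- dim(x)[4L]
  rows <- lapply(seq_len(nw), function(kp) {
    rep <- run_scope(x, scope, labels = labels, participants = participants,
                     config = config, n_reps = n_reps, seed = seed,
                     windows = seq_len(kp), ...)
    data.frame(step = kp, time_ms = kp * 50,
               accuracy_mean = rep$eval$accuracy_mean,
               accuracy_sd = rep$eval$accuracy_sd)
  })
  do.call(rbind, rows)
}

#' Quasi-randomization empirical chance level
#'
#' Estimates the classifier's real chance level: in each run a stratified
#' split is made, the labels of a uniformly random half of the *training*
#' trials are flipped (destroying the label-feature association while
#' keeping the feature distribution and class ratio intact), features are
#' ranked on the flipped training labels, the network is trained, and the
#' untouched test partition is scored. The mean over runs estimates chance.
#' The flip covers the whole training side of the split (training and
#' validation partitions alike), so early stopping cannot re-align the
#' network with the true labels.
#'
#' @param x A `feature_tensor` or feature matrix.
#' @param labels Two-level factor; taken from the tensor when omitted.
#' @param config [ann_config()].
#' @param n_runs Number of randomization runs (default 10).
#' @param split Train/validation/test fractions.
#' @param top_n Number of top-ranked (on the flipped labels) features fed to
#'   the network (default 10).
#' @param flip_fraction Fraction of training labels flipped (default 0.5;
#'   1 inverts all training labels).
#' @param seed Master seed.
#' @return An `eval_result` with protocol `"quasi_random_chance"`.
#' @export
quasi_random_chance <- function(x, labels = NULL, config = ann_config(),
                                n_runs = 10L, split = c(0.6, 0.2, 0.2),
                                top_n = 10L, flip_fraction = 0.5,
                                seed = 1L) {
  fm <- feature_matrix_of(x, labels)
  mat <- fm$mat; labels <- as.factor(fm$labels)
  lv <- levels(labels)
  stopifnot(length(lv) == 2L)
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  acc <- vapply(seq_len(n_runs), function(r) {
    set.seed(run_seeds[r])
    parts <- stratified_split(labels, c(train = split[1L],
                                        validation = split[2L],
                                        test = split[3L]))
    flip_one <- function(lab_vec, frac) {
      n_flip <- floor(frac * length(lab_vec))
      at <- sample(seq_along(lab_vec), n_flip)
      lab_vec[at] <- factor(ifelse(lab_vec[at] == lv[1L], lv[2L], lv[1L]),
                            levels = lv)
      lab_vec
    }
    tr_labels <- flip_one(labels[parts$train], flip_fraction)
    val_labels <- flip_one(labels[parts$validation], flip_fraction)
    fr <- f_ratio(mat[parts$train, , drop = FALSE], tr_labels)
    ord <- fr_order(fr, attr(mat, "feature_index"))
    feats <- ord[seq_len(min(top_n, ncol(mat)))]
    model <- train_ann(mat[parts$train, feats, drop = FALSE], tr_labels,
                       config,
                       validation = list(
                         x = mat[parts$validation, feats, drop = FALSE],
                         labels = val_labels),
                       init_seed = run_seeds[r])
    accuracy_pct(predict_ann(model, mat[parts$test, feats, drop = FALSE]),
                 labels[parts$test])
  }, numeric(1))
  eval_result(acc, "quasi_random_chance",
              extra = list(flip_fraction = flip_fraction))
}
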