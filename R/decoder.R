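#' Feedforward network configuration
#'
#' A two-layer feedforward network: `n_hidden` tan-sigmoid hidden units and
#' linear output units, trained by Levenberg-Marquardt minimization of the
#' mean squared error against one-hot targets.
#'
#' @param n_hidden Hidden units (default 16).
#' @param n_output Output units: 2 (default, one-hot binary coding) or more
#'   (extra units carry constant-zero targets).
#' @param max_epochs Maximum accepted LM steps (default 100).
#' @param mse_goal Stop once training MSE falls below this (default 1e-5).
#' @param lambda_init,lambda_factor,lambda_max LM damping schedule: start at
#'   `lambda_init`, multiply by `lambda_factor` on a rejected step, divide
#'   on an accepted one, abort when `lambda` exceeds `lambda_max`.
#' @param zscore Standardize inputs with training-set statistics (stored in
#'   the model). SL features are bounded in \[0, 1\] but standardization
#'   conditions the LM normal equations; toggleable.
#' @param val_patience Consecutive validation-MSE increases tolerated before
#'   early stopping (when a validation set is given); the best-validation
#'   weights are restored.
#' @return An `ann_config` object.
#' @export
ann_config <- function(n_hidden = 16L, n_output = 2L, max_epochs = 100L,
                       mse_goal = 1e-5, lambda_init = 1e-3,
                       lambda_factor = 10, lambda_max = 1e10,
                       zscore = TRUE, val_patience = 6L) {
  if (n_hidden < 1L) stop("n_hidden must be >= 1")
  if (n_output < 2L) stop("n_output must be >= 2")
  if (mse_goal <= 0) stop("mse_goal must be > 0")
  structure(list(n_hidden = as.integer(n_hidden),
                 n_output = as.integer(n_output),
                 max_epochs = as.integer(max_epochs), mse_goal = mse_goal,
                 lambda_init = lambda_init, lambda_factor = lambda_factor,
                 lambda_max = lambda_max, zscore = isTRUE(zscore),
                 val_patience = as.integer(val_patience)),
            class = "ann_config")
}

ann_forward <- function(W1, b1, W2, b2, X) {
  H <- tanh(sweep(X %*% t(W1), 2L, b1, `+`))
  O <- sweep(H %*% t(W2), 2L, b2, `+`)
  list(H = H, O = O)
}

one_hot <- function(labels, n_output) {
  labels <- as.factor(labels)
  K <- nlevels(labels)
  if (n_output < K) stop("n_output (", n_output, ") < number of classes (", K, ")")
  T <- matrix(0, length(labels), n_output)
  T[cbind(seq_along(labels), as.integer(labels))] <- 1
  T
}

#' Train the feedforward network
#'
#' Inputs are z-scored with training-set statistics (stored in the model),
#' targets are one-hot, and the squared error is minimized by
#' Levenberg-Marquardt with an analytic Jacobian. Training stops at the MSE
#' goal, the epoch cap, damping overflow, or (with a validation set)
#' sustained validation-MSE increase, restoring the best-validation
#' weights. Deterministic given `init_seed`.
#'
#' @param x Trials x features numeric matrix.
#' @param labels Factor of class labels (2 levels).
#' @param config [ann_config()].
#' @param validation Optional list with elements `x` and `labels` used for
#'   early stopping.
#' @param init_seed Seed for the uniform `±1/sqrt(fan_in)` weight
#'   initialization.
#' @return A `trained_ann`: weights, z-scoring statistics, class levels,
#'   and the per-epoch training (and validation) MSE trace.
#' @export
train_ann <- function(x, labels, config = ann_config(), validation = NULL,
                      init_seed = 1L) {
  stopifnot(is.matrix(x))
  if (any(!is.finite(x))) stop("features contain non-finite values")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training set contains a single class")
  }
  n <- nrow(x); d <- ncol(x)
  h <- config$n_hidden; K <- config$n_output

  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  if (!config$zscore) { mu[] <- 0; sdev[] <- 1 }
  X <- sweep(sweep(x, 2L, mu), 2L, sdev, `/`)
  T <- one_hot(labels, K)

  set.seed(as.integer(init_seed))
  W1 <- matrix(stats::runif(h * d, -1, 1) / sqrt(d + 1), h, d)
  b1 <- stats::runif(h, -1, 1) / sqrt(d + 1)
  W2 <- matrix(stats::runif(K * h, -1, 1) / sqrt(h + 1), K, h)
  b2 <- stats::runif(K, -1, 1) / sqrt(h + 1)

  val <- NULL
  if (!is.null(validation)) {
    Xv <- sweep(sweep(validation$x, 2L, mu), 2L, sdev, `/`)
    Tv <- one_hot(factor(validation$labels, levels = levels(labels)), K)
    val <- list(X = Xv, T = Tv)
  }

  mse_of <- function(W1, b1, W2, b2, X, T) {
    E <- ann_forward(W1, b1, W2, b2, X)$O - T
    mean(E^2)
  }

  n_par <- h * d + h + K * h + K
  unpack <- function(th) {
    list(W1 = matrix(th[seq_len(h * d)], h, d),
         b1 = th[h * d + seq_len(h)],
         W2 = matrix(th[h * d + h + seq_len(K * h)], K, h),
         b2 = th[h * d + h + K * h + seq_len(K)])
  }
  pack <- function(W1, b1, W2, b2) c(as.vector(W1), b1, as.vector(W2), b2)

  theta <- pack(W1, b1, W2, b2)
  lambda <- config$lambda_init
  fwd <- ann_forward(W1, b1, W2, b2, X)
  mse <- mean((fwd$O - T)^2)
  trace <- numeric(0)
  val_trace <- numeric(0)
  best_val <- Inf; best_theta <- theta; val_fail <- 0L
  stop_reason <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    H <- fwd$H
    E <- fwd$O - T
    e <- as.vector(E)                       # residuals, sample-major per output
    # Jacobian of residuals w.r.t. packed parameters
    J <- matrix(0, n * K, n_par)
    G <- 1 - H^2                            # tanh'
    for (j in seq_len(h)) {
      GX <- X * G[, j]
      for (k in seq_len(K)) {
        rows <- (k - 1L) * n + seq_len(n)
        J[rows, (seq_len(d) - 1L) * h + j] <- W2[k, j] * GX     # W1[j, ]
        J[rows, h * d + j] <- W2[k, j] * G[, j]                 # b1[j]
        J[rows, h * d + h + (j - 1L) * K + k] <- H[, j]         # W2[k, j]
      }
    }
    for (k in seq_len(K)) {
      J[(k - 1L) * n + seq_len(n), h * d + h + K * h + k] <- 1  # b2[k]
    }
    JtJ <- crossprod(J)
    Jte <- crossprod(J, e)

    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(solve(JtJ + diag(lambda, n_par), -Jte),
                       error = function(err) NULL)
      if (!is.null(step)) {
        cand <- theta + as.vector(step)
        w <- unpack(cand)
        cand_mse <- mse_of(w$W1, w$b1, w$W2, w$b2, X, T)
        if (is.finite(cand_mse) && cand_mse < mse) {
          theta <- cand
          W1 <- w$W1; b1 <- w$b1; W2 <- w$W2; b2 <- w$b2
          mse <- cand_mse
          lambda <- lambda / config$lambda_factor
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * config$lambda_factor
      if (lambda > config$lambda_max) break
    }
    if (!accepted) { stop_reason <- "damping_overflow"; break }

    fwd <- ann_forward(W1, b1, W2, b2, X)
    trace <- c(trace, mse)
    if (!is.null(val)) {
      vm <- mse_of(W1, b1, W2, b2, val$X, val$T)
      val_trace <- c(val_trace, vm)
      if (vm < best_val) {
        best_val <- vm; best_theta <- theta; val_fail <- 0L
      } else {
        val_fail <- val_fail + 1L
        if (val_fail >= config$val_patience) {
          stop_reason <- "early_stopping"
          break
        }
      }
    } else {
      best_theta <- theta
    }
    if (mse <= config$mse_goal) { stop_reason <- "mse_goal"; break }
  }

  if (!is.null(val)) theta <- best_theta
  w <- unpack(theta)
  structure(list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                 mu = mu, sd = sdev, levels = levels(labels),
                 config = config, trace = trace, val_trace = val_trace,
                 stop_reason = stop_reason),
            class = "trained_ann")
}

#' Predict classes with a trained network
#'
#' The predicted class is the argmax over the output units mapped to the
#' training class levels; exact ties resolve to the first class.
#'
#' @param model A `trained_ann`.
#' @param x Trials x features matrix with the training dimensionality.
#' @param type `"class"` (factor) or `"score"` (raw output matrix).
#' @return Factor of predicted labels, or the score matrix.
#' @export
predict_ann <- function(model, x, type = c("class", "score")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "trained_ann"))
  if (!is.matrix(x)) x <- matrix(x, ncol = length(model$mu))
  if (ncol(x) != ncol(model$W1)) {
    stop("feature dimension mismatch: model expects ", ncol(model$W1),
         ", got ", ncol(x))
  }
  X <- sweep(sweep(x, 2L, model$mu), 2L, model$sd, `/`)
  O <- ann_forward(model$W1, model$b1, model$W2, model$b2, X)$O
  if (type == "score") return(O)
  Kc <- length(model$levels)
  cls <- max.col(O[, seq_len(Kc), drop = FALSE], ties.method = "first")
  factor(model$levels[cls], levels = model$levels)
}

#' @export
print.trained_ann <- function(x, ...) {
  cat(sprintf("<trained_ann: %d-%d-%d, %d epochs, final MSE %.3g (%s)>\n",
              ncol(x$W1), nrow(x$W1), nrow(x$W2), length(x$trace),
              if (length(x$trace)) x$trace[length(x$trace)] else NA,
              x$stop_reason))
  invisible(x)
}

# stratified index split; fractions sum to 1, each named part gets at least
# one trial per class or an informative error
stratified_split <- function(labels, fractions = c(train = 0.6,
                                                   validation = 0.2,
                                                   test = 0.2)) {
  labels <- as.factor(labels)
  parts <- lapply(seq_along(fractions), function(i) integer(0))
  names(parts) <- names(fractions)
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    nc <- length(idx)
    counts <- floor(fractions * nc)
    rem <- nc - sum(counts)
    if (rem > 0L) {
      bump <- order(fractions * nc - counts, decreasing = TRUE)[seq_len(rem)]
      counts[bump] <- counts[bump] + 1L
    }
    if (any(counts < 1L)) {
      stop("class '", lv, "' has too few trials (", nc,
           ") to fill every split partition")
    }
    at <- cumsum(c(0L, counts))
    for (i in seq_along(fractions)) {
      parts[[i]] <- c(parts[[i]], idx[(at[i] + 1L):at[i + 1L]])
    }
  }
  parts
}

eval_result <- function(accuracies, protocol, extra = list()) {
  structure(c(list(accuracy_mean = mean(accuracies),
                   accuracy_sd = if (length(accuracies) > 1L)
                                   stats::sd(accuracies) else 0,
                   accuracies = accuracies, protocol = protocol), extra),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result [%s]: accuracy %.1f%% +/- %.2f%% over %d runs>\n",
              x$protocol, x$accuracy_mean, x$accuracy_sd,
              length(x$accuracies)))
  invisible(x)
}

accuracy_pct <- function(pred, truth) 100 * mean(pred == truth)

#' Repeated stratified 60/20/20 evaluation
#'
#' Per repetition: a stratified random split into training (60%),
#' validation (20%, used for early stopping) and test (20%) partitions;
#' the network is trained and the held-out test accuracy recorded. The
#' final accuracy is the mean (with SD) across repetitions.
#'
#' @param x Trials x features matrix.
#' @param labels Two-level factor.
#' @param config [ann_config()].
#' @param n_reps Number of repetitions (default 10).
#' @param split Train/validation/test fractions (default 0.6/0.2/0.2).
#' @param seed Seed controlling splits and weight initializations.
#' @return An `eval_result`.
#' @export
repeated_split_eval <- function(x, labels, config = ann_config(),
                                n_reps = 10L, split = c(0.6, 0.2, 0.2),
                                seed = 1L) {
  stopifnot(is.matrix(x), abs(sum(split) - 1) < 1e-8)
  labels <- as.factor(labels)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  acc <- vapply(seq_len(n_reps), function(r) {
    set.seed(rep_seeds[r])
    parts <- stratified_split(labels, c(train = split[1L],
                                        validation = split[2L],
                                        test = split[3L]))
    model <- train_ann(x[parts$train, , drop = FALSE], labels[parts$train],
                       config,
                       validation = list(x = x[parts$validation, , drop = FALSE],
                                         labels = labels[parts$validation]),
                       init_seed = rep_seeds[r])
    accuracy_pct(predict_ann(model, x[parts$test, , drop = FALSE]),
                 labels[parts$test])
  }, numeric(1))
  eval_result(acc, sprintf("split%d_%d_%d x%d", round(100 * split[1L]),
                           round(100 * split[2L]), round(100 * split[3L]),
                           n_reps))
}

#' Stratified k-fold evaluation
#'
#' @param x Trials x features matrix.
#' @param labels Two-level factor.
#' @param config [ann_config()].
#' @param k Number of folds (5 or 10 typically; `k = n` per class gives
#'   leave-one-out behaviour).
#' @param seed Seed controlling fold assignment and initialization.
#' @return An `eval_result` with per-fold accuracies.
#' @export
kfold_eval <- function(x, labels, config = ann_config(), k = 5L, seed = 1L) {
  stopifnot(is.matrix(x))
  labels <- as.factor(labels)
  if (any(table(labels) < k)) {
    small <- names(which.min(table(labels)))
    stop("class '", small, "' has fewer trials than k = ", k)
  }
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  init_seeds <- sample.int(.Machine$integer.max, k)
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- train_ann(x[tr, , drop = FALSE], labels[tr], config,
                       init_seed = init_seeds[f])
    accuracy_pct(predict_ann(model, x[!tr, , drop = FALSE]), labels[!tr])
  }, numeric(1))
  eval_result(acc, sprintf("kfold%d", k))
}
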