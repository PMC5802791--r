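#' Train the L2-penalized logistic recall classifier
#'
#' Minimizes the objective
#' \deqn{\tfrac12 \|W\|^2 + C \sum_i c_{y_i} \log(1 + e^{-y_i (x_i W + b)})}
#' with labels \eqn{y_i \in \{-1, +1\}} (recalled = +1), an unpenalized
#' intercept and class weights in inverse proportion to class frequency,
#' \eqn{c_k = n / (2 n_k)}, so the classifier learns equally from both
#' classes despite the imbalance between recalled and forgotten words. This
#' is the C-parameterization used by LIBLINEAR-style solvers; the default
#' penalty constant is `C = 2.4e-4`.
#'
#' Optimization is deterministic (BFGS from a zero start with analytic
#' gradients), so retraining on the same rows reproduces the same weights.
#'
#' @param feats a `power_features` object or a numeric matrix.
#' @param labels logical (or 0/1) vector of later-recall outcomes.
#' @param C penalty constant (> 0).
#' @param maxit optimizer iteration cap.
#' @return a `classifier_model`: list with `W`, `b`, `C`, `class_weights`,
#'   `feature_names`, `n_train`.
#' @export
train_classifier <- function(feats, labels, C = 2.4e-4, maxit = 500L) {
  x <- if (inherits(feats, "power_features")) feats$x else as.matrix(feats)
  labels <- as.logical(labels)
  stopifnot(nrow(x) == length(labels), C > 0)
  if (length(unique(labels)) < 2L)
    stop_memloop("training labels contain a single class",
                 class = "memloop_train_error")
  n <- nrow(x)
  p <- ncol(x)
  y <- ifelse(labels, 1, -1)
  cw <- ifelse(labels, n / (2 * sum(labels)), n / (2 * sum(!labels)))

  obj <- function(theta) {
    w <- theta[seq_len(p)]
    b <- theta[p + 1L]
    m <- y * (drop(x %*% w) + b)
    0.5 * sum(w^2) + C * sum(cw * log1p(exp(-m)))
  }
  grad <- function(theta) {
    w <- theta[seq_len(p)]
    b <- theta[p + 1L]
    m <- y * (drop(x %*% w) + b)
    r <- -cw * y * inv_logit(-m)  # d/ds of weighted log-loss
    c(w + C * drop(crossprod(x, r)), C * sum(r))
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  structure(list(W = fit$par[seq_len(p)], b = fit$par[p + 1L], C = C,
                 class_weights = c(forgotten = n / (2 * sum(!labels)),
                                   recalled = n / (2 * sum(labels))),
                 feature_names = colnames(x), n_train = n,
                 objective = fit$value, convergence = fit$convergence),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("classifier_model: %d features, C = %.3g, |W| = %.4g, b = %.4g\n",
              length(x$W), x$C, sqrt(sum(x$W^2)), x$b))
  invisible(x)
}

#' Decode recall probability
#'
#' Computes the decision value `s = x W + b` and the decoded probability
#' `logistic(s)` for each event.
#'
#' @param model a `classifier_model`.
#' @param feats a `power_features` object or matrix with matching columns.
#' @return a data.frame with `score` and `prob` (one row per event).
#' @export
predict_classifier <- function(model, feats) {
  x <- if (inherits(feats, "power_features")) feats$x else as.matrix(feats)
  if (ncol(x) != length(model$W))
    stop_memloop("feature count mismatch: model has %d, data has %d",
                 length(model$W), ncol(x), class = "memloop_shape_error")
  s <- drop(x %*% model$W) + model$b
  data.frame(score = s, prob = inv_logit(s))
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability that
#' a random recalled event scores above a random forgotten event, with ties
#' counting one half.
#'
#' @param scores numeric decision values or probabilities.
#' @param labels logical outcome vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop_memloop("AUC undefined: only one class present",
                 class = "memloop_auc_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated classifier AUC
#'
#' Stratified k-fold cross-validation: the classifier is retrained with the
#' same penalty and class-weight rule on each training split and scores its
#' held-out fold; AUC is computed on the pooled held-out scores. Fold
#' assignment is deterministic (round-robin within class), so the estimate
#' is reproducible.
#'
#' @param feats features (see [train_classifier()]).
#' @param labels logical outcome vector.
#' @param folds number of folds.
#' @param C penalty constant.
#' @return held-out AUC.
#' @export
cv_auc <- function(feats, labels, folds = 5L, C = 2.4e-4) {
  x <- if (inherits(feats, "power_features")) feats$x else as.matrix(feats)
  labels <- as.logical(labels)
  fold <- integer(length(labels))
  fold[labels] <- rep_len(seq_len(folds), sum(labels))
  fold[!labels] <- rep_len(seq_len(folds), sum(!labels))
  scores <- numeric(length(labels))
  for (k in seq_len(folds)) {
    tr <- fold != k
    m <- train_classifier(x[tr, , drop = FALSE], labels[tr], C = C)
    scores[!tr] <- predict_classifier(m, x[!tr, , drop = FALSE])$score
  }
  auc_score(scores, labels)
}

#' Permutation test of classifier performance
#'
#' Randomizes the recalled/forgotten labels, retrains the classifier with the
#' same penalty and class-weight rule, and records the cross-validated AUC
#' under the shuffled labels, for `n_perm` iterations; the p-value is
#' `(1 + #{null >= observed}) / (n_perm + 1)`. The observed AUC uses the
#' same cross-validation procedure with the true labels, so chance
#' performance sits at 0.50.
#'
#' @param feats features (see [train_classifier()]).
#' @param labels logical outcome vector.
#' @param n_perm number of label permutations (the study convention is
#'   1,000; tests use smaller values).
#' @param seed integer seed.
#' @param C penalty constant.
#' @param folds cross-validation folds.
#' @return a `permutation_result`: list with `observed_auc`, `null_auc`
#'   (length `n_perm`), `p_value`.
#' @export
permutation_test <- function(feats, labels, n_perm = 1000L, seed = 1L,
                             C = 2.4e-4, folds = 5L) {
  stopifnot(n_perm >= 1L)
  x <- if (inherits(feats, "power_features")) feats$x else as.matrix(feats)
  labels <- as.logical(labels)
  obs <- cv_auc(x, labels, folds = folds, C = C)
  null_auc <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sh <- sample(labels)
    tryCatch(cv_auc(x, sh, folds = folds, C = C), error = function(e)
      stop_memloop("permutation iteration %d failed: %s", i, conditionMessage(e),
                   class = "memloop_perm_error"))
  }, numeric(1)))
  structure(list(observed_auc = obs, null_auc = null_auc,
                 p_value = (1 + sum(null_auc >= obs)) / (n_perm + 1)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: observed AUC %.3f, null mean %.3f (n = %d), p = %.4g\n",
              x$observed_auc, mean(x$null_auc), length(x$null_auc), x$p_value))
  invisible(x)
}

#' Forward-model feature attribution
#'
#' Transforms discriminative classifier weights into an activation pattern
#' `A = Sigma_x W / var(s)`, where `Sigma_x` is the feature covariance matrix
#' over the supplied events and `var(s)` the variance of the
#' logit-transformed classifier outputs (the decision values). Both use the
#' biased (1/n) estimator; the ratio is invariant to that shared choice.
#' `A[j]` measures the strength and direction of the relation between feature
#' `j` and the classification decision.
#'
#' @param model a `classifier_model`.
#' @param feats events over which to attribute (a `power_features` or matrix).
#' @return a `forward_model_map`: list with `A`, `var_logit`, `feature_names`.
#' @export
forward_model <- function(model, feats) {
  x <- if (inherits(feats, "power_features")) feats$x else as.matrix(feats)
  s <- predict_classifier(model, x)$score
  n <- nrow(x)
  v <- sum((s - mean(s))^2) / n
  if (v == 0)
    stop_memloop("decision scores are constant; forward model undefined",
                 class = "memloop_variance_error")
  xc <- sweep(x, 2, colMeans(x))
  # Sigma_x W = (1/n) X_c' (X_c W) without forming the p x p covariance
  A <- drop(crossprod(xc, xc %*% model$W)) / n / v
  structure(list(A = A, var_logit = v,
                 feature_names = colnames(x) %||% model$feature_names),
            class = "forward_model_map")
}

#' Group-level forward-model map
#'
#' Averages per-subject attribution maps within region x frequency cells and
#' attaches a one-sample t statistic per cell (across subjects), mirroring
#' the group summary of classifier feature use.
#'
#' @param maps list of `forward_model_map`s, one per subject.
#' @param layouts list of matching `electrode_layout`s.
#' @param freqs analysis frequency grid.
#' @return data.frame with `region`, `freq`, `mean_A`, `t`, `df`, `p`,
#'   `n_subjects`.
#' @export
forward_model_group <- function(maps, layouts, freqs = morlet_freqs()) {
  stopifnot(length(maps) == length(layouts))
  cell_rows <- list()
  for (i in seq_along(maps)) {
    lay <- layouts[[i]]
    nf <- length(freqs)
    df <- data.frame(
      subject = i,
      region = rep(lay$pairs$region, each = nf),
      freq = rep(freqs, nrow(lay$pairs)),
      A = maps[[i]]$A)
    cell_rows[[i]] <- stats::aggregate(A ~ region + freq, df, mean)
    cell_rows[[i]]$subject <- i
  }
  all <- do.call(rbind, cell_rows)
  out <- do.call(rbind, lapply(split(all, list(all$region, all$freq), drop = TRUE),
    function(d) {
      n <- nrow(d)
      m <- mean(d$A)
      se <- stats::sd(d$A) / sqrt(n)
      tval <- if (n > 1 && se > 0) m / se else NA_real_
      data.frame(region = d$region[1], freq = d$freq[1], mean_A = m,
                 t = tval, df = n - 1,
                 p = if (is.na(tval)) NA_real_ else
                   2 * stats::pt(-abs(tval), n - 1),
                 n_subjects = n)
    }))
  rownames(out) <- NULL
  out[order(out$region, out$freq), ]
}

#' Serialize / restore a classifier model as JSON
#'
#' @param model a `classifier_model`.
#' @param path file path.
#' @return `read_model` returns the restored `classifier_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  obj <- unclass(model)
  obj$format_version <- "1"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format_version <- NULL
  structure(obj, class = "classifier_model")
}
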