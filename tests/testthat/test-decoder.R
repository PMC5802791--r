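test_that("training achieves the separable limit and honors the regularization path", {
  x <- rbind(matrix(rnorm(20, -3, 0.3), 10, 2), matrix(rnorm(20, 3, 0.3), 10, 2))
  y <- rep(c(FALSE, TRUE), each = 10)
  m <- train_classifier(x, y, C = 1e4)
  expect_equal(mean((predict_classifier(m, x)$prob > 0.5) == y), 1)
  norms <- vapply(c(1, 1e-2, 1e-4, 1e-6),
                  function(C) sqrt(sum(train_classifier(x, y, C = C)$W^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_error(train_classifier(x, rep(TRUE, 20)), class = "memloop_train_error")
})

test_that("training matches a generic convex optimizer on the same objective", {
  set.seed(21)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c(TRUE, FALSE), 10)
  C <- 0.5
  m <- train_classifier(x, y, C = C)
  # independent route: derivative-free Nelder-Mead on the written-out loss
  yy <- ifelse(y, 1, -1)
  cw <- ifelse(y, 20 / (2 * 10), 20 / (2 * 10))
  f <- function(th) {
    marg <- yy * (drop(x %*% th[1:2]) + th[3])
    0.5 * sum(th[1:2]^2) + C * sum(cw * log1p(exp(-marg)))
  }
  o <- optim(c(0, 0, 0), f, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-14))
  expect_lt(max(abs(c(m$W, m$b) - o$par)) / max(abs(o$par)), 1e-4)
})

test_that("training is invariant to event order", {
  fx <- feat_fixture(n_events = 120, seed = 5)
  m1 <- train_classifier(fx$zfeats$x, fx$events$recalled)
  perm <- sample(nrow(fx$zfeats$x))
  m2 <- train_classifier(fx$zfeats$x[perm, ], fx$events$recalled[perm])
  expect_lt(max(abs(m1$W - m2$W)), 1e-6)
})

test_that("prediction implements the logistic decision rule", {
  m <- structure(list(W = c(0, 0, 0), b = 0, feature_names = NULL),
                 class = "classifier_model")
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(predict_classifier(m, x)$prob, rep(0.5, 10))
  m2 <- structure(list(W = c(0.4, -1.2, 2), b = 0.3, feature_names = NULL),
                  class = "classifier_model")
  m2neg <- m2
  m2neg$W <- -m2$W
  expect_equal(predict_classifier(m2, x)$prob,
               predict_classifier(m2neg, -x)$prob)
  xr <- matrix(c(1, 2, -1), 1)
  expect_equal(predict_classifier(m2, xr)$prob,
               plogis(1 * 0.4 + 2 * -1.2 + -1 * 2 + 0.3), tolerance = 1e-12)
  expect_error(predict_classifier(m2, matrix(0, 2, 5)),
               class = "memloop_shape_error")
})

test_that("AUC equals the exhaustive pairwise oracle, with ties at one half", {
  brute <- function(s, y) {
    pos <- s[y]
    neg <- s[!y]
    g <- outer(pos, neg, ">")
    t <- outer(pos, neg, "==")
    (sum(g) + 0.5 * sum(t)) / (length(pos) * length(neg))
  }
  expect_equal(auc_score(1:10, rep(c(FALSE, TRUE), each = 5)), 1)
  s <- c(1, 2, 2, 3, 3, 3)
  y <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(auc_score(s, y), brute(s, y))
  set.seed(8)
  for (i in 1:10) {
    n <- sample(10:100, 1)
    s <- sample(1:20, n, replace = TRUE)  # heavy ties
    y <- runif(n) < 0.4
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(s, y), brute(s, y))
  }
  expect_error(auc_score(1:5, rep(TRUE, 5)), class = "memloop_auc_error")
  set.seed(9)
  s <- rnorm(2000)
  y <- runif(2000) < 0.3
  se <- sqrt((1 / 12) * (1 / sum(y) + 1 / sum(!y)))  # null AUC SE approx
  expect_lt(abs(auc_score(s, y) - 0.5), 3 * se)
})

test_that("permutation p-value hits its floor on a strong-signal fixture", {
  fx <- feat_fixture(n_events = 150, sme = 0.9, seed = 6)
  hf <- fx$zfeats$x[, fx$zfeats$feature_freq >= 7]
  pr <- permutation_test(hf, fx$events$recalled, n_perm = 199, seed = 3)
  expect_equal(pr$p_value, 1 / 200)
  expect_gt(pr$observed_auc, max(pr$null_auc))
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(31)
  x <- matrix(rnorm(60 * 2), 60, 2)
  pvals <- vapply(1:50, function(i) {
    y <- rep(c(TRUE, FALSE), 30)[sample(60)]
    permutation_test(x, y, n_perm = 19, seed = 100 + i)$p_value
  }, numeric(1))
  expect_lte(mean(pvals <= 0.05), 0.16)
})

test_that("forward model equals the covariance-regression oracle", {
  set.seed(12)
  # single feature: s = w x + b implies A = cov(x, s)/var(s) = 1/w
  x1 <- matrix(rnorm(200), 200, 1)
  m1 <- structure(list(W = 2.5, b = 0.4, feature_names = NULL),
                  class = "classifier_model")
  fm1 <- forward_model(m1, x1)
  expect_equal(fm1$A, 1 / 2.5, tolerance = 1e-10)
  # general: A_j equals the regression slope of x_j on the decision score
  x <- matrix(rnorm(300 * 6), 300, 6) %*% matrix(rnorm(36, sd = 0.5), 6, 6)
  m <- structure(list(W = rnorm(6), b = 0.1, feature_names = NULL),
                 class = "classifier_model")
  fm <- forward_model(m, x)
  s <- drop(x %*% m$W) + m$b
  oracle <- apply(x, 2, function(xj) cov(xj, s) / var(s))
  expect_lt(max(abs(fm$A - oracle)) / max(abs(oracle)), 1e-10)
  expect_error(forward_model(m, matrix(1, 5, 6)),
               class = "memloop_variance_error")
})

test_that("group forward-model maps recover the SME sign pattern", {
  cfg <- tiny_cfg(sme_effect = 0.3)
  maps <- list()
  lays <- list()
  for (i in 1:20) {
    lay <- make_layout(cfg, 300 + i)
    sch <- make_schedule(cfg, 400 + i, kind = "record_only")
    ev <- simulate_recall(sch, cfg, seed = 500 + i)
    ev <- ev[1:240, ]
    ft <- normalize_features(simulate_features(ev, cfg, 600 + i, lay),
                             "within_session")
    m <- train_classifier(ft, ev$recalled)
    maps[[i]] <- forward_model(m, ft)
    lays[[i]] <- lay
  }
  g <- forward_model_group(maps, lays)
  hi <- g[g$freq > 70, ]
  lo <- g[g$freq < 10, ]
  expect_gt(mean(hi$mean_A > 0), 0.9)
  expect_gt(mean(lo$mean_A < 0), 0.9)
  # rescaling features (and refitting) preserves the attribution signs
  lay <- lays[[1]]
  sch <- make_schedule(cfg, 401, kind = "record_only")
  ev <- simulate_recall(sch, cfg, seed = 501)[1:240, ]
  ft <- normalize_features(simulate_features(ev, cfg, 601, lay),
                           "within_session")
  f2 <- ft
  f2$x <- 2 * ft$x
  a1 <- forward_model(train_classifier(ft, ev$recalled), ft)$A
  a2 <- forward_model(train_classifier(f2$x, ev$recalled), f2)$A
  expect_equal(sign(a1), sign(a2))
})

test_that("held-out AUC rises with the generating SME", {
  aucs <- vapply(c(0, 0.15, 0.35, 0.7), function(d) {
    fx <- feat_fixture(n_events = 300, sme = d, seed = 77)
    cv_auc(fx$zfeats, fx$events$recalled)
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.03))
  expect_gt(aucs[4], aucs[1] + 0.2)
})

test_that("classifier models round-trip through JSON", {
  fx <- feat_fixture(n_events = 80, seed = 14)
  m <- train_classifier(fx$zfeats, fx$events$recalled)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$W, m$W)
  expect_equal(m2$b, m$b)
  expect_equal(m2$C, m$C)
  expect_equal(unlist(m2$class_weights), unlist(m$class_weights),
               ignore_attr = TRUE)
})
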