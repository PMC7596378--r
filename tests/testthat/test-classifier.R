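# Feature selection, LDA, three-fold testing and AUC.

test_that("Fisher-score selection ranks a perfect feature first and breaks ties low", {
  set.seed(1)
  y <- rep(c(TRUE, FALSE), each = 20)
  X <- matrix(rnorm(40 * 10), 40, 10)
  X[, 7] <- as.numeric(y)   # identical to the label
  expect_equal(select_discriminant_features(X, y, 1), 7L)

  # exact ties: lower index wins
  X2 <- cbind(X[, 7], X[, 7], matrix(rnorm(40 * 3), 40, 3))
  expect_equal(select_discriminant_features(X2, y, 2), c(1L, 2L))

  # zero-variance feature scores 0, never NaN
  X3 <- cbind(const = rep(1, 40), X)
  sel <- select_discriminant_features(X3, y, ncol(X3))
  expect_equal(sel[length(sel)], 1L)

  expect_error(select_discriminant_features(X, rep(TRUE, 40), 2), "classes")
})

test_that("selection matches an exhaustive re-ranking oracle on random labels", {
  set.seed(99)
  X <- matrix(rnorm(200 * 100), 200, 100)
  y <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  k <- 10
  sel <- select_discriminant_features(X, y, k)
  # oracle: score every feature independently with two-sample t-like score
  sc <- vapply(seq_len(ncol(X)), function(j) {
    a <- X[y, j]; b <- X[!y, j]
    abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }, numeric(1))
  expect_equal(sel, order(-sc, seq_along(sc))[seq_len(k)])
})

test_that("LDA weights match a hand-computed small instance", {
  # 3 points per class, 2 features, integer coordinates
  X <- rbind(c(0, 0), c(1, 0), c(0, 1),    # class 0
             c(4, 4), c(5, 4), c(4, 5))    # class 1
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  mod <- lda_fit(X, y)
  mu0 <- colMeans(X[1:3, ]); mu1 <- colMeans(X[4:6, ])
  S <- (crossprod(sweep(X[1:3, ], 2, mu0)) +
          crossprod(sweep(X[4:6, ], 2, mu1))) / 4
  w_hand <- solve(S, mu1 - mu0)
  expect_equal(mod$w, unname(as.numeric(w_hand)), tolerance = 1e-10)

  # widely separated clouds: zero training misclassification
  set.seed(2)
  Xs <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 10), 50, 2))
  ys <- rep(c(FALSE, TRUE), each = 50)
  m2 <- lda_fit(Xs, ys)
  expect_equal(mean(lda_predict(m2, Xs) != ys), 0)
})

test_that("degenerate LDA cases: equal means fall back to the majority prior", {
  set.seed(3)
  X <- matrix(rnorm(60 * 2), 60, 2)
  y <- rep(c(TRUE, FALSE), c(40, 20))
  # force exactly equal class means
  X[y, ] <- sweep(X[y, , drop = FALSE], 2, colMeans(X[y, , drop = FALSE]))
  X[!y, ] <- sweep(X[!y, , drop = FALSE], 2, colMeans(X[!y, , drop = FALSE]))
  mod <- lda_fit(X, y)
  expect_true(all(lda_predict(mod, X)))   # majority class is TRUE

  expect_error(lda_fit(X, rep(TRUE, 60)), "class")

  # singular covariance: ridge applied and flagged
  Xd <- cbind(X[, 1], X[, 1])
  expect_message(md <- lda_fit(Xd, y), "ridge")
  expect_true(md$ridge_applied)
  expect_true(all(is.finite(md$w)))
})

test_that("roc_auc equals brute-force pair counting and is monotone-invariant", {
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  labels <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(roc_auc(scores, labels), auc_oracle(scores, labels))

  expect_equal(roc_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "classes")

  set.seed(4)
  s <- rnorm(50); l <- runif(50) > 0.5
  expect_equal(roc_auc(exp(s), l), roc_auc(s, l))
  # independent implementation cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(roc_auc(s, l),
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("three-fold testing is stratified, deterministic and leak-free", {
  set.seed(5)
  y <- rep(c(TRUE, FALSE), c(24, 36))
  X <- matrix(rnorm(60 * 10), 60, 10)

  cv1 <- three_fold_evaluate(X, y, k_features = 3, seed = 11)
  cv2 <- three_fold_evaluate(X, y, k_features = 3, seed = 11)
  expect_identical(cv1[c("E_pct", "auc_pct")], cv2[c("E_pct", "auc_pct")])

  # per-fold class counts differ by at most one subject
  folds <- cv1$predictions$fold
  for (cls in c(TRUE, FALSE)) {
    counts <- table(folds[y == cls])
    expect_lte(diff(range(counts)), 1)
  }

  # separable features: perfect held-out performance
  Xs <- cbind(X, ifelse(y, 5, -5) + rnorm(60, sd = 0.1))
  cvs <- three_fold_evaluate(Xs, y, k_features = 2, seed = 1)
  expect_equal(cvs$E_pct, 0)
  expect_equal(cvs$auc_pct, 100)

  expect_error(three_fold_evaluate(X[1:8, ], y[1:8], 2, 1), "at least 9")
  expect_error(three_fold_evaluate(X, rep(c(TRUE, FALSE), c(2, 58)), 2, 1),
               "rare")

  # leakage canary: a feature equal to the labels on one held-out fold
  # only (noise everywhere else) must not inflate AUC — with in-fold
  # selection it is never chosen by the models that test on that fold
  fold <- tscqeeg:::stratified_folds(y, 3, 11L)
  set.seed(20)
  aucs <- vapply(1:20, function(s) {
    canary <- rnorm(60)
    canary[fold == 1] <- as.numeric(y[fold == 1])
    Xc <- cbind(matrix(rnorm(60 * 5), 60, 5), canary)
    three_fold_evaluate(Xc, y, k_features = 1, seed = 11)$auc_pct
  }, numeric(1))
  expect_lt(mean(aucs), 65)
})

test_that("per-family report covers the four families plus the combined model", {
  set.seed(6)
  nm <- c(paste0("power.", c("delta1", "delta2", "theta", "alpha", "beta")),
          paste0("reeg_asym.", c("delta1", "delta2", "theta", "alpha", "beta")),
          sprintf("mse.%02d", 1:5), "hurst")
  X <- matrix(rnorm(45 * length(nm)), 45, dimnames = list(NULL, nm))
  y <- rep(c(TRUE, FALSE), c(20, 25))
  rep_tab <- classify_by_family(X, y, k_features = 3, seed = 2)
  expect_setequal(rep_tab$family,
                  c("power", "mse", "reeg_asym", "hurst", "combined"))
  expect_true(all(rep_tab$E_pct >= 0 & rep_tab$E_pct <= 100))
  expect_true(all(rep_tab$auc_pct >= 0 & rep_tab$auc_pct <= 100))
})

test_that("LDA direction agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(7)
  X <- rbind(matrix(rnorm(80, 0), 40, 2), matrix(rnorm(80, 1.5), 40, 2))
  y <- rep(c(FALSE, TRUE), each = 40)
  mod <- lda_fit(X, y)
  ref <- MASS::lda(X, grouping = y)
  w_ref <- as.numeric(ref$scaling)
  # same direction up to positive scale
  cosang <- sum(mod$w * w_ref) / sqrt(sum(mod$w^2) * sum(w_ref^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-8)
})
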