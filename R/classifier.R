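# Binary outcome classification from quantitative EEG features: Fisher-score
# feature selection, linear discriminant analysis, and stratified three-fold
# testing reporting misclassification error E(%) and AUC(%).

#' Rank features by discriminative power
#'
#' Scores each feature by the absolute two-sample standardised mean
#' difference (Fisher criterion)
#' \eqn{|\mu_1 - \mu_0| / \sqrt{(s_1^2 + s_0^2)/2}} and returns the indices
#' of the top `k`. Zero-variance features score 0 (never `NaN`); ties are
#' broken in favour of the lower column index so selection is
#' deterministic. Callers doing cross-validation must invoke this inside
#' each training fold only.
#'
#' @param X numeric matrix, subjects x features.
#' @param y binary labels (logical or 0/1), length `nrow(X)`.
#' @param k number of features to keep.
#' @return integer vector of `k` column indices, best first.
#' @export
select_discriminant_features <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.logical(y)
  if (k > ncol(X)) stop("k exceeds the number of features", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present",
                                  call. = FALSE)
  scores <- fisher_scores(X, y)
  order(-scores, seq_along(scores))[seq_len(k)]
}

fisher_scores <- function(X, y) {
  m1 <- colMeans(X[y, , drop = FALSE])
  m0 <- colMeans(X[!y, , drop = FALSE])
  v1 <- apply(X[y, , drop = FALSE], 2, var)
  v0 <- apply(X[!y, , drop = FALSE], 2, var)
  pooled <- sqrt((v1 + v0) / 2)
  pooled[is.na(pooled)] <- 0
  d <- abs(m1 - m0)
  # zero pooled variance: a constant feature carries no signal (score 0),
  # but a feature constant within each class with distinct means separates
  # perfectly (score Inf, ranked first)
  s <- ifelse(pooled > 0, d / pooled, ifelse(d > 0, Inf, 0))
  s[is.na(s)] <- 0
  s
}

#' Fit a linear discriminant model
#'
#' Two-class LDA from class means and the pooled within-class covariance:
#' discriminant weights \eqn{w = \Sigma^{-1}(\mu_1 - \mu_0)}, score
#' \eqn{s(x) = w^\top x}, and decision threshold
#' \eqn{t = w^\top(\mu_0 + \mu_1)/2 - \log(\pi_1/\pi_0)} (posterior odds
#' 1 under the class priors). A singular pooled covariance is ridge
#' regularised by \eqn{\lambda \mathrm{tr}(\Sigma)/p} (reported in the
#' model and messaged).
#'
#' @param X numeric matrix, subjects x features.
#' @param y binary labels; both classes need at least 2 subjects.
#' @param prior class priors `c(p0, p1)`; default the empirical
#'   proportions.
#' @param ridge ridge fraction used when the covariance is singular.
#' @return object of class `lda_model` with elements `w`, `threshold`,
#'   `means`, `cov`, `prior`, `ridge_applied`.
#' @export
lda_fit <- function(X, y, prior = NULL, ridge = 1e-3) {
  X <- as.matrix(X)
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2 || n0 < 2) {
    stop("each class needs at least 2 subjects", call. = FALSE)
  }
  if (is.null(prior)) prior <- c(n0, n1) / (n0 + n1)
  stopifnot(length(prior) == 2, abs(sum(prior) - 1) < 1e-8)
  mu0 <- colMeans(X[!y, , drop = FALSE])
  mu1 <- colMeans(X[y, , drop = FALSE])
  c0 <- crossprod(sweep(X[!y, , drop = FALSE], 2, mu0))
  c1 <- crossprod(sweep(X[y, , drop = FALSE], 2, mu1))
  S <- (c0 + c1) / (n0 + n1 - 2)
  p <- ncol(X)
  ridge_applied <- FALSE
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) NULL)
  if (is.null(w) || rcond_est(S) < 1e-12) {
    S <- S + diag(ridge * sum(diag(S)) / p + 1e-12, p)
    w <- solve(S, mu1 - mu0)
    ridge_applied <- TRUE
    message("lda_fit: singular pooled covariance; ridge term applied")
  }
  thr <- sum(w * (mu0 + mu1)) / 2 - log(prior[2] / prior[1])
  structure(
    list(w = as.numeric(w), threshold = as.numeric(thr),
         means = rbind(class0 = mu0, class1 = mu1), cov = S,
         prior = prior, ridge_applied = ridge_applied,
         majority = n1 >= n0),
    class = "lda_model"
  )
}

rcond_est <- function(S) {
  if (nrow(S) == 1) return(ifelse(S[1] > 0, 1, 0))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Discriminant scores and class predictions
#'
#' `lda_score()` returns the linear scores \eqn{w^\top x};
#' `lda_predict()` thresholds them. In the degenerate equal-means case all
#' scores coincide up to numerical noise and prediction falls back to the
#' majority-prior class.
#'
#' @param model an `lda_model`.
#' @param X matrix with the same columns the model was fitted on.
#' @return numeric scores / logical predictions.
#' @export
lda_score <- function(model, X) {
  stopifnot(inherits(model, "lda_model"))
  as.numeric(as.matrix(X) %*% model$w)
}

#' @rdname lda_score
#' @export
lda_predict <- function(model, X) {
  s <- lda_score(model, X)
  spread <- diff(range(s))
  if (spread < 1e-10 * (1 + abs(model$threshold))) {
    return(rep(model$prior[2] >= model$prior[1], length(s)))
  }
  s > model$threshold
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: with midranks,
#' \eqn{AUC = (R_1 - n_1(n_1+1)/2) / (n_1 n_0)}, where `R1` is the rank
#' sum of the positive-class scores; tied score pairs count 1/2. Equal to
#' trapezoidal integration of the ROC curve, and invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric classifier scores (larger = more positive).
#' @param labels binary labels.
#' @return proportion in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, n_folds, seed) {
  y <- as.logical(y)
  if (min(sum(y), sum(!y)) < n_folds) {
    stop("a class is too rare to stratify into ", n_folds,
         " folds; use a larger cohort or fewer folds", call. = FALSE)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Three-fold testing of the LDA model
#'
#' Stratified three-fold cross-validation: subjects are partitioned into
#' three folds preserving class balance (per-fold class counts differ by
#' at most one subject); for each fold the most discriminant features are
#' re-selected on the training two-thirds only, the LDA model is fitted on
#' them, and the held-out third is scored. Pooled held-out predictions
#' yield the misclassification error E(\%) and AUC(\%). With
#' `repetitions > 1` the procedure is repeated on fresh partitions and the
#' two figures are averaged.
#'
#' @param X subjects x features matrix.
#' @param y binary outcome.
#' @param k_features number of features selected per training fold.
#' @param seed integer seed for the partition(s).
#' @param n_folds number of folds (default 3).
#' @param repetitions number of repeated partitions (default 1).
#' @param auc per-repetition AUC mode: `"pooled"` (default) over all
#'   held-out scores, or `"per_fold"` averaged across folds.
#' @return object of class `cv_result`: `E_pct`, `auc_pct`, data.frame
#'   `predictions` (subject, fold, score, predicted, observed; first
#'   repetition), `seed`.
#' @export
three_fold_evaluate <- function(X, y, k_features = 5, seed = 1L,
                                n_folds = 3, repetitions = 1,
                                auc = c("pooled", "per_fold")) {
  auc <- match.arg(auc)
  X <- as.matrix(X)
  y <- as.logical(y)
  if (nrow(X) < 9) stop("need at least 9 subjects", call. = FALSE)
  k_features <- min(k_features, ncol(X))
  E_reps <- numeric(repetitions)
  auc_reps <- numeric(repetitions)
  pred_df <- NULL
  for (rep_i in seq_len(repetitions)) {
    fold <- stratified_folds(y, n_folds, seed + (rep_i - 1L) * 1000L)
    scores <- numeric(length(y))
    preds <- logical(length(y))
    auc_folds <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      sel <- select_discriminant_features(X[tr, , drop = FALSE], y[tr],
                                          k_features)
      mod <- lda_fit(X[tr, sel, drop = FALSE], y[tr])
      scores[!tr] <- lda_score(mod, X[!tr, sel, drop = FALSE])
      preds[!tr] <- lda_predict(mod, X[!tr, sel, drop = FALSE])
      auc_folds[f] <- if (length(unique(y[!tr])) == 2) {
        roc_auc(scores[!tr], y[!tr])
      } else {
        NA_real_
      }
    }
    E_reps[rep_i] <- 100 * mean(preds != y)
    auc_reps[rep_i] <- if (auc == "pooled") {
      100 * roc_auc(scores, y)
    } else {
      100 * mean(auc_folds, na.rm = TRUE)
    }
    if (rep_i == 1L) {
      pred_df <- data.frame(
        subject = seq_along(y), fold = fold, score = scores,
        predicted = preds, observed = y
      )
    }
  }
  structure(
    list(E_pct = mean(E_reps), auc_pct = mean(auc_reps),
         predictions = pred_df, seed = seed, repetitions = repetitions),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> E = %.1f%% | AUC = %.1f%% (seed %d, %d rep%s)\n",
              x$E_pct, x$auc_pct, x$seed, x$repetitions,
              if (x$repetitions > 1) "s" else ""))
  invisible(x)
}

#' Per-family classification report
#'
#' Runs [three_fold_evaluate()] separately on each feature family (band
#' power, entropy, rEEG asymmetry, fractality/Hurst) of an aggregated
#' feature matrix, mirroring the per-family layout of a classification
#' results table, plus a combined all-families model.
#'
#' @param X subjects x features matrix with names from
#'   [aggregate_features()].
#' @param y binary outcome.
#' @param k_features,seed,repetitions passed to [three_fold_evaluate()].
#' @return data.frame with columns `family`, `E_pct`, `auc_pct`.
#' @export
classify_by_family <- function(X, y, k_features = 5, seed = 1L,
                               repetitions = 1) {
  fams <- feature_family(colnames(X))
  rows <- lapply(c("power", "mse", "reeg_asym", "hurst"), function(fm) {
    cols <- which(fams == fm)
    if (!length(cols)) return(NULL)
    cv <- three_fold_evaluate(X[, cols, drop = FALSE], y,
                              min(k_features, length(cols)), seed,
                              repetitions = repetitions)
    data.frame(family = fm, E_pct = cv$E_pct, auc_pct = cv$auc_pct)
  })
  all_cv <- three_fold_evaluate(X, y, k_features, seed,
                                repetitions = repetitions)
  rows <- c(rows, list(data.frame(family = "combined", E_pct = all_cv$E_pct,
                                  auc_pct = all_cv$auc_pct)))
  do.call(rbind, rows)
}
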