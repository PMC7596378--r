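# Clinical outcome statistics: ADOS-2 risk categorisation, 2x2 association
# and diagnostic metrics, logistic and linear models, Mann-Whitney tests,
# developmental-quotient transforms and collinearity diagnostics.

#' ADOS-2 risk category
#'
#' Maps an ADOS-2 (Toddler Module) total score to the three risk bands.
#' Non-verbal children: 0-9 no risk, 10-13 mild/moderate risk, above 13
#' high risk. Verbal children: 0-7, 8-11, above 11. Vectorised.
#'
#' @param total_score non-negative integer score(s).
#' @param verbal logical: verbal status at assessment.
#' @return factor with levels `no_risk`, `mild_moderate`, `high`.
#' @examples
#' classify_ados_risk(10, verbal = FALSE)  # mild_moderate
#' classify_ados_risk(12, verbal = TRUE)   # high
#' @export
classify_ados_risk <- function(total_score, verbal) {
  if (any(!is.na(total_score) & total_score < 0)) {
    stop("ADOS-2 total score must be non-negative", call. = FALSE)
  }
  n <- max(length(total_score), length(verbal))
  total_score <- rep_len(total_score, n)
  verbal <- rep_len(as.logical(verbal), n)
  lo <- ifelse(verbal, 7, 9)   # upper edge of no-risk
  hi <- ifelse(verbal, 11, 13) # upper edge of mild/moderate
  cat_chr <- ifelse(is.na(total_score), NA_character_,
                    ifelse(total_score <= lo, "no_risk",
                           ifelse(total_score <= hi, "mild_moderate",
                                  "high")))
  factor(cat_chr, levels = c("no_risk", "mild_moderate", "high"))
}

#' Any-risk dichotomy of the ADOS-2 category
#'
#' TRUE when the category is mild/moderate or high risk; the binary
#' "ASD symptoms" outcome used in the 2x2 and regression analyses.
#'
#' @param category factor from [classify_ados_risk()].
#' @return logical vector.
#' @export
ados_any_risk <- function(category) {
  ifelse(is.na(category), NA, category != "no_risk")
}

#' 2x2 contingency table
#'
#' Exposure x outcome counts: `a` exposed with outcome, `b` exposed
#' without, `c` unexposed with outcome, `d` unexposed without.
#'
#' @param a,b,c,d non-negative integer counts; or build from data with
#'   [table_2x2()].
#' @return object of class `table_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table total must be positive", call. = FALSE)
  structure(as.list(counts), class = "table_2x2")
}

#' @rdname contingency_2x2
#' @param exposure,outcome logical vectors (pairs with `NA` are dropped).
#' @export
table_2x2 <- function(exposure, outcome) {
  ok <- !is.na(exposure) & !is.na(outcome)
  exposure <- as.logical(exposure[ok]); outcome <- as.logical(outcome[ok])
  contingency_2x2(sum(exposure & outcome), sum(exposure & !outcome),
                  sum(!exposure & outcome), sum(!exposure & !outcome))
}

#' @export
print.table_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("outcome+", "outcome-")))
  print(m)
  invisible(x)
}

#' Odds ratio with Wald confidence interval
#'
#' OR = (a d)/(b c); 95\% CI =
#' \eqn{\exp(\log OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}. When any cell
#' is zero the Haldane-Anscombe correction adds 0.5 to every cell (and the
#' result is flagged `corrected`), which keeps the estimate and interval
#' finite.
#'
#' @param t a `table_2x2`.
#' @param conf confidence level (default 0.95).
#' @return list with `or`, `ci_lower`, `ci_upper`, `log_or`, `se`,
#'   `corrected`.
#' @export
odds_ratio <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "table_2x2"))
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  if (corrected) {
    cells <- cells + 0.5
    message("odds_ratio: zero cell; Haldane-Anscombe +0.5 correction applied")
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf) / 2)
  list(
    or = or, ci_lower = exp(log(or) - z * se),
    ci_upper = exp(log(or) + z * se), log_or = log(or), se = se,
    corrected = corrected
  )
}

#' Diagnostic 2x2 metrics
#'
#' Sensitivity a/(a+c), specificity d/(b+d), positive predictive value
#' a/(a+b) and negative predictive value d/(c+d), with exposure read as
#' "test positive" and outcome as "condition present". A metric whose
#' denominator is zero is `NA` (undefined), never 0. `as_percent = TRUE`
#' reports half-up-rounded integer percentages, the convention used when
#' printing such tables.
#'
#' @param t a `table_2x2`.
#' @param as_percent report rounded percentages instead of proportions.
#' @return named list: `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
diagnostic_metrics <- function(t, as_percent = FALSE) {
  stopifnot(inherits(t, "table_2x2"))
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(
    sensitivity = frac(t$a, t$a + t$c),
    specificity = frac(t$d, t$b + t$d),
    ppv = frac(t$a, t$a + t$b),
    npv = frac(t$d, t$c + t$d)
  )
  if (as_percent) m <- lapply(m, function(v) round_half_up(100 * v))
  m
}

#' Logistic regression fit
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, convergence tolerance 1e-12, at most 50 iterations) with the
#' coefficient table reported the way clinical association tables print
#' it: B, S.E., Wald p-value, OR = exp(B) with 95\% Wald CI; plus the
#' likelihood-ratio omnibus model chi-square against the intercept-only
#' model and Nagelkerke's R-squared. Perfect separation is detected and
#' raised as an error naming the offending predictor; a degenerate
#' single-valued outcome returns a result flagged `converged = FALSE`.
#'
#' @param X data.frame or matrix of predictors (no intercept column;
#'   one is added). Logical columns are treated as 0/1.
#' @param y binary outcome.
#' @return object of class `logistic_fit`: `coefficients` data.frame
#'   (term, B, SE, z, p, OR, ci_lower, ci_upper), `model_chisq`,
#'   `model_df`, `model_p`, `r2_nagelkerke`, `converged`, `n`.
#' @export
logistic_fit <- function(X, y) {
  X <- as.data.frame(X)
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- as.numeric(as.logical(y[ok]))
  n <- length(y)
  if (n <= ncol(X)) stop("need more observations than predictors",
                         call. = FALSE)
  if (length(unique(y)) < 2) {
    out <- structure(
      list(coefficients = NULL, converged = FALSE, n = n,
           flag = "degenerate outcome: all responses identical"),
      class = "logistic_fit"
    )
    return(out)
  }
  dat <- cbind(X, .y = y)
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-12, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (any(abs(b[-1]) > 15 & se[-1] > 100)) {
    bad <- names(b[-1])[abs(b[-1]) > 15 & se[-1] > 100][1]
    stop("perfect separation detected for predictor '", bad, "'",
         call. = FALSE)
  }
  z <- b / se
  pvals <- 2 * pnorm(-abs(z))
  ci_lo <- exp(b - 1.96 * se)
  ci_hi <- exp(b + 1.96 * se)
  d0 <- fit$null.deviance
  d1 <- fit$deviance
  chisq <- d0 - d1
  df <- fit$df.null - fit$df.residual
  r2 <- (1 - exp((d1 - d0) / n)) / (1 - exp(-d0 / n))
  structure(
    list(
      coefficients = data.frame(
        term = names(b), B = unname(b), SE = unname(se), z = unname(z),
        p = unname(pvals), OR = unname(exp(b)), ci_lower = unname(ci_lo),
        ci_upper = unname(ci_hi), row.names = NULL
      ),
      model_chisq = chisq, model_df = df,
      model_p = pchisq(chisq, df, lower.tail = FALSE),
      r2_nagelkerke = r2, converged = fit$converged, n = n,
      glm = fit
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!isTRUE(x$converged) && is.null(x$coefficients)) {
    cat("<logistic_fit> not fitted:", x$flag, "\n")
    return(invisible(x))
  }
  cat(sprintf("<logistic_fit> n = %d | model chi-sq %.2f (df %d, p %.4g) | Nagelkerke R2 %.3f\n",
              x$n, x$model_chisq, x$model_df, x$model_p, x$r2_nagelkerke))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: U from rank sums with
#' midranks for ties. The exact null distribution is used for small
#' samples (n1 + n2 at most 12, no ties); otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#' Two samples with all values identical give U = n1 n2 / 2 and p = 1.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `U` (for the first sample), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty",
                                     call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = n1 * n2 / 2, p = 1, method = "degenerate (all ties)"))
  }
  ties <- any(duplicated(c(x, y)))
  use_exact <- (n1 + n2) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Developmental-quotient transforms
#'
#' Elementwise logarithmic (`log`) or reciprocal (`reciprocal`) transform
#' of positive developmental quotients, used to meet the distributional
#' assumptions of the linear outcome models; `inverse_transform_dq()`
#' maps fitted values back to the DQ scale for reporting.
#'
#' @param values positive numeric DQ values (NAs pass through).
#' @param kind `"log"` or `"reciprocal"`.
#' @return transformed numeric vector.
#' @export
transform_dq <- function(values, kind = c("log", "reciprocal")) {
  kind <- match.arg(kind)
  if (any(!is.na(values) & values <= 0)) {
    stop("DQ values must be positive for the ", kind, " transform",
         call. = FALSE)
  }
  switch(kind, log = log(values), reciprocal = 1 / values)
}

#' @rdname transform_dq
#' @export
inverse_transform_dq <- function(values, kind = c("log", "reciprocal")) {
  kind <- match.arg(kind)
  switch(kind, log = exp(values), reciprocal = 1 / values)
}

#' Ordinary least squares with coefficient tests
#'
#' OLS of a (possibly transformed) outcome on a design of EEG flags and
#' covariates, reporting the coefficient table with t-tests and R-squared.
#' A rank-deficient design is an error naming the collinear columns.
#'
#' @param X data.frame or matrix of predictors (intercept added).
#' @param y numeric outcome.
#' @return list with `coefficients` data.frame (term, estimate, SE, t, p),
#'   `r_squared`, `sigma`, `n`, `lm`.
#' @export
linear_model <- function(X, y) {
  X <- as.data.frame(X)
  ok <- complete.cases(X) & !is.na(y)
  dat <- cbind(X[ok, , drop = FALSE], .y = y[ok])
  if (nrow(dat) <= ncol(X)) stop("need more observations than predictors",
                                 call. = FALSE)
  fit <- lm(.y ~ ., data = dat)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  list(
    coefficients = data.frame(
      term = rownames(ct), estimate = ct[, 1], SE = ct[, 2], t = ct[, 3],
      p = ct[, 4], row.names = NULL
    ),
    r_squared = sm$r.squared, sigma = sm$sigma, n = nrow(dat), lm = fit
  )
}

#' Collinearity diagnostics
#'
#' Variance inflation factor of each predictor from regressing it on the
#' remaining predictors: VIF = 1/(1 - R^2_j), tolerance = 1/VIF. A
#' perfectly collinear predictor is reported with `VIF = Inf`,
#' `tolerance = 0`. The conventional screening thresholds are
#' tolerance > 0.1 and VIF < 10.
#'
#' @param X data.frame or matrix with at least two numeric predictors.
#' @return data.frame with columns `predictor`, `r_squared`, `vif`,
#'   `tolerance`.
#' @export
collinearity_check <- function(X) {
  X <- as.data.frame(lapply(as.data.frame(X), as.numeric))
  if (ncol(X) < 2) stop("need at least two predictors", call. = FALSE)
  out <- lapply(seq_along(X), function(j) {
    fit <- lm(X[[j]] ~ ., data = X[-j])
    r2 <- summary(fit)$r.squared
    vif <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    data.frame(predictor = names(X)[j], r_squared = r2, vif = vif,
               tolerance = 1 / vif)
  })
  do.call(rbind, out)
}
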