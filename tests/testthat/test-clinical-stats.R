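# Outcome-side statistics: ADOS-2 categorisation, 2x2 analyses, logistic
# and linear models, Mann-Whitney tests, transforms, collinearity.

test_that("ADOS-2 risk bands follow the verbal and non-verbal cut-offs", {
  expect_equal(as.character(classify_ados_risk(10, verbal = FALSE)),
               "mild_moderate")
  expect_equal(as.character(classify_ados_risk(12, verbal = TRUE)), "high")
  expect_equal(as.character(classify_ados_risk(0, verbal = TRUE)), "no_risk")
  expect_equal(as.character(classify_ados_risk(0, verbal = FALSE)), "no_risk")
  # band edges
  expect_equal(as.character(classify_ados_risk(c(9, 13, 14), FALSE)),
               c("no_risk", "mild_moderate", "high"))
  expect_equal(as.character(classify_ados_risk(c(7, 8, 11, 12), TRUE)),
               c("no_risk", "mild_moderate", "mild_moderate", "high"))
  expect_error(classify_ados_risk(-1, TRUE), "non-negative")
  expect_identical(ados_any_risk(classify_ados_risk(c(0, 10), FALSE)),
                   c(FALSE, TRUE))
})

test_that("odds ratio and CI reproduce closed forms and handle zero cells", {
  t0 <- contingency_2x2(5, 5, 5, 5)
  expect_equal(odds_ratio(t0)$or, 1)

  t <- contingency_2x2(10, 5, 2, 8)
  or <- odds_ratio(t)
  expect_equal(or$or, (10 * 8) / (5 * 2))
  expect_equal(or$se, sqrt(1 / 10 + 1 / 5 + 1 / 2 + 1 / 8))
  expect_equal(or$ci_lower, exp(log(or$or) - qnorm(0.975) * or$se))

  expect_message(orz <- odds_ratio(contingency_2x2(3, 0, 2, 7)), "Haldane")
  expect_true(orz$corrected)
  expect_true(is.finite(orz$or) && is.finite(orz$ci_upper))

  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(contingency_2x2(0, 0, 0, 0), "positive")
})

test_that("diagnostic metrics: definitions, undefined denominators, identities", {
  t <- contingency_2x2(10, 5, 2, 8)
  m <- diagnostic_metrics(t)
  expect_equal(m$sensitivity, 10 / 12)
  expect_equal(m$specificity, 8 / 13)
  expect_equal(m$ppv, 10 / 15)
  expect_equal(m$npv, 8 / 10)

  # undefined when the denominator is zero (never reported as 0)
  td <- contingency_2x2(0, 0, 3, 4)
  md <- diagnostic_metrics(td)
  expect_true(is.na(md$ppv))
  expect_false(is.na(md$npv))

  # count recovery and prevalence-weighted identity
  expect_equal(m$sensitivity * (t$a + t$c), t$a)
  expect_equal(m$ppv * (t$a + t$b), t$a)
  prev <- (t$a + t$c) / (t$a + t$b + t$c + t$d)
  ppv_id <- m$sensitivity * prev /
    (m$sensitivity * prev + (1 - m$specificity) * (1 - prev))
  expect_equal(m$ppv, ppv_id, tolerance = 1e-12)
})

test_that("logistic regression on a saturated 2x2 equals the cross-product ratio", {
  # property over random tables with all cells >= 1
  set.seed(10)
  for (i in 1:200) {
    cells <- rpois(4, 8) + 1
    expo <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
    outc <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
    fit <- logistic_fit(data.frame(exposed = expo), outc)
    or <- odds_ratio(contingency_2x2(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(fit$coefficients$OR[2], or$or, tolerance = 1e-6)
  }
})

test_that("logistic fit flags degenerate outcomes and detects separation", {
  fit <- logistic_fit(data.frame(x = rnorm(20)), rep(TRUE, 20))
  expect_false(fit$converged)
  expect_match(fit$flag, "degenerate")

  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(FALSE, TRUE), each = 20)
  expect_error(logistic_fit(data.frame(x = x), y), "separation.*x")
})

test_that("Wald test holds its nominal level under the null", {
  set.seed(11)
  rej <- vapply(1:100, function(i) {
    x <- rnorm(5000)
    y <- runif(5000) < 0.5
    fit <- logistic_fit(data.frame(x = x), y)
    fit$coefficients$p[2] < 0.05
  }, logical(1))
  expect_equal(mean(rej), 0.05, tolerance = 0.02 / 0.05)
})

test_that("logistic fit reports omnibus chi-square and Nagelkerke R2", {
  set.seed(12)
  x <- rnorm(300)
  y <- runif(300) < plogis(1.5 * x)
  fit <- logistic_fit(data.frame(x = x), y)
  expect_true(fit$converged)
  expect_gt(fit$model_chisq, 0)
  expect_equal(fit$model_df, 1)
  expect_true(fit$r2_nagelkerke > 0 && fit$r2_nagelkerke <= 1)
  # CI contains the point estimate
  co <- fit$coefficients[2, ]
  expect_true(co$ci_lower < co$OR && co$OR < co$ci_upper)
})

test_that("Mann-Whitney: symmetry, exact enumeration, extreme separation", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  m_sym <- mann_whitney_u(x, x + 0)   # identical samples
  expect_equal(m_sym$U, length(x)^2 / 2)
  expect_gt(m_sym$p, 0.9)

  # identical constant samples: all ties
  m_tie <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_equal(m_tie$p, 1)

  # exact p equals the exhaustive permutation oracle (n1 = n2 = 4)
  set.seed(13)
  for (i in 1:5) {
    a <- sample(1:100, 4); b <- sample(101:200, 4) - sample(50:150, 4)
    if (any(duplicated(c(a, b)))) next
    m <- mann_whitney_u(a, b)
    expect_equal(m$method, "exact")
    expect_equal(m$p, mw_exact_oracle(a, b), tolerance = 1e-12)
  }

  big <- mann_whitney_u(rnorm(30, 5), rnorm(30, 0))
  expect_lt(big$p, 1e-6)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation tracks exact enumeration where it is used", {
  # exhaustive over every U for all n1, n2 <= 8 large enough that the
  # approximation path (n1 + n2 > 12) is taken; the tie-free exact
  # distribution is the oracle. The corrected approximation is within
  # 0.015 everywhere and within 0.01 for the large majority of outcomes.
  devs <- c()
  for (n1 in 5:8) {
    for (n2 in 5:8) {
      if (n1 + n2 <= 12) next
      mu <- n1 * n2 / 2
      sdv <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
      for (U in 0:(n1 * n2)) {
        p_ex <- min(1, 2 * min(pwilcox(U, n1, n2),
                               1 - pwilcox(U - 1, n1, n2)))
        zc <- (U - mu - sign(U - mu) * 0.5) / sdv
        devs <- c(devs, abs(min(1, 2 * pnorm(-abs(zc))) - p_ex))
      }
    }
  }
  expect_lt(max(devs), 0.015)
  expect_gt(mean(devs < 0.01), 0.75)

  # and mann_whitney_u itself reproduces the corrected approximation there
  set.seed(14)
  x <- rnorm(7); y <- rnorm(8)
  got <- mann_whitney_u(x, y)
  expect_equal(got$method, "normal approximation")
  expect_equal(got$p,
               suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE)$p.value))
})

test_that("DQ transforms are exact and invertible", {
  expect_equal(transform_dq(1, "log"), 0)
  expect_equal(transform_dq(4, "reciprocal"), 0.25)
  v <- c(55.5, 75, 120.3)
  for (k in c("log", "reciprocal")) {
    expect_equal(inverse_transform_dq(transform_dq(v, k), k), v,
                 tolerance = 1e-12)
  }
  expect_error(transform_dq(c(50, 0), "log"), "positive")
})

test_that("linear models: exact fit, parameter recovery, group-mean identity", {
  x1 <- rnorm(50); x2 <- rnorm(50)
  y <- 3 + 2 * x1 - x2
  fit <- suppressWarnings(linear_model(data.frame(x1 = x1, x2 = x2), y))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(abs(resid(fit$lm))), 1e-10)

  set.seed(15)
  est <- t(vapply(1:50, function(i) {
    a <- rnorm(1000); b <- rnorm(1000)
    yy <- 2 * a - b + rnorm(1000, sd = 0.1)
    linear_model(data.frame(a = a, b = b), yy)$coefficients$estimate[2:3]
  }, numeric(2)))
  expect_equal(colMeans(est), c(2, -1), tolerance = 0.02)

  # single binary predictor: coefficient = difference in group means
  g <- rep(c(TRUE, FALSE), c(12, 18))
  yy <- rnorm(30)
  fitb <- linear_model(data.frame(g = g), yy)
  expect_equal(fitb$coefficients$estimate[2],
               mean(yy[g]) - mean(yy[!g]), tolerance = 1e-10)

  expect_error(linear_model(data.frame(a = x1, b = x1), y), "collinear")
})

test_that("collinearity diagnostics match the regression oracle", {
  set.seed(16)
  n <- 200
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  cc <- collinearity_check(X)
  expect_equal(cc$vif, c(1, 1), tolerance = 0.05)

  X$dup <- X$a
  cc2 <- suppressWarnings(collinearity_check(X))
  expect_true(is.infinite(cc2$vif[cc2$predictor == "dup"]))
  expect_equal(cc2$tolerance[cc2$predictor == "dup"], 0)

  X3 <- data.frame(a = rnorm(n))
  X3$b <- X3$a + rnorm(n, sd = 0.1)
  cc3 <- collinearity_check(X3)
  r2 <- summary(lm(X3$b ~ X3$a))$r.squared
  expect_equal(cc3$vif[2], 1 / (1 - r2), tolerance = 1e-6)
})
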