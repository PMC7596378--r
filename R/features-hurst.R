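# Signal regularity: Hurst exponent by detrended fluctuation analysis.

#' Hurst exponent by detrended fluctuation analysis
#'
#' First-order DFA: the cumulative profile of the mean-removed series is
#' split into non-overlapping windows of size n, linearly detrended per
#' window, and the root-mean-square fluctuation F(n) is computed over at
#' least `n_scales` logarithmically spaced window sizes in
#' `[4, length(x)/4]`. The Hurst exponent is the least-squares slope of
#' log F(n) versus log n. White noise gives H near 0.5; persistent
#' (smoother, more regular) signals give larger H, and values above 1 are
#' legitimate for nonstationary signals, so the estimate is only required
#' to fall in (0, 2). DFA is preferred over rescaled-range analysis for its
#' robustness to slow trends and nonstationarity.
#'
#' The estimate is invariant to affine transforms a*x + b of the input.
#'
#' @param x numeric series, length at least 512.
#' @param n_scales number of window sizes (default 12).
#' @return scalar H.
#' @export
hurst_exponent <- function(x, n_scales = 12) {
  N <- length(x)
  if (N < 512) stop("series must have at least 512 samples", call. = FALSE)
  if (sd(x) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "constant signal"
    return(out)
  }
  prof <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(4), log(N / 4), length.out = n_scales))))
  Fn <- vapply(sizes, function(n) {
    k <- floor(N / n)
    y <- matrix(prof[seq_len(k * n)], nrow = n)
    t <- seq_len(n)
    X <- cbind(1, t)
    beta <- solve(crossprod(X), crossprod(X, y))
    res <- y - X %*% beta
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- Fn > 0
  unname(coef(lm(log(Fn[ok]) ~ log(sizes[ok])))[2])
}
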