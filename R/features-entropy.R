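# Signal complexity: sample entropy and its multiscale extension.

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B), where B counts pairs of templates of length
#' `m` and A pairs of length `m + 1` that match under Chebyshev distance at
#' tolerance `r * sd(x)`; self-matches are excluded and both template sets
#' use the same n - m starting points. Lower values indicate a more
#' regular, more predictable signal.
#'
#' @param x numeric series, length at least 100.
#' @param m embedding (template) length, default 2.
#' @param r tolerance as a fraction of `sd(x)`, default 0.2.
#' @param r_absolute if `TRUE`, `r` is taken as an absolute tolerance in
#'   the units of `x` (used internally by [multiscale_entropy()] in
#'   fixed-r mode).
#' @return non-negative scalar, or `NA` with attribute
#'   `reason = "no template matches"` when no template pair matches at
#'   length `m + 1` (never a silent `Inf`).
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, r_absolute = FALSE) {
  if (length(x) < 100) stop("series must have at least 100 samples",
                            call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (r <= 0) stop("r must be positive", call. = FALSE)
  tol <- if (r_absolute) r else r * sd(x)
  if (tol == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero tolerance (constant signal)"
    return(out)
  }
  cnt <- sampen_counts(as.numeric(x), as.integer(m), tol)
  A <- cnt[1]; B <- cnt[2]
  if (B == 0 || A == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no template matches"
    return(out)
  }
  -log(A / B)
}

#' Multiscale sample entropy
#'
#' Coarse-grains the series at scales `1..max_scale` (non-overlapping means
#' of consecutive samples) and computes [sample_entropy()] at each scale.
#' With `r_mode = "rescaled"` (default) the tolerance is `r` times the SD
#' of the coarse-grained series at each scale; with `"fixed"` it is `r`
#' times the SD of the original series at every scale. The fixed-r curve of
#' white noise decays with scale (coarse-graining shrinks its variance
#' relative to the fixed tolerance), the rescaled-r curve stays flat; for
#' correlated signals both flag the loss of complexity at long time scales.
#'
#' @param x numeric series of length at least `100 * max_scale`.
#' @param max_scale largest coarse-graining factor (default 20).
#' @param m,r sample-entropy parameters.
#' @param r_mode `"rescaled"` or `"fixed"` tolerance convention.
#' @return numeric vector of length `max_scale`, names `scale01`... ;
#'   element 1 equals `sample_entropy(x, m, r)` exactly.
#' @export
multiscale_entropy <- function(x, max_scale = 20, m = 2, r = 0.2,
                               r_mode = c("rescaled", "fixed")) {
  r_mode <- match.arg(r_mode)
  need <- 100 * max_scale
  if (length(x) < need) {
    stop("series too short for max_scale = ", max_scale,
         " (need at least ", need, " samples)", call. = FALSE)
  }
  tol_fixed <- r * sd(x)
  out <- vapply(seq_len(max_scale), function(tau) {
    if (tau == 1) {
      y <- x
    } else {
      nfull <- floor(length(x) / tau) * tau
      y <- colMeans(matrix(x[seq_len(nfull)], nrow = tau))
    }
    v <- if (r_mode == "rescaled") {
      sample_entropy(y, m = m, r = r)
    } else {
      sample_entropy(y, m = m, r = tol_fixed, r_absolute = TRUE)
    }
    as.numeric(v)
  }, numeric(1))
  names(out) <- sprintf("scale%02d", seq_len(max_scale))
  out
}
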