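# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG stream
#'
#' Seeds the generator with `seed`, evaluates `expr`, and restores the
#' caller's RNG state afterwards, so seeded helpers never leak global
#' state. Every randomised operation in the package routes through this.
#'
#' @param seed single integer.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Half-up rounding
#'
#' Rounds to `digits` decimals with halves away from zero, the convention
#' used when printing clinical percentages and odds ratios (R's `round()`
#' is half-even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Simulate fractional Gaussian noise
#'
#' Exact simulation by circulant embedding (Davies-Harte) of the fGn
#' autocovariance \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})/2}.
#' Used as ground truth when validating the DFA-based Hurst estimator.
#'
#' @param n series length.
#' @param H target Hurst exponent in (0, 1).
#' @param seed integer seed.
#' @return numeric vector of length `n` with unit marginal variance.
#' @export
sim_fgn <- function(n, H, seed) {
  stopifnot(n >= 2, H > 0, H < 1)
  with_seed(seed, {
    k <- 0:(n - 1)
    g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
    # circulant first row: gamma(0..n-1), then gamma(n-2..1) mirrored
    row <- c(g, g[(n - 1):2])
    lambda <- Re(fft(row))
    # tiny negative eigenvalues from rounding are clipped
    lambda[lambda < 0] <- 0
    m <- length(row)
    z <- complex(real = rnorm(m), imaginary = rnorm(m))
    x <- Re(fft(sqrt(lambda) * z, inverse = TRUE)) / sqrt(2 * m)
    x[seq_len(n)]
  })
}

tq_log <- function(..., file = getOption("tscqeeg.log_file", NULL)) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
  invisible(msg)
}
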