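# Spectral features: Welch power spectral density and relative band power.

#' EEG frequency bands
#'
#' Default band edges for the five neonatal EEG bands. The upper edge of
#' delta1 is 2 Hz so that the band isolates the very slow delta activity
#' whose persistence at term age marks a dysmature background.
#'
#' @param delta1,delta2,theta,alpha,beta length-2 numeric `c(lo, hi)` Hz.
#' @return a data.frame with columns `name`, `lo`, `hi`; bands must be
#'   ordered and non-overlapping.
#' @export
default_bands <- function(delta1 = c(0.5, 2), delta2 = c(2, 4),
                          theta = c(4, 8), alpha = c(8, 16),
                          beta = c(16, 30)) {
  b <- data.frame(
    name = c("delta1", "delta2", "theta", "alpha", "beta"),
    lo = c(delta1[1], delta2[1], theta[1], alpha[1], beta[1]),
    hi = c(delta1[2], delta2[2], theta[2], alpha[2], beta[2]),
    stringsAsFactors = FALSE
  )
  validate_bands(b)
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("name", "lo", "hi") %in% names(bands)))
  if (any(bands$lo <= 0) || any(bands$hi <= bands$lo)) {
    stop("each band needs 0 < lo < hi", call. = FALSE)
  }
  if (nrow(bands) > 1 && any(bands$lo[-1] < bands$hi[-nrow(bands)])) {
    stop("bands must be ordered and non-overlapping", call. = FALSE)
  }
  bands
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments of
#' `window_s` seconds with 50\% overlap.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param window_s segment length, seconds.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, window_s = 4) {
  nseg <- round(window_s * fs)
  if (length(x) < 2 * nseg) {
    stop("series shorter than two PSD windows (need >= ",
         2 * nseg, " samples)", call. = FALSE)
  }
  step <- floor(nseg / 2)
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  norm <- sum(w^2) * fs
  nfreq <- floor(nseg / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(fft(seg))^2 / norm
    acc <- acc + p[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # fold two-sided spectrum into one-sided
  if (nseg %% 2 == 0) {
    psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  } else {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nseg, psd = psd)
}

#' Relative band power per channel
#'
#' Welch PSD per channel, integrated over each band; relative power is the
#' band integral divided by the total over all defined bands, so the five
#' values sum to 1 per channel. A flat (zero-variance) channel has no
#' defined decomposition and yields `NA`, never a spurious 1/0 split.
#'
#' @param rec an `eeg_recording`.
#' @param bands band table from [default_bands()].
#' @param window_s Welch segment length, seconds.
#' @return data.frame with columns `channel`, `band`, `rel_power`,
#'   `abs_power`.
#' @export
band_power <- function(rec, bands = default_bands(), window_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  validate_bands(bands)
  if (ncol(rec$data) / rec$fs < 30) {
    stop("recording must be at least 30 s for spectral analysis",
         call. = FALSE)
  }
  if (rec$fs < 2 * max(bands$hi)) {
    stop("fs must exceed twice the highest band edge", call. = FALSE)
  }
  out <- lapply(seq_along(rec$channel_labels), function(i) {
    x <- rec$data[i, ]
    if (sd(x) == 0) {
      return(data.frame(channel = rec$channel_labels[i], band = bands$name,
                        rel_power = NA_real_, abs_power = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sp <- welch_psd(x, rec$fs, window_s)
    absp <- vapply(seq_len(nrow(bands)), function(b) {
      sel <- sp$freq >= bands$lo[b] & sp$freq < bands$hi[b]
      sum(sp$psd[sel])
    }, numeric(1))
    data.frame(channel = rec$channel_labels[i], band = bands$name,
               rel_power = absp / sum(absp), abs_power = absp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
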