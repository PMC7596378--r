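# Synthetic neonatal EEG: two-state burst/interburst renewal process with
# gamma-distributed state durations, spectrally shaped noise inside each
# state, and optional interhemispheric asynchrony of burst onsets.

#' 10-20 electrode label sets
#'
#' The 9-channel reduced neonatal array and the full 19-channel 10-20
#' montage. Odd-numbered labels are left hemisphere, even-numbered right,
#' `z` midline.
#'
#' @format character vectors of channel labels.
#' @export
TEN_TWENTY_9 <- c("Fp1", "Fp2", "C3", "C4", "T3", "T4", "O1", "O2", "Cz")

#' @rdname TEN_TWENTY_9
#' @export
TEN_TWENTY_19 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz", "C4", "T4",
  "T5", "P3", "Pz", "P4", "T6", "O1", "O2"
)

channel_side <- function(label) {
  if (grepl("z$", label)) return("mid")
  num <- sub("^[A-Za-z]+", "", label)
  if (as.integer(num) %% 2L == 1L) "left" else "right"
}

# Gaussian noise with a two-component spectrum: a very-slow band
# [0.5, 2) Hz and a faster band [2, 30] Hz, each mildly 1/f-weighted, with
# `slow_frac` of total power in the slow band. Unit variance on return.
shaped_noise <- function(n, fs, slow_frac, f_lo = 0.5, f_split = 2,
                         f_hi = 30) {
  freq <- (0:(n - 1)) * fs / n
  # fold to two-sided frequencies
  freq <- pmin(freq, fs - freq)
  w <- numeric(n)
  in_slow <- freq >= f_lo & freq < f_split
  in_fast <- freq >= f_split & freq <= min(f_hi, fs / 2)
  w[in_slow] <- 1 / freq[in_slow]^0.7
  w[in_fast] <- 1 / freq[in_fast]^0.7
  if (any(in_slow) && slow_frac > 0) {
    w[in_slow] <- w[in_slow] * sqrt(slow_frac / sum(w[in_slow]^2))
  } else {
    w[in_slow] <- 0
  }
  if (any(in_fast) && slow_frac < 1) {
    w[in_fast] <- w[in_fast] * sqrt((1 - slow_frac) / sum(w[in_fast]^2))
  } else {
    w[in_fast] <- 0
  }
  z <- complex(real = rnorm(n), imaginary = rnorm(n))
  x <- Re(fft(z * w, inverse = TRUE))
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

# Alternating interburst/burst schedule from a gamma renewal process.
# Returns data.frame(onset, duration) of bursts within [0, duration_s].
draw_burst_schedule <- function(profile, duration_s) {
  shape <- 1 / profile$ibi_cv^2
  t <- 0
  onsets <- numeric(0)
  durs <- numeric(0)
  # stationary start: begin inside an interburst interval of random phase
  t <- runif(1, 0, profile$ibi_mean_s)
  while (t < duration_s) {
    b <- rgamma(1, shape = shape, scale = profile$burst_mean_s / shape)
    onsets <- c(onsets, t)
    durs <- c(durs, b)
    t <- t + b + rgamma(1, shape = shape, scale = profile$ibi_mean_s / shape)
  }
  data.frame(onset = onsets, duration = durs)
}

state_track <- function(schedule, n, fs) {
  state <- logical(n)
  if (nrow(schedule) == 0) return(state)
  for (i in seq_len(nrow(schedule))) {
    i0 <- max(1L, floor(schedule$onset[i] * fs) + 1L)
    i1 <- min(n, floor((schedule$onset[i] + schedule$duration[i]) * fs))
    if (i1 >= i0) state[i0:i1] <- TRUE
  }
  state
}

# Smooth amplitude envelope (uV RMS) from a burst state track: raised-cosine
# ramps of ~0.25 s avoid clicks at state transitions.
amplitude_envelope <- function(state, fs, amp_burst, amp_inter) {
  ramp_n <- max(3L, round(0.25 * fs))
  if (ramp_n %% 2L == 0L) ramp_n <- ramp_n + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(ramp_n) / (ramp_n + 1))
  w <- w / sum(w)
  sm <- as.numeric(stats::filter(as.numeric(state), w, sides = 2))
  # edge effects from the centred filter: hold nearest defined value
  na_idx <- which(is.na(sm))
  if (length(na_idx)) {
    ok <- which(!is.na(sm))
    sm[na_idx] <- sm[ok[pmax(1L, findInterval(na_idx, ok))]]
    sm[is.na(sm)] <- mean(state)
  }
  amp_inter + (amp_burst - amp_inter) * sm
}

#' Generate a synthetic neonatal EEG recording
#'
#' Simulates a multichannel neonatal EEG background as a two-state
#' burst/interburst renewal process (gamma-distributed durations) whose
#' burst activity is spectrally shaped noise placing `slow_delta_frac` of
#' its power below 2 Hz. Homologous left/right channels share burst timing
#' except for asynchronous events: with probability `asynchrony_prob` a
#' burst is mirrored in the contralateral hemisphere only after
#' `asynchrony_lag_ms`. Midline channels follow the left-hemisphere clock.
#'
#' @param profile a [maturity_profile()].
#' @param duration_s recording duration, seconds (at least 60).
#' @param fs sampling rate, Hz (at least 64).
#' @param channels character vector of 10-20 labels; subset of the
#'   9-channel reduced neonatal array or the full 19-channel set.
#' @param seed integer seed; output is bit-identical for identical
#'   `(profile, duration_s, fs, channels, seed)`.
#' @param subject_id identifier stored in the recording.
#' @return an object of class `eeg_recording`: list with `data`
#'   (channels x samples matrix, microvolts), `fs`, `channel_labels`,
#'   `subject_id`, `ga_weeks`, per-hemisphere logical burst-state tracks
#'   (`state`) and burst-onset times in seconds (`burst_onsets`).
#' @examples
#' rec <- generate_eeg(mature_profile(), duration_s = 60, fs = 64,
#'                     channels = c("C3", "C4"), seed = 1)
#' dim(rec$data)
#' @export
generate_eeg <- function(profile, duration_s, fs,
                         channels = TEN_TWENTY_9, seed = 1L,
                         subject_id = "sim") {
  stopifnot(inherits(profile, "maturity_profile"))
  if (!is.numeric(duration_s) || duration_s <= 0 || !is.numeric(fs) || fs <= 0) {
    stop("duration_s and fs must be positive", call. = FALSE)
  }
  if (duration_s < 60) stop("duration_s must be at least 60 s", call. = FALSE)
  if (fs < 64) stop("fs must be at least 64 Hz", call. = FALSE)
  known <- union(TEN_TWENTY_9, TEN_TWENTY_19)
  bad <- setdiff(channels, known)
  if (length(bad)) {
    stop("unknown channel label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(channels)) stop("duplicate channel labels", call. = FALSE)

  n <- round(duration_s * fs)
  with_seed(seed, {
    sched_l <- draw_burst_schedule(profile, duration_s)
    # mirror to the right hemisphere; asynchronous bursts arrive lagged
    async <- runif(nrow(sched_l)) < profile$asynchrony_prob
    sched_r <- sched_l
    sched_r$onset <- sched_l$onset + async * profile$asynchrony_lag_ms / 1000
    sched_r <- sched_r[sched_r$onset < duration_s, , drop = FALSE]

    st <- list(
      left = state_track(sched_l, n, fs),
      right = state_track(sched_r, n, fs)
    )
    env <- lapply(st, amplitude_envelope, fs = fs,
                  amp_burst = profile$burst_amp_uv,
                  amp_inter = profile$interburst_amp_uv)

    data <- matrix(0, nrow = length(channels), ncol = n,
                   dimnames = list(channels, NULL))
    for (i in seq_along(channels)) {
      side <- channel_side(channels[i])
      e <- if (side == "right") env$right else env$left
      data[i, ] <- e * shaped_noise(n, fs, profile$slow_delta_frac)
    }

    structure(
      list(
        data = data, fs = fs, channel_labels = channels,
        subject_id = subject_id, ga_weeks = profile$ga_weeks,
        state = st,
        burst_onsets = list(left = sched_l$onset, right = sched_r$onset)
      ),
      class = "eeg_recording"
    )
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s: %d ch x %d samples @ %g Hz (%.1f s), GA %g wk\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    x$ga_weeks
  ))
  invisible(x)
}
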