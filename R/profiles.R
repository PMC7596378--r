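#' EEG maturity profile
#'
#' Generative parameters for the synthetic neonatal EEG background. The
#' profile encodes the three machine-readable hallmarks of a dysmature
#' background at term age: abnormal discontinuity (long interburst
#' intervals with deep amplitude suppression), persistence of very slow
#' delta activity (< 2 Hz), and interhemispheric asynchrony of burst
#' onsets. Sleep staging is deliberately not modelled; discontinuity and
#' asynchrony are the only carriers of "immaturity" here.
#'
#' A profile flagged `dysmature = TRUE` must be at least as immature as the
#' mature defaults on each of `ibi_mean_s`, `slow_delta_frac` and
#' `asynchrony_prob` (component-wise), so labels can never contradict the
#' parameters that generated the signal.
#'
#' @param ga_weeks gestational age, weeks.
#' @param ibi_mean_s mean interburst-interval duration, seconds.
#' @param ibi_cv coefficient of variation of interval durations
#'   (dimensionless; also applied to burst durations).
#' @param burst_mean_s mean burst duration, seconds.
#' @param burst_amp_uv burst RMS amplitude, microvolts.
#' @param interburst_amp_uv interburst RMS amplitude, microvolts; must be
#'   below `burst_amp_uv`.
#' @param slow_delta_frac fraction of burst spectral power placed below
#'   2 Hz, in `[0, 1]`.
#' @param asynchrony_prob probability that a burst onset in one hemisphere
#'   is not mirrored within the synchrony window, in `[0, 1]`.
#' @param asynchrony_lag_ms lag applied to asynchronous bursts in the
#'   contralateral hemisphere, milliseconds.
#' @param dysmature logical label; validated against the parameters.
#' @return an object of class `maturity_profile`.
#' @seealso [mature_profile()], [dysmature_profile()], [generate_eeg()]
#' @export
maturity_profile <- function(ga_weeks = 42,
                             ibi_mean_s = 3,
                             ibi_cv = 0.5,
                             burst_mean_s = 2,
                             burst_amp_uv = 50,
                             interburst_amp_uv = 25,
                             slow_delta_frac = 0.4,
                             asynchrony_prob = 0.05,
                             asynchrony_lag_ms = 400,
                             dysmature = FALSE) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      stop(sprintf("`%s` must be a single number", nm), call. = FALSE)
    }
    x
  }
  for (nm in c("ga_weeks", "ibi_mean_s", "ibi_cv", "burst_mean_s",
               "burst_amp_uv", "interburst_amp_uv", "slow_delta_frac",
               "asynchrony_prob", "asynchrony_lag_ms")) {
    num1(get(nm), nm)
  }
  if (ibi_mean_s <= 0 || burst_mean_s <= 0 || burst_amp_uv <= 0 ||
      interburst_amp_uv <= 0 || ibi_cv <= 0) {
    stop("durations, amplitudes and ibi_cv must be positive", call. = FALSE)
  }
  if (asynchrony_lag_ms < 0) stop("asynchrony_lag_ms must be >= 0", call. = FALSE)
  if (burst_amp_uv <= interburst_amp_uv) {
    stop("burst_amp_uv must exceed interburst_amp_uv", call. = FALSE)
  }
  if (slow_delta_frac < 0 || slow_delta_frac > 1) {
    stop("slow_delta_frac must lie in [0, 1]", call. = FALSE)
  }
  if (asynchrony_prob < 0 || asynchrony_prob > 1) {
    stop("asynchrony_prob must lie in [0, 1]", call. = FALSE)
  }
  if (isTRUE(dysmature)) {
    ref <- .mature_defaults
    if (ibi_mean_s < ref$ibi_mean_s ||
        slow_delta_frac < ref$slow_delta_frac ||
        asynchrony_prob < ref$asynchrony_prob) {
      stop(
        "a profile flagged dysmature must have ibi_mean_s, slow_delta_frac ",
        "and asynchrony_prob >= the mature defaults (",
        sprintf("%g s, %g, %g", ref$ibi_mean_s, ref$slow_delta_frac,
                ref$asynchrony_prob), ")",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      ga_weeks = ga_weeks, ibi_mean_s = ibi_mean_s, ibi_cv = ibi_cv,
      burst_mean_s = burst_mean_s, burst_amp_uv = burst_amp_uv,
      interburst_amp_uv = interburst_amp_uv,
      slow_delta_frac = slow_delta_frac,
      asynchrony_prob = asynchrony_prob,
      asynchrony_lag_ms = asynchrony_lag_ms,
      dysmature = isTRUE(dysmature)
    ),
    class = "maturity_profile"
  )
}

# Documented config defaults for a mature term background; these anchor the
# dysmature-consistency invariant. Age-specific interburst-interval norms
# are not modelled; the values are working defaults, not clinical claims.
.mature_defaults <- list(
  ibi_mean_s = 3, slow_delta_frac = 0.4, asynchrony_prob = 0.05
)

#' Default mature and dysmature profiles
#'
#' `mature_profile()`: continuous-leaning trace alternant background of a
#' healthy term neonate (short interburst intervals, moderate slow-delta
#' content, near-synchronous hemispheres). `dysmature_profile()`:
#' excessively discontinuous background with long, deeply suppressed
#' interburst intervals, dominant very-slow delta and frequent
#' interhemispheric asynchrony. Override any field via `...`.
#'
#' @param ... overrides passed to [maturity_profile()].
#' @return a `maturity_profile`.
#' @export
mature_profile <- function(...) {
  args <- modifyList(
    list(ibi_mean_s = 3, slow_delta_frac = 0.4, asynchrony_prob = 0.05,
         burst_amp_uv = 50, interburst_amp_uv = 25, dysmature = FALSE),
    list(...)
  )
  do.call(maturity_profile, args)
}

#' @rdname mature_profile
#' @export
dysmature_profile <- function(...) {
  args <- modifyList(
    list(ibi_mean_s = 8, slow_delta_frac = 0.7, asynchrony_prob = 0.4,
         burst_amp_uv = 50, interburst_amp_uv = 10,
         asynchrony_lag_ms = 600, dysmature = TRUE),
    list(...)
  )
  do.call(maturity_profile, args)
}

#' @export
print.maturity_profile <- function(x, ...) {
  cat(sprintf(
    "<maturity_profile> %s | GA %g wk | IBI %g s (cv %g) | burst %g s\n",
    if (x$dysmature) "dysmature" else "mature",
    x$ga_weeks, x$ibi_mean_s, x$ibi_cv, x$burst_mean_s
  ))
  cat(sprintf(
    "  amp %g/%g uV | slow-delta %.2f | asynchrony p=%.2f lag=%g ms\n",
    x$burst_amp_uv, x$interburst_amp_uv, x$slow_delta_frac,
    x$asynchrony_prob, x$asynchrony_lag_ms
  ))
  invisible(x)
}
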