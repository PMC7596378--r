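# Assembly of the four quantitative feature families into one per-subject
# feature vector, plus light preprocessing.

#' Preprocess an EEG recording
#'
#' Zero-phase band-pass (0.5-30 Hz, order-4 Butterworth applied forwards
#' and backwards) per channel, plus amplitude-clipping detection: 2-s
#' epochs whose peak absolute amplitude exceeds `clip_uv` are counted per
#' channel in the attribute `artifact_epochs`. No component-based artifact
#' removal is attempted; visual artifact rejection is a human step outside
#' this package's scope.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band edges, Hz.
#' @param clip_uv clipping threshold, microvolts (default 500).
#' @return the filtered `eeg_recording` with attribute `artifact_epochs`.
#' @export
preprocess_recording <- function(rec, lo = 0.5, hi = 30, clip_uv = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  nw <- round(2 * rec$fs)
  n_epoch <- floor(ncol(rec$data) / nw)
  clip <- integer(nrow(rec$data))
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    if (sd(x) > 0) rec$data[i, ] <- bandpass_filter(x, rec$fs, lo, hi)
    if (n_epoch > 0) {
      idx <- rep(seq_len(n_epoch), each = nw)
      peaks <- tapply(abs(x[seq_len(n_epoch * nw)]), idx, max)
      clip[i] <- sum(peaks > clip_uv)
    }
  }
  names(clip) <- rec$channel_labels
  attr(rec, "artifact_epochs") <- clip
  rec
}

#' Feature extraction configuration
#'
#' @param bands band table ([default_bands()]).
#' @param reeg_window_s rEEG epoch length, seconds.
#' @param mse_scales number of multiscale-entropy scales.
#' @param mse_m,mse_r sample-entropy embedding length and tolerance
#'   fraction.
#' @param mse_r_mode tolerance convention, see [multiscale_entropy()].
#' @param psd_window_s Welch segment length, seconds.
#' @param preprocess logical; apply [preprocess_recording()] first.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(bands = default_bands(), reeg_window_s = 2,
                           mse_scales = 20, mse_m = 2, mse_r = 0.2,
                           mse_r_mode = "rescaled", psd_window_s = 4,
                           preprocess = TRUE) {
  structure(
    list(bands = validate_bands(bands), reeg_window_s = reeg_window_s,
         mse_scales = mse_scales, mse_m = mse_m, mse_r = mse_r,
         mse_r_mode = mse_r_mode, psd_window_s = psd_window_s,
         preprocess = preprocess),
    class = "feature_config"
  )
}

#' Extract the quantitative dysmaturity feature vector
#'
#' Computes, per channel, the four feature families that describe EEG
#' background dysmaturity: relative power in the five frequency bands,
#' rEEG asymmetry per band, multiscale sample entropy at scales
#' `1..mse_scales`, and the Hurst exponent. Features of a degenerate
#' (constant) channel are `NA`, never silent zeros.
#'
#' @param rec an `eeg_recording`.
#' @param config a [feature_config()].
#' @return named numeric vector with entries
#'   `<channel>.power.<band>`, `<channel>.reeg_asym.<band>`,
#'   `<channel>.mse.<scale>` and `<channel>.hurst`
#'   (per channel: 5 + 5 + `mse_scales` + 1 values).
#' @export
extract_features <- function(rec, config = feature_config()) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(config, "feature_config"))
  if (isTRUE(config$preprocess)) rec <- preprocess_recording(rec)
  bands <- config$bands
  bp <- band_power(rec, bands, config$psd_window_s)
  out <- list()
  for (i in seq_along(rec$channel_labels)) {
    ch <- rec$channel_labels[i]
    x <- rec$data[i, ]
    degenerate <- sd(x) == 0
    pw <- bp$rel_power[bp$channel == ch]
    names(pw) <- paste0(ch, ".power.", bands$name)
    asym <- vapply(seq_len(nrow(bands)), function(b) {
      if (degenerate) return(NA_real_)
      as.numeric(range_eeg(x, rec$fs, config$reeg_window_s,
                           band = c(bands$lo[b], bands$hi[b]))$asymmetry)
    }, numeric(1))
    names(asym) <- paste0(ch, ".reeg_asym.", bands$name)
    mse <- if (degenerate) {
      rep(NA_real_, config$mse_scales)
    } else {
      as.numeric(multiscale_entropy(x, config$mse_scales, config$mse_m,
                                    config$mse_r, config$mse_r_mode))
    }
    names(mse) <- sprintf("%s.mse.%02d", ch, seq_len(config$mse_scales))
    h <- if (degenerate) NA_real_ else as.numeric(hurst_exponent(x))
    names(h) <- paste0(ch, ".hurst")
    out[[ch]] <- c(pw, asym, mse, h)
  }
  v <- unlist(out, use.names = FALSE)
  names(v) <- unlist(lapply(out, names))
  v
}

#' Aggregate channel-level features per subject
#'
#' Collapses a feature vector from [extract_features()] across channels by
#' a summary function (default: median), yielding one value per feature
#' name (`power.delta1`, ..., `mse.20`, `hurst`). `NA` channels are
#' dropped.
#'
#' @param features named vector from [extract_features()].
#' @param fun summary function.
#' @return named numeric vector.
#' @export
aggregate_features <- function(features, fun = median) {
  base <- sub("^[^.]+\\.", "", names(features))
  out <- tapply(features, base, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else fun(v)
  })
  # keep original family ordering, not alphabetical
  ord <- unique(base)
  setNames(as.numeric(out[ord]), ord)
}

#' Feature family of each feature name
#'
#' Maps aggregated feature names to their family: `power`, `reeg_asym`,
#' `mse` (entropy) or `hurst` (fractality).
#'
#' @param feature_names character vector.
#' @return character vector of family labels.
#' @export
feature_family <- function(feature_names) {
  fams <- c("power", "reeg_asym", "mse", "hurst")
  vapply(strsplit(feature_names, ".", fixed = TRUE), function(parts) {
    hit <- intersect(parts, fams)
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
}
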