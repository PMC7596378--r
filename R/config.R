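# Pipeline configuration: nested list, YAML-serialisable, validated
# against the default template (unknown keys are rejected).

#' Default pipeline configuration
#'
#' All tunable parameters of the simulate - features - classify - stats
#' pipeline, each with its documented default:
#' \describe{
#'   \item{cohort}{`n` subjects and the [cohort_design()] risk parameters.}
#'   \item{eeg}{recording duration (s), sampling rate (Hz), channel set,
#'     and the mature/dysmature [maturity_profile()] parameter overrides.}
#'   \item{features}{band edges (Hz), rEEG window (s), multiscale-entropy
#'     `m`, `r`, scale count and tolerance mode, Welch window (s).}
#'   \item{classifier}{features selected per training fold, fold count,
#'     repetitions.}
#' }
#'
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(
    list(
      cohort = list(
        n_subjects = 64,
        p_dysmature = 14 / 63,
        p_asd_given_dysmature = 8 / 14,
        p_asd_given_mature = 11 / 49,
        n_missing_outcome = 1
      ),
      eeg = list(
        duration_s = 120,
        fs = 64,
        channels = TEN_TWENTY_9,
        mature = list(ibi_mean_s = 3, slow_delta_frac = 0.4,
                      asynchrony_prob = 0.05, interburst_amp_uv = 25),
        dysmature = list(ibi_mean_s = 8, slow_delta_frac = 0.7,
                         asynchrony_prob = 0.4, interburst_amp_uv = 10)
      ),
      features = list(
        reeg_window_s = 2, mse_scales = 20, mse_m = 2, mse_r = 0.2,
        mse_r_mode = "rescaled", psd_window_s = 4
      ),
      classifier = list(k_features = 5, n_folds = 3, repetitions = 1)
    ),
    class = "pipeline_config"
  )
}

check_keys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra)) {
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  }
  for (nm in names(cfg)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(cfg[[nm]])) {
      check_keys(cfg[[nm]], template[[nm]], paste0(path, nm, "$"))
    }
  }
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file of overrides, merges it over [default_config()] and
#' rejects unknown keys. `save_config()` writes a config as YAML;
#' `config_hash()` returns an MD5 digest of the resolved configuration,
#' carried on every pipeline report for provenance.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  check_keys(user, cfg)
  out <- modifyList(cfg, user)
  class(out) <- "pipeline_config"
  out
}

#' @rdname load_config
#' @param config a `pipeline_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname load_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
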