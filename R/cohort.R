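# Synthetic cohort of TSC infants: per-subject visual EEG flags, covariates
# and 24-month outcomes, with a configurable dysmaturity -> ASD risk link.

#' Cohort risk design
#'
#' Parameters of the joint distribution of the visual EEG flags, baseline
#' covariates and 24-month outcomes in a simulated TSC cohort. The defaults
#' are calibrated to a 64-infant prospective cohort: 14/63 dysmature
#' backgrounds, ASD risk 8/14 given a dysmature EEG vs 11/49 given a mature
#' one (odds ratio 4.6), TSC2 in 72\%, preventive treatment in 30\%, and
#' developmental quotients centred near the mid-70s with lower means under
#' dysmaturity.
#'
#' @param p_dysmature probability of a dysmature EEG background.
#' @param p_asd_given_dysmature,p_asd_given_mature conditional ASD-risk
#'   probabilities at 24 months.
#' @param p_ied,p_focal_slowing,p_seizure frequencies of the other visual
#'   EEG flags (independent of dysmaturity in the generator).
#' @param p_mutation named probabilities for TSC1 / TSC2 / no identified
#'   variant; must sum to 1.
#' @param p_preventive probability of the preventive-treatment arm.
#' @param p_verbal probability a child is verbal at the ADOS-2 assessment.
#' @param dq_mean_mature,dq_mean_dysmature,dq_sd mean and SD of the normal
#'   distributions the three developmental quotients are drawn from,
#'   truncated to `[1, 160]`.
#' @param n_missing_outcome number of subjects per cohort with missing
#'   ASD/language/motor outcome (default 1, mirroring a cohort with
#'   complete follow-up in all but one infant).
#' @return a list of class `cohort_design`.
#' @export
cohort_design <- function(p_dysmature = 14 / 63,
                          p_asd_given_dysmature = 8 / 14,
                          p_asd_given_mature = 11 / 49,
                          p_ied = 0.44,
                          p_focal_slowing = 0.23,
                          p_seizure = 0.09,
                          p_mutation = c(TSC1 = 0.27, TSC2 = 0.72,
                                         none_identified = 0.01),
                          p_preventive = 0.30,
                          p_verbal = 0.5,
                          dq_mean_mature = 80,
                          dq_mean_dysmature = 65,
                          dq_sd = 15,
                          n_missing_outcome = 1L) {
  probs <- c(p_dysmature, p_asd_given_dysmature, p_asd_given_mature,
             p_ied, p_focal_slowing, p_seizure, p_preventive, p_verbal,
             p_mutation)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p_mutation) - 1) > 1e-8) {
    stop("p_mutation must sum to 1", call. = FALSE)
  }
  if (length(p_mutation) != 3L ||
      !setequal(names(p_mutation), c("TSC1", "TSC2", "none_identified"))) {
    stop("p_mutation must name TSC1, TSC2 and none_identified", call. = FALSE)
  }
  structure(
    list(
      p_dysmature = p_dysmature,
      p_asd_given_dysmature = p_asd_given_dysmature,
      p_asd_given_mature = p_asd_given_mature,
      p_ied = p_ied, p_focal_slowing = p_focal_slowing,
      p_seizure = p_seizure,
      p_mutation = p_mutation[c("TSC1", "TSC2", "none_identified")],
      p_preventive = p_preventive, p_verbal = p_verbal,
      dq_mean_mature = dq_mean_mature,
      dq_mean_dysmature = dq_mean_dysmature, dq_sd = dq_sd,
      n_missing_outcome = as.integer(n_missing_outcome)
    ),
    class = "cohort_design"
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  pmin(hi, pmax(lo, x))
}

# ADOS-2 total score compatible with the target risk dichotomy (any-risk vs
# no-risk) and verbal status; categories follow classify_ados_risk().
draw_ados_score <- function(asd, verbal) {
  if (asd) {
    if (verbal) sample(8:20, 1) else sample(10:24, 1)
  } else {
    if (verbal) sample(0:7, 1) else sample(0:9, 1)
  }
}

#' Generate a synthetic TSC cohort
#'
#' Draws `n` subject records from a [cohort_design()]: dysmaturity is
#' Bernoulli(`p_dysmature`); 24-month ASD status follows the design's
#' conditional probabilities; ADOS-2 total scores are drawn consistently
#' with the risk category and verbal status; developmental quotients are
#' normal draws whose mean depends on dysmaturity. The composite flag
#' `abnormal_eeg` is TRUE iff any of IED, dysmature background, focal
#' slowing or an electrographic seizure is present, for every record.
#'
#' @param n number of subjects (at least 10).
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return a `data.frame`, one row per subject, with the columns documented
#'   in [cohort_schema()].
#' @examples
#' coh <- generate_cohort(63, cohort_design(), seed = 1)
#' table(coh$dysmature_eeg, coh$asd_24m, useNA = "ifany")
#' @export
generate_cohort <- function(n, design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.numeric(n) || n < 10) stop("n must be at least 10", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    dys <- runif(n) < design$p_dysmature
    p_asd <- ifelse(dys, design$p_asd_given_dysmature,
                    design$p_asd_given_mature)
    asd <- runif(n) < p_asd
    verbal <- runif(n) < design$p_verbal
    ados <- mapply(draw_ados_score, asd, verbal)
    ied <- runif(n) < design$p_ied
    focal <- runif(n) < design$p_focal_slowing
    seiz <- runif(n) < design$p_seizure
    dq_mean <- ifelse(dys, design$dq_mean_dysmature, design$dq_mean_mature)
    dq <- function() rtrunc_norm(n, dq_mean, design$dq_sd, 1, 160)
    coh <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      mutation = sample(names(design$p_mutation), n, replace = TRUE,
                        prob = design$p_mutation),
      treatment = ifelse(runif(n) < design$p_preventive,
                         "preventive", "conventional"),
      abnormal_eeg = ied | dys | focal | seiz,
      dysmature_eeg = dys,
      ied_present = ied,
      focal_slowing = focal,
      electrographic_seizure = seiz,
      asd_24m = asd,
      ados_score = as.integer(ados),
      verbal = verbal,
      dq_cognitive = dq(),
      dq_language = dq(),
      dq_motor = dq(),
      ga_first_eeg_weeks = round(rtrunc_norm(n, 42.6, 1.8, 37, 50), 1),
      chron_age_first_eeg_days = as.numeric(rpois(n, 30)),
      stringsAsFactors = FALSE
    )
    k <- design$n_missing_outcome
    if (k > 0) {
      miss <- sample.int(n, min(k, n))
      coh$asd_24m[miss] <- NA
      coh$ados_score[miss] <- NA_integer_
      coh$dq_language[miss] <- NA_real_
      coh$dq_motor[miss] <- NA_real_
    }
    validate_cohort(coh)
  })
}

#' Cohort table schema
#'
#' Column names and types of the per-subject cohort table, as written and
#' validated by [write_cohort()] / [read_cohort()]. Missing values use the
#' token `NA`.
#'
#' @return named character vector mapping column name to type.
#' @export
cohort_schema <- function() {
  c(
    subject_id = "character", mutation = "character",
    treatment = "character", abnormal_eeg = "logical",
    dysmature_eeg = "logical", ied_present = "logical",
    focal_slowing = "logical", electrographic_seizure = "logical",
    asd_24m = "logical", ados_score = "integer", verbal = "logical",
    dq_cognitive = "numeric", dq_language = "numeric", dq_motor = "numeric",
    ga_first_eeg_weeks = "numeric", chron_age_first_eeg_days = "numeric"
  )
}

#' Validate a cohort table
#'
#' Checks the schema, the categorical domains, the DQ range `[0, 160]` and
#' the composite invariant that `abnormal_eeg` equals the disjunction of
#' IED, dysmature background, focal slowing and electrographic seizures.
#'
#' @param coh a cohort `data.frame`.
#' @return the (unchanged) table, invisibly usable in a pipe; errors on any
#'   violation.
#' @export
validate_cohort <- function(coh) {
  schema <- cohort_schema()
  missing_cols <- setdiff(names(schema), names(coh))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(coh), names(schema))
  if (length(extra)) {
    stop("unknown cohort column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!all(coh$mutation %in% c("TSC1", "TSC2", "none_identified"))) {
    stop("mutation must be TSC1, TSC2 or none_identified", call. = FALSE)
  }
  if (!all(coh$treatment %in% c("preventive", "conventional"))) {
    stop("treatment must be preventive or conventional", call. = FALSE)
  }
  comp <- coh$ied_present | coh$dysmature_eeg | coh$focal_slowing |
    coh$electrographic_seizure
  if (!identical(as.logical(coh$abnormal_eeg), as.logical(comp))) {
    stop("abnormal_eeg must equal (IED | dysmature | focal slowing | seizure)",
         call. = FALSE)
  }
  dqs <- unlist(coh[c("dq_cognitive", "dq_language", "dq_motor")])
  dqs <- dqs[!is.na(dqs)]
  if (length(dqs) && (any(dqs < 0) || any(dqs > 160))) {
    stop("developmental quotients must lie in [0, 160]", call. = FALSE)
  }
  if (any(!is.na(coh$ados_score) & coh$ados_score < 0)) {
    stop("ados_score must be non-negative", call. = FALSE)
  }
  coh[names(schema)]
}
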