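# Seeded end-to-end pipeline: simulate -> features -> classify -> stats.

profile_for <- function(dysmature, eeg_cfg) {
  if (dysmature) {
    do.call(dysmature_profile, eeg_cfg$dysmature)
  } else {
    do.call(mature_profile, eeg_cfg$mature)
  }
}

#' Compute the per-subject feature matrix for a cohort
#'
#' Generates one synthetic recording per subject (profile chosen by the
#' subject's dysmaturity flag, per-subject seed derived from `seed`),
#' extracts the four feature families and aggregates them across channels
#' by the median.
#'
#' @param cohort cohort `data.frame` from [generate_cohort()].
#' @param config a `pipeline_config`.
#' @param seed integer base seed.
#' @return list with `X` (subjects x features matrix, rownames =
#'   subject_id) and `per_channel` (tidy data.frame: subject, feature,
#'   value).
#' @export
cohort_features <- function(cohort, config = default_config(), seed = 1L) {
  ecfg <- config$eeg
  fcfg <- do.call(feature_config, config$features)
  rows <- vector("list", nrow(cohort))
  tidy <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    prof <- profile_for(cohort$dysmature_eeg[i], ecfg)
    rec <- generate_eeg(prof, ecfg$duration_s, ecfg$fs, ecfg$channels,
                        seed = seed + i, subject_id = cohort$subject_id[i])
    fv <- extract_features(rec, fcfg)
    rows[[i]] <- aggregate_features(fv)
    tidy[[i]] <- data.frame(subject = cohort$subject_id[i],
                            feature = names(fv), value = unname(fv),
                            stringsAsFactors = FALSE)
  }
  X <- do.call(rbind, rows)
  rownames(X) <- cohort$subject_id
  list(X = X, per_channel = do.call(rbind, tidy))
}

#' Outcome statistics report for a cohort
#'
#' The clinical-statistics block of the pipeline: 2x2 association of each
#' EEG exposure (abnormal first EEG; dysmature background) with the binary
#' ASD outcome (odds ratio with 95\% CI, sensitivity, specificity, PPV,
#' NPV), univariable and multivariable (mutation + treatment) logistic
#' models, Mann-Whitney comparisons of the three developmental quotients
#' by dysmaturity, and linear models of transformed DQs on the dysmaturity
#' flag. Subjects missing the outcome are excluded with a logged count.
#'
#' @param cohort cohort `data.frame`.
#' @return list of class `stats_report`.
#' @export
cohort_stats <- function(cohort) {
  n_missing <- sum(is.na(cohort$asd_24m))
  if (n_missing > 0) {
    tq_log(sprintf("outcome missing for %d/%d subjects; excluded from outcome stats",
                   n_missing, nrow(cohort)))
  }
  cc <- cohort[!is.na(cohort$asd_24m), ]
  two_by_two <- function(exposure) {
    t <- table_2x2(cc[[exposure]], cc$asd_24m)
    or <- odds_ratio(t)
    m <- diagnostic_metrics(t)
    data.frame(
      exposure = exposure, a = t$a, b = t$b, c = t$c, d = t$d,
      or = or$or, ci_lower = or$ci_lower, ci_upper = or$ci_upper,
      sensitivity = m$sensitivity, specificity = m$specificity,
      ppv = m$ppv, npv = m$npv
    )
  }
  assoc <- rbind(two_by_two("abnormal_eeg"), two_by_two("dysmature_eeg"))

  safe_fit <- function(X, y) {
    tryCatch(logistic_fit(X, y), error = function(e) {
      tq_log("logistic model skipped: ", conditionMessage(e))
      structure(list(coefficients = NULL, converged = FALSE,
                     flag = conditionMessage(e)),
                class = "logistic_fit")
    })
  }
  uni <- safe_fit(cc["dysmature_eeg"], cc$asd_24m)
  multi <- safe_fit(
    data.frame(dysmature_eeg = cc$dysmature_eeg,
               tsc2 = cc$mutation == "TSC2",
               preventive = cc$treatment == "preventive"),
    cc$asd_24m
  )

  dq_tests <- do.call(rbind, lapply(
    c("dq_cognitive", "dq_language", "dq_motor"), function(dq) {
      v <- cohort[[dq]]
      g <- cohort$dysmature_eeg
      mw <- mann_whitney_u(v[g & !is.na(v)], v[!g & !is.na(v)])
      data.frame(dq = dq, U = mw$U, p = mw$p,
                 median_dysmature = median(v[g], na.rm = TRUE),
                 median_mature = median(v[!g], na.rm = TRUE))
    }
  ))

  # transformed-outcome linear models; transform choice per DQ domain
  dq_transform <- c(dq_cognitive = "log", dq_language = "log",
                    dq_motor = "reciprocal")
  dq_models <- lapply(names(dq_transform), function(dq) {
    v <- cohort[[dq]]
    keep <- !is.na(v)
    linear_model(data.frame(dysmature_eeg = cohort$dysmature_eeg[keep]),
                 transform_dq(v[keep], dq_transform[[dq]]))
  })
  names(dq_models) <- names(dq_transform)

  structure(
    list(association = assoc, logistic_univariable = uni,
         logistic_multivariable = multi, dq_mann_whitney = dq_tests,
         dq_models = dq_models, n_missing_outcome = n_missing,
         n_analysed = nrow(cc)),
    class = "stats_report"
  )
}

#' Run the full pipeline
#'
#' simulate -> features -> classify -> stats, fully determined by
#' `(config, seed)`. Writes, under `out_dir`: `cohort.csv`,
#' `features.csv` (wide, per subject) and `features_long.csv` (per
#' subject x channel x feature), `classifier_report.csv` (per feature
#' family: E(\%), AUC(\%)), `stats_report.csv` (2x2 associations), and
#' `summary.json` with the headline numbers, the seed and the resolved
#' config hash.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return list with `cohort`, `features`, `classifier`, `stats`,
#'   `summary`, invisibly.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = tempfile("tscqeeg_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  tq_log("pipeline start: seed ", seed, ", config ", hash)

  ccfg <- config$cohort
  design <- cohort_design(
    p_dysmature = ccfg$p_dysmature,
    p_asd_given_dysmature = ccfg$p_asd_given_dysmature,
    p_asd_given_mature = ccfg$p_asd_given_mature,
    n_missing_outcome = ccfg$n_missing_outcome
  )
  cohort <- generate_cohort(ccfg$n_subjects, design, seed = seed)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  feats <- cohort_features(cohort, config, seed = seed)
  write.csv(data.frame(subject_id = rownames(feats$X), feats$X,
                       check.names = FALSE),
            file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(feats$per_channel, file.path(out_dir, "features_long.csv"),
            row.names = FALSE)

  keep <- !is.na(cohort$asd_24m)
  clf <- tryCatch(
    classify_by_family(feats$X[keep, , drop = FALSE],
                       cohort$asd_24m[keep],
                       k_features = config$classifier$k_features,
                       seed = seed,
                       repetitions = config$classifier$repetitions),
    error = function(e) {
      tq_log("classifier stage skipped: ", conditionMessage(e))
      data.frame(family = c("power", "mse", "reeg_asym", "hurst", "combined"),
                 E_pct = NA_real_, auc_pct = NA_real_)
    }
  )
  write.csv(clf, file.path(out_dir, "classifier_report.csv"),
            row.names = FALSE)

  stats <- cohort_stats(cohort)
  write.csv(stats$association, file.path(out_dir, "stats_report.csv"),
            row.names = FALSE)

  summary <- list(
    seed = seed, config_hash = hash, n_subjects = nrow(cohort),
    n_outcome_analysed = stats$n_analysed,
    n_missing_outcome = stats$n_missing_outcome,
    association = stats$association,
    classifier = clf
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tq_log("pipeline done: ", out_dir)
  invisible(list(cohort = cohort, features = feats, classifier = clf,
                 stats = stats, summary = summary, out_dir = out_dir))
}
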