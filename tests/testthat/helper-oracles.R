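# Independent oracles and shared fixtures for the test suite.

# Naive O(n^2) sample entropy: template counting written independently of
# the package implementation (plain R loops, same Richman-Moorman
# convention: n - m templates for both lengths, self-matches excluded,
# Chebyshev distance).
sampen_oracle <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  tol <- r * sd(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= tol) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) NA_real_ else -log(A / B)
}

# Brute-force AUC by exhaustive pairwise comparison (ties count 1/2).
auc_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p-value by enumerating all rank
# assignments of the first sample (no ties assumed).
mw_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  ranks_all <- seq_len(n1 + n2)
  U_all <- apply(combos, 2, function(idx) sum(ranks_all[idx])) -
    n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# Wrap a bare matrix as an eeg_recording for feature-level tests.
as_recording <- function(data, fs, labels = paste0("C", seq_len(nrow(data)) * 2 - 1)) {
  structure(
    list(data = `dimnames<-`(data, list(labels, NULL)), fs = fs,
         channel_labels = labels, subject_id = "fixture", ga_weeks = 42,
         state = NULL, burst_onsets = NULL),
    class = "eeg_recording"
  )
}

sine_recording <- function(freq, fs = 128, duration = 60, amplitude = 1,
                           label = "C3") {
  t <- seq_len(duration * fs) / fs
  as_recording(matrix(amplitude * sin(2 * pi * freq * t), 1), fs, label)
}

# Cached 40 + 40 aggregated feature matrices from the default mature and
# dysmature profiles (2 central channels, 120 s at 64 Hz). Computed once
# per session; reused by the direction-of-effect and classifier checks.
.direction_cache <- new.env(parent = emptyenv())
direction_matrices <- function(n_per_group = 40) {
  key <- paste0("n", n_per_group)
  if (!is.null(.direction_cache[[key]])) return(.direction_cache[[key]])
  cfg <- feature_config()
  one <- function(prof, seed) {
    rec <- generate_eeg(prof, 120, 64, c("C3", "C4"), seed = seed)
    aggregate_features(extract_features(rec, cfg))
  }
  mat <- t(vapply(seq_len(n_per_group),
                  function(s) one(mature_profile(), s),
                  numeric(31)))
  dys <- t(vapply(seq_len(n_per_group),
                  function(s) one(dysmature_profile(), 10000 + s),
                  numeric(31)))
  .direction_cache[[key]] <- list(mature = mat, dysmature = dys)
  .direction_cache[[key]]
}
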