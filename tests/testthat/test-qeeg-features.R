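# The four quantitative feature families: band power, rEEG asymmetry,
# sample/multiscale entropy, Hurst exponent.

test_that("band power concentrates on in-band tones and normalises to 1", {
  rec <- sine_recording(6, fs = 128, duration = 60)
  bp <- band_power(rec)
  expect_gte(bp$rel_power[bp$band == "theta"], 0.99)
  expect_equal(sum(bp$rel_power), 1, tolerance = 1e-9)

  # amplitude 2 at 1 Hz vs amplitude 1 at 10 Hz: power ratio 4 (Parseval)
  t <- seq_len(60 * 128) / 128
  rec2 <- as_recording(matrix(2 * sin(2 * pi * 1 * t) +
                                sin(2 * pi * 10 * t), 1), 128)
  bp2 <- band_power(rec2)
  ratio <- bp2$rel_power[bp2$band == "delta1"] /
    bp2$rel_power[bp2$band == "alpha"]
  expect_equal(ratio, 4, tolerance = 0.05 / 4)

  # degenerate flat channel: undefined, not a spurious split
  rec3 <- as_recording(matrix(0, 1, 128 * 60), 128)
  expect_true(all(is.na(band_power(rec3)$rel_power)))

  # scaling invariance of relative power
  rec4 <- rec2; rec4$data <- rec4$data * 37
  expect_equal(band_power(rec4)$rel_power, bp2$rel_power, tolerance = 1e-12)
})

test_that("band power rejects invalid inputs", {
  short <- as_recording(matrix(rnorm(128 * 10), 1), 128)
  expect_error(band_power(short), "30 s")
  bad_bands <- data.frame(name = c("a", "b"), lo = c(1, 2), hi = c(3, 4))
  expect_error(validate_bands(bad_bands), "non-overlapping")
  slow_fs <- as_recording(matrix(rnorm(40 * 60), 1), 40)
  expect_error(band_power(slow_fs), "twice")
})

test_that("range_eeg matches closed-form and oracle percentiles", {
  fs <- 100
  # constant signal: all epochs zero, asymmetry undefined
  r0 <- range_eeg(rep(5, fs * 10), fs, window_s = 2)
  expect_true(all(r0$epochs == 0))
  expect_true(is.na(r0$asymmetry))
  expect_true(isTRUE(attr(r0$asymmetry, "undefined")))

  # sinusoid amplitude 50: every epoch peak-to-peak ~ 100
  t <- seq_len(fs * 20) / fs
  rs <- range_eeg(50 * sin(2 * pi * 2 * t), fs, window_s = 2)
  expect_true(all(abs(rs$epochs - 100) < 1))

  # right-skewed epoch distribution: positive asymmetry, percentile oracle
  set.seed(42)
  draws <- rexp(500)
  x <- rep(draws, each = fs) * rep(c(1, -1), length.out = fs * 500)
  rr <- range_eeg(x, fs, window_s = 1)
  q <- unname(quantile(rr$epochs, c(0.05, 0.5, 0.95)))
  a_oracle <- ((q[3] - q[2]) - (q[2] - q[1])) / (q[3] - q[1])
  expect_gt(rr$asymmetry, 0)
  expect_equal(rr$asymmetry, a_oracle, tolerance = 1e-12)

  # amplitude-scaling invariance; reflection flips the sign
  rr2 <- range_eeg(x * 10, fs, window_s = 1)
  expect_equal(rr2$asymmetry, rr$asymmetry, tolerance = 1e-9)
  A <- rr$epochs
  refl <- max(A) + min(A) - A   # reflect the epoch distribution
  qr <- unname(quantile(refl, c(0.05, 0.5, 0.95)))
  a_refl <- ((qr[3] - qr[2]) - (qr[2] - qr[1])) / (qr[3] - qr[1])
  expect_equal(a_refl, -rr$asymmetry, tolerance = 1e-9)

  expect_error(range_eeg(rnorm(50), fs, window_s = 2), "two rEEG epochs")
})

test_that("sample_entropy equals the naive oracle and behaves at the extremes", {
  set.seed(7)
  for (k in 1:10) {
    n <- sample(100:300, 1)
    x <- rnorm(n)
    expect_equal(as.numeric(sample_entropy(x)), sampen_oracle(x),
                 tolerance = 1e-12)
  }
  # strictly periodic, period <= m: perfectly predictable
  expect_lte(sample_entropy(rep(c(1, 2), 150), m = 2, r = 0.2), 0.01)
  # ordering destroys irregularity
  set.seed(8)
  z <- rnorm(300)
  expect_gt(as.numeric(sample_entropy(z)), as.numeric(sample_entropy(sort(z))))
  # sentinel on zero matches, never a silent Inf
  v <- sample_entropy(as.numeric(1:120), m = 2, r = 0.001)
  expect_true(is.na(v))
  expect_match(attr(v, "reason"), "match")
  expect_error(sample_entropy(rnorm(50)), "100")
})

test_that("multiscale entropy: definition at scale 1, length guard, noise decay", {
  set.seed(3)
  x <- rnorm(2000)
  mse <- multiscale_entropy(x, max_scale = 20)
  expect_identical(unname(mse[1]), as.numeric(sample_entropy(x)))
  expect_error(multiscale_entropy(rnorm(500), max_scale = 20), "2000")

  # fixed-tolerance curve of white noise decays on average with scale:
  # coarse-graining shrinks the variance relative to the fixed r
  curves <- vapply(1:8, function(s) {
    set.seed(s)
    multiscale_entropy(rnorm(20000), max_scale = 20, r_mode = "fixed")
  }, numeric(20))
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) < 0))
})

test_that("DFA Hurst estimates are affine-invariant and recover known exponents", {
  set.seed(21)
  x <- rnorm(2048)
  expect_equal(hurst_exponent(5 * x + 3), hurst_exponent(x),
               tolerance = 1e-9)
  expect_error(hurst_exponent(rnorm(100)), "512")

  h_wn <- mean(vapply(1:15, function(s) {
    set.seed(s); hurst_exponent(rnorm(8192))
  }, numeric(1)))
  expect_equal(h_wn, 0.5, tolerance = 0.05 / 0.5)

  h_fgn <- mean(vapply(1:15, function(s) {
    hurst_exponent(sim_fgn(8192, 0.8, s))
  }, numeric(1)))
  expect_equal(h_fgn, 0.8, tolerance = 0.07 / 0.8)
})

test_that("extract_features assembles the full named vector per channel", {
  cfg <- feature_config(mse_scales = 5, preprocess = FALSE)
  rec <- generate_eeg(mature_profile(), 60, 64, TEN_TWENTY_9, seed = 1)
  fv <- extract_features(rec, cfg)
  # 9 channels x (5 powers + 5 asymmetries + 5 scales + 1 Hurst)
  expect_length(fv, 9 * 16)
  expect_true(all(grepl("^(Fp1|Fp2|C3|C4|T3|T4|O1|O2|Cz)\\.", names(fv))))
  expect_setequal(unique(feature_family(names(fv))),
                  c("power", "reeg_asym", "mse", "hurst"))

  # degenerate channel: NA features, not silent zeros
  rec$data["Cz", ] <- 0
  fv0 <- extract_features(rec, cfg)
  expect_true(all(is.na(fv0[grepl("^Cz\\.", names(fv0))])))
  expect_false(anyNA(fv0[grepl("^C3\\.", names(fv0))]))

  # channel re-ordering leaves per-channel values unchanged
  rec2 <- rec
  ord <- rev(seq_len(nrow(rec$data)))
  rec2$data <- rec$data[ord, ]
  rec2$channel_labels <- rec$channel_labels[ord]
  fv_r <- extract_features(rec2, cfg)
  expect_equal(fv_r[names(fv0)], fv0, tolerance = 1e-12)
})

test_that("slow-delta persistence raises delta1 relative power (paired profiles)", {
  # paired seeds; band power only, single channel
  diffs <- vapply(1:20, function(s) {
    m <- generate_eeg(mature_profile(), 60, 64, "C3", seed = s)
    d <- generate_eeg(dysmature_profile(), 60, 64, "C3", seed = s)
    bp_m <- band_power(m); bp_d <- band_power(d)
    bp_d$rel_power[bp_d$band == "delta1"] -
      bp_m$rel_power[bp_m$band == "delta1"]
  }, numeric(1))
  # sign test: all/most pairs positive
  p <- binom.test(sum(diffs > 0), length(diffs), alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("aggregate_features takes channel medians and drops NA channels", {
  fv <- c(C3.hurst = 0.5, C4.hurst = 0.7, Cz.hurst = NA,
          C3.power.delta1 = 0.2, C4.power.delta1 = 0.4,
          Cz.power.delta1 = 0.6)
  agg <- aggregate_features(fv)
  expect_equal(unname(agg["hurst"]), 0.6)
  expect_equal(unname(agg["power.delta1"]), 0.4)
})
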