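make_psd <- function(freqs, power) {
  out <- tibble::tibble(freq_hz = freqs, power = power)
  attr(out, "resolution_hz") <- freqs[2] - freqs[1]
  attr(out, "n_bins") <- length(freqs)
  class(out) <- c("psd_estimate", class(out))
  out
}

test_that("Welch PSD locates tones and satisfies Parseval", {
  fs <- 10000
  t <- (0:1749) / fs
  tone <- sin(2 * pi * 100 * t)
  psd <- welch_psd(tone, fs)
  expect_equal(psd$freq_hz[which.max(psd$power)], 100,
               tolerance = attr(psd, "resolution_hz"))

  set.seed(11)
  x <- rnorm(10000, 0, 1.5)
  psd_n <- welch_psd(x, fs)
  integral <- sum(psd_n$power) * attr(psd_n, "resolution_hz")
  expect_equal(integral, var(x), tolerance = 0.02 * var(x))

  expect_true(all(welch_psd(numeric(1750), fs)$power == 0))

  # the T2 geometry: 8 segments of 389 samples; T1 falls back to 1 segment
  expect_identical(attr(welch_psd(numeric(1750), fs), "n_segments"), 8L)
  expect_identical(attr(welch_psd(numeric(150), fs), "n_segments"), 1L)
})

test_that("time-domain features obey the rectified-window contract", {
  w <- structure(list(window_id = "T1", fs = 10000, samples = rep(1, 150)),
                 class = "analysis_window")
  expect_equal(unlist(time_domain_features(w)), c(v_mean = 1, v_diff = 0))
  w$samples <- c(1, 0, 0, 0)
  expect_equal(unlist(time_domain_features(w)), c(v_mean = 0.25, v_diff = 0.75))
  w$samples <- c(0.5, 0.2)
  expect_error(time_domain_features(w), "max != 1")
})

test_that("spectral features match closed forms on degenerate spectra", {
  f <- seq(0, 500, by = 10)
  single <- numeric(length(f)); single[f == 100] <- 4
  sf <- spectral_features(make_psd(f, single))
  expect_equal(sf$f_mean, 100)
  expect_equal(sf$f_median, 100)
  expect_equal(sf$spectral_entropy, 0)
  expect_equal(sf$p_band, sf$p_total)
  expect_equal(sf$p_bandwidth, 10) # half-power crossings straddle the one bin

  flat <- spectral_features(make_psd(f, rep(2, length(f))))
  expect_equal(flat$spectral_entropy, 1)
  expect_equal(flat$f_mean, mean(f))
  expect_equal(flat$snr_db, 0)

  expect_error(spectral_features(make_psd(f, numeric(length(f)))), "Empty spectrum")
})

test_that("median frequency equals a brute-force cumulative-sum oracle", {
  set.seed(21)
  for (rep in 1:5) {
    f <- seq(0, 630, by = 10)
    p <- runif(64)
    got <- spectral_features(make_psd(f, p))$f_median

    # oracle: walk the cumulative sum; each bin's power occupies the interval
    # [f - 5, f + 5), interpolate inside the crossing bin
    total <- sum(p); cum <- 0; oracle <- NA
    for (i in seq_along(p)) {
      if (cum + p[i] >= total / 2) {
        oracle <- (f[i] - 5) + (total / 2 - cum) / p[i] * 10
        break
      }
      cum <- cum + p[i]
    }
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("spectral features are scale-invariant where they must be", {
  set.seed(31)
  f <- seq(0, 630, by = 10)
  p <- runif(64) + 0.1
  a <- spectral_features(make_psd(f, p))
  b <- spectral_features(make_psd(f, 7.3 * p))
  for (col in c("f_mean", "f_median", "p_bandwidth", "spectral_entropy", "snr_db")) {
    expect_equal(b[[col]], a[[col]], tolerance = 1e-12)
  }
  for (col in c("p_mean", "p_max", "p_band", "p_total")) {
    expect_equal(b[[col]], 7.3 * a[[col]], tolerance = 1e-12)
  }

  # translating a narrowband spectrum shifts f_mean and f_median by the shift
  narrow <- exp(-((f - 100) / 30)^2)
  sh <- 5 # bins of 10 Hz -> 50 Hz
  shifted <- c(rep(0, sh), narrow[1:(length(f) - sh)])
  a2 <- spectral_features(make_psd(f, narrow))
  b2 <- spectral_features(make_psd(f, shifted))
  expect_equal(b2$f_mean - a2$f_mean, 50, tolerance = 10)
  expect_equal(b2$f_median - a2$f_median, 50, tolerance = 10)
})

test_that("synthetic windows give v_mean + v_diff = 1 and faster T1 spectra", {
  p <- mean_profile()
  set.seed(41)
  sw <- synth_sweep(p, ce = 0)
  wins <- extract_windows(condition_sweep(sw$samples))
  f1 <- window_features(wins$T1)
  f2 <- window_features(wins$T2)
  expect_equal(f1$v_mean + f1$v_diff, 1, tolerance = 1e-12)
  expect_equal(f2$v_mean + f2$v_diff, 1, tolerance = 1e-12)
  expect_gt(f1$f_mean, f2$f_mean) # R1 window is the high-frequency one
  expect_true(f1$spectral_entropy >= 0 && f1$spectral_entropy <= 1)
  expect_lte(f1$p_band, f1$p_total)
  expect_lte(f1$f_median, 5000)
})

test_that("session feature tables have the canonical layout", {
  p <- mean_profile(noise_sd_uv = 2)
  s <- simulate_session(p)
  feats <- session_features(s)
  expect_setequal(unique(feats$window), c("T1", "T2"))
  expect_equal(nrow(feats), 2 * (nrow(s$sweeps) - 3))
  expect_true(all(c("patient_id", "stim_time_s", "ce_ug_ml", "arass",
                    "spectral_entropy") %in% names(feats)))
  # silent windows (abolished components, noise-free conditions) become NA rows
  p0 <- mean_profile(noise_sd_uv = 0)
  s0 <- simulate_session(p0)
  feats0 <- session_features(s0)
  t1_last <- feats0[feats0$window == "T1", ]
  expect_true(anyNA(t1_last$v_mean)) # post-abolition records are flagged NA
})
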