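test_that("high-pass filter behaves as designed", {
  hp <- butter_highpass(4, 20, 10000)
  expect_lt(abs(sum(hp$b) / sum(hp$a)), 1e-6) # DC fully rejected
  t <- (0:9999) / 10000
  s100 <- sin(2 * pi * 100 * t)
  gain <- sd(filtfilt(s100, hp$b, hp$a)) / sd(s100)
  expect_gt(gain, 0.99) # passband essentially untouched
  set.seed(5)
  x <- rnorm(10000, 0, 2)
  expect_equal(sd(filtfilt(x, hp$b, hp$a)), 2, tolerance = 0.05)
})

test_that("threshold draws honour the Table-1 calibration", {
  # zero-SD population: thresholds are exactly the cohort means
  p <- mean_profile()
  expect_equal(c(p$ce_lor2, p$ce_lor1, p$ce_lorp), c(1.45, 2.99, 4.22))

  # unorderable zero-SD means exhaust the redraw cap
  bad <- degenerate_population()
  bad$ce_mean <- c(lor2 = 4.22, lor1 = 2.99, lorp = 1.45)
  expect_error(draw_ce_thresholds(bad), "degenerate")
})

test_that("the raw rejection rate matches an independent Monte-Carlo oracle", {
  pop <- default_population()
  set.seed(101)
  n <- 4000
  attempts <- vapply(seq_len(n), function(i) draw_ce_thresholds(pop)$attempts,
                     numeric(1))
  observed_reject <- 1 - n / sum(attempts)

  # independent oracle: same factor construction with per-component
  # floor-truncated idiosyncratic deviates, straight vector code
  set.seed(2024)
  N <- 2e5
  rho <- pop$ce_correlation
  z0 <- rnorm(N)
  draw <- function(k) {
    lo <- ((pop$ce_floor - pop$ce_mean[[k]]) / pop$ce_sd[[k]] -
             sqrt(rho) * z0) / sqrt(1 - rho)
    plo <- pnorm(lo)
    zk <- qnorm(plo + runif(N) * (1 - plo))
    zk[!is.finite(zk)] <- lo[!is.finite(zk)]
    pop$ce_mean[[k]] + pop$ce_sd[[k]] * (sqrt(rho) * z0 + sqrt(1 - rho) * zk)
  }
  x2 <- draw("lor2"); x1 <- draw("lor1"); xp <- draw("lorp")
  oracle_reject <- 1 - mean(x2 < x1 & x1 < xp)
  expect_lt(abs(observed_reject - oracle_reject), 0.01)
})

test_that("component scale and the aRASS staircase are calibrated and monotone", {
  expect_equal(component_scale(0, 2), 1)
  expect_equal(component_scale(2, 2), 0)
  expect_equal(component_scale(1, 2, gamma = 1), 0.5)
  expect_error(component_scale(-1, 2), ">= 0")
  ces <- seq(0, 6, by = 0.05)
  expect_true(all(diff(component_scale(ces, 2.5, gamma = 2)) <= 0))

  expect_equal(arass_at(0, 4.22), 0)
  expect_equal(arass_at(c(4.22, 5), 4.22), c(-5, -5))
  # Table-1 medians: aRASS 0 at the mean LOR2 Ce, -2 at the mean LOR1 Ce
  expect_equal(arass_at(1.45, 4.22), 0)
  expect_equal(arass_at(2.99, 4.22), -2)
  expect_true(all(diff(arass_at(ces, 4.22)) <= 0))
})

test_that("synthetic sweeps have the stated time-frequency structure", {
  p <- mean_profile()

  # fully suppressed, noise-free sweep is exactly zero
  sw0 <- synth_sweep(p, ce = 10)
  expect_true(all(sw0$samples == 0))

  # burst energy confined to the component windows: synthesise each
  # component alone and compare in-window with total energy
  set.seed(3)
  t_ms <- (0:1999) / 10
  comps <- reflex_components()
  r1c <- comps; r1c$baseline_amp_uv[r1c$name == "R2"] <- 0
  r2c <- comps; r2c$baseline_amp_uv[r2c$name == "R1"] <- 0
  r1 <- synth_sweep(p, ce = 0, components = r1c)
  r2 <- synth_sweep(p, ce = 0, components = r2c)
  expect_gt(sum(r1$samples[t_ms >= 10 & t_ms < 25]^2) / sum(r1$samples^2), 0.99)
  expect_gt(sum(r2$samples[t_ms >= 25]^2) / sum(r2$samples^2), 0.99)

  # mean frequency of the R2 window near the 60 Hz carrier (independent FFT)
  fm <- fft_mean_freq(r2$samples[t_ms >= 25], 10000)
  expect_lt(abs(fm - 60), 10)
  # and the R1 window is the faster one
  fm1 <- fft_mean_freq(r1$samples[t_ms >= 10 & t_ms < 25], 10000)
  expect_gt(fm1, fm)
})

test_that("sessions reproduce bit-identically and match the study timing", {
  p <- mean_profile()
  s <- simulate_session(p)

  truth <- s$truth
  expect_equal(truth$endpoint, c("lor2", "lor1", "lorp"))
  expect_true(all(diff(truth$time_s) > 0)) # LOR2 < LOR1 < LORP in time
  expect_equal(truth$ce_ug_ml[3], p$ce_lorp, tolerance = 0.25) # staircase grid

  # emergent cross-check of the PK model against the cohort mean LORP time
  expect_lt(abs(truth$time_s[3] - 147.84) / 147.84, 0.25)

  # 6-s cadence, at least 4 baseline sweeps, nonincreasing aRASS
  expect_true(all(diff(s$sedation$time_s) == 6))
  expect_gte(sum(s$sweeps$stim_time_s < 0), 4)
  expect_true(all(diff(s$sedation$arass) <= 0))

  # reproducibility: identical seed, identical session
  p2 <- draw_patient(seed = 77)
  a <- simulate_session(p2)
  b <- simulate_session(p2)
  expect_identical(a$sweeps$samples, b$sweeps$samples)
  expect_identical(a$truth, b$truth)

  # R2 abolished strictly before R1, before LORP, in noisy sessions too
  p3 <- draw_patient(seed = 5)
  s3 <- simulate_session(p3)
  tr3 <- s3$truth
  expect_true(tr3$time_s[1] < tr3$time_s[2] && tr3$time_s[2] < tr3$time_s[3])
})
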