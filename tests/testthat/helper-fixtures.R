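# Shared fixtures for the test suite. Everything is generated in code.

# Population with zero between-patient variability: thresholds exactly at
# the calibrated means, demographics exactly at the cohort means.
degenerate_population <- function(noise_sd_uv = 0) {
  pop <- default_population()
  pop$ce_sd[] <- 0
  pop$age_sd <- 0
  pop$weight_sd <- 0
  pop$height_sd <- 0
  pop$p_female <- 1
  pop$noise_sd_uv <- noise_sd_uv
  pop
}

mean_profile <- function(noise_sd_uv = 0, seed = 1) {
  draw_patient(degenerate_population(noise_sd_uv), seed = seed)
}

# Brute-force Pk oracle: exhaustive enumeration over all unordered pairs.
pk_oracle <- function(indicator, cls) {
  n <- length(indicator)
  C <- D <- T <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (cls[i] == cls[j]) next
      s <- sign(cls[j] - cls[i]) * sign(indicator[j] - indicator[i])
      if (s > 0) C <- C + 1
      else if (s < 0) D <- D + 1
      else T <- T + 1
    }
  }
  list(pk = (C + T / 2) / (C + D + T), C = C, D = D, T = T)
}

# Independent delete-one jackknife built on the brute-force oracle.
pk_jackknife_oracle <- function(indicator, cls) {
  n <- length(indicator)
  reps <- vapply(seq_len(n), function(i) {
    pk_oracle(indicator[-i], cls[-i])$pk
  }, numeric(1))
  sqrt((n - 1) / n * sum((reps - mean(reps))^2))
}

# Simulate multinomial-logit data from known coefficients.
# B: (K-1) x (p+1) matrix, reference class first in `levels`.
sim_mlr_data <- function(n, B, levels = c(0, -1, -2, -3, -4, -5), seed = 1) {
  set.seed(seed)
  p <- ncol(B) - 1
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  eta <- cbind(1, X) %*% t(B)
  prob <- cbind(1, exp(eta)) / (1 + rowSums(exp(eta)))
  y <- apply(prob, 1, function(pr) sample(levels, 1, prob = pr))
  tibble::as_tibble(as.data.frame(X)) |> dplyr::mutate(arass = y)
}

# Plain single-periodogram mean frequency, independent of welch_psd().
fft_mean_freq <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq_len(n %/% 2 + 1)
  p <- Mod(X[half])^2
  f <- (half - 1) * fs / n
  sum(f * p) / sum(p)
}
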