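#' Welch power spectral density estimate
#'
#' One-sided PSD from Hamming-windowed, 50%-overlapped segments, averaged
#' over segments and scaled so that the PSD integrates (sum of power times
#' frequency resolution) to the signal's variance. Long windows are split
#' into `n_segments` segments (the T2 window, 1750 samples, gives 8
#' segments of 389 samples); windows too short for that (the T1 window, 150
#' samples) are analysed as a single Hamming-windowed periodogram with
#' `nfft` at least 256.
#'
#' @param x Numeric signal (an analysis window's samples).
#' @param fs Sampling rate, Hz.
#' @param n_segments Target number of segments for the long-window branch.
#' @param min_segment Minimum segment length for Welch averaging; shorter
#'   windows fall back to one periodogram.
#' @param nfft FFT length; default next power of two at or above the
#'   segment length (at least 256 for the single-periodogram branch).
#' @return A tibble of class `psd_estimate` with columns `freq_hz` and
#'   `power`, and attributes `resolution_hz`, `n_bins`, `n_segments`.
#' @export
welch_psd <- function(x, fs, n_segments = 8, min_segment = 64, nfft = NULL) {
  n <- length(x)
  if (n < 2) abort("Signal too short for a PSD estimate.")
  seg_len <- ceiling(n / (n_segments / 2 + 0.5)) # 50% overlap packing
  if (seg_len >= min_segment && n >= 2 * min_segment) {
    step <- if (n_segments > 1) floor((n - seg_len) / (n_segments - 1)) else 0
    starts <- 1 + step * seq(0, n_segments - 1)
  } else {
    seg_len <- n
    starts <- 1
  }
  if (is.null(nfft)) nfft <- max(256, 2^ceiling(log2(seg_len)))
  if (nfft < seg_len) abort("`nfft` must be at least the segment length.")

  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)) # Hamming
  u <- sum(w^2)
  n_one <- nfft %/% 2 + 1
  acc <- numeric(n_one)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * w
    X <- fft(c(seg, rep(0, nfft - seg_len)))
    p <- Mod(X[seq_len(n_one)])^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist for even nfft)
    dbl <- rep(2, n_one); dbl[1] <- 1
    if (nfft %% 2 == 0) dbl[n_one] <- 1
    acc <- acc + p * dbl
  }
  power <- acc / length(starts)
  out <- tibble(freq_hz = seq(0, fs / 2, length.out = n_one), power = power)
  attr(out, "resolution_hz") <- fs / nfft
  attr(out, "n_bins") <- n_one
  attr(out, "n_segments") <- length(starts)
  class(out) <- c("psd_estimate", class(out))
  out
}

#' Time-domain features of a rectified, normalised window
#'
#' The mean amplitude `v_mean` of the rectified/normalised window (whose
#' maximum is 1 by construction) and `v_diff = 1 - v_mean`, the difference
#' between the maximum and the mean amplitude.
#'
#' @param window A rectified/normalised `analysis_window`
#'   (see [rectify_normalize()]).
#' @return A one-row tibble with `v_mean` and `v_diff`.
#' @export
time_domain_features <- function(window) {
  if (abs(max(window$samples) - 1) > 1e-9) {
    abort("Window is not rectified/normalised (max != 1); apply rectify_normalize() first.")
  }
  v_mean <- mean(window$samples)
  tibble(v_mean = v_mean, v_diff = 1 - v_mean)
}

interp_at <- function(fx, fy, x0) {
  approx(fx, fy, xout = x0, rule = 2)$y
}

#' Frequency-domain features of a PSD estimate
#'
#' The eleven spectral features of the analysis pipeline, computed on the
#' linear-power PSD: mean and maximum power, mean frequency (power-weighted
#' mean), power at the mean frequency (linear interpolation), median
#' frequency (equal-area split, interpolated within the crossing bin), band
#' power over `band`, total power, total power over median frequency, SNR
#' in dB against a median-bin noise floor, half-power bandwidth (span
#' between the outermost crossings of half the maximum, interpolated), and
#' Shannon spectral entropy normalised to `[0, 1]` by `log2(n_bins)`.
#'
#' @param psd A `psd_estimate` tibble from [welch_psd()].
#' @param band Frequency band for `p_band`, Hz (default 30-120).
#' @return A one-row tibble with columns `p_mean`, `p_max`, `f_mean`,
#'   `p_fmean`, `f_median`, `p_band`, `p_total`, `p_total_over_fmedian`,
#'   `snr_db`, `p_bandwidth`, `spectral_entropy`.
#' @export
spectral_features <- function(psd, band = c(30, 120)) {
  f <- psd$freq_hz
  p <- psd$power
  total <- sum(p)
  if (total <= 0) abort("Empty spectrum: total power is zero.")
  n_bins <- length(p)

  p_mean <- mean(p)
  p_max <- max(p)
  f_mean <- sum(f * p) / total
  p_fmean <- interp_at(f, p, f_mean)

  cum <- cumsum(p)
  half <- total / 2
  i <- which(cum >= half)[1]
  # equal-area split with each bin's power spread over its frequency bin
  # [f - df/2, f + df/2); linear interpolation inside the crossing bin, so a
  # single-bin spectrum has its median exactly at that bin's frequency
  df <- if (length(f) > 1) f[2] - f[1] else 0
  cum_before <- if (i == 1) 0 else cum[i - 1]
  f_median <- f[i] - df / 2 + (half - cum_before) / p[i] * df

  p_band <- sum(p[f >= band[1] & f <= band[2]])
  snr_db <- 10 * log10(total / (n_bins * median(p)))

  # half-power bandwidth: outermost crossings of p_max / 2
  hp <- p_max / 2
  above <- which(p >= hp)
  lo_i <- above[1]
  hi_i <- above[length(above)]
  f_lo <- if (lo_i == 1) f[1] else {
    f[lo_i - 1] + (hp - p[lo_i - 1]) / (p[lo_i] - p[lo_i - 1]) * (f[lo_i] - f[lo_i - 1])
  }
  f_hi <- if (hi_i == n_bins) f[n_bins] else {
    f[hi_i] + (p[hi_i] - hp) / (p[hi_i] - p[hi_i + 1]) * (f[hi_i + 1] - f[hi_i])
  }
  p_bandwidth <- f_hi - f_lo

  q <- p / total
  nz <- q > 0
  spectral_entropy <- -sum(q[nz] * log2(q[nz])) / log2(n_bins)

  tibble(
    p_mean = p_mean, p_max = p_max, f_mean = f_mean, p_fmean = p_fmean,
    f_median = f_median, p_band = p_band, p_total = total,
    p_total_over_fmedian = total / f_median, snr_db = snr_db,
    p_bandwidth = p_bandwidth, spectral_entropy = spectral_entropy
  )
}

#' All features of one analysis window
#'
#' Time-domain features are computed on the rectified/normalised window;
#' frequency-domain features on the Welch PSD of the un-rectified window
#' (rectification distorts the spectrum). A silent window (all zeros)
#' yields a row of `NA` features rather than an error, flagging component
#' absence to downstream code.
#'
#' @param window An `analysis_window` (conditioned, un-rectified).
#' @param band Band for `p_band`, Hz.
#' @return A one-row tibble: `window`, then the 13 features.
#' @export
window_features <- function(window, band = c(30, 120)) {
  na_row <- tibble(
    window = window$window_id, v_mean = NA_real_, v_diff = NA_real_,
    p_mean = NA_real_, p_max = NA_real_, f_mean = NA_real_, p_fmean = NA_real_,
    f_median = NA_real_, p_band = NA_real_, p_total = NA_real_,
    p_total_over_fmedian = NA_real_, snr_db = NA_real_, p_bandwidth = NA_real_,
    spectral_entropy = NA_real_
  )
  if (max(abs(window$samples)) == 0) return(na_row)
  td <- time_domain_features(rectify_normalize(window))
  psd <- welch_psd(window$samples, window$fs)
  sf <- spectral_features(psd, band)
  dplyr::bind_cols(tibble(window = window$window_id), td, sf)
}

#' Feature table of one session
#'
#' Applies the full conditioning pipeline (DC removal, linear detrend,
#' sliding 4-sweep average, T1/T2 windowing) and extracts the 13 features
#' of every averaged record.
#'
#' @param session A `blink_session` from [simulate_session()].
#' @param band Band for `p_band`, Hz.
#' @return A tibble, one row per (averaged record, window), with columns
#'   `patient_id`, `stim_time_s`, `ce_ug_ml`, `arass`, `window` and the 13
#'   feature columns.
#' @export
session_features <- function(session, band = c(30, 120)) {
  avg <- rolling_average_sweeps(session$sweeps)
  sed <- session$sedation
  rows <- lapply(seq_len(nrow(avg)), function(i) {
    cond <- condition_sweep(avg$samples[[i]])
    wins <- extract_windows(cond, avg$fs[i])
    feat <- dplyr::bind_rows(window_features(wins$T1, band),
                             window_features(wins$T2, band))
    idx <- which(abs(sed$time_s - avg$stim_time_s[i]) < 1e-9)
    dplyr::bind_cols(
      tibble(patient_id = session$profile$patient_id,
             stim_time_s = avg$stim_time_s[i],
             ce_ug_ml = avg$true_ce[i],
             arass = sed$arass[idx[1]]),
      feat
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a feature table as delimited text
#'
#' Columns are written in the canonical order. All powers are in linear
#' units except `snr_db` (decibels).
#'
#' @param features A feature tibble from [session_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  cols <- c("patient_id", "stim_time_s", "ce_ug_ml", "arass", "window",
            "v_mean", "v_diff", "p_mean", "p_max", "f_mean", "p_fmean",
            "f_median", "p_band", "p_total", "p_total_over_fmedian",
            "snr_db", "p_bandwidth", "spectral_entropy")
  readr::write_csv(features[, cols], path)
  invisible(path)
}
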