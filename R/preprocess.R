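#' Remove the DC component of a signal
#'
#' Subtracts the mean amplitude, leaving a zero-mean signal.
#'
#' @param x Numeric vector of amplitudes.
#' @return Zero-mean numeric vector.
#' @export
remove_dc <- function(x) {
  if (!length(x)) abort("Cannot remove DC from an empty signal.")
  x - mean(x)
}

#' Remove the best straight-line fit
#'
#' Subtracts the least-squares linear trend (slope and intercept) from the
#' signal.
#'
#' @param x Numeric vector of amplitudes (length >= 2).
#' @return Detrended numeric vector.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2) abort("Need at least 2 samples to detrend.")
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc^2)
  x - mean(x) - slope * tc
}

#' Average four consecutive sweeps
#'
#' Pointwise arithmetic mean of exactly four sweeps with identical sampling
#' rate and length. The averaged record keeps the stimulus time of the last
#' (most recent) sweep and the mean of the four true Ce values.
#'
#' @param sweeps A list of 4 sweep lists (as produced by [synth_sweep()] or
#'   a session's `sweeps` rows).
#' @return One averaged sweep list.
#' @export
average_sweeps <- function(sweeps) {
  if (length(sweeps) != 4) abort("Exactly 4 sweeps are required for averaging.")
  fs <- vapply(sweeps, `[[`, numeric(1), "fs")
  len <- vapply(sweeps, function(s) length(s$samples), integer(1))
  if (length(unique(fs)) != 1 || length(unique(len)) != 1) {
    abort("Sweeps to be averaged must share sampling rate and length.")
  }
  samples <- Reduce(`+`, lapply(sweeps, `[[`, "samples")) / 4
  list(
    stim_time_s = sweeps[[4]]$stim_time_s,
    fs = fs[1],
    true_ce = mean(vapply(sweeps, `[[`, numeric(1), "true_ce")),
    samples = samples,
    constituent_times = vapply(sweeps, `[[`, numeric(1), "stim_time_s")
  )
}

#' Sliding 4-sweep averages of a session
#'
#' Applies [average_sweeps()] to a sliding window of the 4 most recent
#' sweeps, advancing one stimulus at a time, so each stimulus from the 4th
#' onward yields one averaged record (preserving the 6-s cadence).
#'
#' @param sweeps A sweeps tibble (columns `stim_time_s`, `true_ce`, `fs`,
#'   list-column `samples`), e.g. a session's `sweeps`.
#' @return A tibble of averaged records: `stim_time_s` (of the most recent
#'   constituent), `first_stim_time_s` (earliest constituent), `true_ce`
#'   (mean of four), `fs`, list-column `samples`.
#' @export
rolling_average_sweeps <- function(sweeps) {
  n <- nrow(sweeps)
  if (n < 4) abort("Need at least 4 sweeps for a sliding 4-sweep average.")
  rows <- lapply(4:n, function(i) {
    block <- lapply((i - 3):i, function(j) {
      list(stim_time_s = sweeps$stim_time_s[j], fs = sweeps$fs[j],
           true_ce = sweeps$true_ce[j], samples = sweeps$samples[[j]])
    })
    avg <- average_sweeps(block)
    tibble(stim_time_s = avg$stim_time_s,
           first_stim_time_s = avg$constituent_times[1],
           true_ce = avg$true_ce, fs = avg$fs, samples = list(avg$samples))
  })
  dplyr::bind_rows(rows)
}

#' Extract the T1 and T2 analysis windows
#'
#' Splits a 2000-sample, 10-kHz sweep into the two half-open analysis
#' windows: T1 = \[10, 25) ms (150 samples, where R1 is expected) and
#' T2 = \[25, 200) ms (1750 samples, where R2 is expected). Sample k
#' (0-based) is taken to occur at k/fs seconds, so the 25-ms boundary
#' sample belongs to T2.
#'
#' @param samples Numeric vector of 2000 amplitudes.
#' @param fs Sampling rate, Hz (must be 10000).
#' @return A named list of two `analysis_window` lists (`T1`, `T2`), each
#'   with `window_id`, `t_start_ms`, `t_end_ms`, `fs`, `samples`.
#' @export
extract_windows <- function(samples, fs = 10000) {
  if (fs != 10000 || length(samples) != 2000) {
    abort(sprintf(
      "Expected a 2000-sample sweep at 10 kHz; got %d samples at %g Hz.",
      length(samples), fs))
  }
  win <- function(id, lo_ms, hi_ms) {
    idx <- seq.int(lo_ms * fs / 1000 + 1, hi_ms * fs / 1000) # half-open [lo, hi)
    structure(list(window_id = id, t_start_ms = lo_ms, t_end_ms = hi_ms,
                   fs = fs, samples = samples[idx]),
              class = "analysis_window")
  }
  list(T1 = win("T1", 10, 25), T2 = win("T2", 25, 200))
}

#' Rectify and normalise an analysis window
#'
#' Absolute value divided by its maximum, yielding samples in `[0, 1]` with
#' maximum exactly 1. Applied only on the time-domain branch of the
#' pipeline; spectral features use the un-rectified window.
#'
#' @param window An `analysis_window` list from [extract_windows()].
#' @return The window with rectified/normalised samples.
#' @export
rectify_normalize <- function(window) {
  m <- max(abs(window$samples))
  if (m == 0) {
    abort(sprintf("Silent window %s: all samples are zero.", window$window_id))
  }
  window$samples <- abs(window$samples) / m
  window
}

#' Condition a sweep for analysis
#'
#' DC removal followed by linear detrending, the fixed conditioning order of
#' the pipeline.
#'
#' @param samples Numeric vector of amplitudes.
#' @return Conditioned numeric vector.
#' @export
condition_sweep <- function(samples) {
  detrend_linear(remove_dc(samples))
}
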