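#' Is a reflex component present in an analysis window?
#'
#' Automatic stand-in for expert marking: a component is called present
#' when the maximum absolute amplitude in its analysis window exceeds
#' `baseline mean + k * baseline SD`, with the baseline taken from the
#' pre-R1 0-9 ms segment of the same (averaged) sweep. With `k = "auto"`
#' the multiplier is calibrated to the window length through the normal
#' extreme-value bound `k = qnorm(1 - alpha / (2 m))` (`m` samples in the
#' window), holding the per-window false-positive rate near `alpha`
#' regardless of window size; a fixed numeric `k` is also accepted.
#'
#' An absolute amplitude floor (`floor_uv`) keeps the criterion meaningful
#' on noise-free synthetic sweeps, where the baseline SD collapses to
#' numerical residue: a deflection must exceed both the statistical
#' threshold and the floor. A zero-variance baseline with a nonzero
#' constant value has no usable noise reference and raises an error; an
#' identically zero baseline simply leaves the floor as the threshold.
#'
#' @param samples Conditioned sweep samples (2000 at 10 kHz).
#' @param window `"T1"` (R1) or `"T2"` (R2).
#' @param fs Sampling rate, Hz.
#' @param k Threshold multiplier, or `"auto"`.
#' @param alpha Per-window false-positive rate for `k = "auto"`.
#' @param baseline_ms Baseline segment, ms (default 0-9, before R1).
#' @param floor_uv Absolute detection floor, µV.
#' @return Logical.
#' @export
component_present <- function(samples, window = c("T2", "T1"), fs = 10000,
                              k = "auto", alpha = 1e-3, baseline_ms = c(0, 9),
                              floor_uv = 0.005) {
  window <- match.arg(window)
  idx <- seq.int(baseline_ms[1] * fs / 1000 + 1, baseline_ms[2] * fs / 1000)
  baseline <- samples[idx]
  win <- extract_windows(samples, fs)[[window]]
  m <- length(win$samples)
  bsd <- sd(baseline)
  bmean <- mean(baseline)
  if (bsd == 0 && any(baseline != 0)) {
    abort("Zero-variance, nonzero baseline: no usable noise reference.")
  }
  k_eff <- if (identical(k, "auto")) stats::qnorm(1 - alpha / (2 * m)) else k
  max(abs(win$samples)) > max(bmean + k_eff * bsd, floor_uv)
}

session_ce_at <- function(session, t) {
  out <- approx(session$trajectory$time_s, session$trajectory$ce_ug_ml,
                xout = pmax(t, 0), rule = 2)$y
  out[t < 0] <- 0
  out
}

#' Detect the three loss-of-response endpoints of a session
#'
#' Runs the conditioning pipeline and the component-presence criterion on
#' every sliding 4-sweep average (R1 in the T1 window, R2 in T2). The loss
#' of a component is bracketed between the earliest constituent stimulus of
#' the last averaged record showing the component (the latest stimulus that
#' is guaranteed to have contributed a detectable component) and the next
#' stimulus; the reported endpoint is the bracket midpoint, with Ce read
#' from the concentration trajectory there. Loss of responsiveness is
#' bracketed the same way between the last record above -5 and the first
#' aRASS -5 sedation record.
#'
#' @param session A `blink_session`.
#' @param k,alpha Presence-criterion controls, see [component_present()].
#' @return A one-row tibble: `patient_id`, `lor2_time_s`, `lor2_ce`,
#'   `lor1_time_s`, `lor1_ce`, `lorp_time_s`, `lorp_ce`, `arass_at_lor2`,
#'   `arass_at_lor1`.
#' @export
detect_endpoints <- function(session, k = "auto", alpha = 1e-3) {
  avg <- rolling_average_sweeps(session$sweeps)
  isi <- session$isi_s
  sed <- session$sedation

  presence <- function(window) {
    vapply(seq_len(nrow(avg)), function(i) {
      component_present(condition_sweep(avg$samples[[i]]), window,
                        avg$fs[i], k = k, alpha = alpha)
    }, logical(1))
  }
  pres_r1 <- presence("T1")
  pres_r2 <- presence("T2")
  if (!pres_r1[1] || !pres_r2[1]) {
    abort("No baseline reflex: a component is absent from the first averaged record.")
  }

  # a real component contributes to >= 4 consecutive sliding averages, so an
  # isolated single-record positive is discounted as a noise artefact
  last_sustained <- function(pres, min_run = 2) {
    r <- rle(pres)
    ends <- cumsum(r$lengths)
    ok <- r$values & r$lengths >= min_run
    if (any(ok)) return(ends[max(which(ok))])
    max(which(pres))
  }

  component_endpoint <- function(pres) {
    j <- last_sustained(pres)
    last_seen <- avg$first_stim_time_s[j]
    mid <- last_seen + isi / 2
    sed_idx <- which(abs(sed$time_s - last_seen) < 1e-9)[1]
    list(time = mid, ce = session_ce_at(session, mid), arass = sed$arass[sed_idx])
  }
  lor2 <- component_endpoint(pres_r2)
  lor1 <- component_endpoint(pres_r1)

  i5 <- which(sed$arass == -5)[1]
  if (is.na(i5)) abort("The session never reaches aRASS -5; LORP undetectable.")
  lorp_mid <- sed$time_s[i5] - isi / 2
  tibble(
    patient_id = session$profile$patient_id,
    lor2_time_s = lor2$time, lor2_ce = lor2$ce,
    lor1_time_s = lor1$time, lor1_ce = lor1$ce,
    lorp_time_s = lorp_mid, lorp_ce = session_ce_at(session, lorp_mid),
    arass_at_lor2 = lor2$arass, arass_at_lor1 = lor1$arass
  )
}

paired_compare <- function(x, y, label) {
  d <- y - x
  if (sd(d) == 0) {
    return(tibble(comparison = label, test = "degenerate (zero-variance differences)",
                  statistic = NA_real_, p_value = NA_real_,
                  mean_difference = mean(d)))
  }
  normal <- suppressWarnings(ks.test(d, "pnorm", mean(d), sd(d))$p.value) > 0.05
  if (normal) {
    tt <- t.test(y, x, paired = TRUE)
    tibble(comparison = label, test = "paired t",
           statistic = unname(tt$statistic), p_value = tt$p.value,
           mean_difference = mean(d))
  } else {
    wt <- suppressWarnings(wilcox.test(y, x, paired = TRUE, exact = FALSE))
    tibble(comparison = label, test = "Wilcoxon signed-rank",
           statistic = unname(wt$statistic), p_value = wt$p.value,
           mean_difference = mean(d))
  }
}

#' Cohort summary of detected endpoints
#'
#' Mean and SD of endpoint times and Ce, median \[min, max\] of the aRASS
#' scores at loss of R2 and R1, the mean within-patient Ce difference
#' between LORP and LOR1, and paired comparisons (paired t or Wilcoxon
#' signed-rank, chosen by a Kolmogorov-Smirnov normality pre-test on the
#' differences) of Ce at LORP vs LOR1 and of the three endpoint times.
#'
#' @param records A tibble of endpoint records from [detect_endpoints()].
#' @return A list of class `cohort_summary` with elements `endpoints`,
#'   `comparisons` and `n`.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) < 3) abort("Cohort summaries need at least 3 records.")
  r <- records
  arass_cell <- function(x) {
    c(median = unname(median(x)), min = min(x), max = max(x))
  }
  a2 <- arass_cell(r$arass_at_lor2)
  a1 <- arass_cell(r$arass_at_lor1)
  endpoints <- tibble(
    endpoint = c("LOR2", "LOR1", "LORP"),
    n = nrow(r),
    time_mean_s = c(mean(r$lor2_time_s), mean(r$lor1_time_s), mean(r$lorp_time_s)),
    time_sd_s = c(sd(r$lor2_time_s), sd(r$lor1_time_s), sd(r$lorp_time_s)),
    ce_mean = c(mean(r$lor2_ce), mean(r$lor1_ce), mean(r$lorp_ce)),
    ce_sd = c(sd(r$lor2_ce), sd(r$lor1_ce), sd(r$lorp_ce)),
    arass_median = unname(c(a2["median"], a1["median"], -5)),
    arass_min = unname(c(a2["min"], a1["min"], -5)),
    arass_max = unname(c(a2["max"], a1["max"], -5))
  )
  comparisons <- dplyr::bind_rows(
    paired_compare(r$lor1_ce, r$lorp_ce, "Ce: LORP vs LOR1"),
    paired_compare(r$lor2_time_s, r$lor1_time_s, "time: LOR1 vs LOR2"),
    paired_compare(r$lor1_time_s, r$lorp_time_s, "time: LORP vs LOR1"),
    paired_compare(r$lor2_time_s, r$lorp_time_s, "time: LORP vs LOR2")
  )
  structure(list(endpoints = endpoints, comparisons = comparisons,
                 n = nrow(r)), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (mean +/- SD; aRASS median [min, max]):\n", x$n))
  e <- x$endpoints
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-4s time %7.2f +/- %6.2f s   Ce %5.2f +/- %4.2f ug/mL   aRASS %g [%g, %g]\n",
                e$endpoint[i], e$time_mean_s[i], e$time_sd_s[i],
                e$ce_mean[i], e$ce_sd[i],
                e$arass_median[i], e$arass_min[i], e$arass_max[i]))
  }
  cat("Paired comparisons:\n")
  cm <- x$comparisons
  for (i in seq_len(nrow(cm))) {
    cat(sprintf("  %-18s %-28s mean diff %6.3f  p = %s\n",
                cm$comparison[i], cm$test[i], cm$mean_difference[i],
                format.pval(cm$p_value[i], digits = 3)))
  }
  invisible(x)
}
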