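#' @noRd
pk_pair_counts <- function(indicator, cls) {
  n <- length(indicator)
  conc <- disc <- tied <- numeric(n)
  for (i in seq_len(n)) {
    dc <- cls - cls[i]
    dx <- indicator - indicator[i]
    cross <- dc != 0
    s <- dc * dx
    conc[i] <- sum(cross & s > 0)
    disc[i] <- sum(cross & s < 0)
    tied[i] <- sum(cross & dx == 0)
  }
  list(per_c = conc, per_d = disc, per_t = tied,
       C = sum(conc) / 2, D = sum(disc) / 2, T = sum(tied) / 2)
}

pk_class_rank <- function(cls) {
  if (is.ordered(cls)) return(as.integer(cls))
  if (is.numeric(cls)) return(cls)
  abort("`class` must be numeric or an ordered factor with a declared order.")
}

pk_from_counts <- function(C, D, T) (C + T / 2) / (C + D + T)

#' Prediction probability (Pk)
#'
#' The probability that an indicator correctly ranks a randomly chosen pair
#' of observations from different ordinal classes; 0.5 is chance, 1 is a
#' perfect predictor. Over all unordered cross-class pairs, a pair is
#' concordant if the indicator ordering matches the class ordering,
#' discordant if reversed, and tied if the indicator values are equal;
#' `pk = (C + T/2) / (C + D + T)`. Pairs tied on class are ignored.
#'
#' The standard error is a delete-one jackknife over observations;
#' replicates whose leave-one-out subset has a single class or no
#' cross-class pairs are skipped with a warning.
#'
#' @param data A data frame.
#' @param indicator Column with the indicator (unquoted).
#' @param class Column with the ordinal class (unquoted); numeric or an
#'   ordered factor. For the aRASS scale use the numeric scores
#'   (0 awake down to -5 unresponsive).
#' @param se `"none"` or `"jackknife"`.
#' @return A one-row tibble: `pk`, `se`, `n_concordant`, `n_discordant`,
#'   `n_tied_indicator`, `n`.
#' @export
#' @examples
#' d <- tibble::tibble(arass = c(0, -1, -2), ce = c(1, 2, 3))
#' prediction_probability(d, ce, arass) # strictly monotone (inverse): pk = 0
prediction_probability <- function(data, indicator, class,
                                   se = c("none", "jackknife")) {
  se <- match.arg(se)
  ind <- dplyr::pull(data, {{ indicator }})
  cls <- pk_class_rank(dplyr::pull(data, {{ class }}))
  keep <- is.finite(ind) & is.finite(cls)
  ind <- ind[keep]; cls <- cls[keep]
  n <- length(ind)
  if (n < 2) abort("Pk needs at least 2 observations.")
  if (length(unique(cls)) < 2) {
    abort("Pk undefined: all observations are in one class.")
  }
  cnt <- pk_pair_counts(ind, cls)
  pk <- pk_from_counts(cnt$C, cnt$D, cnt$T)
  se_val <- NA_real_
  if (se == "jackknife") {
    if (n < 3) abort("The jackknife needs at least 3 observations.")
    Ci <- cnt$C - cnt$per_c
    Di <- cnt$D - cnt$per_d
    Ti <- cnt$T - cnt$per_t
    denom <- Ci + Di + Ti
    multi_class <- vapply(seq_len(n), function(i) {
      length(unique(cls[-i])) >= 2
    }, logical(1))
    valid <- denom > 0 & multi_class
    if (!all(valid)) {
      if (!any(valid)) abort("All jackknife replicates are degenerate.")
      warn(sprintf("%d degenerate jackknife replicate(s) skipped.", sum(!valid)))
    }
    reps <- pk_from_counts(Ci[valid], Di[valid], Ti[valid])
    m <- length(reps)
    se_val <- sqrt((m - 1) / m * sum((reps - mean(reps))^2))
  }
  tibble(pk = pk, se = se_val,
         n_concordant = cnt$C, n_discordant = cnt$D,
         n_tied_indicator = cnt$T, n = n)
}

#' Direction-folded Pk
#'
#' `max(pk, 1 - pk)`: the prediction probability of the better-oriented
#' reading of the indicator, so that negatively associated indicators also
#' report values at or above 0.5.
#'
#' @param pk Raw Pk value(s).
#' @return Folded value(s).
#' @export
directionless_pk <- function(pk) pmax(pk, 1 - pk)

#' Correlation with automatic method choice
#'
#' Pearson correlation when both variables pass a Kolmogorov-Smirnov
#' normality test (at level 0.05, against a normal with the sample moments),
#' Spearman rank correlation otherwise.
#'
#' @param data A data frame.
#' @param x,y Columns (unquoted).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return A one-row tibble: `method`, `estimate`, `p_value`, `n`.
#' @export
correlation <- function(data, x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) abort("Correlation needs at least 3 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) abort("Correlation undefined for constant input.")
  if (method == "auto") {
    normal <- function(v) {
      p <- suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v))$p.value)
      p > 0.05
    }
    method <- if (normal(xv) && normal(yv)) "pearson" else "spearman"
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = method, exact = FALSE))
  tibble(method = method, estimate = unname(ct$estimate),
         p_value = ct$p.value, n = length(xv))
}

#' Pk and correlation table over all extracted features
#'
#' For every (window, feature) combination of a feature table, computes the
#' pooled prediction probability against the sedation scale (raw and
#' direction-folded, with jackknife SE) and the correlations of the feature
#' with the sedation scale and with the propofol effect-site concentration.
#'
#' @param features A feature tibble from [session_features()] (possibly
#'   pooled over patients).
#' @param class_col Column holding the ordinal sedation class (default
#'   `arass`).
#' @param ce_col Column holding the effect-site concentration (default
#'   `ce_ug_ml`).
#' @param se Standard-error method passed to [prediction_probability()].
#' @return A tibble of class `pk_table`: `window`, `feature`, `pk_raw`,
#'   `pk`, `se`, `n`, `r_arass`, `p_arass`, `r_ce`, `p_ce`.
#' @export
pk_table <- function(features, class_col = "arass", ce_col = "ce_ug_ml",
                     se = "jackknife") {
  feature_cols <- c("v_mean", "v_diff", "p_mean", "p_max", "f_mean", "p_fmean",
                    "f_median", "p_band", "p_total", "p_total_over_fmedian",
                    "snr_db", "p_bandwidth", "spectral_entropy")
  combos <- expand.grid(window = unique(features$window),
                        feature = feature_cols, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    w <- combos$window[i]; fc <- combos$feature[i]
    d <- features[features$window == w & is.finite(features[[fc]]), ]
    res <- suppressWarnings(
      prediction_probability(d, .data[[fc]], .data[[class_col]], se = se))
    ra <- correlation(d, .data[[fc]], .data[[class_col]])
    rc <- correlation(d, .data[[fc]], .data[[ce_col]])
    tibble(window = w, feature = fc, pk_raw = res$pk,
           pk = directionless_pk(res$pk), se = res$se, n = res$n,
           r_arass = ra$estimate, p_arass = ra$p_value,
           r_ce = rc$estimate, p_ce = rc$p_value)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pk_table", class(out))
  out
}
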