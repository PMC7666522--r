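#' Published unresponsiveness logit coefficients
#'
#' The fitted binary logit for the probability of unresponsiveness
#' (aRASS = -5) as printed by the source analysis: an intercept and eight
#' slopes on propofol Ce and selected T1/T2 features. The coefficients are
#' shipped as a versioned data file under `inst/extdata` and read here, not
#' hard-coded in logic. Note that the printed frequency-feature slopes are
#' passed through in the units as printed; the original units are not fully
#' specified, which limits out-of-sample use.
#'
#' @return A tibble with columns `term` and `coefficient`.
#' @export
eq1_coefficients <- function() {
  path <- system.file("extdata", "eq1_coefficients.csv", package = "blinksed")
  if (path == "") { # load_all() / source fallback
    path <- file.path("inst", "extdata", "eq1_coefficients.csv")
  }
  readr::read_csv(path, show_col_types = FALSE)
}

#' Evaluate the published unresponsiveness logit
#'
#' Computes `logit = intercept + sum(coefficient * predictor)` and the
#' corresponding probability `1 / (1 + exp(-logit))` for each row of a
#' predictor table. All eight predictors must be present.
#'
#' @param data A data frame with columns named after the non-intercept
#'   terms of `coefficients` (`ce_ug_ml`, `v_mean_T1`, `f_mean_T1`,
#'   `f_median_T1`, `p_bandwidth_T1`, `spectral_entropy_T1`, `f_mean_T2`,
#'   `spectral_entropy_T2`).
#' @param coefficients Coefficient tibble, default [eq1_coefficients()].
#' @return `data` with added columns `logit` and `probability`.
#' @export
eval_eq1 <- function(data, coefficients = eq1_coefficients()) {
  stopifnot(is.data.frame(data))
  terms <- coefficients$term
  slopes <- setdiff(terms, "intercept")
  missing_cols <- setdiff(slopes, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing predictor column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  intercept <- coefficients$coefficient[terms == "intercept"]
  X <- as.matrix(data[, slopes, drop = FALSE])
  beta <- coefficients$coefficient[match(slopes, terms)]
  logit <- intercept + drop(X %*% beta)
  dplyr::mutate(tibble::as_tibble(data),
                logit = logit, probability = 1 / (1 + exp(-logit)))
}
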