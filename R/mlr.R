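mlr_loglik <- function(eta, y_idx) {
  # eta: n x (K-1), reference class has linear predictor 0; y_idx: 1 = reference
  m <- pmax(apply(eta, 1, max), 0)
  lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
  chosen <- ifelse(y_idx == 1, 0, eta[cbind(seq_len(nrow(eta)), pmax(y_idx - 1, 1))])
  sum(chosen - lse)
}

mlr_probs <- function(eta) {
  m <- pmax(apply(eta, 1, max), 0)
  e0 <- exp(-m)
  ek <- exp(eta - m)
  denom <- e0 + rowSums(ek)
  cbind(e0, ek) / denom # column 1 = reference class
}

#' Fit a multinomial logistic regression of sedation depth
#'
#' Maximum-likelihood multinomial logit with the most-awake class as the
#' reference category (each non-reference class gets its own intercept and
#' slope vector: `ln(P_k / P_ref) = beta_0k + sum_j beta_jk X_j`), fitted by
#' Newton-Raphson with step-halving. Converged when the largest score
#' component falls below `tol_score` or the relative log-likelihood change
#' below `tol_ll`. Diverging coefficients (any |beta| above `beta_cap`)
#' raise a separation error naming the offending predictor.
#'
#' @param data A data frame with the response and predictor columns and no
#'   missing values in them.
#' @param response Name of the ordinal response column (e.g. `"arass"`,
#'   numeric with 0 = awake down to -5 = unresponsive).
#' @param predictors Character vector of predictor column names; empty for
#'   an intercept-only model.
#' @param reference Reference class value; default the most awake
#'   (largest) observed class.
#' @param max_iter,tol_score,tol_ll,beta_cap Fitting controls.
#' @return An object of class `blink_mlr`: coefficient matrix
#'   `(K-1) x (p+1)` (rows = non-reference classes, deepest last), class
#'   levels, reference class, log-likelihood, score, variance-covariance
#'   matrix, and the modelling frame.
#' @export
fit_multinomial <- function(data, response, predictors = character(),
                            reference = NULL, max_iter = 100,
                            tol_score = 1e-6, tol_ll = 1e-10, beta_cap = 500) {
  stopifnot(is.data.frame(data))
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  frame <- data[, cols, drop = FALSE]
  if (anyNA(frame)) abort("The modelling frame contains missing values.")
  y <- frame[[response]]
  levels <- sort(unique(y), decreasing = TRUE) # most awake first
  if (length(levels) < 2) abort("At least two response classes are required.")
  if (is.null(reference)) reference <- levels[1]
  if (!reference %in% levels) abort("`reference` is not an observed class.")
  levels <- c(reference, setdiff(levels, reference))
  y_idx <- match(y, levels)
  K <- length(levels)

  X <- cbind(`(Intercept)` = 1,
             as.matrix(frame[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p) abort("Singular design matrix.")
  n_free <- (K - 1) * p
  if (n <= n_free) abort("More free parameters than observations.")

  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y_idx)] <- 1

  B <- matrix(0, K - 1, p,
              dimnames = list(paste0("class_", levels[-1]), colnames(X)))
  eta <- X %*% t(B)
  ll <- mlr_loglik(eta, y_idx)
  converged <- FALSE
  H <- NULL

  for (iter in seq_len(max_iter)) {
    P <- mlr_probs(eta)           # n x K, col 1 = reference
    Pk <- P[, -1, drop = FALSE]   # non-reference probabilities
    G <- t(X) %*% (Y[, -1, drop = FALSE] - Pk)  # p x (K-1) score
    g <- as.vector(G)
    H <- matrix(0, n_free, n_free)
    for (k in seq_len(K - 1)) {
      for (l in k:(K - 1)) {
        w <- if (k == l) Pk[, k] * (1 - Pk[, k]) else -Pk[, k] * Pk[, l]
        blk <- -t(X) %*% (X * w)
        ri <- (k - 1) * p + seq_len(p)
        ci <- (l - 1) * p + seq_len(p)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    step <- tryCatch(solve(-H, g), error = function(e) {
      abort("Singular Hessian; the model is not identifiable on these data.")
    })
    # step-halving: never accept a likelihood decrease
    lambda <- 1
    repeat {
      B_new <- B + lambda * matrix(step, K - 1, p, byrow = TRUE)
      eta_new <- X %*% t(B_new)
      ll_new <- mlr_loglik(eta_new, y_idx)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { ll_new <- ll; B_new <- B; eta_new <- eta; break }
    }
    if (max(abs(B_new)) > beta_cap) {
      worst <- which(abs(B_new) == max(abs(B_new)), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "Apparent complete separation: coefficient for '%s' (class %s) diverged beyond %g.",
        colnames(X)[worst[2]], rownames(B)[worst[1]], beta_cap))
    }
    delta_ll <- ll_new - ll
    B <- B_new; eta <- eta_new; ll <- ll_new
    if (max(abs(g)) < tol_score || abs(delta_ll) <= tol_ll * (abs(ll) + 1e-12)) {
      converged <- TRUE
      break
    }
  }

  # a perfectly saturated fit means the classes are separable in the
  # predictor space: the MLE does not exist
  P_fit <- mlr_probs(eta)
  p_obs <- P_fit[cbind(seq_len(n), y_idx)]
  if (length(predictors) && min(p_obs) > 1 - 1e-6) {
    slopes <- abs(B[, -1, drop = FALSE])
    worst <- which(slopes == max(slopes), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Apparent complete separation: '%s' perfectly predicts the classes.",
      predictors[worst[2]]))
  }

  vcov <- tryCatch(solve(-H), error = function(e) NULL)
  structure(list(
    coefficients = B, levels = levels, reference = reference,
    log_likelihood = ll, vcov = vcov, converged = converged,
    n = n, n_free = n_free, predictors = predictors, response = response,
    frame = tibble::as_tibble(frame)
  ), class = "blink_mlr")
}

#' @export
print.blink_mlr <- function(x, ...) {
  cat(sprintf(
    "<blink_mlr> %d classes (reference %s), %d predictors, n = %d, logLik = %.3f%s\n",
    length(x$levels), format(x$reference), length(x$predictors), x$n,
    x$log_likelihood, if (x$converged) "" else " (NOT converged)"))
  print(x$coefficients)
  invisible(x)
}

#' @export
logLik.blink_mlr <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_free, class = "logLik")
}

#' Predict class probabilities or classes
#'
#' Probabilities are computed through a log-sum-exp softmax and always lie
#' on the probability simplex. Class prediction takes the most probable
#' class; exact ties resolve to the deeper sedation class.
#'
#' @param object A `blink_mlr` fit.
#' @param newdata Data frame with the predictor columns; defaults to the
#'   modelling frame.
#' @param type `"probs"` for the n x K probability matrix (columns in level
#'   order, reference first), `"class"` for predicted class values.
#' @param ... Unused.
#' @export
predict.blink_mlr <- function(object, newdata = NULL,
                              type = c("probs", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$frame
  X <- cbind(1, as.matrix(newdata[, object$predictors, drop = FALSE]))
  P <- mlr_probs(X %*% t(object$coefficients))
  colnames(P) <- as.character(object$levels)
  if (type == "probs") return(P)
  # ties break towards deeper sedation = smaller class value
  pick <- apply(P, 1, function(row) {
    cand <- which(row == max(row))
    cand[which.min(object$levels[cand])]
  })
  object$levels[pick]
}

#' Likelihood-ratio test between nested multinomial fits
#'
#' @param full,reduced `blink_mlr` fits on the same data, `reduced` nested
#'   in `full` (its predictors a subset of the full model's).
#' @return A one-row tibble: `chi2`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (!all(reduced$predictors %in% full$predictors) ||
      full$n != reduced$n ||
      !identical(sort(full$levels), sort(reduced$levels))) {
    abort("`reduced` must be nested in `full` (same data, subset of predictors).")
  }
  chi2 <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  df <- full$n_free - reduced$n_free
  tibble(chi2 = chi2, df = df,
         p_value = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else 1)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell `R2 = 1 - exp(2 (LL0 - LL1) / n)` rescaled by its maximum
#' `1 - exp(2 LL0 / n)` to the `[0, 1]` range.
#'
#' @param model A fitted `blink_mlr`.
#' @param null_model Intercept-only fit on the same data; fitted
#'   automatically when omitted.
#' @return Nagelkerke R-squared.
#' @export
nagelkerke_r2 <- function(model, null_model = NULL) {
  if (is.null(null_model)) {
    null_model <- fit_multinomial(model$frame, model$response, character(),
                                  reference = model$reference)
  }
  ll1 <- model$log_likelihood
  ll0 <- null_model$log_likelihood
  if (ll1 < ll0 - 1e-8) {
    abort("Model log-likelihood is below the null model's; this indicates a fitting bug.")
  }
  n <- model$n
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / n)
  r2_cs / (1 - exp(2 * ll0 / n))
}

#' In-sample classification accuracy
#'
#' Fraction of rows whose argmax-probability class (ties towards deeper
#' sedation) equals the observed class.
#'
#' @param model A fitted `blink_mlr`.
#' @param data Data frame with response and predictors; defaults to the
#'   modelling frame.
#' @return Accuracy in `[0, 1]`.
#' @export
classify_and_accuracy <- function(model, data = NULL) {
  if (is.null(data)) data <- model$frame
  pred <- predict(model, data, type = "class")
  mean(pred == data[[model$response]])
}

#' Model fit diagnostics
#'
#' Overall model chi-squared against the intercept-only model, Nagelkerke
#' R-squared, in-sample accuracy, and per-predictor likelihood-ratio tests
#' (each predictor dropped in turn; with all 6 aRASS classes present each
#' single-column predictor has 5 degrees of freedom).
#'
#' @param model A fitted `blink_mlr`.
#' @return A list of class `mlr_diagnostics`: `overall` (one-row tibble
#'   `chi2`, `df`, `p_value`), `nagelkerke_r2`, `accuracy`, `lr_tests`
#'   (tibble `predictor`, `chi2`, `df`, `p_value`).
#' @export
mlr_diagnostics <- function(model) {
  null_model <- fit_multinomial(model$frame, model$response, character(),
                                reference = model$reference)
  overall <- likelihood_ratio_test(model, null_model)
  lr <- lapply(model$predictors, function(pr) {
    reduced <- fit_multinomial(model$frame, model$response,
                               setdiff(model$predictors, pr),
                               reference = model$reference)
    res <- likelihood_ratio_test(model, reduced)
    dplyr::bind_cols(tibble(predictor = pr), res)
  })
  structure(list(
    overall = overall,
    nagelkerke_r2 = nagelkerke_r2(model, null_model),
    accuracy = classify_and_accuracy(model),
    lr_tests = dplyr::bind_rows(lr)
  ), class = "mlr_diagnostics")
}

#' @export
print.mlr_diagnostics <- function(x, ...) {
  cat(sprintf("Overall chi2 = %.3f (df %d, p = %.3g); Nagelkerke R2 = %.3f; accuracy = %.1f%%\n",
              x$overall$chi2, x$overall$df, x$overall$p_value,
              x$nagelkerke_r2, 100 * x$accuracy))
  print(x$lr_tests)
  invisible(x)
}

#' Select predictive features from a Pk table
#'
#' Features whose direction-folded Pk strictly exceeds `pk_threshold` are
#' selected; features additionally showing |R| above `r_threshold` against
#' the effect-site concentration are flagged as strongly correlated.
#'
#' @param pk_table A `pk_table` tibble from [pk_table()].
#' @param pk_threshold Pk selection threshold (strict inequality).
#' @param r_threshold Absolute correlation threshold for the flag.
#' @return The selected rows with an added `strong_corr` column.
#' @export
select_features <- function(pk_table, pk_threshold = 0.700, r_threshold = 0.500) {
  sel <- pk_table[pk_table$pk > pk_threshold, , drop = FALSE]
  if (!nrow(sel)) abort("No feature exceeds the Pk selection threshold.")
  sel$strong_corr <- abs(sel$r_ce) > r_threshold
  sel
}

#' The study's final predictor set
#'
#' The named preset of predictors retained by the published analysis:
#' propofol Ce plus Vmean, Vdiff, fmean, fmedian, Pbandwidth and spectral
#' entropy from the T1 window, and fmean and spectral entropy from the T2
#' window, in the wide-table naming of [pivot_features_wide()]. The
#' published selection also lists Vdiff(T1); because `v_diff = 1 - v_mean`
#' identically, including both with an intercept makes the design singular,
#' so the preset carries `v_mean_T1` only (Vdiff contributes no additional
#' information).
#'
#' @return Character vector of predictor column names.
#' @export
paper_predictors <- function() {
  c("ce_ug_ml", "v_mean_T1", "f_mean_T1", "f_median_T1",
    "p_bandwidth_T1", "spectral_entropy_T1", "f_mean_T2", "spectral_entropy_T2")
}

#' Pivot a long feature table to one row per stimulus
#'
#' Spreads the T1/T2 window rows into suffixed columns (`v_mean_T1`,
#' `f_mean_T2`, ...) so the table can feed the multinomial model.
#'
#' @param features A long feature tibble from [session_features()].
#' @return A wide tibble, one row per (patient, stimulus).
#' @export
pivot_features_wide <- function(features) {
  tidyr::pivot_wider(
    features,
    id_cols = c("patient_id", "stim_time_s", "ce_ug_ml", "arass"),
    names_from = "window",
    values_from = dplyr::all_of(c(
      "v_mean", "v_diff", "p_mean", "p_max", "f_mean", "p_fmean", "f_median",
      "p_band", "p_total", "p_total_over_fmedian", "snr_db", "p_bandwidth",
      "spectral_entropy")),
    names_sep = "_"
  )
}

#' @export
tidy.blink_mlr <- function(x, ...) {
  B <- x$coefficients
  se <- if (!is.null(x$vcov)) {
    matrix(sqrt(pmax(diag(x$vcov), 0)), nrow(B), ncol(B), byrow = TRUE)
  } else {
    matrix(NA_real_, nrow(B), ncol(B))
  }
  out <- lapply(seq_len(nrow(B)), function(k) {
    tibble(y_level = x$levels[k + 1], term = colnames(B),
           estimate = B[k, ], std_error = se[k, ])
  })
  dplyr::bind_rows(out)
}

#' @export
glance.blink_mlr <- function(x, ...) {
  tibble(log_likelihood = x$log_likelihood, df = x$n_free, nobs = x$n,
         n_classes = length(x$levels), converged = x$converged)
}
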