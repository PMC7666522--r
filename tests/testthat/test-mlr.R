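test_that("a 2-class fit reduces to binary logistic regression", {
  set.seed(42)
  n <- 400
  x <- rnorm(n)
  pr <- 1 / (1 + exp(-(0.5 - 1.2 * x)))
  y <- ifelse(runif(n) < pr, -1, 0) # class -1 with logit 0.5 - 1.2 x vs ref 0
  d <- tibble::tibble(x = x, arass = y)

  fit <- fit_multinomial(d, "arass", "x")
  ref <- stats::glm(I(arass == -1) ~ x, family = stats::binomial(), data = d)
  expect_equal(unname(fit$coefficients[1, ]), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
})

test_that("known 6-class coefficients are recovered within 3 SEs", {
  B <- rbind(c(0.3, 0.8, -0.5),
             c(-0.2, 1.4, 0.3),
             c(0.1, 1.9, 0.9),
             c(-0.4, 2.4, 1.5),
             c(-0.8, 3.0, 2.2))
  d <- sim_mlr_data(5000, B, seed = 314)
  fit <- fit_multinomial(d, "arass", c("x1", "x2"))
  se <- sqrt(pmax(diag(fit$vcov), 0))
  est <- as.vector(t(fit$coefficients)) # class-major, matching vcov layout
  truth <- as.vector(t(B))
  expect_true(all(abs(est - truth) / se < 3))
})

test_that("intercept-only fit on balanced classes is uniform", {
  d <- tibble::tibble(arass = rep(c(0, -1, -2, -3, -4, -5), each = 30))
  fit <- fit_multinomial(d, "arass", character())
  pr <- predict(fit)
  expect_equal(unname(pr[1, ]), rep(1 / 6, 6), tolerance = 1e-8)

  # an exactly tied probability vector resolves to the deepest class
  tied <- structure(list(
    coefficients = matrix(0, 1, 1, dimnames = list("class_-5", "(Intercept)")),
    levels = c(0, -5), reference = 0, predictors = character(),
    frame = tibble::tibble(arass = c(0, -5))), class = "blink_mlr")
  expect_equal(predict(tied, tibble::tibble(arass = 0), type = "class"), -5)
})

test_that("probabilities live on the simplex and the likelihood ascends", {
  B <- rbind(c(0.1, 1), c(-0.2, 2), c(0, 3), c(0.2, 4), c(-0.1, 5))
  d <- sim_mlr_data(600, B, seed = 8)
  fit <- fit_multinomial(d, "arass", "x1")
  P <- predict(fit, tibble::tibble(x1 = c(-50, -1, 0, 1, 50)))
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
  null <- fit_multinomial(d, "arass", character())
  expect_gte(fit$log_likelihood, null$log_likelihood)
})

test_that("separation and singularity are diagnosed", {
  d <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                      arass = rep(c(0, -1), each = 20))
  expect_error(fit_multinomial(d, "arass", "x"), "separation")
  d2 <- tibble::tibble(x = rnorm(40), arass = rep(c(0, -1), 20))
  d2$x2 <- 2 * d2$x
  expect_error(fit_multinomial(d2, "arass", c("x", "x2")), "Singular")
})

test_that("likelihood-ratio tests behave as chi-squared tests", {
  B <- rbind(c(0.3, 0.8, 0), c(-0.2, 1.4, 0), c(0.1, 1.9, 0),
             c(-0.4, 2.4, 0), c(-0.8, 3.0, 0))
  d <- sim_mlr_data(900, B, seed = 27)
  full <- fit_multinomial(d, "arass", c("x1", "x2"))
  reduced <- fit_multinomial(d, "arass", "x1")

  same <- likelihood_ratio_test(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)

  lr <- likelihood_ratio_test(full, reduced)
  expect_equal(lr$df, 5) # one predictor dropped, 6 classes
  expect_gte(lr$chi2, 0)
  expect_gt(lr$p_value, 1e-6) # x2 is null in truth

  expect_error(likelihood_ratio_test(reduced, full), "nested")

  # 2-class toy: chi2 equals the glm deviance difference
  set.seed(5)
  d2 <- tibble::tibble(x = rnorm(200))
  d2$arass <- ifelse(runif(200) < 1 / (1 + exp(-d2$x)), 0, -1)
  f2 <- fit_multinomial(d2, "arass", "x")
  r2 <- fit_multinomial(d2, "arass", character())
  g_full <- stats::glm(I(arass == -1) ~ x, stats::binomial(), data = d2)
  g_null <- stats::glm(I(arass == -1) ~ 1, stats::binomial(), data = d2)
  expect_equal(likelihood_ratio_test(f2, r2)$chi2,
               unname(g_null$deviance - g_full$deviance), tolerance = 1e-6)
})

test_that("Nagelkerke R2 matches hand arithmetic and its limits", {
  B <- rbind(c(0, 2), c(0, 4))
  d <- sim_mlr_data(500, B, levels = c(0, -1, -2), seed = 99)
  fit <- fit_multinomial(d, "arass", "x1")
  null <- fit_multinomial(d, "arass", character())
  ll1 <- fit$log_likelihood; ll0 <- null$log_likelihood; n <- fit$n
  hand <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  expect_equal(nagelkerke_r2(fit, null), hand, tolerance = 1e-9)
  expect_equal(nagelkerke_r2(null, null), 0)
  expect_gt(nagelkerke_r2(fit, null), 0.3)
  expect_lte(nagelkerke_r2(fit, null), 1)
})

test_that("accuracy counts argmax-correct rows", {
  d <- tibble::tibble(arass = rep(-5, 10), x1 = rnorm(10))
  # single-class tables cannot be fitted, but accuracy of any model on them is
  # defined; use a 2-class model evaluated on a single-class table
  B <- rbind(c(4, 0)) # class -5 overwhelmingly likely
  d2 <- sim_mlr_data(200, B, levels = c(0, -5), seed = 3)
  fit <- fit_multinomial(d2, "arass", "x1")
  expect_equal(classify_and_accuracy(fit, d), 1)
  acc <- classify_and_accuracy(fit)
  expect_gte(acc, mean(d2$arass == -5) - 0.05) # at least the majority rate
})

test_that("feature selection applies the strict Pk > 0.700 rule", {
  tab <- tibble::tibble(
    window = c("T1", "T1", "T1", "T2"),
    feature = c("f_mean", "p_mean", "edge", "spectral_entropy"),
    pk = c(0.765, 0.512, 0.700, 0.745),
    r_ce = c(-0.522, -0.064, 0.2, -0.464))
  sel <- select_features(tab)
  expect_setequal(sel$feature, c("f_mean", "spectral_entropy"))
  expect_true(all(sel$strong_corr == (abs(sel$r_ce) > 0.5)))
  expect_error(select_features(tab[tab$pk < 0.6, ]), "No feature")
  # Ce + 5 distinct T1 features + 2 T2 features (Vdiff is aliased with Vmean)
  expect_length(paper_predictors(), 8)
})

test_that("mlr diagnostics and tidiers are coherent", {
  B <- rbind(c(0.3, 0.8, -0.5), c(-0.2, 1.4, 0.3), c(0.1, 1.9, 0.9),
             c(-0.4, 2.4, 1.5), c(-0.8, 3.0, 2.2))
  d <- sim_mlr_data(700, B, seed = 11)
  fit <- fit_multinomial(d, "arass", c("x1", "x2"))
  diag <- mlr_diagnostics(fit)
  expect_equal(diag$overall$df, 10)
  expect_true(all(diag$lr_tests$df == 5))
  expect_true(diag$nagelkerke_r2 > 0 && diag$nagelkerke_r2 <= 1)
  expect_true(diag$accuracy > 1 / 6)

  td <- tidy(fit)
  expect_equal(nrow(td), 5 * 3)
  expect_true(all(c("y_level", "term", "estimate", "std_error") %in% names(td)))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 700)
})

test_that("the published unresponsiveness logit evaluates exactly", {
  zero <- tibble::tibble(ce_ug_ml = 0, v_mean_T1 = 0, f_mean_T1 = 0,
                         f_median_T1 = 0, p_bandwidth_T1 = 0,
                         spectral_entropy_T1 = 0, f_mean_T2 = 0,
                         spectral_entropy_T2 = 0)
  out <- eval_eq1(zero)
  expect_equal(out$logit, -339.206)
  expect_equal(out$probability, 1 / (1 + exp(339.206)))

  unit_ce <- dplyr::mutate(zero, ce_ug_ml = 1)
  expect_equal(eval_eq1(unit_ce)$logit, -339.206 + 2.476)

  # independent dot-product oracle on a fixture vector
  fx <- tibble::tibble(ce_ug_ml = 3.1, v_mean_T1 = 0.44, f_mean_T1 = 120.5,
                       f_median_T1 = 98.2, p_bandwidth_T1 = 180.0,
                       spectral_entropy_T1 = 0.43, f_mean_T2 = 55.1,
                       spectral_entropy_T2 = 0.30)
  oracle <- -339.206 + 2.476 * 3.1 - 0.281 * 0.44 - 5.422 * 120.5 +
    3.234 * 98.2 + 0.116 * 180.0 + 1441.537 * 0.43 + 0.074 * 55.1 -
    38.100 * 0.30
  expect_equal(eval_eq1(fx)$logit, oracle, tolerance = 1e-9)

  expect_error(eval_eq1(zero[, -1]), "Missing predictor")
})
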