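test_that("Pk reproduces its defining anchor cases", {
  # strictly monotone indicator: perfect prediction
  d <- tibble::tibble(cls = c(0, -1, -2, -3, -4, -5), ind = c(6, 5, 4, 3, 2, 1))
  expect_equal(prediction_probability(d, ind, cls)$pk, 1)

  # balanced 4-point construction: exactly chance
  d2 <- tibble::tibble(cls = c(1, 1, 2, 2), ind = c(1, 4, 2, 3))
  r2 <- prediction_probability(d2, ind, cls)
  expect_equal(r2$pk, 0.5)
  expect_equal(c(r2$n_concordant, r2$n_discordant, r2$n_tied_indicator),
               c(2, 2, 0))

  # pure indicator tie across classes
  d3 <- tibble::tibble(cls = c(1, 2), ind = c(2, 2))
  r3 <- prediction_probability(d3, ind, cls)
  expect_equal(r3$pk, 0.5)
  expect_equal(r3$n_tied_indicator, 1)

  expect_error(prediction_probability(tibble::tibble(cls = c(1, 1), ind = 1:2),
                                      ind, cls), "one class")
})

test_that("Pk equals exhaustive pair enumeration on random instances", {
  set.seed(99)
  for (rep in 1:150) {
    n <- sample(3:12, 1)
    cls <- sample(-3:0, n, replace = TRUE)
    if (length(unique(cls)) < 2) next
    ind <- sample(1:6, n, replace = TRUE)
    d <- tibble::tibble(cls = cls, ind = ind)
    got <- prediction_probability(d, ind, cls)
    want <- pk_oracle(ind, cls)
    expect_identical(got$pk, want$pk)
    expect_identical(c(got$n_concordant, got$n_discordant, got$n_tied_indicator),
                     as.numeric(c(want$C, want$D, want$T)))
  }
})

test_that("jackknife standard errors match an independent oracle", {
  # perfectly concordant data: every replicate is 1, se = 0
  d <- tibble::tibble(cls = c(1, 1, 2, 2, 3, 3), ind = c(1, 2, 3, 4, 5, 6))
  expect_equal(prediction_probability(d, ind, cls, se = "jackknife")$se, 0)

  # the 4-point hand case against the oracle jackknife
  d2 <- tibble::tibble(cls = c(1, 1, 2, 2), ind = c(1, 4, 2, 3))
  got <- suppressWarnings(prediction_probability(d2, ind, cls, se = "jackknife"))
  expect_equal(got$se, pk_jackknife_oracle(d2$ind, d2$cls), tolerance = 1e-12)

  # larger random instance
  set.seed(123)
  d3 <- tibble::tibble(cls = sample(1:3, 15, replace = TRUE),
                       ind = rnorm(15))
  got3 <- prediction_probability(d3, ind, cls, se = "jackknife")
  expect_equal(got3$se, pk_jackknife_oracle(d3$ind, d3$cls), tolerance = 1e-12)

  # rank statistic: invariant under strictly increasing transforms
  d4 <- dplyr::mutate(d3, ind2 = exp(ind) + 3)
  got4 <- prediction_probability(d4, ind2, cls, se = "jackknife")
  expect_equal(got4$pk, got3$pk)
  expect_equal(got4$se, got3$se)
})

test_that("Pk symmetry and direction folding", {
  set.seed(7)
  d <- tibble::tibble(cls = sample(1:4, 30, replace = TRUE), ind = rnorm(30))
  pk_pos <- prediction_probability(d, ind, cls)$pk
  d$neg <- -d$ind
  pk_neg <- prediction_probability(d, neg, cls)$pk
  expect_equal(pk_neg, 1 - pk_pos) # no indicator ties with continuous data

  expect_equal(directionless_pk(0.235), 0.765)
  expect_equal(directionless_pk(0.5), 0.5)
  expect_equal(directionless_pk(0.73), 0.73)
})

test_that("correlation chooses and computes methods correctly", {
  d <- tibble::tibble(x = seq(-2, 2, length.out = 20))
  d$y <- 2 * d$x
  expect_equal(correlation(d, x, y, "pearson")$estimate, 1)
  expect_equal(correlation(d, x, y, "spearman")$estimate, 1)

  d$z <- -d$x^3
  expect_equal(correlation(d, x, z, "spearman")$estimate, -1)

  # hand rank-formula oracle on a tie-free 20-point fixture
  set.seed(17)
  a <- rnorm(20); b <- a + rnorm(20)
  rs_oracle <- 1 - 6 * sum((rank(a) - rank(b))^2) / (20 * (20^2 - 1))
  got <- correlation(tibble::tibble(a = a, b = b), a, b, "spearman")
  expect_equal(got$estimate, rs_oracle, tolerance = 1e-12)

  expect_error(correlation(tibble::tibble(a = rep(1, 5), b = 1:5), a, b),
               "constant")
})

test_that("pooled session Pk separates informative from noise indicators", {
  set.seed(55)
  sessions <- simulate_cohort(3, seed = 200, detect = FALSE)
  sed <- dplyr::bind_rows(lapply(sessions, `[[`, "sedation"))
  sed <- sed[sed$arass > -5 | sed$ce_ug_ml > 0, ]
  pk_ce <- prediction_probability(sed, ce_ug_ml, arass)$pk
  sed$noise <- rnorm(nrow(sed))
  pk_noise <- prediction_probability(sed, noise, arass)$pk
  expect_gt(directionless_pk(pk_ce), directionless_pk(pk_noise))
  expect_lt(abs(pk_noise - 0.5), 0.1)
  # deeper sedation pairs with higher Ce: raw Pk of Ce vs aRASS is near 0
  expect_gt(directionless_pk(pk_ce), 0.9)
})

test_that("the Table-3-shaped Pk table is well formed", {
  p <- mean_profile(noise_sd_uv = 2)
  s <- simulate_session(p)
  feats <- session_features(s)
  tab <- suppressWarnings(pk_table(feats))
  expect_equal(nrow(tab), 26) # 13 features x 2 windows
  expect_true(all(tab$pk >= 0.5 - 1e-12))
  expect_true(all(tab$pk >= tab$pk_raw | tab$pk >= 1 - tab$pk_raw))
  expect_true(all(is.finite(tab$se)))
})
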