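#' Schnider propofol model constants
#'
#' The published covariate model for propofol disposition used by effect-site
#' TCI systems: a three-compartment mammillary model with fixed central and
#' deep-peripheral volumes, age-adjusted rapid-peripheral volume and
#' clearances, and lean-body-mass / weight / height adjusted metabolic
#' clearance, plus a first-order effect-site equilibration constant.
#' All structural constants live in this one table so that nothing is
#' scattered through the code.
#'
#' @format A tibble with columns `parameter`, `value`, `unit`, `role`.
#' @export
schnider_constants <- function() {
  tibble::tribble(
    ~parameter,      ~value,  ~unit,    ~role,
    "v1",             4.27,   "L",      "central volume (fixed)",
    "v2_base",       18.9,    "L",      "rapid peripheral volume at age 53",
    "v2_age_slope",  -0.391,  "L/yr",   "V2 adjustment per year beyond 53",
    "v3",           238,      "L",      "slow peripheral volume (fixed)",
    "cl1_base",       1.89,   "L/min",  "metabolic clearance at reference covariates",
    "cl1_wt_slope",   0.0456, "L/min/kg",  "Cl1 per kg beyond 77",
    "cl1_lbm_slope", -0.0681, "L/min/kg",  "Cl1 per kg LBM beyond 59",
    "cl1_ht_slope",   0.0264, "L/min/cm",  "Cl1 per cm beyond 177",
    "cl2_base",       1.29,   "L/min",  "rapid clearance at age 53",
    "cl2_age_slope", -0.024,  "L/min/yr", "Cl2 per year beyond 53",
    "cl3",            0.836,  "L/min",  "slow clearance (fixed)",
    "ke0",            0.456,  "1/min",  "effect-site equilibration rate"
  )
}

schnider_value <- function(name) {
  tab <- schnider_constants()
  tab$value[match(name, tab$parameter)]
}

#' Patient demographics
#'
#' Constructor for the covariate set the Schnider model needs. Defaults are
#' the study population means (61 y, 72 kg, 162 cm, mostly female).
#'
#' @param age Age in years (>= 18).
#' @param weight Body weight in kg.
#' @param height Height in cm.
#' @param sex `"female"` or `"male"`.
#' @return A one-row tibble with columns `age`, `weight`, `height`, `sex`.
#' @export
demographics <- function(age = 61, weight = 72, height = 162, sex = "female") {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.finite(age) || age < 18) {
    abort("`age` must be a finite number >= 18 years.")
  }
  if (!is.finite(weight) || weight <= 0) abort("`weight` must be > 0 kg.")
  if (!is.finite(height) || height <= 0) abort("`height` must be > 0 cm.")
  tibble(age = age, weight = weight, height = height, sex = sex)
}

#' James lean body mass
#'
#' Sex-specific lean body mass (kg) from total weight (kg) and height (cm).
#'
#' @param weight Weight in kg.
#' @param height Height in cm.
#' @param sex `"female"` or `"male"`.
#' @return Lean body mass in kg.
#' @export
james_lbm <- function(weight, height, sex) {
  ifelse(sex == "male",
         1.10 * weight - 128 * (weight / height)^2,
         1.07 * weight - 148 * (weight / height)^2)
}

#' Schnider compartment model for a patient
#'
#' Evaluates the covariate formulas of [schnider_constants()] for one
#' patient and returns the compartmental parameters used by
#' [simulate_infusion()].
#'
#' @param demographics A one-row tibble from [demographics()].
#' @param ke0 Effect-site equilibration rate (1/min). The study does not
#'   print its pump's value; the default is the constant carried in
#'   [schnider_constants()].
#' @return A one-row tibble with columns `v1`, `v2`, `v3` (L), `cl1`, `cl2`,
#'   `cl3` (L/min), `ke0` (1/min) and `lbm` (kg).
#' @export
#' @examples
#' schnider_parameters(demographics(age = 53))$v2  # age term vanishes: 18.9 L
schnider_parameters <- function(demographics, ke0 = schnider_value("ke0")) {
  stopifnot(is.data.frame(demographics), nrow(demographics) == 1)
  d <- demographics
  lbm <- james_lbm(d$weight, d$height, d$sex)
  v2 <- schnider_value("v2_base") + schnider_value("v2_age_slope") * (d$age - 53)
  if (v2 <= 0) {
    abort(sprintf(
      "Schnider V2 is non-positive (%.3f L) at age %.1f; the covariate model is not valid there.",
      v2, d$age))
  }
  cl1 <- schnider_value("cl1_base") +
    schnider_value("cl1_wt_slope") * (d$weight - 77) +
    schnider_value("cl1_lbm_slope") * (lbm - 59) +
    schnider_value("cl1_ht_slope") * (d$height - 177)
  cl2 <- schnider_value("cl2_base") + schnider_value("cl2_age_slope") * (d$age - 53)
  out <- tibble(
    v1 = schnider_value("v1"), v2 = v2, v3 = schnider_value("v3"),
    cl1 = cl1, cl2 = cl2, cl3 = schnider_value("cl3"),
    ke0 = ke0, lbm = lbm
  )
  if (any(unlist(out[c("v1", "v2", "v3", "cl1", "cl2", "cl3", "ke0")]) <= 0)) {
    abort("All compartment volumes, clearances and ke0 must be positive.")
  }
  out
}

#' Study infusion schedule
#'
#' The induction protocol: a single constant-rate zero-order infusion of 1%
#' propofol (10 mg/mL) at 3.3 mL/kg/h, run from time zero until `stop_time_s`
#' (in the study, until loss of responsiveness).
#'
#' @param demographics A one-row tibble from [demographics()].
#' @param stop_time_s Infusion stop time in seconds (> 0).
#' @param rate_ml_kg_h Infusion rate in mL/kg/h of drug solution.
#' @param mg_per_ml Propofol concentration of the solution (mg/mL).
#' @return A tibble of infusion segments with columns `t_start_s`, `t_end_s`
#'   and `rate_mg_min`.
#' @export
#' @examples
#' protocol_infusion(demographics(weight = 72), 147.84)  # 39.6 mg/min
protocol_infusion <- function(demographics, stop_time_s,
                              rate_ml_kg_h = 3.3, mg_per_ml = 10) {
  stopifnot(is.data.frame(demographics), nrow(demographics) == 1)
  if (!is.finite(stop_time_s) || stop_time_s <= 0) {
    abort("`stop_time_s` must be a positive number of seconds.")
  }
  rate <- rate_ml_kg_h * mg_per_ml * demographics$weight / 60
  tibble(t_start_s = 0, t_end_s = stop_time_s, rate_mg_min = rate)
}

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule))
  req <- c("t_start_s", "t_end_s", "rate_mg_min")
  if (!all(req %in% names(schedule))) {
    abort("An infusion schedule needs columns t_start_s, t_end_s, rate_mg_min.")
  }
  if (nrow(schedule)) {
    s <- schedule[order(schedule$t_start_s), ]
    if (any(s$t_end_s <= s$t_start_s) || any(s$rate_mg_min < 0)) {
      abort("Infusion segments must have t_start_s < t_end_s and rate >= 0.")
    }
    if (nrow(s) > 1 && any(s$t_start_s[-1] < s$t_end_s[-nrow(s)])) {
      abort("Infusion segments must not overlap.")
    }
  }
  schedule
}

schedule_rate_at <- function(schedule, times_s) {
  out <- numeric(length(times_s))
  for (i in seq_len(nrow(schedule))) {
    sel <- times_s >= schedule$t_start_s[i] & times_s < schedule$t_end_s[i]
    out[sel] <- schedule$rate_mg_min[i]
  }
  out
}

#' Simulate plasma and effect-site propofol concentration
#'
#' Integrates the three-compartment mammillary system plus first-order
#' effect compartment with a fixed-step classical Runge-Kutta scheme.
#' Micro-rate constants are derived from clearances (k10 = Cl1/V1,
#' k12 = Cl2/V1, k21 = Cl2/V2, k13 = Cl3/V1, k31 = Cl3/V3). Amounts are in
#' mg and volumes in L, so concentrations come out in µg/mL. The cumulative
#' eliminated amount is co-integrated so mass balance can be audited.
#'
#' @param model A one-row tibble from [schnider_parameters()] (or any tibble
#'   with columns `v1`..`cl3`, `ke0`).
#' @param schedule An infusion schedule tibble, see [protocol_infusion()].
#' @param dt_s Integration step in seconds (default 0.1).
#' @param t_end_s End of the simulated grid; defaults to the last segment end.
#' @param method `"fast"` propagates the (affine, per-step constant) RK4 map
#'   through an eigendecomposition; `"loop"` is the plain step-by-step RK4.
#'   Both realise the same fixed-step classical Runge-Kutta scheme and agree
#'   to roundoff; `"auto"` uses the fast path and falls back to the loop if
#'   the eigenbasis is ill-conditioned.
#' @return A tibble of class `ce_trajectory` with columns `time_s`,
#'   `cp_ug_ml`, `ce_ug_ml`, `amount_mg` (drug in the three compartments) and
#'   `eliminated_mg`.
#' @export
simulate_infusion <- function(model, schedule, dt_s = 0.1, t_end_s = NULL,
                              method = c("auto", "fast", "loop")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(model), nrow(model) == 1)
  validate_schedule(schedule)
  if (!is.finite(dt_s) || dt_s <= 0) abort("`dt_s` must be > 0.")
  if (is.null(t_end_s)) t_end_s <- max(schedule$t_end_s, 0)
  if (t_end_s <= 0) abort("`t_end_s` must be > 0.")

  n <- ceiling(t_end_s / dt_s)
  times <- seq(0, by = dt_s, length.out = n + 1)

  # Per-step infusion rate; schedule boundaries are snapped to the grid so
  # each step sees one constant rate (the rate at the step's left edge and
  # midpoint agree except in the snapped boundary step).
  r0 <- schedule_rate_at(schedule, times)

  states <- pk_rk4_propagate(model, r0, dt_s / 60, n, method)
  if (!all(is.finite(states))) {
    abort("Non-finite state encountered; integration aborted.")
  }

  out <- tibble(time_s = times,
                cp_ug_ml = pmax(states[1, ] / model$v1, 0),
                ce_ug_ml = pmax(states[4, ], 0),
                amount_mg = states[1, ] + states[2, ] + states[3, ],
                eliminated_mg = states[5, ])
  class(out) <- c("ce_trajectory", class(out))
  out
}

# System matrix of the 5-state linear ODE (a1, a2, a3, ce, eliminated),
# rate constants per minute.
pk_system_matrix <- function(model) {
  k10 <- model$cl1 / model$v1
  k12 <- model$cl2 / model$v1
  k21 <- model$cl2 / model$v2
  k13 <- model$cl3 / model$v1
  k31 <- model$cl3 / model$v3
  ke0 <- model$ke0
  matrix(c(
    -(k10 + k12 + k13), k21,  k31,  0,    0,
    k12,               -k21,  0,    0,    0,
    k13,                0,   -k31,  0,    0,
    ke0 / model$v1,     0,    0,   -ke0,  0,
    k10,                0,    0,    0,    0), nrow = 5, byrow = TRUE)
}

# One classical RK4 step of x' = M x + b r is exactly x <- A x + P b r with
# A = I + hM + (hM)^2/2 + (hM)^3/6 + (hM)^4/24 and
# P = h(I + hM/2 + (hM)^2/6 + (hM)^3/24).
pk_rk4_operators <- function(M, h) {
  I <- diag(nrow(M))
  hM <- h * M
  hM2 <- hM %*% hM
  hM3 <- hM2 %*% hM
  hM4 <- hM3 %*% hM
  list(A = I + hM + hM2 / 2 + hM3 / 6 + hM4 / 24,
       P = h * (I + hM / 2 + hM2 / 6 + hM3 / 24))
}

pk_rk4_propagate <- function(model, r0, h, n, method) {
  M <- pk_system_matrix(model)
  op <- pk_rk4_operators(M, h)
  if (method %in% c("auto", "fast")) {
    eg <- eigen(op$A)
    kappa <- tryCatch(kappa(eg$vectors, exact = FALSE), error = function(e) Inf)
    if (is.finite(kappa) && kappa < 1e8) {
      return(pk_propagate_eigen(op, eg, r0, n))
    }
    if (method == "fast") {
      warn("Ill-conditioned eigenbasis; falling back to the step loop.")
    }
  }
  pk_propagate_loop(op, r0, n)
}

pk_propagate_loop <- function(op, r0, n) {
  states <- matrix(0, 5, n + 1)
  b <- c(1, 0, 0, 0, 0)
  x <- numeric(5)
  for (i in seq_len(n)) {
    x <- op$A %*% x + op$P %*% (b * r0[i])
    states[, i + 1] <- x
  }
  states
}

# Vectorised propagation over maximal runs of constant infusion rate:
# within a run, x_m = V diag(lambda^m) Vinv x0 + V diag(S_m) Vinv c with
# S_m = (lambda^m - 1)/(lambda - 1)  (m for lambda == 1).
pk_propagate_eigen <- function(op, eg, r0, n) {
  V <- eg$vectors
  lam <- eg$values
  Vinv <- solve(V)
  b <- c(1, 0, 0, 0, 0)
  states <- matrix(0, 5, n + 1)
  x <- numeric(5)
  run_start <- 1
  steps <- r0[seq_len(n)]
  boundaries <- c(which(diff(steps) != 0), n)
  for (bnd in boundaries) {
    L <- bnd - run_start + 1
    r <- steps[run_start]
    cvec <- op$P %*% (b * r)
    w0 <- Vinv %*% x
    wc <- Vinv %*% cvec
    m <- seq_len(L)
    lam_m <- outer(lam, m, `^`)           # 5 x L
    S <- sweep(lam_m - 1, 1, lam - 1, `/`)
    unit <- abs(lam - 1) < 1e-12
    if (any(unit)) S[unit, ] <- matrix(m, sum(unit), L, byrow = TRUE)
    xs <- V %*% (lam_m * drop(w0) + S * drop(wc))
    xs <- Re(xs)
    states[, run_start + m] <- xs
    x <- xs[, L]
    run_start <- bnd + 1
  }
  states
}

#' Total drug infused up to each time of a trajectory grid
#'
#' @param schedule An infusion schedule tibble.
#' @param times_s Numeric vector of times (s).
#' @return Cumulative infused amount (mg) at each time.
#' @export
infused_mg_at <- function(schedule, times_s) {
  out <- numeric(length(times_s))
  for (i in seq_len(nrow(schedule))) {
    dur <- pmin(pmax(times_s - schedule$t_start_s[i], 0),
                schedule$t_end_s[i] - schedule$t_start_s[i])
    out <- out + dur / 60 * schedule$rate_mg_min[i]
  }
  out
}

#' Export a concentration trajectory as delimited text
#'
#' Writes `time_s`, `cp_ug_ml`, `ce_ug_ml` as comma-separated text.
#'
#' @param trajectory A `ce_trajectory` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(trajectory[, c("time_s", "cp_ug_ml", "ce_ug_ml")], path)
  invisible(path)
}
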