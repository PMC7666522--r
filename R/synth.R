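#' Default blink-reflex component templates
#'
#' Template parameters for the two EMG components of the electrically evoked
#' blink reflex: R1, the brief early ipsilateral response (latency about
#' 10 ms), and R2, the prolonged later response that drives the visible
#' blink (latency about 30 ms). Each component is synthesised as a
#' Gaussian-envelope cosine burst whose energy is confined to its analysis
#' window, and whose amplitude fades linearly to abolition at a
#' patient-specific effect-site concentration: R2 is abolished at the
#' patient's `ce_lor2` and R1 at `ce_lor1`, so R2 always disappears first.
#'
#' @return A tibble with one row per component: `name`, `latency_ms`,
#'   `env_width_ms` (Gaussian envelope SD), `center_freq_hz`,
#'   `baseline_amp_uv`, `gamma` (attenuation exponent; 1 = linear fade),
#'   `jitter_sd_ms` (trial-to-trial latency jitter), `window_lo_ms`,
#'   `window_hi_ms` (energy confinement bounds, matching the T1/T2 analysis
#'   windows) and `threshold` (which patient Ce threshold abolishes it).
#' @export
reflex_components <- function() {
  tibble::tribble(
    ~name, ~latency_ms, ~env_width_ms, ~center_freq_hz, ~baseline_amp_uv,
    ~gamma, ~jitter_sd_ms, ~window_lo_ms, ~window_hi_ms, ~threshold,
    "R1",  10.5,         1.5,           150,             80,
    1,      0.2,           10,            25,            "ce_lor1",
    "R2",  32,           12,             60,              50,
    1,      1.0,           25,            200,           "ce_lor2"
  )
}

#' Default simulated population
#'
#' Population-level calibration of the synthetic cohort: the three
#' loss-of-response thresholds (Ce at loss of R2, loss of R1, and loss of
#' responsiveness) are drawn from independent truncated normals with the
#' study cohort's means and SDs, demographics from the study cohort's
#' summary statistics, and the aRASS staircase is placed at fixed fractions
#' of each patient's LORP threshold, chosen so the median aRASS at LOR2 and
#' LOR1 reproduces the cohort medians (0 and -2).
#'
#' The three thresholds share a patient-level sensitivity factor
#' (equicorrelation `ce_correlation`): patients who tolerate more propofol
#' before losing one response tolerate more before losing the others, which
#' both matches the premise of wide between-patient dose variability and
#' keeps ordering violations rare, so that the rejection step does not
#' distort the calibrated marginal means.
#'
#' @return A named list of population parameters.
#' @export
default_population <- function() {
  list(
    ce_mean = c(lor2 = 1.45, lor1 = 2.99, lorp = 4.22),
    ce_sd = c(lor2 = 0.85, lor1 = 1.19, lorp = 1.24),
    ce_floor = 0.1,
    ce_correlation = 0.9,
    age_mean = 61, age_sd = 13,
    weight_mean = 72, weight_sd = 11,
    height_mean = 162, height_sd = 9,
    p_female = 16 / 25,
    arass_fractions = c(0.45, 0.62, 0.78, 0.92, 1.00),
    noise_sd_uv = 2
  )
}

rtruncnorm1 <- function(mean, sd, lower, upper = Inf, n_max = 1000) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      abort("Degenerate draw: zero-SD mean outside the truncation bounds.")
    }
    return(mean)
  }
  for (i in seq_len(n_max)) {
    x <- rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  abort("Truncated-normal rejection sampling failed after 1000 draws.")
}

#' Draw the three Ce thresholds of one patient
#'
#' Each threshold is normal with its calibrated mean and SD; the triple is
#' coupled through a shared standard-normal sensitivity factor so that
#' `cor(x_j, x_k) = ce_correlation` for j != k. The `ce_floor` truncation
#' is applied per component by drawing the component's idiosyncratic
#' deviate from its truncated conditional (inverse-CDF) given the shared
#' factor — a whole-triple rejection at the floor would preferentially
#' discard low-sensitivity patients and inflate all three means. The whole
#' triple is redrawn only when it is not strictly ordered
#' (LOR2 < LOR1 < LORP). The number of attempts is returned so the
#' rejection rate can be audited.
#'
#' @param population A population list, see [default_population()].
#' @param max_redraws Redraw cap; exceeding it signals a degenerate
#'   configuration.
#' @return A list with `thresholds` (named numeric: lor2, lor1, lorp) and
#'   `attempts` (number of triples drawn, including rejected ones).
#' @export
draw_ce_thresholds <- function(population = default_population(),
                               max_redraws = 1000) {
  rho <- population$ce_correlation %||% 0
  keys <- c("lor2", "lor1", "lorp")
  mu <- vapply(keys, function(k) population$ce_mean[[k]], numeric(1))
  sig <- vapply(keys, function(k) population$ce_sd[[k]], numeric(1))
  fl <- population$ce_floor
  if (any(sig == 0) && any(mu[sig == 0] < fl)) {
    abort("Degenerate population: a zero-SD threshold mean lies below the floor.")
  }
  for (attempt in seq_len(max_redraws)) {
    z0 <- rnorm(1)
    x <- numeric(3)
    for (k in 1:3) {
      if (sig[k] == 0) { x[k] <- mu[k]; next }
      lo <- ((fl - mu[k]) / sig[k] - sqrt(rho) * z0) / sqrt(1 - rho)
      plo <- stats::pnorm(lo)
      zk <- stats::qnorm(plo + runif(1) * (1 - plo))
      if (!is.finite(zk)) zk <- lo # saturated far tail: pin at the bound
      x[k] <- mu[k] + sig[k] * (sqrt(rho) * z0 + sqrt(1 - rho) * zk)
    }
    names(x) <- keys
    if (x[["lor2"]] < x[["lor1"]] && x[["lor1"]] < x[["lorp"]]) {
      return(list(thresholds = x, attempts = attempt))
    }
  }
  abort(sprintf(
    "Could not draw strictly ordered Ce thresholds in %d attempts; the population configuration is degenerate.",
    max_redraws))
}

#' Draw a synthetic patient profile
#'
#' Samples demographics and the three Ce thresholds from the population
#' model and attaches the aRASS staircase and noise calibration.
#'
#' @param population A population list, see [default_population()].
#' @param seed Optional integer; if given, seeds the RNG before drawing.
#' @param patient_id Identifier stored in the profile.
#' @return A one-row tibble: `patient_id`, `age`, `weight`, `height`, `sex`,
#'   `ce_lor2`, `ce_lor1`, `ce_lorp`, `arass_fractions` (list column),
#'   `noise_sd_uv`, `rng_seed`, `threshold_attempts`.
#' @export
draw_patient <- function(population = default_population(), seed = NULL,
                         patient_id = 1L) {
  if (!is.null(seed)) set.seed(seed)
  thr <- draw_ce_thresholds(population)
  # bounds keep the Schnider covariate model valid (V2 > 0 needs age < 101)
  # and the demographics within a plausible adult surgical population
  age <- rtruncnorm1(population$age_mean, population$age_sd, 18, 95)
  weight <- rtruncnorm1(population$weight_mean, population$weight_sd, 40, 120)
  height <- rtruncnorm1(population$height_mean, population$height_sd, 140, 200)
  sex <- if (runif(1) < population$p_female) "female" else "male"
  fr <- population$arass_fractions
  if (length(fr) != 5 || any(diff(fr) <= 0) || tail(fr, 1) != 1) {
    abort("`arass_fractions` must be 5 strictly ascending fractions ending at 1.")
  }
  tibble(
    patient_id = patient_id,
    age = age, weight = weight, height = height, sex = sex,
    ce_lor2 = thr$thresholds[["lor2"]],
    ce_lor1 = thr$thresholds[["lor1"]],
    ce_lorp = thr$thresholds[["lorp"]],
    arass_fractions = list(fr),
    noise_sd_uv = population$noise_sd_uv,
    rng_seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    threshold_attempts = thr$attempts
  )
}

#' Concentration-dependent component scale
#'
#' Attenuation of a reflex component with effect-site concentration:
#' `max(0, 1 - ce/abolition_ce)^gamma`. Exactly 1 at Ce = 0 and exactly 0 at
#' and above the abolition threshold; monotone nonincreasing in Ce.
#'
#' @param ce Effect-site concentration(s), µg/mL (>= 0).
#' @param abolition_ce Abolition threshold, µg/mL (> 0).
#' @param gamma Attenuation exponent (> 0); 1 gives a linear fade.
#' @return Scale factor(s) in `[0, 1]`.
#' @export
component_scale <- function(ce, abolition_ce, gamma = 1) {
  if (any(ce < 0)) abort("`ce` must be >= 0.")
  if (abolition_ce <= 0) abort("`abolition_ce` must be > 0.")
  pmax(0, 1 - ce / abolition_ce)^gamma
}

#' aRASS score at a given effect-site concentration
#'
#' Deterministic staircase: score `-k` is assigned once Ce reaches the k-th
#' fraction of the patient's LORP threshold; 0 below the first fraction and
#' exactly -5 at and above `ce_lorp`.
#'
#' @param ce Effect-site concentration(s), µg/mL (>= 0).
#' @param ce_lorp LORP threshold, µg/mL.
#' @param fractions Five ascending fractions of `ce_lorp`, last = 1.
#' @return Integer aRASS score(s) in `{0, -1, ..., -5}`.
#' @export
arass_at <- function(ce, ce_lorp,
                     fractions = default_population()$arass_fractions) {
  if (any(ce < 0)) abort("`ce` must be >= 0.")
  cuts <- fractions * ce_lorp
  -vapply(ce, function(x) sum(x >= cuts), numeric(1))
}

#' Synthesise one blink-reflex EMG sweep
#'
#' A 200-ms, 10-kHz sweep: 20-Hz high-passed (4th-order Butterworth,
#' zero-phase) white Gaussian noise plus, for each reflex component, a
#' Gaussian-envelope cosine burst centred at the component latency (with
#' small trial-to-trial jitter), scaled by [component_scale()] at the
#' current Ce. Burst energy is confined to the component's analysis window
#' so that the T1/T2 split of the analysis pipeline is exact.
#'
#' @param profile A one-row patient profile from [draw_patient()].
#' @param ce Effect-site concentration at the stimulus, µg/mL.
#' @param stim_time_s Stimulus time, seconds since infusion start (negative
#'   for baseline stimuli).
#' @param components Component template tibble, see [reflex_components()].
#' @param fs Sampling rate, Hz.
#' @param duration_s Sweep duration, seconds.
#' @return A list with `stim_time_s`, `fs`, `true_ce` and `samples`
#'   (numeric, µV).
#' @export
synth_sweep <- function(profile, ce, stim_time_s = 0,
                        components = reflex_components(),
                        fs = 10000, duration_s = 0.2) {
  n <- round(fs * duration_s)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  samples <- numeric(n)
  if (profile$noise_sd_uv > 0) {
    noise <- rnorm(n, 0, profile$noise_sd_uv)
    hp <- butter_highpass(4, 20, fs)
    samples <- filtfilt(noise, hp$b, hp$a)
  }
  for (i in seq_len(nrow(components))) {
    comp <- components[i, ]
    thr <- profile[[comp$threshold]]
    sc <- component_scale(ce, thr, comp$gamma)
    if (sc <= 0) next
    lat <- comp$latency_ms + rnorm(1, 0, comp$jitter_sd_ms)
    env <- exp(-(t_ms - lat)^2 / (2 * comp$env_width_ms^2))
    env[t_ms < comp$window_lo_ms | t_ms >= comp$window_hi_ms] <- 0
    # the envelope is truncated to the analysis window, so two spectral
    # hygiene measures matter: the carrier phase is anchored at the window's
    # left edge (the burst starts at zero there, no step discontinuity and
    # no broadband spill), and an envelope-scaled offset keeps the burst's
    # net area exactly zero so that sweep-level DC removal / detrending does
    # not smear burst energy into the other analysis window
    carrier <- sin(2 * pi * comp$center_freq_hz * (t_ms - comp$window_lo_ms) / 1000)
    alpha <- sum(env * carrier) / sum(env)
    burst <- sc * comp$baseline_amp_uv * env * (carrier - alpha)
    samples <- samples + burst
  }
  list(stim_time_s = stim_time_s, fs = fs, true_ce = ce, samples = samples)
}

sweep_list_to_tibble <- function(sweeps) {
  tibble(
    sweep_id = seq_along(sweeps),
    stim_time_s = vapply(sweeps, `[[`, numeric(1), "stim_time_s"),
    true_ce = vapply(sweeps, `[[`, numeric(1), "true_ce"),
    fs = vapply(sweeps, `[[`, numeric(1), "fs"),
    samples = lapply(sweeps, `[[`, "samples")
  )
}

#' Simulate one full induction session
#'
#' Runs the pharmacokinetic model under the study infusion protocol,
#' stimulates the supraorbital nerve every `isi_s` seconds (with
#' `n_baseline` pre-infusion baseline stimuli), records an aRASS sedation
#' record at every stimulus, and stops the infusion at the first stimulus
#' with aRASS -5. Ground-truth endpoints are the Ce threshold crossing
#' times (LOR2, LOR1) and the first -5 record (LORP).
#'
#' @param profile A one-row patient profile from [draw_patient()].
#' @param components Component template tibble.
#' @param isi_s Inter-stimulus interval, seconds.
#' @param n_baseline Number of baseline stimuli before infusion start (>= 4).
#' @param n_post Number of stimuli recorded after the first aRASS -5 record
#'   (the infusion is already stopped); keeping a short observation tail
#'   lets the sliding 4-sweep average reveal the loss of a component that
#'   happens close to LORP.
#' @param dt_s Integration step for the pharmacokinetic grid, seconds.
#' @param horizon_s Maximum simulated time; an error is raised if Ce never
#'   reaches the patient's LORP threshold before it.
#' @param rate_ml_kg_h,mg_per_ml Infusion protocol parameters.
#' @return A list of class `blink_session`: `profile`, `model`, `schedule`,
#'   `trajectory`, `sweeps` (tibble with list-column `samples`), `sedation`
#'   (tibble `time_s`, `arass`, `ce_ug_ml`), `truth` (tibble `endpoint`,
#'   `time_s`, `ce_ug_ml`) and `isi_s`.
#' @export
simulate_session <- function(profile, components = reflex_components(),
                             isi_s = 6, n_baseline = 4, n_post = 4,
                             dt_s = 0.1, horizon_s = 1800,
                             rate_ml_kg_h = 3.3, mg_per_ml = 10) {
  stopifnot(is.data.frame(profile), nrow(profile) == 1)
  if (n_baseline < 4) abort("At least 4 baseline stimuli are required.")
  if (!is.na(profile$rng_seed)) set.seed(profile$rng_seed)

  demo <- demographics(profile$age, profile$weight, profile$height, profile$sex)
  model <- schnider_parameters(demo)

  # Integrate in growing chunks until Ce crosses the LORP threshold.
  t_end <- 420
  repeat {
    schedule <- protocol_infusion(demo, t_end, rate_ml_kg_h, mg_per_ml)
    traj <- simulate_infusion(model, schedule, dt_s, t_end)
    if (any(traj$ce_ug_ml >= profile$ce_lorp)) break
    if (t_end >= horizon_s) {
      abort(sprintf(
        "Ce never reached the LORP threshold (%.2f ug/mL) within %d s.",
        profile$ce_lorp, horizon_s))
    }
    t_end <- min(2 * t_end, horizon_s)
  }

  fractions <- profile$arass_fractions[[1]]
  ce_at <- function(t) {
    out <- approx(traj$time_s, traj$ce_ug_ml, xout = pmax(t, 0), rule = 2)$y
    out[t < 0] <- 0
    out
  }

  # First stimulus at which the staircase reaches -5.
  cross_idx <- which(traj$ce_ug_ml >= profile$ce_lorp)[1]
  t_cross <- traj$time_s[cross_idx]
  t_lorp <- ceiling(t_cross / isi_s) * isi_s
  if (ce_at(t_lorp) < profile$ce_lorp) t_lorp <- t_lorp + isi_s # grid guard

  # The infusion stops at the first -5 record, but observation continues for
  # n_post further stimuli: re-integrate with the truncated schedule so the
  # tail Ce reflects the stopped pump (effect-site Ce keeps equilibrating).
  t_tail <- t_lorp + n_post * isi_s
  schedule <- protocol_infusion(demo, t_lorp, rate_ml_kg_h, mg_per_ml)
  traj <- simulate_infusion(model, schedule, dt_s, t_tail)

  stim_times <- seq(-n_baseline * isi_s, t_tail, by = isi_s)
  ce_stim <- ce_at(stim_times)
  arass <- arass_at(ce_stim, profile$ce_lorp, fractions)
  # LORP is determined once, clinically: the score stays -5 for the short
  # post-stop observation tail even if Ce hovers around the threshold
  i5 <- which(arass == -5)[1]
  if (!is.na(i5)) arass[i5:length(arass)] <- -5

  sweeps <- lapply(seq_along(stim_times), function(i) {
    synth_sweep(profile, ce_stim[i], stim_times[i], components)
  })

  # Truth: linear-interpolated threshold crossing times on the Ce grid.
  crossing_time <- function(threshold) {
    i <- which(traj$ce_ug_ml >= threshold)[1]
    if (i == 1) return(traj$time_s[1])
    t0 <- traj$time_s[i - 1]; t1 <- traj$time_s[i]
    c0 <- traj$ce_ug_ml[i - 1]; c1 <- traj$ce_ug_ml[i]
    t0 + (threshold - c0) / (c1 - c0) * (t1 - t0)
  }
  truth <- tibble(
    endpoint = c("lor2", "lor1", "lorp"),
    time_s = c(crossing_time(profile$ce_lor2),
               crossing_time(profile$ce_lor1),
               t_lorp),
    ce_ug_ml = c(profile$ce_lor2, profile$ce_lor1, ce_at(t_lorp))
  )

  class(traj) <- c("ce_trajectory", class(tibble()))

  out <- list(
    profile = profile,
    model = model,
    schedule = protocol_infusion(demo, t_lorp, rate_ml_kg_h, mg_per_ml),
    trajectory = traj,
    sweeps = sweep_list_to_tibble(sweeps),
    sedation = tibble(time_s = stim_times, arass = as.integer(arass),
                      ce_ug_ml = ce_stim),
    truth = truth,
    isi_s = isi_s
  )
  class(out) <- "blink_session"
  out
}

#' @export
print.blink_session <- function(x, ...) {
  cat(sprintf(
    "<blink_session> patient %s: %d sweeps every %g s, LORP at %.1f s (Ce %.2f ug/mL)\n",
    x$profile$patient_id, nrow(x$sweeps), x$isi_s,
    x$truth$time_s[x$truth$endpoint == "lorp"],
    x$truth$ce_ug_ml[x$truth$endpoint == "lorp"]))
  invisible(x)
}

# Derive a per-patient seed from the master seed so that adding patients
# never changes earlier patients' data.
patient_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 48271 + i * 104729) %% 2147483647)
}

#' Simulate a cohort of induction sessions
#'
#' Draws `n_patients` profiles from the population model and simulates each
#' patient's session with an independent RNG stream derived from
#' `(seed, patient index)`. By default each session is reduced to its
#' detected and true endpoints so that large cohorts fit in memory.
#'
#' @param n_patients Number of patients.
#' @param seed Master seed (integer).
#' @param population Population list, see [default_population()].
#' @param noise_sd_uv Optional override of the population EMG noise SD
#'   (use 0 for noise-free sweeps).
#' @param detect If `TRUE`, run [detect_endpoints()] on each session and
#'   return one row per patient (detected plus true endpoints); if `FALSE`,
#'   return the list of `blink_session` objects.
#' @param ... Passed on to [simulate_session()].
#' @return A tibble (if `detect`) or a list of sessions.
#' @export
simulate_cohort <- function(n_patients, seed = 1, population = default_population(),
                            noise_sd_uv = NULL, detect = TRUE, ...) {
  if (!is.null(noise_sd_uv)) population$noise_sd_uv <- noise_sd_uv
  run_one <- function(i) {
    s <- patient_seed(seed, i)
    set.seed(s)
    profile <- draw_patient(population, patient_id = i)
    profile$rng_seed <- patient_seed(s, 1)
    session <- simulate_session(profile, ...)
    if (!detect) return(session)
    rec <- detect_endpoints(session)
    truth <- session$truth
    rec$true_lor2_ce <- truth$ce_ug_ml[truth$endpoint == "lor2"]
    rec$true_lor1_ce <- truth$ce_ug_ml[truth$endpoint == "lor1"]
    rec$true_lorp_ce <- session$profile$ce_lorp
    rec$true_lor2_time <- truth$time_s[truth$endpoint == "lor2"]
    rec$true_lor1_time <- truth$time_s[truth$endpoint == "lor1"]
    rec$true_lorp_time <- truth$time_s[truth$endpoint == "lorp"]
    rec
  }
  out <- lapply(seq_len(n_patients), run_one)
  if (detect) dplyr::bind_rows(out) else out
}
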