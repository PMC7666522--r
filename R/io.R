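#' Write sweeps as delimited text
#'
#' Long format, exact precision: one row per sample with columns
#' `sweep_id`, `stim_time_s`, `true_ce`, `fs`, `sample_idx` (0-based),
#' `amplitude_uv`. This is the package's lossless interchange format for
#' per-stimulus EMG sweeps.
#'
#' @param sweeps A sweeps tibble (as in a session's `sweeps`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(sweeps, path) {
  long <- tidyr::unnest(
    dplyr::mutate(sweeps,
                  sample_idx = lapply(samples, function(s) seq_along(s) - 1L),
                  amplitude_uv = samples),
    cols = c("sample_idx", "amplitude_uv"))
  # %.17g guarantees binary round-trip of the doubles through text
  lines <- sprintf("%d,%.17g,%.17g,%.17g,%d,%.17g",
                   long$sweep_id, long$stim_time_s, long$true_ce, long$fs,
                   long$sample_idx, long$amplitude_uv)
  writeLines(c("sweep_id,stim_time_s,true_ce,fs,sample_idx,amplitude_uv",
               lines), path)
  invisible(path)
}

#' Read sweeps from delimited text
#'
#' Inverse of [write_sweeps()]. Every sweep must have the expected
#' geometry (consistent sampling rate, contiguous 0-based sample indices);
#' a malformed record raises an error naming the sweep.
#'
#' @param path Input file path.
#' @param expected_fs Required sampling rate, Hz (`NULL` to skip the check).
#' @param expected_n Required samples per sweep (`NULL` to skip).
#' @return A sweeps tibble with list-column `samples`.
#' @export
read_sweeps <- function(path, expected_fs = 10000, expected_n = 2000) {
  # base read.csv parses doubles with correctly-rounded strtod, preserving
  # the bit-exact round-trip that write_sweeps() guarantees
  long <- tibble::as_tibble(utils::read.csv(path))
  req <- c("sweep_id", "stim_time_s", "true_ce", "fs", "sample_idx", "amplitude_uv")
  if (!all(req %in% names(long))) {
    abort(paste0("Sweep file lacks required columns: ",
                 paste(setdiff(req, names(long)), collapse = ", ")))
  }
  split_rows <- split(long, long$sweep_id)
  rows <- lapply(split_rows, function(d) {
    d <- d[order(d$sample_idx), ]
    id <- d$sweep_id[1]
    if (!identical(as.integer(d$sample_idx), seq_len(nrow(d)) - 1L)) {
      abort(sprintf("Sweep %s: sample indices are not contiguous from 0.", id))
    }
    if (!is.null(expected_n) && nrow(d) != expected_n) {
      abort(sprintf("Sweep %s: %d samples, expected %d.", id, nrow(d), expected_n))
    }
    if (!is.null(expected_fs) && any(d$fs != expected_fs)) {
      abort(sprintf("Sweep %s: sampling rate %g, expected %g.", id, d$fs[1], expected_fs))
    }
    tibble(sweep_id = id, stim_time_s = d$stim_time_s[1], true_ce = d$true_ce[1],
           fs = d$fs[1], samples = list(d$amplitude_uv))
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$stim_time_s), ]
}

#' Write / read a sedation table
#'
#' Delimited text with columns `time_s`, `arass`, `ce_ug_ml`.
#'
#' @param sedation A sedation tibble.
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_sedation <- function(sedation, path) {
  readr::write_csv(sedation[, c("time_s", "arass", "ce_ug_ml")], path)
  invisible(path)
}

#' @rdname write_sedation
#' @export
read_sedation <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "arass", "ce_ug_ml") %in% names(out))) {
    abort("Sedation file needs columns time_s, arass, ce_ug_ml.")
  }
  out
}

#' Pipeline configuration
#'
#' All tunable parameters of the simulation-and-analysis pipeline with
#' their documented defaults. Unknown keys are rejected so that typos do
#' not silently fall back to defaults.
#'
#' @param ... Overrides of the default keys.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_patients = 10L,
    noise_sd_uv = NULL,          # NULL = population default
    pk_dt_s = 0.1,
    pk_ke0_per_min = schnider_value("ke0"),
    protocol_infusion_ml_kg_h = 3.3,
    protocol_propofol_mg_per_ml = 10,
    isi_s = 6,
    n_baseline = 4L,
    band_hz = c(30, 120),
    pk_threshold = 0.700,
    r_threshold = 0.500,
    presence_k = "auto",
    presence_alpha = 1e-3,
    mlr_predictors = "auto"      # "auto" (Pk-selected) or "paper-eq1"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates a cohort, extracts features, computes the Pk/correlation
#' table, selects predictors and fits the multinomial sedation model,
#' detects endpoints and writes all artifacts (`features.csv`,
#' `pk_table.csv`, `model.json`, `endpoints.csv`, `summary.txt`,
#' `resolved_config.json`) into `out_dir`. Reruns with the same seed are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts: `features`,
#'   `pk_table`, `model`, `diagnostics`, `endpoints`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    sessions <- simulate_cohort(
      config$n_patients, seed = config$seed, noise_sd_uv = config$noise_sd_uv,
      detect = FALSE, isi_s = config$isi_s, n_baseline = config$n_baseline,
      dt_s = config$pk_dt_s, rate_ml_kg_h = config$protocol_infusion_ml_kg_h,
      mg_per_ml = config$protocol_propofol_mg_per_ml)

    stage <- "features"
    features <- dplyr::bind_rows(lapply(sessions, session_features,
                                        band = config$band_hz))

    stage <- "pk"
    pk_tbl <- pk_table(features)

    stage <- "fit-mlr"
    wide <- pivot_features_wide(features)
    wide <- wide[stats::complete.cases(wide), ]
    predictors <- if (identical(config$mlr_predictors, "paper-eq1")) {
      intersect(paper_predictors(), names(wide))
    } else {
      sel <- select_features(pk_tbl, config$pk_threshold, config$r_threshold)
      preds <- unique(c("ce_ug_ml", paste0(sel$feature, "_", sel$window)))
      # v_diff = 1 - v_mean: keep only one of the aliased pair per window
      aliased <- preds[grepl("^v_diff_", preds) &
                         sub("^v_diff_", "v_mean_", preds) %in% preds]
      setdiff(preds, aliased)
    }
    model <- fit_multinomial(wide, "arass", predictors)
    diagnostics <- mlr_diagnostics(model)

    stage <- "endpoints"
    endpoints <- dplyr::bind_rows(lapply(sessions, detect_endpoints,
                                         k = config$presence_k,
                                         alpha = config$presence_alpha))

    stage <- "report"
    summary <- summarize_cohort(endpoints)

    list(features = features, pk_table = pk_tbl, model = model,
         diagnostics = diagnostics, endpoints = endpoints, summary = summary)
  }, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null",
                               digits = NA)
  stamp <- list(seed = config$seed,
                config_hash = sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)))))

  write_features(result$features, file.path(out_dir, "features.csv"))
  readr::write_csv(result$pk_table, file.path(out_dir, "pk_table.csv"))
  readr::write_csv(result$endpoints, file.path(out_dir, "endpoints.csv"))
  model_json <- list(
    stamp = stamp,
    reference_class = result$model$reference,
    levels = result$model$levels,
    predictors = result$model$predictors,
    coefficients = result$model$coefficients,
    log_likelihood = result$model$log_likelihood,
    overall = as.list(result$diagnostics$overall),
    nagelkerke_r2 = result$diagnostics$nagelkerke_r2,
    accuracy = result$diagnostics$accuracy,
    lr_tests = result$diagnostics$lr_tests
  )
  jsonlite::write_json(model_json, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  writeLines(c(
    sprintf("seed %d  config %s", stamp$seed, stamp$config_hash),
    utils::capture.output(print(result$summary))
  ), file.path(out_dir, "summary.txt"))
  writeLines(as.character(cfg_json), file.path(out_dir, "resolved_config.json"))
  invisible(result)
}
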