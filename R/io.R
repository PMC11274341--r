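# Configuration, serialization and a programmatic command dispatcher.
# Long-format tidy CSV for data, JSON for structured results, YAML for
# configs -- diff-able and spreadsheet-friendly.

#' Write / read run conditions as YAML
#'
#' @param conditions List of [run_condition()]s (or a single one).
#' @param path File path.
#' @return `read_run_conditions` returns a list of [run_condition()]s.
#' @export
write_run_conditions <- function(conditions, path) {
  if (inherits(conditions, "run_condition")) conditions <- list(conditions)
  yaml::write_yaml(lapply(conditions, unclass), path)
  invisible(path)
}

#' @rdname write_run_conditions
#' @export
read_run_conditions <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    run_condition(
      c_mab = x$c_mab, drug_excess = x$drug_excess, mode = x$mode,
      feed_duration = if (identical(x$mode, "fedbatch")) x$feed_duration,
      initial_volume = x$initial_volume,
      feed_volume = if (identical(x$mode, "fedbatch")) x$feed_volume
                    else 0.1 * x$initial_volume,
      sample_times = unlist(x$sample_times),
      sample_volume = x$sample_volume, t_end = x$t_end,
      mab_molar_mass = x$mab_molar_mass
    )
  })
}

#' Write a simulated trajectory as tidy CSV
#'
#' Columns: `run_id`, `time_s`, `species`, `concentration_mmol_l`. Observable
#' species plus `drug` (free payload).
#'
#' @param sim A `conj_sim`.
#' @param path File path.
#' @param run_id Run identifier.
#' @export
write_trajectory_csv <- function(sim, path, run_id = "run1") {
  stopifnot(inherits(sim, "conj_sim"))
  obs <- cbind(sim$observed, drug = sim$free_drug)
  long <- data.frame(
    run_id = run_id,
    time_s = rep(sim$times, times = ncol(obs)),
    species = rep(colnames(obs), each = nrow(obs)),
    concentration_mmol_l = as.numeric(obs)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write / read kinetic observations as tidy CSV
#'
#' Long format with columns `run_id`, `time_s`, `species`,
#' `concentration_mmol_l`; one condition YAML alongside is the canonical way
#' to round-trip a dataset's run conditions.
#'
#' @param dataset A [kinetic_dataset()].
#' @param path CSV path.
#' @return `read_kinetic_csv` returns the long data frame (reassembly into a
#'   dataset requires the run conditions).
#' @export
write_kinetic_csv <- function(dataset, path) {
  rows <- list()
  for (i in seq_along(dataset$runs)) {
    run <- dataset$runs[[i]]
    rid <- if (is.null(run$run_id)) sprintf("run%02d", i) else run$run_id
    rows[[i]] <- data.frame(
      run_id = rid, role = dataset$roles[i],
      time_s = rep(run$times, times = ncol(run$observed)),
      species = rep(colnames(run$observed), each = nrow(run$observed)),
      concentration_mmol_l = as.numeric(run$observed)
    )
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinetic_csv
#' @export
read_kinetic_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a fit result to JSON
#'
#' @param fit A [fit_rates()] result.
#' @param path JSON path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "conj_fit"))
  out <- list(
    modality = fit$spec$modality, variant = fit$spec$variant,
    estimates = as.list(fit$estimates), sigma = as.list(fit$sigma),
    ci_lb = as.list(stats::setNames(fit$ci[, "lb"], names(fit$estimates))),
    ci_ub = as.list(stats::setNames(fit$ci[, "ub"], names(fit$estimates))),
    s2 = fit$s2, k_drug = fit$k_drug,
    rmse_by_species = as.list(fit$rmse_by_species),
    rmse_train = fit$rmse_train, rmse_cv = fit$rmse_cv, rmse_p = fit$rmse_p,
    n_obs = fit$n_obs, n_params = fit$n_params, converged = fit$converged
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Summary table of calibrated model candidates
#'
#' One row per estimated rate with estimate, standard deviation, confidence
#' bounds (L mmol^-1 s^-1) and the candidate's RMSECV / RMSEP (umol/L) on its
#' first row -- the conventional calibration-report layout.
#'
#' @param fits Named list of [fit_rates()] results (names label the
#'   candidates, e.g. `"DAR 8 detailed (4k)"`).
#' @param path Optional CSV path to write to.
#' @return The summary data frame (invisibly if `path` given).
#' @export
write_model_summary <- function(fits, path = NULL) {
  rows <- list()
  for (lab in names(fits)) {
    fit <- fits[[lab]]
    for (j in seq_along(fit$estimates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = if (j == 1) lab else "",
        parameter = names(fit$estimates)[j],
        estimate = unname(fit$estimates[j]),
        sigma = unname(fit$sigma[j]),
        lb = fit$ci[j, "lb"], ub = fit$ci[j, "ub"],
        rmse_cv = if (j == 1) fit$rmse_cv else NA_real_,
        rmse_p = if (j == 1) fit$rmse_p else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    return(invisible(tab))
  }
  tab
}

#' Write a screening result as long-format CSV
#'
#' @param result A [screen_conditions()] result.
#' @param path CSV path.
#' @export
write_screening_csv <- function(result, path) {
  stopifnot(inherits(result, "screening_result"))
  utils::write.csv(result$grid, path, row.names = FALSE)
  invisible(path)
}

#' Load a project configuration from YAML
#'
#' Recognized fields: `preset`, `modality`, `variant`, `payload`, `seed`,
#' `out_dir`, `estimation` (list: `init`, `lower`, `upper`, `multi_start`),
#' `screening` (list: `c_mab_min/max/n`, `excess_min/max/n`), `noise`
#' (list: `relative_sd`, `absolute_sd`) and optional `paths` (named file
#' paths, all of which must exist).
#'
#' @param path YAML path.
#' @return List of class `project_config` with defaults filled in.
#' @export
load_project_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(preset = "dataset1_DAR2_Drug1", modality = NULL,
                   variant = NULL, payload = NULL, seed = 1L,
                   out_dir = ".", estimation = list(), screening = list(),
                   noise = list(), paths = list())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  }
  structure(cfg, class = "project_config")
}

#' Run one pipeline command programmatically
#'
#' The package's command surface: `generate` (synthetic dataset -> CSV +
#' truth JSON), `simulate` (preset run 1 trajectory -> CSV), `fit`
#' (generate + calibrate -> fit JSON), `cv` (leave-one-run-out -> JSON),
#' `sensitivity` (OAT report -> JSON), `screen` (grid -> CSV) and `report`
#' (fit + CV summary table -> CSV). Outputs land in `config$out_dir`; every
#' stochastic step is seeded from `config$seed`.
#'
#' @param command One of `"generate"`, `"simulate"`, `"fit"`, `"cv"`,
#'   `"sensitivity"`, `"screen"`, `"report"`.
#' @param config A [load_project_config()] result or a plain list with the
#'   same fields.
#' @return Named list of written file paths (invisibly) plus the main result.
#' @export
run_command <- function(command = c("generate", "simulate", "fit", "cv",
                                    "sensitivity", "screen", "report"),
                        config) {
  command <- match.arg(command)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  preset <- dataset_preset(config$preset)
  nm <- config$noise
  noise <- noise_model(
    relative_sd = if (is.null(nm$relative_sd)) 0.02 else nm$relative_sd,
    absolute_sd = if (is.null(nm$absolute_sd)) 2e-5 else nm$absolute_sd,
    seed = config$seed
  )
  out <- file.path(config$out_dir, paste0(command, "_", preset$name))
  if (command == "generate") {
    ds <- generate_dataset(preset, noise)
    write_kinetic_csv(ds, paste0(out, ".csv"))
    truth <- attr(ds, "truth")
    jsonlite::write_json(
      list(preset = truth$preset, seed = truth$seed,
           conjugation_rates = truth$rates$conjugation_rates,
           k_drug = truth$rates$k_drug),
      paste0(out, "_truth.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(list(result = ds, files = paste0(out, c(".csv", "_truth.json")))))
  }
  if (command == "simulate") {
    sim <- simulate_conjugation(preset$spec, preset$rates,
                                preset$conditions[[1]], preset$distribution)
    write_trajectory_csv(sim, paste0(out, ".csv"),
                         run_id = paste0(preset$name, "_run01"))
    return(invisible(list(result = sim, files = paste0(out, ".csv"))))
  }
  ds <- generate_dataset(preset, noise)
  est <- config$estimation
  fit_args <- list(dataset = ds,
                   init = est$init, lower = if (is.null(est$lower)) 0 else est$lower,
                   upper = if (is.null(est$upper)) 100 else est$upper,
                   multi_start = isTRUE(est$multi_start))
  if (command == "fit") {
    fit <- do.call(fit_rates, fit_args)
    write_fit_json(fit, paste0(out, ".json"))
    return(invisible(list(result = fit, files = paste0(out, ".json"))))
  }
  if (command == "cv") {
    cv <- cross_validate_loro(ds, init = est$init)
    jsonlite::write_json(list(rmse_cv = cv$rmse_cv, fold_rmse = cv$fold_rmse),
                         paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(list(result = cv, files = paste0(out, ".json"))))
  }
  if (command == "sensitivity") {
    fit <- do.call(fit_rates, fit_args)
    sens <- oat_sensitivity(ds, rate_set(fit$estimates, ds$k_drug))
    jsonlite::write_json(
      list(sum_delta_msqr = as.list(sens$sum_delta_msqr),
           ranking = sens$ranking),
      paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(list(result = sens, files = paste0(out, ".json"))))
  }
  if (command == "screen") {
    sc <- config$screening
    g <- function(field, default) if (is.null(sc[[field]])) default else sc[[field]]
    res <- screen_conditions(
      preset$spec, preset$rates, preset$distribution,
      c_mab_grid = seq(g("c_mab_min", 1.5), g("c_mab_max", 10),
                       length.out = g("c_mab_n", 20)),
      excess_grid = seq(g("excess_min", 5), g("excess_max", 14),
                        length.out = g("excess_n", 20)))
    write_screening_csv(res, paste0(out, ".csv"))
    return(invisible(list(result = res, files = paste0(out, ".csv"))))
  }
  # report: fit + CV (+ test error when the preset has test runs) -> table
  fit <- do.call(fit_rates, fit_args)
  fit$rmse_cv <- cross_validate_loro(ds, init = est$init)$rmse_cv
  if (any(ds$roles == "test")) fit$rmse_p <- evaluate_test(ds, fit)
  lab <- paste(preset$spec$modality, preset$spec$variant)
  tab <- write_model_summary(stats::setNames(list(fit), lab),
                             paste0(out, ".csv"))
  invisible(list(result = tab, files = paste0(out, ".csv")))
}
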