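#' Experimental-design presets for synthetic kinetic datasets
#'
#' Four presets mirror the studied conjugation campaigns: run counts,
#' concentration and excess ranges, feeding modes and train/test splits.
#'
#' * `dataset1_DAR2_Drug1`: 8 batch runs, 1.5--10 g/L mAb, 1x--8x Drug1
#'   (slow depletion preset), 6 train / 2 test; generating rate k1 = 0.251
#'   (simple model).
#' * `dataset2_DAR2_NPM`: 4 batch runs, 1.5--3 g/L, 3x--5x NPM (fast
#'   depletion preset), all train; generating k1 = 4.840.
#' * `dataset3_DAR8_NPM`: 13 runs, 1.5--3 g/L, 6x--13x NPM; 10 fed-batch
#'   training runs with 10/20/30 min feeds and 3 batch test runs; generating
#'   detailed rates (1.220, 1.853, 5.117, 2.312).
#' * `dataset4_DAR8_Drug2`: 4 batch runs at 1.5 and 20 g/L, 11x and 14x
#'   Drug2 (k_drug 0), all train; generating rates as dataset 3 (the payload
#'   showed comparable kinetics).
#'
#' @param name Preset name (see above).
#' @return List of class `dataset_preset`: `name`, `spec` (the generating
#'   [model_spec()]), `rates` ([rate_set()] truth), `distribution`,
#'   `payload_id`, `conditions` (list of [run_condition()]), `roles`
#'   (`"train"`/`"test"` per run).
#' @export
dataset_preset <- function(name = c("dataset1_DAR2_Drug1", "dataset2_DAR2_NPM",
                                    "dataset3_DAR8_NPM", "dataset4_DAR8_Drug2")) {
  name <- match.arg(name)
  kd <- payload_presets()
  batch <- function(c_mab, excess)
    run_condition(c_mab, excess, mode = "batch")
  fed <- function(c_mab, excess, feed_min)
    run_condition(c_mab, excess, mode = "fedbatch",
                  feed_duration = feed_min * 60, initial_volume = 4,
                  feed_volume = 0.4, sample_volume = 0.05)
  out <- switch(
    name,
    dataset1_DAR2_Drug1 = list(
      spec = model_spec("DAR2", "simple"),
      rates = rate_set(0.251, kd[["Drug1"]]),
      distribution = adc1_distribution(),
      payload_id = "Drug1",
      conditions = list(batch(1.5, 1), batch(1.5, 3), batch(3, 2),
                        batch(3, 5), batch(5, 3), batch(10, 8),
                        batch(5, 6), batch(10, 4)),
      roles = c(rep("train", 6), rep("test", 2))
    ),
    dataset2_DAR2_NPM = list(
      spec = model_spec("DAR2", "simple"),
      rates = rate_set(4.840, kd[["NPM"]]),
      distribution = adc1_distribution(),
      payload_id = "NPM",
      conditions = list(batch(1.5, 3), batch(1.5, 5), batch(3, 4),
                        batch(3, 5)),
      roles = rep("train", 4)
    ),
    dataset3_DAR8_NPM = list(
      spec = model_spec("DAR8", "detailed"),
      rates = rate_set(c(1.220, 1.853, 5.117, 2.312), kd[["NPM"]]),
      distribution = adc2_distribution(),
      payload_id = "NPM",
      conditions = list(
        fed(1.5, 6, 10), fed(1.5, 8, 10), fed(1.5, 11, 10),
        fed(1.5, 11, 20), fed(1.5, 11, 30), fed(1.5, 13, 20),
        fed(3, 8, 20), fed(3, 11, 10), fed(3, 11, 30), fed(3, 13, 10),
        batch(1.5, 6), batch(1.5, 11), batch(3, 13)),
      roles = c(rep("train", 10), rep("test", 3))
    ),
    dataset4_DAR8_Drug2 = list(
      spec = model_spec("DAR8", "detailed"),
      rates = rate_set(c(1.220, 1.853, 5.117, 2.312), kd[["Drug2"]]),
      distribution = adc3_distribution(),
      payload_id = "Drug2",
      conditions = list(batch(1.5, 11), batch(1.5, 14), batch(20, 11),
                        batch(20, 14)),
      roles = rep("train", 4)
    )
  )
  out$name <- name
  structure(out, class = "dataset_preset")
}

#' Bundle kinetic observations into a dataset for calibration
#'
#' @param runs List of [kinetic_observation()]s sharing one modality.
#' @param roles Character vector (`"train"`/`"test"`) per run.
#' @param spec The [model_spec()] to calibrate.
#' @param distribution The initial [cysteine_distribution()].
#' @param k_drug Frozen payload depletion rate, s^-1.
#' @param payload_id Optional payload label.
#' @return Object of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(runs, roles, spec, distribution, k_drug,
                            payload_id = NULL) {
  stopifnot(length(runs) == length(roles),
            all(roles %in% c("train", "test")),
            inherits(spec, "model_spec"),
            inherits(distribution, "cysteine_distribution"),
            k_drug >= 0)
  for (r in runs) stopifnot(inherits(r, "kinetic_observation"))
  structure(list(runs = runs, roles = roles, spec = spec,
                 distribution = distribution, k_drug = k_drug,
                 payload_id = payload_id),
            class = "kinetic_dataset")
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat(sprintf("Kinetic dataset (%s %s%s): %d runs (%d train / %d test), k_drug = %g s^-1\n",
              x$spec$modality, x$spec$variant,
              if (is.null(x$payload_id)) "" else paste0(", ", x$payload_id),
              length(x$runs), sum(x$roles == "train"),
              sum(x$roles == "test"), x$k_drug))
  invisible(x)
}

#' Recalibrate a dataset under a different model candidate
#'
#' Returns a copy of the dataset whose `spec` is replaced (e.g. to fit the
#' detailed candidate to data generated under the simple one). The modality
#' must match; only the rate layout changes.
#'
#' @param dataset A [kinetic_dataset()].
#' @param spec A [model_spec()] of the same modality.
#' @return The dataset with the new spec.
#' @export
set_model_spec <- function(dataset, spec) {
  stopifnot(inherits(dataset, "kinetic_dataset"), inherits(spec, "model_spec"))
  if (spec$modality != dataset$spec$modality)
    stop("cannot change modality (", dataset$spec$modality, " -> ",
         spec$modality, ")")
  dataset$spec <- spec
  dataset
}

#' Generate a synthetic kinetic dataset from a design preset
#'
#' Simulates each run of the preset at the generating (truth) rates, reads the
#' observable chain concentrations off at the sampling schedule, and applies
#' the heteroscedastic observation noise
#' `c_obs = max(0, c * (1 + eps_rel) + eps_abs)`. The generating truth is
#' attached for parameter-recovery studies.
#'
#' @param preset A [dataset_preset()] (or its name).
#' @param noise A [noise_model()]; with both SDs 0 the observations equal the
#'   model output exactly.
#' @return A [kinetic_dataset()] with attribute `truth` = list(rates,
#'   distribution, seed, preset name).
#' @export
generate_dataset <- function(preset, noise = noise_model()) {
  if (is.character(preset)) preset <- dataset_preset(preset)
  stopifnot(inherits(preset, "dataset_preset"), inherits(noise, "noise_model"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  runs <- vector("list", length(preset$conditions))
  for (i in seq_along(preset$conditions)) {
    cond <- preset$conditions[[i]]
    sim <- simulate_conjugation(preset$spec, preset$rates, cond,
                                preset$distribution, dense_n = 0)
    obs <- sim$observation$observed
    if (noise$relative_sd > 0 || noise$absolute_sd > 0) {
      eps_rel <- matrix(stats::rnorm(length(obs), 0, noise$relative_sd),
                        nrow = nrow(obs))
      eps_abs <- matrix(stats::rnorm(length(obs), 0, noise$absolute_sd),
                        nrow = nrow(obs))
      obs <- matrix(pmax(0, obs * (1 + eps_rel) + eps_abs),
                    nrow = nrow(obs), dimnames = dimnames(obs))
    }
    runs[[i]] <- kinetic_observation(sim$observation$times, obs, cond,
                                     run_id = sprintf("%s_run%02d",
                                                      preset$name, i))
  }
  ds <- kinetic_dataset(runs, preset$roles, preset$spec,
                        preset$distribution, preset$rates$k_drug,
                        payload_id = preset$payload_id)
  attr(ds, "truth") <- list(rates = preset$rates,
                            distribution = preset$distribution,
                            seed = noise$seed, preset = preset$name)
  ds
}

#' Generate a synthetic absorbance-decay series
#'
#' `A(t) = exp(-k_drug * t)` with optional multiplicative Gaussian noise,
#' renormalized to `A(0) = 1`.
#'
#' @param k_drug First-order depletion rate, s^-1 (>= 0).
#' @param times Sampling times, s (must start at 0 for normalization).
#' @param relative_sd Multiplicative noise SD.
#' @param seed Optional seed.
#' @param payload_id,replicate_id Optional labels.
#' @return List of class `absorbance_series`: `times`,
#'   `normalized_absorbance`, `payload_id`, `replicate_id`.
#' @export
generate_absorbance <- function(k_drug, times = seq(0, 3600, by = 300),
                                relative_sd = 0, seed = NULL,
                                payload_id = NULL, replicate_id = NULL) {
  stopifnot(k_drug >= 0, times[1] == 0)
  if (!is.null(seed)) set.seed(seed)
  a <- exp(-k_drug * times)
  if (relative_sd > 0)
    a <- a * (1 + stats::rnorm(length(a), 0, relative_sd))
  if (any(a <= 0)) stop("noise drove absorbance non-positive; lower relative_sd")
  a <- a / a[1]
  structure(list(times = as.numeric(times), normalized_absorbance = a,
                 payload_id = payload_id, replicate_id = replicate_id),
            class = "absorbance_series")
}
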