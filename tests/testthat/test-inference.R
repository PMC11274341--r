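# a dataset whose predictions are constant (no reactive sites, or zero
# excess) lets residuals be computed by hand
inert_dataset <- function(obs_h0, times = c(60, 120), c_mab = 3) {
  cond <- run_condition(c_mab, 0, sample_times = times, t_end = max(times))
  cm <- mab_molar_conc(cond)
  obs <- matrix(0, nrow = length(times), ncol = 5,
                dimnames = list(NULL, c("H0", "H1", "H2", "L0", "L1")))
  obs[, "H0"] <- obs_h0
  obs[, "L0"] <- 2 * cm
  kinetic_dataset(list(kinetic_observation(times, obs, cond)), "train",
                  model_spec("DAR2", "simple"), adc1_distribution(), 0)
}

test_that("residuals are normalized by the run's maximum concentration", {
  cond <- run_condition(3, 0, sample_times = c(60, 120), t_end = 120)
  cm <- mab_molar_conc(cond)
  # observed H0: {2cm, cm}; predicted constant 2cm (no payload) -> {0, 0.5}
  ds <- inert_dataset(obs_h0 = c(2 * cm, cm))
  r <- residual_vector(ds, 0.251)
  expect_equal(sort(unique(round(r, 12))), c(0, 0.5))
  expect_equal(sum(r != 0), 1)
  # doubling every concentration (data and mAb pool) leaves them unchanged
  ds2 <- inert_dataset(obs_h0 = 2 * c(2 * cm, cm), c_mab = 6)
  expect_equal(residual_vector(ds2, 0.251), r)
  # rates reproducing the data exactly give all-zero residuals
  ds0 <- inert_dataset(obs_h0 = c(2 * cm, 2 * cm))
  expect_true(all(residual_vector(ds0, 0.251) == 0))
})

test_that("parameter covariance matches the closed-form least-squares result", {
  # scalar model y = theta * x at x = {1, 2}, residuals {0.1, -0.1}
  out <- parameter_covariance(matrix(c(1, 2), ncol = 1), c(0.1, -0.1))
  expect_equal(out$s2, 0.02)
  expect_equal(out$covariance[1, 1], 0.02 / 5)
  expect_equal(out$sigma, sqrt(0.004))
  # multivariate oracle: stats::lm on a random linear model
  set.seed(42)
  X <- cbind(1, stats::rnorm(10), stats::runif(10))
  y <- X %*% c(2, -1, 0.5) + stats::rnorm(10, sd = 0.1)
  fit <- stats::lm(y ~ X - 1)
  out <- parameter_covariance(X, stats::residuals(fit))
  expect_equal(unname(out$covariance), unname(stats::vcov(fit)),
               tolerance = 1e-10)
  # zero residuals -> zero sigma; rank deficiency -> flagged, not an error
  expect_equal(parameter_covariance(X, rep(0, 10))$sigma, rep(0, 3))
  Xd <- cbind(X[, 1], X[, 1])
  out <- parameter_covariance(Xd, stats::rnorm(10))
  expect_false(out$identifiable)
  expect_true(all(is.infinite(out$sigma)))
})

test_that("confidence intervals follow the Student-t quantile", {
  ci <- confidence_intervals(c(1, 2), c(0, 0), dof = 10)
  expect_equal(ci[, "lb"], c(1, 2))
  expect_equal(ci[, "ub"], c(1, 2))
  ci <- confidence_intervals(0, 1, dof = 1e6)
  expect_equal(unname(ci[1, ]), c(-1.96, 1.96), tolerance = 1e-3)
  # poorly identified rates may get negative lower bounds
  ci <- confidence_intervals(1.712, 6.585, dof = 50)
  expect_lt(ci[, "lb"], 0)
})

test_that("RMSE is the per-species root mean square, averaged over species", {
  expect_equal(rmse(matrix(1:4, 2), matrix(1:4, 2))$average, 0)
  out <- rmse(matrix(c(3, 4), ncol = 1), matrix(0, 2, 1), scale = 1)
  expect_equal(out$average, sqrt(25 / 2))
  # invariant to time ordering and reported per species
  p <- matrix(stats::runif(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  o <- matrix(stats::runif(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(rmse(p, o)$by_species, rmse(p[perm, ], o[perm, ])$by_species)
  expect_error(rmse(p, o[1:3, ]), "mismatch")
})

test_that("noise-free data is a fixed point of the rate estimator", {
  preset <- tiny_preset(
    model_spec("DAR2", "simple"), rate_set(4.84, 0.041 / 60),
    adc1_distribution(),
    list(run_condition(1.5, 3, sample_times = c(30, 60, 120, 300), t_end = 300),
         run_condition(3, 5, sample_times = c(30, 60, 120, 300), t_end = 300)),
    roles = c("train", "train"))
  ds <- generate_dataset(preset, noise_model(0, 0))
  fit <- fit_rates(ds)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates), 4.84, tolerance = 1e-5)
  expect_lt(fit$rmse_train, 1e-6)
  # residual variance ~ 0 so the CI collapses onto the estimate
  expect_lt(unname(fit$sigma), 1e-5)
})

test_that("structurally absent rates have exactly zero OAT significance", {
  # no heavy chain carries two sites -> the second-step rate k2 is never used
  dist <- cysteine_distribution(c("0" = 0.11, "1" = 0.89, "2" = 0))
  preset <- tiny_preset(
    model_spec("DAR2", "detailed"), rate_set(c(0.251, 1.7), 0), dist,
    list(run_condition(3, 3, sample_times = c(60, 300, 900), t_end = 900)),
    roles = "train")
  ds <- generate_dataset(preset, noise_model(0, 0))
  sens <- oat_sensitivity(ds, preset$rates)
  expect_equal(unname(sens$sum_delta_msqr["k2"]), 0)
  expect_gt(unname(sens$sum_delta_msqr["k1"]), 0)
  expect_equal(sens$ranking[1], "k1")
  # the ranking does not depend on run order
  preset2 <- preset
  preset2$conditions <- c(preset$conditions,
                          list(run_condition(1.5, 4, sample_times = c(60, 300, 900),
                                             t_end = 900)))
  preset2$roles <- c("train", "train")
  ds2 <- generate_dataset(preset2, noise_model(0, 0))
  s1 <- oat_sensitivity(ds2, preset$rates)
  ds2r <- ds2
  ds2r$runs <- rev(ds2$runs)
  s2 <- oat_sensitivity(ds2r, preset$rates)
  expect_equal(s1$sum_delta_msqr, s2$sum_delta_msqr, tolerance = 1e-12)
})

test_that("leave-one-run-out error vanishes on noise-free data", {
  preset <- tiny_preset(
    model_spec("DAR2", "simple"), rate_set(0.251, 0), adc1_distribution(),
    list(run_condition(1.5, 3, sample_times = c(60, 300, 900), t_end = 900),
         run_condition(3, 4, sample_times = c(60, 300, 900), t_end = 900),
         run_condition(5, 2, sample_times = c(60, 300, 900), t_end = 900)),
    roles = rep("train", 3))
  ds <- generate_dataset(preset, noise_model(0, 0))
  cv <- cross_validate_loro(ds)
  expect_equal(cv$n_folds, 3)
  expect_lt(cv$rmse_cv, 1e-5)
  expect_error(cross_validate_loro(
    kinetic_dataset(ds$runs[1], "train", ds$spec, ds$distribution, 0)),
    ">= 2")
})

test_that("candidate selection weighs flags, complexity and parsimony", {
  fake_fit <- function(spec, est, sigma, rmse_cv, rmse_p = rmse_cv) {
    structure(list(estimates = stats::setNames(est, spec$rate_names),
                   sigma = stats::setNames(sigma, spec$rate_names),
                   spec = spec, n_params = spec$n_rate_params,
                   rmse_cv = rmse_cv, rmse_p = rmse_p),
              class = "conj_fit")
  }
  s2 <- model_spec("DAR2", "simple"); d2 <- model_spec("DAR2", "detailed")
  s8 <- model_spec("DAR8", "simple"); d8 <- model_spec("DAR8", "detailed")
  # non-identifiable k2 (relative sigma far above 25%) rejects the detailed
  # DAR2 candidate despite equal errors
  sel <- select_model(list(
    list(spec = s2, fit = fake_fit(s2, 0.251, 0.023, 1.863, 3.188)),
    list(spec = d2, fit = fake_fit(d2, c(0.297, 1.712), c(0.027, 6.585),
                                   1.808, 3.207))))
  expect_equal(sel$selected, 1)
  expect_match(sel$table$notes[2], "k2")
  # all rates well determined and errors halved: detailed DAR8 wins
  sel <- select_model(list(
    list(spec = s8, fit = fake_fit(s8, 1.733, 0.018, 1.213, 1.339)),
    list(spec = d8, fit = fake_fit(d8, c(1.22, 1.853, 5.117, 2.312),
                                   c(0.003, 0.006, 1.015, 0.356),
                                   0.620, 0.964))))
  expect_equal(sel$selected_label, "DAR8 detailed")
  # identical diagnostics: parsimony picks the smaller model
  sel <- select_model(list(
    list(spec = d2, fit = fake_fit(d2, c(0.3, 0.3), c(0.01, 0.01), 1.0)),
    list(spec = s2, fit = fake_fit(s2, 0.3, 0.01, 1.0))))
  expect_equal(sel$selected_label, "DAR2 simple")
  # a well-identified extra rate still has to buy a considerable
  # cross-validation gain: a few percent is not enough
  sel <- select_model(list(
    list(spec = s2, fit = fake_fit(s2, 0.251, 0.023, 1.863, 3.188)),
    list(spec = d2, fit = fake_fit(d2, c(0.297, 0.25), c(0.027, 0.04),
                                   1.808, 3.207))))
  expect_equal(sel$selected_label, "DAR2 simple")
})
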