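# Predicted observables at the sampling times of one run, minimal output.
.predict_run <- function(spec, rates, condition, distribution) {
  sim <- simulate_conjugation(spec, rates, condition, distribution,
                              dense_n = 0)
  sim$observation$observed
}

# Column subset of an observed matrix aligned with the model observables.
.align_obs <- function(observed, obs_names) {
  missing <- setdiff(obs_names, colnames(observed))
  if (length(missing) > 0)
    stop("observations lack species: ", paste(missing, collapse = ", "))
  observed[, obs_names, drop = FALSE]
}

#' Normalized residual vector of a dataset under given rates
#'
#' For every training run, residuals are `(predicted - observed) / scale_run`
#' with `scale_run` the maximum observed concentration across all species and
#' times of that run, so that runs at different mAb concentrations contribute
#' evenly to the squared-error objective. Residuals are concatenated over
#' runs, time points and species.
#'
#' @param dataset A [kinetic_dataset()].
#' @param conjugation_rates Numeric vector of conjugation rates (the frozen
#'   `dataset$k_drug` supplies the depletion rate).
#' @param roles Which runs to include (default `"train"`).
#' @return Numeric residual vector.
#' @export
residual_vector <- function(dataset, conjugation_rates, roles = "train") {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  rates <- rate_set(conjugation_rates, dataset$k_drug)
  obs_names <- model_structure(dataset$spec)$obs_names
  res <- list()
  for (i in which(dataset$roles %in% roles)) {
    run <- dataset$runs[[i]]
    pred <- tryCatch(
      .predict_run(dataset$spec, rates, run$condition, dataset$distribution),
      error = function(e) stop("simulation failed for run ",
                               if (is.null(run$run_id)) i else run$run_id,
                               ": ", conditionMessage(e))
    )
    obs <- .align_obs(run$observed, obs_names)
    scale <- max(obs)
    if (scale <= 0) stop("run ", i, " contains no nonzero observations")
    res[[length(res) + 1L]] <- as.numeric((pred - obs) / scale)
  }
  unlist(res)
}

# Forward finite-difference Jacobian of the residual vector (relative step).
.residual_jacobian <- function(dataset, theta, roles = "train",
                               rel_step = 1e-6) {
  r0 <- residual_vector(dataset, theta, roles)
  J <- matrix(0, nrow = length(r0), ncol = length(theta))
  for (j in seq_along(theta)) {
    h <- rel_step * max(abs(theta[j]), 1e-8)
    th <- theta
    th[j] <- th[j] + h
    J[, j] <- (residual_vector(dataset, th, roles) - r0) / h
  }
  list(J = J, residuals = r0)
}

#' Estimate conjugation rate constants by nonlinear least squares
#'
#' Minimizes the sum of squared normalized residuals (see
#' [residual_vector()]) over the conjugation rates only, with the payload
#' depletion rate frozen at `dataset$k_drug`, using Levenberg--Marquardt
#' (`minpack.lm::nls.lm`). Parameter uncertainty follows from the
#' finite-difference Jacobian at the optimum via [parameter_covariance()] and
#' Student-t [confidence_intervals()].
#'
#' @param dataset A [kinetic_dataset()]; training runs are fitted.
#' @param init Initial rates (default 1 for every parameter).
#' @param lower,upper Box bounds (defaults 0 and 100).
#' @param multi_start If `TRUE`, restart from 5 log-spaced initial values
#'   (1e-2..1e2, all parameters equal) and keep the best optimum.
#' @param max_iter Maximum LM iterations.
#' @return Object of class `conj_fit`: `estimates` (named), `sigma`, `ci`
#'   (matrix lb/ub), `s2`, `covariance`, `rmse_by_species`, `rmse_train`,
#'   `n_obs`, `n_params`, `dof`, `converged`, `identifiable` (sigma finite),
#'   plus `dataset` inputs needed downstream. Slots `rmse_cv` / `rmse_p` are
#'   `NA` until filled by [cross_validate_loro()] / [evaluate_test()].
#' @export
fit_rates <- function(dataset, init = NULL, lower = 0, upper = 100,
                      multi_start = FALSE, max_iter = 100) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  p <- dataset$spec$n_rate_params
  if (is.null(init)) init <- rep(1, p)
  stopifnot(length(init) == p, all(init >= lower), all(init <= upper))
  starts <- if (multi_start) {
    lapply(10^seq(-2, 2, length.out = 5), function(s) rep(s, p))
  } else list(init)
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-12), upper)
    ans <- minpack.lm::nls.lm(
      par = st,
      lower = rep(lower, p), upper = rep(upper, p),
      fn = function(th) residual_vector(dataset, th),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, gtol = 1e-10, maxiter = max_iter)
    )
    if (is.null(best) || ans$deviance < best$deviance) best <- ans
  }
  theta <- as.numeric(best$par)
  names(theta) <- dataset$spec$rate_names
  converged <- best$info %in% 1:4
  jac <- .residual_jacobian(dataset, theta)
  covr <- parameter_covariance(jac$J, jac$residuals,
                               n_obs = length(jac$residuals), n_params = p)
  ci <- confidence_intervals(theta, covr$sigma, dof = length(jac$residuals) - p)
  fitted_rmse <- .dataset_rmse(dataset, rate_set(theta, dataset$k_drug),
                               roles = "train")
  structure(list(estimates = theta,
                 sigma = stats::setNames(covr$sigma, names(theta)),
                 ci = ci, s2 = covr$s2, covariance = covr$covariance,
                 rmse_by_species = fitted_rmse$by_species,
                 rmse_train = fitted_rmse$average,
                 rmse_cv = NA_real_, rmse_p = NA_real_,
                 n_obs = length(jac$residuals), n_params = p,
                 dof = length(jac$residuals) - p,
                 converged = converged,
                 identifiable = is.finite(covr$sigma),
                 spec = dataset$spec, k_drug = dataset$k_drug),
            class = "conj_fit")
}

#' @export
print.conj_fit <- function(x, ...) {
  cat(sprintf("Conjugation-rate fit (%s %s), %sconverged, n = %d, p = %d\n",
              x$spec$modality, x$spec$variant,
              if (x$converged) "" else "NOT ", x$n_obs, x$n_params))
  tab <- data.frame(estimate = x$estimates, sigma = x$sigma,
                    lb = x$ci[, "lb"], ub = x$ci[, "ub"])
  print(round(tab, 4))
  cat(sprintf("train RMSE %.4g umol/L", x$rmse_train))
  if (is.finite(x$rmse_cv)) cat(sprintf(", RMSECV %.4g", x$rmse_cv))
  if (is.finite(x$rmse_p)) cat(sprintf(", RMSEP %.4g", x$rmse_p))
  cat("\n")
  invisible(x)
}

#' Parameter covariance of a least-squares fit
#'
#' `cov = s^2 (J'J)^{-1}` with `s^2 = sum(residual^2) / (n - p)`; parameter
#' standard deviations are the square roots of the diagonal. A rank-deficient
#' Jacobian flags the parameters as non-identifiable (infinite sigma) instead
#' of raising an error.
#'
#' @param jacobian Jacobian of the residual vector at the optimum (n x p).
#' @param residuals Residual vector (length n).
#' @param n_obs,n_params Dimensions (default from inputs).
#' @return List: `covariance` (p x p), `sigma` (length p), `s2`,
#'   `identifiable` (logical).
#' @export
parameter_covariance <- function(jacobian, residuals,
                                 n_obs = length(residuals),
                                 n_params = ncol(jacobian)) {
  jacobian <- as.matrix(jacobian)
  if (n_obs <= n_params) stop("need more observations than parameters")
  s2 <- sum(residuals^2) / (n_obs - n_params)
  jtj <- crossprod(jacobian)
  ok <- qr(jtj)$rank == n_params
  if (ok) {
    covariance <- s2 * solve(jtj)
    sigma <- sqrt(pmax(diag(covariance), 0))
  } else {
    covariance <- matrix(Inf, n_params, n_params)
    sigma <- rep(Inf, n_params)
  }
  list(covariance = covariance, sigma = sigma, s2 = s2, identifiable = ok)
}

#' Student-t confidence intervals for estimated rates
#'
#' `theta_hat +/- t_{dof, 1 - alpha/2} * sigma`, the standard linearized
#' nonlinear-regression interval (nlparci-style). Intervals may include
#' negative values for poorly identified rates.
#'
#' @param estimates,sigma Parameter estimates and standard deviations.
#' @param dof Residual degrees of freedom (n - p), >= 1.
#' @param level Confidence level (default 0.95).
#' @return Matrix with columns `lb`, `ub`.
#' @export
confidence_intervals <- function(estimates, sigma, dof, level = 0.95) {
  stopifnot(length(estimates) == length(sigma), dof >= 1, level > 0, level < 1)
  q <- stats::qt(1 - (1 - level) / 2, df = dof)
  cbind(lb = estimates - q * sigma, ub = estimates + q * sigma)
}

#' Root-mean-squared error per species
#'
#' `RMSE_i = sqrt(mean((predicted_i - observed_i)^2))` per species, then
#' averaged over species to a single figure. Inputs in mmol/L are reported in
#' umol/L by default (`scale = 1000`).
#'
#' @param predicted,observed Aligned matrices (time x species) or vectors.
#' @param scale Unit scale applied to the result (1000: mmol/L -> umol/L).
#' @return List: `by_species` (named), `average`.
#' @export
rmse <- function(predicted, observed, scale = 1000) {
  predicted <- as.matrix(predicted)
  observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed))) stop("shape mismatch")
  if (length(predicted) == 0) stop("empty input")
  by_species <- sqrt(colMeans((predicted - observed)^2)) * scale
  list(by_species = by_species, average = mean(by_species))
}

# Pooled per-species RMSE over a set of runs (rows stacked per run).
.dataset_rmse <- function(dataset, rates, roles = "train", runs_idx = NULL) {
  obs_names <- model_structure(dataset$spec)$obs_names
  if (is.null(runs_idx)) runs_idx <- which(dataset$roles %in% roles)
  preds <- obss <- list()
  for (i in runs_idx) {
    run <- dataset$runs[[i]]
    preds[[length(preds) + 1L]] <-
      .predict_run(dataset$spec, rates, run$condition, dataset$distribution)
    obss[[length(obss) + 1L]] <- .align_obs(run$observed, obs_names)
  }
  rmse(do.call(rbind, preds), do.call(rbind, obss))
}

#' Leave-one-run-out cross-validation error
#'
#' For each training run, refits the conjugation rates (from the default
#' initialization) on the remaining training runs and predicts the held-out
#' run; the fold error is the species-averaged RMSE on that run, and RMSECV is
#' the mean over folds (one fold per training run).
#'
#' @param dataset A [kinetic_dataset()] with >= 2 training runs.
#' @param init,lower,upper Passed to [fit_rates()].
#' @return List of class `loro_cv`: `rmse_cv` (umol/L), `fold_rmse`,
#'   `fold_estimates` (matrix).
#' @export
cross_validate_loro <- function(dataset, init = NULL, lower = 0, upper = 100) {
  train_idx <- which(dataset$roles == "train")
  if (length(train_idx) < 2) stop("need >= 2 training runs for cross-validation")
  fold_rmse <- numeric(length(train_idx))
  fold_est <- matrix(NA_real_, nrow = length(train_idx),
                     ncol = dataset$spec$n_rate_params,
                     dimnames = list(NULL, dataset$spec$rate_names))
  for (f in seq_along(train_idx)) {
    held <- train_idx[f]
    sub <- dataset
    sub$roles[held] <- "test"
    fit <- fit_rates(sub, init = init, lower = lower, upper = upper)
    fold_est[f, ] <- fit$estimates
    fold_rmse[f] <- .dataset_rmse(dataset,
                                  rate_set(fit$estimates, dataset$k_drug),
                                  runs_idx = held)$average
  }
  structure(list(rmse_cv = mean(fold_rmse), fold_rmse = fold_rmse,
                 fold_estimates = fold_est, n_folds = length(train_idx)),
            class = "loro_cv")
}

#' Prediction error on the held-out test runs
#'
#' Applies a fitted model to the untouched test runs and returns the
#' species-averaged RMSE (RMSEP).
#'
#' @param dataset A [kinetic_dataset()] with >= 1 test run.
#' @param fit A [fit_rates()] result.
#' @return RMSEP in umol/L.
#' @export
evaluate_test <- function(dataset, fit) {
  if (!any(dataset$roles == "test")) stop("dataset has no test runs")
  .dataset_rmse(dataset, rate_set(fit$estimates, dataset$k_drug),
                roles = "test")$average
}

#' One-at-a-time local sensitivity and identifiability ranking
#'
#' Each calibrated rate is perturbed by `perturbation` (default 10%) of its
#' nominal value; the finite-difference derivative of every observable
#' trajectory is scaled by the nominal value to a relative sensitivity,
#' averaged over the run's sampling grid, and summarized per species as
#' `delta_msqr = sqrt(mean over runs of sensitivity^2)` (root-mean-square; the
#' literal signed-mean reading is available via `method = "signed"`). Summing
#' over species gives `sum_delta_msqr`, whose descending order ranks the
#' parameters by their impact on the model output: parameters with near-zero
#' values are practically non-identifiable from the data.
#'
#' @param dataset A [kinetic_dataset()] supplying the run conditions, the
#'   model spec and the distribution (training runs are used).
#' @param rates Calibrated [rate_set()] (nominal values).
#' @param perturbation Relative perturbation (default 0.10).
#' @param method `"rms"` (default) or `"signed"`.
#' @return Object of class `sensitivity_report`: `delta_msqr` (parameters x
#'   species), `sum_delta_msqr` (named, per parameter), `ranking` (parameter
#'   names, most important first).
#' @export
oat_sensitivity <- function(dataset, rates, perturbation = 0.10,
                            method = c("rms", "signed")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "kinetic_dataset"), inherits(rates, "rate_set"))
  spec <- dataset$spec
  theta <- rates$conjugation_rates
  stopifnot(length(theta) == spec$n_rate_params)
  obs_names <- model_structure(spec)$obs_names
  run_idx <- which(dataset$roles == "train")
  base <- lapply(run_idx, function(i)
    .predict_run(spec, rates, dataset$runs[[i]]$condition,
                 dataset$distribution))
  # s[run, species] per parameter: time-averaged relative sensitivity
  sens <- array(NA_real_, dim = c(length(theta), length(run_idx),
                                  length(obs_names)),
                dimnames = list(spec$rate_names, NULL, obs_names))
  for (j in seq_along(theta)) {
    h <- perturbation * theta[j]
    if (theta[j] == 0) {
      warning("zero nominal value for ", spec$rate_names[j],
              "; using absolute perturbation 1e-9")
      h <- 1e-9
    }
    th <- theta
    th[j] <- th[j] + h
    pert_rates <- rate_set(th, rates$k_drug)
    for (r in seq_along(run_idx)) {
      pred <- .predict_run(spec, pert_rates,
                           dataset$runs[[run_idx[r]]]$condition,
                           dataset$distribution)
      deriv <- (pred - base[[r]]) / h          # d y / d theta_j
      sens[j, r, ] <- colMeans(deriv) * theta[j]  # relative, time-averaged
    }
  }
  agg <- if (method == "rms") {
    apply(sens, c(1, 3), function(v) sqrt(mean(v^2)))
  } else {
    apply(sens, c(1, 3), function(v) {
      m <- mean(v)
      if (m < 0) NaN else sqrt(m)
    })
  }
  total <- rowSums(agg)
  ranking <- names(sort(total, decreasing = TRUE))
  structure(list(delta_msqr = agg, sum_delta_msqr = total, ranking = ranking,
                 perturbation = perturbation, method = method),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("OAT parameter-identifiability ranking (sum delta_msqr, descending):\n")
  v <- sort(x$sum_delta_msqr, decreasing = TRUE)
  for (nm in names(v)) cat(sprintf("  %-5s %.4g\n", nm, v[nm]))
  invisible(x)
}

#' Select among calibrated model candidates
#'
#' Applies the model-selection criteria to >= 2 candidates fitted on the same
#' dataset: a candidate is flagged when any rate has relative standard
#' deviation above `rel_sigma_max` (default 25%), or a near-zero identifiability
#' value (`sum_delta_msqr` below `neg_frac` of the candidate's largest). Among
#' the unflagged candidates, added complexity must pay for itself in
#' prediction error: a more complex candidate is preferred only when its
#' leave-one-run-out error undercuts the best simpler unflagged candidate by
#' more than `cv_margin` (default 10%, a considerable gain; a few percent is
#' within cross-validation noise). Otherwise the simpler candidate is kept
#' (which also resolves identical candidates by parsimony). If every candidate
#' is flagged, the simplest one is recommended. For a flagged last-step rate
#' the report suggests lumping it with the preceding step's rate. Candidates
#' without RMSECV values are compared by complexity and flags alone.
#'
#' @param candidates List of candidates, each a list with elements `spec`
#'   ([model_spec()]), `fit` ([fit_rates()] result) and optionally
#'   `sensitivity` ([oat_sensitivity()] report) and `label`.
#' @param rel_sigma_max Maximum acceptable sigma / estimate (default 0.25).
#' @param neg_frac A rate is "near-zero influence" when its sum_delta_msqr is
#'   below this fraction of the candidate's maximum (default 0.01).
#' @param cv_margin Minimum relative RMSECV reduction required of a more
#'   complex candidate (default 0.10).
#' @return Object of class `model_selection`: per-candidate flag table,
#'   `selected` (index) and `selected_label`.
#' @export
select_model <- function(candidates, rel_sigma_max = 0.25, neg_frac = 0.01,
                         cv_margin = 0.10) {
  stopifnot(length(candidates) >= 2)
  rows <- list()
  flagged <- logical(length(candidates))
  notes <- character(length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    fit <- cand$fit
    rel_sigma <- fit$sigma / abs(fit$estimates)
    bad_sigma <- names(fit$estimates)[!is.finite(rel_sigma) |
                                        rel_sigma > rel_sigma_max]
    bad_sens <- character(0)
    if (!is.null(cand$sensitivity)) {
      tot <- cand$sensitivity$sum_delta_msqr
      bad_sens <- names(tot)[tot < neg_frac * max(tot)]
    }
    flagged[i] <- length(bad_sigma) > 0 || length(bad_sens) > 0
    note <- character(0)
    if (length(bad_sigma) > 0)
      note <- c(note, paste0("relative sigma > ", rel_sigma_max * 100, "%: ",
                             paste(bad_sigma, collapse = ", ")))
    if (length(bad_sens) > 0) {
      note <- c(note, paste0("near-zero identifiability: ",
                             paste(bad_sens, collapse = ", ")))
      last <- fit$spec$rate_names[fit$n_params]
      if (last %in% bad_sens && fit$n_params >= 2)
        note <- c(note, sprintf(
          "consider lumping %s with %s (shared rate for the last steps)",
          last, fit$spec$rate_names[fit$n_params - 1L]))
    }
    notes[i] <- paste(note, collapse = "; ")
    rows[[i]] <- data.frame(
      label = if (is.null(cand$label))
        paste(cand$spec$modality, cand$spec$variant) else cand$label,
      n_params = fit$n_params,
      rmse_cv = fit$rmse_cv, rmse_p = fit$rmse_p,
      flagged = flagged[i], notes = notes[i],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  np <- tab$n_params
  ok <- which(!flagged)
  if (length(ok) == 0) {
    selected <- which.min(np)
  } else {
    # walk up in complexity; added parameters must buy a considerable
    # cross-validation improvement
    ord <- ok[order(np[ok])]
    selected <- ord[1]
    for (s in ord[-1]) {
      cv_s <- tab$rmse_cv[s]
      cv_cur <- tab$rmse_cv[selected]
      if (is.finite(cv_s) && is.finite(cv_cur)) {
        if (cv_s < (1 - cv_margin) * cv_cur) selected <- s
      } else if (np[s] > np[selected]) {
        selected <- s  # no CV information: fall back to complexity
      }
    }
  }
  structure(list(table = tab, selected = selected,
                 selected_label = tab$label[selected]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model candidate comparison:\n")
  print(x$table, row.names = FALSE)
  cat("Selected:", x$selected_label, "\n")
  invisible(x)
}
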