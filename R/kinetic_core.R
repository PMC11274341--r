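#' Initial hidden state of a conjugation run
#'
#' Partitions the heavy- and light-chain pools (2 chains of each kind per mAb,
#' i.e. `2 * c_mab_molar` mmol/L per chain kind) across the initial
#' reactive-site counts of the cysteine distribution. In batch mode the free
#' payload starts at `drug_excess * c_mab_molar`; in fed-batch mode at 0 (it
#' is fed in during the feed phase).
#'
#' @param condition A [run_condition()].
#' @param distribution A [cysteine_distribution()]; its `max_heavy` must match
#'   the modality of `spec`.
#' @param spec A [model_spec()].
#' @return Object of class `hidden_state`: list with `species` (named molar
#'   concentrations, mmol/L, one per (chain, drugs bound, initial sites)
#'   species), `free_drug` (mmol/L) and `volume` (mL).
#' @export
initial_state <- function(condition, distribution, spec) {
  stopifnot(inherits(condition, "run_condition"),
            inherits(distribution, "cysteine_distribution"),
            inherits(spec, "model_spec"))
  if (distribution$max_heavy != spec$max_heavy)
    stop("distribution modality (max_heavy = ", distribution$max_heavy,
         ") does not match model spec (", spec$max_heavy, ")")
  cm <- mab_molar_conc(condition)
  struct <- model_structure(spec)
  tab <- struct$tab
  conc <- stats::setNames(numeric(struct$n_species), tab$name)
  at0 <- tab$d == 0L
  frac <- ifelse(tab$chain[at0] == "H",
                 distribution$heavy_fractions[as.character(tab$nc[at0])],
                 distribution$light_fractions[as.character(tab$nc[at0])])
  conc[at0] <- 2 * cm * frac
  free_drug <- if (condition$mode == "batch") condition$drug_excess * cm else 0
  structure(list(species = conc, free_drug = free_drug,
                 volume = condition$initial_volume),
            class = "hidden_state")
}

# feed rate (mL/s) and feed drug concentration (mmol/L) of a condition
.feed_params <- function(condition) {
  if (condition$mode != "fedbatch") return(list(q = 0, c_in = 0))
  cm <- mab_molar_conc(condition)
  list(q = condition$feed_volume / condition$feed_duration,
       c_in = condition$drug_excess * cm * condition$initial_volume /
              condition$feed_volume)
}

# deSolve-style RHS over the flat state c(species, drug, volume).
# parms: list(k, k_drug, react_idx, prod_idx, rate_idx, n, q, c_in)
.rhs_flat <- function(t, y, p) {
  conc <- y[seq_len(p$n)]
  cdrug <- y[p$n + 1L]
  flux <- p$k[p$rate_idx] * conc[p$react_idx] * cdrug
  dC <- numeric(p$n)
  dC[p$react_idx] <- -flux
  dC[p$prod_idx] <- dC[p$prod_idx] + flux
  ddrug <- -sum(flux) - p$k_drug * cdrug
  dV <- 0
  if (p$q > 0) {
    V <- y[p$n + 2L]
    dil <- p$q / V
    dC <- dC - conc * dil
    ddrug <- ddrug + (p$c_in - cdrug) * dil
    dV <- p$q
  }
  list(c(dC, ddrug, dV))
}

#' Right-hand side of the conjugation ODE system
#'
#' Evaluates the time derivative of every hidden species for a given state.
#' Each conjugation step is a second-order irreversible reaction between a
#' chain species and free payload: species (chain, d, nc) gains
#' `k_step(chain, d) * c_(chain, d-1, nc) * c_drug` and loses
#' `k_step(chain, d+1) * c_(chain, d, nc) * c_drug`, each term present only
#' when that step exists. Free payload loses every conjugation flux plus the
#' first-order depletion `k_drug * c_drug`. During a fed-batch feed all chain
#' species are diluted by `-(c_i / V) * q_in`, the free payload receives
#' `(c_drug_in - c_drug) * q_in / V`, and `dV/dt = q_in`; in batch mode these
#' terms vanish and the system reduces to the pure reaction rates.
#'
#' @param state A [initial_state()]-shaped `hidden_state`.
#' @param t Time, s (only the feed on/off switch depends on it).
#' @param rates A [rate_set()].
#' @param condition A [run_condition()].
#' @param spec A [model_spec()].
#' @return List with `species` (named derivatives, mmol/L/s), `free_drug` and
#'   `volume` derivatives.
#' @export
conjugation_rhs <- function(state, t, rates, condition, spec) {
  struct <- model_structure(spec)
  stopifnot(length(state$species) == struct$n_species,
            length(rates$conjugation_rates) == spec$n_rate_params)
  feed <- .feed_params(condition)
  q <- if (condition$mode == "fedbatch" && t < condition$feed_duration)
    feed$q else 0
  p <- list(k = rates$conjugation_rates, k_drug = rates$k_drug,
            react_idx = struct$react_idx, prod_idx = struct$prod_idx,
            rate_idx = struct$rate_idx, n = struct$n_species,
            q = q, c_in = feed$c_in)
  y <- c(unname(state$species), state$free_drug, state$volume)
  d <- .rhs_flat(t, y, p)[[1]]
  list(species = stats::setNames(d[seq_len(struct$n_species)],
                                 names(state$species)),
       free_drug = d[struct$n_species + 1L],
       volume = d[struct$n_species + 2L])
}

#' Simulate a conjugation run
#'
#' Integrates the conjugation ODE system with a stiff solver (deSolve's
#' `lsoda`, rtol 1e-8 / atol 1e-12) segment-wise between sampling times; at
#' each sampling time the reactor volume drops by `sample_volume` with
#' concentrations unchanged. Fed-batch feeds are constant-rate over
#' `feed_duration` with feed concentration
#' `drug_excess * c_mab_molar * initial_volume / feed_volume`, so the total
#' payload fed always equals `drug_excess * c_mab_molar * initial_volume`
#' (in mmol after mL-volume scaling).
#'
#' @param spec A [model_spec()].
#' @param rates A [rate_set()] with `length(conjugation_rates) ==
#'   spec$n_rate_params`.
#' @param condition A [run_condition()].
#' @param distribution A [cysteine_distribution()].
#' @param dense_n Approximate number of extra output points spread over the
#'   horizon in addition to sampling times (0 = sampling grid only; fitting
#'   uses 0 for speed).
#' @param rtol,atol Solver tolerances.
#' @return Object of class `conj_sim`: `times` (s), `hidden` (matrix, one
#'   column per hidden species, mmol/L), `free_drug`, `volume`, `observed`
#'   (matrix of collapsed observables H0..Hmax, L0, L1), `observation` (a
#'   [kinetic_observation()] at the sampling times) and the inputs.
#' @export
simulate_conjugation <- function(spec, rates, condition, distribution,
                                 dense_n = 200, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(rates, "rate_set"))
  if (length(rates$conjugation_rates) != spec$n_rate_params)
    stop("rate_set has ", length(rates$conjugation_rates),
         " conjugation rates; model spec needs ", spec$n_rate_params)
  struct <- model_structure(spec)
  state <- initial_state(condition, distribution, spec)
  feed <- .feed_params(condition)
  t_end <- condition$t_end
  breaks <- sort(unique(c(0, condition$sample_times,
                          if (condition$mode == "fedbatch")
                            condition$feed_duration,
                          t_end)))
  breaks <- breaks[breaks <= t_end]
  grid <- if (dense_n > 0) seq(0, t_end, length.out = dense_n + 1) else numeric(0)
  out_times <- sort(unique(c(breaks, grid)))

  y <- c(unname(state$species), state$free_drug, state$volume)
  n <- struct$n_species
  rows <- list()
  times_acc <- numeric(0)
  for (s in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1L]
    seg_times <- unique(c(t0, out_times[out_times > t0 & out_times < t1], t1))
    q_seg <- if (condition$mode == "fedbatch" && t1 <= condition$feed_duration)
      feed$q else 0
    p <- list(k = rates$conjugation_rates, k_drug = rates$k_drug,
              react_idx = struct$react_idx, prod_idx = struct$prod_idx,
              rate_idx = struct$rate_idx, n = n, q = q_seg, c_in = feed$c_in)
    sol <- deSolve::ode(y = y, times = seg_times, func = .rhs_flat, parms = p,
                        method = "lsoda", rtol = rtol, atol = atol)
    istate <- attr(sol, "istate")[1]
    if (!is.null(istate) && istate < 0)
      stop(sprintf("ODE integration failed in segment [%g, %g] s", t0, t1))
    if (anyNA(sol))
      stop(sprintf("ODE integration produced NA in segment [%g, %g] s", t0, t1))
    keep <- if (s == 1L) seq_len(nrow(sol)) else seq_len(nrow(sol))[-1]
    rows[[s]] <- sol[keep, -1, drop = FALSE]
    times_acc <- c(times_acc, sol[keep, 1])
    y <- sol[nrow(sol), -1]
    if (t1 %in% condition$sample_times) {
      y[n + 2L] <- y[n + 2L] - condition$sample_volume
      if (y[n + 2L] <= 0)
        stop(sprintf("reactor volume exhausted by sampling at t = %g s", t1))
    }
  }
  hidden <- do.call(rbind, rows)
  colnames(hidden) <- c(struct$tab$name, ".drug", ".volume")
  free_drug <- hidden[, ".drug"]
  volume <- hidden[, ".volume"]
  hidden <- hidden[, seq_len(n), drop = FALSE]
  observed <- hidden %*% t(struct$collapse)
  obs_idx <- match(condition$sample_times, times_acc)
  observation <- kinetic_observation(
    times = condition$sample_times,
    observed = observed[obs_idx, , drop = FALSE],
    condition = condition
  )
  structure(list(times = times_acc, hidden = hidden, free_drug = free_drug,
                 volume = volume, observed = observed,
                 observation = observation, spec = spec, rates = rates,
                 condition = condition, distribution = distribution,
                 structure = struct),
            class = "conj_sim")
}

#' Observed chain-species time series of one run
#'
#' The reducing assay collapses the hidden initial-site identity: only the
#' drug load per chain is observable.
#'
#' @param times Quench times, s.
#' @param observed Matrix (times x species) of molar concentrations, mmol/L,
#'   with columns named `H0`..`Hmax`, `L0`, `L1`.
#' @param condition The generating [run_condition()].
#' @param run_id Optional identifier.
#' @return Object of class `kinetic_observation`.
#' @export
kinetic_observation <- function(times, observed, condition, run_id = NULL) {
  observed <- as.matrix(observed)
  stopifnot(length(times) == nrow(observed))
  structure(list(times = as.numeric(times), observed = observed,
                 condition = condition, run_id = run_id),
            class = "kinetic_observation")
}

#' Collapse a hidden trajectory onto the observable species
#'
#' `observed(chain, d) = sum over nc >= d of hidden(chain, d, nc)`; chain
#' totals are preserved.
#'
#' @param hidden Matrix of hidden species (columns named as in
#'   `species_table`), or a `conj_sim`.
#' @param spec The [model_spec()] (ignored when `hidden` is a `conj_sim`).
#' @return Matrix with columns `H0`..`Hmax`, `L0`, `L1`.
#' @export
collapse_observables <- function(hidden, spec = NULL) {
  if (inherits(hidden, "conj_sim")) return(hidden$observed)
  stopifnot(inherits(spec, "model_spec"))
  struct <- model_structure(spec)
  hidden <- matrix(as.numeric(hidden), ncol = struct$n_species,
                   dimnames = list(NULL, struct$tab$name))
  hidden %*% t(struct$collapse)
}

#' Drug-to-antibody ratio of a trajectory or observation
#'
#' `DAR = sum_d d * (c_H,d + c_L,d) / c_mab_molar`, with the mAb molar
#' concentration taken as half the total heavy-chain concentration at the same
#' time so that fed-batch dilution cancels. Conjugation being irreversible,
#' DAR is non-decreasing in time.
#'
#' @param x A `conj_sim` or `kinetic_observation`.
#' @param at_time Time (s) at which to evaluate; must lie on the stored grid
#'   (nearest grid point within `tol` seconds is used). Default: last time.
#' @param tol Time-matching tolerance, s.
#' @return DAR (dimensionless, in `[0, 2 * max_heavy + 2]`).
#' @export
compute_dar <- function(x, at_time = NULL, tol = 1e-6) {
  obs <- if (inherits(x, "conj_sim")) x$observed else x$observed
  times <- if (inherits(x, "conj_sim")) x$times else x$times
  if (is.null(at_time)) at_time <- times[length(times)]
  i <- which.min(abs(times - at_time))
  if (abs(times[i] - at_time) > max(tol, 1e-9 * max(times)))
    stop("at_time not on the stored time grid")
  .dar_row(obs[i, ])
}

.dar_row <- function(row) {
  nm <- names(row)
  d <- as.integer(sub("^[HL]", "", nm))
  heavy <- startsWith(nm, "H")
  mab <- sum(row[heavy]) / 2
  if (mab <= 0) stop("zero mAb concentration")
  sum(d * row) / mab
}

#' DAR time course of a simulation
#'
#' @param sim A `conj_sim`.
#' @return Numeric vector of DAR values on `sim$times`.
#' @export
dar_trajectory <- function(sim) {
  stopifnot(inherits(sim, "conj_sim"))
  apply(sim$observed, 1, .dar_row)
}

#' @export
print.conj_sim <- function(x, ...) {
  cat(sprintf("Conjugation simulation (%s %s): %d time points to %.0f s\n",
              x$spec$modality, x$spec$variant, length(x$times),
              max(x$times)))
  cat(sprintf("  final DAR %.3f, residual free payload %.4g mmol/L\n",
              compute_dar(x), x$free_drug[length(x$free_drug)]))
  invisible(x)
}
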