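#' Define a conjugation kinetic model candidate
#'
#' A model candidate is defined by the conjugation modality and the degree of
#' kinetic detail. Site-specific conjugation (`"DAR2"`) attaches payload to up
#' to two engineered hinge cysteines on the heavy chain; interchain-disulfide
#' conjugation (`"DAR8"`) attaches payload stochastically to up to four sites
#' per heavy chain (the fourth representing over-conjugation / mis-alkylation)
#' and one per light chain. The `"simple"` variant uses a single second-order
#' rate constant for every conjugation step; the `"detailed"` variant assigns
#' step-specific rates:
#'
#' * DAR2 detailed: `k1` (first heavy-chain step), `k2` (second step) -- 2 rates.
#' * DAR8 detailed: `k1` (light chain), `k2`, `k3`, `k4/5` (heavy-chain steps
#'   1, 2 and 3--4, the last two steps sharing one lumped rate) -- 4 rates.
#'
#' @param modality `"DAR2"` or `"DAR8"`.
#' @param variant `"simple"` (one rate) or `"detailed"` (step-specific rates).
#' @return An object of class `model_spec` with fields `modality`, `variant`,
#'   `n_rate_params`, `max_heavy` (2 for DAR2, 4 for DAR8) and `rate_names`.
#' @examples
#' model_spec("DAR8", "detailed")$n_rate_params  # 4
#' @export
model_spec <- function(modality = c("DAR2", "DAR8"),
                       variant = c("simple", "detailed")) {
  modality <- match.arg(modality)
  variant <- match.arg(variant)
  max_heavy <- if (modality == "DAR2") 2L else 4L
  rate_names <- if (variant == "simple") {
    "k1"
  } else if (modality == "DAR2") {
    c("k1", "k2")
  } else {
    c("k1", "k2", "k3", "k4/5")
  }
  structure(
    list(modality = modality, variant = variant,
         n_rate_params = length(rate_names),
         max_heavy = max_heavy, rate_names = rate_names),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Conjugation model: %s, %s variant (%d rate parameter%s: %s)\n",
              x$modality, x$variant, x$n_rate_params,
              if (x$n_rate_params > 1) "s" else "",
              paste(x$rate_names, collapse = ", ")))
  invisible(x)
}

#' Bundle conjugation rate constants with a frozen payload depletion rate
#'
#' @param conjugation_rates Numeric vector of second-order conjugation rate
#'   constants in L mmol^-1 s^-1; its length must equal
#'   `model_spec()$n_rate_params` of the model it is used with.
#' @param k_drug First-order payload depletion rate in s^-1 (>= 0). The
#'   depletion rate is never co-estimated with the conjugation rates; it is
#'   measured separately (see [fit_depletion_rate()]) and frozen here.
#' @return Object of class `rate_set`.
#' @export
rate_set <- function(conjugation_rates, k_drug = 0) {
  conjugation_rates <- as.numeric(conjugation_rates)
  stopifnot(length(conjugation_rates) >= 1, is.finite(conjugation_rates),
            length(k_drug) == 1, is.finite(k_drug))
  if (any(conjugation_rates < 0)) stop("conjugation rates must be >= 0")
  if (k_drug < 0) stop("k_drug must be >= 0")
  structure(list(conjugation_rates = unname(conjugation_rates),
                 k_drug = as.numeric(k_drug)),
            class = "rate_set")
}

#' Map a conjugation step to its rate-parameter index
#'
#' The step-rate lookup is total: every (chain kind, step index) pair that
#' exists in the modality maps to exactly one element of
#' `rate_set$conjugation_rates`. Step `d` converts a chain carrying `d - 1`
#' payloads into one carrying `d`.
#'
#' @param spec A [model_spec()].
#' @param chain `"H"` or `"L"`.
#' @param step Conjugation step index (1-based, the payload count of the
#'   product species).
#' @return Integer index into `conjugation_rates`.
#' @export
step_rate_index <- function(spec, chain, step) {
  stopifnot(inherits(spec, "model_spec"), chain %in% c("H", "L"))
  max_step <- if (chain == "H") spec$max_heavy else 1L
  if (any(step < 1L | step > max_step)) {
    stop(sprintf("no conjugation step %s for chain %s in %s",
                 paste(step, collapse = ","), chain, spec$modality))
  }
  if (spec$variant == "simple") return(rep(1L, length(step)))
  if (spec$modality == "DAR2") {
    # detailed DAR2: heavy steps 1, 2 -> k1, k2 (light chain is inert but the
    # lookup stays total)
    if (chain == "L") return(rep(1L, length(step)))
    return(as.integer(step))
  }
  # detailed DAR8: light -> k1; heavy steps 1..4 -> k2, k3, k4/5, k4/5
  if (chain == "L") return(rep(1L, length(step)))
  c(2L, 3L, 4L, 4L)[step]
}

# Hidden-species bookkeeping table for a modality: one row per
# (chain, drugs bound d, initial reactive sites nc) with 0 <= d <= nc.
# Heavy chains span nc = 0..max_heavy, light chains nc = 0..1.
species_table <- function(spec) {
  rows <- list()
  for (nc in 0:spec$max_heavy) for (d in 0:nc) {
    rows[[length(rows) + 1L]] <- data.frame(chain = "H", d = d, nc = nc)
  }
  for (nc in 0:1) for (d in 0:nc) {
    rows[[length(rows) + 1L]] <- data.frame(chain = "L", d = d, nc = nc)
  }
  tab <- do.call(rbind, rows)
  tab$name <- sprintf("%s%d.%dc", tab$chain, tab$d, tab$nc)
  tab$observable <- sprintf("%s%d", tab$chain, tab$d)
  tab
}

# Precomputed index structure shared by the RHS, the observable collapse and
# the simulator.
model_structure <- function(spec) {
  tab <- species_table(spec)
  n <- nrow(tab)
  # reacting species: d < nc; product is the same (chain, nc) at d + 1
  react <- which(tab$d < tab$nc)
  key <- paste(tab$chain, tab$d, tab$nc)
  prod <- match(paste(tab$chain[react], tab$d[react] + 1L, tab$nc[react]), key)
  rate_idx <- integer(length(react))
  for (i in seq_along(react)) {
    rate_idx[i] <- step_rate_index(spec, tab$chain[react[i]],
                                   tab$d[react[i]] + 1L)
  }
  obs_names <- c(sprintf("H%d", 0:spec$max_heavy), "L0", "L1")
  collapse <- matrix(0, nrow = length(obs_names), ncol = n,
                     dimnames = list(obs_names, tab$name))
  collapse[cbind(match(tab$observable, obs_names), seq_len(n))] <- 1
  list(spec = spec, tab = tab, n_species = n,
       react_idx = react, prod_idx = prod, rate_idx = rate_idx,
       obs_names = obs_names, collapse = collapse)
}
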