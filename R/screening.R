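#' In-silico screening of initial mAb concentration and drug excess
#'
#' Simulates a 30-min batch conjugation at every grid point of initial mAb
#' concentration x molar drug excess with a calibrated model and records
#' three outputs: the final DAR (at `t_final`), the residual free-payload
#' concentration, and the reaction time needed to reach the final DAR -- the
#' earliest time from which the DAR stays within `plateau_tol` (relative,
#' default 1%) of its `t_final` value. Grid points where the integration
#' fails are recorded as `NA` and the screening continues.
#'
#' @param spec Calibrated [model_spec()].
#' @param rates Calibrated [rate_set()] (including the payload's frozen
#'   depletion rate).
#' @param distribution The [cysteine_distribution()] of the mAb.
#' @param c_mab_grid mAb concentrations, g/L (default 20 points, 1.5--10).
#' @param excess_grid Molar drug excess values (default 20 points, 5--14).
#' @param t_final Evaluation time, s (default 30 min).
#' @param dt Dense output resolution for plateau detection, s (default 1).
#' @param mab_molar_mass mAb molar mass, g/mol.
#' @return Object of class `screening_result`: a long-format data frame
#'   `grid` with columns `c_mab`, `excess`, `dar_final`, `free_drug`
#'   (mmol/L), `time_to_plateau` (s), plus the axes.
#' @export
screen_conditions <- function(spec, rates, distribution,
                              c_mab_grid = seq(1.5, 10, length.out = 20),
                              excess_grid = seq(5, 14, length.out = 20),
                              t_final = 1800, dt = 1,
                              mab_molar_mass = 148000) {
  grid <- expand.grid(c_mab = c_mab_grid, excess = excess_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$dar_final <- NA_real_
  grid$free_drug <- NA_real_
  grid$time_to_plateau <- NA_real_
  dense_n <- ceiling(t_final / dt)
  for (i in seq_len(nrow(grid))) {
    cond <- run_condition(grid$c_mab[i], grid$excess[i], mode = "batch",
                          sample_times = numeric(0), sample_volume = 0,
                          t_end = t_final, mab_molar_mass = mab_molar_mass)
    sim <- tryCatch(
      simulate_conjugation(spec, rates, cond, distribution, dense_n = dense_n),
      error = function(e) NULL
    )
    if (is.null(sim)) next
    nt <- length(sim$times)
    grid$free_drug[i] <- max(0, sim$free_drug[nt])
    dar <- dar_trajectory(sim)
    dar_f <- dar[nt]
    grid$dar_final[i] <- dar_f
    grid$time_to_plateau[i] <- plateau_time(sim$times, dar, dar_f)
  }
  structure(list(grid = grid, c_mab_grid = c_mab_grid,
                 excess_grid = excess_grid, t_final = t_final),
            class = "screening_result")
}

#' Earliest time from which a DAR trajectory stays at its final plateau
#'
#' Returns the smallest time `t` such that `|DAR(t') - dar_final| /
#' dar_final <= tol` for every `t' >= t`. A zero final DAR (e.g. zero drug
#' excess) returns 0.
#'
#' @param times,dar Trajectory grid and DAR values.
#' @param dar_final Reference final DAR (default: last value).
#' @param tol Relative threshold (default 0.01).
#' @return Time in s.
#' @export
plateau_time <- function(times, dar, dar_final = dar[length(dar)],
                         tol = 0.01) {
  if (dar_final <= 0) return(0)
  outside <- abs(dar - dar_final) / dar_final > tol
  if (!any(outside)) return(times[1])
  last_out <- max(which(outside))
  if (last_out == length(times)) return(times[length(times)])
  times[last_out + 1L]
}

#' @export
print.screening_result <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "In-silico screening: %d x %d grid (c_mab %.3g-%.3g g/L, excess %.3g-%.3gx) at %.0f s\n",
    length(x$c_mab_grid), length(x$excess_grid),
    min(x$c_mab_grid), max(x$c_mab_grid),
    min(x$excess_grid), max(x$excess_grid), x$t_final))
  cat(sprintf("  DAR %.3g-%.3g, free payload up to %.4g mmol/L, plateau times %.0f-%.0f s\n",
              min(g$dar_final, na.rm = TRUE), max(g$dar_final, na.rm = TRUE),
              max(g$free_drug, na.rm = TRUE),
              min(g$time_to_plateau, na.rm = TRUE),
              max(g$time_to_plateau, na.rm = TRUE)))
  invisible(x)
}

#' Heat-map of a screening output
#'
#' Base-graphics filled image of one screening output over the
#' c_mab x excess grid.
#'
#' @param x A [screen_conditions()] result.
#' @param what `"dar_final"`, `"free_drug"` or `"time_to_plateau"`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot_screening <- function(x, what = c("dar_final", "free_drug",
                                       "time_to_plateau"), ...) {
  what <- match.arg(what)
  z <- matrix(x$grid[[what]], nrow = length(x$c_mab_grid))
  graphics::image(x = x$c_mab_grid, y = x$excess_grid, z = z,
                  xlab = "mAb concentration (g/L)", ylab = "molar drug excess",
                  main = what, ...)
  invisible(z)
}
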