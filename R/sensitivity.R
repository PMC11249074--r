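# One-factor-at-a-time sensitivity around the reference point and maximal
# change over the full biological ranges. All analyses perturb one parameter
# while holding the other six at their reference values, and use the same
# initial conditions and horizon as the reference run.

OBSERVABLES <- c("log_volume_ratio", "pi_final", "P_final")

#' Scalar observables of a trajectory
#'
#' The three observables used throughout the sensitivity analyses:
#' the logarithmic volume increase `log(V(t_max)/V(0))` (natural log,
#' dimensionless), and the final osmotic and turgor pressures (Pa).
#'
#' @param traj A `fiber_trajectory` reaching `t_max`.
#' @param which One of `"log_volume_ratio"`, `"pi_final"`, `"P_final"`.
#' @return A single number.
#' @export
trajectory_observable <- function(traj, which = OBSERVABLES) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  which <- match.arg(which)
  n <- nrow(traj)
  switch(which,
    log_volume_ratio = log(traj$V[n] / traj$V[1L]),
    pi_final = traj$pi_fiber[n],
    P_final = traj$P_fiber[n]
  )
}

# run the model with one parameter replaced, all solver settings fixed;
# returns all three observables. Tighter-than-default tolerances because
# sensitivities of the pressure observables to the conductivities are of
# order 1e-5 and their signs must be resolved by the finite differences.
run_point <- function(params, V0, pi0, t_max, rel_tol, abs_tol, output_grid) {
  traj <- simulate_fiber(params, V0 = V0, pi0 = pi0, t_max = t_max,
                         output_grid = output_grid,
                         rel_tol = rel_tol, abs_tol = abs_tol)
  vapply(OBSERVABLES, function(w) trajectory_observable(traj, w), 0)
}

#' One-factor-at-a-time sensitivity table
#'
#' Normalized local sensitivities `S(X, x) = (x_ref / X(x_ref)) * dX/dx` of
#' each observable to each parameter at the reference point, estimated by
#' central finite differences: the parameter is moved to
#' `x_ref (1 +/- h)` with all others fixed at reference, the model re-run,
#' and the derivative normalized so that sensitivities are dimensionless and
#' comparable across parameters.
#'
#' @param parameters Character vector of parameters to perturb; default all
#'   seven.
#' @param observables Character vector of observables; default all three.
#' @param table A `parameter_table` supplying reference values.
#' @param step_fraction Relative step `h` of the central difference, in
#'   `(0, 0.1]` (the exploration window around the reference is at most
#'   +/-10%). Default 0.01.
#' @param V0,pi0 Initial conditions; `pi0 = NULL` means iso-osmotic with the
#'   seed.
#' @param t_max Horizon (s); default 500 h.
#' @param rel_tol,abs_tol,output_grid Solver settings (tight defaults: the
#'   smallest tabulated sensitivities are of order 1e-5).
#' @param check_convergence If `TRUE`, recompute each S with `h/2` and store
#'   the relative discrepancy in attribute `step_halving`.
#' @return A data frame with columns `observable`, `parameter`, `S`,
#'   `step_fraction`, `X_plus`, `X_minus`, `X_ref`.
#' @export
#' @examples
#' \donttest{
#' oat_sensitivity_table(parameters = "alpha",
#'                       observables = "log_volume_ratio")
#' }
oat_sensitivity_table <- function(parameters = NULL, observables = OBSERVABLES,
                                  table = default_parameter_table(),
                                  step_fraction = 0.01,
                                  V0 = default_V0(), pi0 = NULL,
                                  t_max = 500 * 3600,
                                  rel_tol = 1e-11, abs_tol = c(1e-13, 1e-5),
                                  output_grid = 201,
                                  check_convergence = FALSE) {
  if (is.null(parameters)) parameters <- table$parameter
  observables <- match.arg(observables, OBSERVABLES, several.ok = TRUE)
  if (!all(parameters %in% table$parameter))
    stop("unknown parameter(s): ",
         paste(setdiff(parameters, table$parameter), collapse = ", "),
         call. = FALSE)
  if (step_fraction <= 0 || step_fraction > 0.1)
    stop("step_fraction must be in (0, 0.1]", call. = FALSE)
  ref <- reference_parameters(table)
  if (is.null(pi0)) pi0 <- ref$pi_seed
  X0 <- run_point(ref, V0, pi0, t_max, rel_tol, abs_tol, output_grid)

  one_S <- function(parameter, h) {
    x_ref <- table$x_ref[table$parameter == parameter]
    perturb <- function(f) {
      p <- unclass(ref); p[[parameter]] <- x_ref * f
      run_point(structure(p, class = "fiber_params"),
                V0, pi0, t_max, rel_tol, abs_tol, output_grid)
    }
    Xp <- perturb(1 + h); Xm <- perturb(1 - h)
    list(S = (Xp - Xm) / (2 * h) / X0, Xp = Xp, Xm = Xm)
  }

  rows <- list()
  halving <- list()
  for (parameter in parameters) {
    est <- one_S(parameter, step_fraction)
    if (any(X0[observables] == 0))
      stop("observable is zero at the reference point; normalized ",
           "sensitivity undefined", call. = FALSE)
    rows[[parameter]] <- data.frame(
      observable = observables, parameter = parameter,
      S = est$S[observables], step_fraction = step_fraction,
      X_plus = est$Xp[observables], X_minus = est$Xm[observables],
      X_ref = X0[observables], stringsAsFactors = FALSE, row.names = NULL)
    if (check_convergence) {
      est2 <- one_S(parameter, step_fraction / 2)
      halving[[parameter]] <- abs(est2$S[observables] - est$S[observables]) /
        pmax(abs(est$S[observables]), .Machine$double.xmin)
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  if (check_convergence) attr(out, "step_halving") <- halving
  out
}

#' Single one-factor-at-a-time sensitivity
#'
#' Convenience wrapper around [oat_sensitivity_table()] for one
#' (observable, parameter) pair.
#'
#' @inheritParams oat_sensitivity_table
#' @param parameter Name of the parameter to perturb.
#' @param observable Name of the observable.
#' @param ... Passed on to [oat_sensitivity_table()].
#' @return The sensitivity `S` (a single number), with the full report row
#'   in attribute `report`.
#' @export
oat_sensitivity <- function(parameter, observable = "log_volume_ratio", ...) {
  tab <- oat_sensitivity_table(parameters = parameter,
                               observables = observable, ...)
  structure(tab$S[1L], report = tab)
}

#' Maximal change of an observable over a biological parameter range
#'
#' Sweeps one parameter over its full biological range (all others at
#' reference) on a log-spaced grid including both endpoints, and reports
#' `MC = (max X - min X) / X(x_ref)`: the total swing of the observable,
#' normalized by its reference value. Unlike the local sensitivity, MC
#' accounts for how wide each parameter's biological range is, which differs
#' by orders of magnitude between parameters.
#'
#' @inheritParams oat_sensitivity_table
#' @param parameter Parameter to sweep.
#' @param observable Observable name.
#' @param n_grid Number of grid points (>= 2); log-spaced so that ranges
#'   spanning several decades are covered evenly; endpoints always included.
#' @return `MC` (non-negative number) with attribute `sweep`, a data frame of
#'   the grid values and observables.
#' @export
maximal_change <- function(parameter, observable = "log_volume_ratio",
                           table = default_parameter_table(), n_grid = 33,
                           V0 = default_V0(), pi0 = NULL, t_max = 500 * 3600,
                           rel_tol = 1e-10, abs_tol = c(1e-12, 1e-4),
                           output_grid = 201) {
  observable <- match.arg(observable, OBSERVABLES)
  sweep <- mc_sweep(parameter, table, n_grid, V0, pi0, t_max,
                    rel_tol, abs_tol, output_grid)
  X <- sweep$grid_obs[, observable]
  X_ref <- sweep$ref_obs[observable]
  if (X_ref == 0)
    stop("observable is zero at the reference point; MC undefined",
         call. = FALSE)
  structure((max(X) - min(X)) / X_ref,
            sweep = data.frame(value = sweep$grid, X = X))
}

# sweep one parameter over its range, all three observables per grid point
mc_sweep <- function(parameter, table, n_grid, V0, pi0, t_max,
                     rel_tol, abs_tol, output_grid) {
  if (!parameter %in% table$parameter)
    stop("unknown parameter: ", parameter, call. = FALSE)
  if (n_grid < 2) stop("n_grid must be >= 2", call. = FALSE)
  row <- table[table$parameter == parameter, ]
  ref <- reference_parameters(table)
  if (is.null(pi0)) pi0 <- ref$pi_seed
  grid <- exp(seq(log(row$x_min), log(row$x_max), length.out = n_grid))
  grid_obs <- t(vapply(grid, function(x) {
    p <- unclass(ref); p[[parameter]] <- x
    run_point(structure(p, class = "fiber_params"),
              V0, pi0, t_max, rel_tol, abs_tol, output_grid)
  }, stats::setNames(numeric(3), OBSERVABLES)))
  ref_obs <- run_point(ref, V0, pi0, t_max, rel_tol, abs_tol, output_grid)
  list(grid = grid, grid_obs = grid_obs, ref_obs = ref_obs)
}

#' Maximal change for all parameters and observables
#'
#' One log-spaced sweep per parameter serves all three observables.
#'
#' @inheritParams maximal_change
#' @param parameters Parameters to sweep (default: all in `table`).
#' @param observables Observables (default: all three).
#' @return Tidy data frame with columns `observable`, `parameter`, `MC`,
#'   `n_grid`.
#' @export
maximal_change_table <- function(parameters = NULL, observables = OBSERVABLES,
                                 table = default_parameter_table(),
                                 n_grid = 33,
                                 V0 = default_V0(), pi0 = NULL,
                                 t_max = 500 * 3600,
                                 rel_tol = 1e-10, abs_tol = c(1e-12, 1e-4),
                                 output_grid = 201) {
  if (is.null(parameters)) parameters <- table$parameter
  observables <- match.arg(observables, OBSERVABLES, several.ok = TRUE)
  rows <- lapply(parameters, function(parameter) {
    sweep <- mc_sweep(parameter, table, n_grid, V0, pi0, t_max,
                      rel_tol, abs_tol, output_grid)
    mc <- vapply(observables, function(obs)
      (max(sweep$grid_obs[, obs]) - min(sweep$grid_obs[, obs])) /
        sweep$ref_obs[obs], 0)
    data.frame(observable = observables, parameter = parameter, MC = mc,
               n_grid = n_grid, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
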