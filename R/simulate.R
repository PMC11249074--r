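# Forward simulation of the two-variable ODE system. The state vector handed
# to the integrator is (log V, pi_fiber): volume spans many orders of
# magnitude over a 3,000 h run and log-volume keeps relative error uniform.
# The right-hand side is only piecewise smooth (positive parts, schedule
# windows), so integration is split at every schedule breakpoint instead of
# letting the adaptive stepper discover the discontinuities.

#' Simulate the fiber elongation model
#'
#' Integrates fiber volume and osmotic pressure from `t = 0` to `t_max`,
#' optionally with time-varying parameters, and returns a dense trajectory
#' with all derived quantities (turgor, fluxes, relative growth rate)
#' evaluated on the output grid.
#'
#' @param params Base [fiber_params()].
#' @param V0 Initial volume (m^3). Default `1.88e-13` (i.e. 1.88e-4 mm^3).
#' @param pi0 Initial fiber osmotic pressure (Pa). Defaults to
#'   `params$pi_seed` (fiber initially iso-osmotic with the seed).
#' @param t_max Simulation horizon (s). Default 500 h, comparable with the
#'   natural duration of cotton fiber growth.
#' @param schedules List of [parameter_schedule()] objects (possibly empty).
#' @param output_grid Number of uniformly spaced output samples. Default
#'   2001 resolves 50 h windows within 500–3,000 h horizons.
#' @param rel_tol,abs_tol Local error tolerances for the adaptive integrator;
#'   `abs_tol` has one entry for log-volume and one for osmotic pressure (Pa).
#'   The defaults keep the final volume converged to well below 1e-6
#'   relative (halving them moves it by less than that).
#' @return A data frame of class `fiber_trajectory` with columns `t`, `V`,
#'   `pi_fiber`, `dP`, `P_fiber`, `F_m`, `F_p`, `rgr` (SI units) and the
#'   simulation setup stored in attributes.
#' @export
#' @examples
#' traj <- simulate_fiber(reference_parameters(), output_grid = 201)
#' log(traj$V[nrow(traj)] / traj$V[1])
simulate_fiber <- function(params,
                           V0 = default_V0(),
                           pi0 = params$pi_seed,
                           t_max = 500 * 3600,
                           schedules = list(),
                           output_grid = 2001,
                           rel_tol = 1e-10,
                           abs_tol = c(1e-12, 1e-4)) {
  stopifnot(inherits(params, "fiber_params"))
  if (!is.finite(V0) || V0 <= 0) stop("V0 must be > 0", call. = FALSE)
  if (!is.finite(pi0) || pi0 < 0) stop("pi0 must be >= 0", call. = FALSE)
  if (!is.finite(t_max) || t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  if (output_grid < 2) stop("output_grid must be >= 2", call. = FALSE)
  if (any(c(rel_tol, abs_tol) <= 0)) stop("tolerances must be > 0", call. = FALSE)
  if (length(abs_tol) == 1L) abs_tol <- rep(abs_tol, 2L)
  schedules <- as_schedule_list(schedules)

  grid <- seq(0, t_max, length.out = output_grid)
  bps <- sort(unique(unlist(lapply(schedules, schedule_breakpoints))))
  bps <- bps[bps > 0 & bps < t_max]
  seg_bounds <- unique(c(0, bps, t_max))

  y <- c(log(V0), pi0)
  rows_t <- numeric(0); rows_logV <- numeric(0); rows_pi <- numeric(0)
  for (i in seq_len(length(seg_bounds) - 1L)) {
    a <- seg_bounds[i]; b <- seg_bounds[i + 1L]
    mid <- (a + b) / 2
    params_at <- make_params_at(params, schedules, mid)
    times <- unique(c(a, grid[grid > a & grid < b], b))
    sol <- deSolve::ode(y = y, times = times, func = .rhs_ode,
                        parms = list(params_at = params_at),
                        method = "lsoda", rtol = rel_tol, atol = abs_tol)
    if (attr(sol, "istate")[1L] < 0 || any(!is.finite(sol)))
      stop(sprintf("integration failed near t = %.6g s (%.3g h)",
                   sol[nrow(sol), 1L], sol[nrow(sol), 1L] / 3600),
           call. = FALSE)
    keep <- if (i == 1L) seq_len(nrow(sol)) else seq(2L, nrow(sol))
    rows_t <- c(rows_t, sol[keep, 1L])
    rows_logV <- c(rows_logV, sol[keep, 2L])
    rows_pi <- c(rows_pi, sol[keep, 3L])
    y <- as.numeric(sol[nrow(sol), 2:3])
  }

  # derived quantities on the stored grid (output samples plus breakpoints,
  # which aid the extremum and steady-state detectors)
  V <- exp(rows_logV)
  if (!length(schedules)) {
    dP <- .dP(params, V, rows_pi)
    P_fiber <- dP + params$P_seed
    F_m <- params$Lr * V * ((rows_pi - params$pi_seed) - dP)
    F_p <- -params$mu * dP
    rgr <- params$phi * ppart(dP + params$P_seed - params$Y)
  } else {
    pars_t <- lapply(rows_t, function(t)
      evaluate_schedule(schedules, params, t))
    dP <- mapply(function(p, v, pf) .dP(p, v, pf), pars_t, V, rows_pi)
    P_fiber <- dP + vapply(pars_t, `[[`, 0, "P_seed")
    F_m <- mapply(function(p, v, pf, d) p$Lr * v * ((pf - p$pi_seed) - d),
                  pars_t, V, rows_pi, dP)
    F_p <- -vapply(pars_t, `[[`, 0, "mu") * dP
    rgr <- mapply(function(p, d) p$phi * max(d + p$P_seed - p$Y, 0), pars_t, dP)
  }

  traj <- data.frame(t = rows_t, V = V, pi_fiber = rows_pi, dP = dP,
                     P_fiber = P_fiber, F_m = F_m, F_p = F_p, rgr = rgr)
  attr(traj, "params") <- params
  attr(traj, "schedules") <- schedules
  attr(traj, "V0") <- V0
  attr(traj, "pi0") <- pi0
  attr(traj, "t_max") <- t_max
  class(traj) <- c("fiber_trajectory", "data.frame")
  traj
}

# frozen-membership parameter lookup for one integration segment: window and
# pulse membership is decided at the segment midpoint (constant within the
# segment by construction of the breakpoints), continuous shapes at t itself.
make_params_at <- function(base, schedules, t_member) {
  if (!length(schedules)) return(function(t) base)
  function(t) {
    p <- unclass(base)
    for (sc in schedules)
      p[[sc$parameter]] <- schedule_value(sc, base[[sc$parameter]], t,
                                          t_member = t_member)
    structure(p, class = "fiber_params")
  }
}

#' @export
print.fiber_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<fiber_trajectory> %d samples over %.4g h\n", n,
              x$t[n] / 3600))
  cat(sprintf("  V:        %.4g -> %.4g mm^3 (x%.4g)\n",
              x$V[1] * 1e9, x$V[n] * 1e9, x$V[n] / x$V[1]))
  cat(sprintf("  pi_fiber: %.4g -> %.4g MPa\n",
              x$pi_fiber[1] / 1e6, x$pi_fiber[n] / 1e6))
  cat(sprintf("  P_fiber:  %.4g -> %.4g MPa\n",
              x$P_fiber[1] / 1e6, x$P_fiber[n] / 1e6))
  invisible(x)
}

#' Detect the time at which pressures reach steady state
#'
#' Finds the earliest time after which the normalized rates of change of both
#' osmotic and turgor pressure stay below a threshold: for each sample the
#' criterion is `|dX/dt| * t_max / |X| < tol`, i.e. at the current rate the
#' relative change over the whole horizon would be below `tol`. Rates are
#' estimated by centered differences on the output grid.
#'
#' @param traj A `fiber_trajectory`.
#' @param tol Relative-rate threshold (dimensionless). Default 0.01.
#' @return Steady-state onset time (s), or `NA` if the criterion is never met
#'   through the end of the trajectory.
#' @export
detect_steady_state <- function(traj, tol = 0.01) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  t <- traj$t
  t_max <- t[length(t)]
  ok <- rep(TRUE, length(t))
  for (x in list(traj$pi_fiber, traj$P_fiber)) {
    rate <- grid_derivative(t, x)
    crit <- abs(rate) * t_max / pmax(abs(x), .Machine$double.xmin)
    ok <- ok & (crit < tol)
  }
  # earliest index from which the criterion holds through the end
  holds_to_end <- rev(cumprod(rev(ok))) > 0
  if (!any(holds_to_end)) return(NA_real_)
  t[which(holds_to_end)[1L]]
}

grid_derivative <- function(t, x) {
  n <- length(t)
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
  d[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L)
    d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  d
}

#' Interior extrema of a trajectory variable
#'
#' Scans the output grid for interior local maxima and minima, after
#' discarding an initial transient window (only the first few hours of a run
#' depend on the initial conditions). A point counts as an extremum only if
#' it differs from both neighbors by more than a small relative guard, which
#' avoids flagging solver ripple on flat stretches.
#'
#' @param traj A `fiber_trajectory`.
#' @param variable One of `"pi_fiber"`, `"P_fiber"`, `"V"`, `"rgr"`.
#' @param transient_frac Fraction of the horizon discarded at the start
#'   before looking for extrema. Default 0.05.
#' @param guard Relative threshold by which an extremum must exceed (or
#'   undercut) both neighbors. Default 1e-9.
#' @return A data frame with columns `t`, `value`, `kind`
#'   (`"max"`/`"min"`); zero rows for a monotonic series.
#' @export
extract_extrema <- function(traj, variable = c("pi_fiber", "P_fiber", "V", "rgr"),
                            transient_frac = 0.05, guard = 1e-9) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  variable <- match.arg(variable)
  t_max <- traj$t[nrow(traj)]
  keep <- traj$t >= transient_frac * t_max
  t <- traj$t[keep]
  x <- traj[[variable]][keep]
  n <- length(x)
  if (n < 3L)
    return(data.frame(t = numeric(0), value = numeric(0),
                      kind = character(0)))
  i <- 2:(n - 1L)
  scale <- pmax(abs(x[i]), .Machine$double.xmin)
  is_max <- (x[i] - x[i - 1L]) > guard * scale & (x[i] - x[i + 1L]) > guard * scale
  is_min <- (x[i - 1L] - x[i]) > guard * scale & (x[i + 1L] - x[i]) > guard * scale
  idx <- i[is_max | is_min]
  data.frame(
    t = t[idx],
    value = x[idx],
    kind = ifelse(is_max[idx - 1L], "max", "min"),
    stringsAsFactors = FALSE
  )
}
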