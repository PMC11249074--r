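# Classification of pressure trajectories (monotonic vs. peaked), the
# analytic peak-existence condition for constant parameters, and the
# dynamic-parameter scenario suite.

#' Analytic peak-existence condition for constant parameters
#'
#' For constant parameters, a peak of osmotic or turgor pressure requires the
#' solute source `alpha` to lie strictly below a combination of the other
#' parameters,
#' `alpha < phi * Lr * (Y - P_seed) * (phi * (Y - P_seed) - Lr * pi_seed)`,
#' together with fiber turgor initially strictly below seed turgor. The
#' inequality is evaluated verbatim in this product form. As printed it is
#' dimensionally heterogeneous (left side Pa/s, right side not reducible to
#' Pa/s), so a diagnostic flag accompanies the result; the numerical
#' trajectory classifier ([classify_pressures()]) is the source of truth for
#' behavior labels. Over the whole biological parameter range the right-hand
#' side is vanishingly small compared to any admissible `alpha`, so the
#' condition fails throughout: constant biologically plausible parameters
#' cannot produce pressure peaks.
#'
#' @param params A [fiber_params()] object.
#' @return A list of class `peak_condition` with elements `satisfied`
#'   (logical), `alpha`, `threshold` (the right-hand side), and
#'   `dimensionally_consistent` (always `FALSE`, flagging the verbatim form).
#' @export
#' @examples
#' peak_condition(reference_parameters())$satisfied  # FALSE
peak_condition <- function(params) {
  stopifnot(inherits(params, "fiber_params"))
  rhs <- params$phi * params$Lr * (params$Y - params$P_seed) *
    (params$phi * (params$Y - params$P_seed) - params$Lr * params$pi_seed)
  structure(
    list(satisfied = params$alpha < rhs,
         alpha = params$alpha,
         threshold = rhs,
         dimensionally_consistent = FALSE),
    class = "peak_condition")
}

#' @export
print.peak_condition <- function(x, ...) {
  cat(sprintf("<peak_condition> %s (alpha = %.4g, threshold = %.4g)\n",
              if (x$satisfied) "satisfied" else "not satisfied",
              x$alpha, x$threshold))
  if (!x$dimensionally_consistent)
    cat("  note: inequality evaluated verbatim in product form;",
        "units are heterogeneous\n")
  invisible(x)
}

#' Classify pressure trajectories as monotonic or peaked
#'
#' Labels each pressure variable of a trajectory by its interior extrema
#' (after the initial transient; see [extract_extrema()]): no extrema means
#' monotonic (direction from endpoint comparison, with flat series counted as
#' increasing by convention), one interior maximum is a `peak`, one interior
#' minimum a `trough`, anything else `non_monotonic_other`.
#'
#' @param traj A `fiber_trajectory`.
#' @param variables Pressure variables to label.
#' @param ... Passed to [extract_extrema()].
#' @return A data frame with columns `variable`, `label`, `extremum_time`
#'   (s; `NA` for monotonic trajectories).
#' @export
classify_pressures <- function(traj, variables = c("pi_fiber", "P_fiber"),
                               ...) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  rows <- lapply(variables, function(v) {
    ex <- extract_extrema(traj, v, ...)
    x <- traj[[v]]
    if (nrow(ex) == 0L) {
      label <- if (x[length(x)] >= x[1L]) "monotonic_increasing"
               else "monotonic_decreasing"
      t_ex <- NA_real_
    } else if (nrow(ex) == 1L) {
      label <- if (ex$kind == "max") "peak" else "trough"
      t_ex <- ex$t
    } else if (nrow(ex) == 2L && identical(ex$kind, c("max", "min"))) {
      # a peak followed by a rebounding trough still reads as peaked
      label <- "peak"
      t_ex <- ex$t[1L]
    } else {
      label <- "non_monotonic_other"
      t_ex <- ex$t[1L]
    }
    data.frame(variable = v, label = label, extremum_time = t_ex,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

SCENARIOS <- c("reference", "phi_decay", "mu_closure", "combined",
               "alpha_pulse")

#' Run a named dynamic-parameter scenario
#'
#' The scenario suite contrasts the constant-parameter reference run with
#' runs in which one or two parameters follow a prescribed temporal pattern:
#'
#' * `reference` — all parameters constant at reference values.
#' * `phi_decay` — wall extensibility decays linearly from its reference
#'   value at 0 h to zero at 500 h (growth arrest by wall stiffening).
#' * `mu_closure` — plasmodesmal permeability vanishes on the window
#'   200–250 h (transient plasmodesmata closure).
#' * `combined` — both of the above simultaneously.
#' * `alpha_pulse` — the solute source steps from its reference value to the
#'   upper biological limit on 200–250 h (transient osmolyte accumulation).
#'
#' @param name Scenario name.
#' @param params Base parameters (default: reference point).
#' @param t_max Horizon (s); default 500 h.
#' @param alpha_high Pulse plateau for `alpha_pulse` (Pa/s); default the
#'   upper limit of the packaged biological range.
#' @param pulse_start,pulse_duration Window for `mu_closure` /
#'   `alpha_pulse` (s); defaults 200 h and 50 h.
#' @param ... Passed to [simulate_fiber()].
#' @return A list of class `fiber_scenario` with elements `scenario`,
#'   `trajectory`, `labels` (from [classify_pressures()]) and
#'   `final_volume_ratio` (`V(t_max)/V(0)`).
#' @export
#' @examples
#' \donttest{
#' sc <- run_scenario("mu_closure", output_grid = 501)
#' sc$labels
#' }
run_scenario <- function(name = SCENARIOS,
                         params = reference_parameters(),
                         t_max = 500 * 3600,
                         alpha_high = NULL,
                         pulse_start = 200 * 3600,
                         pulse_duration = 50 * 3600,
                         ...) {
  name <- match.arg(name)
  phi_sched <- parameter_schedule("phi", "linear_decay",
                                  t_end_decay = 500 * 3600)
  mu_sched <- parameter_schedule("mu", "closure_window",
                                 t_start = pulse_start,
                                 duration = pulse_duration)
  schedules <- switch(name,
    reference = list(),
    phi_decay = list(phi_sched),
    mu_closure = list(mu_sched),
    combined = list(phi_sched, mu_sched),
    alpha_pulse = {
      if (is.null(alpha_high))
        alpha_high <- default_parameter_table()$x_max[
          default_parameter_table()$parameter == "alpha"]
      list(parameter_schedule("alpha", "pulse", t_start = pulse_start,
                              duration = pulse_duration,
                              high_value = alpha_high))
    })
  traj <- simulate_fiber(params, t_max = t_max, schedules = schedules, ...)
  structure(
    list(scenario = name,
         trajectory = traj,
         labels = classify_pressures(traj),
         final_volume_ratio = traj$V[nrow(traj)] / traj$V[1L]),
    class = "fiber_scenario")
}

#' @export
print.fiber_scenario <- function(x, ...) {
  cat(sprintf("<fiber_scenario> %s: V(t_max)/V(0) = %.4g\n", x$scenario,
              x$final_volume_ratio))
  for (i in seq_len(nrow(x$labels)))
    cat(sprintf("  %-9s %s%s\n", x$labels$variable[i], x$labels$label[i],
                if (is.na(x$labels$extremum_time[i])) "" else
                  sprintf(" at %.4g h", x$labels$extremum_time[i] / 3600)))
  invisible(x)
}

#' Final-volume sweep over plasmodesmata closure timing
#'
#' For each combination of closure start `t0` and closure duration `tdist`,
#' simulates the model to the horizon with plasmodesmal permeability zero on
#' `[t0, t0 + tdist]`, and reports the final volume normalized by its value
#' at the anchor cell (`t0 = 200 h`, `tdist = 50 h`), which is always
#' simulated with the identical configuration so the anchor entry is exactly
#' 1 when present in the grid.
#'
#' @param t0_grid Closure start times (s); default `0, 50, ..., 500` h.
#' @param tdist_grid Closure durations (s); default `0, 50, ..., 500` h.
#' @param params Base parameters.
#' @param t_max Horizon (s); default 3,000 h.
#' @param anchor Anchor `(t0, tdist)` (s) used for normalization.
#' @param ... Passed to [simulate_fiber()].
#' @return A matrix (rows: `t0`, columns: `tdist`, dimnames in hours) of
#'   normalized final volumes, with attributes `anchor_volume` (m^3) and
#'   `clipped` (logical matrix marking windows truncated at the horizon).
#' @export
closure_sweep <- function(t0_grid = seq(0, 500, by = 50) * 3600,
                          tdist_grid = seq(0, 500, by = 50) * 3600,
                          params = reference_parameters(),
                          t_max = 3000 * 3600,
                          anchor = c(200 * 3600, 50 * 3600),
                          ...) {
  if (any(t0_grid < 0) || any(tdist_grid < 0) ||
      any(t0_grid > t_max))
    stop("closure grids must lie within [0, t_max]", call. = FALSE)
  final_V <- function(t0, tdist) {
    tdist_eff <- min(tdist, t_max - t0)
    sched <- if (tdist_eff > 0)
      list(parameter_schedule("mu", "closure_window", t_start = t0,
                              duration = tdist_eff))
    else list()
    traj <- simulate_fiber(params, t_max = t_max, schedules = sched, ...)
    c(V = traj$V[nrow(traj)], clipped = tdist_eff < tdist)
  }
  anchor_run <- final_V(anchor[1L], anchor[2L])
  m <- matrix(NA_real_, length(t0_grid), length(tdist_grid),
              dimnames = list(t0_h = format(t0_grid / 3600, trim = TRUE),
                              tdist_h = format(tdist_grid / 3600, trim = TRUE)))
  clipped <- m > 0
  for (i in seq_along(t0_grid)) {
    for (j in seq_along(tdist_grid)) {
      # the anchor cell reuses the anchor run, so it is exactly 1
      if (t0_grid[i] == anchor[1L] && tdist_grid[j] == anchor[2L]) {
        m[i, j] <- 1
        clipped[i, j] <- anchor_run["clipped"] > 0
      } else {
        r <- final_V(t0_grid[i], tdist_grid[j])
        m[i, j] <- r["V"] / anchor_run["V"]
        clipped[i, j] <- r["clipped"] > 0
      }
    }
  }
  attr(m, "anchor_volume") <- unname(anchor_run["V"])
  attr(m, "clipped") <- clipped
  m
}
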