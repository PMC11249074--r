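# Time-dependent parameter overlays. A schedule replaces one model parameter
# by a prescribed function of time; composing schedules with a base parameter
# set turns the constant-parameter model into the dynamic-parameter
# experiments (extensibility decay, plasmodesmata closure, solute pulse).

SCHEDULE_SHAPES <- c("constant", "linear_decay", "closure_window", "pulse")
SCHEDULABLE <- c("phi", "mu", "alpha")

#' Time-dependent parameter schedule
#'
#' Describes how one of the schedulable parameters (`phi`, `mu`, `alpha`)
#' varies in time. All times are in seconds.
#'
#' Shapes:
#' * `constant` — the base value at all times (identity overlay).
#' * `linear_decay` — the base value at `t = 0`, decreasing linearly to zero
#'   at `t_end_decay` and staying zero afterwards.
#' * `closure_window` — zero on the closed interval
#'   `[t_start, t_start + duration]`, the base value elsewhere (plasmodesmata
#'   closure).
#' * `pulse` — `high_value` on the closed interval, the base value elsewhere
#'   (transient solute-source rise).
#'
#' @param parameter One of `"phi"`, `"mu"`, `"alpha"`.
#' @param shape One of `"constant"`, `"linear_decay"`, `"closure_window"`,
#'   `"pulse"`.
#' @param t_start Window/pulse start (s).
#' @param duration Window/pulse length (s).
#' @param t_end_decay Time at which a linear decay reaches zero (s).
#' @param high_value Pulse plateau, in the parameter's own SI units.
#' @return An object of class `parameter_schedule`.
#' @export
#' @examples
#' # plasmodesmata closed between 200 h and 250 h
#' parameter_schedule("mu", "closure_window",
#'                    t_start = 200 * 3600, duration = 50 * 3600)
parameter_schedule <- function(parameter,
                               shape = c("constant", "linear_decay",
                                         "closure_window", "pulse"),
                               t_start = NA_real_, duration = NA_real_,
                               t_end_decay = NA_real_, high_value = NA_real_) {
  shape <- match.arg(shape)
  if (!parameter %in% SCHEDULABLE)
    stop("schedulable parameters are: ", paste(SCHEDULABLE, collapse = ", "),
         call. = FALSE)
  chk <- function(x, nm, positive = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x < 0 || (positive && x <= 0))
      stop("schedule field '", nm, "' must be a ",
           if (positive) "positive" else "non-negative", " number",
           call. = FALSE)
  }
  if (shape %in% c("closure_window", "pulse")) {
    chk(t_start, "t_start"); chk(duration, "duration")
  }
  if (shape == "pulse") chk(high_value, "high_value")
  if (shape == "linear_decay") chk(t_end_decay, "t_end_decay", positive = TRUE)
  structure(list(parameter = parameter, shape = shape, t_start = t_start,
                 duration = duration, t_end_decay = t_end_decay,
                 high_value = high_value),
            class = "parameter_schedule")
}

#' @export
print.parameter_schedule <- function(x, ...) {
  cat(sprintf("<parameter_schedule> %s: %s", x$parameter, x$shape))
  if (x$shape == "linear_decay")
    cat(sprintf(" (zero at %g h)", x$t_end_decay / 3600))
  if (x$shape %in% c("closure_window", "pulse"))
    cat(sprintf(" on [%g, %g] h", x$t_start / 3600,
                (x$t_start + x$duration) / 3600))
  cat("\n")
  invisible(x)
}

# scalar value of the scheduled parameter at time t, given its base value.
# Window membership is decided at `t_member` (defaults to t); the simulator
# passes the midpoint of the current integration segment so that membership
# is constant within a segment.
schedule_value <- function(schedule, base_value, t, t_member = t) {
  switch(schedule$shape,
    constant = base_value,
    linear_decay = base_value * max(0, 1 - t / schedule$t_end_decay),
    closure_window = if (t_member >= schedule$t_start &&
                         t_member <= schedule$t_start + schedule$duration)
      0 else base_value,
    pulse = if (t_member >= schedule$t_start &&
                t_member <= schedule$t_start + schedule$duration)
      schedule$high_value else base_value,
    stop("unknown schedule shape: ", schedule$shape, call. = FALSE)
  )
}

#' Evaluate schedules at a time point
#'
#' Returns a copy of the base parameters with each scheduled parameter
#' replaced by its value at time `t`. Window and pulse intervals are closed
#' on both ends.
#'
#' @param schedule A [parameter_schedule()] or a list of them (each targeting
#'   a distinct parameter).
#' @param base A [fiber_params()] object with the base (reference) values.
#' @param t Time (s), non-negative.
#' @return A `fiber_params` object.
#' @export
#' @examples
#' sc <- parameter_schedule("phi", "linear_decay", t_end_decay = 500 * 3600)
#' evaluate_schedule(sc, reference_parameters(), t = 250 * 3600)$phi
evaluate_schedule <- function(schedule, base, t) {
  stopifnot(inherits(base, "fiber_params"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("t must be a single non-negative time in seconds", call. = FALSE)
  schedules <- as_schedule_list(schedule)
  p <- unclass(base)
  for (sc in schedules)
    p[[sc$parameter]] <- schedule_value(sc, base[[sc$parameter]], t)
  structure(p, class = "fiber_params")
}

as_schedule_list <- function(x) {
  if (inherits(x, "parameter_schedule")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "parameter_schedule")))
    stop("expected a parameter_schedule or a list of them", call. = FALSE)
  tgt <- vapply(x, `[[`, "", "parameter")
  if (anyDuplicated(tgt))
    stop("each parameter may be scheduled at most once", call. = FALSE)
  x
}

# times at which a schedule's right-hand side is non-smooth; the integrator
# restarts at each of these
schedule_breakpoints <- function(schedule) {
  switch(schedule$shape,
    constant = numeric(0),
    linear_decay = schedule$t_end_decay,
    closure_window = ,
    pulse = c(schedule$t_start, schedule$t_start + schedule$duration)
  )
}
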