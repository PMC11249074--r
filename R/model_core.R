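# Core model algebra: piecewise turgor closure, fluxes, Lockhart growth law,
# and the right-hand side of the two-variable ODE system. All functions are
# pure and work in SI units.

# positive part
ppart <- function(x) pmax(x, 0)

# vectorized turgor-difference closure; V and pi_fiber may be vectors.
# Growth is irreversible, so dV/dt = phi*V*(dP + P_seed - Y)_+ ; substituting
# the water balance F_m + F_p = dV/dt and solving for dP gives two branches:
# below the yield surface the wall does not deform and the balance is purely
# hydraulic, above it the wall yields and the extensibility term enters the
# denominator. The two branches agree exactly on the switching surface.
.dP <- function(params, V, pi_fiber) {
  dpi <- pi_fiber - params$pi_seed
  denom0 <- 1 + params$mu / (params$Lr * V)
  no_growth <- dpi / denom0
  grow <- (dpi + (params$phi / params$Lr) * (params$Y - params$P_seed)) /
    (denom0 + params$phi / params$Lr)
  ifelse(no_growth < params$Y - params$P_seed, no_growth, grow)
}

#' Turgor pressure difference between fiber and seed
#'
#' Computes `dP = P_fiber - P_seed` from the algebraic elimination of fiber
#' turgor: the water balance (membrane flux + plasmodesmal flux = rate of
#' volume change) combined with the irreversible growth law yields a piecewise
#' closed form with a no-growth branch (fiber turgor at or below the yield
#' threshold) and a growth branch. Both branches agree exactly at the
#' switching surface, so `dP` is continuous in the state.
#'
#' @param params A [fiber_params()] object.
#' @param state A [fiber_state()] object.
#' @return The turgor difference (Pa), a single number.
#' @export
#' @examples
#' p <- reference_parameters()
#' delta_P(p, fiber_state(V = 1.88e-13, pi_fiber = p$pi_seed))
delta_P <- function(params, state) {
  stopifnot(inherits(params, "fiber_params"), inherits(state, "fiber_state"))
  if (params$Lr == 0)
    stop("Lr = 0: membrane conductivity must be positive for the turgor ",
         "closure to be defined", call. = FALSE)
  .dP(params, state$V, state$pi_fiber)
}

#' Water flux through the plasma membrane
#'
#' `F_m = Lr * V * (dpi - dP)`, positive when water enters the fiber. The
#' flux is proportional to volume because the lateral membrane area of the
#' elongating cylindrical cell scales with its volume.
#'
#' @inheritParams delta_P
#' @param dP Turgor difference (Pa) computed by [delta_P()] on the same
#'   `(params, state)`.
#' @return Membrane water flux (m^3 s^-1).
#' @export
flux_membrane <- function(params, state, dP = delta_P(params, state)) {
  params$Lr * state$V * ((state$pi_fiber - params$pi_seed) - dP)
}

#' Water flux through plasmodesmata
#'
#' `F_p = -mu * dP`: water moves through the symplastic channels down the
#' turgor gradient, into the fiber when seed turgor exceeds fiber turgor.
#'
#' @inheritParams delta_P
#' @param dP Turgor difference (Pa).
#' @return Plasmodesmal water flux (m^3 s^-1).
#' @export
flux_plasmodesmata <- function(params, dP) {
  -params$mu * dP
}

#' Relative growth rate (Lockhart law)
#'
#' `rgr = phi * (P_fiber - Y)_+` with `P_fiber = dP + P_seed`: irreversible
#' wall expansion proceeds at a rate proportional to turgor in excess of the
#' yield threshold, and is exactly zero at or below it.
#'
#' @inheritParams flux_plasmodesmata
#' @return Relative growth rate (s^-1), always non-negative.
#' @export
growth_rate <- function(params, dP) {
  params$phi * ppart(dP + params$P_seed - params$Y)
}

#' Derived quantities at a state
#'
#' Evaluates turgor difference, fiber turgor, both water fluxes, and the
#' relative growth rate at a given state. The water balance
#' `F_m + F_p = rgr * V` holds exactly (to rounding) by construction of the
#' turgor closure.
#'
#' @inheritParams delta_P
#' @return A list with components `dP`, `P_fiber` (Pa), `F_m`, `F_p`
#'   (m^3 s^-1), `rgr` (s^-1).
#' @export
derived_quantities <- function(params, state) {
  dP <- delta_P(params, state)
  list(
    dP = dP,
    P_fiber = dP + params$P_seed,
    F_m = flux_membrane(params, state, dP),
    F_p = flux_plasmodesmata(params, dP),
    rgr = growth_rate(params, dP)
  )
}

#' Right-hand side of the fiber ODE system
#'
#' Time derivatives of the two state variables. Volume grows per the Lockhart
#' law, `dV/dt = rgr * V` (identical to `F_m + F_p` by construction of the
#' turgor closure; the growth form is used to avoid double round-off).
#' Osmotic pressure changes through the solute source, dilution by growth,
#' and advective solute exchange through plasmodesmata, where the advected
#' concentration follows the flux direction: seed sap enters on inflow
#' (`dP < 0`), fiber sap leaves on outflow (`dP > 0`).
#'
#' @inheritParams delta_P
#' @return A list with `dV_dt` (m^3 s^-1) and `dpi_dt` (Pa s^-1).
#' @export
fiber_rhs <- function(params, state) {
  dP <- delta_P(params, state)
  rgr <- growth_rate(params, dP)
  V <- state$V
  pi_f <- state$pi_fiber
  dV_dt <- rgr * V
  dpi_dt <- params$alpha - pi_f * rgr +
    (params$mu * params$pi_seed / V) * ppart(-dP) -
    (params$mu * pi_f / V) * ppart(dP)
  list(dV_dt = dV_dt, dpi_dt = dpi_dt)
}

# rhs in the form used by the integrator: y = (log V, pi_fiber), with the
# parameter set possibly time-dependent through schedules. `window_time`
# decouples window-membership decisions from the evaluation time so that
# breakpoint-split segments see a constant window state (see simulate_fiber).
.rhs_ode <- function(t, y, ctx) {
  p <- ctx$params_at(t)
  V <- exp(y[1L])
  pi_f <- y[2L]
  dP <- .dP(p, V, pi_f)
  rgr <- p$phi * max(dP + p$P_seed - p$Y, 0)
  dpi <- p$alpha - pi_f * rgr +
    (p$mu * p$pi_seed / V) * max(-dP, 0) -
    (p$mu * pi_f / V) * max(dP, 0)
  list(c(rgr, dpi))
}
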