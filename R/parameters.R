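#' Model parameters for the fiber elongation model
#'
#' Bundles the seven physical parameters of the mechanohydraulic fiber model
#' in strict SI units. Human-facing unit conversion (hours, MPa, mm^3) happens
#' only at the I/O boundary (see [load_run_config()]).
#'
#' @param Lr Relative hydraulic conductivity of the plasma membrane
#'   (Pa^-1 s^-1). This is `2L/r` for a cylindrical cell of radius `r` with
#'   per-area membrane permeability `L`, so the membrane flux scales with
#'   cell volume.
#' @param mu Total plasmodesmal permeability (m^3 Pa^-1 s^-1). Zero means
#'   closed plasmodesmata.
#' @param alpha Normalized solute source rate (Pa s^-1): solute uptake and
#'   synthesis expressed directly as a rate of osmotic-pressure increase.
#' @param pi_seed Osmotic pressure of the seed proper (Pa).
#' @param P_seed Turgor pressure of the seed (Pa).
#' @param Y Yield turgor threshold (Pa): no irreversible wall expansion below
#'   this fiber turgor.
#' @param phi Cell wall extensibility (Pa^-1 s^-1): rate of irreversible
#'   relative expansion per unit turgor in excess of `Y`.
#'
#' @details All parameters must be non-negative; `mu`, `phi` and `alpha` may
#'   be exactly zero (closed plasmodesmata, rigid wall, no solute source).
#'   No ordering constraint between `pi_seed`, `P_seed` and `Y` is imposed.
#'
#' @return An object of class `fiber_params` (a named list).
#' @seealso [reference_parameters()] for the biological reference point.
#' @export
#' @examples
#' p <- fiber_params(Lr = 1.6e-7, mu = 6.7e-23, alpha = 118,
#'                   pi_seed = 1.13e6, P_seed = 1.1e5, Y = 1.1e5,
#'                   phi = 5.2e-12)
fiber_params <- function(Lr, mu, alpha, pi_seed, P_seed, Y, phi) {
  p <- list(Lr = Lr, mu = mu, alpha = alpha, pi_seed = pi_seed,
            P_seed = P_seed, Y = Y, phi = phi)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative, got ", v, call. = FALSE)
  }
  structure(p, class = "fiber_params")
}

#' @export
print.fiber_params <- function(x, ...) {
  cat("<fiber_params> (SI units)\n")
  for (nm in param_names())
    cat(sprintf("  %-8s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
as.list.fiber_params <- function(x, ...) unclass(x)

# canonical parameter order used throughout
param_names <- function() c("Lr", "mu", "alpha", "pi_seed", "P_seed", "Y", "phi")

#' Coerce a named vector or list to `fiber_params`
#'
#' @param x Named numeric vector or list with entries `Lr`, `mu`, `alpha`,
#'   `pi_seed`, `P_seed`, `Y`, `phi` (SI units).
#' @return A `fiber_params` object.
#' @export
as_fiber_params <- function(x) {
  if (inherits(x, "fiber_params")) return(x)
  x <- as.list(x)
  missing <- setdiff(param_names(), names(x))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  do.call(fiber_params, x[param_names()])
}

#' State of the fiber cell
#'
#' The two dynamical variables of the model: cell volume and fiber osmotic
#' pressure. Turgor pressure is not a state variable; it is recovered
#' algebraically from the flux balance (see [delta_P()]).
#'
#' @param V Fiber volume (m^3), strictly positive.
#' @param pi_fiber Fiber osmotic pressure (Pa), non-negative.
#' @return An object of class `fiber_state`.
#' @export
fiber_state <- function(V, pi_fiber) {
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V) || V <= 0)
    stop("V must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(pi_fiber) || length(pi_fiber) != 1L || !is.finite(pi_fiber) ||
      pi_fiber < 0)
    stop("pi_fiber must be a single finite number >= 0", call. = FALSE)
  structure(list(V = V, pi_fiber = pi_fiber), class = "fiber_state")
}

#' @export
print.fiber_state <- function(x, ...) {
  cat(sprintf("<fiber_state> V = %.6g m^3, pi_fiber = %.6g Pa\n",
              x$V, x$pi_fiber))
  invisible(x)
}

#' Biological parameter ranges and reference values
#'
#' Constructs the per-parameter table of biologically relevant ranges with
#' derived reference values. The reference value of each parameter is the
#' geometric mean of its range limits, and the relative deviations
#' `x_min/x_ref - 1` and `x_max/x_ref - 1` quantify how asymmetric the range
#' is around the reference (plasmodesmal permeability spans almost eight
#' orders of magnitude, so its upper relative deviation is in the thousands).
#'
#' @param ranges A data frame with columns `parameter`, `x_min`, `x_max`
#'   (SI units), one row per model parameter. Ranges must satisfy
#'   `0 < x_min <= x_max`.
#' @return A data frame of class `parameter_table` with columns `parameter`,
#'   `x_min`, `x_max`, `x_ref`, `rel_dev_lo`, `rel_dev_hi`.
#' @export
#' @examples
#' build_reference(data.frame(parameter = "phi", x_min = 1.1e-12,
#'                            x_max = 2.5e-11))
build_reference <- function(ranges) {
  ranges <- as.data.frame(ranges)
  need <- c("parameter", "x_min", "x_max")
  if (!all(need %in% names(ranges)))
    stop("ranges must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ranges$x_min)) || any(!is.finite(ranges$x_max)) ||
      any(ranges$x_min <= 0) || any(ranges$x_max < ranges$x_min))
    stop("ranges must satisfy 0 < x_min <= x_max", call. = FALSE)
  out <- data.frame(
    parameter = as.character(ranges$parameter),
    x_min = ranges$x_min,
    x_max = ranges$x_max,
    stringsAsFactors = FALSE
  )
  out$x_ref <- sqrt(out$x_min * out$x_max)
  out$rel_dev_lo <- out$x_min / out$x_ref - 1
  out$rel_dev_hi <- out$x_max / out$x_ref - 1
  class(out) <- c("parameter_table", "data.frame")
  out
}

#' Packaged biological parameter table
#'
#' Loads the packaged ranges of the seven model parameters (literature-derived
#' biologically relevant limits, SI units) and derives reference values via
#' [build_reference()].
#'
#' @return A `parameter_table` data frame with one row per parameter.
#' @export
default_parameter_table <- function() {
  path <- system.file("extdata", "parameter_ranges.csv", package = "fibersim",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- build_reference(tab[, c("parameter", "x_min", "x_max")])
  out$unit <- tab$unit
  out$description <- tab$description
  out
}

#' Reference model parameters
#'
#' The reference parameter point: geometric means of the biological ranges.
#'
#' @param table A `parameter_table`; defaults to the packaged one.
#' @return A `fiber_params` object.
#' @export
reference_parameters <- function(table = default_parameter_table()) {
  x <- stats::setNames(table$x_ref, table$parameter)
  as_fiber_params(x)
}

# default initial volume (m^3): 1.88e-4 mm^3
default_V0 <- function() 1.88e-13
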