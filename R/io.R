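# Configuration, unit conversion, fixture generation, and the experiment
# entry points. Human-facing files use hours / MPa / mm^3; everything inside
# the package is strict SI. Conversion constants are exact.

HOUR <- 3600          # s per h
MPA <- 1e6            # Pa per MPa
MM3 <- 1e-9           # m^3 per mm^3

# accepted unit strings per quantity kind, with factors to SI
UNIT_FACTORS <- list(
  time = c(s = 1, h = HOUR),
  volume = c(m3 = 1, mm3 = MM3),
  pressure = c(Pa = 1, MPa = MPA),
  Lr = c(`Pa-1.s-1` = 1),
  mu = c(`m3.Pa-1.s-1` = 1),
  alpha = c(`Pa.s-1` = 1, `Pa/s` = 1, `MPa/h` = MPA / HOUR),
  pi_seed = c(Pa = 1, MPa = MPA),
  P_seed = c(Pa = 1, MPa = MPA),
  Y = c(Pa = 1, MPa = MPA),
  phi = c(`Pa-1.s-1` = 1)
)

# convert a {value, unit} block to SI; bare numbers are rejected so that a
# config can never silently mix scales
convert_quantity <- function(q, kind, key) {
  if (!is.list(q) || is.null(q$value) || is.null(q$unit))
    stop("config entry '", key, "' must be a {value, unit} block",
         call. = FALSE)
  factors <- UNIT_FACTORS[[kind]]
  if (is.null(factors) || !q$unit %in% names(factors))
    stop("config entry '", key, "': unknown unit '", q$unit,
         "' (accepted: ", paste(names(UNIT_FACTORS[[kind]]), collapse = ", "),
         ")", call. = FALSE)
  as.numeric(q$value) * factors[[q$unit]]
}

#' Load a run configuration file
#'
#' Reads a YAML or JSON run configuration, converts every quantity to SI,
#' and fills unspecified parameters from the packaged biological reference
#' table. Every physical quantity in the file must be a `{value, unit}`
#' block; bare numbers are rejected. Parameter values falling outside ten
#' times the packaged biological range are rejected as likely unit mistakes.
#'
#' Recognized top-level keys: `experiment`, `seed`, `parameters` (named
#' blocks for any of the seven model parameters), `initial` (`V0`, `pi0`),
#' `t_max`, `output_grid`, `rel_tol`, `abs_tol`, `schedules` (list of
#' `{parameter, shape, t_start, duration, t_end_decay, high_value}` with
#' times as `{value, unit}` blocks).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `run_config` with elements `experiment`, `seed`,
#'   `params` ([fiber_params()]), `V0`, `pi0`, `t_max`, `output_grid`,
#'   `rel_tol`, `abs_tol`, `schedules`, and `defaults_used` (names of
#'   parameters taken from the packaged table).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else stop("config must be .yaml, .yml or .json", call. = FALSE)

  known <- c("experiment", "seed", "parameters", "initial", "t_max",
             "output_grid", "rel_tol", "abs_tol", "schedules")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  table <- default_parameter_table()
  p <- stats::setNames(as.list(table$x_ref), table$parameter)
  defaults_used <- table$parameter
  for (nm in names(raw$parameters)) {
    if (!nm %in% table$parameter)
      stop("unknown parameter in config: ", nm, call. = FALSE)
    v <- convert_quantity(raw$parameters[[nm]], nm, paste0("parameters.", nm))
    row <- table[table$parameter == nm, ]
    if (v > 0 && (v < row$x_min / 10 || v > row$x_max * 10))
      stop("parameters.", nm, " = ", v, " is outside 10x the biological ",
           "range [", row$x_min, ", ", row$x_max, "]; check units",
           call. = FALSE)
    p[[nm]] <- v
    defaults_used <- setdiff(defaults_used, nm)
  }

  V0 <- if (!is.null(raw$initial$V0))
    convert_quantity(raw$initial$V0, "volume", "initial.V0") else default_V0()
  pi0 <- if (!is.null(raw$initial$pi0))
    convert_quantity(raw$initial$pi0, "pressure", "initial.pi0") else p$pi_seed
  t_max <- if (!is.null(raw$t_max))
    convert_quantity(raw$t_max, "time", "t_max") else 500 * HOUR

  schedules <- lapply(raw$schedules, function(sc) {
    get_t <- function(field) {
      if (is.null(sc[[field]])) NA_real_
      else convert_quantity(sc[[field]], "time", paste0("schedules.", field))
    }
    high <- if (is.null(sc$high_value)) NA_real_
      else convert_quantity(sc$high_value, sc$parameter, "schedules.high_value")
    parameter_schedule(sc$parameter, sc$shape,
                       t_start = get_t("t_start"),
                       duration = get_t("duration"),
                       t_end_decay = get_t("t_end_decay"),
                       high_value = high)
  })

  structure(
    list(experiment = raw$experiment %||% NA_character_,
         seed = raw$seed %||% 1L,
         params = as_fiber_params(p),
         V0 = V0, pi0 = pi0, t_max = t_max,
         output_grid = raw$output_grid %||% 2001,
         rel_tol = raw$rel_tol %||% 1e-10,
         abs_tol = raw$abs_tol %||% c(1e-12, 1e-4),
         schedules = schedules,
         defaults_used = defaults_used),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory as CSV in human units
#'
#' Columns: `t_h`, `V_mm3`, `pi_fiber_MPa`, `P_fiber_MPa`, `dP_MPa`,
#' `F_m_mm3_per_h`, `F_p_mm3_per_h`, `rgr_per_h`.
#'
#' @param traj A `fiber_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  out <- data.frame(
    t_h = traj$t / HOUR,
    V_mm3 = traj$V / MM3,
    pi_fiber_MPa = traj$pi_fiber / MPA,
    P_fiber_MPa = traj$P_fiber / MPA,
    dP_MPa = traj$dP / MPA,
    F_m_mm3_per_h = traj$F_m / MM3 * HOUR,
    F_p_mm3_per_h = traj$F_p / MM3 * HOUR,
    rgr_per_h = traj$rgr * HOUR
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' Converts the human-unit columns back to SI and restores the
#' `fiber_trajectory` class, so detectors and classifiers can run on saved
#' trajectories.
#'
#' @param path CSV file path.
#' @return A `fiber_trajectory` data frame.
#' @export
read_trajectory_csv <- function(path) {
  raw <- utils::read.csv(path)
  need <- c("t_h", "V_mm3", "pi_fiber_MPa", "P_fiber_MPa", "dP_MPa",
            "F_m_mm3_per_h", "F_p_mm3_per_h", "rgr_per_h")
  if (!all(need %in% names(raw)))
    stop("not a trajectory CSV (missing: ",
         paste(setdiff(need, names(raw)), collapse = ", "), ")",
         call. = FALSE)
  traj <- data.frame(
    t = raw$t_h * HOUR,
    V = raw$V_mm3 * MM3,
    pi_fiber = raw$pi_fiber_MPa * MPA,
    dP = raw$dP_MPa * MPA,
    P_fiber = raw$P_fiber_MPa * MPA,
    F_m = raw$F_m_mm3_per_h * MM3 / HOUR,
    F_p = raw$F_p_mm3_per_h * MM3 / HOUR,
    rgr = raw$rgr_per_h / HOUR
  )
  class(traj) <- c("fiber_trajectory", "data.frame")
  traj
}

#' Random parameter sets from the biological ranges
#'
#' Draws `n` parameter sets, each coordinate log-uniform and independent over
#' its biological range. Log-uniform sampling matches the geometry of the
#' ranges (several span multiple decades, and the reference point is the
#' geometric mean, i.e. the log-midpoint). Used for property checks over
#' biologically plausible parameter space.
#'
#' @param seed Integer seed; draws are reproducible.
#' @param n Number of parameter sets (>= 1).
#' @param table A `parameter_table`.
#' @return A data frame with `n` rows and one column per parameter (SI
#'   units); rows convert to [fiber_params()] via [as_fiber_params()].
#' @export
#' @examples
#' draws <- generate_fixture(seed = 1, n = 3)
#' as_fiber_params(draws[1, ])
generate_fixture <- function(seed, n, table = default_parameter_table()) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  cols <- lapply(seq_len(nrow(table)), function(i)
    exp(stats::runif(n, log(table$x_min[i]), log(table$x_max[i]))))
  out <- as.data.frame(stats::setNames(cols, table$parameter))
  out
}

#' Run a named experiment and write its outputs
#'
#' Orchestrates the standard experiments end to end and writes their outputs
#' (CSV tables and trajectories, JSON summaries) into `out_dir`:
#'
#' * `figure2` — reference trajectory (volume, pressures, fluxes vs. time).
#' * `table2` — one-factor-at-a-time sensitivities, wide (3 observables x
#'   7 parameters) and tidy CSV.
#' * `figure3` — maximal change over the biological ranges, tidy CSV.
#' * `figure4a`, `figure4d`, `figure4f`, `alpha_pulse` — dynamic-parameter
#'   scenarios (extensibility decay, plasmodesmata closure, both combined,
#'   solute pulse): trajectory CSV plus JSON verdict with behavior labels.
#' * `figure4e` — closure-timing sweep, long CSV
#'   (`t0_h, tdist_h, normalized_final_volume`).
#'
#' @param name Experiment name.
#' @param out_dir Output directory (created if needed).
#' @param config Optional `run_config` from [load_run_config()]; defaults to
#'   the packaged reference setup.
#' @param seed Seed recorded in summaries (the experiments themselves are
#'   deterministic).
#' @param quick If `TRUE`, use coarser grids (for smoke tests).
#' @return Character vector of the files written, invisibly.
#' @export
run_experiment <- function(name = c("figure2", "table2", "figure3",
                                    "figure4a", "figure4d", "figure4e",
                                    "figure4f", "alpha_pulse"),
                           out_dir = ".", config = NULL, seed = 1L,
                           quick = FALSE) {
  name <- match.arg(name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- if (is.null(config)) reference_parameters() else config$params
  files <- character(0)
  emit <- function(fn) files <<- c(files, file.path(out_dir, fn))

  if (name == "figure2") {
    traj <- simulate_fiber(params,
                           V0 = config$V0 %||% default_V0(),
                           pi0 = config$pi0 %||% params$pi_seed,
                           t_max = config$t_max %||% (500 * HOUR),
                           output_grid = if (quick) 201 else 2001)
    write_trajectory_csv(traj, file.path(out_dir, "figure2_trajectory.csv"))
    emit("figure2_trajectory.csv")
  } else if (name == "table2") {
    tab <- oat_sensitivity_table(output_grid = if (quick) 101 else 201)
    utils::write.csv(tab, file.path(out_dir, "table2_tidy.csv"),
                     row.names = FALSE, quote = FALSE)
    wide <- stats::reshape(tab[, c("observable", "parameter", "S")],
                           idvar = "observable", timevar = "parameter",
                           direction = "wide")
    names(wide) <- sub("^S\\.", "", names(wide))
    utils::write.csv(wide, file.path(out_dir, "table2_wide.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("table2_tidy.csv"); emit("table2_wide.csv")
  } else if (name == "figure3") {
    tab <- maximal_change_table(n_grid = if (quick) 9 else 33)
    utils::write.csv(tab, file.path(out_dir, "figure3_maximal_change.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("figure3_maximal_change.csv")
  } else if (name == "figure4e") {
    by <- if (quick) 250 else 50
    m <- closure_sweep(t0_grid = seq(0, 500, by = by) * HOUR,
                       tdist_grid = seq(0, 500, by = by) * HOUR,
                       params = params,
                       output_grid = if (quick) 301 else 1001)
    long <- data.frame(
      t0_h = rep(as.numeric(rownames(m)), times = ncol(m)),
      tdist_h = rep(as.numeric(colnames(m)), each = nrow(m)),
      normalized_final_volume = as.vector(m)
    )
    utils::write.csv(long, file.path(out_dir, "figure4e_closure_sweep.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("figure4e_closure_sweep.csv")
  } else {
    scen <- switch(name, figure4a = "phi_decay", figure4d = "mu_closure",
                   figure4f = "combined", alpha_pulse = "alpha_pulse")
    res <- run_scenario(scen, params = params,
                        output_grid = if (quick) 501 else 2001)
    write_trajectory_csv(res$trajectory,
                         file.path(out_dir, paste0(name, "_trajectory.csv")))
    verdict <- list(
      scenario = scen, seed = seed,
      final_volume_ratio = res$final_volume_ratio,
      labels = res$labels
    )
    jsonlite::write_json(verdict,
                         file.path(out_dir, paste0(name, "_verdict.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    emit(paste0(name, "_trajectory.csv"))
    emit(paste0(name, "_verdict.json"))
  }
  invisible(files)
}
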