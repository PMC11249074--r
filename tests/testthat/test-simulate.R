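HOUR <- 3600

test_that("frozen system stays exactly at its initial state", {
  p <- fiber_params(Lr = ref_params$Lr, mu = 0, alpha = 0,
                    pi_seed = ref_params$pi_seed, P_seed = ref_params$P_seed,
                    Y = ref_params$Y, phi = 0)
  traj <- simulate_fiber(p, pi0 = 1.5e6, output_grid = 101)
  expect_equal(traj$V, rep(traj$V[1], 101))
  expect_equal(traj$pi_fiber, rep(1.5e6, 101), tolerance = 1e-12)
  expect_equal(detect_steady_state(traj), 0)
})

test_that("trajectory satisfies its structural invariants", {
  traj <- simulate_fiber(ref_params, output_grid = 401)
  expect_true(all(diff(traj$t) > 0))
  expect_true(all(traj$V > 0))
  expect_true(all(diff(traj$V) >= 0))  # growth is irreversible
  expect_equal(traj$t[1], 0)
  expect_equal(traj$t[nrow(traj)], 500 * HOUR)
  # stored derived columns equal fresh model-core evaluations
  i <- c(1, 100, 250, 401)
  for (k in i) {
    dq <- derived_quantities(ref_params,
                             fiber_state(traj$V[k], traj$pi_fiber[k]))
    expect_equal(traj$dP[k], dq$dP)
    expect_equal(traj$F_m[k], dq$F_m)
    expect_equal(traj$rgr[k], dq$rgr)
  }
})

test_that("water is conserved along the trajectory", {
  traj <- simulate_fiber(ref_params, output_grid = 2001)
  flux <- traj$F_m + traj$F_p
  gained <- sum(diff(traj$t) * (head(flux, -1) + tail(flux, -1)) / 2)
  expect_equal(gained, traj$V[nrow(traj)] - traj$V[1], tolerance = 1e-3)
})

test_that("solution is converged with respect to solver tolerance", {
  # halving the tolerances from their defaults moves the final volume by
  # less than 1e-6 relative
  V_end <- function(f) {
    traj <- simulate_fiber(ref_params, output_grid = 101,
                           rel_tol = 1e-10 * f,
                           abs_tol = c(1e-12, 1e-4) * f)
    traj$V[nrow(traj)]
  }
  expect_equal(V_end(1), V_end(0.5), tolerance = 1e-6)
})

test_that("closed plasmodesmata recover the classical Lockhart steady state", {
  p <- as_fiber_params(modifyList(as.list(ref_params), list(mu = 0)))
  # independent oracle: at steady state the source balances dilution,
  # alpha = pi * phi * (dP(pi) + P_seed - Y), with dP from the growth branch
  balance <- function(pi_f) {
    dP <- (pi_f - p$pi_seed + (p$phi / p$Lr) * (p$Y - p$P_seed)) /
      (1 + p$phi / p$Lr)
    p$alpha - pi_f * p$phi * (dP + p$P_seed - p$Y)
  }
  pi_inf <- stats::uniroot(balance, c(p$pi_seed, 1e8), tol = 1e-10)$root
  dP_inf <- ((pi_inf - p$pi_seed) + (p$phi / p$Lr) * (p$Y - p$P_seed)) /
    (1 + p$phi / p$Lr)
  traj <- simulate_fiber(p, t_max = 3000 * HOUR, output_grid = 501)
  n <- nrow(traj)
  expect_equal(traj$pi_fiber[n], pi_inf, tolerance = 1e-4)
  expect_equal(traj$dP[n], dP_inf, tolerance = 1e-4)
  expect_equal(traj$rgr[n], p$alpha / pi_inf, tolerance = 1e-4)
})

test_that("reference run: monotonic pressures, settling growth rate", {
  traj <- simulate_fiber(ref_params, output_grid = 2001)
  expect_identical(nrow(extract_extrema(traj, "pi_fiber")), 0L)
  expect_identical(nrow(extract_extrema(traj, "P_fiber")), 0L)
  # growth rate becomes constant once the pressures level off
  n <- nrow(traj)
  late <- traj$rgr[traj$t > 450 * HOUR]
  expect_lt(max(late) / min(late) - 1, 0.01)
  # doubling the solute source gives a strictly larger final volume
  p2 <- as_fiber_params(modifyList(as.list(ref_params),
                                   list(alpha = 2 * ref_params$alpha)))
  traj2 <- simulate_fiber(p2, output_grid = 101)
  expect_gt(traj2$V[101], traj$V[n])
})

test_that("integration restarts exactly at schedule breakpoints", {
  sched <- list(parameter_schedule("mu", "closure_window",
                                   t_start = 200 * HOUR,
                                   duration = 50 * HOUR))
  traj <- simulate_fiber(ref_params, schedules = sched, output_grid = 301)
  expect_true(all(c(200 * HOUR, 250 * HOUR) %in% traj$t))
})

test_that("solute pulse delays the steady state past the pulse window", {
  res <- run_scenario("alpha_pulse", output_grid = 1001)
  t_ss <- detect_steady_state(res$trajectory)
  expect_gt(t_ss, 250 * HOUR)
})

test_that("extremum detector flags shapes and ignores monotone series", {
  t <- seq(0, 500 * HOUR, length.out = 201)
  up <- synthetic_trajectory(t, P_fiber = seq(1e5, 5e5, length.out = 201))
  expect_identical(nrow(extract_extrema(up, "P_fiber")), 0L)
  bump <- 2e5 + 1e5 * exp(-((t - 250 * HOUR) / (40 * HOUR))^2)
  peaky <- synthetic_trajectory(t, P_fiber = bump)
  ex <- extract_extrema(peaky, "P_fiber")
  expect_identical(ex$kind, "max")
  expect_equal(ex$t, 250 * HOUR, tolerance = 0.01)
  flat <- synthetic_trajectory(t, P_fiber = rep(2e5, 201))
  expect_identical(nrow(extract_extrema(flat, "P_fiber")), 0L)
})

test_that("simulator rejects invalid configurations", {
  expect_error(simulate_fiber(ref_params, V0 = -1), "V0")
  expect_error(simulate_fiber(ref_params, t_max = 0), "t_max")
  expect_error(simulate_fiber(ref_params, rel_tol = 0), "tolerances")
  expect_error(simulate_fiber(ref_params, output_grid = 1), "output_grid")
})
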