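# Shared fixtures and independent oracles for the test suite.

ref_table <- default_parameter_table()
ref_params <- reference_parameters(ref_table)

# printed one-factor-at-a-time sensitivities (3 observables x 7 parameters)
printed_sensitivities <- rbind(
  log_volume_ratio = c(Lr = 2.00e-4, mu = -8.37e-1, alpha = 1.35,
                       pi_seed = -6.80e-1, P_seed = 2.79e-1, Y = -2.74e-1,
                       phi = 1.51),
  pi_final = c(Lr = -1.16e-5, mu = -5.30e-6, alpha = 4.41e-1,
               pi_seed = 1.19e-1, P_seed = -1.18e-2, Y = 1.16e-2,
               phi = -4.42e-1),
  P_final = c(Lr = 1.48e-5, mu = -6.16e-6, alpha = 5.46e-1,
              pi_seed = -1.16e-1, P_seed = 1.15e-2, Y = 1.44e-2,
              phi = -5.47e-1)
)

# independent oracle for the turgor closure: bracketing root of the flux
# balance  Lr V (dpi - dP) - mu dP = phi V (dP + P_seed - Y)_+ , whose left
# minus right side is continuous and strictly decreasing in dP, so the root
# is unique. Never uses the closed form under test.
oracle_dP <- function(params, V, pi_fiber) {
  f <- function(dP)
    params$Lr * V * ((pi_fiber - params$pi_seed) - dP) - params$mu * dP -
      params$phi * V * max(dP + params$P_seed - params$Y, 0)
  stats::uniroot(f, c(-1e9, 1e9), tol = 1e-14)$root
}

# random valid model state (volume within a few decades of the initial
# volume, osmotic pressure up to a few MPa)
random_state <- function() {
  list(V = exp(stats::runif(1, log(1e-14), log(1e-9))),
       pi_fiber = stats::runif(1, 0, 5e6))
}

# synthetic trajectory from a bare time/value series, for detector tests
synthetic_trajectory <- function(t, pi_fiber = NULL, P_fiber = NULL,
                                 V = NULL) {
  n <- length(t)
  traj <- data.frame(
    t = t,
    V = if (is.null(V)) rep(1e-13, n) else V,
    pi_fiber = if (is.null(pi_fiber)) rep(1e6, n) else pi_fiber,
    dP = rep(0, n),
    P_fiber = if (is.null(P_fiber)) rep(1e5, n) else P_fiber,
    F_m = rep(0, n), F_p = rep(0, n), rgr = rep(0, n)
  )
  class(traj) <- c("fiber_trajectory", "data.frame")
  traj
}
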