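test_that("parameter and state constructors enforce their invariants", {
  expect_error(fiber_params(Lr = -1e-7, mu = 0, alpha = 0, pi_seed = 1e6,
                            P_seed = 1e5, Y = 1e5, phi = 0),
               "non-negative")
  expect_error(fiber_state(V = 0, pi_fiber = 1e6), "V must be")
  expect_error(fiber_state(V = 1e-13, pi_fiber = -1), "pi_fiber")
  # mu, phi, alpha may be exactly zero
  expect_s3_class(fiber_params(Lr = 1e-7, mu = 0, alpha = 0, pi_seed = 1e6,
                               P_seed = 1e5, Y = 1e5, phi = 0),
                  "fiber_params")
  expect_error(as_fiber_params(c(Lr = 1e-7)), "missing parameters")
})

test_that("turgor closure reduces to the classical limits", {
  # closed plasmodesmata, below yield: dP equals the osmotic difference
  p <- fiber_params(Lr = 1e-7, mu = 0, alpha = 100, pi_seed = 1.1e6,
                    P_seed = 1e5, Y = 2e5, phi = 5e-12)
  dpi <- 0.5 * (p$Y - p$P_seed)
  st <- fiber_state(V = 1e-13, pi_fiber = p$pi_seed + dpi)
  expect_equal(delta_P(p, st), dpi)
  expect_equal(growth_rate(p, delta_P(p, st)), 0)

  # rigid wall (phi = 0): both branches coincide for any osmotic difference
  p0 <- fiber_params(Lr = 1e-7, mu = 5e-23, alpha = 100, pi_seed = 1.1e6,
                     P_seed = 1e5, Y = 1e5, phi = 0)
  for (pif in c(0, 5e5, 1.1e6, 4e6)) {
    st <- fiber_state(V = 1e-13, pi_fiber = pif)
    expect_equal(delta_P(p0, st),
                 (pif - p0$pi_seed) / (1 + p0$mu / (p0$Lr * st$V)))
  }

  # zero membrane conductivity is an unphysical configuration
  pz <- fiber_params(Lr = 0, mu = 0, alpha = 0, pi_seed = 1e6, P_seed = 1e5,
                     Y = 1e5, phi = 0)
  expect_error(delta_P(pz, fiber_state(1e-13, 1e6)), "Lr = 0")
})

test_that("fluxes and growth law obey their unit arithmetic and signs", {
  p <- fiber_params(Lr = 1e-7, mu = 6.67e-23, alpha = 100, pi_seed = 1e6,
                    P_seed = 1e5, Y = 1e5, phi = 5.3e-12)
  # membrane flux: Lr V (dpi - dP), zero at equilibrium
  st <- fiber_state(V = 1e-13, pi_fiber = p$pi_seed + 2e6)
  expect_equal(flux_membrane(p, st, dP = 2e6), 0)
  expect_equal(flux_membrane(p, st, dP = 1e6), 1e-14)  # Lr V * 1e6
  # plasmodesmal flux: -mu dP
  expect_equal(flux_plasmodesmata(p, dP = 1e5), -6.67e-18)
  expect_equal(flux_plasmodesmata(p, dP = 0), 0)
  p_closed <- fiber_params(Lr = 1e-7, mu = 0, alpha = 100, pi_seed = 1e6,
                           P_seed = 1e5, Y = 1e5, phi = 5.3e-12)
  expect_equal(flux_plasmodesmata(p_closed, dP = 3e6), 0)
  # Lockhart law: positive part, exactly zero at and below the threshold
  expect_equal(growth_rate(p, dP = p$Y - p$P_seed), 0)       # P_fiber = Y
  expect_equal(growth_rate(p, dP = p$Y - p$P_seed - 1e4), 0) # P_fiber < Y
  expect_equal(growth_rate(p, dP = p$Y - p$P_seed + 1e5), 5.3e-7)
})

test_that("closed form of the turgor closure matches the flux-balance root", {
  # at the reference point with the fiber iso-osmotic with the seed
  st <- fiber_state(V = 1.88e-13, pi_fiber = ref_params$pi_seed)
  expect_equal(delta_P(ref_params, st),
               oracle_dP(ref_params, st$V, st$pi_fiber), tolerance = 1e-12)
  # and across random parameter/state draws
  draws <- generate_fixture(seed = 101, n = 200)
  set.seed(101)
  for (i in seq_len(nrow(draws))) {
    p <- as_fiber_params(draws[i, ])
    s <- random_state()
    got <- delta_P(p, fiber_state(s$V, s$pi_fiber))
    want <- oracle_dP(p, s$V, s$pi_fiber)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("turgor closure is continuous across the switching surface", {
  # tune pi_fiber so the no-growth branch value sits exactly on the surface
  p <- fiber_params(Lr = 1e-7, mu = 5e-23, alpha = 100, pi_seed = 1e6,
                    P_seed = 1e5, Y = 3e5, phi = 5e-12)
  V <- 1.88e-13
  dpi_star <- (p$Y - p$P_seed) * (1 + p$mu / (p$Lr * V))
  no_growth <- function(dpi) dpi / (1 + p$mu / (p$Lr * V))
  growth <- function(dpi)
    (dpi + (p$phi / p$Lr) * (p$Y - p$P_seed)) /
      (1 + p$mu / (p$Lr * V) + p$phi / p$Lr)
  expect_equal(no_growth(dpi_star), growth(dpi_star), tolerance = 1e-12)
  # delta_P approaches the same value from both sides
  eps <- 1e-6 * abs(dpi_star)
  lo <- delta_P(p, fiber_state(V, p$pi_seed + dpi_star - eps))
  hi <- delta_P(p, fiber_state(V, p$pi_seed + dpi_star + eps))
  expect_equal(lo, hi, tolerance = 1e-5)
})

test_that("water balance holds exactly and rhs is internally consistent", {
  draws <- generate_fixture(seed = 202, n = 200)
  set.seed(202)
  for (i in seq_len(nrow(draws))) {
    p <- as_fiber_params(draws[i, ])
    s <- random_state()
    st <- fiber_state(s$V, s$pi_fiber)
    dq <- derived_quantities(p, st)
    # condition the residual on the magnitudes entering the balance before
    # cancellation (dpi - dP may cancel almost completely)
    dpi <- st$pi_fiber - p$pi_seed
    scale <- max(p$Lr * st$V * (abs(dpi) + abs(dq$dP)),
                 p$mu * abs(dq$dP), abs(dq$rgr * st$V), 1e-300)
    expect_lt(abs(dq$rgr * st$V - (dq$F_m + dq$F_p)) / scale, 1e-12)
    expect_gte(dq$rgr, 0)
  }
  # dV/dt from the growth law equals the flux sum at the reference state
  st <- fiber_state(1.88e-13, ref_params$pi_seed)
  rhs <- fiber_rhs(ref_params, st)
  dq <- derived_quantities(ref_params, st)
  expect_equal(rhs$dV_dt, dq$F_m + dq$F_p,
               tolerance = 10 * .Machine$double.eps)
})

test_that("rhs limiting cases: equilibrium, closed channels, source shift", {
  # full equilibrium: no source, iso-osmotic, rigid wall at/below yield
  p <- fiber_params(Lr = 1e-7, mu = 5e-23, alpha = 0, pi_seed = 1e6,
                    P_seed = 1e5, Y = 2e5, phi = 5e-12)
  st <- fiber_state(1e-13, p$pi_seed)
  rhs <- fiber_rhs(p, st)
  expect_equal(rhs$dV_dt, 0)
  expect_equal(rhs$dpi_dt, 0)

  # closed plasmodesmata: solute balance is source minus dilution only
  p2 <- fiber_params(Lr = 1e-7, mu = 0, alpha = 120, pi_seed = 1e6,
                     P_seed = 1e5, Y = 1.1e5, phi = 5e-12)
  st2 <- fiber_state(1e-13, 3e6)
  rhs2 <- fiber_rhs(p2, st2)
  expect_equal(rhs2$dpi_dt,
               p2$alpha - st2$pi_fiber / st2$V * rhs2$dV_dt)

  # raising alpha raises dpi/dt by exactly the increment
  p3 <- as_fiber_params(modifyList(as.list(p2), list(alpha = 150)))
  expect_equal(fiber_rhs(p3, st2)$dpi_dt - rhs2$dpi_dt, 30)
})

test_that("opening plasmodesmata weakly drains a pressurized fiber", {
  # with fiber turgor above seed turgor (dP > 0), increasing mu reduces the
  # net water influx at fixed state
  st <- fiber_state(1.88e-13, 3e6)
  mus <- c(0, 1e-24, 1e-22, 1e-20)
  influx <- vapply(mus, function(m) {
    p <- as_fiber_params(modifyList(as.list(ref_params), list(mu = m)))
    dq <- derived_quantities(p, st)
    expect_gt(dq$dP, 0)
    dq$F_m + dq$F_p
  }, 0)
  expect_true(all(diff(influx) <= 0))
})
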