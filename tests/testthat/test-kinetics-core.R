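test_that("simplified scheme reproduces two-state binding and conserves mass", {
  r <- rate_constants(k1P = 1e7, k_neg1P = 1e-2, identical_species = TRUE)
  tot <- reaction_totals(1e-7, 5e-9, 0)
  tc <- simulate_scheme(r, tot, c(0, 10^(0:4)))
  expect_lt(conservation_error(tc), 1e-8)

  EP_cf <- two_state_complex(1e-7, 5e-9, 1e-9)
  expect_equal(tail(bound_ligand(tc), 1) / 5e-9, EP_cf / 5e-9,
               tolerance = 1e-6)

  # conservation holds across schemes and parameter draws
  set.seed(11)
  for (i in 1:3) {
    r2 <- rate_constants(k1P = 10^runif(1, 5, 7), k_neg1P = 10^runif(1, -3, -1),
                         k1D = 10^runif(1, 5, 7), k_neg1D = 10^runif(1, -3, -1),
                         k_thetaD = 10^runif(1, 2, 4))
    tot2 <- reaction_totals(1e-7, 5e-9, 10^runif(1, -7, -5))
    tc2 <- simulate_scheme(r2, tot2, c(0, 10, 100, 1000))
    expect_lt(conservation_error(tc2), 1e-8)
    tcc <- simulate_scheme(r2, tot2, c(0, 1, 10), variant = "complete")
    expect_lt(conservation_error(tcc), 1e-8)
  }
})

test_that("equilibrium_state matches the ODE long-time limit", {
  set.seed(21)
  for (i in 1:3) {
    r <- rate_constants(k1P = 10^runif(1, 5, 7), k_neg1P = 10^runif(1, -3, -2),
                        k1D = 10^runif(1, 5, 7), k_neg1D = 10^runif(1, -3, -2),
                        k_thetaD = 10^runif(1, 2, 3.5))
    tot <- reaction_totals(1e-7, 5e-9, 10^runif(1, -7, -6))
    eq <- equilibrium_state(r, tot)
    tc <- simulate_scheme(r, tot, c(0, 10^(2:6)))
    final <- tc$states[nrow(tc$states), ]
    expect_equal(unname(eq[c("EP", "ED")]) / tot$P_total,
                 unname(final[c("EP", "ED")]) / tot$P_total,
                 tolerance = 1e-6)
  }

  # transfer constants that break detailed balance shift the stationary
  # state; the root-finder must still agree with the ODE
  r_inc <- rate_constants(k1P = 1e6, k_neg1P = 1e-2, k1D = 5e5,
                          k_neg1D = 2e-2, k_thetaD = 2000, k_thetaP = 100,
                          consistency = "none")
  tot <- reaction_totals(1e-7, 5e-9, 5e-7)
  eq <- equilibrium_state(r_inc, tot)
  tc <- simulate_scheme(r_inc, tot, c(0, 10^(2:6)))
  expect_equal(eq[["EP"]], tail(bound_ligand(tc), 1), tolerance = 1e-6)
})

test_that("equilibrium has the excess-protein limit and competitive symmetry", {
  r <- rate_constants(k1P = 1e6, k_neg1P = 1e-2, identical_species = TRUE)
  Kd <- 1e-8
  eq <- equilibrium_state(r, reaction_totals(1e-5, 1e-12, 0))
  expect_equal(eq[["EP"]] / 1e-12, 1e-5 / (1e-5 + Kd), tolerance = 1e-4)

  # equal K_d, equal trace totals: the two complexes are interchangeable
  eq2 <- equilibrium_state(r, reaction_totals(5e-8, 2e-9, 2e-9))
  expect_equal(eq2[["EP"]], eq2[["ED"]], tolerance = 1e-9)
})

test_that("thermodynamically consistent transfer leaves equilibria unchanged", {
  tot <- reaction_totals(1e-7, 5e-9, 1e-6)
  r0 <- rate_constants(k1P = 1e6, k_neg1P = 5e-3, k1D = 2e6, k_neg1D = 2e-3)
  r1 <- rate_constants(k1P = 1e6, k_neg1P = 5e-3, k1D = 2e6, k_neg1D = 2e-3,
                       k_thetaD = 5000)   # k_thetaP derived consistently
  expect_equal(equilibrium_state(r0, tot), equilibrium_state(r1, tot),
               tolerance = 1e-6)
})

test_that("complete scheme converges to the simplified scheme under fast exchange", {
  p <- preset_registry()[["TREX1_ssDNA_25C"]]
  r <- preset_rates(p)
  tot <- reaction_totals(1e-7, 5e-9, 1e-6)
  eq0 <- equilibrium_state(r, reaction_totals(1e-7, 5e-9, 0))
  y0 <- eq0; y0["D"] <- 1e-6
  times <- seq(0, 600, by = 10)
  tc_s <- simulate_scheme(r, tot, times, state0 = y0)
  tc_c <- simulate_scheme(r, tot, times, variant = "complete",
                          state0 = c(y0, EPs = 0, EDs = 0, T = 0))
  b_s <- bound_ligand(tc_s)
  b_c <- bound_ligand(tc_c)
  expect_lt(max(abs(b_c - b_s)) / max(b_s), 0.02)

  # independent fixed-fine-step RK4 integration of the complete scheme
  lam <- tc_c$exchange_rate
  ork <- rk4_complete(unclass(r), lam,
                      c(y0[["E"]], y0[["P"]], 1e-6, y0[["EP"]], 0, 0, 0, 0),
                      t_end = 200, dt = 1 / (3 * lam))
  tgt <- seq(0, 200, 10)
  idx <- vapply(tgt, function(t) which.min(abs(ork$times - t)), integer(1))
  expect_lt(max(abs(ork$bound[idx] - bound_ligand(tc_c)[1:21])) / max(b_s),
            1e-3)
})

test_that("excess-competitor chase decays are one-phase exponential", {
  p <- preset_registry()[["TREX1_ssDNA_25C"]]
  r <- preset_rates(p)
  D <- 5e-7   # 100x the 5 nM labelled ligand
  tot <- reaction_totals(1e-7, 5e-9, D)
  eq0 <- equilibrium_state(r, reaction_totals(1e-7, 5e-9, 0))
  y0 <- eq0; y0["D"] <- D
  times <- seq(0, 1200, by = 10)
  tc <- simulate_scheme(r, tot, times, state0 = y0)
  f <- bound_ligand(tc) / bound_ligand(tc)[1]
  fit <- fit_exponential_decay(times, f)
  expect_lt(sqrt(fit$rss / length(f)) / abs(fit$amplitude), 0.01)
})

test_that("predicted_koff has the documented limits and matches the ODE decay", {
  r0 <- rate_constants(k1P = 1e6, k_neg1P = 1e-2, identical_species = TRUE)
  # classic plateau at saturating competitor
  expect_equal(predicted_koff(r0, 1, P_free = 5e-9), 1e-2, tolerance = 1e-6)
  # no competitor: rebinding wins, nothing observable dissociates
  expect_identical(predicted_koff(r0, 0, P_free = 5e-9), 0)

  # monotone nondecreasing; strictly increasing and asymptotically linear
  # with transfer; saturating without
  p <- preset_registry()[["TREX1_ssDNA_25C"]]
  r <- preset_rates(p)
  D <- 10^seq(-9, -4, length.out = 40)
  k_dt <- predicted_koff(r, D, P_free = 5e-10)
  expect_true(all(diff(k_dt) > 0))
  slope_tail <- diff(tail(k_dt, 2)) / diff(tail(D, 2))
  expect_equal(slope_tail, p$k_theta, tolerance = 0.01)
  k_cl <- predicted_koff(r0, D, P_free = 5e-10)
  expect_true(all(diff(k_cl) >= 0))
  expect_lt(max(k_cl), 1e-2 + 1e-12)

  # chase decay rate of the simulated scheme at saturating capture
  D10 <- 1e-5
  tot <- reaction_totals(1e-7, 5e-9, D10)
  eq0 <- equilibrium_state(r, reaction_totals(1e-7, 5e-9, 0))
  y0 <- eq0; y0["D"] <- D10
  times <- seq(0, 300, by = 2)
  tc <- simulate_scheme(r, tot, times, state0 = y0)
  f <- bound_ligand(tc) / bound_ligand(tc)[1]
  fit <- fit_exponential_decay(times, f)
  expect_equal(fit$k * abs(fit$amplitude),
               predicted_koff(r, D10, P_free = eq0[["P"]]),
               tolerance = 0.05)
})

test_that("flux_partition behaves as a pathway branching ratio", {
  expect_identical(flux_partition(1e-2, 1e3, 0), 0)
  expect_equal(flux_partition(1e-2, 1e3, 1e-2 / 1e3), 0.5)
  # a protein with the cross-study average ratio of 1e5 /M reaches equal
  # flux at 10 uM competitor
  expect_equal(flux_partition(1e-3, 1e2, 1e-5), 0.5)
  expect_error(flux_partition(0, 1e3, 0), "undefined")
  expect_error(flux_partition(-1, 1e3, 1e-6), ">= 0")
})

test_that("rate-constant validation and consistency checks work", {
  expect_error(rate_constants(k1P = -1, k_neg1P = 1e-2), "> 0")
  expect_error(rate_constants(k1P = 1e6, k_neg1P = -1e-2), ">= 0")
  expect_error(reaction_totals(-1e-9, 5e-9), ">= 0")
  expect_warning(
    rate_constants(k1P = 1e6, k_neg1P = 1e-2, k_thetaD = 1000,
                   k_thetaP = 10),
    "inconsistent")
  expect_error(
    rate_constants(k1P = 1e6, k_neg1P = 1e-2, k_thetaD = 1000,
                   k_thetaP = 10, consistency = "error"),
    "inconsistent")
  r <- rate_constants(k1P = 1e6, k_neg1P = 1e-2, identical_species = TRUE)
  expect_error(simulate_scheme(r, reaction_totals(1e-7, 5e-9), c(-1, 0)),
               "nonnegative")
  expect_error(simulate_scheme(r, reaction_totals(1e-7, 5e-9), c(0, 10),
                               state0 = c(E = 1e-7, P = 0, D = 0,
                                          EP = 1e-9, ED = 0)),
               "inconsistent")
})
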