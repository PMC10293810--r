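# Independent oracles used by the kinetics tests. These deliberately do not
# call into the package's integration or fitting code paths.

# closed-form two-state binding: complex concentration from totals and K_d
two_state_complex <- function(E0, L0, Kd) {
  b <- E0 + L0 + Kd
  (b - sqrt(b * b - 4 * E0 * L0)) / 2
}

# fixed-fine-step RK4 integration of the complete competition scheme with
# the same micro-rate construction the package documents (association into
# the partial state, doubled dissociation from it, 4x transfer into a
# shared ternary that decays at the exchange rate toward either side)
rk4_complete <- function(rates, lambda, y0, t_end, dt) {
  deriv <- function(y) {
    E <- y[1]; P <- y[2]; D <- y[3]; EP <- y[4]; ED <- y[5]
    EPs <- y[6]; EDs <- y[7]; Tn <- y[8]
    aP <- rates$k1P * E * P;  dP <- 2 * rates$k_neg1P * EPs
    aD <- rates$k1D * E * D;  dD <- 2 * rates$k_neg1D * EDs
    cP <- lambda * EPs - lambda * EP
    cD <- lambda * EDs - lambda * ED
    tfP <- 4 * rates$k_thetaD * EPs * D
    tfD <- 4 * rates$k_thetaP * EDs * P
    c(-aP - aD + dP + dD,
      -aP + dP - tfD + lambda * Tn,
      -aD + dD - tfP + lambda * Tn,
      cP,
      cD,
      aP - dP - cP - tfP + lambda * Tn,
      aD - dD - cD - tfD + lambda * Tn,
      tfP + tfD - 2 * lambda * Tn)
  }
  n <- ceiling(t_end / dt)
  y <- y0
  out_t <- numeric(n + 1); out_b <- numeric(n + 1)
  out_t[1] <- 0; out_b[1] <- y[4] + y[6] + y[8]
  for (i in seq_len(n)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out_t[i + 1] <- i * dt
    out_b[i + 1] <- y[4] + y[6] + y[8]   # EP + EP* + T
  }
  list(times = out_t, bound = out_b)
}

# small deterministic plate for IO tests
tiny_plate <- function() {
  p <- preset_registry()[["TREX1_ssDNA_25C"]]
  des <- fp_plate_design(competitor_M = c(0, 5e-7, 1e-6, 2e-6, 4e-6, 8e-6),
                         replicates = 2, read_interval_s = 120,
                         duration_s = 1200)
  generate_fpcd_dataset(p, des, seed = 42)$plate
}
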