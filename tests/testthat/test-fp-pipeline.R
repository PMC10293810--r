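test_that("normalization maps the anchors and recovers generating fractions", {
  plate <- tiny_plate()
  norm <- normalize_polarization(plate, anchors = "range")
  i_max <- which.max(plate$polarization_mP)
  i_min <- which.min(plate$polarization_mP)
  expect_equal(norm$fraction[i_max], 1)
  expect_equal(norm$fraction[i_min], 0)

  # flat plate is degenerate data
  flat <- plate
  flat$polarization_mP <- 100 + rep_len(c(-0.5, 0.5), nrow(flat))
  expect_error(normalize_polarization(flat), "degenerate")

  # plateau anchors recover the generating bound fractions within the
  # noise level (fractions here are of the pre-equilibrated complex)
  p <- preset_registry()[["TREX1_ssDNA_25C"]]
  des <- fp_plate_design_for(p)
  ds <- generate_fpcd_dataset(p, des, seed = 5)
  norm <- normalize_polarization(ds$plate)
  fb <- ds$truth$bound_fraction
  truth_frac <- (fb - min(fb)) / (fb[1, 1] - min(fb))
  err <- vapply(seq_along(des$competitor_M), function(i) {
    sel <- norm$condition_id == sprintf("D%02d", i) & norm$replicate == 1
    mean(abs(norm$fraction[sel] - truth_frac[, i]))
  }, numeric(1))
  noise_frac <- des$noise_sd_mP / (140 * fb[1, 1])
  expect_lt(mean(err), noise_frac)
})

test_that("exponential decay regression is exact on noiseless data", {
  tt <- seq(0, 600, by = 10)
  fit <- fit_exponential_decay(tt, 0.8 * exp(-0.01 * tt) + 0.2)
  expect_equal(fit$k, 0.01, tolerance = 1e-8)
  expect_equal(fit$amplitude, 0.8, tolerance = 1e-8)
  expect_equal(fit$plateau, 0.2, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_false(fit$partial)

  # fixed-start variant gives the same answer when f0 is the truth
  fit0 <- fit_exponential_decay(tt, 0.8 * exp(-0.01 * tt) + 0.2, f0 = 1)
  expect_equal(fit0$k, 0.01, tolerance = 1e-8)
  expect_equal(fit0$amplitude, 0.8, tolerance = 1e-8)

  # constant signal: no dissociation, amplitude indistinguishable from 0
  fitc <- fit_exponential_decay(tt, rep(1, length(tt)))
  expect_lt(abs(fitc$amplitude), 1e-8)
  expect_lt(koff_obs_from_fit(fitc), 1e-9)

  expect_error(fit_exponential_decay(c(0, 1, 2), c(1, 1, 1)), "at least 5")
})

test_that("noisy decay rates are recovered without material bias", {
  tt <- seq(0, 600, by = 10)
  set.seed(31)
  ks <- replicate(1000, {
    y <- 0.9 * exp(-6.8e-3 * tt) + 0.1 + rnorm(length(tt), sd = 0.02)
    fit_exponential_decay(tt, y)$k
  })
  expect_lt(abs(median(ks) / 6.8e-3 - 1), 0.03)
})

test_that("off-rate conventions implement initial slope and relaxation rate", {
  fit <- structure(list(k = 0.01, amplitude = 0.8, plateau = 0.2,
                        rss = 0, n = 20, converged = TRUE, partial = FALSE),
                   class = "exp_fit")
  expect_equal(koff_obs_from_fit(fit), 0.008)
  expect_equal(koff_obs_from_fit(fit, "rate"), 0.01)
  # full-dissociation limit: both conventions agree
  fit$amplitude <- 1; fit$plateau <- 0
  expect_equal(koff_obs_from_fit(fit), koff_obs_from_fit(fit, "rate"))
})

test_that("saturating-competitor chase recovers the intrinsic off-rate", {
  # classic competitor at saturation: k_off^obs -> k_neg1P
  p <- parameter_preset("classic_sat", k_neg1 = 7.0e-3, k_theta = 0,
                        K_d_app = 8.9e-9)
  des <- fp_plate_design(competitor_M = c(0, 10^seq(-6.5, -5, length.out = 7)),
                         noise_sd_mP = 0.5)
  ds <- generate_fpcd_dataset(p, des, seed = 8)
  prof <- fpcd_koff_profile(ds$plate)
  top <- prof$profile[which.max(prof$profile$competitor_M), ]
  expect_equal(top$koff_obs, 7.0e-3, tolerance = 0.05)
})

test_that("competition regression has the exact linear and nested limits", {
  D <- c(0, 2e-7 * 2^(0:7))
  # pure transfer: profile through the origin with slope k_theta
  prof <- data.frame(competitor_M = D, koff_obs = 2000 * D)
  ft <- suppressWarnings(fit_competition_models(prof))
  expect_equal(ft$direct_transfer$k_thetaD, 2000, tolerance = 1e-6)
  expect_equal(ft$selected, "direct_transfer")

  # classic-generated noiseless data: the transfer estimate collapses to 0
  prof2 <- data.frame(competitor_M = D,
                      koff_obs = 0.019 * D / (D + 5e-7))
  ft2 <- suppressWarnings(fit_competition_models(prof2))
  expect_equal(ft2$classic$k_neg1P, 0.019, tolerance = 1e-6)
  expect_equal(ft2$classic$K_c, 5e-7, tolerance = 1e-4)
  expect_lt(ft2$direct_transfer$k_thetaD * max(D), 1e-3 * 0.019)
  expect_equal(ft2$selected, "classic")

  # BIC matches its closed form on the fitted RSS (noisy data, so the
  # RSS is far above the numerical floor)
  set.seed(17)
  prof3 <- data.frame(competitor_M = D,
                      koff_obs = (0.007 + 1500 * D) * (1 + rnorm(9, 0, 0.05)))
  ft3 <- suppressWarnings(fit_competition_models(prof3))
  n <- nrow(prof3)
  expect_equal(ft3$classic$bic, n * log(ft3$classic$rss / n) + 2 * log(n))
  expect_equal(ft3$direct_transfer$bic,
               n * log(ft3$direct_transfer$rss / n) + 3 * log(n))

  expect_error(fit_competition_models(
    data.frame(competitor_M = c(1e-6, 2e-6, 4e-6), koff_obs = 1:3)),
    ">= 4")
})

test_that("BIC selects the generating competition model under noise", {
  reg <- preset_registry()
  # classic truth (fast TREX1 dsDNA scenario)
  sel_cl <- vapply(1:40, function(s) {
    prof <- generate_koff_profile(reg[["TREX1_dsDNA_25C"]],
                                  noise_rel = 0.05, seed = s)
    suppressWarnings(fit_competition_models(prof))$selected
  }, character(1))
  expect_gte(mean(sel_cl == "classic"), 0.85)

  # direct-transfer truth
  ok_dt <- vapply(1:40, function(s) {
    prof <- generate_koff_profile(reg[["TREX1_ssDNA_25C"]],
                                  noise_rel = 0.05, seed = s)
    ft <- suppressWarnings(fit_competition_models(prof))
    ft$selected == "direct_transfer" &&
      abs(ft$direct_transfer$k_thetaD / 1500 - 1) <= 0.15
  }, logical(1))
  expect_gte(mean(ok_dt), 0.9)
})

test_that("full FPCD pipeline recovers generating rate constants", {
  p <- preset_registry()[["TREX1_ssDNA_4C"]]
  ds <- generate_fpcd_dataset(p, fp_plate_design_for(p), seed = 3)
  a <- analyze_fpcd(ds$plate)
  expect_equal(a$competition$selected, "direct_transfer")
  expect_equal(a$competition$k_neg1P, p$k_neg1, tolerance = 0.15)
  expect_equal(a$competition$k_thetaD, p$k_theta, tolerance = 0.15)

  # rerunning the pipeline on identical input is bit-identical
  b <- analyze_fpcd(ds$plate)
  expect_identical(a$competition, b$competition)
  expect_identical(a$profile$profile, b$profile$profile)
})

test_that("K_d regression recovers standard, Hill and depletion isotherms", {
  iso <- generate_isotherm(8.9e-9, noise_sd_mP = 0, seed = 1)
  f <- fit_kd(iso$isotherm$protein_M, iso$isotherm$polarization_mP)
  expect_equal(f$K_d, 8.9e-9, tolerance = 1e-6)

  # nested-model identity: hill at n_H = 1 matches the standard fit and
  # pays the extra-parameter BIC penalty
  fh <- fit_kd(iso$isotherm$protein_M, iso$isotherm$polarization_mP, "hill")
  expect_equal(fh$K_d, f$K_d, tolerance = 1e-3)
  expect_equal(fh$n_H, 1, tolerance = 1e-3)
  expect_gt(fh$bic, f$bic)

  # cooperative truth: hill must win the BIC comparison almost always
  wins <- vapply(1:100, function(s) {
    iso <- generate_isotherm(50e-9, n_H = 2, seed = s)
    fs <- fit_kd(iso$isotherm$protein_M, iso$isotherm$polarization_mP)
    fh <- fit_kd(iso$isotherm$protein_M, iso$isotherm$polarization_mP,
                 "hill")
    fh$bic < fs$bic
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  # ligand depletion: quadratic recovers the true K_d where the standard
  # apparent K_d is inflated, and tight binders trigger the caveat warning
  iso2 <- generate_isotherm(5e-9, ligand_M = 1e-8, depletion = TRUE,
                            noise_sd_mP = 0, seed = 2)
  fq <- suppressWarnings(fit_kd(iso2$isotherm$protein_M,
                                iso2$isotherm$polarization_mP, "quadratic",
                                ligand_M = 1e-8))
  expect_equal(fq$K_d, 5e-9, tolerance = 1e-4)
  fs2 <- fit_kd(iso2$isotherm$protein_M, iso2$isotherm$polarization_mP)
  expect_gt(fs2$K_d, fq$K_d)
  expect_warning(
    fit_kd(iso2$isotherm$protein_M, iso2$isotherm$polarization_mP,
           "quadratic", ligand_M = 1e-8),
    "ligand-limited")
})

test_that("stoichiometry breakpoints give ligands per functional unit", {
  E <- seq(1e-9, 2e-7, length.out = 24)
  st1 <- fit_stoichiometry(E, 60 + 1.4e9 * pmin(E, 5e-8), ligand_M = 5e-8)
  expect_equal(st1$ratio, 1, tolerance = 1e-6)
  # two ligands per functional unit (homodimer scenario)
  st2 <- fit_stoichiometry(E, 60 + 1.4e9 * pmin(E, 2.5e-8), ligand_M = 5e-8)
  expect_equal(st2$ratio, 2, tolerance = 1e-6)

  # noisy recovery of the breakpoint
  brk <- vapply(1:100, function(s) {
    set.seed(s)
    y <- 60 + 1.4e9 * pmin(E, 5e-8) + rnorm(length(E), sd = 0.03 * 140)
    fit_stoichiometry(E, y, ligand_M = 5e-8)$breakpoint_M
  }, numeric(1))
  expect_lt(median(abs(brk / 5e-8 - 1)), 0.1)

  # a titration that never breaks has no stoichiometry
  expect_error(fit_stoichiometry(E, 60 + 1e9 * E, ligand_M = 5e-8),
               "breakpoint")
})
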