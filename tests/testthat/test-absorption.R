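test_that("solubility profile reproduces the anchored weak-base values", {
  sp <- solubility_profile()
  expect_equal(solubility_at_ph(sp, 3), 0.7)
  expect_equal(solubility_at_ph(sp, 6.8), 0.02)
  expect_equal(solubility_at_ph(sp, 1), 223)
  # log-linear interpolation between anchors; clamped outside
  expect_equal(log10(solubility_at_ph(sp, 2)),
               mean(log10(c(223, 0.7))), tolerance = 1e-12)
  expect_equal(solubility_at_ph(sp, 0.2), 223)
  expect_equal(solubility_at_ph(sp, 8.5), 0.02)
  # monotone non-increasing for a base
  ph <- seq(0, 9, by = 0.1)
  expect_true(all(diff(solubility_at_ph(sp, ph)) <= 0))
  expect_error(solubility_at_ph(sp, 9.5), "pH")
})

test_that("Henderson-Hasselbalch mode doubles intrinsic solubility at pH = pKa", {
  hh <- solubility_profile(mode = "henderson_hasselbalch",
                           intrinsic_solubility = 0.01, pka = 5.1)
  expect_equal(solubility_at_ph(hh, 5.1), 0.02)
  expect_equal(solubility_at_ph(hh, 9), 0.01, tolerance = 1e-3)
  expect_error(solubility_profile(mode = "henderson_hasselbalch"), "needs")
})

test_that("DLM dissolution rate follows the Nernst-Brunner form", {
  f <- formulation_params(dose_mg = 100, particle_radius_um = 60)
  expect_equal(dissolution_rate_dlm(0, 0, 1, f), 0)
  expect_equal(dissolution_rate_dlm(50, 1, 1, f), 0) # sink equality
  # r > 30 um regime: h fixed at 30 um, rate ~ 1/r, so halving radius doubles it
  f120 <- formulation_params(dose_mg = 100, particle_radius_um = 120)
  f60 <- formulation_params(dose_mg = 100, particle_radius_um = 60)
  r120 <- dissolution_rate_dlm(100, 0, 0.5, f120)
  r60 <- dissolution_rate_dlm(100, 0, 0.5, f60)
  expect_equal(r60 / r120, 2, tolerance = 1e-9)
  # closed-form check: rate = 3 D M / (rho r h) * S
  D <- 9e-6 * 3600; rho <- 1200; r <- 60e-4; h <- 30e-4
  expect_equal(r60, 3 * D * 100 / (rho * r * h) * 0.5, tolerance = 1e-9)
  # shrinking spheres: at 1/8 of reference mass the radius halves
  f30 <- formulation_params(dose_mg = 100, particle_radius_um = 30)
  rate_full <- dissolution_rate_dlm(100, 0, 0.1, f30)
  rate_eighth <- dissolution_rate_dlm(12.5, 0, 0.1, f30)
  # rate ~ M / r^2 with h = r: (1/8) / (1/4) = 1/2
  expect_equal(rate_eighth / rate_full, 0.5, tolerance = 1e-9)
})

test_that("Peff mapping supports pass-through and log-linear calibration", {
  expect_equal(peff_from_papp(12.53e-6, optimized_peff = 1.00e-4), 1.00e-4)
  expect_equal(peff_from_papp(2e-5, calibration = list(a = 0, b = 1)), 2e-5)
  expect_equal(peff_from_papp(12.53e-6, calibration = list(a = log10(8), b = 1)),
               1.0024e-4, tolerance = 1e-4)
  expect_error(peff_from_papp(1e-5), "config error")
})

test_that("transit chain matches the analytic catenary solution when nothing limits", {
  skip_if_not_installed("Matrix")
  # infinite solubility + immediate dissolution: luminal dissolved amounts
  # follow a linear catenary chain with absorption; compare against the
  # matrix-exponential solution of the same linear system
  gi <- gi_physiology()
  cmp <- compound_params()
  r <- simulate_subject(compound = cmp, solubility = unlimited_solubility(),
                        regimen = dosing_regimen(100, 0),
                        feedback = FALSE, washout = 36,
                        rtol = 1e-10, atol = 1e-12)
  kt <- gi$segments$transit_rate
  peff_cmh <- cmp$peff * 3600
  ka <- ifelse(is.na(gi$segments$radius_cm), 0,
               2 * peff_cmh * gi$segments$surface_enhancement /
                 gi$segments$radius_cm)
  ka[1] <- 0
  A <- matrix(0, 9, 9)
  for (i in 1:9) A[i, i] <- -(kt[i] + ka[i])
  for (i in 2:9) A[i, i - 1] <- kt[i - 1]
  tt <- c(6, 12, 24)
  for (t1 in tt) {
    expA <- as.matrix(Matrix::expm(A * t1))
    lum_analytic <- expA %*% c(100, rep(0, 8))
    lum_sim <- vapply(1:9, function(i)
      stats::approx(r$time, r$state[, paste0("sol", i)] +
                      r$state[, paste0("dis", i)], xout = t1)$y, numeric(1))
    expect_equal(sum(lum_sim), sum(lum_analytic), tolerance = 5e-3)
  }
  # fraction absorbed at the end matches 1 - survived - exited
  fa_sim <- sum(r$state[nrow(r$state), paste0("gabs", 1:9)]) / 100
  t_end <- max(r$time)
  surv <- sum(as.matrix(Matrix::expm(A * t_end)) %*% c(100, rep(0, 8))) / 100
  exited_frac <- unname(r$state[nrow(r$state), "exited"]) / 100
  fa_analytic <- 1 - surv - exited_frac
  expect_equal(fa_sim, fa_analytic, tolerance = 5e-3)
})

test_that("raising gastric pH strictly slows gastric dissolution of the base", {
  f <- formulation_params()
  sp <- solubility_profile()
  s_low <- solubility_at_ph(sp, 1.5)
  s_high <- solubility_at_ph(sp, 5)
  expect_gt(s_low, s_high)
  rate_low <- dissolution_rate_dlm(50, 0.01, s_low, f)
  rate_high <- dissolution_rate_dlm(50, 0.01, s_high, f)
  expect_gt(rate_low, rate_high)
})

test_that("no permeability means no absorption and full recovery in the lumen", {
  cmp <- compound_params(peff = 1e-12) # effectively zero
  r <- simulate_subject(compound = cmp, regimen = dosing_regimen(100, 0),
                        feedback = FALSE, washout = 60,
                        rtol = 1e-8, atol = 1e-10)
  fa <- sum(r$state[nrow(r$state), paste0("gabs", 1:9)]) / 100
  expect_lt(fa, 1e-4)
  lum_plus_exited <- sum(r$state[nrow(r$state),
                                 c(paste0("sol", 1:9), paste0("dis", 1:9),
                                   "exited")])
  expect_equal(lum_plus_exited, 100, tolerance = 1e-3)
})

test_that("luminal dissolved concentration respects the supersaturation cap", {
  r <- simulate_subject(regimen = dosing_regimen(100, 0), feedback = FALSE,
                        washout = 24)
  f <- formulation_params()
  sp <- solubility_profile()
  gi <- gi_physiology()
  for (i in 2:9) {
    conc <- r$state[, paste0("dis", i)] / gi$segments$volume_ml[i]
    cap <- f$supersaturation_ratio *
      solubility_at_ph(sp, gi$segments$baseline_ph[i])
    expect_lt(max(conc), cap * 1.10) # fast precipitation clamps near the cap
  }
})
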