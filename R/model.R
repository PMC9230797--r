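#' Oral dosing regimen
#'
#' @param dose_mg Dose per administration (mg), > 0; recycled to match
#'   `times`.
#' @param times Administration times (h), strictly increasing, starting at 0.
#' @param prandial_state `"fasted"` or `"fed"` (single value; the GI
#'   physiology of the whole simulation follows it).
#' @return An object of class `dosing_regimen`.
#' @export
dosing_regimen <- function(dose_mg, times = 0,
                           prandial_state = c("fasted", "fed")) {
  prandial_state <- match.arg(prandial_state)
  if (any(dose_mg < 0)) stop("doses must be >= 0")
  if (is.unsorted(times, strictly = TRUE)) stop("dose times must be increasing")
  structure(list(dose_mg = rep(dose_mg, length.out = length(times)),
                 times = times, prandial_state = prandial_state),
            class = "dosing_regimen")
}

# state-vector layout of the coupled absorption/PBPK/PD system
.tissue_names <- c("adipose", "bone", "brain", "gut", "heart", "kidney",
                   "liver", "lung", "muscle", "skin", "spleen")
.state_layout <- function() {
  nm <- c(paste0("sol", 1:9), paste0("dis", 1:9), paste0("gabs", 1:9),
          "exited",
          .tissue_names, "ven", "art",
          "cmet", "cbil", "cren", "cadd",
          "m1c", "m1sac", "cmhep", "cmren", "cmadd",
          "R")
  stats::setNames(seq_along(nm), nm)
}

#' Assemble the coupled model for one subject
#'
#' Precomputes everything the ODE right-hand side needs: segment transit and
#' absorption rate constants, per-segment solubility at baseline pH, scaled
#' tissue partition coefficients, IVIVE'd hepatic intrinsic clearances and
#' the metabolite's whole-organ metabolic clearance.
#'
#' The gastric pH seen by dissolution is the PD response `clamp(R, 1, 8)`
#' when feedback is enabled, otherwise the gastric baseline; a fed-state
#' meal elevation (first-order return to baseline) is added in either case.
#'
#' @param subject A `subject_physiology`.
#' @param compound A [compound_params()].
#' @param metabolite A [metabolite_params()].
#' @param formulation A [formulation_params()].
#' @param gi A [gi_physiology()] (fasted or fed).
#' @param solubility A [solubility_profile()].
#' @param pd A [pd_params()].
#' @param baseline A [fourier_baseline()].
#' @param kp_scalar Calibrated Kp scalar; `NULL` calibrates against the
#'   reference subject's `vss_target`.
#' @param feedback Couple the PD response back into gastric dissolution?
#' @return An object of class `tegopbpk_model`.
#' @export
build_model <- function(subject, compound,
                        metabolite = metabolite_params(),
                        formulation = formulation_params(),
                        gi = gi_physiology(),
                        solubility = solubility_profile(),
                        pd = pd_params(),
                        baseline = fourier_baseline(),
                        kp_scalar = NULL, feedback = TRUE) {
  if (is.null(kp_scalar)) {
    kp_scalar <- if (!is.null(compound$kp_scalar)) compound$kp_scalar
      else as.numeric(calibrate_kp_scalar(compound))
  }
  kp <- kp_rodgers_rowland(compound, kp_scalar = kp_scalar)
  seg <- gi$segments
  peff_cmh <- compound$peff * 3600
  ka <- ifelse(is.na(seg$radius_cm), 0,
               2 * peff_cmh * seg$surface_enhancement / seg$radius_cm)
  ka[1] <- 0 # no gastric absorption
  clint <- ivive_hepatic_clint(compound, subject)
  fub <- compound$fu / compound$bp
  q <- subject$organ_flows
  q_h <- hepatic_flow(subject)
  v <- subject$organ_volumes
  bile_factor <- 1 + formulation$bile_solubilization * seg$bile_salt_mM
  sol_base <- solubility_at_ph(solubility,
                               pmin(pmax(seg$baseline_ph, 0), 9)) * bile_factor

  structure(list(
    subject = subject, compound = compound, metabolite = metabolite,
    formulation = formulation, gi = gi, solubility = solubility,
    pd = pd, baseline = baseline, feedback = feedback,
    kp_scalar = kp_scalar, kp = kp,
    seg_kt = seg$transit_rate, seg_vol = seg$volume_ml, seg_ka = ka,
    seg_sol_base = sol_base, seg_bile_factor = bile_factor,
    clint_met = clint$metabolic, clint_bil = clint$biliary,
    fub = fub, q = q, q_h = q_h, v = v,
    v_ven = subject$blood_volume * 2 / 3,
    v_art = subject$blood_volume * 1 / 3,
    q_co = subject$cardiac_output,
    cl_womc_m1 = womc_clearance(metabolite, subject),
    idx = .state_layout()),
    class = "tegopbpk_model") -> m
  m$cc <- .compile_model(m)
  m
}

# Flatten every parameter the RHS needs into one plain list of doubles.
# Tissue order: adipose bone brain gut heart kidney liver lung muscle skin
# spleen (liver = 7, lung = 8, gut = 4, kidney = 6, spleen = 11).
.compile_model <- function(model) {
  solb <- model$solubility
  hh <- solb$mode == "henderson_hasselbalch"
  q_tis <- unname(model$q[.tissue_names]) # lung missing -> NA
  q_tis[8] <- 0 # lung handled separately
  bl <- model$baseline
  list(
    hh = hh,
    s0 = if (hh) solb$intrinsic_solubility else 0,
    spka = if (hh) solb$pka else 0,
    aph = if (hh) 0 else solb$anchors$ph,
    alog = if (hh) 0 else log10(solb$anchors$solubility),
    bl_const = all(bl$a == 0) && all(bl$b == 0),
    bl_a0 = bl$a0, bl_a = bl$a, bl_b = bl$b, bl_w = bl$w,
    feedback = model$feedback,
    kp = unname(model$kp[.tissue_names]),
    v_tis = unname(model$v[.tissue_names]),
    q_tis = q_tis,
    q_h = model$q_h, q_co = model$q_co,
    v_ven = model$v_ven, v_art = model$v_art,
    bp = model$compound$bp, fub = model$fub,
    clint_met = model$clint_met, clint_bil = model$clint_bil,
    cl_renal = model$compound$cl_renal,
    cl_add = model$compound$cl_additional,
    fm_met = model$compound$fm_metabolite,
    seg_kt = model$seg_kt, seg_vol = model$seg_vol, seg_ka = model$seg_ka,
    seg_sol_base = model$seg_sol_base,
    bile1 = model$seg_bile_factor[1],
    fed = model$gi$prandial_state == "fed",
    meal_amp = model$gi$gastric_ph_initial - model$gi$segments$baseline_ph[1],
    meal_rate = model$gi$gastric_ph_return_rate,
    ref_mass = max(model$formulation$dose_mg, 1e-9),
    r0 = model$formulation$particle_radius_um * 1e-4,
    D_h = model$formulation$diffusion_coeff * 3600,
    rho = model$formulation$particle_density * 1000,
    ssr = model$formulation$supersaturation_ratio,
    kprec = model$formulation$precipitation_rate,
    bw = model$subject$body_weight,
    mw_ratio = model$metabolite$mw / model$compound$mw,
    vc_m1 = model$metabolite$vss * model$subject$body_weight,
    kin_sac = model$metabolite$k_in_sac,
    kout_sac = model$metabolite$k_out_sac,
    vsac_bw = model$metabolite$v_sac * model$subject$body_weight,
    cl_m1_hep = model$cl_womc_m1 * model$metabolite$bp,
    cl_m1_ren = model$metabolite$cl_renal,
    cl_m1_add = model$metabolite$cl_additional,
    pd_reduced = model$pd$mode == "reduced",
    emax = model$pd$emax, ec50g = model$pd$ec50^model$pd$gamma,
    gamma = model$pd$gamma, kin_pd = model$pd$k_in, kout_pd = model$pd$k_out)
}

# derivative of the monolithic ODE system (amounts in mg, time in h);
# parms is the .compile_model() list
.model_rhs <- function(t, y, cc) {
  sol <- y[1:9]; dis <- y[10:18]

  base_t <- if (cc$bl_const) cc$bl_a0 else {
    s <- cc$bl_a0
    for (i in 1:6) s <- s + cc$bl_a[i] * cos(i * cc$bl_w * t) +
        cc$bl_b[i] * sin(i * cc$bl_w * t)
    s
  }
  meal_elev <- if (cc$fed) cc$meal_amp * exp(-cc$meal_rate * t) else 0
  ph_stom <- (if (cc$feedback) y[51] else base_t) + meal_elev
  if (ph_stom < 1) ph_stom <- 1 else if (ph_stom > 8) ph_stom <- 8

  seg_sol <- cc$seg_sol_base
  seg_sol[1] <- cc$bile1 * if (cc$hh) {
    cc$s0 * (1 + 10^(cc$spka - ph_stom))
  } else {
    aph <- cc$aph; alog <- cc$alog; n_a <- length(aph)
    if (ph_stom <= aph[1]) 10^alog[1]
    else if (ph_stom >= aph[n_a]) 10^alog[n_a]
    else {
      j <- findInterval(ph_stom, aph)
      10^(alog[j] + (alog[j + 1] - alog[j]) * (ph_stom - aph[j]) /
            (aph[j + 1] - aph[j]))
    }
  }

  conc <- dis / cc$seg_vol # mg/mL
  # Nernst-Brunner, shrinking monodisperse spheres, h = min(r, 30 um);
  # radius floored at 1% of r0 so the rate stays Lipschitz as solid -> 0
  frac <- sol / cc$ref_mass
  frac[frac < 0] <- 0
  r <- frac^(1 / 3)
  r[r < 0.01] <- 0.01
  r <- cc$r0 * r
  h <- r
  h[h > 30e-4] <- 30e-4
  drive <- seg_sol - conc
  drive[drive < 0] <- 0
  solpos <- sol
  solpos[solpos < 0] <- 0
  dissolve <- 3 * cc$D_h * solpos / (cc$rho * r * h) * drive
  excess <- conc - seg_sol
  excess[excess < 0] <- 0
  over <- conc - cc$ssr * seg_sol
  over[over < 0] <- 0
  precip <- (cc$kprec * excess + 500 * over) * cc$seg_vol

  kt <- cc$seg_kt
  in_sol <- c(0, kt[1:8] * sol[1:8])
  in_dis <- c(0, kt[1:8] * dis[1:8])
  absflux <- cc$seg_ka * dis
  dsol <- in_sol - kt * sol - dissolve + precip
  ddis <- in_dis - kt * dis + dissolve - precip - absflux
  dexited <- kt[9] * (sol[9] + dis[9])

  # parent whole-body PBPK (blood concentrations, mg/L)
  cv_t <- y[29:39] / cc$v_tis * cc$bp / cc$kp # blood leaving each tissue
  c_ven <- y[40] / cc$v_ven
  c_art <- y[41] / cc$v_art

  dt_tissue <- cc$q_tis * (c_art - cv_t)
  met_flux <- cc$clint_met * cc$fub * cv_t[7]
  bil_flux <- cc$clint_bil * cc$fub * cv_t[7]
  dt_tissue[7] <- cc$q_tis[7] * c_art + cc$q_tis[4] * cv_t[4] +
    cc$q_tis[11] * cv_t[11] + sum(absflux) -
    cc$q_h * cv_t[7] - met_flux - bil_flux
  dt_tissue[8] <- cc$q_co * (c_ven - cv_t[8]) # lung in series
  ren_flux <- cc$cl_renal * c_art / cc$bp
  dt_tissue[6] <- dt_tissue[6] - ren_flux
  add_flux <- cc$cl_add * c_ven / cc$bp
  # venous return: adipose bone brain heart kidney muscle skin + liver outflow
  iv <- c(1:3, 5:6, 9:10)
  dven <- sum(cc$q_tis[iv] * cv_t[iv]) +
    cc$q_h * cv_t[7] - cc$q_co * c_ven - add_flux
  dart <- cc$q_co * (cv_t[8] - c_art)

  # metabolite: lumped central + single adjusting compartment
  cp_m1 <- y[46] / cc$vc_m1 # plasma-referenced, mg/L
  form_m1 <- cc$fm_met * met_flux * cc$mw_ratio
  sac_in <- cc$kin_sac * cp_m1 * cc$vsac_bw
  sac_out <- cc$kout_sac * y[47]
  hep_m1 <- cc$cl_m1_hep * cp_m1
  ren_m1 <- cc$cl_m1_ren * cp_m1
  add_m1 <- cc$cl_m1_add * cp_m1
  dm1c <- form_m1 - sac_in + sac_out - hep_m1 - ren_m1 - add_m1

  # PD turnover driven by venous plasma parent concentration (ng/mL)
  cp <- c_ven / cc$bp * 1000
  hill <- if (cp > 0) { cpg <- cp^cc$gamma; cpg / (cc$ec50g + cpg) } else 0
  effect <- base_t * (1 + cc$emax * hill)
  dR <- if (cc$pd_reduced) cc$kin_pd * effect - cc$kout_pd * y[51]
  else cc$kin_pd * (effect + base_t) - cc$kout_pd * y[51]

  dy <- c(dsol, ddis, absflux, dexited, dt_tissue, dven, dart,
          met_flux, bil_flux, ren_flux, add_flux,
          dm1c, sac_in - sac_out, hep_m1, ren_m1, add_m1, dR)
  if (any(!is.finite(dy)))
    stop("non-finite derivative at t = ", signif(t, 6), "; state: ",
         paste(signif(y, 4), collapse = ","))
  list(dy)
}

#' Simulate one subject under a dosing regimen
#'
#' Integrates the monolithic absorption + PBPK + PD system with `lsoda`
#' (adaptive stiff/non-stiff switching; default rtol 1e-8, atol 1e-10 mg)
#' over the regimen horizon plus a 48-h washout. Doses enter as solid-mass
#' impulses into the stomach. Deterministic given its inputs.
#'
#' @inheritParams build_model
#' @param regimen A [dosing_regimen()].
#' @param dt_out Output resolution (h); default 1/12 (5 min).
#' @param washout Post-dose washout (h), default 48.
#' @param rtol,atol Solver tolerances.
#' @param model Optionally a prebuilt [build_model()] object (overrides the
#'   component arguments).
#' @return An object of class `simulation_result`: list with `time` (h),
#'   `cp_parent`, `cp_m1` (plasma, ng/mL), `gastric_ph`, `state` (full
#'   trajectory matrix), `mass_balance` (max relative residual), `model`,
#'   `regimen`.
#' @export
simulate_subject <- function(subject = reference_physiology(),
                             compound = compound_params(),
                             metabolite = metabolite_params(),
                             formulation = formulation_params(),
                             gi = NULL,
                             solubility = solubility_profile(),
                             pd = pd_params(),
                             baseline = fourier_baseline(),
                             regimen = dosing_regimen(100, 0),
                             kp_scalar = NULL, feedback = TRUE,
                             dt_out = 1 / 12, washout = 48,
                             rtol = 1e-8, atol = 1e-10,
                             model = NULL) {
  if (is.null(gi)) {
    gi <- gi_physiology()
    if (regimen$prandial_state == "fed") gi <- fed_state_adjust(gi)
  }
  if (is.null(model)) {
    model <- build_model(subject, compound, metabolite, formulation, gi,
                         solubility, pd, baseline,
                         kp_scalar = kp_scalar, feedback = feedback)
  }
  ix <- model$idx
  horizon <- max(regimen$times) + washout
  times <- seq(0, horizon, by = dt_out)
  y0 <- numeric(length(ix))
  names(y0) <- names(ix)
  r0 <- baseline_ph(model$baseline, 0)
  if (model$pd$mode == "as_printed")
    r0 <- 2 * (model$pd$k_in / model$pd$k_out) * r0
  y0[ix[["R"]]] <- r0

  dose_at_zero <- any(regimen$times == 0)
  if (dose_at_zero) y0[ix[["sol1"]]] <- regimen$dose_mg[regimen$times == 0]
  ev_times <- regimen$times[regimen$times > 0]
  events <- if (length(ev_times)) {
    list(data = data.frame(var = "sol1", time = ev_times,
                           value = regimen$dose_mg[regimen$times > 0],
                           method = "add"))
  } else NULL

  out <- deSolve::lsoda(y0, times, .model_rhs, parms = model$cc,
                        rtol = rtol, atol = atol, maxsteps = 200000,
                        events = events)
  if (attr(out, "istate")[1] < 0)
    stop("solver failure; last valid time ", max(out[, "time"]))
  st <- out[, -1, drop = FALSE]
  tt <- out[, 1]

  bp <- model$compound$bp
  cp_parent <- st[, "ven"] / model$v_ven / bp * 1000 # ng/mL
  cp_m1 <- st[, "m1c"] / (model$metabolite$vss * model$subject$body_weight) * 1000
  gi_ph <- {
    base_t <- baseline_ph(model$baseline, tt)
    elev <- (model$gi$gastric_ph_initial - model$gi$segments$baseline_ph[1]) *
      exp(-model$gi$gastric_ph_return_rate * tt) *
      (model$gi$prandial_state == "fed")
    raw <- if (model$feedback) st[, "R"] else base_t
    pmin(pmax(raw + elev, 1), 8)
  }

  # the stored state at an event time is pre-impulse, so count a dose as
  # administered only strictly before the output time (t = 0 lives in y0)
  dosed <- vapply(tt, function(x)
    sum(regimen$dose_mg[regimen$times < x | regimen$times == 0]), numeric(1))
  parent_total <- rowSums(st[, c(paste0("sol", 1:9), paste0("dis", 1:9),
                                 "exited", .tissue_names, "ven", "art",
                                 "cmet", "cbil", "cren", "cadd")])
  mb <- max(abs(parent_total - dosed)) / max(dosed)
  m1_total <- rowSums(st[, c("m1c", "m1sac", "cmhep", "cmren", "cmadd")])
  m1_expected <- st[, "cmet"] * model$compound$fm_metabolite *
    model$metabolite$mw / model$compound$mw
  mb_m1 <- max(abs(m1_total - m1_expected)) / max(dosed)

  structure(list(time = tt, cp_parent = as.numeric(cp_parent),
                 cp_m1 = as.numeric(cp_m1),
                 gastric_ph = as.numeric(gi_ph),
                 state = st, mass_balance = mb, mass_balance_m1 = mb_m1,
                 model = model, regimen = regimen),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Coupled PBPK/PD simulation\n")
  cat(sprintf("  regimen: %s mg at t = %s h (%s)\n",
              paste(unique(x$regimen$dose_mg), collapse = "/"),
              paste(x$regimen$times, collapse = ", "),
              x$regimen$prandial_state))
  cat(sprintf("  horizon: %.1f h at %.3g h resolution\n",
              max(x$time), x$time[2] - x$time[1]))
  cat(sprintf("  parent Cmax: %.1f ng/mL; M1 Cmax: %.1f ng/mL\n",
              max(x$cp_parent), max(x$cp_m1)))
  cat(sprintf("  mass-balance residual: %.2g (parent), %.2g (M1)\n",
              x$mass_balance, x$mass_balance_m1))
  invisible(x)
}

#' Per-segment luminal time course as a tidy data frame
#'
#' @param result A [simulate_subject()] result.
#' @return Data frame with columns `time_h`, `segment`, `solid_mg`,
#'   `dissolved_mg`, `absorbed_mg`.
#' @export
luminal_profile <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  segs <- result$model$gi$segments$segment
  do.call(rbind, lapply(seq_along(segs), function(i) {
    data.frame(time_h = result$time, segment = segs[i],
               solid_mg = result$state[, paste0("sol", i)],
               dissolved_mg = result$state[, paste0("dis", i)],
               absorbed_mg = result$state[, paste0("gabs", i)],
               stringsAsFactors = FALSE)
  }))
}
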