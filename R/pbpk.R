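#' Compound parameter set for the parent drug (full PBPK)
#'
#' Physicochemical, absorption, distribution and elimination constants for a
#' monoprotic weak base handled by the full perfusion-limited PBPK model.
#' Defaults are the tegoprazan model-final values: MW 387.38, logP 2.323,
#' pKa 5.1, B/P 0.792, fu 0.087, optimized Peff 1.00e-4 cm/s, Vss target
#' 1.0 L/kg (achieved via the Kp scalar), rCYP intrinsic clearances
#' (3A4 1.920, 2C19 0.710, 2C8 0.060, 2C9 0.140, 2D6 0.020, 2E1 0.030
#' µL/min/pmol), additional HLM CLint 15.96 µL/min/mg, biliary CLint
#' 1.29 µL/min/10^6 cells, renal CL 1.1 L/h, additional systemic CL 1.43 L/h.
#'
#' @param mw Molecular weight (g/mol).
#' @param logp Octanol-water log P.
#' @param pka Basic pKa (monoprotic base).
#' @param bp Blood-to-plasma concentration ratio, > 0.
#' @param fu Unbound fraction in plasma, in (0, 1].
#' @param papp_caco2 Caco-2 Papp (cm/s).
#' @param peff Optimized effective jejunal permeability (cm/s).
#' @param vss_target Target steady-state volume of distribution (L/kg) for
#'   Kp-scalar calibration; `NA` to use unscaled Rodgers-Rowland Kps.
#' @param kp_scalar Global Kp multiplier; `NULL` means calibrate to
#'   `vss_target` at simulation time.
#' @param clint_cyp Named vector of rCYP intrinsic clearances (µL/min/pmol).
#' @param clint_hlm_additional Additional HLM CLint (µL/min/mg protein).
#' @param biliary_clint Biliary CLint (µL/min/10^6 hepatocytes).
#' @param cl_renal Renal clearance (L/h, plasma-referenced).
#' @param cl_additional Additional systemic clearance (L/h, applied to venous
#'   blood, plasma-referenced).
#' @param fm_metabolite Fraction of hepatic metabolic clearance that forms
#'   the measured metabolite (default 1).
#' @return An object of class `compound_params`.
#' @export
compound_params <- function(mw = 387.38, logp = 2.323, pka = 5.1,
                            bp = 0.792, fu = 0.087,
                            papp_caco2 = 12.53e-6, peff = 1.00e-4,
                            vss_target = 1.0, kp_scalar = NULL,
                            clint_cyp = c(CYP3A4 = 1.920, CYP2C19 = 0.710,
                                          CYP2C8 = 0.060, CYP2C9 = 0.140,
                                          CYP2D6 = 0.020, CYP2E1 = 0.030),
                            clint_hlm_additional = 15.96,
                            biliary_clint = 1.29,
                            cl_renal = 1.1, cl_additional = 1.43,
                            fm_metabolite = 1.0) {
  if (fu <= 0 || fu > 1) stop("fu must be in (0, 1]")
  if (bp <= 0) stop("B/P must be > 0")
  if (any(c(clint_cyp, clint_hlm_additional, biliary_clint,
            cl_renal, cl_additional) < 0))
    stop("clearances must be >= 0")
  structure(list(mw = mw, logp = logp, pka = pka, bp = bp, fu = fu,
                 papp_caco2 = papp_caco2, peff = peff,
                 vss_target = vss_target, kp_scalar = kp_scalar,
                 clint_cyp = clint_cyp,
                 clint_hlm_additional = clint_hlm_additional,
                 biliary_clint = biliary_clint, cl_renal = cl_renal,
                 cl_additional = cl_additional,
                 fm_metabolite = fm_metabolite),
            class = "compound_params")
}

#' Metabolite parameter set (minimal PBPK with single adjusting compartment)
#'
#' Defaults are the M1 model-final values: MW 373.36, logP 2.1, pKa 5.35,
#' B/P 1.116, fu 0.257, Vss 1.72 L/kg, SAC rates k_in 40/h, k_out 7.76/h,
#' V_sac 1.23 L/kg, whole-organ metabolic clearance from CLint,HLM
#' 2.353 µL/min/mg + CLint,HLC 3.15 µL/min/mg, renal CL 1.1 L/h, additional
#' systemic CL 1.44 L/h.
#'
#' @param mw,logp,pka,bp,fu As in [compound_params()].
#' @param vss Central volume of distribution (L/kg), > 0.
#' @param k_in_sac,k_out_sac SAC input/output rate constants (1/h), > 0.
#' @param v_sac SAC volume (L/kg), > 0.
#' @param clint_hlm,clint_hlc Microsomal and cytosolic CLint (µL/min/mg).
#' @param cl_renal,cl_additional Renal / additional systemic CL (L/h).
#' @return An object of class `metabolite_params`.
#' @export
metabolite_params <- function(mw = 373.36, logp = 2.1, pka = 5.35,
                              bp = 1.116, fu = 0.257,
                              vss = 1.72, k_in_sac = 40, k_out_sac = 7.76,
                              v_sac = 1.23,
                              clint_hlm = 2.353, clint_hlc = 3.15,
                              cl_renal = 1.1, cl_additional = 1.44) {
  if (fu <= 0 || fu > 1) stop("fu must be in (0, 1]")
  if (bp <= 0) stop("B/P must be > 0")
  if (vss <= 0 || k_in_sac <= 0 || k_out_sac <= 0 || v_sac <= 0)
    stop("vss, k_in_sac, k_out_sac, v_sac must all be > 0")
  if (any(c(clint_hlm, clint_hlc, cl_renal, cl_additional) < 0))
    stop("clearances must be >= 0")
  structure(list(mw = mw, logp = logp, pka = pka, bp = bp, fu = fu,
                 vss = vss, k_in_sac = k_in_sac, k_out_sac = k_out_sac,
                 v_sac = v_sac, clint_hlm = clint_hlm, clint_hlc = clint_hlc,
                 cl_renal = cl_renal, cl_additional = cl_additional),
            class = "metabolite_params")
}

#' Tissue composition table for Rodgers-Rowland partitioning
#'
#' Fractional tissue volumes of extracellular and intracellular water,
#' neutral lipid and neutral phospholipid, and the tissue:plasma albumin
#' ratio, from the published Rodgers-Rowland tissue-composition dataset.
#' The `plasma` row carries the plasma neutral-lipid/phospholipid fractions.
#'
#' @return Data frame with one row per tissue.
#' @export
tissue_composition <- function() {
  data.frame(
    tissue = c("adipose", "bone", "brain", "gut", "heart", "kidney",
               "liver", "lung", "muscle", "skin", "spleen", "plasma"),
    f_ew = c(0.135, 0.100, 0.162, 0.282, 0.320, 0.273,
             0.161, 0.336, 0.118, 0.382, 0.207, 0.945),
    f_iw = c(0.017, 0.346, 0.620, 0.475, 0.456, 0.483,
             0.573, 0.446, 0.630, 0.291, 0.579, 0),
    f_nl = c(0.853, 0.017, 0.039, 0.038, 0.014, 0.012,
             0.014, 0.022, 0.010, 0.060, 0.0077, 0.0023),
    f_np = c(0.0016, 0.0017, 0.0015, 0.0125, 0.0111, 0.0240,
             0.0240, 0.0128, 0.0072, 0.0044, 0.0113, 0.0013),
    ra = c(0.049, 0.100, 0.048, 0.158, 0.157, 0.130,
           0.086, 0.212, 0.064, 0.277, 0.097, 1),
    stringsAsFactors = FALSE)
}

#' Rodgers-Rowland tissue:plasma partition coefficients (very weak base)
#'
#' Tissue:plasma Kp for a monoprotic base with pKa below intracellular pH
#' (predominantly neutral), using the tissue-composition method: water
#' partitioning with Henderson-Hasselbalch ionization at plasma pH 7.4 and
#' intracellular pH 7.0, partitioning into neutral lipid and neutral
#' phospholipid, and extracellular protein binding scaled by the
#' tissue:plasma albumin ratio. The result is multiplied by `kp_scalar`.
#'
#' @param compound A [compound_params()] (uses `logp`, `pka`, `fu`).
#' @param composition Tissue-composition table, default [tissue_composition()].
#' @param kp_scalar Global scalar applied to all tissues (default 1).
#' @param ph_plasma,ph_iw Plasma and intracellular water pH.
#' @return Named vector of Kp values (tissue:plasma), one per tissue row
#'   excluding plasma.
#' @export
kp_rodgers_rowland <- function(compound, composition = tissue_composition(),
                               kp_scalar = 1, ph_plasma = 7.4, ph_iw = 7.0) {
  stopifnot(inherits(compound, c("compound_params", "metabolite_params")) ||
              is.list(compound))
  P <- 10^compound$logp
  X_p <- 1 + 10^(compound$pka - ph_plasma) # ionized:neutral + 1, plasma
  X_iw <- 1 + 10^(compound$pka - ph_iw)
  pl <- composition[composition$tissue == "plasma", ]
  lip_p <- P * pl$f_nl + (0.3 * P + 0.7) * pl$f_np
  # unbound-plasma-referenced binding term attributed to albumin/lipoprotein
  ka_alb <- max(0, 1 / compound$fu - 1 - lip_p) # == (1-fu)/fu minus plasma lipid
  tis <- composition[composition$tissue != "plasma", ]
  kp_u <- tis$f_ew +
    (X_iw / X_p) * tis$f_iw +
    (P * tis$f_nl + (0.3 * P + 0.7) * tis$f_np) / X_p +
    ka_alb * tis$ra
  kp <- kp_scalar * compound$fu * kp_u
  stats::setNames(kp, tis$tissue)
}

#' Steady-state volume of distribution from tissue Kps
#'
#' `Vss = (V_plasma + sum_t Kp_t * V_t) / BW` (L/kg), with plasma volume
#' `V_blood * (1 - hematocrit)`.
#'
#' @param kp Named Kp vector from [kp_rodgers_rowland()].
#' @param subject A `subject_physiology`.
#' @return Vss (L/kg).
#' @export
vss_from_kp <- function(kp, subject) {
  v <- subject$organ_volumes[names(kp)]
  v_plasma <- subject$blood_volume * (1 - subject$hematocrit)
  (v_plasma + sum(kp * v)) / subject$body_weight
}

#' Calibrate the global Kp scalar to a target Vss
#'
#' Bisection on the scalar so that [vss_from_kp()] hits the target (for the
#' tegoprazan model, 1.0 L/kg, adjusted down from the unscaled prediction).
#' Vss is linear in the scalar, so the solve also has a closed form; bisection
#' is kept as the generic method and converges to `tol`.
#'
#' @param compound A [compound_params()] with `vss_target` set.
#' @param subject A `subject_physiology`.
#' @param composition Tissue composition table.
#' @param tol Absolute tolerance on Vss (L/kg).
#' @return The calibrated scalar (attribute `vss` carries the achieved Vss).
#' @export
calibrate_kp_scalar <- function(compound, subject = reference_physiology(),
                                composition = tissue_composition(),
                                tol = 1e-10) {
  target <- compound$vss_target
  if (is.null(target) || is.na(target)) return(1)
  kp1 <- kp_rodgers_rowland(compound, composition, kp_scalar = 1)
  f <- function(s) vss_from_kp(kp1 * s, subject) - target
  lo <- 0; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol / max(1, abs(f(1)))) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  structure(s, vss = vss_from_kp(kp1 * s, subject))
}

#' IVIVE scale-up of hepatic intrinsic clearance
#'
#' Whole-liver metabolic intrinsic clearance (L/h) from per-pmol rCYP
#' clearances and additional per-mg microsomal clearance:
#' `[sum(clint_cyp * abundance) + clint_hlm_additional] * MPPGL * liver_g`,
#' plus the biliary contribution `biliary_clint * HPGL * liver_g`, all
#' converted from µL/min to L/h. Microsomal binding is taken as unity.
#'
#' @param compound A [compound_params()].
#' @param subject A `subject_physiology`.
#' @return List with `metabolic` and `biliary` intrinsic clearances (L/h).
#' @export
ivive_hepatic_clint <- function(compound, subject) {
  iso <- intersect(names(compound$clint_cyp), names(subject$cyp_abundance))
  per_mg <- sum(compound$clint_cyp[iso] * subject$cyp_abundance[iso]) +
    compound$clint_hlm_additional # uL/min/mg microsomal protein
  liver_g <- subject$liver_weight * 1000
  ul_min_to_l_h <- 60 / 1e6
  list(
    metabolic = per_mg * subject$MPPGL * liver_g * ul_min_to_l_h,
    biliary = compound$biliary_clint * subject$HPGL * liver_g * ul_min_to_l_h)
}

#' Well-stirred hepatic clearance
#'
#' `CL_H = Q_H * fu_b * CLint_u / (Q_H + fu_b * CLint_u)` (blood-referenced),
#' with `fu_b = fu_plasma / (B/P)`.
#'
#' @param q_h Hepatic blood flow (L/h), > 0.
#' @param fu_blood Unbound fraction in blood.
#' @param clint_u Unbound intrinsic clearance (L/h).
#' @return Hepatic blood clearance (L/h).
#' @export
hepatic_clearance_well_stirred <- function(q_h, fu_blood, clint_u) {
  if (q_h <= 0) stop("q_h must be > 0")
  if (fu_blood < 0 || clint_u < 0) stop("inputs must be >= 0")
  x <- fu_blood * clint_u
  q_h * x / (q_h + x)
}

#' Whole-organ metabolic clearance for the metabolite (WOMC)
#'
#' IVIVE of the M1 microsomal + cytosolic intrinsic clearance through the
#' well-stirred liver embedded in the lumped minimal-PBPK model:
#' HLM CLint scales by MPPGL, HLC CLint by CPPGL (mg cytosolic protein per g
#' liver), then the well-stirred equation with the subject's hepatic flow.
#'
#' @param metabolite A [metabolite_params()].
#' @param subject A `subject_physiology`.
#' @return Hepatic blood clearance of the metabolite (L/h).
#' @export
womc_clearance <- function(metabolite, subject) {
  liver_g <- subject$liver_weight * 1000
  ul_min_to_l_h <- 60 / 1e6
  clint <- (metabolite$clint_hlm * subject$MPPGL +
              metabolite$clint_hlc * subject$CPPGL) * liver_g * ul_min_to_l_h
  q_h <- hepatic_flow(subject)
  hepatic_clearance_well_stirred(q_h, metabolite$fu / metabolite$bp, clint)
}

#' Total hepatic blood inflow (hepatic artery + portal drainage)
#' @param subject A `subject_physiology`.
#' @return Q_H (L/h).
#' @export
hepatic_flow <- function(subject) {
  unname(subject$organ_flows[["liver"]] + subject$organ_flows[["gut"]] +
           subject$organ_flows[["spleen"]])
}
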