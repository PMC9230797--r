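#' pH-dependent solubility profile of a weak base
#'
#' Two modes. `"interpolated"` (default): log10(solubility) is
#' piecewise-linear in pH through anchor points, clamped beyond the anchored
#' range. The shipped tegoprazan anchors are 223 mg/mL at pH 1, 0.7 mg/mL at
#' pH 3 and 0.02 mg/mL at pH 6.8. `"henderson_hasselbalch"`:
#' `S(pH) = S_int * (1 + 10^(pKa - pH))` for a monoprotic base. The anchored
#' points are not Henderson-Hasselbalch-consistent for pKa 5.1, which is why
#' interpolation is the default.
#'
#' @param anchors Data frame with columns `ph` and `solubility` (mg/mL),
#'   sorted by pH, solubilities > 0 and non-increasing with pH.
#' @param mode `"interpolated"` or `"henderson_hasselbalch"`.
#' @param intrinsic_solubility Intrinsic (neutral-form) solubility (mg/mL),
#'   HH mode only.
#' @param pka Basic pKa, HH mode only.
#' @return An object of class `solubility_profile`.
#' @export
solubility_profile <- function(anchors = data.frame(
                                 ph = c(1, 3, 6.8),
                                 solubility = c(223, 0.7, 0.02)),
                               mode = c("interpolated", "henderson_hasselbalch"),
                               intrinsic_solubility = NULL, pka = NULL) {
  mode <- match.arg(mode)
  if (mode == "interpolated") {
    if (is.null(anchors) || nrow(anchors) == 0)
      stop("config error: interpolated mode needs at least one anchor point")
    if (is.unsorted(anchors$ph, strictly = TRUE))
      stop("anchors must be sorted by pH")
    if (any(anchors$solubility <= 0)) stop("anchor solubilities must be > 0")
    if (any(diff(anchors$solubility) > 0))
      stop("solubility of a base must be non-increasing with pH")
  } else {
    if (is.null(intrinsic_solubility) || is.null(pka))
      stop("HH mode needs intrinsic_solubility and pka")
  }
  structure(list(anchors = anchors, mode = mode,
                 intrinsic_solubility = intrinsic_solubility, pka = pka),
            class = "solubility_profile")
}

#' Solubility at a given pH
#'
#' @param profile A [solubility_profile()].
#' @param ph pH in `[0, 9]`; vectorized.
#' @return Solubility (mg/mL).
#' @export
solubility_at_ph <- function(profile, ph) {
  stopifnot(inherits(profile, "solubility_profile"))
  if (any(ph < 0 | ph > 9)) stop("pH must be in [0, 9]")
  if (profile$mode == "henderson_hasselbalch") {
    return(profile$intrinsic_solubility * (1 + 10^(profile$pka - ph)))
  }
  a <- profile$anchors
  logs <- stats::approx(a$ph, log10(a$solubility), xout = ph, rule = 2)$y
  10^logs
}

#' Formulation parameters for an immediate-release solid oral dose
#'
#' Diffusion-layer-model inputs for a film-coated immediate-release tablet
#' releasing a monodisperse particle population. Defaults are the standard
#' simulator-style values (the source publication used unreported simulator
#' defaults): radius 30 µm, density 1.2 g/mL, aqueous diffusion coefficient
#' 9.0e-6 cm²/s, supersaturation ratio 10, precipitation rate 4/h.
#'
#' @param dose_mg Dose (mg), > 0.
#' @param particle_radius_um Initial particle radius (µm).
#' @param particle_density Particle true density (g/mL).
#' @param diffusion_coeff Aqueous diffusion coefficient (cm²/s).
#' @param supersaturation_ratio Maximum supersaturation (>= 1).
#' @param precipitation_rate First-order precipitation rate (1/h).
#' @param bile_solubilization Multiplicative solubility enhancement per mM
#'   bile salt above fasted baseline (default 0 = off).
#' @return An object of class `formulation_params`.
#' @export
formulation_params <- function(dose_mg = 100, particle_radius_um = 30,
                               particle_density = 1.2,
                               diffusion_coeff = 9.0e-6,
                               supersaturation_ratio = 10,
                               precipitation_rate = 4,
                               bile_solubilization = 0) {
  if (dose_mg < 0) stop("dose_mg must be >= 0")
  if (particle_radius_um <= 0 || particle_density <= 0 || diffusion_coeff <= 0)
    stop("particle radius, density and diffusion coefficient must be > 0")
  if (supersaturation_ratio < 1) stop("supersaturation_ratio must be >= 1")
  if (precipitation_rate < 0) stop("precipitation_rate must be >= 0")
  structure(list(dose_mg = dose_mg, particle_radius_um = particle_radius_um,
                 particle_density = particle_density,
                 diffusion_coeff = diffusion_coeff,
                 supersaturation_ratio = supersaturation_ratio,
                 precipitation_rate = precipitation_rate,
                 bile_solubilization = bile_solubilization),
            class = "formulation_params")
}

#' Diffusion-layer-model dissolution rate (Nernst-Brunner)
#'
#' `rate = 3 D M / (rho r h) * (S_surface - C_bulk)` for monodisperse
#' shrinking spheres, with current radius `r = r0 * (M / M_ref)^(1/3)` and
#' diffusion-layer thickness `h = min(r, 30 um)`. A negative driving force
#' (bulk above solubility) does not dissolve "backwards" here; precipitation
#' is handled separately at the formulation's first-order precipitation rate.
#'
#' @param solid_mg Undissolved mass in the segment (mg), `>= 0`.
#' @param dissolved_conc Bulk dissolved concentration (mg/mL).
#' @param solubility Surface solubility at segment pH (mg/mL).
#' @param formulation A [formulation_params()].
#' @param ref_mass_mg Mass at which the particle radius equals the initial
#'   radius (default: the dose).
#' @return Dissolution rate (mg/h), `>= 0`.
#' @export
dissolution_rate_dlm <- function(solid_mg, dissolved_conc, solubility,
                                 formulation,
                                 ref_mass_mg = formulation$dose_mg) {
  if (solid_mg <= 0 || ref_mass_mg <= 0) return(0)
  r0 <- formulation$particle_radius_um * 1e-4 # cm
  r <- r0 * (solid_mg / ref_mass_mg)^(1 / 3)
  h <- min(r, 30e-4) # cm
  D <- formulation$diffusion_coeff * 3600 # cm^2/h
  rho <- formulation$particle_density * 1000 # mg/cm^3
  drive <- solubility - dissolved_conc # mg/mL = mg/cm^3
  if (drive <= 0) return(0)
  3 * D * solid_mg / (rho * r * h) * drive
}

#' Effective human jejunal permeability from Caco-2 permeability
#'
#' Either a log-linear calibration `log10(Peff) = a + b*log10(Papp)` (both in
#' cm/s) or, in the default pass-through mode, the optimized effective
#' permeability supplied in the compound configuration (for tegoprazan the
#' model-final value 1.00e-4 cm/s).
#'
#' @param papp_caco2 Caco-2 apparent permeability (cm/s), > 0.
#' @param calibration `NULL`, or list with `a`, `b`.
#' @param optimized_peff Optimized Peff (cm/s) used in pass-through mode.
#' @return Effective permeability (cm/s).
#' @export
peff_from_papp <- function(papp_caco2, calibration = NULL,
                           optimized_peff = NULL) {
  if (!is.null(calibration)) {
    if (papp_caco2 <= 0) stop("papp_caco2 must be > 0")
    return(10^(calibration$a + calibration$b * log10(papp_caco2)))
  }
  if (is.null(optimized_peff))
    stop("config error: need either a calibration or an optimized Peff")
  optimized_peff
}
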