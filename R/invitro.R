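#' In-vitro assay containers
#'
#' Lightweight S3 containers for the three in-vitro assay types consumed by
#' the clearance/permeability calculators: substrate-depletion incubations in
#' human liver microsomes (HLM), Caco-2 bidirectional transport, and
#' recombinant-CYP (rCYP) depletion.
#'
#' @param timepoints Sampling times (min), strictly increasing, starting at 0.
#' @param percent_remaining Percent of the t = 0 concentration remaining at
#'   each timepoint (100 at t = 0 by construction). A matrix with one column
#'   per replicate is accepted; a vector is treated as a single replicate.
#' @param protein_conc Microsomal protein concentration (mg/mL), > 0.
#' @param incubation_volume Incubation volume (µL), > 0.
#' @return An object of class `depletion_assay`.
#' @export
depletion_assay <- function(timepoints, percent_remaining,
                            protein_conc, incubation_volume = 160) {
  timepoints <- as.numeric(timepoints)
  pr <- as.matrix(percent_remaining)
  if (length(timepoints) != nrow(pr))
    stop("timepoints and percent_remaining must have matching length")
  if (timepoints[1] != 0 || any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing and start at 0")
  if (!is.numeric(protein_conc) || protein_conc <= 0)
    stop("protein_conc must be > 0 (mg/mL)")
  if (incubation_volume <= 0) stop("incubation_volume must be > 0 (uL)")
  structure(
    list(timepoints = timepoints, percent_remaining = pr,
         protein_conc = protein_conc, incubation_volume = incubation_volume),
    class = "depletion_assay")
}

#' @rdname depletion_assay
#' @param direction `"AtoB"` (apical to basolateral) or `"BtoA"`.
#' @param times Collection times (min).
#' @param cumulative_amount Cumulative transported amount (nmol) at each
#'   collection time; matrix columns are replicates. Must be non-decreasing.
#' @param donor_conc Donor concentration (µM), > 0.
#' @param insert_area Insert filter area (cm²), > 0. Default 1.12 cm²
#'   (standard 12-well Transwell format).
#' @return An object of class `transport_assay`.
#' @export
transport_assay <- function(direction = c("AtoB", "BtoA"), times,
                            cumulative_amount, donor_conc, insert_area = 1.12) {
  direction <- match.arg(direction)
  times <- as.numeric(times)
  ca <- as.matrix(cumulative_amount)
  if (length(times) != nrow(ca))
    stop("times and cumulative_amount must have matching length")
  if (any(apply(ca, 2, function(x) any(diff(x) < 0))))
    stop("cumulative_amount must be non-decreasing within each replicate")
  if (donor_conc <= 0) stop("donor_conc must be > 0 (uM)")
  if (insert_area <= 0) stop("insert_area must be > 0 (cm^2)")
  structure(
    list(direction = direction, times = times, cumulative_amount = ca,
         donor_conc = donor_conc, insert_area = insert_area),
    class = "transport_assay")
}

#' @rdname depletion_assay
#' @param isoform CYP isoform name, e.g. `"CYP3A4"`.
#' @param cyp_amount Total CYP in the incubation (pmol), > 0.
#' @return An object of class `rcyp_assay` (inherits `depletion_assay` so the
#'   depletion-rate fitter applies unchanged).
#' @export
rcyp_assay <- function(isoform, timepoints, percent_remaining, cyp_amount,
                       incubation_volume = 1400) {
  if (cyp_amount <= 0) stop("cyp_amount must be > 0 (pmol)")
  obj <- depletion_assay(timepoints, percent_remaining,
                         protein_conc = 1, # unused for rCYP scaling
                         incubation_volume = incubation_volume)
  obj$isoform <- isoform
  obj$cyp_amount <- cyp_amount
  class(obj) <- c("rcyp_assay", "depletion_assay")
  obj
}

#' First-order depletion rate from a substrate-depletion series
#'
#' Fits ln(percent remaining) against time by ordinary least squares over all
#' points with a positive remaining fraction (the terminal slope equals the
#' full-series slope for a mono-exponential). Replicates are pooled into one
#' regression.
#'
#' @param assay A [depletion_assay()] or [rcyp_assay()].
#' @return First-order depletion rate constant k (1/min), `>= 0`.
#' @export
fit_depletion_rate <- function(assay) {
  stopifnot(inherits(assay, "depletion_assay"))
  t <- rep(assay$timepoints, ncol(assay$percent_remaining))
  y <- as.vector(assay$percent_remaining)
  pos <- y > 0
  if (any(!pos))
    warning(sum(!pos), " non-positive remaining value(s) excluded from fit")
  t <- t[pos]; y <- y[pos]
  if (length(unique(t)) < 3)
    stop("invalid assay: fewer than 3 usable timepoints")
  fit <- stats::lm.fit(cbind(1, t), log(y))
  max(0, -unname(fit$coefficients[2]))
}

#' Microsomal intrinsic clearance from a depletion rate (Eq. CLint = k / C)
#'
#' Scales the first-order depletion rate constant by the microsomal protein
#' concentration: `CLint = k / protein_conc` with protein concentration in
#' mg/µL, giving µL/min/mg protein. With 0.5 mg/mL protein, k = 0.00798/min
#' gives 15.96 µL/min/mg (the tegoprazan HLM value).
#'
#' @param k First-order depletion rate (1/min), `>= 0`.
#' @param protein_conc Microsomal protein concentration (mg/mL), > 0.
#' @return Intrinsic clearance (µL/min/mg protein).
#' @export
clint_microsomal <- function(k, protein_conc) {
  if (k < 0) stop("k must be >= 0")
  if (protein_conc <= 0) stop("protein_conc must be > 0 (mg/mL)")
  k / (protein_conc / 1000) # mg/mL -> mg/uL
}

#' Recombinant-CYP intrinsic clearance (per pmol CYP)
#'
#' `CLint = (0.693 / t_half) * (1400 / cyp_amount)` with the fixed 1400 µL
#' incubation volume of the rCYP depletion assay; units µL/min/pmol CYP.
#' An infinite half-life (no depletion) returns 0.
#'
#' @param t_half Depletion half-life (min), > 0 (may be `Inf`).
#' @param cyp_amount Total CYP in the incubation (pmol), > 0.
#' @return Intrinsic clearance (µL/min/pmol CYP).
#' @export
clint_rcyp <- function(t_half, cyp_amount) {
  if (cyp_amount <= 0) stop("cyp_amount must be > 0 (pmol)")
  if (is.infinite(t_half)) return(0)
  if (!is.finite(t_half) || t_half <= 0) stop("t_half must be > 0 (min)")
  (0.693 / t_half) * (1400 / cyp_amount)
}

#' Apparent permeability from a Caco-2 transport assay
#'
#' The transport rate is the OLS slope of cumulative transported amount (nmol)
#' versus time; `Papp = rate / (donor_conc * area)` converted to cm/s
#' (donor concentration in nmol/cm³ = µM). Replicates are fitted separately;
#' the per-replicate values, their mean and SD are returned.
#'
#' @param assay A [transport_assay()].
#' @return A list with elements `papp` (per-replicate, cm/s), `mean`, `sd`,
#'   and `transport_rate` (nmol/min per replicate).
#' @export
papp <- function(assay) {
  stopifnot(inherits(assay, "transport_assay"))
  if (length(assay$times) < 3) stop("need >= 3 collection times")
  rates <- apply(assay$cumulative_amount, 2, function(y) {
    unname(stats::lm.fit(cbind(1, assay$times), y)$coefficients[2])
  })
  papp_vals <- vapply(rates, function(r) {
    if (r <= 0) {
      warning("non-positive transport rate; Papp set to 0")
      return(0)
    }
    # nmol/min / (nmol/cm^3 * cm^2) = cm/min -> cm/s
    r / (assay$donor_conc * assay$insert_area) / 60
  }, numeric(1))
  list(papp = papp_vals, mean = mean(papp_vals),
       sd = stats::sd(papp_vals), transport_rate = rates)
}

#' Efflux ratio from bidirectional permeabilities
#'
#' @param papp_BA Basolateral-to-apical Papp (cm/s).
#' @param papp_AB Apical-to-basolateral Papp (cm/s), > 0.
#' @return `papp_BA / papp_AB` (dimensionless). Values below 2 indicate
#'   negligible efflux-transporter involvement.
#' @export
efflux_ratio <- function(papp_BA, papp_AB) {
  if (papp_AB <= 0) stop("undefined efflux ratio: papp_AB must be > 0")
  papp_BA / papp_AB
}
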