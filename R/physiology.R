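#' Reference adult physiology
#'
#' Organ volumes, regional blood flows, hepatic scaling factors and CYP
#' abundances of a healthy-adult reference subject (70 kg), assembled from
#' standard published human population values and fully overridable. Cardiac
#' output is the sum of the regional flows; the lung receives the total.
#'
#' @param body_weight Body weight (kg).
#' @param sex `"M"` or `"F"` (metadata only in the reference subject).
#' @param age Age (years).
#' @return An object of class `subject_physiology` with elements:
#'   `organ_volumes` (L), `organ_flows` (L/h), `liver_weight` (kg),
#'   `MPPGL` (mg microsomal protein/g liver), `CPPGL` (mg cytosolic
#'   protein/g liver), `HPGL` (10^6 hepatocytes/g liver),
#'   `cyp_abundance` (pmol/mg microsomal protein), `hematocrit`,
#'   `cardiac_output` (L/h).
#' @export
reference_physiology <- function(body_weight = 70, sex = "M", age = 30) {
  volumes <- c(adipose = 14.5, bone = 10.5, brain = 1.45, gut = 1.65,
               heart = 0.33, kidney = 0.31, liver = 1.65, lung = 0.53,
               muscle = 29.0, skin = 3.1, spleen = 0.19)
  flows <- c(adipose = 19.5, bone = 19.5, brain = 46.8, gut = 58.5,
             heart = 15.6, kidney = 74.1, liver = 25.35, # hepatic artery
             muscle = 66.3, skin = 19.5, spleen = 11.7)
  structure(list(
    sex = sex, age = age, body_weight = body_weight,
    organ_volumes = volumes,
    organ_flows = flows,
    blood_volume = 5.1, # L; venous 2/3, arterial 1/3
    cardiac_output = sum(flows),
    liver_weight = 1.65,
    MPPGL = 40, CPPGL = 80.7, HPGL = 120,
    cyp_abundance = c(CYP3A4 = 137, CYP2C19 = 14, CYP2C8 = 24,
                      CYP2C9 = 73, CYP2D6 = 8, CYP2E1 = 61),
    hematocrit = 0.45),
    class = "subject_physiology")
}

#' Sample a virtual population
#'
#' Draws `n` virtual subjects around the reference physiology with independent
#' log-normal inter-individual variability (mean preserved on the natural
#' scale) on body weight, organ volumes, flows, MPPGL and CYP abundances.
#' Organ volumes and flows additionally scale with body weight (allometric
#' exponent 1 for volumes, 0.75 for flows). Demographics (age range, sex
#' ratio) follow the virtual-trial design: ages uniform on the configured
#' range, male:female 1:1.
#'
#' @param n Number of subjects, > 0.
#' @param seed Integer seed; the draw is deterministic given `(n, seed, cv)`.
#' @param cv Named list/vector of coefficients of variation (fractions), with
#'   any of `body_weight`, `volumes`, `flows`, `MPPGL`, `cyp`. All `>= 0`.
#' @param age_range Age range (years), default 20-40.
#' @param reference Reference subject, default [reference_physiology()].
#' @return A list of `subject_physiology` objects.
#' @export
sample_population <- function(n, seed,
                              cv = c(body_weight = 0.15, volumes = 0.15,
                                     flows = 0.15, MPPGL = 0.3, cyp = 0.4),
                              age_range = c(20, 40),
                              reference = reference_physiology()) {
  if (n <= 0) stop("n must be > 0")
  cv_full <- c(body_weight = 0.15, volumes = 0.15, flows = 0.15,
               MPPGL = 0.3, cyp = 0.4)
  cv_full[names(cv)] <- unlist(cv)
  if (any(cv_full < 0)) stop("config error: CV must be >= 0")
  rlnorm_mean1 <- function(k, cvi) {
    if (cvi == 0) return(rep(1, k))
    sdlog <- sqrt(log(1 + cvi^2))
    stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  with_local_seed <- function(expr) { # restore caller RNG state afterwards
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  with_local_seed({
    lapply(seq_len(n), function(i) {
      s <- reference
      s$sex <- if (i %% 2 == 1) "M" else "F"
      s$age <- stats::runif(1, age_range[1], age_range[2])
      bw_mult <- rlnorm_mean1(1, cv_full[["body_weight"]])
      s$body_weight <- reference$body_weight * bw_mult
      vol_mult <- rlnorm_mean1(length(s$organ_volumes), cv_full[["volumes"]])
      s$organ_volumes <- reference$organ_volumes * bw_mult * vol_mult
      flow_mult <- rlnorm_mean1(length(s$organ_flows), cv_full[["flows"]])
      s$organ_flows <- reference$organ_flows * bw_mult^0.75 * flow_mult
      s$blood_volume <- reference$blood_volume * bw_mult
      s$cardiac_output <- sum(s$organ_flows)
      s$liver_weight <- s$organ_volumes[["liver"]] # density ~1 kg/L
      s$MPPGL <- reference$MPPGL * rlnorm_mean1(1, cv_full[["MPPGL"]])
      s$cyp_abundance <- reference$cyp_abundance *
        rlnorm_mean1(length(reference$cyp_abundance), cv_full[["cyp"]])
      s
    })
  })
}

#' Gastrointestinal physiology (nine segments)
#'
#' Segment geometry, baseline pH, luminal fluid volumes, transit rates and
#' bile-salt concentrations for the compartmental absorption-transit model:
#' stomach, duodenum, jejunum I-II, ileum I-IV, colon. Defaults are standard
#' fasted human values; the fasted gastric mean residence time is 0.4 h and
#' the gastric baseline pH equals the PD module's default baseline (1.49).
#'
#' @param prandial_state `"fasted"` or `"fed"`. Construct fed physiology via
#'   [fed_state_adjust()] rather than directly.
#' @return An object of class `gi_physiology`: a list with a `segments`
#'   data.frame (`segment`, `baseline_ph`, `volume_ml`, `transit_rate`
#'   (1/h), `radius_cm`, `surface_enhancement`, `length_cm`,
#'   `bile_salt_mM`), `prandial_state`, and fed-state pH dynamics fields
#'   (`gastric_ph_initial`, `gastric_ph_return_rate`).
#' @export
gi_physiology <- function(prandial_state = "fasted") {
  if (!identical(prandial_state, "fasted"))
    stop("construct fed physiology with fed_state_adjust()")
  seg <- data.frame(
    segment = c("stomach", "duodenum", "jejunum1", "jejunum2",
                "ileum1", "ileum2", "ileum3", "ileum4", "colon"),
    baseline_ph = c(1.49, 6.0, 6.2, 6.4, 6.6, 6.9, 7.1, 7.4, 6.4),
    volume_ml = c(46, 42, 78, 78, 53, 45, 38, 30, 50),
    transit_rate = c(1 / 0.4, 1 / 0.26, 1 / 0.95, 1 / 0.76,
                     1 / 0.59, 1 / 0.43, 1 / 0.31, 1 / 0.26, 1 / 13.5),
    radius_cm = c(NA, 2.0, 1.75, 1.6, 1.5, 1.4, 1.3, 1.2, 2.5),
    surface_enhancement = c(0, 10, 10, 10, 10, 10, 10, 10, 1),
    length_cm = c(NA, 30, 60, 60, 60, 60, 60, 45, 150),
    bile_salt_mM = c(0, 3, 2, 2, 1, 1, 1, 1, 0),
    stringsAsFactors = FALSE)
  structure(list(segments = seg, prandial_state = "fasted",
                 gastric_ph_initial = seg$baseline_ph[1],
                 gastric_ph_return_rate = 0),
            class = "gi_physiology")
}

#' Fed-state adjustment of GI physiology
#'
#' Converts fasted GI physiology into the state 30 min after a high-fat meal:
#' gastric emptying is slowed so the mean gastric residence time is 2.704x
#' the fasted value (a 170.4% increase), the gastric pH starts elevated by
#' the meal buffer and returns first-order to the fasted baseline, and
#' bile-salt concentrations rise in the upper small intestine. All other
#' fields are unchanged.
#'
#' @param physiology A fasted [gi_physiology()].
#' @param meal `"high_fat"` (default) or `"none"` (returns input unchanged).
#' @param mrt_factor Multiplier on gastric mean residence time; default 2.704.
#' @param gastric_ph_initial Fed initial gastric pH; default 4.5.
#' @param gastric_ph_return_rate First-order return rate to fasted baseline
#'   (1/h); default 0.693 (1 h half-life).
#' @return A fed-state `gi_physiology`.
#' @export
fed_state_adjust <- function(physiology, meal = c("high_fat", "none"),
                             mrt_factor = 2.704,
                             gastric_ph_initial = 4.5,
                             gastric_ph_return_rate = 0.693) {
  stopifnot(inherits(physiology, "gi_physiology"))
  meal <- match.arg(meal)
  if (meal == "none") return(physiology)
  if (physiology$prandial_state != "fasted")
    stop("physiology is already in the fed state")
  fed <- physiology
  fed$segments$transit_rate[1] <- physiology$segments$transit_rate[1] / mrt_factor
  fed$segments$bile_salt_mM <- physiology$segments$bile_salt_mM *
    ifelse(physiology$segments$segment %in%
             c("duodenum", "jejunum1", "jejunum2"), 5, 1)
  fed$gastric_ph_initial <- gastric_ph_initial
  fed$gastric_ph_return_rate <- gastric_ph_return_rate
  fed$prandial_state <- "fed"
  fed
}
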