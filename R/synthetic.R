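#' Generate a synthetic observed PK dataset
#'
#' Emulates the structure of the clinical dataset the verification stage
#' assumes: n subjects, a single oral dose, sparse sampling at the clinical
#' schedule, proportional log-normal residual error and LLOQ censoring.
#' Subjects are drawn from the virtual population generator, simulated with
#' the full coupled model, and sampled at the schedule. The generating truth
#' (per-subject parameter multipliers are implicit in the returned subjects;
#' the master seed, error model and noiseless values) is returned alongside.
#'
#' @param n_subjects Number of subjects (clinical design: 12).
#' @param dose_mg Dose (mg), default 100.
#' @param schedule Sampling times (h); default the clinical schedule
#'   0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 48.
#' @param cv Proportional residual error CV (fraction), default 0.15.
#' @param lloq Lower limit of quantification (ng/mL); values below are set
#'   `NA` and flagged censored. Default 0 (no censoring).
#' @param seed Master seed; the dataset is byte-reproducible given
#'   `(arguments, seed)`.
#' @param ... Passed to [simulate_subject()] / [sample_population()]
#'   consumers: `compound`, `pd`, `feedback`, `population_cv`.
#' @param population_cv CV table for [sample_population()].
#' @return List with `data` (data.frame: `subject_id`, `time_h`, `analyte`,
#'   `conc_ng_ml`, `censored`, `dose_mg`, `lloq`), `truth` (list: seed,
#'   error model, noiseless concentrations, subjects), `n_censored`.
#' @export
generate_observed_pk <- function(n_subjects = 12, dose_mg = 100,
                                 schedule = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4,
                                              6, 8, 12, 24, 48),
                                 cv = 0.15, lloq = 0, seed = 1,
                                 population_cv = c(body_weight = 0.15,
                                                   volumes = 0.15,
                                                   flows = 0.15,
                                                   MPPGL = 0.3, cyp = 0.4),
                                 ...) {
  if (cv < 0) stop("cv must be >= 0")
  regimen <- dosing_regimen(dose_mg, 0)
  horizon <- max(schedule)
  if (horizon > max(regimen$times) + 48)
    stop("schedule extends beyond the simulation horizon")
  pop <- sample_population(n_subjects, seed = seed, cv = population_cv)
  dots <- list(...)
  if (is.null(dots$kp_scalar)) {
    cmp <- if (!is.null(dots$compound)) dots$compound else compound_params()
    dots$kp_scalar <- if (!is.null(cmp$kp_scalar)) cmp$kp_scalar
      else as.numeric(calibrate_kp_scalar(cmp))
  }

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 104729L)

  rows <- list(); truth_conc <- list()
  for (i in seq_len(n_subjects)) {
    r <- do.call(simulate_subject,
                 c(list(subject = pop[[i]], regimen = regimen), dots))
    for (analyte in c("tegoprazan", "M1")) {
      cp <- if (analyte == "tegoprazan") r$cp_parent else r$cp_m1
      true_c <- stats::approx(r$time, cp, xout = schedule, rule = 2)$y
      eps <- if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        stats::rlnorm(length(schedule), -sdlog^2 / 2, sdlog)
      } else rep(1, length(schedule))
      obs <- true_c * eps
      censored <- obs < lloq
      obs[censored] <- NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = i, time_h = schedule, analyte = analyte,
        conc_ng_ml = obs, censored = censored,
        dose_mg = dose_mg, lloq = lloq, stringsAsFactors = FALSE)
      truth_conc[[paste(i, analyte)]] <- true_c
    }
  }
  data <- do.call(rbind, rows)
  list(data = data,
       truth = list(seed = seed, cv = cv, lloq = lloq, schedule = schedule,
                    noiseless = truth_conc, subjects = pop),
       n_censored = sum(data$censored))
}

#' Generate a synthetic 24-h gastric pH recording
#'
#' Integrates the indirect-response pH model driven by a supplied plasma
#' concentration profile and adds iid Gaussian measurement noise (clamped to
#' pH > 0). The generating parameters are returned as the truth record.
#'
#' @param baseline A [fourier_baseline()].
#' @param pd A [pd_params()] (the generating truth).
#' @param pk_times,pk_conc Driving plasma concentration profile (h, ng/mL).
#' @param noise_sd Gaussian noise SD (pH units), default 0.
#' @param sampling Sampling interval (h), default 0.25 (15 min).
#' @param horizon Recording length (h), default 24.
#' @param seed Seed for the noise draw.
#' @return List with `times`, `ph`, `truth` (baseline, pd, seed, noise_sd).
#' @export
generate_ph_series <- function(baseline, pd, pk_times, pk_conc,
                               noise_sd = 0, sampling = 0.25, horizon = 24,
                               seed = 1) {
  if (max(pk_times) < horizon)
    stop("pk profile must cover the recording horizon")
  cp_fun <- stats::approxfun(pk_times, pk_conc, rule = 2)
  times <- seq(0, horizon, by = sampling)
  r0 <- baseline_ph(baseline, 0)
  if (pd$mode == "as_printed") r0 <- 2 * (pd$k_in / pd$k_out) * r0
  rhs <- function(t, y, parms) {
    base <- baseline_ph(baseline, t)
    eff <- ph_effect(pd, base, cp_fun(t))
    list(pd_rhs(pd, y[1], eff, base))
  }
  out <- deSolve::lsoda(c(R = r0), times, rhs, rtol = 1e-9, atol = 1e-9)
  ph <- out[, "R"]
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    ph <- pmax(ph + stats::rnorm(length(ph), 0, noise_sd), 1e-6)
  }
  list(times = times, ph = as.numeric(ph),
       truth = list(baseline = baseline, pd = pd, noise_sd = noise_sd,
                    seed = seed))
}
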