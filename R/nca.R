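#' Non-compartmental analysis of a concentration-time profile
#'
#' AUC by the linear-up/log-down trapezoid rule (configurable to pure
#' linear), terminal slope by log-linear regression on the terminal points
#' (best adjusted-R^2 subset of the last points after Cmax, minimum 3), and
#' the usual derived quantities. If the terminal slope is not estimable
#' (fewer than 3 positive post-peak points, or a non-negative slope),
#' `auc_inf`, `cl_f`, and `t_half` are returned as `NA` rather than
#' fabricated.
#'
#' @param time Sampling times (h).
#' @param conc Concentrations (ng/mL), same length.
#' @param dose_mg Administered dose (mg) for CL/F.
#' @param method `"linear_up_log_down"` (default) or `"linear"`.
#' @return An object of class `pk_summary`: `auc_0_t` (ng*h/mL), `auc_inf`,
#'   `cmax`, `tmax` (earliest time attaining Cmax), `cl_f` (L/h),
#'   `t_half` (h), `lambda_z` (1/h), `n_lambda_z`.
#' @export
nca <- function(time, conc, dose_mg = NA,
                method = c("linear_up_log_down", "linear")) {
  method <- match.arg(method)
  if (length(time) != length(conc)) stop("time and conc must match in length")
  keep <- is.finite(time) & is.finite(conc)
  time <- time[keep]; conc <- conc[keep]
  o <- order(time); time <- time[o]; conc <- conc[o]
  if (length(conc) < 3 || !any(conc > 0))
    stop("need at least 3 samples with a positive concentration")

  auc <- 0
  for (i in seq_len(length(time) - 1)) {
    dt <- time[i + 1] - time[i]
    c1 <- conc[i]; c2 <- conc[i + 1]
    if (method == "linear" || c2 >= c1 || c2 <= 0 || c1 <= 0) {
      auc <- auc + dt * (c1 + c2) / 2
    } else {
      auc <- auc + dt * (c1 - c2) / log(c1 / c2)
    }
  }

  cmax <- max(conc)
  tmax <- time[which.max(conc)] # which.max -> earliest tie

  # terminal slope: choose the best adjusted-R^2 tail among post-Cmax points
  i_max <- which.max(conc)
  cand <- which(seq_along(conc) > i_max & conc > 0)
  lambda_z <- NA_real_; n_lz <- 0L
  if (length(cand) >= 3) {
    best_adjr2 <- -Inf
    for (k in 3:length(cand)) {
      idx <- utils::tail(cand, k)
      ly <- log(conc[idx])
      fit <- stats::lm.fit(cbind(1, time[idx]), ly)
      sl <- -unname(fit$coefficients[2])
      sst <- sum((ly - mean(ly))^2)
      if (sst == 0) next
      r2 <- 1 - sum(fit$residuals^2) / sst
      adjr2 <- 1 - (1 - r2) * (k - 1) / (k - 2)
      if (sl > 0 && adjr2 > best_adjr2 + 1e-4) {
        best_adjr2 <- adjr2; lambda_z <- sl; n_lz <- k
      }
    }
  }

  c_last <- conc[max(which(conc > 0))]
  auc_inf <- if (is.finite(lambda_z)) auc + c_last / lambda_z else NA_real_
  cl_f <- if (!is.na(dose_mg) && is.finite(auc_inf))
    dose_mg * 1e6 / auc_inf / 1000 else NA_real_ # mg -> ng; ng/(ng*h/mL) -> L/h
  structure(list(auc_0_t = auc, auc_inf = auc_inf, cmax = cmax, tmax = tmax,
                 cl_f = cl_f,
                 t_half = if (is.finite(lambda_z)) log(2) / lambda_z else NA_real_,
                 lambda_z = lambda_z, n_lambda_z = n_lz),
            class = "pk_summary")
}

#' @export
print.pk_summary <- function(x, ...) {
  cat(sprintf(
    "NCA: AUC0-t %.4g ng*h/mL | AUCinf %.4g | Cmax %.4g ng/mL | Tmax %.3g h | CL/F %.4g L/h | t1/2 %.3g h\n",
    x$auc_0_t, x$auc_inf, x$cmax, x$tmax, x$cl_f, x$t_half))
  invisible(x)
}

#' Predicted/observed verification ratio with bootstrap CI
#'
#' `ratio = mean(predicted) / observed_mean`, with a nonparametric bootstrap
#' (resampling the predicted individual values, default 2000 resamples,
#' seeded) for the 95% CI of the ratio. The model-acceptance flag follows
#' the 0.7-1.3 criterion applied to the ratio and its CI.
#'
#' @param predicted Vector of individual predicted values (one per subject).
#' @param observed_mean Observed arithmetic mean, > 0.
#' @param parameter Parameter label (e.g. `"Cmax"`).
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return An object of class `ratio_report`: `parameter`, `predicted_mean`,
#'   `observed_mean`, `ratio`, `ci_95`, `pass`.
#' @export
ratio_report <- function(predicted, observed_mean, parameter = "",
                         n_boot = 2000, seed = 1) {
  if (length(predicted) == 0) stop("predicted set is empty")
  if (observed_mean <= 0) stop("observed_mean must be > 0")
  ratio <- mean(predicted) / observed_mean
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(predicted)
  boot <- vapply(seq_len(n_boot), function(i)
    mean(predicted[sample.int(n, n, replace = TRUE)]) / observed_mean,
    numeric(1))
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  structure(list(parameter = parameter, predicted_mean = mean(predicted),
                 observed_mean = observed_mean, ratio = ratio, ci_95 = ci,
                 pass = ratio >= 0.7 && ratio <= 1.3 &&
                   ci[1] >= 0.7 && ci[2] <= 1.3),
            class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf("%s: predicted %.4g / observed %.4g = %.2f (95%% CI %.2f-%.2f) %s\n",
              x$parameter, x$predicted_mean, x$observed_mean, x$ratio,
              x$ci_95[1], x$ci_95[2],
              if (x$pass) "PASS (0.7-1.3)" else "outside 0.7-1.3"))
  invisible(x)
}

#' Percent change from a to b
#'
#' `(b - a) / a * 100`; e.g. fasted Cmax 684.9 to fed 470.7 ng/mL is -31.3%.
#'
#' @param a Reference value, > 0.
#' @param b Comparison value.
#' @return Percent change.
#' @export
percent_change <- function(a, b) {
  if (a <= 0) stop("reference value must be > 0")
  (b - a) / a * 100
}
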