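# Green-Kubo shear viscosity: eta = V / (k_B T) * integral of the
# off-diagonal stress autocorrelation <P_ab(0) P_ab(t)> dt, averaged over
# the three independent off-diagonal components.

# multi-origin autocorrelation estimate of one series, lags 0..max_lag
acf_multi_origin <- function(x, max_lag) {
  n <- length(x)
  S <- corr_sums_fft(matrix(x, ncol = 1))[, 1]
  S[seq_len(max_lag + 1)] / (n - (0:max_lag))
}

#' Green-Kubo viscosity from an off-diagonal stress series
#'
#' Estimates the stress autocorrelation for each of pxy, pxz, pyz with all
#' time origins (FFT), averages the three, and integrates (trapezoid) up to
#' `t_upper`. By default `t_upper` is ten times the estimated correlation
#' time of the averaged ACF (capped at half the series length) — the
#' integral of a noisy single-trajectory ACF never truly converges, so the
#' running integral and a plateau diagnostic are always returned.
#'
#' Units: with stress in kcal mol^-1 A^-3, volume in A^3, time in ps, the
#' internal viscosity unit is kcal mol^-1 A^-3 ps; multiply by
#' `des_units()$mPas_per_internal_viscosity` (or pass `convert = TRUE`) for
#' mPa s.
#'
#' @param stress Tibble with columns `time` (ps), `pxy`, `pxz`, `pyz`.
#' @param volume Cell volume, A^3.
#' @param temperature Temperature, K.
#' @param t_upper Integration limit, ps; must be at most half the series
#'   duration.
#' @param convert Also report `eta_mPas` (default FALSE).
#' @return Object of class `viscosity_result`: `eta` (internal units),
#'   optionally `eta_mPas`, `t_upper`, `acf` tibble (`lag`, `acf`,
#'   `running_eta`), `tau_c` (ACF correlation-time estimate, ps),
#'   `plateau_drift` (relative drift of the running integral over the final
#'   quarter of the window).
#' @export
green_kubo_viscosity <- function(stress, volume, temperature, t_upper = NULL,
                                 convert = FALSE) {
  dt <- stress$time[2] - stress$time[1]
  n <- nrow(stress)
  max_lag <- floor((n - 1) / 2)
  C <- (acf_multi_origin(stress$pxy, max_lag) +
          acf_multi_origin(stress$pxz, max_lag) +
          acf_multi_origin(stress$pyz, max_lag)) / 3
  lags <- dt * (0:max_lag)
  if (all(C == 0)) {
    tau_c <- dt
  } else {
    # correlation time: integral of C/C(0) up to its first non-positive value
    stop_i <- which(C <= 0)[1]
    upto <- if (is.na(stop_i)) length(C) else max(2, stop_i - 1)
    tau_c <- max(trapz(lags[1:upto], C[1:upto] / C[1]), dt)
  }
  if (is.null(t_upper)) {
    t_upper <- min(10 * tau_c, lags[length(lags)])
  } else if (t_upper > dt * (n - 1) / 2 + 1e-9) {
    stop("range error: t_upper exceeds half the series duration")
  }
  res <- viscosity_from_acf(lags, C, volume, temperature, t_upper,
                            convert = convert)
  res$tau_c <- tau_c
  res
}

#' Green-Kubo integral of a given stress autocorrelation
#'
#' The integration core of [green_kubo_viscosity()], usable directly with
#' an analytic or externally estimated autocorrelation function.
#'
#' @param lags Lag times, ps (starting at 0, uniform).
#' @param acf_values Stress ACF at those lags.
#' @param volume,temperature,t_upper,convert As in
#'   [green_kubo_viscosity()].
#' @return A `viscosity_result`.
#' @export
viscosity_from_acf <- function(lags, acf_values, volume, temperature,
                               t_upper = max(lags), convert = FALSE) {
  keep <- lags <= t_upper + 1e-12
  u <- des_units()
  pref <- volume / (u$k_B * temperature)
  run <- c(0, cumsum(diff(lags[keep]) *
                       (utils::head(acf_values[keep], -1) +
                          utils::tail(acf_values[keep], -1)) / 2))
  eta_run <- pref * run
  eta <- eta_run[length(eta_run)]
  q3 <- eta_run[max(1, floor(0.75 * length(eta_run)))]
  drift <- if (abs(eta) > 0) abs(eta - q3) / abs(eta) else 0
  out <- list(eta = eta,
              t_upper = t_upper,
              acf = tibble::tibble(lag = lags[keep],
                                   acf = acf_values[keep],
                                   running_eta = eta_run),
              plateau_drift = drift)
  if (convert) out$eta_mPas <- eta * u$mPas_per_internal_viscosity
  structure(out, class = "viscosity_result")
}

#' @export
print.viscosity_result <- function(x, ...) {
  cat(sprintf(
    "<viscosity_result> eta = %.6g internal units (t_upper = %.4g ps, plateau drift %.1f%%)\n",
    x$eta, x$t_upper, 100 * x$plateau_drift))
  if (!is.null(x$eta_mPas)) cat(sprintf("  = %.6g mPa s\n", x$eta_mPas))
  invisible(x)
}

#' @export
glance.viscosity_result <- function(x, ...) {
  tibble::tibble(eta = x$eta,
                 eta_mPas = x$eta_mPas %||% NA_real_,
                 t_upper = x$t_upper,
                 tau_c = x$tau_c %||% NA_real_,
                 plateau_drift = x$plateau_drift)
}
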