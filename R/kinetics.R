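#' Normalize a 2D IR waiting-time series by a reference window
#'
#' Each waiting-time spectrum is divided by the absolute value of its own
#' integrated area over `norm_window` (conventionally a ~25 cm^-2 square on
#' the 1 -> 2 diagonal peak of the low-frequency component). This removes
#' vibrational population and orientational relaxation from the series so
#' that only relative redistribution remains.
#'
#' @param series a [spectrum2d_series()].
#' @param norm_window a [spectral_window()] inside both axis ranges.
#' @param floor_frac error floor: a window integral whose magnitude falls
#'   below `floor_frac * max(abs(matrix))` at any waiting time aborts with an
#'   error naming that `T_w`.
#' @return A normalized [spectrum2d_series()]; the per-`T_w` normalization
#'   factors are logged in `metadata$normalization_factors`.
#' @export
normalize_series <- function(series, norm_window, floor_frac = 1e-12) {
  stopifnot(inherits(series, "spectrum2d_series"),
            inherits(norm_window, "spectral_window"))
  factors <- numeric(length(series$waiting_times))
  mats <- series$matrices
  for (i in seq_along(mats)) {
    v <- abs(window_integral(series, mats[[i]], norm_window))
    if (v < floor_frac * max(abs(mats[[i]])))
      stop(sprintf("normalization window integral vanishes at T_w = %g ps",
                   series$waiting_times[i]))
    factors[i] <- v
    mats[[i]] <- mats[[i]] / v
  }
  out <- series
  out$matrices <- mats
  out$metadata$normalization_factors <-
    data.frame(waiting_time = series$waiting_times, factor = factors)
  out
}

#' Subtract the zero-waiting-time spectrum from a series
#'
#' Removes everything already present at `T_w = 0` (diagonal peaks and their
#' static tails), leaving the waiting-time-dependent changes; the `T_w = 0`
#' entry becomes identically zero and is retained.
#'
#' @param series a [spectrum2d_series()] containing `T_w = 0`.
#' @return A difference [spectrum2d_series()].
#' @export
subtract_reference <- function(series) {
  stopifnot(inherits(series, "spectrum2d_series"))
  i0 <- which(abs(series$waiting_times) < 1e-12)
  if (length(i0) != 1L)
    stop("series must contain exactly one T_w = 0 spectrum")
  ref <- series$matrices[[i0]]
  out <- series
  out$matrices <- lapply(series$matrices, function(m) m - ref)
  out$metadata$reference_subtracted <- TRUE
  out
}

#' Integrated cross-peak magnitude versus waiting time
#'
#' Two-dimensional trapezoidal integral of a (typically normalized and
#' reference-subtracted) series over `cross_window` at every waiting time.
#' Integrals are signed; the default window of the protocol is a 5x5 cm^-2
#' square at (pump = SHB fundamental, probe = WHB fundamental), i.e. the
#' SHB -> WHB exchange pathway.
#'
#' @param diff_series a [spectrum2d_series()] (usually from
#'   [subtract_reference()]).
#' @param cross_window a [spectral_window()] inside both axis ranges.
#' @return data.frame with columns `waiting_time` (ps) and `magnitude`.
#' @export
cross_peak_trace <- function(diff_series, cross_window) {
  stopifnot(inherits(diff_series, "spectrum2d_series"),
            inherits(cross_window, "spectral_window"))
  rng_tau <- range(diff_series$omega_tau)
  rng_t <- range(diff_series$omega_t)
  if (cross_window$tau_lo < rng_tau[1L] || cross_window$tau_hi > rng_tau[2L] ||
      cross_window$t_lo < rng_t[1L] || cross_window$t_hi > rng_t[2L])
    stop("cross window extends outside the 2D grid")
  mag <- vapply(diff_series$matrices,
                function(m) window_integral(diff_series, m, cross_window),
                numeric(1L))
  data.frame(waiting_time = diff_series$waiting_times, magnitude = mag)
}

#' Fit single-exponential exchange kinetics to a cross-peak trace
#'
#' Least-squares fit of `m(T_w) = A (1 - exp(-T_w / tau))`; the forward
#' exchange rate is reported as `k1 = 1/tau`. If a free-energy difference
#' and temperature are supplied, the reverse time constant is derived by
#' detailed balance (see [reverse_rate()]).
#'
#' @param trace data.frame with `waiting_time` and `magnitude` (>= 4 rows).
#' @param temperature_c optional temperature label, degC.
#' @param dG optional free-energy difference WHB - SHB, kJ mol^-1, used with
#'   `temperature_c` to derive the reverse rate.
#' @param tau_bounds allowed range for `tau`, ps; a converged `tau` on a
#'   bound is reported as an error with diagnostics.
#' @return An object of class `exchange_kinetics`: `tau_forward`, `tau_se`,
#'   `k_forward`, `amplitude`, and (when derivable) `tau_reverse`,
#'   `k_reverse`, `dG_used`.
#' @export
fit_exchange <- function(trace, temperature_c = NA_real_, dG = NULL,
                         tau_bounds = c(1e-3, 1e3)) {
  stopifnot(is.data.frame(trace),
            all(c("waiting_time", "magnitude") %in% names(trace)))
  if (nrow(trace) < 4L)
    stop("exchange fit needs >= 4 waiting times, got ", nrow(trace))
  tw <- trace$waiting_time
  m <- trace$magnitude
  a0 <- m[which.max(tw)]
  if (a0 == 0) a0 <- max(abs(m)) * sign(sum(m))
  if (a0 == 0) a0 <- 1
  half <- tw[which.min(abs(m - a0 / 2))]
  tau0 <- min(max(half / log(2), tau_bounds[1L] * 2), tau_bounds[2L] / 2)
  fit <- nls.lm(par = c(A = a0, tau = tau0),
                fn = function(p) m - p[1L] * (1 - exp(-tw / p[2L])),
                lower = c(-Inf, tau_bounds[1L]),
                upper = c(Inf, tau_bounds[2L]),
                control = nls.lm.control(maxiter = 400, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info == 0 || fit$info == 5)
    stop("exchange fit did not converge: ", fit$message)
  tau <- unname(fit$par[2L])
  if (tau <= tau_bounds[1L] * (1 + 1e-8) || tau >= tau_bounds[2L] / (1 + 1e-8))
    stop(sprintf(paste0("fitted tau = %.4g ps sits on the bound [%g, %g]; ",
                        "the trace is not a saturating exponential ",
                        "(amplitude %.4g, residual norm %.4g)"),
                 tau, tau_bounds[1L], tau_bounds[2L], fit$par[1L],
                 sqrt(fit$deviance)))
  dtw <- min(diff(sort(unique(tw))))
  if (tau < 0.5 * dtw)
    stop(sprintf(paste0("fitted tau = %.4g ps is below the waiting-time ",
                        "resolution (%g ps): the trace rises as a step and ",
                        "the rate is unidentifiable (amplitude %.4g)"),
                 tau, dtw, fit$par[1L]))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(NA_real_, NA_real_))
  out <- list(temperature = temperature_c,
              tau_forward = tau, tau_se = unname(se[2L]),
              k_forward = 1 / tau,
              amplitude = unname(fit$par[1L]),
              tau_reverse = NA_real_, k_reverse = NA_real_,
              dG_used = NA_real_)
  if (!is.null(dG)) {
    if (is.na(temperature_c))
      stop("deriving the reverse rate needs temperature_c alongside dG")
    kr <- reverse_rate(out$k_forward, dG, celsius_to_kelvin(temperature_c))
    out$tau_reverse <- 1 / kr
    out$k_reverse <- kr
    out$dG_used <- dG
  }
  structure(out, class = "exchange_kinetics")
}

#' @export
print.exchange_kinetics <- function(x, ...) {
  cat(sprintf("exchange kinetics (T = %s degC): tau_forward = %.4g +/- %.2g ps (k1 = %.4g ps-1)\n",
              format(x$temperature), x$tau_forward, x$tau_se, x$k_forward))
  if (!is.na(x$tau_reverse))
    cat(sprintf("  detailed balance with dG = %.3f kJ/mol: tau_reverse = %.4g ps\n",
                x$dG_used, x$tau_reverse))
  invisible(x)
}

#' Arrhenius fit of rate constants
#'
#' Ordinary least squares of `ln k` on `1/T`; the activation energy is
#' `Ea = -slope * R`.
#'
#' @param temperature_k temperatures, K (>= 3).
#' @param k rate constants, ps^-1 (> 0), same length.
#' @return An object of class `arrhenius_result`: `Ea` (kJ mol^-1),
#'   `Ea_se`, `ln_prefactor` (ln ps^-1) with `ln_prefactor_se`, `n_points`.
#' @examples
#' arrhenius_fit(c(296.15, 323.15, 333.15, 358.15),
#'               1 / c(0.53, 0.33, 0.28, 0.21))
#' @export
arrhenius_fit <- function(temperature_k, k) {
  if (length(temperature_k) < 3L)
    stop("Arrhenius fit needs >= 3 points, got ", length(temperature_k))
  stopifnot(length(k) == length(temperature_k))
  if (any(k <= 0)) stop("rate constants must be positive")
  if (any(temperature_k <= 0)) stop("temperatures must be in Kelvin (> 0)")
  invT <- 1 / temperature_k
  fit <- lm(log(k) ~ invT)
  vc <- quiet_vcov(fit)
  structure(list(Ea = -unname(coef(fit)[2L]) * .R / 1000,
                 Ea_se = sqrt(vc[2L, 2L]) * .R / 1000,
                 ln_prefactor = unname(coef(fit)[1L]),
                 ln_prefactor_se = sqrt(vc[1L, 1L]),
                 n_points = length(k),
                 temperatures = temperature_k, k = k),
            class = "arrhenius_result")
}

#' @export
print.arrhenius_result <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%d points): Ea = %.3f +/- %.3f kJ/mol\n",
              x$n_points, x$Ea, x$Ea_se))
  invisible(x)
}

#' Reverse rate constant by detailed balance
#'
#' For the equilibrium SHB <-> WHB with free-energy difference
#' `dG = G_WHB - G_SHB`, detailed balance `k1/k_-1 = exp(-dG/(R T))` gives
#' `k_reverse = k_forward * exp(+dG/(R T))` (molar convention, dG converted
#' to J mol^-1 internally).
#'
#' @param k_forward forward rate, ps^-1.
#' @param dG free-energy difference, kJ mol^-1.
#' @param temperature_k temperature, K (> 0).
#' @return reverse rate constant(s), ps^-1.
#' @examples
#' 1 / reverse_rate(1 / 0.53, 1.68, 296.15)   # ~0.27 ps
#' @export
reverse_rate <- function(k_forward, dG, temperature_k) {
  if (any(temperature_k <= 0)) stop("temperature must be positive (Kelvin)")
  if (any(k_forward < 0)) stop("k_forward must be non-negative")
  k_forward * exp(dG * 1000 / (.R * temperature_k))
}
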