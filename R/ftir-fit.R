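#' Smoothed second derivative of a spectrum
#'
#' Savitzky-Golay local-polynomial second derivative, the standard way to
#' expose overlapping sub-bands as local minima. Defaults (11-point window,
#' cubic polynomial) suit a 1 cm^-1 sampling interval.
#'
#' @param spectrum a [spectrum1d()] on a uniform grid (or set
#'   `resample = TRUE`).
#' @param window_pts odd filter window length, points; must exceed
#'   `poly_order` and be shorter than the spectrum.
#' @param poly_order local polynomial order.
#' @param resample if `TRUE`, a non-uniform grid is first resampled onto a
#'   uniform grid of the same length by cubic spline; otherwise a non-uniform
#'   grid is an error.
#' @return A [spectrum1d()] holding the second derivative (absorbance cm^2)
#'   on the (possibly resampled) grid. Endpoints are computed with the
#'   asymmetric boundary filters of the same polynomial; metadata flags this
#'   in `endpoint_handling`.
#' @export
second_derivative <- function(spectrum, window_pts = 11L, poly_order = 3L,
                              resample = FALSE) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  if (window_pts %% 2L != 1L) stop("window_pts must be odd")
  if (window_pts <= poly_order)
    stop("window_pts must exceed poly_order")
  if (window_pts >= length(spectrum$wavenumber))
    stop("window_pts must be smaller than the spectrum length")
  if (poly_order < 2L) stop("poly_order must be >= 2 for a second derivative")
  x <- spectrum$wavenumber
  y <- spectrum$absorbance
  resampled <- FALSE
  if (!is_uniform_grid(x)) {
    if (!resample)
      stop("non-uniform wavenumber grid; set resample = TRUE to spline-resample")
    xu <- seq(min(x), max(x), length.out = length(x))
    y <- spline(x, y, xout = xu)$y
    x <- xu
    resampled <- TRUE
  }
  h <- mean(diff(x))
  d2 <- sgolayfilt(y, p = poly_order, n = window_pts, m = 2L, ts = h)
  spectrum1d(x, d2, temperature = spectrum$temperature,
             metadata = c(spectrum$metadata,
                          list(derivative = 2L,
                               window_pts = window_pts,
                               poly_order = poly_order,
                               resampled = resampled,
                               endpoint_handling = "asymmetric boundary filters")))
}

## internal: indices of local minima of a vector (strictly below neighbours,
## negative values only)
local_minima <- function(v) {
  i <- 2:(length(v) - 1L)
  i[v[i] < v[i - 1L] & v[i] <= v[i + 1L] & v[i] < 0]
}

## internal: refine a grid minimum by quadratic interpolation
refine_minimum <- function(x, v, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (denom <= 0) return(x[i])
  x[i] + 0.5 * (v[i - 1L] - v[i + 1L]) / denom * (x[i] - x[i - 1L])
}

#' Locate amide-I sub-band candidates from the second derivative
#'
#' @param spectrum a [spectrum1d()].
#' @inheritParams second_derivative
#' @return numeric vector of candidate centers (cm^-1, quadratically
#'   refined), ordered by depth of the second-derivative minimum.
#' @export
second_derivative_minima <- function(spectrum, window_pts = 11L,
                                     poly_order = 3L, resample = FALSE) {
  d2 <- second_derivative(spectrum, window_pts, poly_order, resample)
  idx <- local_minima(d2$absorbance)
  idx <- idx[order(d2$absorbance[idx])]
  vapply(idx, function(i) refine_minimum(d2$wavenumber, d2$absorbance, i),
         numeric(1L))
}

## internal: model prediction for the two-Voigt parameter vector
two_voigt_model <- function(p, wavenumber, linear_baseline) {
  y <- voigt_profile(wavenumber,
                     voigt_component(p[1L], p[2L], p[3L], p[4L])) +
    voigt_profile(wavenumber,
                  voigt_component(p[5L], p[6L], p[7L], p[8L])) + p[9L]
  if (linear_baseline) y <- y + p[10L] * (wavenumber - mean(wavenumber))
  y
}

#' Fit two Voigt components to an amide-I band
#'
#' Nonlinear least squares (Levenberg-Marquardt) for a sum of two Voigt
#' profiles plus a constant (optionally linear) baseline. Initial centers
#' come from the two deepest second-derivative minima unless an `init` fit is
#' supplied. Centers are bounded to +/- `center_window` cm^-1 of their
#' initial values and widths to (0.1, 30) cm^-1, which prevents the two
#' components from swapping roles during optimization; the returned
#' components are sorted so `shb$center < whb$center`.
#'
#' @param spectrum a [spectrum1d()].
#' @param init optional `two_component_fit` (or list with `shb`/`whb`
#'   [voigt_component()]s) used as the starting point.
#' @param linear_baseline fit a linear baseline term in addition to the
#'   constant offset.
#' @param center_window half-width of the center bound, cm^-1.
#' @param window_pts,poly_order second-derivative settings for automatic
#'   initialization.
#' @param warn_threshold residual RMS relative to the maximum absorbance
#'   above which a quality warning is emitted (not an error).
#' @return An object of class `two_component_fit`: fields `shb`, `whb`
#'   ([voigt_component()]s with standard errors), `baseline`,
#'   `residual_rms`, `temperature`, `fitted`, `convergence`.
#' @export
fit_two_voigt <- function(spectrum, init = NULL, linear_baseline = FALSE,
                          center_window = 10, window_pts = 11L,
                          poly_order = 3L, warn_threshold = 0.02) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  x <- spectrum$wavenumber
  y <- spectrum$absorbance
  if (is.null(init)) {
    cand <- second_derivative_minima(spectrum, window_pts, poly_order,
                                     resample = TRUE)
    if (length(cand) < 2L)
      stop("found ", length(cand), " second-derivative minima; ",
           "supply an explicit `init` with both component guesses")
    centers <- sort(cand[1:2])
    # crude width guess from the full band's half-maximum width
    above <- x[y >= max(y) / 2]
    w_band <- max(diff(range(above)), 4)
    heights <- approx(x, y, xout = centers)$y
    total_area <- trapz(x, pmax(y - min(y), 0))
    areas <- total_area * heights / sum(heights)
    init <- list(
      shb = voigt_component(centers[1L], w_band / 4, w_band / 8, areas[1L]),
      whb = voigt_component(centers[2L], w_band / 4, w_band / 8, areas[2L])
    )
  }
  p0 <- c(init$shb$center, init$shb$sigma, init$shb$gamma, init$shb$area,
          init$whb$center, init$whb$sigma, init$whb$gamma, init$whb$area,
          min(y))
  lower <- c(p0[1L] - center_window, 0.1, 0.1, 0,
             p0[5L] - center_window, 0.1, 0.1, 0, -Inf)
  upper <- c(p0[1L] + center_window, 30, 30, Inf,
             p0[5L] + center_window, 30, 30, Inf, Inf)
  if (linear_baseline) {
    p0 <- c(p0, 0); lower <- c(lower, -Inf); upper <- c(upper, Inf)
  }
  p0 <- pmin(pmax(p0, lower), upper)
  fit <- nls.lm(par = p0,
                fn = function(p) y - two_voigt_model(p, x, linear_baseline),
                lower = lower, upper = upper,
                control = nls.lm.control(maxiter = 400, ftol = 1e-14,
                                         ptol = 1e-14))
  if (fit$info == 0 || fit$info == 5)
    stop("two-Voigt fit did not converge (", fit$message,
         "); last residual norm ", format(sqrt(fit$deviance)))
  p <- fit$par
  se <- tryCatch({
    sm <- summary(fit)
    sm$coefficients[, "Std. Error"]
  }, error = function(e) rep(NA_real_, length(p)))
  comp <- function(k) voigt_component(
    p[k], p[k + 1L], p[k + 2L], p[k + 3L],
    se = c(center = se[k], sigma = se[k + 1L], gamma = se[k + 2L],
           area = se[k + 3L]))
  c1 <- comp(1L); c2 <- comp(5L)
  if (c2$center < c1$center) { tmp <- c1; c1 <- c2; c2 <- tmp }
  fitted <- two_voigt_model(p, x, linear_baseline)
  rms <- sqrt(mean((y - fitted)^2))
  if (max(abs(y)) > 0 && rms / max(abs(y)) > warn_threshold)
    warning(sprintf("two-Voigt fit residual RMS is %.2f%% of the band maximum",
                    100 * rms / max(abs(y))))
  structure(list(shb = c1, whb = c2,
                 baseline = if (linear_baseline) p[9:10] else p[9L],
                 residual_rms = rms,
                 temperature = spectrum$temperature,
                 fitted = fitted,
                 convergence = list(info = fit$info, message = fit$message,
                                    iterations = fit$niter)),
            class = "two_component_fit")
}

#' @export
print.two_component_fit <- function(x, ...) {
  cat(sprintf(paste0("two-component Voigt fit (T = %s degC)\n",
                     "  SHB: center %.2f cm-1, area %.4g\n",
                     "  WHB: center %.2f cm-1, area %.4g\n",
                     "  split %.2f cm-1, area ratio SHB/WHB %.3f, residual RMS %.3g\n"),
              format(x$temperature), x$shb$center, x$shb$area,
              x$whb$center, x$whb$area, x$whb$center - x$shb$center,
              x$shb$area / x$whb$area, x$residual_rms))
  invisible(x)
}

#' Temperature drift rate of a fitted sub-band center
#'
#' Ordinary least-squares slope of a component's center against temperature,
#' across a temperature-ordered list of [fit_two_voigt()] results.
#'
#' @param fits list of `two_component_fit` objects (>= 3 temperatures).
#' @param which `"shb"` or `"whb"`.
#' @return list with `slope` (cm^-1 per degC), `se`, `n`, and the underlying
#'   `centers`/`temperatures`.
#' @export
peak_shift_rate <- function(fits, which = c("shb", "whb")) {
  which <- match.arg(which)
  if (length(fits) < 3L)
    stop("peak_shift_rate needs >= 3 temperatures, got ", length(fits))
  temps <- vapply(fits, function(f) f$temperature, numeric(1L))
  centers <- vapply(fits, function(f) f[[which]]$center, numeric(1L))
  fit <- lm(centers ~ temps)
  se2 <- sqrt(quiet_vcov(fit)[2L, 2L])
  list(slope = unname(coef(fit)[2L]), se = unname(se2),
       n = length(fits), centers = centers, temperatures = temps)
}
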