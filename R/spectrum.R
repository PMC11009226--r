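#' Construct a one-dimensional infrared spectrum
#'
#' The basic FTIR record: a strictly increasing wavenumber grid, absorbance
#' values and the sample temperature.
#'
#' @param wavenumber strictly increasing numeric vector, cm^-1 (length >= 16).
#' @param absorbance numeric vector of the same length, absorbance units.
#' @param temperature sample temperature, degrees Celsius.
#' @param metadata optional named list of free-form metadata.
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(wavenumber, absorbance, temperature = NA_real_,
                       metadata = list()) {
  stopifnot(is.numeric(wavenumber), is.numeric(absorbance))
  if (length(wavenumber) != length(absorbance))
    stop("wavenumber and absorbance must have equal length")
  if (length(wavenumber) < 16L)
    stop("a spectrum needs at least 16 points, got ", length(wavenumber))
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber grid must be strictly increasing")
  structure(list(wavenumber = as.numeric(wavenumber),
                 absorbance = as.numeric(absorbance),
                 temperature = as.numeric(temperature),
                 metadata = metadata),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("spectrum1d: %d points, %.1f-%.1f cm-1, T = %s degC\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              format(x$temperature)))
  invisible(x)
}

#' @export
plot.spectrum1d <- function(x, ...) {
  plot(x$wavenumber, x$absorbance, type = "l",
       xlab = expression(paste("wavenumber (", cm^-1, ")")),
       ylab = "absorbance", ...)
  invisible(x)
}

#' Construct a waiting-time series of 2D IR spectra
#'
#' The 2D IR record: real-valued matrices (rows = probe axis `omega_t`,
#' columns = pump axis `omega_tau`) indexed by waiting time, sharing axes.
#'
#' @param omega_tau strictly increasing pump-axis vector, cm^-1.
#' @param omega_t strictly increasing probe-axis vector, cm^-1.
#' @param waiting_times numeric vector of waiting times, ps; must include 0.
#' @param matrices list of matrices, one per waiting time, each with
#'   `length(omega_t)` rows and `length(omega_tau)` columns.
#' @param temperature sample temperature, degrees Celsius.
#' @param metadata optional named list.
#' @return An object of class `spectrum2d_series`.
#' @export
spectrum2d_series <- function(omega_tau, omega_t, waiting_times, matrices,
                              temperature = NA_real_, metadata = list()) {
  stopifnot(is.numeric(omega_tau), is.numeric(omega_t),
            is.numeric(waiting_times), is.list(matrices))
  if (any(diff(omega_tau) <= 0) || any(diff(omega_t) <= 0))
    stop("2D axes must be strictly increasing")
  if (length(matrices) != length(waiting_times))
    stop("one matrix per waiting time required")
  if (!any(abs(waiting_times) < 1e-12))
    stop("waiting_times must include T_w = 0")
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    if (!is.matrix(m) || nrow(m) != length(omega_t) ||
        ncol(m) != length(omega_tau))
      stop("matrix ", i, " does not match the axis lengths (",
           length(omega_t), " x ", length(omega_tau), ")")
  }
  ord <- order(waiting_times)
  structure(list(omega_tau = as.numeric(omega_tau),
                 omega_t = as.numeric(omega_t),
                 waiting_times = as.numeric(waiting_times)[ord],
                 matrices = matrices[ord],
                 temperature = as.numeric(temperature),
                 metadata = metadata),
            class = "spectrum2d_series")
}

#' @export
print.spectrum2d_series <- function(x, ...) {
  cat(sprintf(paste0("spectrum2d_series: %d waiting times (%.2f-%.2f ps), ",
                     "%d x %d grid, T = %s degC\n"),
              length(x$waiting_times), min(x$waiting_times),
              max(x$waiting_times), length(x$omega_t), length(x$omega_tau),
              format(x$temperature)))
  invisible(x)
}

#' Define a rectangular spectral integration window
#'
#' @param tau_lo,tau_hi pump-axis bounds, cm^-1 (`tau_lo < tau_hi`).
#' @param t_lo,t_hi probe-axis bounds, cm^-1 (`t_lo < t_hi`).
#' @return An object of class `spectral_window` with an `area` field
#'   (cm^-2).
#' @export
spectral_window <- function(tau_lo, tau_hi, t_lo, t_hi) {
  stopifnot(tau_lo < tau_hi, t_lo < t_hi)
  structure(list(tau_lo = tau_lo, tau_hi = tau_hi, t_lo = t_lo, t_hi = t_hi,
                 area = (tau_hi - tau_lo) * (t_hi - t_lo)),
            class = "spectral_window")
}

## internal: square window of side `size` centered at (pump, probe)
centered_window <- function(pump, probe, size = 5) {
  spectral_window(pump - size / 2, pump + size / 2,
                  probe - size / 2, probe + size / 2)
}

## internal: 2D trapezoidal integral of a series matrix over a window
window_integral <- function(series, matrix, window) {
  itau <- series$omega_tau >= window$tau_lo & series$omega_tau <= window$tau_hi
  it <- series$omega_t >= window$t_lo & series$omega_t <= window$t_hi
  if (sum(itau) < 2L || sum(it) < 2L)
    stop(sprintf("window [%g, %g] x [%g, %g] covers fewer than 2 grid points per axis",
                 window$tau_lo, window$tau_hi, window$t_lo, window$t_hi))
  sub <- matrix[it, itau, drop = FALSE]
  rows <- apply(sub, 1L, function(r) trapz(series$omega_tau[itau], r))
  trapz(series$omega_t[it], rows)
}
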