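## Faddeeva function w(z) = exp(-z^2) erfc(-iz) for Im(z) >= 0.
##
## Weideman's rational approximation (SIAM Rev. 36, 1994, N = 48 terms) in the
## interior, switching to a 9-level Laplace continued fraction once
## |Re z| + Im z > 15 where the rational form degrades and the continued
## fraction is already at machine precision. Coefficients are computed once
## and cached.
.voigt_env <- new.env(parent = emptyenv())

weideman_coefficients <- function(N = 48L) {
  key <- paste0("wc", N)
  if (!is.null(.voigt_env[[key]])) return(.voigt_env[[key]])
  M <- 2L * N
  M2 <- 2L * M
  k <- seq.int(-M + 1L, M - 1L)
  L <- sqrt(N / sqrt(2))
  theta <- k * pi / M
  t <- L * tan(theta / 2)
  f <- c(0, exp(-t^2) * (L^2 + t^2))
  half <- ceiling(length(f) / 2)
  fs <- c(f[(half + 1L):length(f)], f[1L:half])   # fftshift
  a <- Re(fft(fs)) / M2
  out <- list(L = L, a = rev(a[2L:(N + 1L)]))
  .voigt_env[[key]] <- out
  out
}

faddeeva <- function(z) {
  stopifnot(all(Im(z) >= 0))
  w <- complex(length.out = length(z))
  big <- (abs(Re(z)) + Im(z)) > 15
  if (any(big)) {
    zz <- z[big]
    f <- 0 + 0i
    for (k in 9:1) f <- (k / 2) / (zz - f)
    w[big] <- (1i / sqrt(pi)) / (zz - f)
  }
  if (any(!big)) {
    wc <- weideman_coefficients()
    zz <- z[!big]
    Z <- (wc$L + 1i * zz) / (wc$L - 1i * zz)
    p <- rep(0 + 0i, length(zz))
    for (ak in wc$a) p <- p * Z + ak
    w[!big] <- 2 * p / (wc$L - 1i * zz)^2 + (1 / sqrt(pi)) / (wc$L - 1i * zz)
  }
  w
}

#' Construct a Voigt line-shape component
#'
#' A Voigt profile is the convolution of a Gaussian (standard deviation
#' `sigma`) and a Lorentzian (half-width at half maximum `gamma`), the
#' standard model for an infrared band that carries both inhomogeneous and
#' lifetime broadening.
#'
#' @param center peak position, cm^-1.
#' @param sigma Gaussian standard deviation, cm^-1 (>= 0).
#' @param gamma Lorentzian HWHM, cm^-1 (>= 0). `sigma` and `gamma` must not
#'   both be zero.
#' @param area integrated band area, absorbance * cm^-1 (> 0).
#' @param se optional named numeric vector of standard errors
#'   (`center`, `sigma`, `gamma`, `area`).
#' @return An object of class `voigt_component`.
#' @seealso [voigt_profile()]
#' @export
voigt_component <- function(center, sigma, gamma, area = 1, se = NULL) {
  stopifnot(is.numeric(center), is.numeric(sigma), is.numeric(gamma),
            is.numeric(area), length(center) == 1L)
  if (sigma < 0 || gamma < 0)
    stop("Voigt widths must be non-negative (sigma = ", sigma,
         ", gamma = ", gamma, ")")
  if (sigma == 0 && gamma == 0)
    stop("degenerate Voigt component: sigma and gamma cannot both be zero")
  if (area < 0) stop("component area must be non-negative")
  structure(list(center = center, sigma = sigma, gamma = gamma,
                 area = area, se = se),
            class = "voigt_component")
}

#' @export
print.voigt_component <- function(x, ...) {
  cat(sprintf("Voigt component: center %.2f cm-1, sigma %.3f, gamma %.3f, area %.4g\n",
              x$center, x$sigma, x$gamma, x$area))
  invisible(x)
}

#' Evaluate a Voigt profile
#'
#' Computes the unit-area Voigt function scaled by `component$area`, via the
#' real part of the Faddeeva function `w(z)` with
#' `z = (x - center + i gamma) / (sigma sqrt(2))`. The pure-Gaussian
#' (`gamma = 0`) and pure-Lorentzian (`sigma = 0`) limits are evaluated with
#' their closed forms.
#'
#' @param wavenumber numeric vector of abscissa values, cm^-1.
#' @param component a [voigt_component()].
#' @return absorbance vector of the same length as `wavenumber`.
#' @examples
#' vc <- voigt_component(1607.8, sigma = 3.8, gamma = 1.3, area = 2.26)
#' y <- voigt_profile(seq(1560, 1660, 0.5), vc)
#' @export
voigt_profile <- function(wavenumber, component) {
  stopifnot(inherits(component, "voigt_component"), is.numeric(wavenumber))
  x <- wavenumber - component$center
  s <- component$sigma
  g <- component$gamma
  if (s == 0 && g == 0)
    stop("degenerate Voigt component: sigma and gamma cannot both be zero")
  if (g == 0) {
    y <- exp(-x^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  } else if (s == 0) {
    y <- (g / pi) / (x^2 + g^2)
  } else {
    z <- complex(real = x, imaginary = g) / (s * sqrt(2))
    y <- Re(faddeeva(z)) / (s * sqrt(2 * pi))
  }
  component$area * y
}
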