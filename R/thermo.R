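#' Dipole-corrected two-state equilibrium constant
#'
#' The integrated absorption of each amide-I sub-band is proportional to the
#' state concentration times the squared transition dipole, so the WHB/SHB
#' concentration ratio is
#' `K_eq = (A_WHB * mu_SHB^2) / (A_SHB * mu_WHB^2)`.
#'
#' @param area_whb,area_shb integrated component areas, absorbance*cm^-1
#'   (> 0); vectors are accepted.
#' @param mu_shb,mu_whb transition dipole magnitudes, Debye (> 0).
#' @return equilibrium constant(s), dimensionless.
#' @examples
#' equilibrium_constant(1, 2.260, mu_shb = 0.344, mu_whb = 0.321)
#' @export
equilibrium_constant <- function(area_whb, area_shb, mu_shb = 0.344,
                                 mu_whb = 0.321) {
  if (any(area_whb <= 0) || any(area_shb <= 0))
    stop("component areas must be positive")
  if (mu_shb <= 0 || mu_whb <= 0)
    stop("transition dipoles must be positive")
  (area_whb * mu_shb^2) / (area_shb * mu_whb^2)
}

#' Van't Hoff fit of an equilibrium-constant series
#'
#' Unweighted ordinary least squares of `ln K_eq` on `1/T`:
#' `ln K_eq = -dH/(R T) + dS/R`. Standard errors and the dH-dS covariance
#' come from the regression covariance matrix (they describe regression
#' scatter only).
#'
#' @param temperature_k temperatures, K (>= 3 values).
#' @param keq equilibrium constants (> 0), same length.
#' @return An object of class `vant_hoff_fit`: `dH` (kJ mol^-1), `dS`
#'   (J mol^-1 K^-1), `dH_se`, `dS_se`, `cov_dH_dS` (kJ * J / mol^2 / K),
#'   plus the input series.
#' @export
vant_hoff_fit <- function(temperature_k, keq) {
  if (length(temperature_k) < 3L)
    stop("van't Hoff fit needs >= 3 temperatures, got ", length(temperature_k))
  stopifnot(length(temperature_k) == length(keq))
  if (any(keq <= 0)) stop("all keq values must be positive")
  if (any(temperature_k <= 0)) stop("temperatures must be in Kelvin (> 0)")
  invT <- 1 / temperature_k
  fit <- lm(log(keq) ~ invT)
  cf <- coef(fit)
  vc <- quiet_vcov(fit)
  dH <- -unname(cf[2L]) * .R / 1000           # kJ/mol
  dS <- unname(cf[1L]) * .R                   # J/mol/K
  dH_se <- sqrt(vc[2L, 2L]) * .R / 1000
  dS_se <- sqrt(vc[1L, 1L]) * .R
  cov_dH_dS <- -vc[1L, 2L] * .R^2 / 1000      # cov(dH [kJ], dS [J])
  structure(list(dH = dH, dS = dS, dH_se = dH_se, dS_se = dS_se,
                 cov_dH_dS = cov_dH_dS,
                 temperatures = temperature_k, keq = keq,
                 residuals = unname(residuals(fit))),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit (%d temperatures)\n  dH = %.3f +/- %.3f kJ/mol\n  dS = %.3f +/- %.3f J/mol/K\n",
              length(x$temperatures), x$dH, x$dH_se, x$dS, x$dS_se))
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T dS / 1000` in kJ mol^-1. If standard errors are supplied the
#' uncertainty is propagated (including the dH-dS covariance when given).
#'
#' @param dH enthalpy, kJ mol^-1.
#' @param dS entropy, J mol^-1 K^-1.
#' @param temperature_k temperature(s), K (> 0).
#' @param dH_se,dS_se optional standard errors.
#' @param cov_dH_dS optional covariance of dH (kJ) and dS (J).
#' @return If no errors are given, numeric `dG` (kJ mol^-1); otherwise a
#'   data.frame with `temperature_k`, `dG`, `dG_se`.
#' @examples
#' gibbs(6.22, 15.34, celsius_to_kelvin(23))
#' @export
gibbs <- function(dH, dS, temperature_k, dH_se = NULL, dS_se = NULL,
                  cov_dH_dS = 0) {
  if (any(temperature_k <= 0)) stop("temperature must be positive (Kelvin)")
  dG <- dH - temperature_k * dS / 1000
  if (is.null(dH_se) && is.null(dS_se)) return(dG)
  if (is.null(dH_se)) dH_se <- 0
  if (is.null(dS_se)) dS_se <- 0
  v <- dH_se^2 + (temperature_k * dS_se / 1000)^2 -
    2 * temperature_k * cov_dH_dS / 1000
  data.frame(temperature_k = temperature_k, dG = dG,
             dG_se = sqrt(pmax(v, 0)))
}

#' Assemble a thermodynamic result from per-temperature component areas
#'
#' Converts fitted component areas to equilibrium constants (see
#' [equilibrium_constant()]), runs the van't Hoff regression and evaluates
#' `dG(T)` at the input temperatures.
#'
#' @param area_shb,area_whb component-area vectors over temperature.
#' @param temperature_c temperatures, degC.
#' @param mu_shb,mu_whb transition dipoles, Debye.
#' @return An object of class `thermo_result` with fields `temperatures`
#'   (K), `keq`, `dH`, `dS` (with SEs), `dG` (data.frame with SEs),
#'   `dipole_ratio_sq` (`mu_shb^2 / mu_whb^2`), `mu_shb`, `mu_whb`.
#' @export
thermo_from_areas <- function(area_shb, area_whb, temperature_c,
                              mu_shb = 0.344, mu_whb = 0.321) {
  tk <- celsius_to_kelvin(temperature_c)
  keq <- equilibrium_constant(area_whb, area_shb, mu_shb, mu_whb)
  vh <- vant_hoff_fit(tk, keq)
  dG <- gibbs(vh$dH, vh$dS, tk, vh$dH_se, vh$dS_se, vh$cov_dH_dS)
  res <- list(temperatures = tk, keq = keq,
              dH = vh$dH, dH_se = vh$dH_se,
              dS = vh$dS, dS_se = vh$dS_se,
              cov_dH_dS = vh$cov_dH_dS, dG = dG,
              dipole_ratio_sq = mu_shb^2 / mu_whb^2,
              mu_shb = mu_shb, mu_whb = mu_whb)
  # internal consistency of the reported dG values
  stopifnot(max(abs(res$dG$dG - (res$dH - tk * res$dS / 1000))) < 1e-9)
  structure(res, class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("thermo_result: dH = %.3f +/- %.3f kJ/mol, dS = %.3f +/- %.3f J/mol/K\n",
              x$dH, x$dH_se, x$dS, x$dS_se))
  cat(sprintf("  dG(%.1f K) = %.3f kJ/mol ... dG(%.1f K) = %.3f kJ/mol\n",
              min(x$temperatures), max(x$dG$dG),
              max(x$temperatures), min(x$dG$dG)))
  invisible(x)
}

#' Sensitivity of the van't Hoff parameters to the WHB transition dipole
#'
#' The WHB transition dipole is the least certain input of the analysis.
#' For each alternative `mu_whb`, every equilibrium constant is rescaled by
#' the squared-dipole factor `(mu_whb_base / mu_whb_alt)^2` and the van't
#' Hoff regression repeated. Because the factor is temperature independent,
#' `dH` is invariant and `dS` shifts by exactly `R * ln(factor)`.
#'
#' @param base a [thermo_from_areas()] result.
#' @param mu_whb_alternatives vector of alternative WHB dipoles, Debye (> 0).
#' @return data.frame with columns `mu_whb`, `factor`, `dH`, `dH_se`, `dS`,
#'   `dS_se`.
#' @export
dipole_sensitivity <- function(base, mu_whb_alternatives) {
  stopifnot(inherits(base, "thermo_result"))
  if (any(mu_whb_alternatives <= 0))
    stop("alternative dipoles must be positive")
  rows <- lapply(mu_whb_alternatives, function(mu) {
    factor <- (base$mu_whb / mu)^2
    vh <- vant_hoff_fit(base$temperatures, base$keq * factor)
    data.frame(mu_whb = mu, factor = factor,
               dH = vh$dH, dH_se = vh$dH_se, dS = vh$dS, dS_se = vh$dS_se)
  })
  do.call(rbind, rows)
}
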