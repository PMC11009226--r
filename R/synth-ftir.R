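#' Parameters for the synthetic FTIR generator
#'
#' Describes a two-component amide-I band: a low-frequency component from the
#' strongly hydrogen-bonded (SHB) carbonyl and a high-frequency component from
#' the weakly hydrogen-bonded (WHB) carbonyl. The component area ratio is
#' governed by two-state thermodynamics (`dH`, `dS`) through
#' `A_WHB / A_SHB = K_eq(T) * mu_whb^2 / mu_shb^2`, the inverse of the
#' dipole-corrected equilibrium-constant relation used by the analysis; the
#' centers drift linearly with temperature and the total band area falls
#' linearly with temperature (extinction-coefficient loss).
#'
#' Component widths default to sigma = 3.8, gamma = 1.3 cm^-1 (Voigt FWHM
#' about 10.4 cm^-1): narrow enough that a 13.1 cm^-1 doublet with a 2.26
#' amplitude ratio is resolvable as two second-derivative minima near the
#' component centers, while the summed envelope retains a realistic
#' ~20 cm^-1 apparent width.
#'
#' @param center_shb,center_whb component centers at `ref_temp_c`, cm^-1.
#' @param shift_rate_shb,shift_rate_whb linear center drift, cm^-1 per degC.
#' @param gaussian_sigma,lorentzian_gamma length-2 vectors (SHB, WHB) of
#'   Gaussian sigma and Lorentzian HWHM, cm^-1; scalars are recycled.
#' @param total_area summed component area at `ref_temp_c`, absorbance*cm^-1.
#' @param dH enthalpy of the SHB -> WHB transition, kJ mol^-1.
#' @param dS entropy of the SHB -> WHB transition, J mol^-1 K^-1.
#' @param mu_shb,mu_whb amide-I transition dipole magnitudes, Debye.
#' @param extinction_slope fractional total-area loss per degC.
#' @param noise_sd Gaussian noise standard deviation, absorbance units.
#' @param grid strictly increasing wavenumber grid, cm^-1.
#' @param ref_temp_c reference temperature for centers/areas, degC.
#' @return An object of class `ftir_gen_params`.
#' @export
ftir_gen_params <- function(center_shb = 1607.8, center_whb = 1620.9,
                            shift_rate_shb = 0.07, shift_rate_whb = 0.02,
                            gaussian_sigma = c(3.8, 3.8),
                            lorentzian_gamma = c(1.3, 1.3),
                            total_area = 1,
                            dH = 6.22, dS = 15.34,
                            mu_shb = 0.344, mu_whb = 0.321,
                            extinction_slope = 0.002,
                            noise_sd = 0,
                            grid = seq(1540, 1690, by = 1),
                            ref_temp_c = 23) {
  gaussian_sigma <- rep_len(gaussian_sigma, 2L)
  lorentzian_gamma <- rep_len(lorentzian_gamma, 2L)
  if (any(gaussian_sigma <= 0) || any(lorentzian_gamma <= 0))
    stop("component widths must be positive")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (mu_shb <= 0 || mu_whb <= 0) stop("transition dipoles must be positive")
  if (total_area < 0) stop("total_area must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(center_shb = center_shb, center_whb = center_whb,
                 shift_rate_shb = shift_rate_shb,
                 shift_rate_whb = shift_rate_whb,
                 gaussian_sigma = gaussian_sigma,
                 lorentzian_gamma = lorentzian_gamma,
                 total_area = total_area, dH = dH, dS = dS,
                 mu_shb = mu_shb, mu_whb = mu_whb,
                 extinction_slope = extinction_slope,
                 noise_sd = noise_sd, grid = grid, ref_temp_c = ref_temp_c),
            class = "ftir_gen_params")
}

#' Two-state equilibrium constant from van't Hoff thermodynamics
#'
#' `K_eq(T) = exp(-dH/(R T) + dS/R)`, i.e. the WHB/SHB concentration ratio.
#'
#' @param dH enthalpy, kJ mol^-1.
#' @param dS entropy, J mol^-1 K^-1.
#' @param temperature_k temperature(s), K.
#' @return equilibrium constant(s), dimensionless.
#' @export
keq_from_thermo <- function(dH, dS, temperature_k) {
  stopifnot(all(temperature_k > 0))
  exp(-dH * 1000 / (.R * temperature_k) + dS / .R)
}

## internal: per-temperature component geometry and areas for the generator
ftir_components_at <- function(params, temp_c) {
  dt <- temp_c - params$ref_temp_c
  cs <- params$center_shb + params$shift_rate_shb * dt
  cw <- params$center_whb + params$shift_rate_whb * dt
  keq <- keq_from_thermo(params$dH, params$dS, celsius_to_kelvin(temp_c))
  ratio_wh_sh <- keq * params$mu_whb^2 / params$mu_shb^2   # A_WHB / A_SHB
  total <- params$total_area * max(0, 1 - params$extinction_slope * dt)
  a_shb <- total / (1 + ratio_wh_sh)
  a_whb <- total - a_shb
  list(
    shb = voigt_component(cs, params$gaussian_sigma[1L],
                          params$lorentzian_gamma[1L], a_shb),
    whb = voigt_component(cw, params$gaussian_sigma[2L],
                          params$lorentzian_gamma[2L], a_whb),
    keq = keq
  )
}

#' Simulate a temperature series of amide-I FTIR spectra
#'
#' Each spectrum is the sum of the SHB and WHB Voigt components at that
#' temperature (see [ftir_gen_params()]) plus optional Gaussian noise.
#'
#' @param params an [ftir_gen_params()] object.
#' @param temperatures temperatures, degC (0-100).
#' @param seed optional integer seed for the noise; the global RNG state is
#'   left untouched.
#' @return A list of [spectrum1d()] objects ordered by temperature, with the
#'   generating component truth stored in each spectrum's metadata.
#' @examples
#' sp <- simulate_ftir(ftir_gen_params(), temperatures = c(23, 50))
#' sp[[1]]
#' @export
simulate_ftir <- function(params, temperatures = c(23, 33, 43, 53, 63, 73, 85),
                          seed = NULL) {
  stopifnot(inherits(params, "ftir_gen_params"))
  if (any(temperatures < 0 | temperatures > 100))
    stop("temperatures must lie in 0-100 degC")
  temperatures <- sort(temperatures)
  rng <- range(params$grid)
  for (tc in temperatures) {
    comps <- ftir_components_at(params, tc)
    for (side in c("shb", "whb")) {
      cc <- comps[[side]]
      half <- 5 * (cc$sigma + cc$gamma)
      if (cc$center - half < rng[1L] || cc$center + half > rng[2L])
        stop(sprintf(
          "grid [%g, %g] does not cover the %s component at %.1f cm-1 (+/- 5 widths) at %g degC",
          rng[1L], rng[2L], toupper(side), cc$center, tc))
    }
  }
  with_seed(seed, lapply(temperatures, function(tc) {
    comps <- ftir_components_at(params, tc)
    y <- voigt_profile(params$grid, comps$shb) +
      voigt_profile(params$grid, comps$whb)
    if (params$noise_sd > 0)
      y <- y + rnorm(length(y), sd = params$noise_sd)
    spectrum1d(params$grid, y, temperature = tc,
               metadata = list(generator = "simulate_ftir",
                               true_shb = comps$shb, true_whb = comps$whb,
                               keq = comps$keq, noise_sd = params$noise_sd))
  }))
}
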