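#' Physical constants used throughout the package
#'
#' All molar energies in this package use the gas constant `R` in
#' J mol^-1 K^-1, never the per-molecule Boltzmann constant: detailed-balance
#' and van't Hoff relations are evaluated as exp(-dG / (R T)) with dG in
#' J mol^-1. Temperatures convert as K = degC + 273.15.
#'
#' @return A list with elements `R` (8.314462618 J mol^-1 K^-1) and
#'   `celsius_offset` (273.15 K).
#' @examples
#' phys_constants()$R
#' @export
phys_constants <- function() {
  list(R = 8.314462618, celsius_offset = 273.15)
}

#' Convert Celsius to Kelvin
#'
#' @param temp_c temperature(s) in degrees Celsius.
#' @return temperature(s) in Kelvin.
#' @export
celsius_to_kelvin <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  temp_c + phys_constants()$celsius_offset
}

## internal: gas constant shortcut
.R <- 8.314462618

## internal: evaluate code with a temporary RNG seed, restoring global state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

## internal: trapezoidal integral
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## internal: is a grid uniform (relative tolerance on spacing)?
is_uniform_grid <- function(x, rtol = 1e-6) {
  d <- diff(x)
  max(d) - min(d) <= rtol * abs(mean(d))
}

## internal: vcov of an lm without the noise-free "perfect fit" warning
quiet_vcov <- function(fit) {
  withCallingHandlers(vcov(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
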