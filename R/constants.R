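#' Physical constants for Eyring kinetics
#'
#' Single source of truth for every kinetics operation in the package.
#' Units are chosen so that activation free energies are in kcal/mol and
#' rate constants in s^-1.
#'
#' @format A named list with components
#' \describe{
#'   \item{R}{gas constant, 1.987204e-3 kcal mol^-1 K^-1}
#'   \item{kB_h}{Boltzmann constant over Planck constant, 2.083661e10 s^-1 K^-1}
#'   \item{kappa}{transmission coefficient, 1 (the universal default)}
#' }
#' @export
eyring_constants <- list(
  R     = 1.987204e-3,
  kB_h  = 2.083661e10,
  kappa = 1
)
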