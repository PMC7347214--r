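#' Physical constants used by the hydrodynamic conversions
#'
#' CGS units throughout: the gas constant in erg/(mol K), Avogadro's number
#' per mol, and the density (g/ml) and viscosity (poise) of water at 20 C from
#' the standard water tables.
#'
#' @return Named list with `R`, `NA.` (Avogadro), `T20` (293.15 K),
#'   `rho20w` and `eta20w`.
#' @examples
#' physicalConstants()$R
#' @export
physicalConstants <- function() list(
    R      = 8.314462618e7,   # erg / (mol K)
    NA.    = 6.02214076e23,   # 1 / mol
    T20    = 293.15,          # K
    rho20w = 0.998234,        # g / ml, water at 20 C
    eta20w = 0.010020)        # poise,  water at 20 C

# svedberg unit in seconds
SVEDBERG <- 1e-13
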