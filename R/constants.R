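# Physical constants and unit conversions used throughout the package.
# Thermal energy is pinned to 4.11 pN nm at 298 K and scaled linearly in T.

.KBT_298 <- 4.11            # pN nm at 298 K
.PNNM_TO_KCALMOL <- 1e-21 * 6.02214076e23 / 4184  # 1 pN nm = 0.14393 kcal/mol

#' Thermal energy in piconewton nanometres
#'
#' Returns \eqn{k_B T} in pN nm, anchored at 4.11 pN nm for T = 298 K.
#'
#' @param temperature Absolute temperature in kelvin.
#' @return Thermal energy in pN nm.
#' @examples
#' kbT()        # 4.11
#' kbT(310)
#' @export
kbT <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  .KBT_298 * temperature / 298
}

#' Convert pN nm to kcal/mol
#'
#' @param x Energy in pN nm (scalar or vector).
#' @return Energy in kcal/mol.
#' @examples
#' pNnmToKcalMol(1)      # 0.14393
#' pNnmToKcalMol(101.5)  # ~14.6
#' @export
pNnmToKcalMol <- function(x) {
  stopifnot(is.numeric(x))
  x * .PNNM_TO_KCALMOL
}
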