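# Internal unit system for normal-mode work: kcal/mol, Angstrom, amu.
# Eigenvalues of the mass-weighted Hessian then carry units
# kcal mol^-1 A^-2 amu^-1; sqrt(lambda) converts to wavenumbers or angular
# frequency with the constants below.

#' Physical constants and unit conversions
#'
#' Conversion factors used throughout the package. The mass-weighted Hessian
#' is built in kcal mol\eqn{^{-1}} \eqn{\AA^{-2}} amu\eqn{^{-1}}; the square
#' root of an eigenvalue in those units is converted to cm\eqn{^{-1}} by
#' `FREQ_CM1` (108.591 to six significant figures) and to angular ps\eqn{^{-1}}
#' by `FREQ_PS1` (20.4548).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{FREQ_CM1}{sqrt(kcal/mol/A^2/amu) to cm^-1: 108.591359}
#'   \item{FREQ_PS1}{sqrt(kcal/mol/A^2/amu) to angular ps^-1: 20.454828}
#'   \item{KB_KCAL}{Boltzmann constant, kcal mol^-1 K^-1}
#'   \item{KB_KJ}{Boltzmann constant, kJ mol^-1 K^-1}
#'   \item{CM1_K}{hc/kB in K per cm^-1 (1.438777): x = CM1_K * nu / T}
#'   \item{KCAL_A2_TO_KJ_NM2}{spring constant kcal/mol/A^2 to kJ/mol/nm^2 (418.4)}
#' }
#' @export
vedmap_constants <- list(
  FREQ_CM1 = sqrt(418.4) / (2 * pi * 2.99792458e-2),
  FREQ_PS1 = sqrt(418.4),
  KB_KCAL  = 1.987204259e-3,
  KB_KJ    = 8.31446262e-3,
  CM1_K    = 1.43877688,
  KCAL_A2_TO_KJ_NM2 = 418.4
)

# standard atomic weights (amu) for elements seen in protein work
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, MG = 24.305, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, ZN = 65.38, CU = 63.546
)

element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    bad <- unique(el[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}
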