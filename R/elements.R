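#' Monoisotopic element masses
#'
#' Masses of the most abundant stable isotope of each supported element, in
#' daltons, taken from the NIST/AME atomic mass evaluation at full published
#' precision (the CODATA-recommended values, >= 9 significant decimals where
#' available). All mass arithmetic in the package goes through this table.
#'
#' @return A named numeric vector of monoisotopic masses (Da), one entry per
#'   supported element symbol.
#' @examples
#' element_masses()[["O"]]
#' @export
element_masses <- function() {
  .element_masses
}

# AME2012/NIST monoisotopic masses, Da. 12C defines the scale exactly.
.element_masses <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668
)
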