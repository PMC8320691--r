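# Decimal-aware round-half-even.
#
# PMDs are reported at a fixed decimal precision, and inputs are themselves
# often decimal-rounded masses (e.g. 4-decimal database masses), so exact
# decimal halves like 27.0235 occur in practice. Binary doubles represent
# such halves inexactly and base round() can fall either way, so values whose
# scaled fractional part lies within 1e-6 of .5 are treated as true halves
# and rounded to the even last digit.
round_pmd <- function(x, digits) {
  if (!is.numeric(digits) || length(digits) != 1L || is.na(digits) ||
      digits < 0 || digits != floor(digits)) {
    stop("`digits` must be a single non-negative integer", call. = FALSE)
  }
  s <- 10^digits
  y <- x * s
  fl <- floor(y)
  frac <- y - fl
  half <- abs(frac - 0.5) < 1e-6
  out <- ifelse(half, ifelse(fl %% 2 == 0, fl, fl + 1), round(y))
  out / s
}

#' Paired mass distance between two masses
#'
#' The PMD is the absolute difference of two monoisotopic masses (or two m/z
#' values sharing adduct and charge state), rounded to a fixed number of
#' decimals. Rounding is decimal-aware round-half-even, so e.g. a distance of
#' exactly 27.0235 Da rounds to 27.024 at 3 decimals.
#'
#' Because the PMD is a difference, any mass shift shared by both species
#' (a common adduct, e.g. proton loss) cancels: the PMD of two neutral
#' compounds equals the PMD of their ions when both carry the same adduct.
#'
#' @param m1,m2 Numeric masses in Da (vectorized, recycled).
#' @param digits Number of decimals to round to (default 3, the precision
#'   used for database PMDs; experimental matching typically uses 2).
#' @return Numeric vector of non-negative PMDs in Da.
#' @examples
#' pmd(74.0242, 44.0262, 3)       # 29.998
#' pmd(457.1124, 455.0968, 3)     # 2.016, the [M-H]- pair of FMN/FMNH2
#' @export
pmd <- function(m1, m2, digits = 3) {
  if (!is.numeric(m1) || !is.numeric(m2)) {
    stop("`m1` and `m2` must be numeric", call. = FALSE)
  }
  round_pmd(abs(m1 - m2), digits)
}
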