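# Hill-order helper: C first, H second, all other elements alphabetical.
hill_order <- function(symbols) {
  rest <- sort(setdiff(unique(symbols), c("C", "H")))
  ord <- c("C", "H", rest)
  symbols[order(match(symbols, ord))]
}

new_chem_formula <- function(counts) {
  counts <- counts[counts != 0L]
  counts <- counts[hill_order(names(counts))]
  structure(as.integer(counts), names = names(counts), class = "chem_formula")
}

#' Parse a molecular formula string
#'
#' Parses a Hill-order-style formula string such as `"C17H21N4O9P"` into a
#' named integer vector of element counts. Multi-digit counts and repeated
#' element symbols are supported; a repeated symbol accumulates.
#'
#' @param text A single formula string.
#' @return A `chem_formula` object: a named integer vector of element counts
#'   in Hill order (C, H, then alphabetical), with zero-count elements
#'   dropped.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C2H4NO2")
#' @seealso [format_formula()], [monoisotopic_mass()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single formula string", call. = FALSE)
  }
  if (!nzchar(text)) {
    stop("cannot parse an empty formula string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(text)) {
    stop("malformed formula string: '", text, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Za-z]+", "", tokens)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  bad <- setdiff(syms, names(.element_masses))
  if (length(bad) > 0L) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- vapply(split(cnts, syms), sum, integer(1))
  new_chem_formula(counts)
}

#' Format a formula as a Hill-order string
#'
#' @param f A `chem_formula` (from [parse_formula()]) or a named integer
#'   vector of element counts.
#' @return A formula string with counts of 1 omitted.
#' @examples
#' format_formula(parse_formula("O1H2"))
#' @export
format_formula <- function(f) {
  f <- as_chem_formula(f)
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

as_chem_formula <- function(f) {
  if (inherits(f, "chem_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f))) {
    bad <- setdiff(names(f), names(.element_masses))
    if (length(bad) > 0L) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(f < 0)) stop("formula counts must be non-negative", call. = FALSE)
    return(new_chem_formula(f))
  }
  stop("cannot interpret `f` as a molecular formula", call. = FALSE)
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of one or more formulas
#'
#' Sums monoisotopic element masses (see [element_masses()]) over the element
#' counts of each formula. The value is kept at full double precision
#' internally; rounding only happens when PMDs are taken (see [pmd()]).
#'
#' @param f A formula string, a character vector of formula strings, a
#'   `chem_formula`, or a list of either.
#' @return A numeric vector of masses in Da. An empty formula has mass 0.
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass(c("C2H4NO2", "C17H21N4O9P"))
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f) && length(f) > 1L) {
    return(vapply(f, function(x) monoisotopic_mass(x), numeric(1),
                  USE.NAMES = FALSE))
  }
  if (is.list(f) && !inherits(f, "chem_formula")) {
    return(vapply(f, monoisotopic_mass, numeric(1), USE.NAMES = FALSE))
  }
  fl <- as_chem_formula(f)
  if (length(fl) == 0L) return(0)
  sum(.element_masses[names(fl)] * as.numeric(fl))
}

new_comp_delta <- function(counts) {
  counts <- counts[counts != 0L]
  counts <- counts[hill_order(names(counts))]
  structure(as.integer(counts), names = names(counts), class = "comp_delta")
}

#' Signed element-count difference between two formulas
#'
#' Computes the per-element difference `a - b` with zero entries dropped: the
#' elemental-composition change of a substrate/product pair. Its mass (see
#' [delta_mass()]) equals `monoisotopic_mass(a) - monoisotopic_mass(b)`
#' exactly.
#'
#' @param a,b Formulas (strings or `chem_formula` objects).
#' @return A `comp_delta`: a named integer vector of signed non-zero counts.
#' @examples
#' formula_delta("C2H4NO2", "HNO2")  # +2C3H
#' formula_delta("C2H4O", "O2")      # +2C4H/-O
#' @export
formula_delta <- function(a, b) {
  a <- as_chem_formula(a)
  b <- as_chem_formula(b)
  syms <- union(names(a), names(b))
  d <- vapply(syms, function(s) {
    sum(a[names(a) == s]) - sum(b[names(b) == s])
  }, integer(1))
  new_comp_delta(d)
}

#' Signed mass of a composition delta
#'
#' @param d A `comp_delta` (from [formula_delta()] or [parse_delta()]).
#' @return Signed mass in Da (sum of element monoisotopic masses weighted by
#'   the signed counts).
#' @examples
#' delta_mass(formula_delta("C2H6", "C2H4"))  # mass of 2 H
#' @export
delta_mass <- function(d) {
  d <- as_comp_delta(d)
  if (length(d) == 0L) return(0)
  sum(.element_masses[names(d)] * as.numeric(d))
}

as_comp_delta <- function(d) {
  if (inherits(d, "comp_delta")) return(d)
  if (is.character(d)) return(parse_delta(d))
  if (is.numeric(d) && !is.null(names(d))) {
    bad <- setdiff(names(d), names(.element_masses))
    if (length(bad) > 0L) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    return(new_comp_delta(d))
  }
  stop("cannot interpret `d` as a composition delta", call. = FALSE)
}

delta_tokens <- function(counts) {
  # counts: positive integer vector, Hill-ordered; count precedes symbol,
  # count 1 omitted ("+2C3H" style).
  paste0(ifelse(counts == 1L, "", counts), names(counts), collapse = "")
}

#' Render a composition delta in gain/loss notation
#'
#' Gains are rendered first as `"+"` followed by count-element tokens in Hill
#' order (count 1 omitted); losses follow after `"/-"` in the same style.
#' The empty delta renders as `"0"`. Examples: `"+2H"`, `"+2C3H"`,
#' `"+2C4H/-O"`.
#'
#' @param d A `comp_delta`, or a named integer vector of signed counts.
#' @return A single string.
#' @examples
#' format_delta(formula_delta("C2H4O", "O2"))
#' @export
format_delta <- function(d) {
  d <- as_comp_delta(d)
  if (length(d) == 0L) return("0")
  gains <- d[d > 0L]
  losses <- -d[d < 0L]
  out <- ""
  if (length(gains) > 0L) out <- paste0("+", delta_tokens(gains))
  if (length(losses) > 0L) {
    sep <- if (length(gains) > 0L) "/-" else "-"
    out <- paste0(out, sep, delta_tokens(losses))
  }
  out
}

#' Parse a gain/loss composition-delta string
#'
#' Inverse of [format_delta()]. Accepts the ASCII hyphen and the Unicode
#' minus sign interchangeably, e.g. `"+2C4H/-O"` or `"+2C4H/−O"`;
#' `"0"` parses to the empty delta.
#'
#' @param text A single delta string.
#' @return A `comp_delta`.
#' @examples
#' parse_delta("+2C3H")
#' parse_delta("+2C4H/-O")
#' @export
parse_delta <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single delta string", call. = FALSE)
  }
  text <- gsub("−", "-", text)
  if (text == "0" || text == "") return(new_comp_delta(integer(0)))
  parts <- strsplit(text, "/", fixed = TRUE)[[1]]
  counts <- integer(0)
  for (part in parts) {
    sign <- substr(part, 1, 1)
    if (!sign %in% c("+", "-")) {
      stop("delta part must start with '+' or '-': '", part, "'",
           call. = FALSE)
    }
    body <- substr(part, 2, nchar(part))
    m <- gregexpr("([0-9]*)([A-Z][a-z]?)", body, perl = TRUE)[[1]]
    tokens <- regmatches(body, list(m))[[1]]
    if (!nzchar(body) || sum(nchar(tokens)) != nchar(body)) {
      stop("malformed delta string: '", text, "'", call. = FALSE)
    }
    syms <- gsub("[0-9]", "", tokens)
    cnts <- sub("[A-Za-z]+$", "", tokens)
    cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
    bad <- setdiff(syms, names(.element_masses))
    if (length(bad) > 0L) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    sgn <- if (sign == "+") 1L else -1L
    for (i in seq_along(syms)) {
      counts[syms[i]] <- sum(counts[names(counts) == syms[i]]) + sgn * cnts[i]
    }
  }
  new_comp_delta(counts)
}

#' @export
print.comp_delta <- function(x, ...) {
  cat("<composition delta> ", format_delta(x), "\n", sep = "")
  invisible(x)
}
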