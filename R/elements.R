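#' Monoisotopic atomic masses
#'
#' Returns the table of monoisotopic atomic masses (mass of the most abundant
#' naturally occurring isotope, in Da) used throughout the package. Values are
#' IUPAC/CODATA recommendations to at least six decimal places, which is the
#' precision required to reproduce four-decimal theoretical m/z values.
#'
#' @return A named numeric vector, element symbol to monoisotopic mass (Da).
#' @examples
#' element_masses()[["C"]]  # 12 exactly, by definition
#' @export
element_masses <- function() {
  c(
    H  = 1.00782503207,
    C  = 12,
    N  = 14.0030740048,
    O  = 15.9949146196,
    S  = 31.97207100,
    P  = 30.97376163,
    K  = 38.96370668,
    Li = 7.01600455,
    Cl = 34.96885268,
    Na = 22.9897692809,
    F  = 18.99840322,
    Br = 78.9183371,
    I  = 126.904473,
    Si = 27.9769265325,
    B  = 11.0093054
  )
}

#' Mass of a proton (Da)
#'
#' Used when converting a neutral monoisotopic mass to the m/z of the
#' protonated (\[M+H\]+) ion.
#' @export
PROTON_MASS <- 1.007276466

#' Parse a Hill-style elemental formula
#'
#' Splits a molecular formula such as `"C15H20O4"` into element counts.
#' Parsing is case sensitive on element symbols (an uppercase letter followed
#' by an optional lowercase letter), with optional positive integer counts.
#' Repeated elements are summed.
#'
#' @param formula A single formula string. The empty string yields an empty
#'   composition (mass 0).
#' @return A named integer vector of element counts (class
#'   `"elemental_composition"`).
#' @examples
#' parse_formula("C15H20O4")
#' parse_formula("C16H20N2O9S2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  formula <- trimws(formula)
  if (!nzchar(formula)) {
    return(structure(integer(0), class = "elemental_composition"))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("malformed formula: ", sQuote(formula), call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(cnt), suppressWarnings(as.integer(cnt)), 1L)
  known <- names(element_masses())
  bad <- setdiff(sym, known)
  if (length(bad)) {
    stop("unknown element symbol(s) in ", sQuote(formula), ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(cnt)) || any(cnt < 1L)) {
    stop("element counts must be positive integers in ", sQuote(formula),
         call. = FALSE)
  }
  counts <- tapply(cnt, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  # Hill order: C, H, then alphabetical
  ord <- order(match(names(out), c("C", "H"), nomatch = 3L), names(out))
  structure(out[ord], class = "elemental_composition")
}

#' Format an elemental composition as a Hill formula string
#'
#' Inverse of [parse_formula()]: `parse_formula(format_formula(x))` equals `x`.
#'
#' @param comp A named integer vector of element counts.
#' @return A single formula string.
#' @export
format_formula <- function(comp) {
  if (length(comp) == 0L) return("")
  ord <- order(match(names(comp), c("C", "H"), nomatch = 3L), names(comp))
  comp <- comp[ord]
  paste0(names(comp), ifelse(comp > 1L, comp, ""), collapse = "")
}

#' Monoisotopic mass of an elemental composition
#'
#' Sums `count * atomic mass` over the composition.
#'
#' @param comp A named integer vector of element counts, as returned by
#'   [parse_formula()]. An empty composition has mass 0.
#' @param masses Atomic mass table; defaults to [element_masses()].
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))   # 18.010565
#' monoisotopic_mass(parse_formula("C15H20O4"))  # abscisic acid, 264.1362
#' @export
monoisotopic_mass <- function(comp, masses = element_masses()) {
  if (length(comp) == 0L) return(0)
  missing_el <- setdiff(names(comp), names(masses))
  if (length(missing_el)) {
    stop("no atomic mass for element(s): ", paste(missing_el, collapse = ", "),
         call. = FALSE)
  }
  sum(as.numeric(comp) * masses[names(comp)])
}

# Monoisotopic mass straight from a formula string.
formula_mass <- function(formula, masses = element_masses()) {
  monoisotopic_mass(parse_formula(formula), masses)
}
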