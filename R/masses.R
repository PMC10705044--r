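# Elemental mass tables and chemical-formula arithmetic.
#
# Masses are embedded as versioned constants (IUPAC 2021 standard atomic
# weights; monoisotopic = most abundant isotope, CODATA/AME2020) so results
# are bit-stable across environments. Coverage is the element set occurring
# in small-molecule pharmaceuticals and their transformation products.

.mass_table_version <- "IUPAC-2021/AME-2020 v1"

# Standard (abundance-averaged) atomic weights, g/mol.
.average_mass <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998403163,
  Na = 22.98976928, Mg = 24.305, P = 30.973761998, S = 32.06,
  Cl = 35.45, K = 39.0983, Ca = 40.078, Br = 79.904, I = 126.90447
)

# Most-abundant-isotope (monoisotopic) masses, Da.
.monoisotopic_mass <- c(
  H = 1.00782503207, C = 12, N = 14.0030740048, O = 15.9949146196,
  F = 18.99840322, Na = 22.9897692809, Mg = 23.985041700,
  P = 30.97376163, S = 31.97207100, Cl = 34.96885268,
  K = 38.96370668, Ca = 39.96259098, Br = 78.9183371, I = 126.904473
)

# Mass of a proton (Da); charge carriers for adduct m/z.
.proton_mass <- 1.007276466879
.electron_mass <- 0.000548579909

#' Parse a chemical formula into element counts
#'
#' Accepts Hill-style formulas of element symbols with optional integer
#' counts, e.g. `"C14H11Cl2NO3"`. Parentheses and isotopic labels are not
#' supported (none of the compounds screened here need them).
#'
#' @param formula Character scalar formula string.
#' @return Named integer vector of positive element counts.
#' @examples
#' parse_formula("C15H22O3")
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("formula must be a single non-empty string")
  }
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  matched <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(attr(tokens, "match.length")) != nchar(formula)) {
    stop("malformed formula: ", formula)
  }
  elements <- sub("[0-9]*$", "", matched)
  counts <- as.integer(sub("^[A-Za-z]+", "", paste0(matched, "")))
  counts[is.na(counts)] <- 1L
  unknown <- setdiff(elements, names(.average_mass))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 1L)) stop("element counts must be positive integers")
  out <- tapply(counts, factor(elements, levels = unique(elements)), sum)
  setNames(as.integer(out), names(out))
}

#' Average (abundance-weighted) molecular mass
#'
#' @param formula Formula string or a parsed element-count vector.
#' @return Molecular mass in g/mol.
#' @examples
#' average_mass("C37H67NO13")  # erythromycin, ~733.9
#' @export
average_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(.average_mass[names(counts)] * counts)
}

#' Monoisotopic molecular mass
#'
#' Sum of most-abundant-isotope masses; the theoretical neutral mass used
#' for ppm mass-error screening of high-resolution MS peaks.
#'
#' @inheritParams average_mass
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C")  # exactly 12 by definition
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(.monoisotopic_mass[names(counts)] * counts)
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' Supported singly charged positive-mode adducts: `"[M+H]+"` (default) and
#' `"[M+Na]+"`.
#'
#' @param neutral_mass Neutral monoisotopic mass, Da.
#' @param adduct Adduct identifier.
#' @return Theoretical m/z.
#' @export
adduct_mz <- function(neutral_mass, adduct = "[M+H]+") {
  check_scalar_number(neutral_mass, "neutral_mass", lower = 0,
                      strict_lower = TRUE)
  shift <- switch(adduct,
    "[M+H]+" = .proton_mass,
    "[M+Na]+" = .monoisotopic_mass[["Na"]] - .electron_mass,
    stop("unknown adduct: ", adduct)
  )
  neutral_mass + shift
}

#' Signed mass error in parts per million
#'
#' @param observed_mz Observed m/z.
#' @param theoretical_mz Theoretical m/z (> 0).
#' @return Signed ppm error, `1e6 * (observed - theoretical) / theoretical`.
#' @export
mass_error_ppm <- function(observed_mz, theoretical_mz) {
  if (any(!is.finite(theoretical_mz)) || any(theoretical_mz <= 0)) {
    stop("theoretical_mz must be positive")
  }
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}
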