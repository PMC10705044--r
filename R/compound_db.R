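# Built-in compound database (PCDL dialect) for suspect screening.

#' Built-in compound database of parent pharmaceuticals and degradation
#' products
#'
#' Returns the package's personal compound database and library (PCDL):
#' the three parent pharmaceuticals diclofenac (DCF), erythromycin (ERY)
#' and gemfibrozil (GEM) plus the literature degradation products tracked
#' in granular-sludge exposure studies (DCF1--DCF3, ERY1--ERY2,
#' GEM1--GEM3). A user-supplied database in the same dialect (columns
#' `code`, `name`, `formula`, `parent`, `pathway_position`) can be used
#' anywhere this one is accepted; see [read_compound_db()].
#'
#' Notes on two formulas:
#' \itemize{
#'   \item The DCF parent is recorded as C14H11Cl2NO2 (mass ~296.1 g/mol,
#'     the accepted diclofenac formula); the hydroxylated product DCF1 is
#'     C14H11Cl2NO3. Some printed tables conflate the two; the
#'     mass-consistent assignment is used here.
#'   \item GEM2 (5-(2-formylphenoxy)-2,2-dimethylpentanoic acid) has no
#'     literature formula at hand; C15H20O4 is inferred from GEM1
#'     (C15H22O4) by oxidation of the hydroxymethyl to a formyl group.
#' }
#'
#' @return A data.frame with one row per compound.
#' @export
compound_db <- function() {
  db <- data.frame(
    code = c("DCF", "DCF1", "DCF2", "DCF3",
             "ERY", "ERY1", "ERY2",
             "GEM", "GEM1", "GEM2", "GEM3"),
    name = c(
      "diclofenac",
      "hydroxy-diclofenac",
      "1-(2-chloro-4-hydroxyphenyl)-3H-indol-2-one",
      "1-(4-hydroxyphenyl)-2,3-dihydro-1H-indol-2-one",
      "erythromycin",
      "3-depyranosyloxy erythromycin",
      "7,12-dihydroxy-6-deoxyerythronolide B",
      "gemfibrozil",
      "5-[2-(hydroxymethyl)phenoxy]-2,2-dimethylpentanoic acid",
      "5-(2-formylphenoxy)-2,2-dimethylpentanoic acid",
      "2-[(4-carboxy-4-methylpentyl)oxy]benzoic acid"
    ),
    formula = c("C14H11Cl2NO2", "C14H11Cl2NO3", "C14H10ClNO2", "C14H11NO2",
                "C37H67NO13", "C29H53NO10", "C21H38O8",
                "C15H22O3", "C15H22O4", "C15H20O4", "C15H20O5"),
    parent = c(NA, "DCF", "DCF", "DCF",
               NA, "ERY", "ERY",
               NA, "GEM", "GEM", "GEM"),
    pathway_position = c("parent", "primary", "secondary", "tertiary",
                         "parent", "primary", "secondary",
                         "parent", "primary", "secondary", "tertiary"),
    stringsAsFactors = FALSE
  )
  validate_compound_db(db)
}

#' Read a compound database from a delimited file
#'
#' @param path Path to a CSV file with columns `code`, `name`, `formula`,
#'   `parent`, `pathway_position`.
#' @return Validated compound database data.frame.
#' @export
read_compound_db <- function(path) {
  db <- read.csv(path, stringsAsFactors = FALSE)
  validate_compound_db(db)
}

validate_compound_db <- function(db) {
  needed <- c("code", "name", "formula", "parent", "pathway_position")
  missing <- setdiff(needed, names(db))
  if (length(missing)) {
    stop("compound database lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(db$code)) stop("duplicate compound codes in database")
  for (f in db$formula) parse_formula(f)  # errors on malformed formulas
  nonparent <- db[db$pathway_position != "parent", ]
  orphan <- setdiff(nonparent$parent, db$code)
  if (length(orphan) || anyNA(nonparent$parent)) {
    stop("degradation product(s) reference a parent absent from the database")
  }
  db
}
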