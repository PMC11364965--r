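#' Construct a compound database
#'
#' A compound database is a data frame with one row per catalogued compound:
#' `name`, `class` (hormone class, e.g. `"cytokinins"`), `monoisotopic_mass`
#' (Da) and optional `formula`, `smiles`, `inchi`, `predicted_rt` (minutes).
#' Names are unique (whitespace-trimmed, case preserved); catalogued masses
#' must be positive and, when a formula is present, agree with the
#' formula-derived monoisotopic mass within `mass_tol`.
#'
#' @param entries A data frame with at least `name`, `class`,
#'   `monoisotopic_mass`.
#' @param provenance Free-text description of where the catalogue came from.
#' @param mass_tol Maximum allowed |catalogued - formula-derived| mass
#'   deviation in Da (default 0.005, matching the 2-4 decimal precision of
#'   catalogued masses).
#' @return A data frame of class `"compound_db"`.
#' @export
compound_db <- function(entries, provenance = "user", mass_tol = 0.005) {
  stopifnot(is.data.frame(entries))
  need <- c("name", "class", "monoisotopic_mass")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols)) {
    stop("compound database is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  db <- as.data.frame(entries, stringsAsFactors = FALSE)
  db$name <- trimws(as.character(db$name))
  db$class <- trimws(as.character(db$class))
  for (col in c("formula", "smiles", "inchi")) {
    if (!col %in% names(db)) db[[col]] <- rep(NA_character_, nrow(db))
    db[[col]] <- as.character(db[[col]])
    db[[col]][!nzchar(trimws(ifelse(is.na(db[[col]]), "", db[[col]])))] <- NA_character_
  }
  if (!"predicted_rt" %in% names(db)) db$predicted_rt <- rep(NA_real_, nrow(db))

  problems <- character(0)
  mass_raw <- db$monoisotopic_mass
  mass_num <- suppressWarnings(as.numeric(mass_raw))
  bad_mass <- which(is.na(mass_num) | mass_num <= 0)
  if (length(bad_mass)) {
    problems <- c(problems, sprintf(
      "row %d (%s): monoisotopic_mass %s is not a positive number",
      bad_mass, db$name[bad_mass], as.character(mass_raw[bad_mass])))
  }
  db$monoisotopic_mass <- mass_num
  db$predicted_rt <- suppressWarnings(as.numeric(db$predicted_rt))

  empty <- which(!nzchar(db$name))
  if (length(empty)) {
    problems <- c(problems, sprintf("row %d: empty compound name", empty))
  }
  dup <- db$name[duplicated(db$name)]
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate compound name(s): ",
                                   paste(unique(dup), collapse = ", ")))
  }
  has_f <- !is.na(db$formula)
  if (any(has_f) && length(bad_mass) == 0L) {
    fmass <- vapply(db$formula[has_f], formula_mass, numeric(1))
    dev <- abs(db$monoisotopic_mass[has_f] - fmass)
    off <- which(dev > mass_tol)
    if (length(off)) {
      idx <- which(has_f)[off]
      problems <- c(problems, sprintf(
        "row %d (%s): catalogued mass %.4f deviates from formula mass %.4f by %.4f Da",
        idx, db$name[idx], db$monoisotopic_mass[idx], fmass[off], dev[off]))
    }
  }
  if (length(problems)) {
    stop("invalid compound database:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  db <- db[, c("name", "class", "formula", "monoisotopic_mass",
               "smiles", "inchi", "predicted_rt")]
  rownames(db) <- NULL
  class(db) <- c("compound_db", "data.frame")
  attr(db, "provenance") <- provenance
  db
}

#' Load a compound database from CSV
#'
#' The CSV must have a header with columns `name`, `class`,
#' `monoisotopic_mass`; `formula`, `smiles`, `inchi` and `predicted_rt` are
#' optional. Row-level problems (non-numeric masses, duplicate names,
#' formula/mass disagreement) are collected and reported together.
#'
#' @param path Path to a CSV file.
#' @param mass_tol See [compound_db()].
#' @return A `"compound_db"` data frame.
#' @examples
#' db <- load_compound_db(hormonomics_example("fixture_compounds.csv"))
#' nrow(db)
#' @export
load_compound_db <- function(path, mass_tol = 0.005) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  compound_db(raw, provenance = path, mass_tol = mass_tol)
}

#' Cross-check catalogued masses against formulas
#'
#' Report-only validation: lists every entry whose catalogued monoisotopic
#' mass deviates from its formula-derived mass by more than `tol`. Entries
#' without a formula cannot be verified and are counted separately.
#'
#' @param db A `"compound_db"`.
#' @param tol Tolerance in Da (default 0.005).
#' @return A data frame of class `"db_validation"` with columns `name`,
#'   `catalogued`, `computed`, `deviation`; attribute `unverifiable` holds
#'   the number of entries lacking a formula. An empty report means clean.
#' @export
validate_db <- function(db, tol = 0.005) {
  stopifnot(inherits(db, "compound_db"))
  has_f <- !is.na(db$formula)
  out <- data.frame(name = character(0), catalogued = numeric(0),
                    computed = numeric(0), deviation = numeric(0),
                    stringsAsFactors = FALSE)
  if (any(has_f)) {
    fmass <- vapply(db$formula[has_f], formula_mass, numeric(1))
    dev <- abs(db$monoisotopic_mass[has_f] - fmass)
    off <- dev > tol
    out <- data.frame(name = db$name[has_f][off],
                      catalogued = db$monoisotopic_mass[has_f][off],
                      computed = unname(fmass[off]),
                      deviation = unname(dev[off]),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("db_validation", "data.frame")
  attr(out, "unverifiable") <- sum(!has_f)
  attr(out, "tol") <- tol
  out
}

#' @export
print.db_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat(sprintf("clean: no catalogued mass deviates by more than %g Da (%d unverifiable)\n",
                attr(x, "tol"), attr(x, "unverifiable")))
  } else {
    cat(sprintf("%d entr%s deviate by more than %g Da (%d unverifiable):\n",
                nrow(x), if (nrow(x) == 1L) "y" else "ies",
                attr(x, "tol"), attr(x, "unverifiable")))
    print.data.frame(x, ...)
  }
  invisible(x)
}

#' @export
print.compound_db <- function(x, ...) {
  cat(sprintf("<compound database> %d compounds, %d classes (%s)\n",
              nrow(x), length(unique(x$class)),
              attr(x, "provenance")))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
hormonomics_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "hormonomics")))
  }
  path <- system.file("extdata", file, package = "hormonomics")
  if (!nzchar(path)) stop("no packaged file called ", sQuote(file), call. = FALSE)
  path
}

#' The packaged fixture compound database
#'
#' A small, self-contained catalogue of phytohormones and hormone metabolites
#' (abscisic acid and hydroxylated relatives, melatonin and its conjugates,
#' serotonin, cytokinins, auxins and auxin amino-acid conjugates, tryptophan
#' metabolites, and assorted standards), each with hormone class, elemental
#' formula, formula-derived monoisotopic mass, SMILES and, where available,
#' a predicted retention time on the reference 25-minute gradient.
#'
#' @return A `"compound_db"` data frame.
#' @export
fixture_compounds <- function() {
  load_compound_db(hormonomics_example("fixture_compounds.csv"))
}
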