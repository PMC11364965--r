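#' Moiety table for adduct and biotransformation notation
#'
#' The small chemical moieties that can be added to or removed from a parent
#' molecule in shift notation (e.g. `"M-OH+CH3"`). Masses are neutral-moiety
#' monoisotopic masses; ionic adducts (Li, K, NH4, H) deliberately use the
#' neutral atom/group mass without electron correction (about 0.00055 Da),
#' which is far below both the four-decimal printed precision of theoretical
#' m/z values and the 0.02 Da search tolerances used in screening.
#'
#' @return A data frame with columns `token`, `formula` and `mass` (Da).
#' @export
moiety_table <- function() {
  tokens <- c(H = "H", H2 = "H2", OH = "HO", CH3 = "CH3", NH2 = "H2N",
              NH3 = "H3N", NH4 = "H4N", COOH = "CHO2", C6H12O6 = "C6H12O6",
              H2O = "H2O", CH3OH = "CH4O", Li = "Li", K = "K")
  data.frame(
    token = names(tokens),
    formula = unname(tokens),
    mass = vapply(unname(tokens), formula_mass, numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Moiety tokens, longest first so that e.g. "NH3" is not read as "N","H3".
.moiety_tokens <- function() {
  tk <- moiety_table()$token
  tk[order(nchar(tk), decreasing = TRUE)]
}

#' Parse mass-shift notation
#'
#' Parses notation of the form `"M"`, `"M+H"`, `"M-OH+CH3"`, `"M+H-2H2O"`
#' into a signed list of moiety terms with a net monoisotopic mass delta.
#' A leading integer on a term is a multiplier (`"2H2O"` means two waters);
#' multipliers only appear as leading integers, there is no nesting.
#'
#' @param notation A single string beginning with `"M"`.
#' @param kind Rule category. Defaults to `"identity"` for the bare `"M"` and
#'   `"biotransformation"` otherwise; [builtin_ruleset()] assigns
#'   `"adduct"` / `"protonation"` for its own rules.
#' @return An object of class `"mass_shift_rule"`: a list with elements
#'   `label` (canonical notation), `kind`, `delta` (Da) and `terms`
#'   (data frame `sign`, `coef`, `token`, `mass`).
#' @examples
#' parse_shift("M-OH+CH3")
#' parse_shift("M+H-2H2O")
#' @export
parse_shift <- function(notation, kind = NULL) {
  stopifnot(is.character(notation), length(notation) == 1L, !is.na(notation))
  s <- gsub("[[:space:]]", "", notation)
  if (!startsWith(s, "M")) {
    stop("shift notation must begin with 'M': ", sQuote(notation),
         call. = FALSE)
  }
  rest <- substring(s, 2L)
  terms <- data.frame(sign = integer(0), coef = integer(0),
                      token = character(0), mass = numeric(0),
                      stringsAsFactors = FALSE)
  if (nzchar(rest)) {
    if (!grepl("^[+-]", rest)) {
      stop("expected '+' or '-' after 'M' in ", sQuote(notation),
           call. = FALSE)
    }
    # split into sign-prefixed chunks
    pieces <- regmatches(rest, gregexpr("[+-][^+-]*", rest))[[1]]
    if (sum(nchar(pieces)) != nchar(rest)) {
      stop("malformed sign sequence in ", sQuote(notation), call. = FALSE)
    }
    mt <- moiety_table()
    for (p in pieces) {
      sign <- if (startsWith(p, "+")) 1L else -1L
      body <- substring(p, 2L)
      coef_str <- sub("^([0-9]*).*$", "\\1", body)
      coef <- if (nzchar(coef_str)) as.integer(coef_str) else 1L
      tok <- substring(body, nchar(coef_str) + 1L)
      if (!nzchar(tok) || !(tok %in% mt$token)) {
        stop("unknown moiety token ", sQuote(tok), " in ", sQuote(notation),
             call. = FALSE)
      }
      if (is.na(coef) || coef < 1L) {
        stop("bad coefficient in ", sQuote(notation), call. = FALSE)
      }
      terms <- rbind(terms, data.frame(
        sign = sign, coef = coef, token = tok,
        mass = mt$mass[match(tok, mt$token)], stringsAsFactors = FALSE))
    }
  }
  if (is.null(kind)) {
    kind <- if (nrow(terms) == 0L) "identity" else "biotransformation"
  }
  kind <- match.arg(kind,
                    c("adduct", "biotransformation", "protonation", "identity"))
  label <- if (nrow(terms) == 0L) "M" else paste0(
    "M", paste0(ifelse(terms$sign > 0L, "+", "-"),
                ifelse(terms$coef > 1L, terms$coef, ""), terms$token,
                collapse = ""))
  structure(
    list(label = label, kind = kind,
         delta = sum(terms$sign * terms$coef * terms$mass), terms = terms),
    class = "mass_shift_rule")
}

#' Net mass delta of a shift rule
#'
#' Recomputes the signed sum of moiety masses from the rule's terms.
#'
#' @param rule A `"mass_shift_rule"` object.
#' @return Signed mass delta in Da.
#' @export
shift_delta <- function(rule) {
  stopifnot(inherits(rule, "mass_shift_rule"))
  if (nrow(rule$terms) == 0L) return(0)
  sum(rule$terms$sign * rule$terms$coef * rule$terms$mass)
}

#' Apply a mass shift to a neutral monoisotopic mass
#'
#' In `"neutral_shift"` mode the theoretical value is `mass + delta`; in
#' `"protonated"` mode a proton mass (1.007276 Da) is added on top, giving
#' the \[M+H\]+ m/z of the shifted species. The package default throughout is
#' `"neutral_shift"`, which is the convention that reproduces the published
#' worked examples for biotransformed phytohormones.
#'
#' @param mass Neutral monoisotopic mass (Da), positive. Vectorised.
#' @param rule A `"mass_shift_rule"`.
#' @param mode `"neutral_shift"` or `"protonated"`.
#' @return Theoretical m/z (Da).
#' @examples
#' aba <- monoisotopic_mass(parse_formula("C15H20O4"))
#' apply_shift(aba, parse_shift("M-OH+CH3"))  # 262.1569
#' @export
apply_shift <- function(mass, rule, mode = c("neutral_shift", "protonated")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(mass), all(mass > 0))
  out <- mass + shift_delta(rule) + if (mode == "protonated") PROTON_MASS else 0
  if (any(out <= 0)) {
    stop("shift ", sQuote(rule$label),
         " yields a non-positive mass (moiety heavier than the molecule)",
         call. = FALSE)
  }
  out
}

# The published rule lists. Adducts: 7; biotransformations: 27.
.adduct_labels <- c("M+H-2H2O", "M+H-H2O", "M+NH4-H2O", "M+Li", "M+NH4",
                    "M+CH3OH-H", "M+K")
.biotransformation_labels <- c(
  "M+CH3", "M+C6H12O6", "M+OH", "M+COOH", "M+NH2", "M+NH3",
  "M-H+OH", "M-H+2OH", "M-H+NH2",
  "M-CH3+H", "M-CH3+OH", "M-CH3+NH2",
  "M-C6H12O6+H", "M-C6H12O6+OH", "M-C6H12O6+NH2", "M-C6H12O6+CH3",
  "M-OH+H2", "M-OH+CH3", "M-OH+C6H12O6", "M-OH+COOH", "M-OH+NH2", "M-OH+NH3",
  "M-NH2+H2", "M-NH2+CH3", "M-NH2+C6H12O6", "M-NH2+COOH", "M-NH2+OH")
# Chemically common alternate for methanol adduction, not in the default set:
# "M+CH3OH+H" (the published adduct list prints M+CH3OH-H and is kept as is).

#' Built-in searchable rule sets
#'
#' The four searchable databases: the bare monoisotopic mass (identity rule),
#' the \[M+H\]+ adduct, the 7 common electrospray adducts, and the 27
#' synthetic biotransformations (mass shifts modelling plausible enzymatic
#' modifications: methylation, hydroxylation, glycosylation, amination,
#' carboxylation, and their removals/exchanges).
#'
#' @param name One of `"PGR_Monoisotopic"`, `"PGR_MplusH"`, `"PGR_Adducts"`,
#'   `"PGR_Biotransformations"`, or the short aliases `"monoisotopic"`,
#'   `"mh"`, `"adducts"`, `"biotransformations"`.
#' @return An object of class `"mass_ruleset"`: list with `name` and `rules`
#'   (a list of `"mass_shift_rule"`).
#' @examples
#' length(builtin_ruleset("biotransformations")$rules)  # 27
#' @export
builtin_ruleset <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  canon <- c(monoisotopic = "PGR_Monoisotopic", mh = "PGR_MplusH",
             adducts = "PGR_Adducts", biotransformations = "PGR_Biotransformations")
  if (name %in% names(canon)) name <- canon[[name]]
  rules <- switch(name,
    PGR_Monoisotopic = list(parse_shift("M")),
    PGR_MplusH = list(parse_shift("M+H", kind = "protonation")),
    PGR_Adducts = lapply(.adduct_labels, parse_shift, kind = "adduct"),
    PGR_Biotransformations = lapply(.biotransformation_labels, parse_shift,
                                    kind = "biotransformation"),
    stop("unknown rule set ", sQuote(name), "; expected one of ",
         paste(canon, collapse = ", "), call. = FALSE))
  structure(list(name = name, rules = rules), class = "mass_ruleset")
}

#' @export
print.mass_shift_rule <- function(x, ...) {
  cat(sprintf("<mass shift> %s  (%s)  delta = %+.6f Da\n",
              x$label, x$kind, x$delta))
  invisible(x)
}

#' @export
print.mass_ruleset <- function(x, ...) {
  cat(sprintf("<rule set> %s: %d rule(s)\n", x$name, length(x$rules)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.mass_ruleset <- function(x, ...) {
  data.frame(
    label = vapply(x$rules, `[[`, character(1), "label"),
    kind = vapply(x$rules, `[[`, character(1), "kind"),
    delta = vapply(x$rules, `[[`, numeric(1), "delta"),
    stringsAsFactors = FALSE)
}

#' Serialize / read a rule set as CSV
#'
#' CSV columns are `label,kind,delta`; `label` is re-parsed on read (it
#' round-trips through [parse_shift()]) and the stored `delta` is checked
#' against the recomputed one.
#'
#' @param ruleset A `"mass_ruleset"`.
#' @param path CSV file path.
#' @return `read_ruleset()` returns a `"mass_ruleset"`;
#'   `write_ruleset()` returns `path` invisibly.
#' @export
write_ruleset <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "mass_ruleset"))
  utils::write.csv(as.data.frame(ruleset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ruleset
#' @param name Name for the rule set read from `path`.
#' @export
read_ruleset <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "kind", "delta")
  if (!all(need %in% names(df))) {
    stop("rule-set CSV must have columns label,kind,delta", call. = FALSE)
  }
  rules <- Map(parse_shift, df$label, df$kind)
  bad <- abs(vapply(rules, `[[`, numeric(1), "delta") - df$delta) > 1e-6
  if (any(bad)) {
    stop("stored delta disagrees with recomputed delta for: ",
         paste(df$label[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, rules = unname(rules)), class = "mass_ruleset")
}

#' Expand a compound database by a rule set
#'
#' Computes the theoretical m/z of every compound under every rule, in
#' database order crossed with rule order (compound-major). Entries whose
#' shifted mass would be non-positive are dropped and reported in the
#' `"rejected"` attribute.
#'
#' @param db A `"compound_db"` (see [load_compound_db()]).
#' @param rules A `"mass_ruleset"` or the name of a built-in one.
#' @param mode Shift mode, see [apply_shift()].
#' @return A data frame of class `"shifted_entries"` with columns
#'   `compound`, `class`, `rule`, `kind`, `theoretical_mz`, `parent_mass`,
#'   `predicted_rt`.
#' @export
expand_database <- function(db, rules, mode = c("neutral_shift", "protonated")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "compound_db"))
  if (is.character(rules)) rules <- builtin_ruleset(rules)
  stopifnot(inherits(rules, "mass_ruleset"))
  nr <- length(rules$rules)
  nc <- nrow(db)
  if (nc == 0L || nr == 0L) {
    out <- data.frame(compound = character(0), class = character(0),
                      rule = character(0), kind = character(0),
                      theoretical_mz = numeric(0), parent_mass = numeric(0),
                      predicted_rt = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("shifted_entries", "data.frame")
    attr(out, "rejected") <- out[0, c("compound", "rule")]
    return(out)
  }
  deltas <- vapply(rules$rules, shift_delta, numeric(1))
  labels <- vapply(rules$rules, `[[`, character(1), "label")
  kinds <- vapply(rules$rules, `[[`, character(1), "kind")
  ci <- rep(seq_len(nc), each = nr)
  ri <- rep(seq_len(nr), times = nc)
  mz <- db$monoisotopic_mass[ci] + deltas[ri] +
    if (mode == "protonated") PROTON_MASS else 0
  out <- data.frame(
    compound = db$name[ci], class = db$class[ci],
    rule = labels[ri], kind = kinds[ri],
    theoretical_mz = mz, parent_mass = db$monoisotopic_mass[ci],
    predicted_rt = if ("predicted_rt" %in% names(db))
      db$predicted_rt[ci] else NA_real_,
    stringsAsFactors = FALSE)
  keep <- out$theoretical_mz > 0
  rejected <- out[!keep, c("compound", "rule")]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shifted_entries", "data.frame")
  attr(out, "rejected") <- rejected
  attr(out, "mode") <- mode
  out
}
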