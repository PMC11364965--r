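#' Read an untargeted LC-MS peak table
#'
#' The expected CSV layout is the common aligned-feature-table contract:
#' a header row, m/z in the first column, retention time (minutes) in the
#' second, and one intensity column per sample in the remaining columns.
#' No assumption is made about signal-to-noise filtering; that is the job of
#' the upstream peak picking/alignment software.
#'
#' @param path CSV file path.
#' @param max_bytes Maximum file size in bytes (default 10485760, i.e. 10 MB);
#'   raise or set to `Inf` to override.
#' @return A data frame of class `"peak_table"` with columns `row_index`,
#'   `mz`, `rt`, then one column per sample; attribute `sample_names`.
#' @export
read_peak_table <- function(path, max_bytes = 10485760) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sz <- file.size(path)
  if (is.finite(max_bytes) && sz > max_bytes) {
    stop(sprintf("peak table is %d bytes, over the %d byte limit (raise max_bytes to override)",
                 sz, as.integer(max_bytes)), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2L) {
    stop("peak table needs at least 2 columns (m/z, RT); got ", ncol(raw),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("peak table ", basename(path), " has a header but no features")
  }
  mz <- suppressWarnings(as.numeric(raw[[1L]]))
  rt <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(is.na(mz) | is.na(rt) | mz <= 0 | rt < 0)
  if (length(bad)) {
    stop("non-numeric or out-of-range m/z / RT at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  peak_table(mz, rt,
             intensities = if (ncol(raw) > 2L) raw[, -(1:2), drop = FALSE] else NULL,
             source = path)
}

#' Build a peak table in code
#'
#' @param mz Observed m/z values (positive).
#' @param rt Observed retention times in minutes (non-negative).
#' @param intensities Optional data frame / matrix of per-sample intensities,
#'   one row per feature.
#' @param source Free-text provenance string.
#' @return A `"peak_table"` data frame; see [read_peak_table()].
#' @export
peak_table <- function(mz, rt, intensities = NULL, source = "in-memory") {
  stopifnot(is.numeric(mz), is.numeric(rt), length(mz) == length(rt),
            all(mz > 0), all(rt >= 0))
  out <- data.frame(row_index = seq_along(mz), mz = mz, rt = rt)
  sample_names <- character(0)
  if (!is.null(intensities)) {
    intensities <- as.data.frame(intensities)
    stopifnot(nrow(intensities) == length(mz))
    sample_names <- colnames(intensities)
    out <- cbind(out, intensities)
  }
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  attr(out, "sample_names") <- sample_names
  attr(out, "source") <- source
  out
}

#' Mass tolerance
#'
#' @param value Positive tolerance value.
#' @param unit `"da"` (absolute Daltons) or `"ppm"` (parts per million of the
#'   reference m/z).
#' @return An object of class `"mass_tolerance"`.
#' @examples
#' tolerance(0.02, "da")
#' tolerance(10, "ppm")
#' @export
tolerance <- function(value, unit = c("da", "ppm")) {
  unit <- match.arg(tolower(unit), c("da", "ppm"))
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  structure(list(value = value, unit = unit), class = "mass_tolerance")
}

#' @export
print.mass_tolerance <- function(x, ...) {
  cat(sprintf("+/- %g %s\n", x$value, if (x$unit == "da") "Da" else "ppm"))
  invisible(x)
}

#' Convert a tolerance to Daltons at a given m/z
#'
#' ppm tolerances are evaluated at the theoretical (database) m/z, so each
#' database entry has a single, deterministic window.
#'
#' @param tol A `"mass_tolerance"`.
#' @param at_mz Reference m/z (vectorised, positive).
#' @return Tolerance in Da.
#' @export
tolerance_in_da <- function(tol, at_mz) {
  stopifnot(inherits(tol, "mass_tolerance"), all(at_mz > 0))
  if (tol$unit == "da") rep(tol$value, length(at_mz)) else at_mz * tol$value / 1e6
}

#' Percent retention-time match
#'
#' Scores how close an observed retention time is to the predicted retention
#' time of a database compound: `100 * (1 - |rt_obs - rt_pred| / rt_pred)`,
#' clipped to `[0, 100]`. 100 means an exact match; the score reaches 0 when
#' the absolute deviation equals the predicted retention time.
#'
#' @param rt_obs Observed RT in minutes (vectorised).
#' @param rt_pred Predicted RT in minutes (positive, vectorised).
#' @return Percent match in `[0, 100]`.
#' @examples
#' rt_match_percent(3.94, 4.20)  # 93.81
#' @export
rt_match_percent <- function(rt_obs, rt_pred) {
  if (any(!is.na(rt_pred) & rt_pred <= 0)) {
    stop("rt_match_percent is undefined for non-positive predicted RT",
         call. = FALSE)
  }
  pmax(0, 100 * (1 - abs(rt_obs - rt_pred) / rt_pred))
}

# Guard for floating-point noise right at the tolerance boundary: one nano-Da,
# far below instrument precision, keeps |delta| == tol cases inclusive.
.MZ_BOUNDARY_EPS <- 1e-9

#' Match peak-table features to expanded database entries on m/z
#'
#' Returns one annotation per (feature, entry) pair whose m/z difference is
#' within tolerance (inclusive at the boundary). A feature may match several
#' isobaric entries; all are returned. The retention-time match percentage is
#' computed where the entry carries a predicted RT and is `NA` otherwise.
#' Annotations carry MSI (metabolomics standards initiative) level 3: two
#' orthogonal physicochemical properties, no reference standard.
#'
#' @param table A `"peak_table"`.
#' @param entries A `"shifted_entries"` data frame (see [expand_database()]).
#' @param tol A `"mass_tolerance"`.
#' @return A data frame of class `"annotations"`: `row_index`, `mz`, `rt`,
#'   `compound`, `class`, `rule`, `theoretical_mz`, `delta_mz`
#'   (observed - theoretical), `predicted_rt`, `rt_match_pct`, `msi_level`.
#' @export
match_features <- function(table, entries, tol) {
  stopifnot(inherits(table, "peak_table"), is.data.frame(entries),
            inherits(tol, "mass_tolerance"))
  if (nrow(entries) == 0L) stop("no database entries to match against",
                                call. = FALSE)
  ord <- order(table$mz)
  mz_sorted <- table$mz[ord]
  tol_da <- tolerance_in_da(tol, entries$theoretical_mz)
  lo <- entries$theoretical_mz - tol_da - .MZ_BOUNDARY_EPS
  hi <- entries$theoretical_mz + tol_da + .MZ_BOUNDARY_EPS
  i0 <- findInterval(lo, mz_sorted, left.open = TRUE) + 1L
  i1 <- findInterval(hi, mz_sorted)
  n_hit <- pmax(0L, i1 - i0 + 1L)
  ei <- rep.int(seq_len(nrow(entries)), n_hit)
  fi <- ord[unlist(lapply(which(n_hit > 0L), function(j) seq.int(i0[j], i1[j])),
                   use.names = FALSE)]
  out <- data.frame(
    row_index = table$row_index[fi],
    mz = table$mz[fi],
    rt = table$rt[fi],
    compound = entries$compound[ei],
    class = if ("class" %in% names(entries)) entries$class[ei] else NA_character_,
    rule = entries$rule[ei],
    theoretical_mz = entries$theoretical_mz[ei],
    delta_mz = table$mz[fi] - entries$theoretical_mz[ei],
    predicted_rt = entries$predicted_rt[ei],
    stringsAsFactors = FALSE)
  has_rt <- !is.na(out$predicted_rt) & out$predicted_rt > 0
  out$rt_match_pct <- rep(NA_real_, nrow(out))
  out$rt_match_pct[has_rt] <- rt_match_percent(out$rt[has_rt],
                                               out$predicted_rt[has_rt])
  out$msi_level <- rep(3L, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("annotations", "data.frame")
  out
}

#' Rank annotations by retention-time match
#'
#' Annotations are grouped by feature (ascending `row_index`); within a
#' feature they are sorted by descending percent RT match. Entries without a
#' predicted RT sort last, and ties are broken by ascending |delta m/z| and
#' then compound name. The output is a permutation of the input.
#'
#' @param annots An `"annotations"` data frame.
#' @return The same rows, reordered.
#' @export
rank_annotations <- function(annots) {
  stopifnot(is.data.frame(annots))
  if (nrow(annots) == 0L) return(annots)
  o <- order(annots$row_index, is.na(annots$rt_match_pct),
             -replace(annots$rt_match_pct, is.na(annots$rt_match_pct), -Inf),
             abs(annots$delta_mz), annots$compound)
  out <- annots[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove duplicate compound/rule hits
#'
#' Keeps the first (i.e. highest-ranked, if the input is ranked) annotation
#' per `(compound, rule)` pair; output order follows first occurrence.
#' Idempotent.
#'
#' @param annots An `"annotations"` data frame, normally ranked.
#' @return The deduplicated subset.
#' @export
dedup_compounds <- function(annots) {
  stopifnot(is.data.frame(annots))
  if (nrow(annots) == 0L) return(annots)
  out <- annots[!duplicated(paste(annots$compound, annots$rule, sep = "\r")), ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match rate against a reference compound list
#'
#' The proportion (in percent) of deduplicated annotations whose matched
#' feature m/z also falls within tolerance of some reference compound:
#' `100 * n_hits / n_reference`. Because matching is m/z-first, two or more
#' isobaric compounds can annotate the same feature, so the rate may exceed
#' 100 percent.
#'
#' @param annots An `"annotations"` data frame (deduplicated internally).
#' @param reference A data frame with columns `name` and `mz` (the reference
#'   compounds' m/z values on the same scale as the annotated features).
#' @param tol A `"mass_tolerance"` (default +/- 0.02 Da).
#' @return Percent match rate.
#' @export
match_rate <- function(annots, reference, tol = tolerance(0.02, "da")) {
  stopifnot(is.data.frame(annots), is.data.frame(reference))
  if (nrow(reference) == 0L) stop("empty reference list", call. = FALSE)
  if (!all(c("name", "mz") %in% names(reference))) {
    stop("reference must have columns 'name' and 'mz'", call. = FALSE)
  }
  ded <- dedup_compounds(annots)
  if (nrow(ded) == 0L) return(0)
  tol_da <- tolerance_in_da(tol, reference$mz)
  hit <- vapply(ded$mz, function(m) {
    any(abs(m - reference$mz) <= tol_da + .MZ_BOUNDARY_EPS)
  }, logical(1))
  100 * sum(hit) / nrow(reference)
}

#' Screen a peak table against a phytohormone database
#'
#' The full annotation pipeline: read the peak table, expand the compound
#' database under the chosen rule set and shift mode, match features on m/z
#' within tolerance, and rank by percent RT match. Features matching nothing
#' can optionally be appended as unannotated rows.
#'
#' @param peaks A `"peak_table"` or a path to a peak-table CSV.
#' @param db A `"compound_db"`.
#' @param ruleset A `"mass_ruleset"` or built-in name (default `"mh"`, the
#'   \[M+H\]+ database used for validation screening).
#' @param tol A `"mass_tolerance"` (default +/- 0.02 Da).
#' @param mode Shift mode, see [apply_shift()].
#' @param keep_unannotated If `TRUE`, features with no match are appended
#'   with `NA` annotation columns. Default `FALSE`.
#' @return A ranked `"annotations"` data frame, with the per-sample intensity
#'   columns of the peak table merged back on.
#' @examples
#' db <- fixture_compounds()
#' pk <- peak_table(mz = c(262.1596, 500.1), rt = c(3.67, 5.0))
#' screen(pk, db, ruleset = "biotransformations")
#' @export
screen <- function(peaks, db, ruleset = "mh", tol = tolerance(0.02, "da"),
                   mode = c("neutral_shift", "protonated"),
                   keep_unannotated = FALSE) {
  mode <- match.arg(mode)
  if (is.character(peaks)) peaks <- read_peak_table(peaks)
  stopifnot(inherits(peaks, "peak_table"), inherits(db, "compound_db"))
  entries <- expand_database(db, ruleset, mode = mode)
  ann <- rank_annotations(match_features(peaks, entries, tol))
  sample_names <- attr(peaks, "sample_names")
  if (length(sample_names)) {
    idx <- match(ann$row_index, peaks$row_index)
    ann <- cbind(ann, peaks[idx, sample_names, drop = FALSE])
    rownames(ann) <- NULL
  }
  if (keep_unannotated) {
    missing_rows <- setdiff(peaks$row_index, ann$row_index)
    if (length(missing_rows)) {
      idx <- match(missing_rows, peaks$row_index)
      extra <- ann[rep(NA_integer_, length(missing_rows)), , drop = FALSE]
      extra$row_index <- missing_rows
      extra$mz <- peaks$mz[idx]
      extra$rt <- peaks$rt[idx]
      if (length(sample_names)) {
        extra[, sample_names] <- peaks[idx, sample_names, drop = FALSE]
      }
      ann <- rbind(ann, extra)
      rownames(ann) <- NULL
    }
  }
  class(ann) <- c("annotations", "data.frame")
  attr(ann, "tolerance") <- tol
  attr(ann, "mode") <- mode
  ann
}

#' Write screening results with display headers
#'
#' Writes a "screener output" CSV whose headers mirror the web-tool style:
#' `Compound name`, `Biotransformation`, `Actual m/z` (theoretical),
#' `Experimental m/z`, `Experimental RT`, `Predicted RT`, `%RT match`,
#' `Delta m/z`, followed by the per-sample intensity columns. m/z values are
#' printed to 4 decimals, RT to 2, percent match to 1; pass `digits = NA`
#' for full precision.
#'
#' @param annots An `"annotations"` data frame from [screen()].
#' @param path Output CSV path.
#' @param digits If `NA`, write full precision.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(annots, path, digits = TRUE) {
  stopifnot(is.data.frame(annots))
  core <- c(row_index = "Feature row", compound = "Compound name",
            rule = "Biotransformation", theoretical_mz = "Actual m/z",
            mz = "Experimental m/z", rt = "Experimental RT",
            predicted_rt = "Predicted RT", rt_match_pct = "%RT match",
            delta_mz = "Delta m/z")
  extra <- setdiff(names(annots), c(names(core), "class", "msi_level", "kind"))
  out <- annots[, c(names(core), extra), drop = FALSE]
  if (isTRUE(digits)) {
    for (col in c("theoretical_mz", "mz", "delta_mz")) {
      out[[col]] <- round(out[[col]], 4)
    }
    for (col in c("rt", "predicted_rt")) out[[col]] <- round(out[[col]], 2)
    out$rt_match_pct <- round(out$rt_match_pct, 1)
  }
  names(out)[seq_along(core)] <- unname(core)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
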