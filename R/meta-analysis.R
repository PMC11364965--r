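#' Read a study manifest for a meta-analysis
#'
#' One row per study: `study_id`, `species`, `ionization` (`ESI_pos`,
#' `ESI_neg` or `both`), `gradient_status` (`same_as_reference`, `different`,
#' `not_provided`, `direct_injection`), `peak_table_path`, and optionally
#' `reequil_start` (minutes; default 15). Studies acquired in both ionization
#' modes are listed as two rows, one per polarity peak table.
#'
#' @param path Manifest CSV path.
#' @return A data frame of study configurations.
#' @export
read_study_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "species", "ionization", "gradient_status",
            "peak_table_path")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"reequil_start" %in% names(df)) df$reequil_start <- 15
  df$reequil_start[is.na(df$reequil_start)] <- 15
  bad <- setdiff(df$gradient_status,
                 c("same_as_reference", "different", "not_provided",
                   "direct_injection"))
  if (length(bad)) {
    stop("unknown gradient_status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Gradient-dependent retention filtering
#'
#' Applies the retention rules used when pooling heterogeneous studies:
#' \itemize{
#'   \item `same_as_reference` (same gradient and column as the
#'     retention-model training runs): keep annotations with RT match > 70\%;
#'   \item `different` (different gradient or column): keep RT match > 50\%;
#'   \item `not_provided` (chromatography not reported): keep features with
#'     observed RT strictly between 1 minute and the start of column
#'     re-equilibration;
#'   \item `direct_injection`: no retention information, keep everything.
#' }
#' Threshold comparisons are strict. Where a percent-match rule applies,
#' annotations lacking an RT match (no predicted RT) are dropped with a
#' warning.
#'
#' @param annots An `"annotations"` data frame.
#' @param gradient_status One of the four statuses above.
#' @param reequil_start Start of column re-equilibration in minutes
#'   (default 15, the last compositional change of the reference 25-minute
#'   gradient).
#' @return The filtered subset of `annots`.
#' @export
apply_retention_rules <- function(annots,
                                  gradient_status = c("same_as_reference",
                                                      "different",
                                                      "not_provided",
                                                      "direct_injection"),
                                  reequil_start = 15) {
  gradient_status <- match.arg(gradient_status)
  stopifnot(is.data.frame(annots))
  if (nrow(annots) == 0L || gradient_status == "direct_injection") {
    return(annots)
  }
  keep <- switch(gradient_status,
    same_as_reference = ,
    different = {
      thr <- if (gradient_status == "same_as_reference") 70 else 50
      no_score <- is.na(annots$rt_match_pct)
      if (any(no_score)) {
        warning(sum(no_score),
                " annotation(s) without an RT match dropped under the '",
                gradient_status, "' rule")
      }
      !no_score & annots$rt_match_pct > thr
    },
    not_provided = annots$rt > 1 & annots$rt < reequil_start)
  out <- annots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen one study with the meta-analysis defaults
#'
#' Runs the pipeline screen -> rank -> retention filter -> deduplicate for a
#' single study configuration, with the pooled-analysis defaults: the
#' \[M+H\]+ rule set and a +/- 0.02 Da tolerance. An unreadable peak table
#' skips the study (returns `NULL`) with a warning rather than failing the
#' whole analysis.
#'
#' @param cfg A one-row data frame or list with at least `study_id`,
#'   `gradient_status`, `peak_table_path`, optionally `reequil_start`.
#' @param db A `"compound_db"`.
#' @param ruleset Rule set or name (default `"mh"`).
#' @param tol A `"mass_tolerance"` (default +/- 0.02 Da).
#' @param mode Shift mode, see [apply_shift()].
#' @return A deduplicated, filtered `"annotations"` data frame with a
#'   `study_id` column, or `NULL` if the peak table could not be read.
#' @export
screen_study <- function(cfg, db, ruleset = "mh", tol = tolerance(0.02, "da"),
                         mode = "neutral_shift") {
  cfg <- as.list(cfg)
  stopifnot(!is.null(cfg$study_id), !is.null(cfg$gradient_status),
            !is.null(cfg$peak_table_path))
  reequil <- if (is.null(cfg$reequil_start) || is.na(cfg$reequil_start)) 15
             else cfg$reequil_start
  peaks <- tryCatch(read_peak_table(cfg$peak_table_path),
                    error = function(e) {
                      warning("study ", cfg$study_id, " skipped: ",
                              conditionMessage(e))
                      NULL
                    })
  if (is.null(peaks)) return(NULL)
  ann <- screen(peaks, db, ruleset = ruleset, tol = tol, mode = mode)
  ann <- apply_retention_rules(ann, cfg$gradient_status,
                               reequil_start = reequil)
  ann <- dedup_compounds(ann)
  if (nrow(ann)) ann$study_id <- cfg$study_id
  else ann$study_id <- character(0)
  ann
}

#' Class-binned summary across studies
#'
#' Counts the distinct compounds per hormone class for each study, next to
#' the total number of catalogued compounds per class (the `database_total`
#' column). Compounds whose class is not in the database are binned as
#' `"unclassified"` with a warning. Counts are of deduplicated compounds and
#' do not depend on annotation order.
#'
#' @param per_study A named list of `"annotations"` data frames, one per
#'   study (names are study ids); `NULL` elements (skipped studies) are
#'   ignored.
#' @param db The `"compound_db"` the studies were screened against.
#' @return A data frame of class `"class_summary"`: one row per class,
#'   columns `class`, `database_total`, then one count column per study.
#' @export
class_summary <- function(per_study, db) {
  stopifnot(is.list(per_study), inherits(db, "compound_db"))
  per_study <- Filter(Negate(is.null), per_study)
  if (length(per_study) == 0L) stop("no study results", call. = FALSE)
  if (is.null(names(per_study)) || any(!nzchar(names(per_study)))) {
    names(per_study) <- vapply(per_study, function(a) {
      if (nrow(a) && "study_id" %in% names(a)) a$study_id[1L] else "study"
    }, character(1))
  }
  # class of each distinct compound seen in each study ("unclassified" when
  # the compound is not catalogued)
  study_classes <- lapply(per_study, function(ann) {
    cpds <- unique(ann$compound)
    cls <- db$class[match(cpds, db$name)]
    cls[is.na(cls)] <- "unclassified"
    cls
  })
  unknown_seen <- any(vapply(study_classes,
                             function(cl) any(cl == "unclassified"),
                             logical(1)))
  classes <- sort(unique(db$class))
  if (unknown_seen) classes <- c(classes, "unclassified")
  totals <- as.integer(table(factor(db$class, levels = classes)))
  out <- data.frame(class = classes, database_total = totals,
                    stringsAsFactors = FALSE)
  for (sid in names(study_classes)) {
    out[[sid]] <- as.integer(table(factor(study_classes[[sid]],
                                          levels = classes)))
  }
  if (unknown_seen) {
    warning("annotations for compounds absent from the database were binned as 'unclassified'")
  }
  rownames(out) <- NULL
  class(out) <- c("class_summary", "data.frame")
  out
}

#' Run the whole meta-analysis
#'
#' Convenience wrapper: screens every study in a manifest and returns both
#' the per-study annotation lists and the class-binned summary.
#'
#' @param manifest A manifest data frame (see [read_study_manifest()]) or a
#'   path to one.
#' @param db A `"compound_db"`.
#' @inheritParams screen_study
#' @return A list with elements `per_study` (named list of annotation data
#'   frames) and `summary` (a `"class_summary"`).
#' @export
meta_analysis <- function(manifest, db, ruleset = "mh",
                          tol = tolerance(0.02, "da"),
                          mode = "neutral_shift") {
  if (is.character(manifest)) manifest <- read_study_manifest(manifest)
  res <- lapply(seq_len(nrow(manifest)), function(i) {
    screen_study(manifest[i, ], db, ruleset = ruleset, tol = tol, mode = mode)
  })
  names(res) <- manifest$study_id
  list(per_study = res, summary = class_summary(res, db))
}
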