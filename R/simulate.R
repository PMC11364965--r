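#' Generate a synthetic peak table with known ground truth
#'
#' Builds a feature table that emulates the output of peak alignment on an
#' untargeted LC-MS run: "spike" features placed at the theoretical m/z of
#' chosen database compounds under chosen shift rules (with optional Gaussian
#' m/z and RT noise), plus "decoy" features drawn uniformly over the
#' 100-1000 m/z scan range and rejected until they sit at least
#' `decoy_min_distance` away from every theoretical m/z of the fully expanded
#' database (identity, \[M+H\]+, all adducts and all biotransformations, in
#' both shift modes) - so any decoy annotation is attributable to the
#' matcher, not to the generator. Intensities are log-normal
#' (meanlog 10, sdlog 1) and play no role in matching.
#'
#' Randomness flows from the single `seed` through one stream in a fixed
#' draw order: spike m/z noise, spike RT noise, decoy positions, intensities.
#'
#' @param db A `"compound_db"`.
#' @param spikes A data frame with columns `compound` and `rule` (shift
#'   notation, e.g. `"M+H"`), and optionally per-spike `mz_noise_sd`,
#'   `rt_noise_sd` (overriding the function-level defaults) and
#'   `intensity_scale`. May have zero rows.
#' @param n_decoys Number of decoy features (default 0).
#' @param decoy_min_distance Minimum distance (Da) between a decoy and any
#'   expanded-database m/z; must exceed the match tolerance you intend to
#'   screen with (default 0.05).
#' @param n_samples Number of intensity columns (default 3).
#' @param mz_noise_sd,rt_noise_sd Default Gaussian noise standard deviations
#'   for spikes (Da / minutes; default 0).
#' @param seed Integer seed (required).
#' @param mode Shift mode for the spikes' theoretical m/z.
#' @return A list with `peaks` (a `"peak_table"`, spikes first then decoys)
#'   and `truth` (data frame `row_index`, `source` = `"spike"`/`"decoy"`,
#'   `compound`, `rule`, `theoretical_mz`).
#' @examples
#' db <- fixture_compounds()
#' sim <- simulate_peak_table(db,
#'   spikes = data.frame(compound = db$name[1:3], rule = "M+H"),
#'   n_decoys = 10, seed = 1)
#' @export
simulate_peak_table <- function(db, spikes, n_decoys = 0,
                                decoy_min_distance = 0.05, n_samples = 3,
                                mz_noise_sd = 0, rt_noise_sd = 0, seed,
                                mode = "neutral_shift") {
  stopifnot(inherits(db, "compound_db"), is.data.frame(spikes))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (nrow(spikes) > 0 &&
      !all(c("compound", "rule") %in% names(spikes))) {
    stop("spikes needs columns 'compound' and 'rule'", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_spikes <- nrow(spikes)
  if (n_spikes > 0) {
    if (!"mz_noise_sd" %in% names(spikes)) spikes$mz_noise_sd <- mz_noise_sd
    if (!"rt_noise_sd" %in% names(spikes)) spikes$rt_noise_sd <- rt_noise_sd
    if (!"intensity_scale" %in% names(spikes)) spikes$intensity_scale <- 1
    stopifnot(all(spikes$mz_noise_sd >= 0), all(spikes$rt_noise_sd >= 0),
              all(spikes$intensity_scale > 0))
    miss <- setdiff(spikes$compound, db$name)
    if (length(miss)) {
      stop("spiked compound(s) not in the database: ",
           paste(unique(miss), collapse = ", "), call. = FALSE)
    }
    di <- match(spikes$compound, db$name)
    rules <- lapply(spikes$rule, parse_shift)
    theo <- mapply(function(m, r) apply_shift(m, r, mode = mode),
                   db$monoisotopic_mass[di], rules)
    prt <- db$predicted_rt[di]
    if (any(is.na(prt))) {
      stop("spiked compound(s) without a predicted RT: ",
           paste(unique(spikes$compound[is.na(prt)]), collapse = ", "),
           call. = FALSE)
    }
    spike_mz <- theo + stats::rnorm(n_spikes, 0, spikes$mz_noise_sd)
    spike_rt <- pmax(0, prt + stats::rnorm(n_spikes, 0, spikes$rt_noise_sd))
  } else {
    theo <- spike_mz <- spike_rt <- numeric(0)
  }

  decoy_mz <- numeric(0)
  if (n_decoys > 0) {
    # avoid the FULL expanded database so decoys can never legitimately match
    all_mz <- sort(unique(unlist(lapply(
      c("monoisotopic", "mh", "adducts", "biotransformations"),
      function(rs) {
        c(expand_database(db, rs, mode = "neutral_shift")$theoretical_mz,
          expand_database(db, rs, mode = "protonated")$theoretical_mz)
      }))))
    attempts <- 0L
    while (length(decoy_mz) < n_decoys) {
      need <- n_decoys - length(decoy_mz)
      cand <- stats::runif(need, 100, 1000)
      if (length(all_mz)) {
        i <- findInterval(cand, all_mz)
        d_lo <- ifelse(i >= 1L, cand - all_mz[pmax(i, 1L)], Inf)
        d_hi <- ifelse(i < length(all_mz),
                       all_mz[pmin(i + 1L, length(all_mz))] - cand, Inf)
        ok <- pmin(d_lo, d_hi) >= decoy_min_distance
      } else {
        ok <- rep(TRUE, need)
      }
      decoy_mz <- c(decoy_mz, cand[ok])
      attempts <- attempts + need
      if (attempts > 1e5L) {
        stop("decoy generation exceeded 100000 attempts; the database is too dense for decoy_min_distance = ",
             decoy_min_distance, call. = FALSE)
      }
    }
  }
  decoy_rt <- if (n_decoys > 0) stats::runif(n_decoys, 0.5, 20) else numeric(0)

  mz <- c(spike_mz, decoy_mz)
  rt <- c(spike_rt, decoy_rt)
  n <- length(mz)
  inten <- NULL
  if (n > 0 && n_samples > 0) {
    scale <- c(if (n_spikes) spikes$intensity_scale else numeric(0),
               rep(1, n_decoys))
    inten <- matrix(stats::rlnorm(n * n_samples, meanlog = 10, sdlog = 1),
                    nrow = n) * scale
    colnames(inten) <- paste0("sample_", seq_len(n_samples))
  }
  peaks <- peak_table(mz, rt, intensities = inten, source = "simulated")
  truth <- data.frame(
    row_index = seq_len(n),
    source = c(rep("spike", n_spikes), rep("decoy", n_decoys)),
    compound = c(if (n_spikes) spikes$compound else character(0),
                 rep(NA_character_, n_decoys)),
    rule = c(if (n_spikes) vapply(rules, `[[`, character(1), "label")
             else character(0), rep(NA_character_, n_decoys)),
    theoretical_mz = c(theo, rep(NA_real_, n_decoys)),
    stringsAsFactors = FALSE)
  list(peaks = peaks, truth = truth)
}

#' Score annotation recovery against a simulation's ground truth
#'
#' `recall` is the fraction of spiked (compound, rule) pairs that received an
#' annotation on their own feature row; `false_annotation_count` is the
#' number of annotations landing on decoy rows. With no spikes, recall is
#' reported as `NA` (not applicable).
#'
#' @param annots An `"annotations"` data frame produced from the simulated
#'   peak table.
#' @param truth The `truth` component returned by [simulate_peak_table()].
#' @return A list with `recall`, `false_annotation_count`, `n_spikes`,
#'   `n_decoys`.
#' @export
score_recovery <- function(annots, truth) {
  stopifnot(is.data.frame(annots), is.data.frame(truth))
  if (nrow(annots) && !all(annots$row_index %in% truth$row_index)) {
    stop("annotations reference feature rows absent from the truth manifest",
         call. = FALSE)
  }
  spikes <- truth[truth$source == "spike", , drop = FALSE]
  decoy_rows <- truth$row_index[truth$source == "decoy"]
  recovered <- if (nrow(spikes)) {
    mapply(function(ri, cpd, rl) {
      any(annots$row_index == ri & annots$compound == cpd & annots$rule == rl)
    }, spikes$row_index, spikes$compound, spikes$rule)
  } else {
    logical(0)
  }
  list(
    recall = if (nrow(spikes)) mean(recovered) else NA_real_,
    false_annotation_count = sum(annots$row_index %in% decoy_rows),
    n_spikes = nrow(spikes),
    n_decoys = length(decoy_rows))
}
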