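#' Physicochemical descriptors for a structure
#'
#' Deterministic featurization of a SMILES string into a fixed-length numeric
#' vector: OpenBabel bulk properties (molecular weight, logP, topological
#' polar surface area, molar refractivity, hydrogen-bond donor/acceptor
#' counts), element counts from the molecular formula, and simple topology
#' counts read from the canonical SMILES (aromatic atoms, ring closures,
#' branch points). The schema is versioned so persisted models can refuse
#' incompatible inputs.
#'
#' @param smiles A single SMILES string.
#' @return A named numeric vector with attribute `schema`.
#' @examples
#' \donttest{featurize("CCO")}
#' @export
featurize <- function(smiles) {
  m <- featurize_matrix(smiles)
  out <- m[1L, ]
  attr(out, "schema") <- attr(m, "schema")
  out
}

.DESCRIPTOR_SCHEMA <- "pchem-1"
.DESCRIPTOR_NAMES <- c("MW", "logP", "TPSA", "MR", "HBA", "HBD",
                       "nC", "nH", "nN", "nO", "nS", "nHal",
                       "het_ratio", "n_aromatic", "n_rings", "n_branch")

#' Featurize a vector of SMILES strings
#'
#' Matrix-returning workhorse behind [featurize()]; one row per structure.
#' Unparseable structures raise an error naming the offending input.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A numeric matrix, one row per structure, with attribute `schema`.
#' @export
featurize_matrix <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L, all(!is.na(smiles)))
  rows <- lapply(seq_along(smiles), function(i) {
    s <- smiles[[i]]
    sdf <- tryCatch(ChemmineR::smiles2sdf(s),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(sdf)) {
      stop("cannot parse structure ", sQuote(s),
           if (!is.null(names(smiles))) paste0(" (", names(smiles)[i], ")"),
           call. = FALSE)
    }
    p <- ChemmineR::propOB(sdf)
    comp <- parse_formula(p$formula[1L])
    cnt <- function(el) if (el %in% names(comp)) as.numeric(comp[[el]]) else 0
    n_heavy <- sum(comp[names(comp) != "H"])
    cansmi <- p$cansmiNS[1L]
    bare <- gsub("\\[[^]]*\\]", "", cansmi)  # bracket atoms counted via formula
    c(MW = p$MW[1L], logP = p$logP[1L], TPSA = p$TPSA[1L], MR = p$MR[1L],
      HBA = p$HBA1[1L], HBD = p$HBD[1L],
      nC = cnt("C"), nH = cnt("H"), nN = cnt("N"), nO = cnt("O"),
      nS = cnt("S"), nHal = cnt("F") + cnt("Cl") + cnt("Br") + cnt("I"),
      het_ratio = if (n_heavy > 0) (n_heavy - cnt("C")) / n_heavy else 0,
      n_aromatic = lengths(regmatches(bare, gregexpr("[cnosp]", bare))),
      n_rings = lengths(regmatches(bare, gregexpr("[0-9]", bare))) / 2,
      n_branch = lengths(regmatches(bare, gregexpr("\\(", bare))))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- .DESCRIPTOR_NAMES
  rownames(m) <- names(smiles)
  if (any(!is.finite(m))) stop("non-finite descriptor values", call. = FALSE)
  attr(m, "schema") <- .DESCRIPTOR_SCHEMA
  m
}

#' Train a retention-time regression model
#'
#' Fits a random forest mapping structure descriptors to observed retention
#' times. Featurization is a pluggable strategy: any deterministic function
#' from a character vector of structures to a numeric descriptor matrix can
#' replace the default physicochemical set. Training is reproducible under a
#' fixed seed. Trees consider all descriptors at each split (`mtry = p`),
#' which suits small curated descriptor sets where most columns are
#' informative.
#'
#' @param records A data frame with columns `compound_name`, `smiles`,
#'   `rt_observed` (minutes, positive). At least 10 records.
#' @param algorithm Currently `"random_forest"` (alias `"rf"`).
#' @param seed Integer seed; required and stored in the model metadata.
#' @param featurizer Function: character vector of structures -> numeric
#'   matrix. Defaults to [featurize_matrix()].
#' @param ntree Number of trees (default 500).
#' @return An object of class `"rt_model"` with `print`, `summary` and
#'   `predict` methods.
#' @examples
#' \donttest{
#' tr <- rt_training_set()
#' fit <- train_rt_model(tr, seed = 1)
#' predict(fit, tr$smiles[1:3])
#' }
#' @export
train_rt_model <- function(records, algorithm = c("random_forest", "rf"),
                           seed, featurizer = featurize_matrix, ntree = 500) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.data.frame(records),
            all(c("compound_name", "smiles", "rt_observed") %in% names(records)))
  if (missing(seed)) stop("a training seed is required", call. = FALSE)
  if (nrow(records) < 10L) {
    stop("need at least 10 training records, got ", nrow(records),
         call. = FALSE)
  }
  if (any(!is.finite(records$rt_observed) | records$rt_observed <= 0)) {
    stop("rt_observed must be positive and finite", call. = FALSE)
  }
  structures <- as.character(records$smiles)
  names(structures) <- records$compound_name
  X <- featurizer(structures)
  stopifnot(is.matrix(X), nrow(X) == nrow(records))
  y <- records$rt_observed
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = X, y = y, ntree = ntree,
                                    mtry = ncol(X), importance = TRUE)
  structure(
    list(algorithm = "random_forest", fit = fit,
         schema = attr(X, "schema"),
         descriptor_names = colnames(X),
         featurizer = featurizer,
         training = list(n = nrow(records), seed = as.integer(seed),
                         ntree = ntree,
                         rt_range = range(y))),
    class = "rt_model")
}

#' Predict retention time for structures
#'
#' @param object An `"rt_model"`.
#' @param newdata Character vector of structures (SMILES under the default
#'   featurizer), or a precomputed descriptor matrix with matching columns.
#' @param ... Unused.
#' @return Predicted retention times in minutes (named if `newdata` is named).
#' @export
predict.rt_model <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    X <- object$featurizer(newdata)
  } else {
    X <- as.matrix(newdata)
  }
  if (!identical(colnames(X), object$descriptor_names)) {
    stop("descriptor columns do not match the model's schema (",
         object$schema, ")", call. = FALSE)
  }
  as.numeric(stats::predict(object$fit, X))
}

#' @rdname predict.rt_model
#' @param model An `"rt_model"`.
#' @param structure Character vector of structures.
#' @export
predict_rt <- function(model, structure) {
  stopifnot(inherits(model, "rt_model"))
  predict(model, structure)
}

#' @export
print.rt_model <- function(x, ...) {
  cat(sprintf("<rt model> random forest, %d trees, trained on n = %d (seed %d)\n",
              x$training$ntree, x$training$n, x$training$seed))
  cat(sprintf("  descriptors: %s (%d)\n", x$schema, length(x$descriptor_names)))
  cat(sprintf("  training RT range: %.2f - %.2f min\n",
              x$training$rt_range[1], x$training$rt_range[2]))
  invisible(x)
}

#' @export
summary.rt_model <- function(object, ...) {
  print(object)
  oob <- object$fit$predicted
  cat(sprintf("  out-of-bag RMSE: %.3f min\n",
              sqrt(mean((oob - object$fit$y)^2))))
  invisible(object)
}

#' Regression metrics for retention-time predictions
#'
#' Computes root mean squared error, mean absolute error, coefficient of
#' determination and a 95% band on the residuals. The 95% band is, by
#' default, the 95th percentile of |residuals| (`ci_method = "quantile"`,
#' type-7 quantile); `ci_method = "normal"` gives 1.96 x sd(residuals)
#' instead.
#'
#' @param rt_pred Predicted RTs (minutes).
#' @param rt_obs Observed RTs (minutes); same length, at least 2.
#' @param ci_method `"quantile"` or `"normal"`.
#' @return An object of class `"rt_metrics"`: list with `rmse`, `r2`, `mae`,
#'   `ci95`, `n`.
#' @export
evaluate_rt_model <- function(rt_pred, rt_obs,
                              ci_method = c("quantile", "normal")) {
  ci_method <- match.arg(ci_method)
  stopifnot(is.numeric(rt_pred), is.numeric(rt_obs),
            length(rt_pred) == length(rt_obs))
  if (length(rt_obs) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (stats::var(rt_obs) == 0) {
    stop("R-squared is undefined for zero-variance observed RT", call. = FALSE)
  }
  d <- rt_pred - rt_obs
  structure(
    list(rmse = sqrt(mean(d^2)),
         r2 = 1 - sum(d^2) / sum((rt_obs - mean(rt_obs))^2),
         mae = mean(abs(d)),
         ci95 = if (ci_method == "quantile") {
           unname(stats::quantile(abs(d), 0.95))
         } else {
           1.96 * stats::sd(d)
         },
         n = length(d), ci_method = ci_method),
    class = "rt_metrics")
}

#' @export
print.rt_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.3f min | MAE %.3f min | R2 %.3f | 95%% band +/- %.3f min (%s, n = %d)\n",
              x$rmse, x$mae, x$r2, x$ci95, x$ci_method, x$n))
  invisible(x)
}

#' Signed retention-time deviation
#'
#' `rt_pred - rt_obs`, the convention used when tabulating prediction error
#' per training compound.
#'
#' @param rt_pred Predicted RT (minutes), vectorised.
#' @param rt_obs Observed RT (minutes), vectorised.
#' @return Signed deviation in minutes.
#' @examples
#' delta_rt(2.45, 1.23)  # 1.22
#' @export
delta_rt <- function(rt_pred, rt_obs) rt_pred - rt_obs

#' The packaged 46-compound retention-time training set
#'
#' Standards mixture used to calibrate the retention-time model on the
#' reference 25-minute water/acetonitrile gradient: compound name, curated
#' SMILES, the published model-predicted RT, the experimental RT and their
#' signed difference (all minutes).
#'
#' @return A data frame with columns `compound_name`, `smiles`,
#'   `rt_predicted`, `rt_observed`, `delta_rt`.
#' @export
rt_training_set <- function() {
  utils::read.csv(hormonomics_example("rt_training_set.csv"),
                  stringsAsFactors = FALSE)
}
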