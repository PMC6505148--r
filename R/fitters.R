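## Exported fitters for the multi-trait and multi-trait multi-environment
## models, including their cross-validation drivers.

## testingSet can be: NULL; a vector of record indices (mask the whole
## multi-trait row); a 2-column (record, trait) matrix of cells; or a
## CVPartitions object (handled by the CV drivers).
.resolveCells <- function(testingSet, n, L) {
  if (is.null(testingSet)) return(matrix(integer(0), 0, 2))
  if (is.matrix(testingSet)) {
    if (ncol(testingSet) != 2L)
      stopUsage("testingSet matrix must have two columns (record, trait)")
    storage.mode(testingSet) <- "integer"
    return(testingSet)
  }
  rec <- as.integer(testingSet)
  if (length(rec) && (min(rec) < 1L || max(rec) > n))
    stopData("testingSet record indices out of range")
  cbind(rep(rec, each = L), rep(seq_len(L), times = length(rec)))
}

.recordCells <- function(records, L) {
  cbind(rep(as.integer(records), each = L),
        rep(seq_len(L), times = length(records)))
}

.makeMTFit <- function(out, Yorig, cells, envLabels, settings, priors, cls) {
  st <- out$state
  naCells <- which(is.na(Yorig) | st$mask, arr.ind = TRUE)
  colnames(naCells) <- c("record", "trait")
  common <- list(Y = Yorig, yHat = out$yHat, SD.yHat = out$SD.yHat,
                 beta = out$beta, SD.beta = out$SD.beta,
                 b1 = out$b1, SD.b1 = out$SD.b1,
                 varTrait = out$SigmaT, SD.varTrait = out$SD.SigmaT,
                 vare = out$Re, SD.vare = out$SD.Re,
                 dfe = st$pri$nuRes + st$n, Se = st$pri$SRes,
                 NAvalues = naCells, envLabels = envLabels,
                 nIter = settings@nIter, burnIn = settings@burnIn,
                 thin = settings@thin)
  if (cls == "MultiTraitMEFit") {
    common <- c(common, list(b2 = out$b2, SD.b2 = out$SD.b2,
                             varEnv = out$SigmaE, SD.varEnv = out$SD.SigmaE))
  }
  do.call(new, c(list(cls), common))
}

#' Fit the Bayesian multi-trait model (single environment design)
#'
#' Gibbs sampler for Y = 1 beta' + Z1 b1 + E with matrix-variate normal
#' line effects (whitened through the relationship-matrix Cholesky factor;
#' see \code{\link{buildDesign}}), unstructured trait genetic covariance
#' SigmaT and residual covariance Re, both with inverse-Wishart full
#' conditionals, and a flat prior on the per-trait intercepts. Masked
#' testing cells and naturally missing cells are predicted by data
#' augmentation from their conditional normal given the observed traits of
#' the same record.
#'
#' @param Y n x L numeric response matrix (L >= 2), missing values allowed.
#' @param Z1 n x J whitened line design matrix.
#' @param settings a \linkS4class{ChainSettings}.
#' @param testingSet optional: vector of record indices (whole rows
#'   masked), a 2-column (record, trait) cell matrix, or a
#'   \linkS4class{CVPartitions} object, in which case the model is refitted
#'   per partition and per-partition accuracies are returned.
#' @param priors optional overrides of the prior hyperparameters
#'   (\code{nuT}, \code{ST}, \code{nuRes}, \code{SRes}, \code{betaVar});
#'   defaults are weakly informative: nu = L + 2, identity scales, flat
#'   beta.
#' @param control internal update toggles and initial values used by
#'   validation experiments.
#' @return a \linkS4class{MultiTraitFit}, or a
#'   \linkS4class{GenomicCVResult} when \code{testingSet} is a
#'   \linkS4class{CVPartitions}.
#' @export
fitMultiTrait <- function(Y, Z1, settings, testingSet = NULL,
                          priors = list(), control = list()) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2L)
    stopUsage("Y has a single trait; use the univariate engine ",
              "(fitUnivariate) instead")
  stopifnot(is(settings, "ChainSettings"))
  n <- nrow(Y)
  envLabels <- rep(NA_character_, n)
  if (is(testingSet, "CVPartitions")) {
    return(withSeed(settings@seed,
      .cvDriver(Y, testingSet, envLabels, model = "multi-trait",
                fitOnce = function(cells) {
                  st <- .mtmeInit(Y, X = matrix(1, n, 1), Z1 = Z1,
                                  settings = settings, maskCells = cells,
                                  priors = priors, control = control)
                  .mtmeRun(st, settings)$yHat
                })))
  }
  cells <- .resolveCells(testingSet, n, ncol(Y))
  withSeed(settings@seed, {
    st <- .mtmeInit(Y, X = matrix(1, n, 1), Z1 = Z1, settings = settings,
                    maskCells = cells, priors = priors, control = control)
    out <- .mtmeRun(st, settings)
    .makeMTFit(out, Y, cells, envLabels, settings, priors, "MultiTraitFit")
  })
}

#' Fit the Bayesian multi-trait multi-environment model
#'
#' Gibbs sampler for the full model Y = X beta + Z1 b1 + Z2 b2 + E, where
#' b2 carries the genotype-by-environment-by-trait interaction with prior
#' row covariance SigmaE (x) I on the whitened scale and column covariance
#' SigmaT. SigmaT pools information from both effect matrices; SigmaE has
#' an inverse-Wishart full conditional derived from the environment-blocked
#' layout of b2. All designs must come from one \code{\link{buildDesign}}
#' call so line and environment orderings agree.
#'
#' Note the overall scale is shared between SigmaE and SigmaT (only their
#' Kronecker product enters the likelihood), so individual scales should be
#' interpreted with care; correlations are identified.
#'
#' @param Y n x L numeric response matrix (L >= 2).
#' @param X n x I environment incidence matrix (I >= 2).
#' @param Z1 n x J whitened line design.
#' @param Z2 n x (I J) whitened line-by-environment design.
#' @param settings a \linkS4class{ChainSettings}.
#' @param testingSet as in \code{\link{fitMultiTrait}}.
#' @param priors optional prior overrides (additionally \code{nuE},
#'   \code{SE}; defaults nuE = I + 2, identity scale).
#' @param control internal update toggles / initial values.
#' @param envNames environment labels for the columns of X (default: its
#'   column names).
#' @return a \linkS4class{MultiTraitMEFit}, or a
#'   \linkS4class{GenomicCVResult} for a \linkS4class{CVPartitions}
#'   testing set.
#' @export
fitMultiTraitME <- function(Y, X, Z1, Z2, settings, testingSet = NULL,
                            priors = list(), control = list(),
                            envNames = colnames(X)) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (ncol(X) < 2L)
    stopUsage("a single environment was supplied; use fitMultiTrait instead")
  if (ncol(Y) < 2L)
    stopUsage("Y has a single trait; use the univariate engine ",
              "(fitUnivariate) instead")
  stopifnot(is(settings, "ChainSettings"))
  n <- nrow(Y)
  if (is.null(envNames)) envNames <- paste0("Env", seq_len(ncol(X)))
  envLabels <- envNames[max.col(X, ties.method = "first")]
  if (is(testingSet, "CVPartitions")) {
    return(withSeed(settings@seed,
      .cvDriver(Y, testingSet, envLabels, model = "multi-trait multi-env",
                fitOnce = function(cells) {
                  st <- .mtmeInit(Y, X = X, Z1 = Z1, Z2 = Z2,
                                  settings = settings, maskCells = cells,
                                  priors = priors, control = control)
                  .mtmeRun(st, settings)$yHat
                })))
  }
  cells <- .resolveCells(testingSet, n, ncol(Y))
  withSeed(settings@seed, {
    st <- .mtmeInit(Y, X = X, Z1 = Z1, Z2 = Z2, settings = settings,
                    maskCells = cells, priors = priors, control = control)
    out <- .mtmeRun(st, settings)
    .makeMTFit(out, Y, cells, envLabels, settings, priors, "MultiTraitMEFit")
  })
}

## Shared cross-validation driver: refit per partition with whole testing
## rows masked, score testing cells.
.cvDriver <- function(Y, partitionSet, envLabels, model, fitOnce) {
  L <- ncol(Y)
  if (length(partitionSet@gid) != nrow(Y))
    stopData("partition set was built for ", length(partitionSet@gid),
             " records but Y has ", nrow(Y))
  traitNms <- colnames(Y)
  if (is.null(traitNms)) traitNms <- paste0("T", seq_len(L))
  results <- NULL; predictions <- NULL
  for (p in seq_along(partitionSet@partitions)) {
    cells <- .recordCells(partitionSet@partitions[[p]], L)
    yHat <- fitOnce(cells)
    results <- rbind(results,
      .metricRows(Y, yHat, cells, envLabels, traitNms, p))
    predictions <- rbind(predictions,
      .predictionRows(Y, yHat, cells, partitionSet@gid, envLabels, traitNms, p))
  }
  new("GenomicCVResult",
      results = results %||% data.frame(),
      predictions = predictions %||% data.frame(),
      scheme = partitionSet@scheme, model = model)
}

#' @describeIn MultiTraitFit prediction-accuracy summary over the masked
#'   testing cells (SE columns are \code{NaN}: a single testing set admits
#'   no standard error); an empty data frame when nothing was masked.
#' @param object a fitted model.
#' @param ... unused.
#' @export
setMethod("summary", "MultiTraitFit", function(object, ...) {
  cells <- object@NAvalues
  if (nrow(cells)) {
    keep <- is.finite(object@Y[cells])
    cells <- cells[keep, , drop = FALSE]
  }
  traitNms <- colnames(object@Y)
  if (is.null(traitNms)) traitNms <- paste0("T", seq_len(ncol(object@Y)))
  rows <- .metricRows(object@Y, object@yHat, cells, object@envLabels,
                      traitNms, partition = 1L)
  summarizeMetrics(rows %||% data.frame(
    Environment = character(0), Trait = character(0),
    Partition = integer(0), Pearson = numeric(0), MAAPE = numeric(0)))
})

#' @describeIn GenomicCVResult summary table (mean +/- SE over partitions)
#'   or, with \code{information = "complete"}, the per-partition records.
#' @param object a cross-validation result.
#' @param information \code{"summary"} (default) or \code{"complete"}.
#' @param ... unused.
#' @export
setMethod("summary", "GenomicCVResult",
          function(object, information = c("summary", "complete"), ...) {
  information <- match.arg(information)
  if (information == "complete") return(object@results)
  summarizeMetrics(object@results)
})
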