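## S4 classes for phenotype data, model settings, fitted models and
## cross-validation results.

#' Phenotype table for multi-trait (multi-environment) analyses
#'
#' Long-format container holding one record per line-by-environment cell with
#' one column per trait. Single-environment studies carry an \code{NA}
#' environment label. Records are expected to be put in canonical order
#' (environment, then line, byte-wise collation) with
#' \code{\link{canonicalizePheno}} before design matrices are built; a wrong
#' ordering silently misaligns lines with the relationship matrix and yields
#' incorrect estimates.
#'
#' @slot gid character vector of line identifiers (one per record).
#' @slot env character vector of environment identifiers; all \code{NA} for a
#'   single-environment study.
#' @slot Y numeric matrix of trait values, records in rows, traits in columns
#'   (missing values allowed).
#' @slot traitNames character vector of trait names (column names of
#'   \code{Y}).
#' @slot envNames character vector of distinct environment names (empty when
#'   the study has no environment structure).
#' @export
setClass("PhenoTable",
  representation(gid = "character", env = "character", Y = "matrix",
                 traitNames = "character", envNames = "character"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@gid)
    if (length(object@env) != n) msg <- c(msg, "gid and env lengths differ")
    if (nrow(object@Y) != n) msg <- c(msg, "Y row count does not match records")
    if (ncol(object@Y) != length(object@traitNames))
      msg <- c(msg, "traitNames length does not match Y columns")
    key <- paste(object@gid, object@env, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (gid, env) record")
    if (length(msg)) msg else TRUE
  })

#' MCMC chain settings
#'
#' @slot nIter total number of Gibbs iterations.
#' @slot burnIn number of initial iterations discarded.
#' @slot thin thinning interval for retained draws.
#' @slot blockSize number of random-effect rows updated jointly per block;
#'   must be at least 50 and less than 1000.
#' @slot seed integer seed for the chain.
#' @export
setClass("ChainSettings",
  representation(nIter = "integer", burnIn = "integer", thin = "integer",
                 blockSize = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@nIter < 1L) msg <- c(msg, "nIter must be positive")
    if (object@burnIn < 0L || object@burnIn >= object@nIter)
      msg <- c(msg, "burnIn must be non-negative and smaller than nIter")
    if (object@thin < 1L) msg <- c(msg, "thin must be a positive integer")
    if (object@blockSize < 50L || object@blockSize >= 1000L)
      msg <- c(msg, "blockSize must be at least 50 but less than 1000")
    if ((object@nIter - object@burnIn) / object@thin < 10)
      msg <- c(msg, "settings must retain at least 10 posterior samples")
    if (length(msg)) msg else TRUE
  })

#' Whitened design matrices for the multi-trait multi-environment model
#'
#' Bundle of the fixed-effect incidence matrix X (one column per
#' environment, no intercept), the whitened line design Z1 = Z_G L (with
#' G = L L') and, for multi-environment layouts, the whitened
#' line-by-environment design Z2 = Z_EG L2 with I_I (x) G = L2 L2'.
#'
#' @slot X environment incidence matrix (n x I); a single all-ones column
#'   when the study has one environment.
#' @slot Z1 whitened line design (n x J).
#' @slot Z2 whitened line-by-environment design (n x IJ) or \code{NULL}.
#' @slot lineOrder,envOrder identifier orderings the columns refer to.
#' @slot n,J,I dimensions (records, lines, environments).
#' @export
setClass("DesignBundle",
  representation(X = "matrix", Z1 = "matrix", Z2 = "ANY",
                 lineOrder = "character", envOrder = "character",
                 n = "integer", J = "integer", I = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@X) != object@n || nrow(object@Z1) != object@n)
      msg <- c(msg, "X and Z1 must have one row per record")
    if (ncol(object@Z1) != object@J) msg <- c(msg, "Z1 must have J columns")
    if (!is.null(object@Z2) && ncol(object@Z2) != object@I * object@J)
      msg <- c(msg, "Z2 must have I*J columns")
    if (length(msg)) msg else TRUE
  })

#' Cross-validation partition set
#'
#' Testing sets (record indices into a canonicalized \linkS4class{PhenoTable})
#' for either the random cross-validation scheme or K-fold (CV2-style)
#' partitioning.
#'
#' @slot partitions list of integer vectors of testing record indices.
#' @slot scheme \code{"random"} or \code{"kfold"}.
#' @slot params echo of the generating parameters (including the seed).
#' @slot gid,env record identifiers the indices refer to.
#' @export
setClass("CVPartitions",
  representation(partitions = "list", scheme = "character", params = "list",
                 gid = "character", env = "character"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@gid)
    for (p in object@partitions) {
      if (anyDuplicated(p)) msg <- c(msg, "duplicated index within a partition")
      if (length(p) && (min(p) < 1 || max(p) > n))
        msg <- c(msg, "partition index out of range")
    }
    if (!object@scheme %in% c("random", "kfold", "custom"))
      msg <- c(msg, "unknown scheme")
    if (length(msg)) unique(msg) else TRUE
  })

#' Univariate Bayesian regression fit
#'
#' Posterior summaries from the single-trait Gibbs sampler
#' (\code{\link{fitUnivariate}}): the engine behind GBLUP-type fits and both
#' stages of regressor stacking.
#'
#' @slot intercept posterior mean intercept.
#' @slot effects named list of posterior-mean effect vectors, one per
#'   predictor component.
#' @slot varComponents named numeric vector of posterior-mean component
#'   variances.
#' @slot varE posterior mean residual variance.
#' @slot yHat fitted values (intercept + sum of component contributions at
#'   posterior means); for masked/missing records these are the model
#'   predictions.
#' @slot probIn posterior mean inclusion probability per component (1 for
#'   BRR components).
#' @slot settings echo of the chain settings used.
#' @export
setClass("UnivariateFit",
  representation(intercept = "numeric", effects = "list",
                 varComponents = "numeric", varE = "numeric",
                 yHat = "numeric", probIn = "numeric", settings = "list"))

#' Multi-trait model fit (single environment design)
#'
#' Posterior summaries for the matrix-variate multi-trait model
#' Y = 1 beta' + Z1 b1 + E with b1 ~ MN(0, I, SigmaT) on the whitened scale
#' and E ~ MN(0, I, Re). Covariance matrices are unstructured and estimated
#' with inverse-Wishart full conditionals.
#'
#' @slot Y observed response copy (with NAs where masked/missing).
#' @slot yHat,SD.yHat posterior mean and SD of fitted/predicted values.
#' @slot beta,SD.beta fixed-effect (intercept-per-trait) summaries.
#' @slot b1,SD.b1 whitened line-effect summaries (J x L).
#' @slot varTrait,SD.varTrait trait genetic covariance summaries (L x L).
#' @slot vare,SD.vare residual covariance summaries (L x L).
#' @slot dfe degrees of freedom of the residual inverse-Wishart update.
#' @slot Se prior scale matrix used in the residual covariance update.
#' @slot NAvalues two-column matrix of (record, trait) cells that were
#'   missing or masked before fitting.
#' @slot envLabels per-record environment labels (all \code{NA} for a
#'   single-environment fit); used by \code{summary} to group testing-cell
#'   metrics.
#' @slot nIter,burnIn,thin chain settings echo.
#' @export
setClass("MultiTraitFit",
  representation(Y = "matrix", yHat = "matrix", SD.yHat = "matrix",
                 envLabels = "character",
                 beta = "matrix", SD.beta = "matrix",
                 b1 = "matrix", SD.b1 = "matrix",
                 varTrait = "matrix", SD.varTrait = "matrix",
                 vare = "matrix", SD.vare = "matrix",
                 dfe = "numeric", Se = "matrix", NAvalues = "matrix",
                 nIter = "integer", burnIn = "integer", thin = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (any(!is.finite(object@yHat)))
      msg <- c(msg, "yHat must be finite everywhere (including masked cells)")
    if (any(diag(object@varTrait) < 0) || any(diag(object@vare) < 0))
      msg <- c(msg, "covariance summaries must have non-negative diagonals")
    if (length(msg)) msg else TRUE
  })

#' Multi-trait multi-environment model fit
#'
#' Extends \linkS4class{MultiTraitFit} with the genotype-by-environment
#' interaction effects b2 ~ MN(0, SigmaE (x) I, SigmaT) (whitened scale) and
#' the unstructured environment covariance SigmaE.
#'
#' @slot b2,SD.b2 whitened interaction-effect summaries (IJ x L).
#' @slot varEnv,SD.varEnv environment covariance summaries (I x I).
#' @export
setClass("MultiTraitMEFit",
  contains = "MultiTraitFit",
  representation(b2 = "matrix", SD.b2 = "matrix",
                 varEnv = "matrix", SD.varEnv = "matrix"),
  validity = function(object) {
    if (any(diag(object@varEnv) < 0))
      "varEnv must have a non-negative diagonal" else TRUE
  })

#' Cross-validated prediction results
#'
#' Per-partition prediction-accuracy records produced when a fitter is run
#' with a cross-validation partition set.
#'
#' @slot results data.frame with columns Environment, Trait, Partition,
#'   Pearson, MAAPE (one row per environment-trait-partition combination).
#' @slot predictions data.frame of testing-cell observations and predictions
#'   (columns Partition, Record, GID, Environment, Trait, Observed,
#'   Predicted).
#' @slot scheme partitioning scheme label.
#' @slot model fitting engine label.
#' @export
setClass("GenomicCVResult",
  representation(results = "data.frame", predictions = "data.frame",
                 scheme = "character", model = "character"))

#' Column-standardized stage-1 predictions for regressor stacking
#'
#' @slot Zhat n x L matrix of scaled predictions (each column centred and
#'   scaled to unit sample SD over the rows used for the statistics).
#' @slot center,scale per-trait location and scale used.
#' @export
setClass("StackedPredictors",
  representation(Zhat = "matrix", center = "numeric", scale = "numeric"),
  validity = function(object) {
    if (ncol(object@Zhat) != length(object@center) ||
        ncol(object@Zhat) != length(object@scale))
      "center/scale must have one entry per column" else TRUE
  })

#' Two-stage regressor stacking result
#'
#' Extends \linkS4class{GenomicCVResult} with the stage-2 meta-model
#' coefficient summaries and the scaling parameters applied to the stage-1
#' predictions.
#'
#' @slot coefficients list (one element per partition) of L x L matrices:
#'   row = target trait, column = coefficient on each trait's scaled
#'   stage-1 prediction.
#' @slot scaleParams list (one per partition) with components center and
#'   scale.
#' @export
setClass("StackingResult",
  contains = "GenomicCVResult",
  representation(coefficients = "list", scaleParams = "list"))

#' Ground-truth parameters of a synthetic data set
#'
#' Holds the generative parameters and the realized random effects of a
#' simulated multi-trait (multi-environment) data set so that estimates can
#' be compared with the truth.
#'
#' @slot beta I x L fixed effects.
#' @slot SigmaT,Re L x L trait genetic and residual covariances.
#' @slot SigmaE I x I environment covariance (\code{NULL} for one
#'   environment).
#' @slot b1 realized line effects (J x L, on the unwhitened scale).
#' @slot b2 realized interaction effects (IJ x L) or \code{NULL}.
#' @slot seed seed the realization was drawn with (may be \code{NULL}).
#' @export
setClass("SimulationTruth",
  representation(beta = "matrix", SigmaT = "matrix", SigmaE = "ANY",
                 Re = "matrix", b1 = "ANY", b2 = "ANY", seed = "ANY"),
  validity = function(object) {
    msg <- character(0)
    for (nm in c("SigmaT", "Re")) {
      S <- slot(object, nm)
      if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
        msg <- c(msg, paste(nm, "must be symmetric"))
      else if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
        msg <- c(msg, paste(nm, "must be positive definite"))
    }
    if (length(msg)) msg else TRUE
  })
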