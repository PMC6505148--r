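## Two-stage Bayesian multi-output regressor stacking: univariate GBLUP-type
## fits per trait (stage 1), column standardisation of their predictions,
## and per-trait meta-models on the scaled predictions of all traits
## (stage 2). The meta-model corrects each trait's first-stage predictions
## with information from the other traits' predictions.

#' Standardize stage-1 predictions
#'
#' Centres and scales each column of the stage-1 prediction matrix to mean
#' zero and unit sample standard deviation (n - 1 denominator), storing the
#' statistics used.
#'
#' @param yhat n x L matrix of stage-1 predictions.
#' @return a \linkS4class{StackedPredictors}.
#' @export
scalePredictions <- function(yhat) {
  yhat <- as.matrix(yhat)
  ctr <- colMeans(yhat)
  scl <- apply(yhat, 2L, stats::sd)
  bad <- !is.finite(scl) | scl <= 1e-12 * pmax(1, abs(ctr))
  if (any(bad)) {
    nm <- colnames(yhat)[which(bad)[1L]] %||% which(bad)[1L]
    stopData("stage-1 predictions for trait '", nm,
             "' have zero standard deviation; cannot be scaled")
  }
  Zhat <- sweep(sweep(yhat, 2L, ctr), 2L, scl, "/")
  new("StackedPredictors", Zhat = Zhat, center = ctr, scale = scl)
}

.stackOnePartition <- function(Y, test, components, covModel, settings,
                               traitNms) {
  L <- ncol(Y)
  n <- nrow(Y)
  Zraw <- matrix(NA_real_, n, L, dimnames = list(NULL, traitNms))
  for (l in seq_len(L)) {
    y <- Y[, l]
    y[test] <- NA
    f1 <- .uniFit(y, components, settings)
    Zraw[, l] <- fittedValues(f1)
  }
  sp <- scalePredictions(Zraw)
  pred <- matrix(NA_real_, n, L, dimnames = list(NULL, traitNms))
  coefs <- matrix(NA_real_, L, L,
                  dimnames = list(traitNms, paste0("Z_", traitNms)))
  for (l in seq_len(L)) {
    y <- Y[, l]
    y[test] <- NA
    f2 <- .uniFit(y, list(stack = list(X = sp@Zhat, model = covModel)),
                  settings)
    pred[, l] <- fittedValues(f2)
    coefs[l, ] <- f2@effects$stack
  }
  list(pred = pred, coefs = coefs,
       scaleParams = list(center = sp@center, scale = sp@scale))
}

.normalizePartitions <- function(partitions, n) {
  if (is(partitions, "CVPartitions")) return(partitions@partitions)
  if (is.list(partitions)) return(lapply(partitions, as.integer))
  list(as.integer(partitions))
}

#' Multi-output regressor stacking with cross-validation
#'
#' Per partition: (1) each trait is fitted univariately with the supplied
#' predictor components (testing rows masked) to obtain predictions at all
#' records; (2) the L prediction columns are standardized; (3) each trait
#' is refitted on the L scaled predictions plus an intercept using
#' \code{covModel} (testing rows masked again); (4) testing-cell
#' predictions are scored per (environment, trait, partition). Stage 1 is
#' refitted within every partition so no testing information leaks into
#' stage 2.
#'
#' @param Y n x L response matrix.
#' @param components named list of stage-1 predictor components, as in
#'   \code{\link{fitUnivariate}} (each honours its own model label).
#' @param settings a \linkS4class{ChainSettings}; applies to every stage-1
#'   and stage-2 chain.
#' @param partitions a \linkS4class{CVPartitions}, a list of testing-index
#'   vectors, or a single index vector.
#' @param covModel stage-2 model label (default \code{"BRR"};
#'   \code{"BayesB"} available).
#' @param envLabels optional per-record environment labels for metric
#'   grouping (taken from the partition object when available).
#' @return a \linkS4class{StackingResult}.
#' @export
fitStacking <- function(Y, components, settings, partitions,
                        covModel = "BRR", envLabels = NULL) {
  Y <- as.matrix(Y)
  stopifnot(is(settings, "ChainSettings"))
  .uniCheckModel(covModel)
  n <- nrow(Y)
  traitNms <- colnames(Y) %||% paste0("T", seq_len(ncol(Y)))
  colnames(Y) <- traitNms
  gid <- as.character(seq_len(n))
  if (is(partitions, "CVPartitions")) {
    if (length(partitions@gid) != n)
      stopData("partition set record count does not match Y")
    gid <- partitions@gid
    if (is.null(envLabels)) envLabels <- partitions@env
  }
  if (is.null(envLabels)) envLabels <- rep(NA_character_, n)
  parts <- .normalizePartitions(partitions, n)
  scheme <- if (is(partitions, "CVPartitions")) partitions@scheme else "custom"
  withSeed(settings@seed, {
    results <- NULL; predictions <- NULL
    coefs <- list(); scaleParams <- list()
    for (p in seq_along(parts)) {
      test <- parts[[p]]
      one <- .stackOnePartition(Y, test, components, covModel, settings,
                                traitNms)
      cells <- .recordCells(test, ncol(Y))
      results <- rbind(results,
        .metricRows(Y, one$pred, cells, envLabels, traitNms, p))
      predictions <- rbind(predictions,
        .predictionRows(Y, one$pred, cells, gid, envLabels, traitNms, p))
      coefs[[p]] <- one$coefs
      scaleParams[[p]] <- one$scaleParams
    }
    new("StackingResult", results = results %||% data.frame(),
        predictions = predictions %||% data.frame(),
        scheme = scheme, model = paste0("stacking(", covModel, ")"),
        coefficients = coefs, scaleParams = scaleParams)
  })
}

#' Whole-environment hold-out prediction by regressor stacking
#'
#' Masks every trait value of the records belonging to the testing
#' environments and runs the two-stage stacking procedure once, training on
#' the remaining environments. Accuracies are reported per (testing
#' environment, trait).
#'
#' @param table a \linkS4class{PhenoTable}; canonicalized internally. The
#'   predictor components must be built on the same canonical record
#'   ordering (use \code{\link{buildDesign}} on this table).
#' @param testingEnv character vector of environments to hold out; must be
#'   a non-empty proper subset of the table's environments.
#' @param components stage-1 predictor components (see
#'   \code{\link{fitUnivariate}}).
#' @param covModel stage-2 model label (default \code{"BRR"}).
#' @param settings a \linkS4class{ChainSettings}.
#' @return a \linkS4class{StackingResult} with scheme \code{"env-holdout"}
#'   (its summary has no SE columns: there is a single testing set).
#' @export
fitStackingEnv <- function(table, testingEnv, components, covModel = "BRR",
                           settings = NULL) {
  stopifnot(is(table, "PhenoTable"))
  stopifnot(is(settings, "ChainSettings"))
  .uniCheckModel(covModel)
  table <- canonicalizePheno(table)
  envs <- table@envNames
  if (length(testingEnv) == 0L) stopUsage("testingEnv must be non-empty")
  unknown <- setdiff(testingEnv, envs)
  if (length(unknown))
    stopData("unknown environment(s): ", paste(unknown, collapse = ", "))
  if (all(envs %in% testingEnv))
    stopUsage("testingEnv must leave at least one environment for training")
  test <- which(table@env %in% testingEnv)
  Y <- table@Y
  traitNms <- table@traitNames
  withSeed(settings@seed, {
    one <- .stackOnePartition(Y, test, components, covModel, settings,
                              traitNms)
    cells <- .recordCells(test, ncol(Y))
    results <- .metricRows(Y, one$pred, cells, table@env, traitNms, 1L)
    predictions <- .predictionRows(Y, one$pred, cells, table@gid, table@env,
                                   traitNms, 1L)
    new("StackingResult", results = results %||% data.frame(),
        predictions = predictions %||% data.frame(),
        scheme = "env-holdout", model = paste0("stacking(", covModel, ")"),
        coefficients = list(one$coefs), scaleParams = list(one$scaleParams))
  })
}

#' @describeIn StackingResult summary table; for whole-environment hold-outs
#'   (a single testing set) the SE columns are dropped.
#' @param object a stacking result.
#' @param information \code{"summary"} or \code{"complete"}.
#' @param ... unused.
#' @export
setMethod("summary", "StackingResult",
          function(object, information = c("summary", "complete"), ...) {
  information <- match.arg(information)
  if (information == "complete") return(object@results)
  out <- summarizeMetrics(object@results)
  if (object@scheme == "env-holdout") {
    out <- out[, c("Environment", "Trait", "Pearson", "MAAPE")]
  }
  out
})
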