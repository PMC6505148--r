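## Generics and accessors. Slot access from user code should go through
## these rather than `@`.

#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))
#' @export
setGeneric("envNames", function(x) standardGeneric("envNames"))
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))
#' @export
setGeneric("fittedValues", function(object) standardGeneric("fittedValues"))
#' @export
setGeneric("traitCov", function(object) standardGeneric("traitCov"))
#' @export
setGeneric("envCov", function(object) standardGeneric("envCov"))
#' @export
setGeneric("residCov", function(object) standardGeneric("residCov"))
#' @export
setGeneric("lineEffects", function(object) standardGeneric("lineEffects"))
#' @export
setGeneric("interactionEffects",
           function(object) standardGeneric("interactionEffects"))
#' @export
setGeneric("metricsTable", function(object) standardGeneric("metricsTable"))
#' @export
setGeneric("predictionsTable",
           function(object) standardGeneric("predictionsTable"))
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))

#' @describeIn PhenoTable number of records
#' @param x,object a BayesMTGP object.
#' @export
setMethod("nRecords", "PhenoTable", function(x) length(x@gid))
#' @describeIn PhenoTable trait names
#' @export
setMethod("traitNames", "PhenoTable", function(x) x@traitNames)
#' @describeIn PhenoTable distinct environment names
#' @export
setMethod("envNames", "PhenoTable", function(x) x@envNames)
#' @describeIn PhenoTable distinct line identifiers (sorted)
#' @export
setMethod("lineIds", "PhenoTable", function(x) idSort(unique(x@gid)))

#' @describeIn MultiTraitFit posterior mean fitted/predicted values
#' @export
setMethod("fittedValues", "MultiTraitFit", function(object) object@yHat)
#' @describeIn MultiTraitFit posterior mean trait genetic covariance
#' @export
setMethod("traitCov", "MultiTraitFit", function(object) object@varTrait)
#' @describeIn MultiTraitFit posterior mean residual covariance
#' @export
setMethod("residCov", "MultiTraitFit", function(object) object@vare)
#' @describeIn MultiTraitFit posterior mean whitened line effects
#' @export
setMethod("lineEffects", "MultiTraitFit", function(object) object@b1)
#' @describeIn MultiTraitMEFit posterior mean environment covariance
#' @param object a fitted model.
#' @export
setMethod("envCov", "MultiTraitMEFit", function(object) object@varEnv)
#' @describeIn MultiTraitMEFit posterior mean whitened interaction effects
#' @export
setMethod("interactionEffects", "MultiTraitMEFit", function(object) object@b2)

#' @describeIn UnivariateFit fitted values at posterior means
#' @param object a fitted model.
#' @export
setMethod("fittedValues", "UnivariateFit", function(object) object@yHat)

#' @describeIn GenomicCVResult per-partition metric records
#' @param object a cross-validation result.
#' @export
setMethod("metricsTable", "GenomicCVResult", function(object) object@results)
#' @describeIn GenomicCVResult testing-cell observations and predictions
#' @export
setMethod("predictionsTable", "GenomicCVResult",
          function(object) object@predictions)

#' @describeIn CVPartitions list of testing-index vectors
#' @param x a partition set.
#' @export
setMethod("partitions", "CVPartitions", function(x) x@partitions)
#' @describeIn CVPartitions number of records partitioned
#' @export
setMethod("nRecords", "CVPartitions", function(x) length(x@gid))

setMethod("show", "PhenoTable", function(object) {
  I <- max(1L, length(object@envNames))
  cat("PhenoTable:", length(object@gid), "records,",
      length(unique(object@gid)), "lines,", I, "environment(s),",
      length(object@traitNames), "trait(s)\n")
  cat("  traits:", paste(object@traitNames, collapse = ", "), "\n")
  if (length(object@envNames))
    cat("  environments:", paste(object@envNames, collapse = ", "), "\n")
})

setMethod("show", "ChainSettings", function(object) {
  cat(sprintf("ChainSettings: nIter=%d burnIn=%d thin=%d blockSize=%d seed=%d\n",
              object@nIter, object@burnIn, object@thin, object@blockSize,
              object@seed))
})

setMethod("show", "DesignBundle", function(object) {
  cat(sprintf("DesignBundle: n=%d J=%d I=%d (Z2 %s)\n", object@n, object@J,
              object@I, if (is.null(object@Z2)) "absent" else "present"))
})

setMethod("show", "CVPartitions", function(object) {
  sizes <- vapply(object@partitions, length, 1L)
  cat(sprintf("CVPartitions (%s): %d partition(s) over %d records; sizes %s\n",
              object@scheme, length(object@partitions), length(object@gid),
              paste(sizes, collapse = "/")))
})

setMethod("show", "MultiTraitFit", function(object) {
  cat(sprintf("%s: %d records x %d traits; nIter=%d burnIn=%d thin=%d\n",
              class(object), nrow(object@Y), ncol(object@Y), object@nIter,
              object@burnIn, object@thin))
  cat("  trait genetic covariance (posterior mean):\n")
  print(round(object@varTrait, 4))
})

setMethod("show", "GenomicCVResult", function(object) {
  cat(sprintf("%s (%s, %s): %d partition(s)\n", class(object), object@model,
              object@scheme, length(unique(object@results$Partition))))
  print(summary(object))
})

setMethod("show", "UnivariateFit", function(object) {
  cat(sprintf("UnivariateFit: intercept=%.4f varE=%.4f components: %s\n",
              object@intercept, object@varE,
              paste(names(object@effects), collapse = ", ")))
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf("SimulationTruth: I=%d L=%d%s\n", nrow(object@beta),
              ncol(object@beta),
              if (is.null(object@SigmaE)) "" else " (with environment covariance)"))
})
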