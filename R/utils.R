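## Internal utilities: classified conditions, seed scoping, small helpers.

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm rbinom runif rchisq rbeta rWishart cov var sd cor
#'   cov2cor setNames na.omit
#' @importFrom utils read.csv write.csv head modifyList packageVersion
#' @importFrom tools md5sum
#' @importFrom jsonlite write_json
NULL

## Conditions carry a class so the CLI can map them onto exit codes:
## usage errors -> 1, data validation -> 2, numerical failures -> 3.
stopUsage <- function(...) {
  stop(errorCondition(paste0(...), class = c("bmtgpUsageError", "error", "condition")))
}

stopData <- function(...) {
  stop(errorCondition(paste0(...), class = c("bmtgpDataError", "error", "condition")))
}

stopNumeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("bmtgpNumericError", "error", "condition")))
}

## Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
## All exported stochastic entry points route their `seed` argument through
## here, so a fixed seed gives bitwise-identical output regardless of the
## surrounding RNG state (determinism contract).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stopUsage("'seed' must be a single finite number")
  }
  has.old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has.old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has.old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Locale-independent (byte-wise) ordering used for all identifier sorting.
## Integer-like identifier vectors are ordered numerically.
idOrder <- function(...) {
  keys <- list(...)
  keys <- lapply(keys, function(k) {
    k <- as.character(k)
    if (length(k) && all(grepl("^[0-9]+$", k[!is.na(k)]))) as.numeric(k) else k
  })
  do.call(order, c(keys, list(method = "radix", na.last = TRUE)))
}

idSort <- function(x) {
  x[idOrder(x)]
}

isSquare <- function(M) is.matrix(M) && nrow(M) == ncol(M)

checkSymmetric <- function(M, tol = 1e-8, what = "matrix") {
  if (!isSquare(M)) stopData(what, " must be a square matrix")
  scale <- max(1, max(abs(M)))
  if (max(abs(M - t(M))) > tol * scale) {
    stopData(what, " is not symmetric within tolerance")
  }
  (M + t(M)) / 2
}

## Running mean/SD accumulator over retained MCMC draws.
newAccumulator <- function(dim) {
  list(n = 0L, sum = array(0, dim), sumsq = array(0, dim))
}

accAdd <- function(acc, x) {
  acc$n <- acc$n + 1L
  acc$sum <- acc$sum + x
  acc$sumsq <- acc$sumsq + x * x
  acc
}

accMean <- function(acc) acc$sum / acc$n

accSD <- function(acc) {
  m <- acc$sum / acc$n
  v <- acc$sumsq / acc$n - m * m
  sqrt(pmax(v, 0))
}
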