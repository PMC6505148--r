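## Phenotype ingestion, canonical ordering, marker QC and construction of
## the whitened design matrices.

#' Construct a phenotype table
#'
#' @param gid line identifiers (one per record; coerced to character).
#' @param Y numeric matrix (or data.frame) of trait values, one column per
#'   trait; missing values allowed.
#' @param env optional environment identifiers (one per record). Omit (or
#'   pass \code{NULL}) for a single-environment study.
#' @param traitNames trait names; defaults to the column names of \code{Y}.
#' @return a \linkS4class{PhenoTable}.
#' @export
phenoTable <- function(gid, Y, env = NULL, traitNames = colnames(Y)) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  gid <- as.character(gid)
  if (is.null(traitNames)) traitNames <- paste0("T", seq_len(ncol(Y)))
  colnames(Y) <- traitNames
  if (is.null(env)) {
    env <- rep(NA_character_, length(gid))
  } else {
    env <- as.character(env)
  }
  envs <- idSort(unique(env[!is.na(env)]))
  obj <- new("PhenoTable", gid = gid, env = env, Y = Y,
             traitNames = as.character(traitNames), envNames = envs)
  validObject(obj)
  obj
}

#' Read a phenotype table from a delimited text file
#'
#' Expected layout: a header row; a line-identifier column (default
#' \code{"GID"}); optionally an environment column; the remaining (or
#' explicitly named) columns are traits. Empty cells and the token
#' \code{"NA"} are read as missing.
#'
#' @param path path to a CSV file.
#' @param gidCol name of the line-identifier column.
#' @param envCol name of the environment column, or \code{NULL} when the
#'   study has a single environment.
#' @param traitCols names of the trait columns; default: every column that
#'   is neither \code{gidCol} nor \code{envCol}.
#' @param sep field separator (default comma).
#' @return a \linkS4class{PhenoTable} (not yet canonicalized; see
#'   \code{\link{canonicalizePheno}}).
#' @export
readPhenotypes <- function(path, gidCol = "GID", envCol = NULL,
                           traitCols = NULL, sep = ",") {
  if (!file.exists(path)) stopUsage("phenotype file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, header = TRUE,
                         colClasses = "character", check.names = FALSE,
                         na.strings = c("NA", ""))
  if (nrow(raw) == 0L) stopData("phenotype file has no data rows: ", path)
  if (!gidCol %in% names(raw))
    stopData("column '", gidCol, "' not found in ", path)
  if (!is.null(envCol) && !envCol %in% names(raw))
    stopData("column '", envCol, "' not found in ", path)
  if (is.null(traitCols)) {
    traitCols <- setdiff(names(raw), c(gidCol, envCol))
  } else if (!all(traitCols %in% names(raw))) {
    stopData("trait column(s) missing: ",
             paste(setdiff(traitCols, names(raw)), collapse = ", "))
  }
  if (length(traitCols) == 0L) stopData("no trait columns in ", path)
  Y <- matrix(NA_real_, nrow(raw), length(traitCols),
              dimnames = list(NULL, traitCols))
  for (tc in traitCols) {
    cell <- raw[[tc]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell))
    if (length(bad)) {
      stopData("non-numeric value '", cell[bad[1L]], "' for trait '", tc,
               "' at data row ", bad[1L])
    }
    Y[, tc] <- num
  }
  env <- if (is.null(envCol)) NULL else raw[[envCol]]
  tryCatch(
    phenoTable(gid = raw[[gidCol]], Y = Y, env = env, traitNames = traitCols),
    error = function(e) stopData("invalid phenotype table in ", path, ": ",
                                 conditionMessage(e)))
}

#' Canonicalize record order
#'
#' Sorts records by environment and then by line identifier, ascending, using
#' byte-wise (locale-independent) collation for strings; identifier vectors
#' that are entirely integer-like are ordered numerically. Idempotent.
#' Fitting functions assume this ordering, which aligns records with the
#' rows/columns of the relationship matrix and design matrices; an
#' inconsistent ordering produces incorrect estimates.
#'
#' @param table a \linkS4class{PhenoTable}.
#' @return the table with records in canonical order.
#' @export
canonicalizePheno <- function(table) {
  stopifnot(is(table, "PhenoTable"))
  o <- idOrder(table@env, table@gid)
  new("PhenoTable", gid = table@gid[o], env = table@env[o],
      Y = table@Y[o, , drop = FALSE], traitNames = table@traitNames,
      envNames = table@envNames)
}

#' Marker quality control and imputation
#'
#' Applies, in order: (1) removal of markers whose missing fraction exceeds
#' \code{maxMissing}; (2) imputation of remaining missing entries with
#' binomial(2, f) draws, where f is the marker's observed allele frequency;
#' (3) removal of markers whose minor allele frequency, computed after
#' imputation, is below \code{minMAF}.
#'
#' @param W marker dosage matrix with entries in \{0, 1, 2\} or \code{NA}.
#' @param maxMissing maximum tolerated missing fraction per marker
#'   (default 0.20).
#' @param minMAF minimum minor allele frequency (default 0.05).
#' @param seed optional seed for the imputation draws; a fixed seed makes
#'   the result deterministic.
#' @return the filtered (and imputed) marker matrix.
#' @export
filterMarkers <- function(W, maxMissing = 0.20, minMAF = 0.05, seed = NULL) {
  if (!is.matrix(W)) stopData("W must be a matrix")
  vals <- W[!is.na(W)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stopData("marker dosages must be coded 0/1/2 (or NA)")
  withSeed(seed, {
    missFrac <- colMeans(is.na(W))
    keep <- missFrac <= maxMissing
    W <- W[, keep, drop = FALSE]
    if (ncol(W) == 0L) stopData("all markers removed by the missingness filter")
    for (j in seq_len(ncol(W))) {
      miss <- is.na(W[, j])
      if (any(miss)) {
        f <- mean(W[!miss, j]) / 2
        W[miss, j] <- stats::rbinom(sum(miss), 2L, f)
      }
    }
    f <- colMeans(W) / 2
    maf <- pmin(f, 1 - f)
    W <- W[, maf >= minMAF, drop = FALSE]
    if (ncol(W) == 0L) stopData("all markers removed by the MAF filter")
    W
  })
}

#' Build whitened design matrices
#'
#' Constructs, for a canonicalized phenotype table and a genomic
#' relationship matrix G:
#' \itemize{
#'   \item X: environment incidence matrix (no intercept, one column per
#'     environment); a single all-ones column when there is one environment;
#'   \item Z1 = Z_G L, the line incidence matrix whitened by the safe
#'     Cholesky factor L of G (G = L L');
#'   \item Z2 = Z_EG L2, the line-by-environment interaction incidence
#'     whitened by L2 with I_I (x) G = L2 L2' (absent when I = 1).
#' }
#' Whitening turns the correlated genomic random effects into iid rows, so
#' the fitters place standard matrix-normal priors on the transformed
#' effects. The interaction columns are ordered environment-major: column
#' (i - 1) * J + j refers to environment i, line j.
#'
#' @param table a \linkS4class{PhenoTable}; canonicalized internally
#'   (\code{\link{canonicalizePheno}} is idempotent).
#' @param G genomic relationship matrix with line identifiers as dimnames
#'   covering every line in \code{table}.
#' @return a \linkS4class{DesignBundle}.
#' @export
buildDesign <- function(table, G) {
  stopifnot(is(table, "PhenoTable"))
  if (is.null(rownames(G))) stopData("G must carry line identifiers as rownames")
  table <- canonicalizePheno(table)
  lines <- idSort(unique(table@gid))
  missing <- setdiff(lines, rownames(G))
  if (length(missing)) {
    stopData("line(s) absent from the relationship matrix: ",
             paste(missing, collapse = ", "))
  }
  G <- G[lines, lines, drop = FALSE]
  J <- length(lines)
  n <- length(table@gid)
  I <- max(1L, length(table@envNames))
  L <- safeCholesky(G)

  lineIdx <- match(table@gid, lines)
  ZG <- matrix(0, n, J)
  ZG[cbind(seq_len(n), lineIdx)] <- 1
  Z1 <- ZG %*% L

  if (I >= 2L) {
    envIdx <- match(table@env, table@envNames)
    X <- matrix(0, n, I, dimnames = list(NULL, table@envNames))
    X[cbind(seq_len(n), envIdx)] <- 1
    ## Z2 = Z_EG (I (x) L): record r gets L[line(r), ] in its environment block
    Z2 <- matrix(0, n, I * J)
    for (r in seq_len(n)) {
      cols <- (envIdx[r] - 1L) * J + seq_len(J)
      Z2[r, cols] <- L[lineIdx[r], ]
    }
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(all)"))
    Z2 <- NULL
  }
  new("DesignBundle", X = X, Z1 = Z1, Z2 = Z2, lineOrder = lines,
      envOrder = if (I >= 2L) table@envNames else character(0),
      n = as.integer(n), J = as.integer(J), I = as.integer(I))
}

#' Read a square matrix (GRM or covariance) from CSV
#'
#' Format: header row of identifiers, first column of identifiers, numeric
#' body.
#'
#' @param path path to a CSV file.
#' @return numeric matrix with dimnames.
#' @export
readMatrixCSV <- function(path) {
  if (!file.exists(path)) stopUsage("matrix file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, row.names = 1,
                         check.names = FALSE)
  as.matrix(raw)
}

#' Write a matrix to CSV with identifiers
#'
#' @param M matrix to write.
#' @param path destination path.
#' @export
writeMatrixCSV <- function(M, path) {
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}
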