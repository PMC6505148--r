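## Synthetic-data generator: marker matrices and phenotype tables drawn from
## the generative multi-trait multi-environment model with known covariance
## parameters, emulating the structure of small plant-breeding trials.

#' Simulate a marker dosage matrix
#'
#' Per marker, an allele frequency f is drawn uniformly from
#' \code{mafRange} and the J dosages are binomial(2, f). Missing entries
#' are inserted completely at random at rate \code{missingRate}.
#'
#' @param J number of lines.
#' @param p number of markers.
#' @param mafRange allele-frequency range (0 < lo <= hi < 0.5 not enforced
#'   above 0.5 for the upper bound of the *minor* allele: frequencies are
#'   drawn as given).
#' @param missingRate fraction of entries set to missing (default 0).
#' @param seed integer seed (fixed seed => bitwise identical output).
#' @return J x p integer dosage matrix with line rownames \code{L001, ...}
#'   and marker colnames \code{M0001, ...}.
#' @export
simulateMarkers <- function(J, p, mafRange = c(0.1, 0.45), missingRate = 0,
                            seed = NULL) {
  if (length(mafRange) != 2L || mafRange[1L] <= 0 || mafRange[2L] >= 0.5 ||
      mafRange[1L] > mafRange[2L])
    stopUsage("mafRange must satisfy 0 < lo <= hi < 0.5")
  if (missingRate < 0 || missingRate >= 1)
    stopUsage("missingRate must lie in [0, 1)")
  withSeed(seed, {
    f <- stats::runif(p, mafRange[1L], mafRange[2L])
    W <- matrix(stats::rbinom(J * p, 2L, rep(f, each = J)), J, p)
    if (missingRate > 0) {
      nMiss <- floor(missingRate * J * p)
      if (nMiss > 0) W[sample.int(J * p, nMiss)] <- NA
    }
    dimnames(W) <- list(sprintf("L%03d", seq_len(J)),
                        sprintf("M%04d", seq_len(p)))
    W
  })
}

#' Bundle ground-truth simulation parameters
#'
#' @param beta I x L fixed-effect matrix (environment by trait).
#' @param SigmaT L x L trait genetic covariance.
#' @param Re L x L residual covariance.
#' @param SigmaE I x I environment covariance (\code{NULL} when I = 1).
#' @return a \linkS4class{SimulationTruth} (realized effects empty until
#'   \code{\link{simulateTraits}} fills them).
#' @export
simulationTruth <- function(beta, SigmaT, Re, SigmaE = NULL) {
  obj <- new("SimulationTruth", beta = as.matrix(beta),
             SigmaT = as.matrix(SigmaT), Re = as.matrix(Re),
             SigmaE = if (is.null(SigmaE)) NULL else as.matrix(SigmaE),
             b1 = NULL, b2 = NULL, seed = NULL)
  validObject(obj)
  obj
}

#' Simulate phenotypes from the multi-trait multi-environment model
#'
#' Draws line effects b1 ~ MN(0, G, SigmaT), interaction effects
#' b2 ~ MN(0, SigmaE (x) G, SigmaT) (when more than one environment) and
#' residuals E ~ MN(0, I, Re), and assembles
#' Y = X beta + Z_G b1 + Z_EG b2 + E over the complete J x I layout. The
#' realized effects are stored in the returned truth object so estimates
#' can be compared against them exactly.
#'
#' @param G genomic relationship matrix with line rownames.
#' @param envNames environment names (length I).
#' @param traitNames trait names (length L).
#' @param truth a \linkS4class{SimulationTruth} with dimensions matching
#'   (I, L).
#' @param seed integer seed.
#' @return list with elements \code{pheno} (a canonicalized
#'   \linkS4class{PhenoTable}) and \code{truth} (the input truth with
#'   realized \code{b1}, \code{b2} and the seed filled in).
#' @export
simulateTraits <- function(G, envNames, traitNames, truth, seed = NULL) {
  stopifnot(is(truth, "SimulationTruth"))
  J <- nrow(G)
  I <- length(envNames)
  L <- length(traitNames)
  if (is.null(rownames(G))) stopData("G must carry line rownames")
  if (nrow(truth@beta) != I || ncol(truth@beta) != L)
    stopData("truth beta must be ", I, " x ", L)
  if (nrow(truth@SigmaT) != L || nrow(truth@Re) != L)
    stopData("SigmaT and Re must be ", L, " x ", L)
  if (I > 1L && (is.null(truth@SigmaE) || nrow(truth@SigmaE) != I))
    stopData("SigmaE must be ", I, " x ", I, " for ", I, " environments")
  lines <- idSort(rownames(G))
  G <- G[lines, lines, drop = FALSE]
  envs <- idSort(as.character(envNames))
  withSeed(seed, {
    b1 <- rMatrixNormal(matrix(0, J, L), G, truth@SigmaT)
    b2 <- if (I > 1L)
      rMatrixNormal(matrix(0, I * J, L), kronProd(truth@SigmaE, G),
                    truth@SigmaT) else NULL
    n <- I * J
    ## canonical (env-major, line-sorted) complete layout
    gid <- rep(lines, times = I)
    env <- if (I > 1L) rep(envs, each = J) else rep(NA_character_, n)
    envIdx <- rep(seq_len(I), each = J)
    lineIdx <- rep(seq_len(J), times = I)
    E <- matrix(stats::rnorm(n * L), n, L) %*% chol(truth@Re)
    Y <- truth@beta[envIdx, , drop = FALSE] + b1[lineIdx, , drop = FALSE] + E
    if (I > 1L) Y <- Y + b2[(envIdx - 1L) * J + lineIdx, , drop = FALSE]
    colnames(Y) <- traitNames
    truth@b1 <- b1
    truth@b2 <- b2
    truth@seed <- seed
    pheno <- phenoTable(gid = gid, Y = Y,
                        env = if (I > 1L) env else NULL,
                        traitNames = traitNames)
    list(pheno = canonicalizePheno(pheno), truth = truth)
  })
}

## Default truth parameters for the two toy-structure presets. Scales are
## chosen to look like small wheat (centred traits, one environment) and
## maize (yield/anthesis-silking interval/plant height over three
## environments) trials with heritabilities around one half.
.presetTruth <- function(name) {
  corMat <- function(L, rho) {
    R <- matrix(rho, L, L); diag(R) <- 1; R
  }
  scaleCov <- function(sds, R) diag(sds) %*% R %*% diag(sds)
  switch(name,
    mada_like = {
      sds <- c(8, 2.4, 4.9, 6.8, 167, 29)       # PH FL FE NS SY NP scales
      R <- diag(6)
      R[1, 2] <- R[2, 1] <- -0.2
      R[2, 3] <- R[3, 2] <- 0.27
      R[2, 5] <- R[5, 2] <- 0.43
      R[4, 5] <- R[5, 4] <- 0.33
      R[1, 6] <- R[6, 1] <- -0.48
      list(I = 1L, L = 6L,
           envNames = "E1",
           traitNames = c("PH", "FL", "FE", "NS", "SY", "NP"),
           beta = matrix(0, 1, 6),
           SigmaT = scaleCov(sds, R),
           Re = scaleCov(sds, diag(6)),
           SigmaE = NULL)
    },
    maize_like = {
      R <- diag(3)
      R[1, 3] <- R[3, 1] <- 0.6
      R[1, 2] <- R[2, 1] <- -0.1
      R[2, 3] <- R[3, 2] <- 0.15
      list(I = 3L, L = 3L,
           envNames = c("EBU", "KAK", "KTI"),
           traitNames = c("Yield", "ASI", "PH"),
           beta = matrix(c(6.0, 5.5, 6.5,
                           2.0, 2.5, 1.8,
                           240, 230, 250), 3, 3),
           SigmaT = scaleCov(c(0.65, 0.55, 8.0), R),
           Re = scaleCov(c(0.70, 0.65, 9.5), diag(3)),
           SigmaE = scaleCov(rep(sqrt(0.5), 3), corMat(3, 0.8)))
    },
    stopUsage("unknown preset '", name, "'; available: mada_like, maize_like"))
}

#' Simulate a full toy data set from a named preset
#'
#' Presets mirror the structure of two packaged toy breeding data sets:
#' \code{"mada_like"} (30 wheat lines, 6 centred traits, 1 environment) and
#' \code{"maize_like"} (30 maize lines, 3 traits, 3 environments). Markers
#' are simulated, the relationship matrix is built with
#' \code{\link{grmVanRaden}}, and phenotypes are drawn from the generative
#' model with fixed, documented covariance parameters.
#'
#' @param preset \code{"mada_like"} or \code{"maize_like"}.
#' @param seed integer seed.
#' @param J number of lines (default 30, the toy size).
#' @param p number of markers for the relationship matrix (default 200).
#' @return list with \code{markers}, \code{G}, \code{pheno} and
#'   \code{truth}.
#' @export
simulatePreset <- function(preset = c("maize_like", "mada_like"), seed = 1L,
                           J = 30L, p = 200L) {
  preset <- match.arg(preset)
  cfg <- .presetTruth(preset)
  withSeed(seed, {
    W <- simulateMarkers(J, p)
    G <- grmVanRaden(W)
    truth <- simulationTruth(cfg$beta, cfg$SigmaT, cfg$Re, cfg$SigmaE)
    sim <- simulateTraits(G, cfg$envNames, cfg$traitNames, truth)
    list(markers = W, G = G, pheno = sim$pheno, truth = sim$truth)
  })
}
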