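## Random-sampling primitives shared by the model fitters.

#' Chain settings constructor
#'
#' @param nIter total Gibbs iterations.
#' @param burnIn discarded initial iterations (must be < nIter).
#' @param thin thinning interval (default 2).
#' @param blockSize rows of the random-effect matrices updated jointly per
#'   block; at least 50 but less than 1000 (default 50).
#' @param seed integer chain seed.
#' @return a validated \linkS4class{ChainSettings}.
#' @export
chainSettings <- function(nIter, burnIn, thin = 2L, blockSize = 50L,
                          seed = 1L) {
  tryCatch(
    new("ChainSettings", nIter = as.integer(nIter),
        burnIn = as.integer(burnIn), thin = as.integer(thin),
        blockSize = as.integer(blockSize), seed = as.integer(seed)),
    error = function(e) stopUsage(conditionMessage(e)))
}

#' Sample from a matrix-variate normal distribution
#'
#' Draws M + L_U Z L_V' where Z has iid standard normal entries and L_U,
#' L_V are PSD-safe Cholesky factors of the row and column covariance
#' matrices, so that vec of the draw has covariance V (x) U.
#'
#' @param M n x p location matrix.
#' @param U n x n row covariance (symmetric PSD).
#' @param V p x p column covariance (symmetric PSD).
#' @return an n x p matrix.
#' @export
rMatrixNormal <- function(M, U, V) {
  M <- as.matrix(M)
  if (nrow(U) != nrow(M) || ncol(U) != nrow(M))
    stopData("row covariance U must be ", nrow(M), " x ", nrow(M))
  if (nrow(V) != ncol(M) || ncol(V) != ncol(M))
    stopData("column covariance V must be ", ncol(M), " x ", ncol(M))
  Lu <- safeCholesky(U)
  Lv <- safeCholesky(V)
  Z <- matrix(stats::rnorm(nrow(M) * ncol(M)), nrow(M), ncol(M))
  M + Lu %*% Z %*% t(Lv)
}

#' Sample from an inverse-Wishart distribution
#'
#' Parameterised so that the density is proportional to
#' |S|^(df/2) |X|^(-(df + p + 1)/2) exp(-tr(S X^-1)/2); the mean is
#' S / (df - p - 1) for df > p + 1. Implemented through
#' \code{stats::rWishart} on the inverted scale matrix.
#'
#' @param df degrees of freedom (> p - 1).
#' @param S positive-definite p x p scale matrix.
#' @return a symmetric positive-definite p x p matrix.
#' @export
rInvWishart <- function(df, S) {
  S <- checkSymmetric(S, what = "inverse-Wishart scale")
  p <- nrow(S)
  if (df <= p - 1) stopData("inverse-Wishart df must exceed dim - 1")
  R <- tryCatch(chol(S), error = function(e)
    stopData("inverse-Wishart scale matrix is not positive definite"))
  Sinv <- chol2inv(R)
  Sinv <- (Sinv + t(Sinv)) / 2
  W <- stats::rWishart(1L, df, Sinv)[, , 1L]
  X <- chol2inv(chol(W))
  X <- (X + t(X)) / 2
  dimnames(X) <- dimnames(S)
  X
}

## Draw from a scaled inverse chi-square: S0 / chisq_df.
rScaledInvChisq <- function(df, S0) S0 / stats::rchisq(1L, df)

## ---------------------------------------------------------------------------
## Univariate Gibbs engine (BRR and BayesB components).
##
## Model: y = mu + sum_c X_c u_c + e, e ~ N(0, sigma2 I).
## BRR: u_c ~ N(0, sigma2_c I), sigma2_c ~ scaled-inv-chisq.
## BayesB: per-effect mixture of a point mass at zero (probability pi) and a
## normal slab whose variance has a scaled-inv-chisq prior (a scaled-t slab
## after marginalisation); pi gets a Beta prior.
## Missing responses are imputed from their predictive distribution each
## iteration (data augmentation), which doubles as the prediction mechanism
## for masked testing cells.

.uniCheckModel <- function(model) {
  if (model %in% c("BRR", "BayesB")) return(model)
  if (model %in% c("BayesA", "BayesC", "BL"))
    stopUsage("model '", model, "' is not implemented in this engine ",
              "(available: BRR, BayesB)")
  stopUsage("unknown model label '", model, "'")
}

.uniInit <- function(y, components, settings, control = list()) {
  y <- as.numeric(y)
  n <- length(y)
  if (length(components) < 1L) stopUsage("at least one predictor component required")
  obs <- !is.na(y)
  if (!any(obs)) stopData("response is entirely missing")
  if (sum(obs) < 3L) stopData("need at least 3 observed response values")
  if (is.null(names(components)))
    names(components) <- paste0("comp", seq_along(components))
  varY <- stats::var(y[obs])
  if (!is.finite(varY) || varY <= 0) varY <- 1
  K <- length(components)
  ctl <- modifyList(list(updateIntercept = TRUE, updateVarE = TRUE,
                         updateVarComp = TRUE, interceptVar = Inf,
                         dfe0 = 5, R2 = 0.5), control)
  comps <- lapply(names(components), function(nm) {
    comp <- components[[nm]]
    X <- as.matrix(comp$X)
    if (nrow(X) != n) stopData("component '", nm, "' design has ", nrow(X),
                               " rows; response has ", n)
    model <- .uniCheckModel(comp$model)
    q <- ncol(X)
    share <- ctl$R2 * varY / K
    st <- list(name = nm, X = X, q = q, model = model, u = rep(0, q),
               Xu = rep(0, n))
    if (model == "BRR") {
      st$XtX <- crossprod(X)
      st$df0 <- comp$df0 %||% 5
      st$S0 <- (st$df0 + 2) * share          # prior mode share of var(y)
      st$sigma2c <- share
    } else {                                  # BayesB
      st$xtx <- colSums(X * X)
      st$dfSlab <- comp$dfSlab %||% 5
      st$probZero0 <- comp$probZero0 %||% 0.5
      st$counts <- comp$counts %||% 10
      msx <- sum(colMeans(X * X))
      if (msx <= 0) msx <- 1
      inShare <- max(1 - st$probZero0, 1e-3)
      mode <- share / (msx * inShare)
      ## sigma_j^2 ~ Sb / chisq_dfSlab, with Sb set so the prior mode
      ## (Sb / (dfSlab + 2)) equals the per-effect variance share
      st$Sb <- comp$slabScale %||% (mode * (st$dfSlab + 2))
      st$sigma2j <- rep(st$Sb / (st$dfSlab + 2), q)
      st$probZero <- st$probZero0
      st$delta <- rep(0L, q)
    }
    st
  })
  names(comps) <- names(components)
  mu <- mean(y[obs])
  e <- ifelse(obs, y - mu, 0)
  list(n = n, obs = obs, mu = mu, e = e, comps = comps,
       sigma2 = ctl$R2 * varY,
       dfe0 = ctl$dfe0, Se0 = (ctl$dfe0 + 2) * ctl$R2 * varY,
       ctl = ctl, varY = varY)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.uniLinpred <- function(st) {
  lp <- rep(st$mu, st$n)
  for (comp in st$comps) lp <- lp + comp$Xu
  lp
}

.uniScan <- function(st) {
  n <- st$n
  ## data augmentation for missing responses
  miss <- !st$obs
  if (any(miss)) st$e[miss] <- stats::rnorm(sum(miss), 0, sqrt(st$sigma2))

  ## intercept
  if (st$ctl$updateIntercept) {
    r <- st$e + st$mu
    if (is.finite(st$ctl$interceptVar)) {
      prec <- n / st$sigma2 + 1 / st$ctl$interceptVar
      m <- (sum(r) / st$sigma2) / prec
      st$mu <- stats::rnorm(1L, m, sqrt(1 / prec))
    } else {
      st$mu <- stats::rnorm(1L, mean(r), sqrt(st$sigma2 / n))
    }
    st$e <- r - st$mu
  }

  for (ci in seq_along(st$comps)) {
    comp <- st$comps[[ci]]
    if (comp$model == "BRR") {
      r <- st$e + comp$Xu
      C <- comp$XtX
      diag(C) <- diag(C) + st$sigma2 / comp$sigma2c
      R <- chol(C)
      m <- backsolve(R, backsolve(R, crossprod(comp$X, r), transpose = TRUE))
      u <- m + sqrt(st$sigma2) * backsolve(R, stats::rnorm(comp$q))
      comp$u <- as.numeric(u)
      comp$Xu <- as.numeric(comp$X %*% comp$u)
      st$e <- r - comp$Xu
      if (st$ctl$updateVarComp) {
        comp$sigma2c <- (comp$S0 + sum(comp$u^2)) /
          stats::rchisq(1L, comp$df0 + comp$q)
      }
    } else {                                  # BayesB coordinate scan
      probIn <- 1 - comp$probZero
      for (j in seq_len(comp$q)) {
        xj <- comp$X[, j]
        uo <- comp$u[j]
        xe <- sum(xj * st$e) + comp$xtx[j] * uo
        cj <- comp$xtx[j] + st$sigma2 / comp$sigma2j[j]
        logBF <- 0.5 * (log(st$sigma2) - log(comp$sigma2j[j] * cj)) +
          0.5 * xe^2 / (st$sigma2 * cj)
        logOdds <- log(probIn) - log1p(-probIn) + logBF
        pIn <- 1 / (1 + exp(-logOdds))
        if (stats::runif(1L) < pIn) {
          un <- stats::rnorm(1L, xe / cj, sqrt(st$sigma2 / cj))
          comp$delta[j] <- 1L
        } else {
          un <- 0
          comp$delta[j] <- 0L
        }
        if (un != uo) st$e <- st$e + xj * (uo - un)
        comp$u[j] <- un
      }
      comp$Xu <- as.numeric(comp$X %*% comp$u)
      if (st$ctl$updateVarComp) {
        inc <- comp$delta == 1L
        comp$sigma2j[inc] <- (comp$Sb + comp$u[inc]^2) /
          stats::rchisq(sum(inc), comp$dfSlab + 1)
        comp$sigma2j[!inc] <- comp$Sb / stats::rchisq(sum(!inc), comp$dfSlab)
        nz <- sum(!inc)
        comp$probZero <- stats::rbeta(1L,
          comp$counts * comp$probZero0 + nz,
          comp$counts * (1 - comp$probZero0) + comp$q - nz)
        comp$probZero <- min(max(comp$probZero, 1e-6), 1 - 1e-6)
      }
    }
    st$comps[[ci]] <- comp
  }

  if (st$ctl$updateVarE) {
    st$sigma2 <- (st$Se0 + sum(st$e^2)) / stats::rchisq(1L, st$dfe0 + n)
  }
  st
}

#' Fit a univariate Bayesian regression by Gibbs sampling
#'
#' The single-trait engine used for GBLUP-type fits and for both stages of
#' regressor stacking. Each predictor component is a list with elements
#' \code{X} (design matrix) and \code{model} (\code{"BRR"} or
#' \code{"BayesB"}; \code{"BayesA"}, \code{"BayesC"} and \code{"BL"} raise a
#' not-implemented error). Missing response entries are sampled from their
#' predictive distribution each iteration, so the fitted values at missing
#' (masked) records are model predictions.
#'
#' Default hyperpriors: component and residual variances carry scaled
#' inverse chi-square priors with 5 degrees of freedom and scales chosen so
#' the prior mode equals half the sample variance of the observed response,
#' split equally across components. BayesB additionally places a
#' Beta(p0 pi0, p0 (1 - pi0)) prior on the point-mass probability with
#' pi0 = 0.5, p0 = 10, and a 5-df scaled-t slab. Individual components may
#' override these via optional fields (\code{df0}, \code{dfSlab},
#' \code{probZero0}, \code{counts}, \code{slabScale}).
#'
#' @param y numeric response vector, missing values allowed.
#' @param components named list of predictor components (see above).
#' @param settings a \linkS4class{ChainSettings}.
#' @param control internal toggles used for validation experiments (fixing
#'   variances or the intercept, prior overrides); not needed for ordinary
#'   fits.
#' @return a \linkS4class{UnivariateFit}.
#' @export
fitUnivariate <- function(y, components, settings, control = list()) {
  stopifnot(is(settings, "ChainSettings"))
  withSeed(settings@seed, .uniFit(y, components, settings, control))
}

## Engine body without seed handling, so composite procedures (stacking,
## cross-validation loops) can run many fits off one seeded stream.
.uniFit <- function(y, components, settings, control = list()) {
  {
    st <- .uniInit(y, components, settings, control)
    nComp <- length(st$comps)
    accMu <- 0; accS2 <- 0; nAcc <- 0L
    accU <- lapply(st$comps, function(c) rep(0, c$q))
    accVc <- rep(0, nComp)
    accIn <- rep(0, nComp)
    for (it in seq_len(settings@nIter)) {
      st <- .uniScan(st)
      if (it > settings@burnIn && (it - settings@burnIn) %% settings@thin == 0L) {
        nAcc <- nAcc + 1L
        accMu <- accMu + st$mu
        accS2 <- accS2 + st$sigma2
        for (ci in seq_len(nComp)) {
          comp <- st$comps[[ci]]
          accU[[ci]] <- accU[[ci]] + comp$u
          accVc[ci] <- accVc[ci] +
            if (comp$model == "BRR") comp$sigma2c else mean(comp$sigma2j)
          accIn[ci] <- accIn[ci] +
            if (comp$model == "BRR") 1 else mean(comp$delta)
        }
      }
    }
    effects <- lapply(accU, function(u) u / nAcc)
    names(effects) <- names(st$comps)
    mu <- accMu / nAcc
    yHat <- rep(mu, st$n)
    for (ci in seq_len(nComp))
      yHat <- yHat + as.numeric(st$comps[[ci]]$X %*% effects[[ci]])
    new("UnivariateFit", intercept = mu, effects = effects,
        varComponents = stats::setNames(accVc / nAcc, names(st$comps)),
        varE = accS2 / nAcc, yHat = yHat,
        probIn = stats::setNames(accIn / nAcc, names(st$comps)),
        settings = list(nIter = settings@nIter, burnIn = settings@burnIn,
                        thin = settings@thin, seed = settings@seed))
  }
}
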