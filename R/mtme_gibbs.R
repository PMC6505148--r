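## Blocked Gibbs sampler for the matrix-variate multi-trait
## (multi-environment) model
##
##   Y = X beta + Z1 b1 + Z2 b2 + E,
##   b1 ~ MN(0, I_J, SigmaT)          (whitened line effects)
##   b2 ~ MN(0, SigmaE (x) I_J, SigmaT)  (whitened line-by-environment effects)
##   E  ~ MN(0, I_n, Re)
##
## with inverse-Wishart priors on the unstructured covariance matrices
## SigmaT (traits), SigmaE (environments) and Re (residuals), and a flat
## (optionally conjugate matrix-normal) prior on beta.
##
## The b1/b2 full conditionals do not factor as matrix normals because the
## likelihood couples traits through Re while the prior couples them through
## SigmaT. The sampler therefore transforms the trait axis with the
## simultaneous diagonaliser M of (SigmaT, Re) -- M' Re M = I and
## M' SigmaT M = D diagonal -- after which the transformed trait columns are
## conditionally independent ridge-type regressions; each column is sampled
## exactly, sweeping the coefficient rows in blocks of blockSize. Masked and
## missing response cells are refreshed from their conditional normal given
## the observed traits of the same record (data augmentation), which is also
## the prediction mechanism for testing cells.

.mtmeDefaultPriors <- function(L, I) {
  list(nuT = L + 2, ST = diag(L), nuRes = L + 2, SRes = diag(L),
       nuE = if (!is.null(I)) I + 2 else NULL,
       SE = if (!is.null(I)) diag(I) else NULL,
       betaVar = Inf)
}

.mtmeInit <- function(Y, X, Z1, Z2 = NULL, settings, maskCells = NULL,
                      priors = list(), control = list()) {
  Y <- as.matrix(Y)
  n <- nrow(Y); L <- ncol(Y)
  X <- as.matrix(X)
  Z1 <- as.matrix(Z1)
  if (nrow(X) != n || nrow(Z1) != n)
    stopData("X and Z1 must have one row per record of Y")
  J <- ncol(Z1)
  I <- if (is.null(Z2)) NULL else {
    Z2 <- as.matrix(Z2)
    if (nrow(Z2) != n) stopData("Z2 must have one row per record of Y")
    if (ncol(Z2) %% J != 0L)
      stopData("Z2 column count must be a multiple of the Z1 column count")
    ncol(Z2) %/% J
  }
  pri <- modifyList(.mtmeDefaultPriors(L, I), priors)
  ctl <- modifyList(list(updateBeta = TRUE, updateB1 = TRUE, updateB2 = TRUE,
                         updateSigmaT = TRUE, updateSigmaE = TRUE,
                         updateRe = TRUE), control)

  mask <- is.na(Y)
  if (!is.null(maskCells) && nrow(maskCells)) {
    if (max(maskCells[, 1L]) > n || max(maskCells[, 2L]) > L ||
        min(maskCells) < 1L)
      stopData("testing-set cell indices out of range")
    mask[maskCells] <- TRUE
  }
  Yobs <- Y
  Yobs[mask] <- NA
  ## initialize masked cells at trait means of the remaining observations
  colMu <- colMeans(Yobs, na.rm = TRUE)
  colMu[!is.finite(colMu)] <- 0
  Yfill <- Yobs
  for (l in seq_len(L)) Yfill[mask[, l], l] <- colMu[l]

  S0 <- stats::cov(Yfill)
  S0[!is.finite(S0)] <- 0
  S0 <- S0 + diag(1e-6 * max(diag(S0), 1), L)

  st <- list(
    Y = Yfill, Yobs = Yobs, mask = mask, n = n, L = L, J = J, I = I,
    X = X, Z1 = Z1, Z2 = Z2,
    XtX = crossprod(X), Z1tZ1 = crossprod(Z1),
    Z2tZ2 = if (!is.null(Z2)) crossprod(Z2) else NULL,
    beta = ctl$beta0 %||% matrix(0, ncol(X), L),
    b1 = ctl$b10 %||% matrix(0, J, L),
    b2 = if (!is.null(Z2)) (ctl$b20 %||% matrix(0, I * J, L)) else NULL,
    SigmaT = ctl$SigmaT0 %||% (S0 / 2),
    SigmaE = if (!is.null(Z2)) (ctl$SigmaE0 %||% diag(I)) else NULL,
    Re = ctl$Re0 %||% (S0 / 2),
    pri = pri, ctl = ctl,
    blocksJ = .rowBlocks(J, settings@blockSize),
    blocksIJ = if (!is.null(Z2)) .rowBlocks(I * J, settings@blockSize) else NULL,
    predMean = Yfill)
  ## rows fully masked vs partially masked, grouped once
  nMaskRow <- rowSums(mask)
  st$rowsFull <- which(nMaskRow == L)
  st$rowsPart <- which(nMaskRow > 0L & nMaskRow < L)
  st
}

.rowBlocks <- function(m, bs) {
  if (m <= bs) return(list(seq_len(m)))
  split(seq_len(m), ceiling(seq_len(m) / bs))
}

.mtmeLinpred <- function(st) {
  lp <- st$X %*% st$beta + st$Z1 %*% st$b1
  if (!is.null(st$Z2)) lp <- lp + st$Z2 %*% st$b2
  lp
}

## one full Gibbs scan; returns the updated state
.mtmeScan <- function(st) {
  L <- st$L; n <- st$n; J <- st$J
  pri <- st$pri; ctl <- st$ctl

  ## --- data augmentation of masked / missing cells -------------------------
  lp <- .mtmeLinpred(st)
  st$predMean <- lp
  if (length(st$rowsFull)) {
    idx <- st$rowsFull
    Znoise <- matrix(stats::rnorm(length(idx) * L), length(idx), L)
    st$Y[idx, ] <- lp[idx, , drop = FALSE] + Znoise %*% chol(st$Re)
  }
  for (r in st$rowsPart) {
    m <- which(st$mask[r, ]); o <- which(!st$mask[r, ])
    Roo <- st$Re[o, o, drop = FALSE]
    Rmo <- st$Re[m, o, drop = FALSE]
    W <- Rmo %*% chol2inv(chol(Roo))
    cm <- lp[r, m] + as.numeric(W %*% (st$Y[r, o] - lp[r, o]))
    cv <- st$Re[m, m, drop = FALSE] - W %*% t(Rmo)
    cv <- (cv + t(cv)) / 2
    st$predMean[r, m] <- cm
    st$Y[r, m] <- cm + as.numeric(safeCholesky(cv) %*% stats::rnorm(length(m)))
  }

  ## --- beta (matrix-normal full conditional; flat or conjugate prior) ------
  if (ctl$updateBeta) {
    Ry <- st$Y - st$Z1 %*% st$b1
    if (!is.null(st$Z2)) Ry <- Ry - st$Z2 %*% st$b2
    C <- st$XtX
    if (is.finite(pri$betaVar)) diag(C) <- diag(C) + 1 / pri$betaVar
    Rc <- chol(C)
    Bhat <- backsolve(Rc, backsolve(Rc, crossprod(st$X, Ry), transpose = TRUE))
    A <- backsolve(Rc, diag(ncol(st$X)))
    Z <- matrix(stats::rnorm(ncol(st$X) * L), ncol(st$X), L)
    st$beta <- Bhat + A %*% Z %*% chol(st$Re)
  }

  ## --- simultaneous diagonalisation of (SigmaT, Re) on the trait axis ------
  URe <- chol(st$Re)
  LRe <- t(URe)
  T1 <- forwardsolve(LRe, st$SigmaT)
  A <- t(forwardsolve(LRe, t(T1)))
  A <- (A + t(A)) / 2
  ee <- eigen(A, symmetric = TRUE)
  d <- pmax(ee$values, 1e-12 * max(abs(ee$values), 1))
  M <- backsolve(URe, ee$vectors)       # M' Re M = I, M' SigmaT M = diag(d)
  Minv <- t(ee$vectors) %*% URe

  ## --- b1 ------------------------------------------------------------------
  if (ctl$updateB1) {
    R1 <- st$Y - st$X %*% st$beta
    if (!is.null(st$Z2)) R1 <- R1 - st$Z2 %*% st$b2
    Yt <- R1 %*% M
    Bt <- st$b1 %*% M
    for (k in seq_len(L)) {
      P <- st$Z1tZ1
      diag(P) <- diag(P) + 1 / d[k]
      Bt[, k] <- .blockDrawGaussian(P, crossprod(st$Z1, Yt[, k]), Bt[, k],
                                    st$blocksJ)
    }
    st$b1 <- Bt %*% Minv
  }

  ## --- b2 ------------------------------------------------------------------
  if (!is.null(st$Z2) && ctl$updateB2) {
    SigmaEinv <- chol2inv(chol(st$SigmaE))
    KE <- kronProd(SigmaEinv, diag(J))
    R2y <- st$Y - st$X %*% st$beta - st$Z1 %*% st$b1
    Yt <- R2y %*% M
    Bt <- st$b2 %*% M
    for (k in seq_len(L)) {
      P <- st$Z2tZ2 + KE / d[k]
      Bt[, k] <- .blockDrawGaussian(P, crossprod(st$Z2, Yt[, k]), Bt[, k],
                                    st$blocksIJ)
    }
    st$b2 <- Bt %*% Minv
  }

  ## --- SigmaT (inverse-Wishart, pooling both effect matrices) --------------
  if (ctl$updateSigmaT) {
    S <- pri$ST + crossprod(st$b1)
    df <- pri$nuT + J
    if (!is.null(st$Z2)) {
      SigmaEinv <- chol2inv(chol(st$SigmaE))
      KE <- kronProd(SigmaEinv, diag(J))
      Q2 <- crossprod(st$b2, KE %*% st$b2)
      S <- S + (Q2 + t(Q2)) / 2
      df <- df + st$I * J
    }
    st$SigmaT <- rInvWishart(df, (S + t(S)) / 2)
  }

  ## --- SigmaE --------------------------------------------------------------
  if (!is.null(st$Z2) && ctl$updateSigmaE) {
    SigmaTinv <- chol2inv(chol(st$SigmaT))
    I <- st$I
    Tm <- matrix(0, I, I)
    Bi <- lapply(seq_len(I), function(i)
      st$b2[(i - 1L) * J + seq_len(J), , drop = FALSE])
    BiS <- lapply(Bi, function(B) B %*% SigmaTinv)
    for (i in seq_len(I)) {
      for (k in i:I) {
        Tm[i, k] <- sum(Bi[[i]] * BiS[[k]])
        Tm[k, i] <- Tm[i, k]
      }
    }
    st$SigmaE <- rInvWishart(pri$nuE + J * L, pri$SE + Tm)
  }

  ## --- Re ------------------------------------------------------------------
  if (ctl$updateRe) {
    E <- st$Y - .mtmeLinpred(st)
    st$Re <- rInvWishart(pri$nuRes + n, pri$SRes + crossprod(E))
  }
  st
}

## Draw x ~ N(P^{-1} ell, P^{-1}) by sweeping row blocks: each block is an
## exact draw from its full conditional given the other blocks (valid Gibbs
## move; a single block is an exact joint draw).
.blockDrawGaussian <- function(P, ell, b, blocks) {
  s <- as.numeric(P %*% b)
  for (B in blocks) {
    Pbb <- P[B, B, drop = FALSE]
    rhs <- ell[B] - s[B] + as.numeric(Pbb %*% b[B])
    Rb <- chol(Pbb)
    m <- backsolve(Rb, backsolve(Rb, rhs, transpose = TRUE))
    bn <- as.numeric(m + backsolve(Rb, stats::rnorm(length(B))))
    delta <- bn - b[B]
    s <- s + as.numeric(P[, B, drop = FALSE] %*% delta)
    b[B] <- bn
  }
  b
}

## Run the chain and accumulate posterior summaries. Returns a list of
## summary matrices; the exported fitters wrap it in the S4 result classes.
.mtmeRun <- function(st, settings) {
  accs <- list(yHat = newAccumulator(dim(st$Y)),
               beta = newAccumulator(dim(st$beta)),
               b1 = newAccumulator(dim(st$b1)),
               SigmaT = newAccumulator(dim(st$SigmaT)),
               Re = newAccumulator(dim(st$Re)))
  if (!is.null(st$Z2)) {
    accs$b2 <- newAccumulator(dim(st$b2))
    accs$SigmaE <- newAccumulator(dim(st$SigmaE))
  }
  for (it in seq_len(settings@nIter)) {
    st <- .mtmeScan(st)
    if (it > settings@burnIn &&
        (it - settings@burnIn) %% settings@thin == 0L) {
      ## fitted surface, with masked cells at their conditional means
      fitDraw <- .mtmeLinpred(st)
      fitDraw[st$mask] <- st$predMean[st$mask]
      accs$yHat <- accAdd(accs$yHat, fitDraw)
      accs$beta <- accAdd(accs$beta, st$beta)
      accs$b1 <- accAdd(accs$b1, st$b1)
      accs$SigmaT <- accAdd(accs$SigmaT, st$SigmaT)
      accs$Re <- accAdd(accs$Re, st$Re)
      if (!is.null(st$Z2)) {
        accs$b2 <- accAdd(accs$b2, st$b2)
        accs$SigmaE <- accAdd(accs$SigmaE, st$SigmaE)
      }
    }
  }
  out <- list(state = st)
  for (nm in names(accs)) {
    out[[nm]] <- accMean(accs[[nm]])
    out[[paste0("SD.", nm)]] <- accSD(accs[[nm]])
  }
  out
}
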