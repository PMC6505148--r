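## Shared fixtures and statistical helpers for the test suite.

## random symmetric positive-definite matrix
rndPD <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p, p)
  scale * (crossprod(A) / p + diag(p))
}

## batch-means standard error for autocorrelated chains
bmSE <- function(x, nBatch = 50) {
  n <- length(x)
  m <- floor(n / nBatch)
  x <- x[seq_len(m * nBatch)]
  means <- tapply(x, rep(seq_len(nBatch), each = m), mean)
  stats::sd(means) / sqrt(nBatch)
}

## z statistics comparing moments of an iid forward sample with an
## autocorrelated successive-conditional chain (Geweke-style joint test)
gewekeZ <- function(fwd, suc) {
  nF <- length(fwd)
  zMean <- (mean(fwd) - mean(suc)) /
    sqrt(stats::var(fwd) / nF + bmSE(suc)^2)
  vF <- stats::var(fwd)
  ## SE of the forward variance from its fourth moment; chain side by batch
  ## means on centred squares
  m4 <- mean((fwd - mean(fwd))^4)
  seVF <- sqrt(max(m4 - vF^2, 0) / nF)
  zVar <- (vF - stats::var(suc)) /
    sqrt(seVF^2 + bmSE((suc - mean(suc))^2)^2)
  c(mean = zMean, var = zVar)
}

## small complete-layout design for the matrix-variate samplers
tinyDesign <- function(J = 3, I = 2, seed = 1) {
  set.seed(seed)
  X <- kronecker(diag(I), matrix(1, J, 1))
  Z1 <- do.call(rbind, replicate(I, diag(J) * 0.9 + 0.1, simplify = FALSE))
  Z2 <- kronecker(diag(I), diag(J) * 0.8 + 0.1)
  list(X = X, Z1 = Z1, Z2 = Z2, n = I * J, J = J, I = I)
}

## phenotype CSV written to a temp file; returns the path
writePhenoCSV <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

## Maize-style toy phenotype rows (structure of the printed toy listing)
maizeToyDf <- function() {
  data.frame(
    Line = rep(c("CKDHL0008", "CKDHL0039", "CKDHL0042", "CKDHL0050"), 2),
    Env = rep(c("EBU", "KAK"), each = 4),
    Yield = c(6.88, 6.85, 6.37, 4.98, 7.07, 8.62, 5.16, 5.77),
    ASI = c(2.7, 1.3, 2.3, 3.1, 1.4, 2.3, 1.0, 1.7),
    PH = c(226, 239, 238, 239, 242, 250, 248, 227))
}

## Wheat-style toy phenotype rows (GID + six centred traits)
madaToyDf <- function() {
  data.frame(
    GID = c("9", "11", "12", "15", "20", "21"),
    PH = c(29.7776, 3.2210, 6.1670, 6.8117, -14.4480, -13.2185),
    FL = c(-8.8882, -7.1111, -9.5337, 4.6377, 3.2525, 3.8902),
    FE = c(-4.939, -0.3694, -12.4368, 11.7886, 6.4078, 0.09722),
    NS = c(1.041, -3.8894, 2.5825, -0.03378, -14.2346, 5.3568),
    SY = c(169.06, -107.19, -160.54, 235.70, 131.87, 164.06),
    NP = c(28.8025, 58.2516, 17.1278, -19.6571, 42.2962, 36.8239))
}

## printed 6x6 trait genetic covariance of the wheat toy analysis
madaTraitCov <- function() {
  v <- c(64.4266, -4.2148, 6.3730, -0.0049, -103.8781, -114.4456,
         -4.2148, 5.9607, 3.2257, -0.1355, 175.7770, -21.0909,
         6.3730, 3.2257, 23.8617, 1.3721, -133.4962, -43.6292,
         -0.0049, -0.1355, 1.3721, 46.2903, 370.1770, -59.0136,
         -103.8781, 175.7770, -133.4962, 370.1770, 27963.1634, 604.6203,
         -114.4456, -21.0909, -43.6292, -59.0136, 604.6203, 872.3525)
  matrix(v, 6, 6, dimnames = list(c("PH", "FL", "FE", "NS", "SY", "NP"),
                                  c("PH", "FL", "FE", "NS", "SY", "NP")))
}

## printed 3x3 trait genetic covariance of the maize toy analysis
maizeTraitCov <- function() {
  v <- c(0.0956, -0.0027, 0.9642,
         -0.0027, 0.0654, 0.1893,
         0.9642, 0.1893, 23.0647)
  matrix(v, 3, 3, dimnames = list(c("Yield", "ASI", "PH"),
                                  c("Yield", "ASI", "PH")))
}
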