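test_that("scalePredictions standardizes columns and stores the statistics", {
  ## hand example: column (1,2,3) centres at 2 with sample SD 1
  sp <- scalePredictions(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
  expect_equal(sp@Zhat[, "a"], c(-1, 0, 1))
  expect_equal(sp@center, c(a = 2, b = 20))
  expect_equal(sp@scale[["b"]], 10)
  ## columns have mean 0 and unit sample SD
  expect_lt(max(abs(colMeans(sp@Zhat))), 1e-8)
  expect_lt(max(abs(apply(sp@Zhat, 2, sd) - 1)), 1e-8)
  ## already-standardized input passes through unchanged
  expect_equal(scalePredictions(sp@Zhat)@Zhat, sp@Zhat, tolerance = 1e-12)
  ## constant column errors, naming the trait
  expect_error(scalePredictions(cbind(ok = 1:5, flat = rep(2, 5))), "flat")
})

stackFixture <- function(rho, J = 60, seed = 1) {
  ## two traits with genetic correlation rho over two environments
  W <- simulateMarkers(J, 150, seed = seed)
  G <- grmVanRaden(W)
  R <- matrix(c(1, rho, rho, 1), 2)
  truth <- simulationTruth(matrix(c(10, 11, 20, 19), 2, 2),
                           SigmaT = R, Re = 0.6 * diag(2),
                           SigmaE = 0.3 * diag(2) + 0.1)
  sim <- simulateTraits(G, c("E1", "E2"), c("A", "B"), truth,
                        seed = seed + 500)
  d <- buildDesign(sim$pheno, G)
  comps <- list(Env = list(X = d@X, model = "BRR"),
                Gen = list(X = d@Z1, model = "BRR"),
                EnvGen = list(X = d@Z2, model = "BRR"))
  list(pheno = sim$pheno, comps = comps)
}

test_that("stacking predicts held-out cells and honours masking", {
  fx <- stackFixture(0.8, seed = 3)
  st <- chainSettings(400, 150, seed = 5)
  cv <- cvRandomPartition(fx$pheno, nPartitions = 2, pTesting = 0.2,
                          seed = 11)
  res <- fitStacking(fx$pheno@Y, fx$comps, st, cv)
  expect_s4_class(res, "StackingResult")
  ## predictions exist for every masked cell
  pt <- predictionsTable(res)
  nTest <- sum(lengths(partitions(cv)))
  expect_equal(nrow(pt), nTest * 2L)
  expect_true(all(is.finite(pt$Predicted)))
  ## coefficient matrices are L x L per partition
  expect_length(res@coefficients, 2L)
  expect_equal(dim(res@coefficients[[1]]), c(2L, 2L))

  ## masked responses are never read (bitwise invariance)
  Y2 <- fx$pheno@Y
  Y2[partitions(cv)[[1]], ] <- 123.45
  ## rebuild a partition object over the altered copy, same indices
  res2 <- fitStacking(Y2, fx$comps, st,
                      cv)
  p1 <- predictionsTable(res2)
  idx <- p1$Partition == 1
  expect_identical(p1$Predicted[idx], pt$Predicted[idx])

  ## unknown stage-2 label errors before any fitting
  expect_error(fitStacking(fx$pheno@Y, fx$comps, st, cv,
                           covModel = "wrong"), "unknown model")
})

test_that("a single partition yields undefined standard errors", {
  fx <- stackFixture(0.5, J = 30, seed = 7)
  st <- chainSettings(300, 120, seed = 6)
  res <- fitStacking(fx$pheno@Y, fx$comps, st,
                     cvCustom(fx$pheno, testing = c(2L, 9L, 21L, 40L)))
  sm <- summary(res)
  expect_true(all(is.nan(sm$SE_Pearson)))
  expect_true(all(is.nan(sm$SE_MAAPE)))
})

test_that("stage-2 coefficients load positively on the trait's own prediction", {
  st <- chainSettings(500, 200, seed = 8)
  hits <- 0L
  nSeeds <- 5L
  for (s in seq_len(nSeeds)) {
    fx <- stackFixture(0.6, J = 40, seed = 40 + s)
    res <- fitStacking(fx$pheno@Y, fx$comps, st,
                       cvCustom(fx$pheno, testing = seq(1, 80, by = 5)))
    co <- res@coefficients[[1]]
    if (all(diag(co) > 0)) hits <- hits + 1L
  }
  expect_gte(hits, nSeeds - 1L)
})

test_that("whole-environment hold-out trains on the remaining environments", {
  fx <- stackFixture(0.9, J = 40, seed = 9)
  st <- chainSettings(400, 150, seed = 10)
  res <- fitStackingEnv(fx$pheno, "E2", fx$comps, settings = st)
  sm <- summary(res)
  ## metrics only for the held-out environment, one row per trait, no SE
  ## columns for the single testing set
  expect_equal(nrow(sm), 2L)
  expect_true(all(sm$Environment == "E2"))
  expect_named(sm, c("Environment", "Trait", "Pearson", "MAAPE"))

  ## validation errors
  expect_error(fitStackingEnv(fx$pheno, c("E1", "E2"), fx$comps,
                              settings = st), "at least one environment")
  expect_error(fitStackingEnv(fx$pheno, "E9", fx$comps, settings = st),
               "unknown environment")
  expect_error(fitStackingEnv(fx$pheno, character(0), fx$comps,
                              settings = st), "non-empty")
})

test_that("with a single trait, stacking reduces to the plain univariate fit", {
  ## stage 2 then regresses y on its own scaled stage-1 prediction, so the
  ## testing accuracy must track the stage-1 GBLUP accuracy closely
  J <- 60
  W <- simulateMarkers(J, 150, seed = 17)
  G <- grmVanRaden(W)
  b <- as.numeric(rMatrixNormal(matrix(0, J, 1), G, matrix(1)))
  set.seed(18)
  gid <- rep(sprintf("L%03d", 1:J), 2)
  env <- rep(c("E1", "E2"), each = J)
  y <- 10 + c(b, b) + rnorm(2 * J, 0, sqrt(var(b)))    # h2 = 0.5
  tab <- canonicalizePheno(phenoTable(gid,
    matrix(y, ncol = 1, dimnames = list(NULL, "A")), env = env))
  d <- buildDesign(tab, G)
  comps <- list(Env = list(X = d@X, model = "BRR"),
                Gen = list(X = d@Z1, model = "BRR"))
  st <- chainSettings(800, 300, seed = 19)
  cv <- cvRandomPartition(tab, nPartitions = 5, pTesting = 0.2, seed = 123)
  res <- fitStacking(tab@Y, comps, st, cv)
  pStack <- mean(summary(res, information = "complete")$Pearson,
                 na.rm = TRUE)
  pStage1 <- mean(vapply(seq_along(partitions(cv)), function(p) {
    test <- partitions(cv)[[p]]
    yy <- tab@Y[, 1]; yy[test] <- NA
    f <- fitUnivariate(yy, comps, st)
    pearsonCor(tab@Y[test, 1], fittedValues(f)[test])
  }, numeric(1)))
  expect_lt(abs(pStack - pStage1), 0.1)
})

test_that("duplicated environments transfer almost perfectly at high heritability", {
  ## hold out one of two identical environments: the genomic term carries
  ## the signal across, so testing accuracy is high
  set.seed(61)
  J <- 60
  W <- simulateMarkers(J, 200, seed = 12)
  G <- grmVanRaden(W)
  b <- as.numeric(rMatrixNormal(matrix(0, J, 1), G, matrix(1)))
  ## residual SD set from the realized between-line variance so the
  ## line-to-line heritability is 0.9 (the uncentered GRM puts much of
  ## var(b) into a shared component absorbed by the intercept)
  sdE <- sqrt(stats::var(b) / 9)
  e1 <- rnorm(J, 0, sdE)
  e2 <- rnorm(J, 0, sdE)
  gid <- rep(sprintf("L%03d", 1:J), 2)
  env <- rep(c("E1", "E2"), each = J)
  Y <- cbind(A = c(10 + b + e1, 10 + b + e2),
             B = c(5 + 0.5 * b + e1 * 0.5, 5 + 0.5 * b + e2 * 0.5))
  tab <- canonicalizePheno(phenoTable(gid, Y, env = env))
  d <- buildDesign(tab, G)
  comps <- list(Env = list(X = d@X, model = "BRR"),
                Gen = list(X = d@Z1, model = "BRR"))
  st <- chainSettings(600, 200, seed = 13)
  res <- fitStackingEnv(tab, "E2", comps, settings = st)
  sm <- summary(res)
  expect_gt(min(sm$Pearson), 0.8)
})
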