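test_that("readPhenotypes parses single- and multi-environment layouts", {
  ## wheat-style: GID + six traits, one environment
  p1 <- writePhenoCSV(madaToyDf())
  tab1 <- readPhenotypes(p1, gidCol = "GID")
  expect_s4_class(tab1, "PhenoTable")
  expect_equal(nRecords(tab1), 6L)
  expect_equal(traitNames(tab1), c("PH", "FL", "FE", "NS", "SY", "NP"))
  expect_length(envNames(tab1), 0L)
  expect_equal(unname(tab1@Y[1, "PH"]), 29.7776)

  ## maize-style: Line + Env + three traits
  p2 <- writePhenoCSV(maizeToyDf())
  tab2 <- readPhenotypes(p2, gidCol = "Line", envCol = "Env")
  expect_equal(traitNames(tab2), c("Yield", "ASI", "PH"))
  expect_equal(envNames(tab2), c("EBU", "KAK"))

  ## missing tokens preserved as NA
  df <- maizeToyDf(); df$Yield[2] <- NA
  tab3 <- readPhenotypes(writePhenoCSV(df), gidCol = "Line", envCol = "Env")
  expect_true(is.na(tab3@Y[2, "Yield"]))

  ## empty data section, bad numeric cell and duplicates all error
  empty <- tempfile(fileext = ".csv")
  writeLines("GID,T1,T2", empty)
  expect_error(readPhenotypes(empty), "no data rows")
  df2 <- madaToyDf(); df2$PH <- as.character(df2$PH); df2$PH[3] <- "x9"
  expect_error(readPhenotypes(writePhenoCSV(df2)), "row 3")
  df3 <- maizeToyDf(); df3$Line[2] <- df3$Line[1]
  expect_error(readPhenotypes(writePhenoCSV(df3), gidCol = "Line",
                              envCol = "Env"), "duplicate")
})

test_that("canonicalizePheno sorts by environment then line and is idempotent", {
  df <- maizeToyDf()
  set.seed(11)
  shuffled <- df[sample(nrow(df)), ]
  tab <- readPhenotypes(writePhenoCSV(shuffled), gidCol = "Line",
                        envCol = "Env")
  canon <- canonicalizePheno(tab)
  ## EBU block first, lines ascending within each environment block
  expect_equal(canon@env, rep(c("EBU", "KAK"), each = 4))
  expect_equal(canon@gid[1:4], sort(unique(df$Line)))
  ## idempotence
  again <- canonicalizePheno(canon)
  expect_identical(again@gid, canon@gid)
  expect_identical(again@Y, canon@Y)
  ## single record unchanged
  one <- phenoTable("g1", matrix(1:2, 1, 2))
  expect_identical(canonicalizePheno(one)@Y, one@Y)
  ## integer-like identifiers sort numerically (9 before 11)
  t2 <- canonicalizePheno(readPhenotypes(writePhenoCSV(madaToyDf())))
  expect_equal(t2@gid[1:3], c("9", "11", "12"))
})

test_that("filterMarkers applies missingness, imputation and MAF rules in order", {
  ## marker 2 has 30% missing -> dropped by step 1 before any imputation
  set.seed(12)
  W <- matrix(sample(0:2, 40, replace = TRUE, prob = c(.25, .5, .25)), 10, 4)
  colnames(W) <- paste0("m", 1:4)
  W[1:3, 2] <- NA
  out <- filterMarkers(W, seed = 1)
  expect_false("m2" %in% colnames(out))

  ## monomorphic marker dropped by the MAF filter
  W2 <- cbind(mono = rep(0, 10), poly = rep(c(0, 1, 2), length.out = 10))
  expect_identical(colnames(filterMarkers(W2, seed = 1)), "poly")

  ## clean input passes through unchanged
  expect_identical(filterMarkers(W2[, "poly", drop = FALSE], seed = 1),
                   W2[, "poly", drop = FALSE])

  ## deterministic given a seed; monotone in the MAF threshold
  W3 <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                      prob = c(.3, .4, .2, .1)), 20, 10)
  expect_identical(filterMarkers(W3, seed = 5), filterMarkers(W3, seed = 5))
  n1 <- ncol(filterMarkers(W3, minMAF = 0.05, seed = 5))
  n2 <- ncol(filterMarkers(W3, minMAF = 0.20, seed = 5))
  expect_lte(n2, n1)

  expect_error(filterMarkers(matrix(3, 2, 2)), "0/1/2")
  expect_error(filterMarkers(matrix(c(0, NA, NA, NA), 4, 1), seed = 1),
               "missingness filter")
})

test_that("buildDesign produces consistent whitened designs", {
  ## identity GRM leaves the incidence matrices unwhitened
  df <- maizeToyDf()
  tab <- canonicalizePheno(readPhenotypes(writePhenoCSV(df), gidCol = "Line",
                                          envCol = "Env"))
  lines <- lineIds(tab)
  G <- diag(length(lines)); dimnames(G) <- list(lines, lines)
  d <- buildDesign(tab, G)
  expect_equal(d@I, 2L)
  expect_true(all(d@Z1 %in% c(0, 1)))
  expect_equal(rowSums(d@X), rep(1, d@n))
  expect_equal(rowSums(d@Z1), rep(1, d@n))

  ## non-trivial G: per-environment block of Z1 Z1' equals G
  set.seed(13)
  G2 <- rndPD(4); dimnames(G2) <- list(lines, lines)
  d2 <- buildDesign(tab, G2)
  ebu <- which(tab@env == "EBU")
  expect_equal(tcrossprod(d2@Z1)[ebu, ebu], G2, ignore_attr = TRUE)
  ## complete layout: Z2 Z2' = Z_EG (I x G) Z_EG'
  ZEG <- matrix(0, d2@n, 2 * 4)
  envIdx <- match(tab@env, d2@envOrder)
  lineIdx <- match(tab@gid, d2@lineOrder)
  ZEG[cbind(seq_len(d2@n), (envIdx - 1) * 4 + lineIdx)] <- 1
  expect_equal(tcrossprod(d2@Z2),
               ZEG %*% kronecker(diag(2), G2) %*% t(ZEG),
               tolerance = 1e-8, ignore_attr = TRUE)

  ## incomplete layout keeps rows consistent
  tab3 <- canonicalizePheno(readPhenotypes(writePhenoCSV(df[-3, ]),
                                           gidCol = "Line", envCol = "Env"))
  d3 <- buildDesign(tab3, G2)
  expect_equal(d3@n, 7L)
  expect_equal(nrow(d3@X), 7L)
  expect_equal(nrow(d3@Z2), 7L)

  ## single environment: X is a ones column, Z2 absent
  tabM <- canonicalizePheno(readPhenotypes(writePhenoCSV(madaToyDf())))
  GM <- diag(6); dimnames(GM) <- list(lineIds(tabM), lineIds(tabM))
  dM <- buildDesign(tabM, GM)
  expect_equal(dM@X, matrix(1, 6, 1), ignore_attr = TRUE)
  expect_null(dM@Z2)

  ## unknown line reported by name
  Gsmall <- G2[1:3, 1:3]
  expect_error(buildDesign(tab, Gsmall), "absent from the relationship")
})
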