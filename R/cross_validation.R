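## Cross-validation designs for incomplete field trials: random
## (line, environment)-cell masking and K-fold CV2-style partitioning.

#' Random cross-validation partitions
#'
#' Builds \code{nPartitions} testing sets over the records of a
#' canonicalized phenotype table. Per partition, m = round(pTesting * N)
#' lines are drawn (N = total records; half-up rounding). Lines are sampled
#' with replacement when fewer distinct lines than m exist, and without
#' replacement otherwise. For each drawn line one of its available
#' environments is picked uniformly; the selected distinct cells form the
#' testing set (duplicate cells arising from with-replacement draws
#' collapse, so a testing set can be smaller than m). The same record may
#' appear in several partitions.
#'
#' @param table a \linkS4class{PhenoTable}; canonicalized internally.
#' @param nPartitions number of random partitions (default 10).
#' @param pTesting testing fraction in (0, 1) (default 0.2).
#' @param seed integer seed; partitions are a pure function of
#'   (table, parameters, seed).
#' @return a \linkS4class{CVPartitions} with scheme \code{"random"}.
#' @export
cvRandomPartition <- function(table, nPartitions = 10L, pTesting = 0.2,
                              seed = 123L) {
  stopifnot(is(table, "PhenoTable"))
  if (pTesting <= 0 || pTesting >= 1)
    stopUsage("pTesting must lie strictly between 0 and 1")
  if (nPartitions < 1L) stopUsage("nPartitions must be positive")
  table <- canonicalizePheno(table)
  N <- nRecords(table)
  m <- floor(pTesting * N + 0.5)            # half-up rounding
  if (m == 0L) stopUsage("pTesting * N rounds to zero testing cells")
  lines <- idSort(unique(table@gid))
  J <- length(lines)
  byLine <- split(seq_len(N), table@gid)
  withSeed(seed, {
    parts <- lapply(seq_len(nPartitions), function(p) {
      replace <- J < m
      drawn <- sample(lines, m, replace = replace)
      cellIdx <- vapply(drawn, function(ln) {
        recs <- byLine[[ln]]
        if (length(recs) == 1L) recs else sample(recs, 1L)
      }, integer(1L))
      sort(unique(as.integer(cellIdx)))
    })
    new("CVPartitions", partitions = parts, scheme = "random",
        params = list(nPartitions = as.integer(nPartitions),
                      pTesting = pTesting, m = m, seed = as.integer(seed)),
        gid = table@gid, env = table@env)
  })
}

#' K-fold (CV2-style) cross-validation partitions
#'
#' Assigns every record to exactly one of k folds of near-equal size
#' (sizes differ by at most one). Each line's records are dealt onto
#' consecutive positions of a cyclic shuffled fold order, so a line with at
#' most k records lands in that many distinct folds: lines tested in some
#' environments remain in training in the others (the CV2 design of
#' incomplete field trials).
#'
#' @param table a \linkS4class{PhenoTable}; canonicalized internally.
#' @param k number of folds (2 <= k <= number of records).
#' @param seed integer seed.
#' @return a \linkS4class{CVPartitions} with scheme \code{"kfold"}.
#' @export
cvKFold <- function(table, k = 5L, seed = 123L) {
  stopifnot(is(table, "PhenoTable"))
  table <- canonicalizePheno(table)
  N <- nRecords(table)
  k <- as.integer(k)
  if (k < 2L || k > N)
    stopUsage("k must satisfy 2 <= k <= ", N, " (number of records)")
  withSeed(seed, {
    foldOrder <- sample.int(k)
    lineOrder <- sample(idSort(unique(table@gid)))
    byLine <- split(seq_len(N), table@gid)
    assign <- integer(N)
    pos <- 0L
    for (ln in lineOrder) {
      recs <- byLine[[ln]]
      if (length(recs) > 1L) recs <- sample(recs)
      for (r in recs) {
        assign[r] <- foldOrder[(pos %% k) + 1L]
        pos <- pos + 1L
      }
    }
    parts <- lapply(seq_len(k), function(f) sort(which(assign == f)))
    new("CVPartitions", partitions = parts, scheme = "kfold",
        params = list(k = k, seed = as.integer(seed)),
        gid = table@gid, env = table@env)
  })
}

#' Single user-defined testing set as a partition object
#'
#' @param table a \linkS4class{PhenoTable} (canonicalized internally).
#' @param testing integer vector of testing record indices.
#' @return a \linkS4class{CVPartitions} with one partition.
#' @export
cvCustom <- function(table, testing) {
  stopifnot(is(table, "PhenoTable"))
  table <- canonicalizePheno(table)
  new("CVPartitions", partitions = list(sort(unique(as.integer(testing)))),
      scheme = "custom", params = list(), gid = table@gid, env = table@env)
}

#' @describeIn CVPartitions long-format view (columns partition,
#'   record_index, gid, env) suitable for CSV audit files.
#' @param x a partition set.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "CVPartitions", function(x, ...) {
  rows <- lapply(seq_along(x@partitions), function(p) {
    idx <- x@partitions[[p]]
    data.frame(partition = p, record_index = idx, gid = x@gid[idx],
               env = x@env[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})
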