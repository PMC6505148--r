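## Prediction-accuracy metrics and the mean +/- SE summary table.

#' Pearson correlation between observed and predicted values
#'
#' Standard product-moment correlation. When either vector has zero
#' variance (or fewer than two pairs are available) the result is the
#' undefined-value marker \code{NaN} rather than an error, so degenerate
#' testing sets propagate cleanly into summaries.
#'
#' @param obs,pred numeric vectors of equal length; pairs with a missing
#'   entry are dropped.
#' @return a scalar in [-1, 1], or \code{NaN}.
#' @export
pearsonCor <- function(obs, pred) {
  if (length(obs) != length(pred)) stopData("obs and pred lengths differ")
  keep <- is.finite(obs) & is.finite(pred)
  obs <- obs[keep]; pred <- pred[keep]
  if (length(obs) < 2L) return(NaN)
  so <- stats::sd(obs); sp <- stats::sd(pred)
  if (!is.finite(so) || !is.finite(sp) || so == 0 || sp == 0) return(NaN)
  stats::cor(obs, pred)
}

#' Mean arctangent absolute percentage error (MAAPE)
#'
#' mean over i of atan(|(obs_i - pred_i) / obs_i|), a bounded accuracy
#' metric (values in [0, pi/2]) that remains defined when the response
#' contains zeros: a zero observation with a different prediction
#' contributes atan(Inf) = pi/2, while an exact match contributes 0 even at
#' obs = 0.
#'
#' @param obs,pred numeric vectors of equal length; pairs with a missing
#'   entry are dropped.
#' @return a scalar in [0, pi/2].
#' @export
maape <- function(obs, pred) {
  if (length(obs) != length(pred)) stopData("obs and pred lengths differ")
  keep <- is.finite(obs) & is.finite(pred)
  obs <- obs[keep]; pred <- pred[keep]
  if (!length(obs)) return(NaN)
  ape <- ifelse(obs == pred, 0, abs((obs - pred) / obs))  # 0/0 -> 0, x/0 -> Inf
  mean(atan(ape))
}

#' Summarize per-partition prediction metrics
#'
#' Averages Pearson and MAAPE over partitions for every (environment,
#' trait) combination and attaches standard errors
#' SE = sd(partition values) / sqrt(number of partitions). With a single
#' partition the SE columns are \code{NaN}: no standard error can be
#' computed from one testing set. Rows are ordered by environment, then
#' trait.
#'
#' @param results data.frame with columns Environment, Trait, Partition,
#'   Pearson, MAAPE (Environment may be \code{NA} throughout for
#'   single-environment fits).
#' @return data.frame with columns Environment, Trait, Pearson, SE_Pearson,
#'   MAAPE, SE_MAAPE.
#' @export
summarizeMetrics <- function(results) {
  stopifnot(is.data.frame(results))
  if (!nrow(results)) {
    return(data.frame(Environment = character(0), Trait = character(0),
                      Pearson = numeric(0), SE_Pearson = numeric(0),
                      MAAPE = numeric(0), SE_MAAPE = numeric(0)))
  }
  envKey <- ifelse(is.na(results$Environment), "", results$Environment)
  key <- paste(envKey, results$Trait, sep = "\r")
  groups <- split(seq_len(nrow(results)), key)
  rows <- lapply(groups, function(idx) {
    sub <- results[idx, , drop = FALSE]
    m <- nrow(sub)
    se <- function(x) if (m < 2L) NaN else stats::sd(x) / sqrt(m)
    data.frame(Environment = sub$Environment[1L], Trait = sub$Trait[1L],
               Pearson = mean(sub$Pearson), SE_Pearson = se(sub$Pearson),
               MAAPE = mean(sub$MAAPE), SE_MAAPE = se(sub$MAAPE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[idOrder(out$Environment, out$Trait), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a metrics table to CSV, preserving NaN markers
#'
#' \code{write.csv} renders both \code{NA} and \code{NaN} as "NA"; summary
#' tables use \code{NaN} as the undefined-value marker (e.g. standard
#' errors from a single testing set), so numeric columns are formatted as
#' text first to keep the distinction.
#'
#' @param df data.frame (e.g. from \code{\link{summarizeMetrics}}).
#' @param path destination path.
#' @export
writeSummaryCSV <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- as.character(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

## Per-partition metric rows over a set of masked cells.
## cells: 2-column (record, trait) matrix; env: per-record labels (may be NA).
.metricRows <- function(Yobs, pred, cells, env, traitNames, partition) {
  if (!nrow(cells)) return(NULL)
  df <- data.frame(Environment = env[cells[, 1L]],
                   Trait = traitNames[cells[, 2L]],
                   Observed = Yobs[cells], Predicted = pred[cells],
                   stringsAsFactors = FALSE)
  df <- df[is.finite(df$Observed), , drop = FALSE]
  if (!nrow(df)) return(NULL)
  envKey <- ifelse(is.na(df$Environment), "", df$Environment)
  groups <- split(seq_len(nrow(df)), paste(envKey, df$Trait, sep = "\r"))
  rows <- lapply(groups, function(idx) {
    sub <- df[idx, , drop = FALSE]
    data.frame(Environment = sub$Environment[1L], Trait = sub$Trait[1L],
               Partition = partition,
               Pearson = pearsonCor(sub$Observed, sub$Predicted),
               MAAPE = maape(sub$Observed, sub$Predicted),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.predictionRows <- function(Yobs, pred, cells, gid, env, traitNames,
                            partition) {
  if (!nrow(cells)) return(NULL)
  data.frame(Partition = partition, Record = cells[, 1L],
             GID = gid[cells[, 1L]], Environment = env[cells[, 1L]],
             Trait = traitNames[cells[, 2L]], Observed = Yobs[cells],
             Predicted = pred[cells], stringsAsFactors = FALSE)
}
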