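#' Rank frequently-regulated target genes
#'
#' Counts, per target, the distinct regulators whose interaction score is at
#' least `min_score`, sorted by descending count with a lexicographic
#' tiebreak.
#'
#' @param table an `interaction_table`.
#' @param min_score score threshold.
#' @return Data frame with columns `target`, `regulator_count`.
#' @export
rank_frequent_targets <- function(table, min_score = 0) {
  stopifnot(is.data.frame(table))
  keep <- table[table$score >= min_score, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(data.frame(target = character(), regulator_count = integer()))
  }
  agg <- tapply(keep$regulator, keep$target, function(r) length(unique(r)))
  out <- data.frame(target = names(agg), regulator_count = as.integer(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$regulator_count, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize per-regulator lag distributions in a context
#'
#' Lag estimates proxy a regulator's spatial range: bigger lags mean a
#' regulator's influence reaches farther along the spatial graph. Only rows
#' with a positive score (detected interactions) contribute. The regulators
#' with the largest and smallest mean lag are flagged as the longest- and
#' shortest-range in the context; with a single regulator neither flag is
#' set.
#'
#' @param table an `interaction_table`.
#' @param context context label to summarize (must be present).
#' @return A list of class `lag_summary`: `per_regulator` data frame
#'   (`regulator`, `n_targets`, `mean_lag`, `weighted_mean_lag`,
#'   `longest_range`, `shortest_range`), `lags` (named list of lag vectors),
#'   `context`.
#' @export
summarize_lags <- function(table, context = "") {
  stopifnot(is.data.frame(table))
  if (!context %in% table$context) {
    stop("context '", context, "' absent from the interaction table", call. = FALSE)
  }
  rows <- table[table$context == context & table$score > 0, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no detected interactions (score > 0) in context '", context, "'",
         call. = FALSE)
  }
  regs <- sort(unique(rows$regulator))
  lag_list <- lapply(regs, function(r) rows$lag[rows$regulator == r])
  names(lag_list) <- regs
  mean_lag <- vapply(lag_list, mean, 0)
  wmean <- vapply(regs, function(r) {
    sub <- rows[rows$regulator == r, ]
    sum(sub$lag * sub$score) / sum(sub$score)
  }, 0)
  df <- data.frame(regulator = regs,
                   n_targets = vapply(lag_list, length, 0L),
                   mean_lag = mean_lag, weighted_mean_lag = wmean,
                   longest_range = FALSE, shortest_range = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) > 1L) {
    df$longest_range[which.max(df$mean_lag)] <- TRUE
    df$shortest_range[which.min(df$mean_lag)] <- TRUE
  }
  rownames(df) <- NULL
  structure(list(per_regulator = df, lags = lag_list, context = context),
            class = "lag_summary")
}

#' @export
print.lag_summary <- function(x, ...) {
  cat("lag_summary for context '", x$context, "':\n", sep = "")
  print(x$per_regulator)
  invisible(x)
}

#' Area under the precision-recall curve of a score ranking
#'
#' Average-precision form: precision is accumulated at each positive in the
#' descending-score ranking (ties broken by input order, making the value
#' deterministic).
#'
#' @param scores numeric scores, larger = more confident.
#' @param labels logical (or 0/1) ground-truth positives, same length.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels))
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Write a run-metadata JSON record
#'
#' Serializes the effective configuration (plus arbitrary extras such as
#' per-lambda validity fractions) so a run can be reproduced exactly.
#'
#' @param path output file.
#' @param config a config object (any named list).
#' @param extra optional named list merged in under `extra`.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, config, extra = NULL) {
  rec <- list(tool = "spagranger",
              version = as.character(utils::packageVersion("spagranger")),
              config = unclass(config))
  if (!is.null(extra)) rec$extra <- extra
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
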