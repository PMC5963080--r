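#' Ranking metrics for link prediction
#'
#' Five metrics over a labelled [scored_ranking()], split into two families:
#'
#' * link-equality metrics pool all candidate links — [auroc()], [aupr()],
#'   [precision_at_k()]. Hub nodes, whose many links are typically easier to
#'   predict, can dominate them.
#' * node-equality metrics average per node with equal weight —
#'   [mean_average_precision()] and [averaged_r_precision()] — so
#'   performance at low-degree nodes counts as much as at hubs.
#'
#' Except for AUROC, metrics are computed on the deterministic ranking
#' (descending score, lexicographic pair tie-break). AUROC uses the standard
#' probabilistic definition in which score ties earn half credit, making it
#' invariant to tie-break order and to any strictly monotone transform of
#' the scores.
#'
#' @param r a labelled `scored_ranking` (no `NA` labels).
#' @name metrics
NULL

check_labels <- function(r) {
  if (nrow(r) == 0L) stop("empty ranking")
  if (anyNA(r$label)) stop("ranking has unlabelled pairs")
}

#' @rdname metrics
#' @return `auroc`: probability that a uniformly random positive outranks a
#'   uniformly random negative, ties counted half.
#' @export
auroc <- function(r) {
  check_labels(r)
  n1 <- sum(r$label); n0 <- sum(!r$label)
  if (n1 == 0L || n0 == 0L) stop("AUROC needs at least one positive and one negative")
  rk <- rank(r$score, ties.method = "average")
  (sum(rk[r$label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname metrics
#' @return `aupr`: area under the precision-recall step curve, accumulated
#'   at each positive (equivalently, average precision over the positives).
#' @export
aupr <- function(r) {
  check_labels(r)
  npos <- sum(r$label)
  if (npos == 0L) stop("AUPR needs at least one positive")
  hits <- which(r$label)
  mean(seq_along(hits) / hits)
}

#' @rdname metrics
#' @param k_ratio fraction of the positive count used as the cutoff
#'   `k = ceiling(k_ratio * n_positives)` (default 0.3).
#' @return `precision_at_k`: fraction of the top-k ranked pairs that are
#'   positive.
#' @export
precision_at_k <- function(r, k_ratio = 0.3) {
  check_labels(r)
  stopifnot(k_ratio > 0, k_ratio <= 1)
  npos <- sum(r$label)
  if (npos == 0L) stop("precision@k needs at least one positive")
  k <- ceiling(k_ratio * npos)
  mean(r$label[seq_len(min(k, nrow(r)))])
}

#' Per-node sublists of a global ranking
#'
#' For each node appearing in any evaluated pair, the sublist of the global
#' ranking restricted to pairs incident to that node, preserving global rank
#' order. The basis of the node-equality metrics: every pair appears in
#' exactly two sublists (one per endpoint).
#'
#' @param r a `scored_ranking`.
#' @return named list of data.frames (rank-ordered sublists).
#' @export
per_node_lists <- function(r) {
  if (nrow(r) == 0L) return(stats::setNames(list(), character()))
  idx <- c(seq_len(nrow(r)), seq_len(nrow(r)))
  node <- c(r$u, r$v)
  by_node <- split(idx, node)
  lapply(by_node, function(i) r[sort(i), , drop = FALSE])
}

#' @rdname metrics
#' @return `mean_average_precision`: mean over nodes with at least one
#'   positive in their sublist of that node's average precision (precision
#'   at each positive's rank within the sublist, averaged over the node's
#'   positives). Nodes with no positive are excluded (their AP is
#'   undefined).
#' @export
mean_average_precision <- function(r) {
  check_labels(r)
  aps <- vapply(per_node_lists(r), function(sub) {
    hits <- which(sub$label)
    if (length(hits) == 0L) return(NA_real_)
    mean(seq_along(hits) / hits)
  }, numeric(1))
  aps <- aps[!is.na(aps)]
  if (length(aps) == 0L) stop("no node has a positive in its list")
  mean(aps)
}

#' @rdname metrics
#' @return `averaged_r_precision`: mean over qualifying nodes of the
#'   fraction of that node's top-R sublist entries that are positive, where
#'   R is the node's positive count.
#' @export
averaged_r_precision <- function(r) {
  check_labels(r)
  rps <- vapply(per_node_lists(r), function(sub) {
    R <- sum(sub$label)
    if (R == 0L) return(NA_real_)
    sum(sub$label[seq_len(R)]) / R
  }, numeric(1))
  rps <- rps[!is.na(rps)]
  if (length(rps) == 0L) stop("no node has a positive in its list")
  mean(rps)
}

#' All five metrics for one ranking
#'
#' @param r a labelled `scored_ranking`.
#' @param k_ratio cutoff ratio for [precision_at_k()].
#' @return named numeric vector `auroc`, `aupr`, `precision_at_k`, `map`,
#'   `r_precision`, all in `[0, 1]`.
#' @export
evaluate_ranking <- function(r, k_ratio = 0.3) {
  c(auroc = auroc(r), aupr = aupr(r),
    precision_at_k = precision_at_k(r, k_ratio),
    map = mean_average_precision(r),
    r_precision = averaged_r_precision(r))
}

#' Aggregate metric values across runs and test significance
#'
#' Implements the reporting protocol: per metric, the mean and standard
#' deviation over runs for each method, and a two-tailed two-sample t-test
#' (pooled variance) of every method against the best-scoring method for
#' that metric at significance level `alpha`. The verdict is
#' `"not-different"` when the test fails to reject (or for the best method
#' itself) and `"different"` otherwise. Runs with zero variance in both
#' groups are handled by an exact-equality fast path (equal means:
#' not-different; unequal: different). With the default three runs per
#' method the test has little power; verdicts should be read accordingly.
#'
#' @param runs data.frame with columns `method`, `metric`, `run`, `value`
#'   (one row per method x metric x run; equal run counts per method).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `metric`, `method`, `mean`, `sd`,
#'   `best` (logical), `p_value`, `verdict`.
#' @export
aggregate_runs <- function(runs, alpha = 0.05) {
  stopifnot(all(c("method", "metric", "run", "value") %in% names(runs)))
  counts <- table(runs$method, runs$metric)
  if (length(unique(counts)) > 1L) stop("unequal run counts across methods")
  if (any(counts < 2L)) stop("need at least two runs per method")
  out <- list()
  for (met in unique(runs$metric)) {
    sub <- runs[runs$metric == met, , drop = FALSE]
    vals <- split(sub$value, sub$method)
    means <- vapply(vals, mean, numeric(1))
    sds <- vapply(vals, stats::sd, numeric(1))
    best <- names(means)[which.max(means)]
    res <- data.frame(metric = met, method = names(means),
                      mean = unname(means), sd = unname(sds),
                      best = names(means) == best,
                      p_value = NA_real_, verdict = "not-different",
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(res))) {
      m <- res$method[i]
      if (m == best) next
      x <- vals[[m]]; y <- vals[[best]]
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        res$p_value[i] <- if (mean(x) == mean(y)) 1 else 0
      } else {
        res$p_value[i] <- stats::t.test(x, y, var.equal = TRUE,
                                        alternative = "two.sided")$p.value
      }
      if (res$p_value[i] < alpha) res$verdict[i] <- "different"
    }
    out[[met]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary table across methods and metrics
#'
#' One row per method, one column per metric, values formatted
#' `mean` with a trailing `*` for methods not significantly different from
#' the best and the best itself shown in brackets — mirroring the layout of
#' published link-prediction comparison tables.
#'
#' @param agg output of [aggregate_runs()].
#' @param digits decimal places.
#' @return a character matrix (methods x metrics).
#' @export
format_summary <- function(agg, digits = 4L) {
  methods <- unique(agg$method)
  metrics <- unique(agg$metric)
  out <- matrix("", length(methods), length(metrics),
                dimnames = list(methods, metrics))
  for (i in seq_len(nrow(agg))) {
    v <- sprintf(paste0("%.", digits, "f"), agg$mean[i])
    if (agg$best[i]) v <- paste0("[", v, "]")
    else if (agg$verdict[i] == "not-different") v <- paste0(v, "*")
    out[agg$method[i], agg$metric[i]] <- v
  }
  out
}
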