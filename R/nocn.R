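#' Test positives with no prior common neighbours
#'
#' Identifies the test positives whose endpoints share no common neighbour
#' in the induction graph — links that neighbourhood-overlap heuristics
#' cannot recall (CN scores them exactly 0) and arguably the most
#' interesting predictions. Endpoints absent from the induction graph have
#' empty neighbourhoods and are therefore included.
#'
#' @param induction the induction `temporal_graph`.
#' @param test_pos data.frame of test-positive pairs (`u`, `v`).
#' @param bipartite use the two-hop (bipartite) common-neighbour variant;
#'   defaults to `TRUE` when the induction graph carries a partition.
#' @return logical vector, one entry per row of `test_pos`.
#' @export
find_no_cn_positives <- function(induction, test_pos,
                                 bipartite = !is.null(induction$partition)) {
  ctx <- heuristic_context(induction, bipartite)
  vapply(seq_len(nrow(test_pos)), function(i) {
    u <- test_pos$u[i]; v <- test_pos$v[i]
    nu <- ctx$adj[[u]]
    if (is.null(nu)) nu <- character()
    nv <- ctx$adj[[v]]
    if (is.null(nv)) nv <- character()
    if (bipartite) {
      # hat on the second (B-side when partitioned) argument
      if (!is.null(ctx$partition) &&
          !is.na(ctx$partition[u]) && ctx$partition[[u]] == "B") {
        tmp <- nu; nu <- nv; nv <- tmp
      }
      nv <- unique(unlist(ctx$adj[nv], use.names = FALSE))
      if (is.null(nv)) nv <- character()
    }
    length(intersect(nu, nv)) == 0L
  }, logical(1))
}

#' Fraction of a link subset ranked in the top half
#'
#' With balanced positives and negatives a good predictor ranks most true
#' links in the top half of the full list; this measures how a method
#' treats a designated subset (typically the no-common-neighbour
#' positives). "Top half" is rank `<= floor(n/2)` of the full ranking after
#' the deterministic tie-break. `ties = "expected"` instead returns the
#' expected fraction under random tie-breaking within equal-score groups —
#' relevant for heuristics that score many links 0.
#'
#' @param r a `scored_ranking` over all evaluated pairs.
#' @param subset data.frame of pairs (`u`, `v`), all present in `r`.
#' @param ties `"lexicographic"` (deterministic ranks) or `"expected"`.
#' @return fraction in `[0, 1]`.
#' @export
top_half_fraction <- function(r, subset,
                              ties = c("lexicographic", "expected")) {
  ties <- match.arg(ties)
  if (nrow(r) == 0L) stop("empty ranking")
  cp <- canonical_pairs(subset$u, subset$v)
  keys <- pair_key(cp$u, cp$v)
  pos <- match(keys, pair_key(r$u, r$v))
  if (anyNA(pos)) {
    stop("subset pair(s) missing from ranking: ",
         paste(utils::head(keys[is.na(pos)], 3L), collapse = ", "))
  }
  half <- floor(nrow(r) / 2)
  if (ties == "lexicographic") {
    return(mean(pos <= half))
  }
  # expected membership under random ordering within tied-score groups
  grp <- match(r$score, unique(r$score))
  starts <- tapply(seq_len(nrow(r)), grp, min)
  sizes <- tabulate(grp)
  p_top <- pmin(pmax(half - (starts - 1), 0), sizes) / sizes
  mean(p_top[grp[pos]])
}

#' No-common-neighbour diagnostic report
#'
#' Quantifies the no-CN test positives and how each method's ranking treats
#' them, under both tie-handling conventions.
#'
#' @param induction the induction `temporal_graph`.
#' @param test_pos data.frame of test-positive pairs.
#' @param rankings named list of `scored_ranking`s (one per method, all over
#'   the same evaluation pairs).
#' @inheritParams find_no_cn_positives
#' @return list with `n_test_pos`, `n_no_cn`, `frac_no_cn`, and a
#'   data.frame `per_method` (`method`, `top_half_frac`,
#'   `top_half_frac_expected`).
#' @export
no_cn_report <- function(induction, test_pos, rankings,
                         bipartite = !is.null(induction$partition)) {
  flag <- find_no_cn_positives(induction, test_pos, bipartite)
  sub <- test_pos[flag, , drop = FALSE]
  per_method <- data.frame(method = names(rankings),
                           top_half_frac = NA_real_,
                           top_half_frac_expected = NA_real_,
                           stringsAsFactors = FALSE)
  if (nrow(sub) > 0L) {
    for (i in seq_along(rankings)) {
      per_method$top_half_frac[i] <-
        top_half_fraction(rankings[[i]], sub, "lexicographic")
      per_method$top_half_frac_expected[i] <-
        top_half_fraction(rankings[[i]], sub, "expected")
    }
  }
  list(n_test_pos = nrow(test_pos), n_no_cn = nrow(sub),
       frac_no_cn = if (nrow(test_pos) > 0L) nrow(sub) / nrow(test_pos) else 0,
       per_method = per_method)
}
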