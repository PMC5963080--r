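#' Neighbourhood heuristics for link prediction
#'
#' Classic neighbourhood-overlap scores for a candidate pair `(u, v)` with
#' neighbour sets `N(u)`, `N(v)` in the induction graph:
#'
#' * Common Neighbours (CN): `|N(u) & N(v)|`
#' * Adamic-Adar (AA, common-neighbour-count variant): `1 / log(CN)`
#' * Jaccard Index (JI): `|N(u) & N(v)| / |N(u) | N(v)|`
#'
#' On a bipartite graph `N(u)` and `N(v)` never intersect, so the second
#' argument's neighbourhood is replaced by its two-hop neighbourhood
#' `Nhat(v)` — the set of neighbours of neighbours of `v` — giving
#' `|N(u) & Nhat(v)|` and so on. The A-partition node is always taken as the
#' first argument so bipartite scores are well defined for unordered pairs.
#'
#' AA is undefined at CN = 1 (division by `log 1 = 0`) and CN = 0; the
#' package assigns 0 at CN = 0 (no shared evidence) and the finite cap
#' `2 / log 2` at CN = 1, which sits strictly above the CN = 2 score so the
#' decreasing-in-CN ordering of the formula is preserved without infinities
#' in ranked lists.
#'
#' @param g the induction `temporal_graph`.
#' @param u,v node ids; `u != v`, both present in `g`.
#' @param bipartite use the two-hop form for the second argument; defaults
#'   to `TRUE` when `g` carries a partition.
#' @param hat_excludes_self if `TRUE`, drop `v` itself from `Nhat(v)`;
#'   the default keeps it (a sensitivity switch, see the vignette).
#' @return a single numeric score (integer-valued for CN).
#' @name heuristics
NULL

# neighbour sets as an environment-free lookup closure over the graph
heuristic_context <- function(g, bipartite = !is.null(g$partition),
                              hat_excludes_self = FALSE) {
  adj <- adjacency_list(g)
  list(adj = adj, bipartite = bipartite, partition = g$partition,
       hat_excludes_self = hat_excludes_self)
}

# returns list(nu, nv) with the bipartite hat already applied to v's side
pair_neighbourhoods <- function(ctx, u, v) {
  if (!u %in% names(ctx$adj)) stop("unknown node: ", u)
  if (!v %in% names(ctx$adj)) stop("unknown node: ", v)
  if (u == v) stop("self-pair: ", u)
  if (ctx$bipartite && !is.null(ctx$partition)) {
    # canonical order: A-side node first
    if (ctx$partition[[u]] == "B") { tmp <- u; u <- v; v <- tmp }
  }
  nv <- ctx$adj[[v]]
  if (ctx$bipartite) {
    nv <- unique(unlist(ctx$adj[nv], use.names = FALSE))
    if (is.null(nv)) nv <- character()
    if (ctx$hat_excludes_self) nv <- setdiff(nv, v)
  }
  list(nu = ctx$adj[[u]], nv = nv)
}

#' @rdname heuristics
#' @export
common_neighbours <- function(g, u, v, bipartite = !is.null(g$partition),
                              hat_excludes_self = FALSE) {
  ctx <- heuristic_context(g, bipartite, hat_excludes_self)
  nb <- pair_neighbourhoods(ctx, u, v)
  length(intersect(nb$nu, nb$nv))
}

#' @rdname heuristics
#' @export
adamic_adar <- function(g, u, v, bipartite = !is.null(g$partition),
                        hat_excludes_self = FALSE) {
  cn <- common_neighbours(g, u, v, bipartite, hat_excludes_self)
  aa_from_cn(cn)
}

aa_from_cn <- function(cn) {
  ifelse(cn == 0, 0, ifelse(cn == 1, 2 / log(2), 1 / log(cn)))
}

#' @rdname heuristics
#' @export
jaccard <- function(g, u, v, bipartite = !is.null(g$partition),
                    hat_excludes_self = FALSE) {
  ctx <- heuristic_context(g, bipartite, hat_excludes_self)
  nb <- pair_neighbourhoods(ctx, u, v)
  un <- length(union(nb$nu, nb$nv))
  if (un == 0L) return(0)
  length(intersect(nb$nu, nb$nv)) / un
}

#' Ranked list of scored candidate links
#'
#' Builds the package's common ranking container: pairs sorted by descending
#' score with a deterministic lexicographic tie-break on the canonical pair,
#' carrying an optional truth label per pair.
#'
#' @param u,v character vectors of pair endpoints.
#' @param score numeric scores.
#' @param label optional logical truth labels (`TRUE` = positive).
#' @return a data.frame of class `scored_ranking` with columns `u`, `v`,
#'   `score`, `label`, ordered by rank.
#' @export
scored_ranking <- function(u, v, score, label = NULL) {
  cp <- canonical_pairs(as.character(u), as.character(v))
  if (is.null(label)) label <- rep(NA, length(score))
  df <- data.frame(u = cp$u, v = cp$v, score = as.numeric(score),
                   label = as.logical(label), stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$u, df$v), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("scored_ranking", "data.frame")
  df
}

#' Score a batch of candidate pairs with a heuristic
#'
#' @param g the induction `temporal_graph`.
#' @param pairs data.frame with columns `u`, `v`.
#' @param method one of `"cn"`, `"aa"`, `"ji"`.
#' @param label optional logical truth labels, one per pair.
#' @inheritParams heuristics
#' @return a [scored_ranking()].
#' @export
score_all <- function(g, pairs, method = c("cn", "aa", "ji"), label = NULL,
                      bipartite = !is.null(g$partition),
                      hat_excludes_self = FALSE) {
  method <- match.arg(method)
  ctx <- heuristic_context(g, bipartite, hat_excludes_self)
  n <- nrow(pairs)
  score <- numeric(n)
  for (i in seq_len(n)) {
    nb <- pair_neighbourhoods(ctx, pairs$u[i], pairs$v[i])
    cn <- length(intersect(nb$nu, nb$nv))
    score[i] <- switch(method,
      cn = cn,
      aa = aa_from_cn(cn),
      ji = {
        un <- length(union(nb$nu, nb$nv))
        if (un == 0L) 0 else cn / un
      })
  }
  scored_ranking(pairs$u, pairs$v, score, label)
}

#' Write a scored ranking as TSV
#'
#' Columns: `u`, `v`, `score`, `label` (1/0, empty when unknown).
#'
#' @param r a `scored_ranking`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(r, path) {
  lab <- ifelse(is.na(r$label), "", as.integer(r$label))
  utils::write.table(
    data.frame(r$u, r$v, r$score, lab),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("u", "v", "score", "label"))
  invisible(path)
}
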