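#' Synthetic graph configuration
#'
#' Parameters for the stochastic-block-model generator that stands in for
#' real biomedical interaction graphs in tests and examples. Community
#' structure (dense within blocks, sparse between) is the signal both the
#' neighbourhood heuristics and the walk embeddings exploit. Optional link
#' timestamps emulate literature-derived graphs: years are drawn with
#' probability density proportional to `rank^skew` over `year_range`, so
#' `skew = 0` is uniform and larger values concentrate links in late years,
#' producing the test-only-node phenomenon of time-sliced corpora.
#'
#' @param n_nodes node count.
#' @param n_blocks number of blocks (communities); must be even in
#'   bipartite mode, where blocks alternate partitions and consecutive
#'   block pairs form drug--target style communities.
#' @param p_intra within-community link probability.
#' @param p_inter between-community link probability (`<= p_intra`).
#' @param bipartite if `TRUE` only cross-partition pairs are eligible.
#' @param year_range optional integer `c(first, last)` year; `NULL` for an
#'   undated graph.
#' @param skew late-publication skew exponent (`>= 0`).
#' @param unseen_frac_target optional target fraction of nodes whose first
#'   link falls after the cut year handed to [generate_split_scenario()].
#' @param seed integer seed.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 400L, n_blocks = 4L, p_intra = 0.25,
                         p_inter = 0.02, bipartite = FALSE,
                         year_range = NULL, skew = 0,
                         unseen_frac_target = NULL, seed = 1L) {
  stopifnot(n_nodes >= n_blocks, p_inter >= 0, p_intra >= p_inter,
            p_intra <= 1, skew >= 0)
  if (bipartite && n_blocks %% 2L != 0L) {
    stop("bipartite mode needs an even number of blocks")
  }
  if (!is.null(year_range)) {
    stopifnot(length(year_range) == 2L, year_range[1] <= year_range[2])
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 n_blocks = as.integer(n_blocks),
                 p_intra = p_intra, p_inter = p_inter,
                 bipartite = bipartite, year_range = year_range,
                 skew = skew, unseen_frac_target = unseen_frac_target,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# year sampler: density proportional to rank^skew, ascending with year
sample_years <- function(n, year_range, skew) {
  yrs <- seq.int(year_range[1], year_range[2])
  w <- seq_along(yrs)^skew
  yrs[sample.int(length(yrs), n, replace = TRUE, prob = w)]
}

#' Generate a synthetic community-structured graph
#'
#' Draws a stochastic block model per [synth_config()]: nodes are assigned
#' contiguously to blocks; each eligible pair is linked independently with
#' `p_intra` (same community) or `p_inter` (different community). In
#' bipartite mode blocks alternate `"A"`/`"B"` partitions, block `2k-1`
#' pairs with block `2k` as one community, and only cross-partition pairs
#' are eligible. With a `year_range`, each link gets a skew-sampled year;
#' with `unseen_frac_target` and a `cut_year`, a matching fraction of nodes
#' is designated "late" and all their links are dated after the cut so the
#' nodes first appear in the test era (a warning reports the achieved
#' fraction if it misses the target by more than 0.05).
#'
#' @param cfg a [synth_config()].
#' @param cut_year optional year at which [generate_split_scenario()] will
#'   slice; required for `unseen_frac_target`.
#' @return a [temporal_graph()] (with partition in bipartite mode).
#' @export
generate_graph <- function(cfg, cut_year = NULL) {
  withr::local_seed(cfg$seed)
  n <- cfg$n_nodes
  width <- max(4L, nchar(as.character(n)))
  nodes <- sprintf(paste0("n%0", width, "d"), seq_len(n))
  block <- ceiling(seq_len(n) / (n / cfg$n_blocks))
  block <- pmin(block, cfg$n_blocks)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  bi <- block[pr[, 1L]]; bj <- block[pr[, 2L]]
  if (cfg$bipartite) {
    part <- ifelse(block %% 2L == 1L, "A", "B")
    eligible <- part[pr[, 1L]] != part[pr[, 2L]]
    community_i <- ceiling(bi / 2); community_j <- ceiling(bj / 2)
    p <- ifelse(community_i == community_j, cfg$p_intra, cfg$p_inter)
  } else {
    part <- NULL
    eligible <- TRUE
    p <- ifelse(bi == bj, cfg$p_intra, cfg$p_inter)
  }
  linked <- eligible & stats::runif(nrow(pr)) < p
  links <- data.frame(u = nodes[pr[linked, 1L]], v = nodes[pr[linked, 2L]],
                      stringsAsFactors = FALSE)
  year <- NULL
  if (!is.null(cfg$year_range)) {
    m <- nrow(links)
    year <- sample_years(m, cfg$year_range, cfg$skew)
    if (!is.null(cfg$unseen_frac_target)) {
      if (is.null(cut_year)) stop("unseen_frac_target needs a cut_year")
      if (cut_year >= cfg$year_range[2]) stop("cut_year leaves no test era")
      late_nodes <- sample(nodes, ceiling(cfg$unseen_frac_target * n))
      late_link <- links$u %in% late_nodes | links$v %in% late_nodes
      year[late_link] <- sample_years(sum(late_link),
                                      c(cut_year + 1L, cfg$year_range[2]),
                                      cfg$skew)
      first <- tapply(rep(year, 2L), c(links$u, links$v), min)
      achieved <- mean(first > cut_year)
      if (abs(achieved - cfg$unseen_frac_target) > 0.05) {
        warning(sprintf("achieved unseen fraction %.3f (target %.3f)",
                        achieved, cfg$unseen_frac_target))
      }
    }
  }
  g <- temporal_graph(nodes = nodes, links = links, year = year)
  if (cfg$bipartite) g <- attach_partition(g, stats::setNames(part, nodes))
  attr(g, "block") <- stats::setNames(block, nodes)
  g
}

#' Generate a time-slice scenario with ground truth
#'
#' Wraps [generate_graph()] and derives the ground truth needed by the
#' time-slicing tests: each linked node's first-link year, the set of nodes
#' unseen up to `cut_year`, and the block assignment.
#'
#' @param cfg a [synth_config()] with a `year_range`.
#' @param cut_year the intended induction/test boundary year.
#' @return list with `graph`, `first_link_year` (named integer vector over
#'   linked nodes), `unseen_nodes` (first link after `cut_year`),
#'   `unseen_frac`, and `block`.
#' @export
generate_split_scenario <- function(cfg, cut_year) {
  if (is.null(cfg$year_range)) stop("scenario needs a year_range")
  stopifnot(cut_year >= cfg$year_range[1], cut_year <= cfg$year_range[2])
  g <- generate_graph(cfg, cut_year = cut_year)
  first <- tapply(rep(g$year, 2L), c(g$links$u, g$links$v), min)
  first <- stats::setNames(as.integer(first), names(first))
  unseen <- names(first)[first > cut_year]
  list(graph = g, first_link_year = first, unseen_nodes = unseen,
       unseen_frac = length(unseen) / length(first),
       block = attr(g, "block"))
}
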