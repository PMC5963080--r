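# fixture builders used across test files

path_graph <- function(ids) {
  temporal_graph(nodes = ids,
                 links = data.frame(u = ids[-length(ids)], v = ids[-1]))
}

cycle_graph <- function(n) {
  ids <- sprintf("c%02d", 1:n)
  temporal_graph(nodes = ids,
                 links = data.frame(u = ids, v = ids[c(2:n, 1)]))
}

star_graph <- function(n_leaves) {
  leaves <- sprintf("leaf%02d", seq_len(n_leaves))
  temporal_graph(nodes = c("hub", leaves),
                 links = data.frame(u = rep("hub", n_leaves), v = leaves))
}

# Erdos-Renyi style random graph on `ids`; returns the edge data.frame too
random_graph <- function(n, p, prefix = "v") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  comb <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(comb)) < p
  edges <- data.frame(u = comb[1, keep], v = comb[2, keep],
                      stringsAsFactors = FALSE)
  temporal_graph(nodes = ids, links = edges)
}

# random bipartite graph with |A| = na, |B| = nb
random_bipartite <- function(na, nb, p) {
  a <- sprintf("a%02d", seq_len(na))
  b <- sprintf("b%02d", seq_len(nb))
  grid <- expand.grid(u = a, v = b, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < p
  g <- temporal_graph(nodes = c(a, b), links = grid[keep, ])
  attach_partition(g, stats::setNames(rep(c("A", "B"), c(na, nb)), c(a, b)))
}

edge_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_labels <- function(split) {
  c(rep(TRUE, nrow(split$test_pos)), rep(FALSE, nrow(split$test_neg)))
}

test_pairs <- function(split) rbind(split$test_pos, split$test_neg)
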