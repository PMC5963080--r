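#' Random-walk and embedding configuration
#'
#' Bundles the walk and training hyperparameters. Defaults follow the
#' standard DeepWalk/node2vec settings for biomedical graphs: window 10,
#' walk length 40, 10 walks per vertex, 100-dimensional embeddings, and
#' return/in-out parameters p = 2, q = 4 for the biased (node2vec) walk
#' mode. `p` and `q` are only consulted in biased mode.
#'
#' @param walk_length steps per walk.
#' @param walks_per_vertex walks started from every node.
#' @param window skip-gram context window (nodes each side).
#' @param dimensions embedding dimension.
#' @param p return parameter (unnormalized weight 1/p to step back).
#' @param q in-out parameter (weight 1/q to leave the previous node's
#'   neighbourhood).
#' @param epochs passes of the skip-gram trainer over the corpus.
#' @param negative negative samples per positive pair.
#' @param alpha initial skip-gram learning rate.
#' @param seed integer seed.
#' @return a list of class `walk_config`.
#' @export
walk_config <- function(walk_length = 40L, walks_per_vertex = 10L,
                        window = 10L, dimensions = 100L, p = 2, q = 4,
                        epochs = 5L, negative = 5L, alpha = 0.025,
                        seed = 1L) {
  stopifnot(walk_length >= 1, walks_per_vertex >= 1, window >= 1,
            dimensions >= 1, p > 0, q > 0, epochs >= 1)
  structure(list(walk_length = as.integer(walk_length),
                 walks_per_vertex = as.integer(walks_per_vertex),
                 window = as.integer(window),
                 dimensions = as.integer(dimensions),
                 p = p, q = q, epochs = as.integer(epochs),
                 negative = as.integer(negative), alpha = alpha,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Generate a random-walk corpus over a graph
#'
#' Starts exactly `walks_per_vertex` walks from every node of `g`. In
#' `"uniform"` mode (DeepWalk) the next node is uniform over the current
#' node's neighbours. In `"biased"` mode (node2vec) the walk is second-order:
#' from the pair (previous, current) the candidate next node `x` gets
#' unnormalized weight `1/p` if `x` is the previous node, `1` if `x` is a
#' neighbour of the previous node, and `1/q` otherwise. Walks starting at
#' isolated nodes have length 1.
#'
#' @param g the induction `temporal_graph`.
#' @param cfg a [walk_config()].
#' @param mode `"uniform"` or `"biased"`.
#' @return an object of class `walk_corpus`: list with `walks` (list of
#'   integer vectors, 1-based into `nodes`) and `nodes` (the vocabulary).
#' @export
generate_walks <- function(g, cfg = walk_config(),
                           mode = c("uniform", "biased")) {
  mode <- match.arg(mode)
  if (length(g$nodes) == 0L) stop("graph is empty")
  adj <- adjacency_list(g)
  adj_idx <- lapply(adj, function(nb) match(nb, g$nodes))
  walks <- gen_walks_cpp(adj_idx, cfg$walk_length, cfg$walks_per_vertex,
                         mode == "biased", cfg$p, cfg$q, cfg$seed)
  structure(list(walks = walks, nodes = g$nodes, mode = mode),
            class = "walk_corpus")
}

#' Write a walk corpus as text
#'
#' One space-delimited walk (sequence of node ids) per line.
#'
#' @param corpus a `walk_corpus`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_walks <- function(corpus, path) {
  lines <- vapply(corpus$walks,
                  function(w) paste(corpus$nodes[w], collapse = " "), "")
  writeLines(lines, path)
  invisible(path)
}

#' Node embedding table
#'
#' A matrix of node vectors (rows named by node id) plus a per-node
#' provenance flag: `"trained"` for vectors learned from the walk corpus,
#' `"random-init"` for fallback vectors assigned to nodes absent from the
#' induction corpus (e.g. nodes first appearing in the test slice).
#'
#' @param vectors numeric matrix with rownames = node ids.
#' @param origin character vector (`"trained"`/`"random-init"`), one per row.
#' @return an object of class `embedding_table`.
#' @export
embedding_table <- function(vectors, origin = rep("trained", nrow(vectors))) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)),
            length(origin) == nrow(vectors))
  structure(list(vectors = vectors,
                 origin = stats::setNames(origin, rownames(vectors))),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d nodes x %d dims (%d trained, %d random-init)\n",
              nrow(x$vectors), ncol(x$vectors),
              sum(x$origin == "trained"), sum(x$origin == "random-init")))
  invisible(x)
}

#' Train node embeddings from a walk corpus
#'
#' Runs the package's seeded skip-gram-with-negative-sampling trainer
#' (word2vec-style, single-threaded and deterministic per seed) over the
#' walk corpus, treating walks as sentences. Every node occurring in the
#' corpus receives a vector of `cfg$dimensions` reals; nodes co-occurring
#' within the window end up closer in cosine similarity than random pairs.
#'
#' @param corpus a `walk_corpus` from [generate_walks()].
#' @param cfg a [walk_config()].
#' @return an [embedding_table()] covering every node in the corpus.
#' @export
train_embeddings <- function(corpus, cfg = walk_config()) {
  if (length(corpus$walks) == 0L) stop("empty walk corpus")
  # length-1 walks (isolated nodes) carry no co-occurrence and train nothing;
  # such nodes are left to the random-init path of complete_table()
  walks <- corpus$walks[lengths(corpus$walks) >= 2L]
  if (length(walks) == 0L) stop("empty walk corpus (no co-occurrences)")
  occ <- sort(unique(unlist(walks, use.names = FALSE)))
  remap <- match(seq_along(corpus$nodes), occ)
  walks <- lapply(walks, function(w) remap[w])
  mat <- sgns_train_cpp(walks, length(occ), cfg$dimensions, cfg$window,
                        cfg$epochs, cfg$negative, cfg$alpha, cfg$seed)
  rownames(mat) <- corpus$nodes[occ]
  embedding_table(mat)
}

#' Concatenate-and-normalize post-processing for proximity embeddings
#'
#' Combines a first-order and a second-order proximity embedding table
#' (each of dimension d/2) into one table of dimension d by per-node
#' concatenation followed by L2 normalization, the standard post-processing
#' for LINE-style embeddings. All-zero concatenations pass through
#' unnormalized.
#'
#' @param first,second `embedding_table`s over the same node set, equal
#'   dimensions.
#' @return an [embedding_table()] with unit-norm (or zero) rows.
#' @export
line_postprocess <- function(first, second) {
  if (!setequal(rownames(first$vectors), rownames(second$vectors))) {
    stop("first- and second-order tables cover different nodes")
  }
  if (ncol(first$vectors) != ncol(second$vectors)) {
    stop("first- and second-order tables have different dimensions")
  }
  nodes <- rownames(first$vectors)
  cat_mat <- cbind(first$vectors[nodes, , drop = FALSE],
                   second$vectors[nodes, , drop = FALSE])
  nrm <- sqrt(rowSums(cat_mat^2))
  scale <- ifelse(nrm > 0, 1 / nrm, 1)
  embedding_table(cat_mat * scale, origin = unname(first$origin[nodes]))
}

#' Fill in random-init vectors for uncovered nodes
#'
#' Nodes in `all_nodes` missing from the table (typically nodes whose first
#' link falls after the induction slice) receive seeded random vectors with
#' components i.i.d. uniform in `[-0.5/dim, 0.5/dim]` — the standard
#' word-embedding initialization — flagged `"random-init"`. Trained vectors
#' are untouched.
#'
#' @param t an `embedding_table`.
#' @param all_nodes character vector of nodes that must be covered.
#' @param seed integer seed.
#' @return an [embedding_table()] covering `all_nodes`.
#' @export
complete_table <- function(t, all_nodes, seed = 1L) {
  missing <- setdiff(all_nodes, rownames(t$vectors))
  if (length(missing) == 0L) return(t)
  dim <- ncol(t$vectors)
  withr::local_seed(seed)
  fill <- matrix(stats::runif(length(missing) * dim, -0.5 / dim, 0.5 / dim),
                 nrow = length(missing), dimnames = list(missing, NULL))
  embedding_table(rbind(t$vectors, fill),
                  origin = c(unname(t$origin),
                             rep("random-init", length(missing))))
}

#' Read/write embeddings in word2vec text format
#'
#' Header line `<count> <dim>`, then one `<node-id> <v1> ... <vdim>` line
#' per node. The provenance flag is not part of the format; read tables are
#' flagged `"trained"`.
#'
#' @param t an `embedding_table`.
#' @param path file path.
#' @return `write_embeddings`: `path` invisibly; `read_embeddings`: an
#'   [embedding_table()].
#' @export
write_embeddings <- function(t, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(t$vectors), ncol(t$vectors)), con)
  body <- apply(t$vectors, 1L, function(v)
    paste(format(v, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = " "))
  writeLines(paste(rownames(t$vectors), body), con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1L], "\\s+")[[1L]])
  fields <- strsplit(lines[-1L], "\\s+")
  if (length(fields) != hdr[1L]) stop("embedding count does not match header")
  ids <- vapply(fields, `[[`, "", 1L)
  mat <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(hdr[2L])))
  rownames(mat) <- ids
  embedding_table(mat)
}
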