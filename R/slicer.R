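#' Link split container
#'
#' Holds the link sets of one evaluation scenario: the induction links (used
#' to build node representations), the predictor's training positives (by
#' design a subset of the induction links — the representation learner sees
#' everything the predictor trains on), the held-out test positives, and
#' 1:1 negative pair samples for train and test. All pair data.frames have
#' columns `u`, `v` in canonical order.
#'
#' @param induction,train_pos,test_pos,train_neg,test_neg pair data.frames.
#' @param seed the integer seed the split was drawn with.
#' @param meta list of slicing parameters, echoed for the run manifest.
#' @return an object of class `link_split`.
#' @export
link_split <- function(induction, train_pos, test_pos, train_neg, test_neg,
                       seed, meta = list()) {
  structure(list(induction = induction, train_pos = train_pos,
                 test_pos = test_pos, train_neg = train_neg,
                 test_neg = test_neg, seed = seed, meta = meta),
            class = "link_split")
}

#' @export
print.link_split <- function(x, ...) {
  cat(sprintf(paste0("link_split: induction %d | train +%d/-%d | ",
                     "test +%d/-%d (seed %d)\n"),
              nrow(x$induction), nrow(x$train_pos), nrow(x$train_neg),
              nrow(x$test_pos), nrow(x$test_neg), x$seed))
  invisible(x)
}

#' Check the structural invariants of a link split
#'
#' Asserts, against the full graph: train positives are a subset of the
#' induction links; test positives are disjoint from induction; the negative
#' sets are mutually disjoint and disjoint from every positive link of the
#' full graph; negative counts match positive counts 1:1; no negative is a
#' self-pair; under a bipartite graph every negative crosses the partition.
#'
#' @param split a `link_split`.
#' @param g the full `temporal_graph` the split was drawn from.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_split <- function(split, g) {
  k <- function(df) pair_key(df$u, df$v)
  ind <- k(split$induction); trp <- k(split$train_pos)
  tep <- k(split$test_pos); trn <- k(split$train_neg); ten <- k(split$test_neg)
  all_pos <- link_keys(g)
  if (!all(trp %in% ind)) stop("train positives not a subset of induction")
  if (length(intersect(tep, ind)) > 0L) stop("test positives overlap induction")
  if (length(intersect(trn, ten)) > 0L) stop("train/test negatives overlap")
  if (length(intersect(c(trn, ten), all_pos)) > 0L) {
    stop("negative pair coincides with a positive link")
  }
  if (length(trn) != length(trp)) stop("train negatives not 1:1 with positives")
  if (length(ten) != length(tep)) stop("test negatives not 1:1 with positives")
  negs <- rbind(split$train_neg, split$test_neg)
  if (any(negs$u == negs$v)) stop("self-pair among negatives")
  if (!is.null(g$partition) && nrow(negs) > 0L) {
    if (any(g$partition[negs$u] == g$partition[negs$v])) {
      stop("negative pair does not cross the bipartite partition")
    }
  }
  invisible(TRUE)
}

#' Random link slicing with connectivity maintenance
#'
#' Splits the links of `g` at random into induction (default 60%) and test
#' (default 40%) sets such that removing the test links does not disconnect
#' any connected component of `g`: a link is only eligible for removal if its
#' endpoints remain mutually reachable without it. The predictor's training
#' positives (default 10% of all links) are drawn uniformly from the
#' induction links. Negatives are sampled 1:1 via [sample_negatives()].
#'
#' @param g a `temporal_graph`.
#' @param frac_induction fraction of links kept for induction (default 0.6).
#' @param frac_train fraction of all links used as training positives
#'   (default 0.1); must be below `frac_induction`.
#' @param seed integer seed.
#' @return a [link_split()].
#' @export
random_slice <- function(g, frac_induction = 0.6, frac_train = 0.1, seed = 1L) {
  stopifnot(frac_train > 0, frac_train < frac_induction, frac_induction < 1)
  m <- n_links(g)
  if (m < 3L) stop("graph has too few links to slice")
  n_test <- round((1 - frac_induction) * m)
  withr::local_seed(seed)
  idx <- match(c(g$links$u, g$links$v), g$nodes)
  edges <- matrix(idx, ncol = 2L)
  ord <- sample.int(m)
  removed <- select_removable_edges(edges, length(g$nodes), ord, n_test)
  if (length(removed) < n_test) {
    stop(sprintf(paste0("cannot remove %d links while preserving ",
                        "connectivity; at most %d removable ",
                        "(max test fraction %.3f)"),
                 n_test, length(removed), length(removed) / m))
  }
  is_test <- seq_len(m) %in% removed
  induction <- g$links[!is_test, , drop = FALSE]
  test_pos <- g$links[is_test, , drop = FALSE]
  n_train <- round(frac_train * m)
  train_pos <- induction[sample.int(nrow(induction), n_train), , drop = FALSE]
  neg <- sample_negatives(g, n_train = nrow(train_pos),
                          n_test = nrow(test_pos),
                          seed = sample.int(.Machine$integer.max, 1L))
  link_split(induction, train_pos, test_pos, neg$train_neg, neg$test_neg,
             seed = seed,
             meta = list(mode = "random", frac_induction = frac_induction,
                         frac_train = frac_train))
}

#' Chronological link slicing
#'
#' Splits the links of `g` by the year each link formed: induction links are
#' those with `year <= induction_end`; training positives are the induction
#' links with `year >= train_start` (the train window sits inside the
#' induction window); test positives have
#' `induction_end < year <= test_end`. Connectivity of the induction graph is
#' not (and cannot be) enforced — slice membership is dictated by history.
#' Negatives are sampled 1:1 via [sample_negatives()].
#'
#' @param g a `temporal_graph` with year data.
#' @param induction_end last year (inclusive) of the induction slice.
#' @param train_start first year (inclusive) of the training window.
#' @param test_end last year (inclusive) of the test slice.
#' @param seed integer seed for negative sampling.
#' @return a [link_split()].
#' @export
time_slice <- function(g, induction_end, train_start, test_end, seed = 1L) {
  if (is.null(g$year)) stop("graph has no year data")
  stopifnot(train_start <= induction_end, induction_end < test_end)
  ind <- g$year <= induction_end
  trn <- ind & g$year >= train_start
  tst <- g$year > induction_end & g$year <= test_end
  if (!any(ind)) stop("empty induction slice (no links up to ", induction_end, ")")
  if (!any(trn)) stop(sprintf("empty train slice (%d-%d)", train_start,
                              induction_end))
  if (!any(tst)) stop(sprintf("empty test slice (%d-%d)", induction_end + 1L,
                              test_end))
  withr::local_seed(seed)
  neg <- sample_negatives(g, n_train = sum(trn), n_test = sum(tst),
                          seed = sample.int(.Machine$integer.max, 1L))
  link_split(g$links[ind, , drop = FALSE], g$links[trn, , drop = FALSE],
             g$links[tst, , drop = FALSE], neg$train_neg, neg$test_neg,
             seed = seed,
             meta = list(mode = "time", induction_end = induction_end,
                         train_start = train_start, test_end = test_end))
}

#' Sample negative node pairs
#'
#' Draws uniformly random unlinked node pairs to serve as negative examples,
#' excluding every positive link of the full graph (all slices — within one
#' experiment a positive must never double as a negative), with no
#' duplicates, no self-pairs, and train/test sets disjoint. For bipartite
#' graphs only cross-partition pairs are eligible.
#'
#' @param g the full `temporal_graph`.
#' @param n_train,n_test number of training / test negatives to draw.
#' @param seed integer seed.
#' @return list with pair data.frames `train_neg` and `test_neg`.
#' @export
sample_negatives <- function(g, n_train, n_test, seed = 1L) {
  withr::local_seed(seed)
  n_need <- n_train + n_test
  nodes <- g$nodes
  bip <- !is.null(g$partition)
  if (bip) {
    a_nodes <- nodes[g$partition == "A"]
    b_nodes <- nodes[g$partition == "B"]
    total <- as.double(length(a_nodes)) * length(b_nodes)
  } else {
    total <- choose(length(nodes), 2)
  }
  avail <- total - n_links(g)
  if (avail < n_need) {
    stop(sprintf("need %d negative pairs but only %.0f unlinked pairs exist",
                 n_need, avail))
  }
  pos <- link_keys(g)
  draw_batch <- function(n) {
    if (bip) {
      u <- a_nodes[sample.int(length(a_nodes), n, replace = TRUE)]
      v <- b_nodes[sample.int(length(b_nodes), n, replace = TRUE)]
    } else {
      u <- nodes[sample.int(length(nodes), n, replace = TRUE)]
      v <- nodes[sample.int(length(nodes), n, replace = TRUE)]
    }
    cp <- canonical_pairs(u, v)
    keep <- cp$u != cp$v
    pair_key(cp$u[keep], cp$v[keep])
  }
  if (avail <= 2e5 || n_need > avail / 4) {
    # dense regime: enumerate every unlinked pair and sample exactly
    if (bip) {
      grid <- expand.grid(u = a_nodes, v = b_nodes, stringsAsFactors = FALSE)
      cp <- canonical_pairs(grid$u, grid$v)
    } else {
      comb <- utils::combn(nodes, 2L)
      cp <- list(u = comb[1L, ], v = comb[2L, ])
    }
    keys <- pair_key(cp$u, cp$v)
    keys <- keys[!keys %in% pos]
    chosen <- sample(keys, n_need)
  } else {
    # sparse regime: rejection sampling
    chosen <- character(0)
    tries <- 0L
    while (length(chosen) < n_need) {
      tries <- tries + 1L
      if (tries > 200L) stop("negative sampling failed to converge")
      batch <- draw_batch(2L * (n_need - length(chosen)) + 16L)
      batch <- batch[!batch %in% pos]
      chosen <- unique(c(chosen, batch))
    }
    chosen <- chosen[seq_len(n_need)]
  }
  parts <- strsplit(chosen, "\r", fixed = TRUE)
  df <- data.frame(u = vapply(parts, `[[`, "", 1L),
                   v = vapply(parts, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  list(train_neg = df[seq_len(n_train), , drop = FALSE],
       test_neg = df[n_train + seq_len(n_test), , drop = FALSE])
}

#' Write a split to disk
#'
#' Writes five edge-list files (`induction`, `train_pos`, `train_neg`,
#' `test_pos`, `test_neg`) plus a JSON sidecar with the slicing parameters
#' and seed.
#'
#' @param split a `link_split`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("induction", "train_pos", "train_neg", "test_pos",
                 "test_neg")) {
    df <- split[[part]]
    writeLines(paste(df$u, df$v), file.path(dir, paste0(part, ".tsv")))
  }
  jsonlite::write_json(c(split$meta, list(seed = split$seed)),
                       file.path(dir, "split.json"), auto_unbox = TRUE)
  invisible(dir)
}
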