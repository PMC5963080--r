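test_that("walk corpus has exactly walks_per_vertex walks per node", {
  withr::with_seed(2, g <- random_graph(15, 0.3))
  cfg <- walk_config(walk_length = 12, walks_per_vertex = 7, seed = 3)
  corp <- generate_walks(g, cfg, "uniform")
  expect_length(corp$walks, 15 * 7)
  starts <- vapply(corp$walks, `[[`, integer(1), 1L)
  expect_true(all(table(starts) == 7))
  expect_true(all(lengths(corp$walks) == 12 |
                    lengths(corp$walks) == 1))
})

test_that("isolated nodes emit length-1 walks", {
  g <- temporal_graph(nodes = "lonely")
  corp <- generate_walks(g, walk_config(walks_per_vertex = 10, seed = 1))
  expect_length(corp$walks, 10L)
  expect_true(all(lengths(corp$walks) == 1L))
})

test_that("uniform walks pick neighbours uniformly", {
  g <- path_graph(c("a", "b", "c"))
  cfg <- walk_config(walk_length = 2, walks_per_vertex = 10000, seed = 42)
  corp <- generate_walks(g, cfg, "uniform")
  b_idx <- match("b", corp$nodes)
  from_b <- Filter(function(w) w[1] == b_idx, corp$walks)
  steps <- vapply(from_b, `[[`, integer(1), 2L)
  freq_a <- mean(corp$nodes[steps] == "a")
  expect_equal(freq_a, 0.5, tolerance = 0.1)  # 0.5 +/- 0.05 absolute
  expect_true(abs(freq_a - 0.5) < 0.05)
})

test_that("biased walks honour the 1/p, 1, 1/q transition weights", {
  # triangle with p = 2, q = 4: from (prev, cur) the return weight is 1/2 and
  # the advance candidate is a neighbour of prev (weight 1): P(return) = 1/3
  g <- cycle_graph(3)
  cfg <- walk_config(walk_length = 3, walks_per_vertex = 4000, p = 2, q = 4,
                     seed = 7)
  corp <- generate_walks(g, cfg, "biased")
  ret <- vapply(corp$walks, function(w) w[3] == w[1], logical(1))
  expect_equal(mean(ret), 1 / 3, tolerance = 0.09)  # 1/3 +/- 0.03 absolute
  expect_true(abs(mean(ret) - 1 / 3) < 0.03)
})

test_that("the in-out parameter q governs leaving the neighbourhood", {
  # path a-b-c: from (a, b) the only candidates are a (1/p) and c (1/q);
  # with p = 1, q = 9 the walk should return ~90% of the time
  g <- path_graph(c("a", "b", "c"))
  cfg <- walk_config(walk_length = 3, walks_per_vertex = 6000, p = 1, q = 9,
                     seed = 11)
  corp <- generate_walks(g, cfg, "biased")
  a_idx <- match("a", corp$nodes)
  from_a <- Filter(function(w) w[1] == a_idx, corp$walks)
  ret <- vapply(from_a, function(w) w[3] == w[1], logical(1))
  expect_equal(mean(ret), 0.9, tolerance = 0.05)
})

test_that("walks are reproducible per seed", {
  withr::with_seed(4, g <- random_graph(20, 0.25))
  cfg <- walk_config(seed = 5)
  expect_identical(generate_walks(g, cfg, "biased")$walks,
                   generate_walks(g, cfg, "biased")$walks)
  cfg2 <- walk_config(seed = 6)
  expect_false(identical(generate_walks(g, cfg, "uniform")$walks,
                         generate_walks(g, cfg2, "uniform")$walks))
})

test_that("trained embeddings separate two disconnected cliques", {
  ids <- c(sprintf("p%02d", 1:20), sprintf("q%02d", 1:20))
  clique_edges <- function(members) {
    comb <- utils::combn(members, 2)
    data.frame(u = comb[1, ], v = comb[2, ])
  }
  g <- temporal_graph(ids, rbind(clique_edges(ids[1:20]),
                                 clique_edges(ids[21:40])))
  cfg <- walk_config(walk_length = 20, walks_per_vertex = 5, window = 5,
                     dimensions = 32, epochs = 3, seed = 9)
  emb <- train_embeddings(generate_walks(g, cfg, "uniform"), cfg)
  expect_equal(dim(emb$vectors), c(40L, 32L))
  V <- emb$vectors / sqrt(rowSums(emb$vectors^2))
  S <- V %*% t(V)
  intra <- c(S[1:20, 1:20][upper.tri(S[1:20, 1:20])],
             S[21:40, 21:40][upper.tri(S[21:40, 21:40])])
  inter <- S[1:20, 21:40]
  expect_gt(mean(intra), mean(inter))
})

test_that("default embedding dimension is 100 and training is deterministic", {
  withr::with_seed(10, g <- random_graph(12, 0.4))
  cfg <- walk_config(walk_length = 10, walks_per_vertex = 2, epochs = 1,
                     seed = 20)
  corp <- generate_walks(g, cfg, "uniform")
  emb <- train_embeddings(corp, cfg)
  expect_equal(ncol(emb$vectors), 100L)
  expect_identical(emb$vectors, train_embeddings(corp, cfg)$vectors)
  expect_error(train_embeddings(structure(list(walks = list(),
                                               nodes = character()),
                                          class = "walk_corpus"), cfg),
               "empty")
})

test_that("concatenate-and-normalize post-processing", {
  t1 <- embedding_table(matrix(c(3, 0,
                                 1, 0,
                                 0, 0), 3, 2, byrow = TRUE,
                               dimnames = list(c("a", "b", "c"), NULL)))
  t2 <- embedding_table(matrix(c(0, 4,
                                 0, 0,
                                 0, 0), 3, 2, byrow = TRUE,
                               dimnames = list(c("a", "b", "c"), NULL)))
  out <- line_postprocess(t1, t2)
  expect_equal(unname(out$vectors["a", ]), c(0.6, 0, 0, 0.8))
  expect_equal(unname(out$vectors["b", ]), c(1, 0, 0, 0))   # unit after norm
  expect_equal(unname(out$vectors["c", ]), c(0, 0, 0, 0))   # zero passes through
  nrm <- sqrt(rowSums(out$vectors^2))
  expect_true(all(abs(nrm[c("a", "b")] - 1) < 1e-12))
  t3 <- embedding_table(matrix(0, 1, 2, dimnames = list("a", NULL)))
  expect_error(line_postprocess(t1, t3), "different nodes")
})

test_that("completion assigns seeded random-init vectors to missing nodes", {
  t1 <- embedding_table(matrix(rnorm(10), 5, 2,
                               dimnames = list(letters[1:5], NULL)))
  same <- complete_table(t1, letters[1:5], seed = 1)
  expect_identical(same$vectors, t1$vectors)

  full <- complete_table(t1, letters[1:10], seed = 2)
  expect_equal(sum(full$origin == "random-init"), 5L)
  expect_true(all(full$origin[letters[1:5]] == "trained"))
  expect_identical(full$vectors, complete_table(t1, letters[1:10], 2)$vectors)
  # uniform in [-0.5/dim, 0.5/dim]
  newv <- full$vectors[letters[6:10], ]
  expect_true(all(abs(newv) <= 0.5 / 2))
})

test_that("word2vec text format round-trips", {
  withr::with_seed(12, {
    m <- matrix(rnorm(12), 4, 3, dimnames = list(c("n1", "n2", "n3", "n4"),
                                                 NULL))
  })
  t1 <- embedding_table(m)
  f <- withr::local_tempfile()
  write_embeddings(t1, f)
  expect_equal(readLines(f)[1], "4 3")
  t2 <- read_embeddings(f)
  expect_equal(t2$vectors, m, tolerance = 1e-12)
})
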