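test_that("common neighbours on toy graphs", {
  g <- path_graph(c("a", "b", "c"))
  expect_equal(common_neighbours(g, "a", "c"), 1L)
  expect_equal(common_neighbours(g, "a", "b"), 0L)

  g2 <- temporal_graph(
    c("u", "v", "x", "y", "z", "w"),
    data.frame(u = c("u", "u", "u", "v", "v", "v"),
               v = c("x", "y", "z", "y", "z", "w")))
  expect_equal(common_neighbours(g2, "u", "v"), 2L)
})

test_that("bipartite common neighbours uses the two-hop set of the second argument", {
  # drugs {d1,d2}, targets {t1,t2}; links d1-t1, d2-t1, d2-t2
  g <- temporal_graph(c("d1", "d2", "t1", "t2"),
                      data.frame(u = c("d1", "d2", "d2"),
                                 v = c("t1", "t1", "t2")))
  g <- attach_partition(g, c(d1 = "A", d2 = "A", t1 = "B", t2 = "B"))
  # N(d1) = {t1}; Nhat(t2) = N(d2) = {t1, t2}  ->  intersection {t1}
  expect_equal(common_neighbours(g, "d1", "t2"), 1L)
  # argument order must not matter: A-side is canonicalized first
  expect_equal(common_neighbours(g, "t2", "d1"), 1L)
})

test_that("adamic-adar handles the degenerate counts and decreases in CN", {
  expect_equal(linksliced:::aa_from_cn(0), 0)
  expect_equal(linksliced:::aa_from_cn(1), 2 / log(2))
  expect_equal(linksliced:::aa_from_cn(3), 1 / log(3), tolerance = 1e-12)
  expect_equal(1 / log(3), 0.9102392, tolerance = 1e-6)
  scores <- linksliced:::aa_from_cn(c(1, 2, 5, 50))
  expect_true(all(diff(scores) < 0))
})

test_that("jaccard index on toy neighbourhoods", {
  g2 <- temporal_graph(
    c("u", "v", "x", "y", "z", "w"),
    data.frame(u = c("u", "u", "u", "v", "v", "v"),
               v = c("x", "y", "z", "y", "z", "w")))
  expect_equal(jaccard(g2, "u", "v"), 2 / 4)

  # identical neighbourhoods -> 1; disjoint -> 0
  sq <- cycle_graph(4)
  expect_equal(jaccard(sq, "c01", "c03"), 1)
  g3 <- temporal_graph(c("a", "b", "x", "y"),
                       data.frame(u = c("a", "b"), v = c("x", "y")))
  expect_equal(jaccard(g3, "a", "b"), 0)
  # isolated pair: empty union -> 0 by convention
  g4 <- temporal_graph(c("a", "b", "c", "d"),
                       data.frame(u = "c", v = "d"))
  expect_equal(jaccard(g4, "a", "b"), 0)
})

test_that("heuristics match the set-algebra oracle on random graphs", {
  withr::with_seed(1234, {
    for (rep in 1:10) {
      g <- random_graph(sample(4:12, 1), runif(1, 0.2, 0.5))
      pairs <- utils::combn(g$nodes, 2)
      for (j in seq_len(ncol(pairs))) {
        u <- pairs[1, j]; v <- pairs[2, j]
        expect_equal(common_neighbours(g, u, v),
                     oracle_heuristic(g$links, u, v, "cn"))
        expect_equal(adamic_adar(g, u, v),
                     oracle_heuristic(g$links, u, v, "aa"))
        expect_equal(jaccard(g, u, v),
                     oracle_heuristic(g$links, u, v, "ji"))
      }
    }
  })
})

test_that("non-bipartite heuristics are symmetric; bipartite hat is on v", {
  withr::with_seed(99, g <- random_graph(10, 0.4))
  pairs <- utils::combn(g$nodes, 2)
  for (j in seq_len(ncol(pairs))) {
    u <- pairs[1, j]; v <- pairs[2, j]
    expect_equal(common_neighbours(g, u, v), common_neighbours(g, v, u))
    expect_equal(jaccard(g, u, v), jaccard(g, v, u))
  }
  # without partition canonicalization the hat side matters
  withr::with_seed(100, gb <- random_bipartite(5, 5, 0.4))
  raw <- temporal_graph(gb$nodes, gb$links)  # partition dropped
  vals_uv <- sapply(seq_len(nrow(gb$links)), function(i)
    common_neighbours(raw, gb$links$u[i], gb$links$v[i], bipartite = TRUE))
  vals_vu <- sapply(seq_len(nrow(gb$links)), function(i)
    common_neighbours(raw, gb$links$v[i], gb$links$u[i], bipartite = TRUE))
  expect_false(isTRUE(all.equal(vals_uv, vals_vu)))
})

test_that("the hat-set self-exclusion switch changes only v's membership", {
  g <- temporal_graph(c("d1", "d2", "t1", "t2"),
                      data.frame(u = c("d1", "d2", "d2"),
                                 v = c("t1", "t1", "t2")))
  g <- attach_partition(g, c(d1 = "A", d2 = "A", t1 = "B", t2 = "B"))
  # Nhat(t1) = {t1, t2}; with exclusion {t2}; N(d1) = {t1}
  expect_equal(common_neighbours(g, "d1", "t1"), 1L)
  expect_equal(common_neighbours(g, "d1", "t1", hat_excludes_self = TRUE), 0L)
})

test_that("batch scoring equals singly-scored pairs and breaks ties lexicographically", {
  withr::with_seed(7, g <- random_graph(30, 0.2))
  withr::with_seed(8, {
    comb <- utils::combn(g$nodes, 2)
    sel <- comb[, sample(ncol(comb), 20)]
  })
  pairs <- data.frame(u = sel[1, ], v = sel[2, ])
  for (m in c("cn", "aa", "ji")) {
    rk <- score_all(g, pairs, m)
    single <- mapply(function(u, v) switch(m,
                                           cn = common_neighbours(g, u, v),
                                           aa = adamic_adar(g, u, v),
                                           ji = jaccard(g, u, v)),
                     pairs$u, pairs$v)
    expect_setequal(rk$score, single)
    expect_true(all(diff(rk$score) <= 0))
    # within tied scores, pairs are in lexicographic order
    for (s in unique(rk$score)) {
      sub <- rk[rk$score == s, ]
      expect_false(is.unsorted(paste(sub$u, sub$v)))
    }
  }
  expect_equal(nrow(score_all(g, pairs[0, ], "cn")), 0L)
})

test_that("rankings are written as TSV with labels", {
  r <- scored_ranking(c("a", "c"), c("b", "d"), c(0.2, 0.9), c(TRUE, FALSE))
  expect_equal(r$u[1], "c")  # higher score first
  f <- withr::local_tempfile()
  write_ranking(r, f)
  back <- read.delim(f, colClasses = c("character", "character",
                                       "numeric", "integer"))
  expect_equal(back$score, c(0.9, 0.2))
  expect_equal(back$label, c(0L, 1L))
})
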