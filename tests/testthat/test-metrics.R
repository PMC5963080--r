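# small builder: a ranking whose order is forced by strictly decreasing scores
ranked <- function(labels, u = NULL, v = NULL) {
  n <- length(labels)
  if (is.null(u)) {
    u <- sprintf("L%02d", 1:n)
    v <- sprintf("R%02d", 1:n)
  }
  scored_ranking(u, v, seq(n, 1), labels)
}

test_that("auroc matches hand-enumerated pair counting", {
  # ranking [+,-,+,-]: 4 pos-neg pairs, 3 concordant -> 0.75
  expect_equal(auroc(ranked(c(TRUE, FALSE, TRUE, FALSE))), 0.75)
  expect_equal(auroc(ranked(c(TRUE, TRUE, FALSE, FALSE))), 1.0)
  expect_equal(auroc(ranked(c(FALSE, FALSE, TRUE))), 0.0)
  expect_error(auroc(ranked(c(TRUE, TRUE))), "positive and one negative")
})

test_that("auroc gives ties half credit and ignores monotone transforms", {
  r <- scored_ranking(c("a", "b", "c", "d"), c("w", "x", "y", "z"),
                      c(1, 1, 1, 0), c(TRUE, FALSE, TRUE, FALSE))
  # two positives tie two of three... enumerate: pairs (p1,n1)=0.5,(p1,n2)=1,
  # (p2,n1)=0.5,(p2,n2)=1 -> 0.75
  expect_equal(auroc(r), 0.75)
  r2 <- scored_ranking(c("a", "b", "c", "d"), c("w", "x", "y", "z"),
                       exp(c(1, 1, 1, 0)), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(auroc(r2), auroc(r))
})

test_that("aupr follows the step-curve summation", {
  expect_equal(aupr(ranked(c(TRUE, FALSE, TRUE))), (1 + 2 / 3) / 2)
  expect_equal(aupr(ranked(c(TRUE, TRUE, FALSE))), 1.0)
  # two positives ranked last in a list of 10: (1/9 + 2/10) / 2
  lab <- c(rep(FALSE, 8), TRUE, TRUE)
  expect_equal(aupr(ranked(lab)), (1 / 9 + 2 / 10) / 2)
  expect_equal(oracle_aupr(lab), (1 / 9 + 2 / 10) / 2)
  expect_error(aupr(ranked(c(FALSE, FALSE))), "positive")
})

test_that("precision at k derives k from the positive count", {
  lab <- c(rep(TRUE, 3), rep(FALSE, 4), rep(TRUE, 7))  # 10 positives
  # k = ceil(0.3 * 10) = 3; top-3 all positive
  expect_equal(precision_at_k(ranked(lab), 0.3), 1.0)
  inv <- c(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(precision_at_k(ranked(inv), 0.3), 0.0)
  expect_equal(precision_at_k(ranked(c(TRUE, FALSE, TRUE, FALSE)), 1.0), 0.5)
})

test_that("per-node sublists preserve global order and cover each pair twice", {
  r <- scored_ranking(c("a", "a", "b"), c("b", "c", "c"),
                      c(3, 2, 1), c(TRUE, FALSE, TRUE))
  lists <- per_node_lists(r)
  expect_setequal(names(lists), c("a", "b", "c"))
  expect_equal(nrow(lists$a), 2L)
  expect_equal(nrow(lists$b), 2L)
  expect_equal(nrow(lists$c), 2L)
  expect_equal(sum(vapply(lists, nrow, integer(1))), 2L * nrow(r))
  # global order preserved within each sublist
  expect_true(all(diff(lists$c$score) <= 0))
  expect_length(per_node_lists(r[0, ]), 0L)
})

test_that("MAP averages per-node average precision over qualifying nodes", {
  # single node x with list [+,-,+] against distinct partners
  r <- scored_ranking(c("x", "x", "x"), c("p1", "p2", "p3"),
                      c(3, 2, 1), c(TRUE, FALSE, TRUE))
  # x: AP = (1 + 2/3)/2; p1: [+] -> 1; p3: [+] -> 1; p2 excluded
  expect_equal(mean_average_precision(r), ((1 + 2 / 3) / 2 + 1 + 1) / 3)
  # node-equality: unweighted mean of per-node APs regardless of list length
  r2 <- ranked(c(TRUE, TRUE, FALSE, FALSE))  # disjoint pairs
  expect_equal(mean_average_precision(r2), 1.0)
  expect_error(mean_average_precision(ranked(c(FALSE, FALSE))), "no node")
})

test_that("averaged R-precision counts positives within each node's top R", {
  # node x: positives at sublist ranks 1 and 3, R = 2 -> 0.5
  r <- scored_ranking(c("x", "x", "x"), c("p1", "p2", "p3"),
                      c(3, 2, 1), c(TRUE, FALSE, TRUE))
  # x: 0.5; p1: 1; p3: 1
  expect_equal(averaged_r_precision(r), (0.5 + 1 + 1) / 3)
  # positives at ranks 3,4 of a 4-list -> node scores 0
  r2 <- scored_ranking(c("x", "x", "x", "x"), c("p1", "p2", "p3", "p4"),
                       c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE))
  lists <- per_node_lists(r2)
  expect_equal(sum(lists$x$label[1:2]) / 2, 0)
})

test_that("all five metrics agree with the oracles on random rankings", {
  withr::with_seed(2024, {
    pool <- sprintf("n%02d", 1:6)
    for (rep in 1:25) {
      n <- sample(3:10, 1)
      repeat {
        comb <- utils::combn(pool, 2)
        sel <- comb[, sample(ncol(comb), n), drop = FALSE]
        break
      }
      label <- runif(n) < 0.5
      if (!any(label) || all(label)) next
      score <- sample(seq(n, 1))  # distinct scores, random placement
      r <- scored_ranking(sel[1, ], sel[2, ], score, label)
      lab <- r$label
      expect_equal(auroc(r), oracle_auroc(r$score, r$label))
      expect_equal(aupr(r), oracle_aupr(lab))
      expect_equal(precision_at_k(r, 0.3),
                   oracle_precision_at_k(lab, 0.3))
      expect_equal(mean_average_precision(r), oracle_map(r$u, r$v, lab))
      expect_equal(averaged_r_precision(r),
                   oracle_r_precision(r$u, r$v, lab))
    }
  })
})

test_that("MAP weighs nodes equally regardless of their degree", {
  # node a: single pair, AP 1.0; hub h: four pairs with AP 0.5 however many
  # links it has; partners (x, t1..t4) contribute their own single-entry APs
  r <- scored_ranking(c("a", rep("h", 4)),
                      c("x", sprintf("t%d", 1:4)),
                      c(5, 4, 3, 2, 1),
                      c(TRUE, FALSE, TRUE, FALSE, TRUE))
  lists <- per_node_lists(r)
  ap_h <- mean(c(1 / 2, 2 / 4))
  ap_partners <- c(1, 1, 1)  # x, t1 (excluded: negative), t2 [+], t4 [+] ...
  # qualifying nodes: a (1), h (ap_h), x (1), t2 (1), t4 (1)
  expect_equal(mean_average_precision(r), mean(c(1, ap_h, 1, 1, 1)))
  # the hub's many links enter once via ap_h, not once per link
  expect_equal(sum(lists$h$label), 2)
})

test_that("run aggregation computes means, sds and t-test verdicts", {
  runs <- data.frame(
    method = rep(c("m1", "m2"), each = 3),
    metric = "auroc", run = rep(1:3, 2),
    value = c(0.9, 0.9, 0.9, 0.5, 0.5, 0.5))
  agg <- aggregate_runs(runs)
  expect_equal(agg$mean, c(0.9, 0.5))
  expect_true(agg$best[agg$method == "m1"])
  expect_equal(agg$verdict[agg$method == "m2"], "different")  # 0-variance path

  same <- data.frame(method = rep(c("m1", "m2"), each = 2),
                     metric = "map", run = rep(1:2, 2),
                     value = rep(0.7, 4))
  agg2 <- aggregate_runs(same)
  expect_true(all(agg2$verdict == "not-different"))
  expect_equal(agg2$sd, c(0, 0))

  bad <- runs[-1, ]
  expect_error(aggregate_runs(bad), "unequal run counts")
})

test_that("t-test verdicts match the textbook pooled computation", {
  x <- c(0.80, 0.81, 0.79)
  y <- c(0.80, 0.80, 0.81)
  runs <- data.frame(method = rep(c("mx", "my"), each = 3),
                     metric = "aupr", run = rep(1:3, 2),
                     value = c(x, y))
  agg <- aggregate_runs(runs)
  # independent computation: pooled two-sample t with 4 df
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_manual <- 2 * pt(-abs(tstat), df = 4)
  row <- agg[!agg$best, ]
  expect_equal(row$p_value, p_manual, tolerance = 1e-12)
  expect_equal(row$verdict, ifelse(p_manual < 0.05, "different",
                                   "not-different"))
})

test_that("summary formatting marks the best and non-different methods", {
  runs <- data.frame(method = rep(c("m1", "m2"), each = 3),
                     metric = "auroc", run = rep(1:3, 2),
                     value = c(0.9, 0.91, 0.89, 0.895, 0.905, 0.9))
  tab <- format_summary(aggregate_runs(runs))
  expect_match(tab["m1", "auroc"], "\\[0\\.9000\\]")
  expect_match(tab["m2", "auroc"], "\\*$")
})
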