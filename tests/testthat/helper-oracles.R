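# Independent brute-force oracles, written directly from the definitions.
# They never share code with the package implementations they check.

# AUROC: enumerate all positive-negative score pairs, half credit for ties
oracle_auroc <- function(score, label) {
  ps <- score[label]
  ns <- score[!label]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# AUPR as step-curve summation: walk the ranked list, add precision at each
# positive, divide by total positives
oracle_aupr <- function(label_ranked) {
  npos <- sum(label_ranked)
  acc <- 0
  hits <- 0
  for (i in seq_along(label_ranked)) {
    if (label_ranked[i]) {
      hits <- hits + 1
      acc <- acc + hits / i
    }
  }
  acc / npos
}

oracle_precision_at_k <- function(label_ranked, k_ratio) {
  k <- ceiling(k_ratio * sum(label_ranked))
  sum(label_ranked[1:min(k, length(label_ranked))]) / min(k, length(label_ranked))
}

# node-equality metrics: scan the global ranked list per node
oracle_map <- function(u, v, label_ranked) {
  nodes <- unique(c(u, v))
  aps <- c()
  for (nd in nodes) {
    rows <- which(u == nd | v == nd)   # already in global rank order
    lab <- label_ranked[rows]
    if (!any(lab)) next
    prec <- c()
    hits <- 0
    for (i in seq_along(lab)) {
      if (lab[i]) {
        hits <- hits + 1
        prec <- c(prec, hits / i)
      }
    }
    aps <- c(aps, mean(prec))
  }
  mean(aps)
}

oracle_r_precision <- function(u, v, label_ranked) {
  nodes <- unique(c(u, v))
  vals <- c()
  for (nd in nodes) {
    rows <- which(u == nd | v == nd)
    lab <- label_ranked[rows]
    R <- sum(lab)
    if (R == 0) next
    vals <- c(vals, sum(lab[1:R]) / R)
  }
  mean(vals)
}

# heuristic oracles from explicit neighbour-set construction
oracle_neighbour_set <- function(edges, x) {
  unique(c(edges$v[edges$u == x], edges$u[edges$v == x]))
}

oracle_heuristic <- function(edges, u, v, method, bipartite = FALSE,
                             hat_excludes_self = FALSE) {
  nu <- oracle_neighbour_set(edges, u)
  nv <- oracle_neighbour_set(edges, v)
  if (bipartite) {
    hat <- unique(unlist(lapply(nv, function(w) oracle_neighbour_set(edges, w))))
    if (hat_excludes_self) hat <- setdiff(hat, v)
    nv <- hat
  }
  cn <- length(intersect(nu, nv))
  if (method == "cn") return(cn)
  if (method == "aa") {
    if (cn == 0) return(0)
    if (cn == 1) return(2 / log(2))
    return(1 / log(cn))
  }
  un <- length(union(nu, nv))
  if (un == 0) return(0)
  cn / un
}
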