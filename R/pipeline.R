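#' Method specifications for an experiment
#'
#' `method_heuristic()` names one of the neighbourhood baselines;
#' `method_embedding()` names a walk-embedding + combiner + neural
#' predictor combination. Pass a list of these to [experiment_config()].
#'
#' @param method heuristic id: `"cn"`, `"aa"` or `"ji"`.
#' @return a method specification list.
#' @export
method_heuristic <- function(method = c("cn", "aa", "ji")) {
  method <- match.arg(method)
  structure(list(type = "heuristic", method = method,
                 name = toupper(method)), class = "lp_method")
}

#' @rdname method_heuristic
#' @param mode walk mode: `"uniform"` (DeepWalk-style) or `"biased"`
#'   (node2vec-style).
#' @param combine node-combination operator (see [combine()]).
#' @param walk a [walk_config()].
#' @param predictor a [predictor_config()].
#' @param name display name; defaults to a descriptive composite.
#' @export
method_embedding <- function(mode = c("uniform", "biased"),
                             combine = "hadamard", walk = walk_config(),
                             predictor = predictor_config(), name = NULL) {
  mode <- match.arg(mode)
  if (is.null(name)) {
    name <- paste0(if (mode == "uniform") "deepwalk" else "node2vec",
                   "-", combine)
  }
  structure(list(type = "embedding", mode = mode, combine = combine,
                 walk = walk, predictor = predictor, name = name),
            class = "lp_method")
}

#' Experiment configuration
#'
#' Everything needed to run a full evaluation: the graph (or a
#' [synth_config()] to generate one), the slicing mode and parameters, the
#' methods to compare, the precision@k ratio, the number of runs and the
#' base seed. Run `r` uses seed `seed + r`, so all randomness — slicing,
#' negative sampling, walks, trainer and predictor initialization — is
#' reproducible, and within a run every method consumes the identical
#' split.
#'
#' @param graph a `temporal_graph`, or a `synth_config` to generate one per
#'   experiment.
#' @param slicing list: `mode = "random"` with optional `frac_induction`,
#'   `frac_train`, or `mode = "time"` with `induction_end`, `train_start`,
#'   `test_end`.
#' @param methods non-empty list of [method_heuristic()] /
#'   [method_embedding()] specs.
#' @param k_ratio precision@k cutoff ratio (default 0.3 of the positives).
#' @param n_runs independent repetitions (default 3).
#' @param seed base integer seed.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(graph, slicing = list(mode = "random"),
                              methods, k_ratio = 0.3, n_runs = 3L,
                              seed = 1L) {
  stopifnot(n_runs >= 1, length(methods) >= 1)
  structure(list(graph = graph, slicing = slicing, methods = methods,
                 k_ratio = k_ratio, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# derive a small positive sub-seed deterministically
sub_seed <- function(seed, salt) {
  (seed * 7919L + salt * 104729L) %% 2147483629L + 1L
}

# score one method on one split; returns a labelled scored_ranking over the
# test pairs and, for embedding methods, the embedding table used
score_method <- function(spec, g, split, run_seed) {
  induction_g <- temporal_graph(nodes = g$nodes, links = split$induction,
                                partition = g$partition)
  eval_pairs <- rbind(split$test_pos, split$test_neg)
  eval_label <- c(rep(TRUE, nrow(split$test_pos)),
                  rep(FALSE, nrow(split$test_neg)))
  if (spec$type == "heuristic") {
    return(score_all(induction_g, eval_pairs, spec$method,
                     label = eval_label))
  }
  wcfg <- spec$walk
  wcfg$seed <- sub_seed(run_seed, 11L)
  corpus <- generate_walks(induction_g, wcfg, spec$mode)
  emb <- train_embeddings(corpus, wcfg)
  emb <- complete_table(emb, g$nodes, seed = sub_seed(run_seed, 13L))
  pcfg <- spec$predictor
  pcfg$seed <- sub_seed(run_seed, 17L)
  Xp <- combine_pairs(emb, split$train_pos, spec$combine, g$partition)
  Xn <- combine_pairs(emb, split$train_neg, spec$combine, g$partition)
  model <- train_predictor(Xp, Xn, pcfg)
  predict_links(model, eval_pairs, emb, spec$combine, label = eval_label,
                partition = g$partition)
}

make_split <- function(g, slicing, run_seed) {
  if (slicing$mode == "random") {
    random_slice(g,
                 frac_induction = slicing$frac_induction %||% 0.6,
                 frac_train = slicing$frac_train %||% 0.1,
                 seed = run_seed)
  } else if (slicing$mode == "time") {
    time_slice(g, slicing$induction_end, slicing$train_start,
               slicing$test_end, seed = run_seed)
  } else {
    stop("unknown slicing mode: ", slicing$mode)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full link-prediction evaluation experiment
#'
#' For each of `n_runs` runs: slice the graph, sample 1:1 negatives, score
#' every configured method on the identical split, compute the five
#' metrics, and collect the no-common-neighbour diagnostic. Results are
#' aggregated with [aggregate_runs()].
#'
#' @param cfg an [experiment_config()].
#' @param verbose print per-run progress.
#' @return list of class `experiment_result` with components `runs` (long
#'   data.frame method x metric x run), `summary` ([aggregate_runs()]
#'   output), `no_cn` (per-run diagnostic list), `manifest` (seeds and
#'   parameters), and `rankings` (per run, per method).
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  g <- if (inherits(cfg$graph, "synth_config")) {
    generate_graph(cfg$graph)
  } else {
    cfg$graph
  }
  runs <- list()
  no_cn <- list()
  rankings_all <- list()
  for (r in seq_len(cfg$n_runs)) {
    run_seed <- cfg$seed + r
    split <- make_split(g, cfg$slicing, run_seed)
    induction_g <- temporal_graph(nodes = g$nodes, links = split$induction,
                                  partition = g$partition)
    rankings <- list()
    for (spec in cfg$methods) {
      if (verbose) message("run ", r, ": ", spec$name)
      rk <- score_method(spec, g, split, run_seed)
      rankings[[spec$name]] <- rk
      vals <- evaluate_ranking(rk, cfg$k_ratio)
      runs[[length(runs) + 1L]] <- data.frame(
        method = spec$name, metric = names(vals), run = r,
        value = unname(vals), stringsAsFactors = FALSE)
    }
    no_cn[[r]] <- no_cn_report(induction_g, split$test_pos, rankings)
    rankings_all[[r]] <- rankings
  }
  runs <- do.call(rbind, runs)
  structure(list(
    runs = runs,
    summary = if (cfg$n_runs >= 2L) aggregate_runs(runs) else NULL,
    no_cn = no_cn,
    rankings = rankings_all,
    manifest = list(seed = cfg$seed, n_runs = cfg$n_runs,
                    k_ratio = cfg$k_ratio, slicing = cfg$slicing,
                    methods = vapply(cfg$methods, `[[`, "", "name"),
                    n_nodes = length(g$nodes), n_links = n_links(g))),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result:", x$manifest$n_runs, "run(s) of",
      length(x$manifest$methods), "method(s) on",
      x$manifest$n_nodes, "nodes /", x$manifest$n_links, "links\n")
  if (!is.null(x$summary)) {
    cat("\nmean over runs ([best], * not significantly different):\n")
    print(format_summary(x$summary), quote = FALSE)
  }
  mean_no_cn <- mean(vapply(x$no_cn, `[[`, numeric(1), "frac_no_cn"))
  cat(sprintf("\nno-common-neighbour positives: %.1f%% of test positives\n",
              100 * mean_no_cn))
  invisible(x)
}
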