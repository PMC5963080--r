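#' Combine two node vectors into a link representation
#'
#' The five node-combination operators (binary operators are element-wise):
#' `average` `(x_i + y_i)/2`, `concatenate` `x || y` (doubles the
#' dimension), `hadamard` `x_i * y_i`, `weighted_l1` `|x_i - y_i|`, and
#' `weighted_l2` `|x_i - y_i|^2`. All but `concatenate` are symmetric in
#' their arguments; for `concatenate` callers should pass endpoints in
#' canonical order (see [combine_pairs()]).
#'
#' @param x,y numeric vectors of equal length.
#' @param op operator name.
#' @return the combined numeric vector.
#' @export
combine <- function(x, y, op = c("average", "concatenate", "hadamard",
                                 "weighted_l1", "weighted_l2")) {
  op <- match.arg(op)
  if (length(x) != length(y)) stop("vectors have different dimensions")
  switch(op,
         average = (x + y) / 2,
         concatenate = c(x, y),
         hadamard = x * y,
         weighted_l1 = abs(x - y),
         weighted_l2 = (x - y)^2)
}

#' Combine endpoint embeddings for a batch of pairs
#'
#' Row-wise [combine()] over an embedding table. Pairs are put in canonical
#' order first (lexicographic; for bipartite graphs pass `partition` to put
#' the A-side endpoint first) so the asymmetric `concatenate` operator is
#' order-independent for unordered pairs.
#'
#' @param emb an [embedding_table()] covering all endpoints.
#' @param pairs data.frame with columns `u`, `v`.
#' @param op operator name as in [combine()].
#' @param partition optional named `"A"`/`"B"` labels; A-side first.
#' @return numeric matrix, one row per pair.
#' @export
combine_pairs <- function(emb, pairs, op = "hadamard", partition = NULL) {
  u <- pairs$u
  v <- pairs$v
  if (!is.null(partition)) {
    swap <- partition[u] == "B"
    tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  } else {
    cp <- canonical_pairs(u, v)
    u <- cp$u; v <- cp$v
  }
  missing <- setdiff(unique(c(u, v)), rownames(emb$vectors))
  if (length(missing) > 0L) {
    stop("no embedding vector for node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         " (run complete_table() first)")
  }
  X <- emb$vectors[u, , drop = FALSE]
  Y <- emb$vectors[v, , drop = FALSE]
  out <- switch(op,
                average = (X + Y) / 2,
                concatenate = cbind(X, Y),
                hadamard = X * Y,
                weighted_l1 = abs(X - Y),
                weighted_l2 = (X - Y)^2,
                stop("unknown operator: ", op))
  rownames(out) <- NULL
  out
}

#' Predictor configuration
#'
#' The minimalist feed-forward link predictor: a single hidden layer of
#' rectified linear units (default 100) and a sigmoid output giving the
#' probability of a link, trained on cross-entropy for exactly `epochs`
#' passes (default 7) with Adam at its conventional default rate and
#' mini-batches of 32. No early stopping, dropout or validation split.
#'
#' @param hidden_units hidden layer width.
#' @param epochs training passes.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param seed integer seed for initialization and shuffling.
#' @return a list of class `predictor_config`.
#' @export
predictor_config <- function(hidden_units = 100L, epochs = 7L,
                             learning_rate = 1e-3, batch_size = 32L,
                             seed = 1L) {
  stopifnot(hidden_units >= 1, epochs >= 1, batch_size >= 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "predictor_config")
}

#' Train the neural link predictor
#'
#' Fits the single-hidden-layer classifier of [predictor_config()] on
#' combined link vectors: positives labelled 1, negatives 0. Initialization
#' (Glorot-uniform), shuffling and optimization are all determined by the
#' config seed.
#'
#' @param pos_vecs,neg_vecs numeric matrices of combined vectors (rows =
#'   examples), equal column counts, both non-empty.
#' @param cfg a [predictor_config()].
#' @return an object of class `link_predictor` holding the weights, the
#'   config, and the per-epoch mean training loss (`loss`).
#' @export
train_predictor <- function(pos_vecs, neg_vecs, cfg = predictor_config()) {
  if (NROW(pos_vecs) == 0L || NROW(neg_vecs) == 0L) {
    stop("both classes must be non-empty")
  }
  if (NCOL(pos_vecs) != NCOL(neg_vecs)) stop("dimension mismatch")
  X <- rbind(pos_vecs, neg_vecs)
  y <- c(rep(1, nrow(pos_vecs)), rep(0, nrow(neg_vecs)))
  d <- ncol(X); h <- cfg$hidden_units
  withr::local_seed(cfg$seed)
  lim1 <- sqrt(6 / (d + h)); lim2 <- sqrt(6 / (h + 1))
  W1 <- matrix(stats::runif(d * h, -lim1, lim1), d, h)
  b1 <- rep(0, h)
  W2 <- matrix(stats::runif(h, -lim2, lim2), h, 1)
  b2 <- 0
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  loss_hist <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batch_losses <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      m <- length(idx)
      # forward
      Z1 <- sweep(Xb %*% params$W1, 2L, params$b1, `+`)
      A1 <- pmax(Z1, 0)
      z2 <- drop(A1 %*% params$W2) + params$b2
      p <- 1 / (1 + exp(-z2))
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      batch_losses <- c(batch_losses,
                        -mean(yb * log(pc) + (1 - yb) * log(1 - pc)))
      # backward (cross-entropy + sigmoid -> p - y)
      dz2 <- (p - yb) / m
      gW2 <- t(A1) %*% dz2
      gb2 <- sum(dz2)
      dA1 <- outer(dz2, drop(params$W2))
      dZ1 <- dA1 * (Z1 > 0)
      gW1 <- t(Xb) %*% dZ1
      gb1 <- colSums(dZ1)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      step <- step + 1L
      for (nm in names(params)) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] -
          cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_hist[epoch] <- mean(batch_losses)
  }
  structure(list(params = params, cfg = cfg, input_dim = d,
                 loss = loss_hist),
            class = "link_predictor")
}

# forward pass: probabilities for a matrix of combined vectors
predictor_prob <- function(model, X) {
  if (ncol(X) != model$input_dim) stop("input dimension mismatch")
  A1 <- pmax(sweep(X %*% model$params$W1, 2L, model$params$b1, `+`), 0)
  drop(1 / (1 + exp(-(A1 %*% model$params$W2 + model$params$b2))))
}

#' Score candidate pairs with a trained predictor
#'
#' Combines the endpoint embeddings of each pair with `op`, runs the
#' predictor forward, and returns the ranked list of link probabilities.
#'
#' @param model a `link_predictor` from [train_predictor()].
#' @param pairs data.frame with columns `u`, `v`.
#' @param emb an [embedding_table()] covering all endpoints (use
#'   [complete_table()] to cover test-only nodes).
#' @param op combination operator, as used at training time.
#' @param label optional logical truth labels.
#' @param partition optional bipartite labels for canonical endpoint order.
#' @return a [scored_ranking()] of probabilities in `[0, 1]`.
#' @export
predict_links <- function(model, pairs, emb, op = "hadamard", label = NULL,
                          partition = NULL) {
  if (nrow(pairs) == 0L) {
    return(scored_ranking(character(), character(), numeric()))
  }
  X <- combine_pairs(emb, pairs, op, partition)
  scored_ranking(pairs$u, pairs$v, predictor_prob(model, X), label)
}

#' Save / load a trained predictor as JSON
#'
#' Weights and config in one plain-text file.
#'
#' @param model a `link_predictor`.
#' @param path file path.
#' @return `save_predictor`: `path` invisibly; `load_predictor`: the model.
#' @export
save_predictor <- function(model, path) {
  obj <- list(W1 = model$params$W1, b1 = model$params$b1,
              W2 = drop(model$params$W2), b2 = model$params$b2,
              cfg = unclass(model$cfg), input_dim = model$input_dim,
              loss = model$loss)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(predictor_config, obj$cfg[c("hidden_units", "epochs",
                                             "learning_rate", "batch_size",
                                             "seed")])
  structure(list(params = list(W1 = obj$W1, b1 = obj$b1,
                               W2 = matrix(obj$W2, ncol = 1L), b2 = obj$b2),
                 cfg = cfg, input_dim = obj$input_dim, loss = obj$loss),
            class = "link_predictor")
}
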