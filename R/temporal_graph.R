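#' Undirected temporal graph
#'
#' The central container of the package: an undirected simple graph over
#' opaque string node identifiers, optionally carrying one integer year per
#' link (the year the interaction was first observed) and/or a two-way
#' partition of the nodes (for bipartite drug--target style graphs).
#'
#' Links are stored canonically: for every link the lexicographically smaller
#' endpoint comes first, there are no self-links and no duplicates.
#'
#' @param nodes character vector of node ids (may include isolated nodes).
#' @param links two-column character matrix or data.frame of endpoints.
#' @param year optional integer vector, one entry per link.
#' @param partition optional named character vector mapping every node id to
#'   `"A"` or `"B"`.
#'
#' @return An object of class `temporal_graph` with components `nodes`
#'   (sorted character vector), `links` (data.frame with columns `u`, `v`),
#'   `year` (integer vector or `NULL`) and `partition` (named character
#'   vector or `NULL`).
#' @export
temporal_graph <- function(nodes = character(), links = NULL, year = NULL,
                           partition = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  if (is.null(links) || NROW(links) == 0L) {
    links <- data.frame(u = character(), v = character(),
                        stringsAsFactors = FALSE)
    year <- if (is.null(year)) NULL else integer()
  } else {
    links <- as.data.frame(links, stringsAsFactors = FALSE)
    names(links)[1:2] <- c("u", "v")
    links$u <- as.character(links$u)
    links$v <- as.character(links$v)
    if (!is.null(year) && length(year) != nrow(links)) {
      stop("`year` must have one entry per link")
    }
    cp <- canonical_pairs(links$u, links$v)
    links <- data.frame(u = cp$u, v = cp$v, stringsAsFactors = FALSE)
    if (any(links$u == links$v)) stop("self-links are not allowed")
    key <- pair_key(links$u, links$v)
    if (anyDuplicated(key)) stop("duplicate links are not allowed")
    missing <- setdiff(unique(c(links$u, links$v)), nodes)
    if (length(missing) > 0L) {
      stop("link endpoint(s) not in node set: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    if (!is.null(year)) {
      year <- as.integer(year)
      if (anyNA(year)) stop("`year` must be integer with no missing values")
    }
  }
  g <- structure(list(nodes = nodes, links = links, year = year,
                      partition = NULL),
                 class = "temporal_graph")
  if (!is.null(partition)) g <- attach_partition(g, partition)
  g
}

#' @export
print.temporal_graph <- function(x, ...) {
  cat("temporal_graph:", length(x$nodes), "nodes,", nrow(x$links), "links")
  if (!is.null(x$year)) {
    cat(sprintf("; years %d-%d", min(x$year), max(x$year)))
  }
  if (!is.null(x$partition)) {
    cat(sprintf("; bipartite (|A| = %d, |B| = %d)",
                sum(x$partition == "A"), sum(x$partition == "B")))
  }
  cat("\n")
  invisible(x)
}

#' Number of links in a graph
#' @param g a `temporal_graph`.
#' @return integer count of undirected links.
#' @export
n_links <- function(g) nrow(g$links)

# canonical unordered-pair ordering: lexicographically smaller id first
canonical_pairs <- function(u, v) {
  swap <- u > v
  list(u = ifelse(swap, v, u), v = ifelse(swap, u, v))
}

# stable string key for an unordered pair (assumes canonical order)
pair_key <- function(u, v) paste(u, v, sep = "\r")

# keys of all links of g
link_keys <- function(g) pair_key(g$links$u, g$links$v)

#' Read an undirected edge list
#'
#' Parses a whitespace-delimited edge-list file with lines `<u> <v>` or, with
#' `has_year = TRUE`, `<u> <v> <year>`. Lines starting with `#` and blank
#' lines are ignored. Duplicate observations of the same unordered pair are
#' collapsed to a single link; when their years conflict the earliest year is
#' kept (a link "forms" at first observation). Self-links are dropped and
#' their count reported via [message()].
#'
#' @param path file path.
#' @param has_year logical; if `TRUE` every line must carry an integer year.
#' @return a [temporal_graph()].
#' @export
read_edge_list <- function(path, has_year = FALSE) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(lines) == 0L) return(temporal_graph())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  want <- if (has_year) 3L else 2L
  bad <- which(nf != want)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected %d fields, found %d", lineno[bad[1L]],
                 want, nf[bad[1L]]))
  }
  u <- vapply(fields, `[[`, "", 1L)
  v <- vapply(fields, `[[`, "", 2L)
  year <- NULL
  if (has_year) {
    ystr <- vapply(fields, `[[`, "", 3L)
    year <- suppressWarnings(as.integer(ystr))
    if (anyNA(year)) {
      b <- which(is.na(year))[1L]
      stop(sprintf("line %d: year '%s' is not an integer", lineno[b], ystr[b]))
    }
  }
  cp <- canonical_pairs(u, v)
  u <- cp$u; v <- cp$v
  self <- u == v
  if (any(self)) {
    message(sum(self), " self-link(s) dropped")
    u <- u[!self]; v <- v[!self]
    if (has_year) year <- year[!self]
  }
  key <- pair_key(u, v)
  if (has_year && length(key) > 0L) {
    # earliest year wins on duplicates
    ord <- order(key, year)
    u <- u[ord]; v <- v[ord]; year <- year[ord]; key <- key[ord]
    first <- !duplicated(key)
    u <- u[first]; v <- v[first]; year <- year[first]
  } else {
    first <- !duplicated(key)
    u <- u[first]; v <- v[first]
  }
  temporal_graph(nodes = unique(c(u, v)),
                 links = data.frame(u = u, v = v, stringsAsFactors = FALSE),
                 year = year)
}

#' Write an edge list
#'
#' Inverse of [read_edge_list()] on canonical graphs: writes one `<u> <v>` or
#' `<u> <v> <year>` line per link. Isolated nodes are not representable in
#' the format and are dropped on a round trip.
#'
#' @param g a `temporal_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  if (is.null(g$year)) {
    lines <- paste(g$links$u, g$links$v)
  } else {
    lines <- paste(g$links$u, g$links$v, g$year)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a node partition file
#'
#' Each non-comment line is `<node-id> <A|B>`.
#'
#' @param path file path.
#' @return named character vector of `"A"`/`"B"` labels.
#' @export
read_partition <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    b <- which(nf != 2L)[1L]
    stop(sprintf("line %d: expected 2 fields, found %d", lineno[b], nf[b]))
  }
  lab <- vapply(fields, `[[`, "", 2L)
  if (!all(lab %in% c("A", "B"))) {
    b <- which(!lab %in% c("A", "B"))[1L]
    stop(sprintf("line %d: label must be A or B, found '%s'", lineno[b], lab[b]))
  }
  stats::setNames(lab, vapply(fields, `[[`, "", 1L))
}

#' Attach a bipartite partition to a graph
#'
#' Labels every node `"A"` or `"B"` and verifies that every link crosses the
#' partition (the graph is bipartite under the given labelling). Used for
#' drug--target style graphs where one side holds chemicals and the other
#' proteins.
#'
#' @param g a `temporal_graph`.
#' @param labels named character vector mapping every node of `g` to `"A"` or
#'   `"B"`.
#' @return `g` with `partition` set.
#' @export
attach_partition <- function(g, labels) {
  labels <- stats::setNames(as.character(labels), names(labels))
  missing <- setdiff(g$nodes, names(labels))
  if (length(missing) > 0L) {
    stop("unlabeled node(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  labels <- labels[g$nodes]
  if (!all(labels %in% c("A", "B"))) stop("labels must be 'A' or 'B'")
  same <- labels[g$links$u] == labels[g$links$v]
  if (any(same)) {
    i <- which(same)[1L]
    stop(sprintf("not bipartite under this labelling: link %s--%s joins two '%s' nodes",
                 g$links$u[i], g$links$v[i], labels[[g$links$u[i]]]))
  }
  g$partition <- labels
  g
}

#' Neighbour set of a node
#'
#' @param g a `temporal_graph`.
#' @param u a node id present in `g`.
#' @return character vector of the nodes sharing a link with `u` (never
#'   containing `u` itself); empty for isolated nodes.
#' @export
neighbours <- function(g, u) {
  if (!u %in% g$nodes) stop("unknown node: ", u)
  c(g$links$v[g$links$u == u], g$links$u[g$links$v == u])
}

# adjacency list for all nodes; isolated nodes map to character(0)
adjacency_list <- function(g) {
  adj <- lapply(stats::setNames(vector("list", length(g$nodes)), g$nodes),
                function(x) character())
  if (nrow(g$links) > 0L) {
    ends <- c(g$links$u, g$links$v)
    nbrs <- c(g$links$v, g$links$u)
    adj[names(adj)] <- split(nbrs, factor(ends, levels = g$nodes))
  }
  adj
}

# igraph view of a temporal_graph (internal)
as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$links, directed = FALSE, vertices = g$nodes)
}

#' Induced subgraph on a subset of links
#'
#' Keeps the full node set (so nodes isolated by link removal remain, as they
#' do when a graph is sliced) and the given links, with their years and the
#' partition carried over.
#'
#' @param g a `temporal_graph`.
#' @param idx integer or logical index into the links of `g`.
#' @return a `temporal_graph`.
#' @export
subgraph_links <- function(g, idx) {
  temporal_graph(nodes = g$nodes, links = g$links[idx, , drop = FALSE],
                 year = if (is.null(g$year)) NULL else g$year[idx],
                 partition = g$partition)
}
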