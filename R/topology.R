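# Network topology: largest connected component, degree, betweenness
# centrality (Brandes' algorithm) and hub/bottleneck classification.

#' Construct a simple undirected graph
#'
#' Nodes are gene identifiers; edges are unordered pairs. Duplicate edges
#' are collapsed; self-loops are an error (they are quarantined upstream by
#' [aggregate_evidence()]).
#'
#' @param edges Two-column data.frame (or matrix) of edge endpoints;
#'   may be empty.
#' @param nodes Optional extra node ids (isolated nodes).
#' @return An object of class `simple_graph` with elements `nodes`
#'   (character) and `edges` (data.frame with columns `a`, `b`, canonical
#'   order, deduplicated).
#' @export
simple_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    e <- data.frame(a = character(0), b = character(0),
                    stringsAsFactors = FALSE)
  } else {
    x <- as.character(edges[[1]])
    y <- as.character(edges[[2]])
    if (any(x == y)) stop("self-loops are not allowed in a simple graph")
    e <- data.frame(a = pmin(x, y), b = pmax(x, y), stringsAsFactors = FALSE)
    e <- e[!duplicated(e), , drop = FALSE]
    e <- e[order(e$a, e$b), , drop = FALSE]
    rownames(e) <- NULL
  }
  all_nodes <- sort(unique(c(e$a, e$b, as.character(nodes))))
  structure(list(nodes = all_nodes, edges = e), class = "simple_graph")
}

#' @export
print.simple_graph <- function(x, ...) {
  cat(sprintf("<simple_graph> %d node(s), %d edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

.tn_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component; if several
#' components tie for size, the one containing the lexicographically
#' smallest node id wins. Only this component is used for topological
#' analysis.
#'
#' @param g A [simple_graph()].
#' @return A [simple_graph()] restricted to the winning component.
#' @export
largest_component <- function(g) {
  stopifnot(inherits(g, "simple_graph"))
  if (length(g$nodes) == 0L) stop("empty graph")
  comp <- igraph::components(.tn_igraph(g))
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: component holding the smallest node id (nodes are sorted)
    first_member <- vapply(best, function(ci) {
      min(g$nodes[comp$membership == ci])
    }, character(1))
    best <- best[order(first_member)[1]]
  }
  keep <- g$nodes[comp$membership == best]
  e <- g$edges[g$edges$a %in% keep & g$edges$b %in% keep, , drop = FALSE]
  simple_graph(e, nodes = keep)
}

#' Node degrees
#'
#' @param g A [simple_graph()].
#' @return Named integer vector: number of incident edges per node
#'   (0 for isolated nodes).
#' @export
node_degree <- function(g) {
  stopifnot(inherits(g, "simple_graph"))
  d <- setNames(integer(length(g$nodes)), g$nodes)
  if (nrow(g$edges) > 0) {
    tab <- table(c(g$edges$a, g$edges$b))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' Unnormalized shortest-path betweenness on an undirected simple graph:
#' endpoints excluded, each unordered source-target pair counted once,
#' fractional credit shared across equal-length shortest paths. Computed
#' with Brandes' single-source accumulation (one BFS per source).
#'
#' @param g A [simple_graph()].
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_brandes <- function(g) {
  stopifnot(inherits(g, "simple_graph"))
  n <- length(g$nodes)
  bc <- setNames(numeric(n), g$nodes)
  if (n == 0L || nrow(g$edges) == 0L) return(bc)
  idx <- setNames(seq_len(n), g$nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$edges))) {
    i <- idx[[g$edges$a[k]]]; j <- idx[[g$edges$b[k]]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    S <- integer(0)                    # nodes in nondecreasing distance
    sigma <- numeric(n); sigma[s] <- 1 # shortest-path counts
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    queue <- c(s); qi <- 1L
    while (qi <= length(queue)) {
      v <- queue[qi]; qi <- qi + 1L
      S <- c(S, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(S)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2  # each unordered pair was accumulated from both endpoints
}

#' Centrality table with hub and bottleneck calls
#'
#' Computes degree and betweenness on a graph (conventionally the largest
#' component of the high-confidence direct-physical PPI network) and flags
#' hubs and bottlenecks via [classify_hubs_bottlenecks()].
#'
#' @param g A [simple_graph()].
#' @param fraction Top fraction flagged on each measure (default 0.10).
#' @return A data.frame with columns `node`, `degree`, `betweenness`,
#'   `is_hub`, `is_bottleneck`.
#' @export
centrality_table <- function(g, fraction = 0.10) {
  cent <- data.frame(node = g$nodes,
                     degree = unname(node_degree(g)),
                     betweenness = unname(betweenness_brandes(g)),
                     stringsAsFactors = FALSE)
  classify_hubs_bottlenecks(cent, fraction = fraction)
}

#' Flag hubs and bottlenecks
#'
#' For each measure independently, nodes are ranked in descending order,
#' `k = ceiling(fraction * N)` sets the cutoff at the k-th ranked value,
#' and every node whose value reaches the cutoff is flagged
#' (tie-inclusive: ties at the boundary may push the flagged set beyond
#' the nominal fraction). Hubs are called on degree, bottlenecks on
#' betweenness.
#'
#' @param cent Data.frame with columns `node`, `degree`, `betweenness`.
#' @param fraction Top fraction in `(0, 1]`; default 0.10.
#' @return `cent` with logical columns `is_hub` and `is_bottleneck` added.
#' @export
classify_hubs_bottlenecks <- function(cent, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1, nrow(cent) > 0)
  k <- ceiling(fraction * nrow(cent))
  top_cut <- function(v) sort(v, decreasing = TRUE)[k]
  cent$is_hub <- cent$degree >= top_cut(cent$degree)
  cent$is_bottleneck <- cent$betweenness >= top_cut(cent$betweenness)
  cent
}
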