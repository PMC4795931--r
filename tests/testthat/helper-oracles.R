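# Independent oracles used to validate the package's implementations.
# Each deliberately uses the most direct (brute-force) formulation.

# Hypergeometric upper tail by direct enumeration of binomial-coefficient
# ratios. choose() is exact in double precision for the N used here.
oracle_fisher_tail <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Textbook multiple-testing step formulas, computed from the definitions.
oracle_adjust <- function(p, method) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- switch(method,
    bonferroni = pmin(1, m * ps),
    holm = cummax(pmin(1, (m - seq_len(m) + 1) * ps)),
    bh = rev(cummin(rev(pmin(1, m * ps / seq_len(m))))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Betweenness by explicit enumeration of every shortest path between every
# unordered node pair (BFS predecessor DAG + recursive path expansion).
oracle_betweenness <- function(g) {
  nodes <- g$nodes
  n <- length(nodes)
  adj <- setNames(vector("list", n), nodes)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges$a[i]; b <- g$edges$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bc <- setNames(numeric(n), nodes)
  bfs <- function(s) {
    dist <- setNames(rep(Inf, n), nodes)
    dist[s] <- 0
    preds <- setNames(vector("list", n), nodes)
    q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          q <- c(q, w)
        }
        if (dist[w] == dist[v] + 1) preds[[w]] <- c(preds[[w]], v)
      }
    }
    list(dist = dist, preds = preds)
  }
  all_paths <- function(preds, s, t) {
    if (t == s) return(list(s))
    out <- list()
    for (p in preds[[t]]) {
      for (pp in all_paths(preds, s, p)) out <- c(out, list(c(pp, t)))
    }
    out
  }
  for (si in seq_len(n - 1)) {
    s <- nodes[si]
    b <- bfs(s)
    for (t in nodes[(si + 1):n]) {
      if (is.infinite(b$dist[t])) next
      paths <- all_paths(b$preds, s, t)
      np <- length(paths)
      for (pth in paths) {
        interior <- setdiff(pth, c(s, t))
        bc[interior] <- bc[interior] + 1 / np
      }
    }
  }
  bc
}

# UPGMA oracle that recomputes every average inter-cluster distance from
# the original matrix at each step (no Lance-Williams update), with the
# same smallest-original-index tie-break.
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)  # member original indices
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- NULL; best_val <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        v <- mean(d[clusters[[i]], clusters[[j]]])
        lo <- min(min(clusters[[i]]), min(clusters[[j]]))
        hi <- max(min(clusters[[i]]), min(clusters[[j]]))
        better <- v < best_val - 1e-15 ||
          (abs(v - best_val) <= 1e-15 &&
           (is.null(best) || lo < best[3] ||
            (lo == best[3] && hi < best[4])))
        if (better) { best_val <- v; best <- c(i, j, lo, hi) }
      }
    }
    heights[step] <- best_val
    merges[[step]] <- sort(c(min(clusters[[best[1]]]),
                             min(clusters[[best[2]]])))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-c(best[1], best[2])], list(merged))
  }
  list(heights = heights, merges = merges)
}

# Random connected Erdos-Renyi graph (resamples until connected).
random_connected_graph <- function(n, p, seed) {
  for (k in 0:200) {
    g <- generate_random_graph(n, p, seed = seed + 7919L * k)
    ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = data.frame(name = g$nodes))
    if (igraph::is_connected(ig)) return(g)
  }
  stop("could not generate a connected graph")
}

# Merge-height comparison helper: heights of an hclust vs the oracle,
# plus agreement of the merged smallest-member pairs.
upgma_matches_oracle <- function(dg, orc, tol = 1e-9) {
  if (max(abs(dg$height - orc$heights)) > tol) return(FALSE)
  # reconstruct smallest-member merge pairs from the hclust merge matrix
  members <- function(i) {
    if (i < 0) return(-i)
    c(members(dg$merge[i, 1]), members(dg$merge[i, 2]))
  }
  for (s in seq_len(nrow(dg$merge))) {
    got <- sort(c(min(members(dg$merge[s, 1])),
                  min(members(dg$merge[s, 2]))))
    if (!identical(got, orc$merges[[s]])) return(FALSE)
  }
  TRUE
}
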