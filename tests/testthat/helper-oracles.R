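# Brute-force reference implementations, independent of the package (and of
# igraph): used to cross-check centrality, coreness, Fisher p and the
# moderated t-test.

# All-pairs shortest-path betweenness by explicit geodesic enumeration.
# edges: data.frame from/to (character); directed flag. Returns named
# vector over `nodes`, normalized like the package ((N-1)(N-2), halved for
# undirected graphs).
oracle_betweenness <- function(edges, nodes, directed) {
  n <- length(nodes)
  adj <- setNames(vector("list", n), nodes)
  add <- function(a, b) adj[[a]] <<- c(adj[[a]], b)
  for (i in seq_len(nrow(edges))) {
    add(edges$from[i], edges$to[i])
    if (!directed) add(edges$to[i], edges$from[i])
  }
  # enumerate every geodesic s -> t by DFS over BFS distance levels
  paths_through <- setNames(numeric(n), nodes)
  for (s in nodes) {
    dist <- setNames(rep(Inf, n), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
    for (t in nodes) {
      if (t == s || is.infinite(dist[t])) next
      # collect all geodesics s->t
      geodesics <- list()
      walk <- function(path) {
        u <- path[length(path)]
        if (u == t) {
          geodesics[[length(geodesics) + 1L]] <<- path
          return()
        }
        for (v in adj[[u]]) {
          if (dist[v] == dist[u] + 1 && dist[v] <= dist[t]) walk(c(path, v))
        }
      }
      walk(s)
      if (!length(geodesics)) next
      inner <- unlist(lapply(geodesics, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        tab <- table(inner)
        paths_through[names(tab)] <- paths_through[names(tab)] +
          as.numeric(tab) / length(geodesics)
      }
    }
  }
  if (!directed) paths_through <- paths_through / 2
  denom <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  paths_through / denom
}

# k-core by literal iterative pruning on an undirected simple graph.
oracle_kcore <- function(edges, nodes) {
  pairs <- unique(t(apply(as.matrix(edges[c("from", "to")]), 1, sort)))
  core <- setNames(rep(0L, length(nodes)), nodes)
  k <- 1L
  alive <- nodes
  repeat {
    repeat {
      deg <- setNames(rep(0L, length(alive)), alive)
      for (i in seq_len(nrow(pairs))) {
        if (pairs[i, 1] %in% alive && pairs[i, 2] %in% alive) {
          deg[pairs[i, 1]] <- deg[pairs[i, 1]] + 1L
          deg[pairs[i, 2]] <- deg[pairs[i, 2]] + 1L
        }
      }
      drop <- names(deg)[deg < k]
      if (!length(drop)) break
      alive <- setdiff(alive, drop)
    }
    if (!length(alive)) break
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# Fisher over-representation p by exhaustive enumeration of all 2x2 tables
# at the fixed margins.
oracle_fisher <- function(n_f, n, N_f, N) {
  lo <- max(0, n + N_f - N)
  hi <- min(n, N_f)
  probs <- vapply(lo:hi, function(x) {
    choose(N_f, x) * choose(N - N_f, n - x) / choose(N, n)
  }, numeric(1))
  sum(probs[(lo:hi) >= n_f])
}

# Classical pooled two-sample t-test p-values per row of a log2 matrix.
oracle_pooled_t <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- apply(mat[, idx1, drop = FALSE], 1, var)
  v2 <- apply(mat[, idx2, drop = FALSE], 1, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tstat), df = n1 + n2 - 2)
}

# Seeded random simple digraph as an edge tibble.
random_digraph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- expand.grid(from = nodes, to = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  idx <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  tibble::as_tibble(pairs[idx, ])
}
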