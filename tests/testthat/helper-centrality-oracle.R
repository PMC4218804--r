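# Brute-force centrality oracle over an adjacency matrix.  Deliberately
# naive and structurally different from the package implementation:
# Floyd-Warshall distances, exhaustive simple-path enumeration for path
# counts, exhaustive subset enumeration for maximal cliques, and exact
# expectation over all edge subsets for the percolation index.

fw_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# all shortest simple paths s -> t as a list of vertex vectors
enumerate_shortest_paths <- function(adj, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  target_len <- D[s, t]
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      if (length(path) - 1 == target_len) paths[[length(paths) + 1]] <<- path
      return()
    }
    if (length(path) - 1 >= target_len) return()
    for (v in which(adj[u, ] == 1)) {
      if (!(v %in% path) && D[s, v] == length(path) &&
          D[s, v] + D[v, t] == target_len) {
        walk(c(path, v))
      }
    }
  }
  walk(s)
  paths
}

oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in which(adj[u, ] == 1)) {
        if (comp[v] == 0L) { comp[v] <- cur; queue <- c(queue, v) }
      }
    }
  }
  comp
}

oracle_centralities <- function(adj, dmnc_epsilon = 1.7,
                                epc_retention = 0.5, epc_exact_max_edges = 10) {
  n <- nrow(adj)
  D <- fw_distances(adj)
  comp <- oracle_components(adj)
  deg <- rowSums(adj)

  # path enumeration shared by betweenness / stress
  betw <- numeric(n)
  stress <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- enumerate_shortest_paths(adj, D, s, t)
      if (length(ps) == 0) next
      interior <- table(unlist(lapply(ps, function(p) setdiff(p, c(s, t)))))
      if (length(interior)) {
        idx <- as.integer(names(interior))
        betw[idx] <- betw[idx] + as.numeric(interior) / length(ps)
        stress[idx] <- stress[idx] + as.numeric(interior)
      }
    }
  }

  # cliques by subset enumeration
  is_clique <- function(mem) {
    if (length(mem) < 2) return(TRUE)
    all(adj[mem, mem][upper.tri(diag(length(mem)))] == 1)
  }
  maximal_cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    mem <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(mem) < 2 || !is_clique(mem)) next
    extendable <- any(vapply(setdiff(seq_len(n), mem), function(v) {
      all(adj[v, mem] == 1)
    }, logical(1)))
    if (!extendable) maximal_cliques[[length(maximal_cliques) + 1]] <- mem
  }
  mcc <- numeric(n)
  for (cl in maximal_cliques) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  }
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) == 0) { mcc[v] <- 0; next }
    if (sum(adj[nb, nb]) == 0) mcc[v] <- deg[v]
  }

  mnc <- dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) == 0) next
    sub <- adj[nb, nb, drop = FALSE]
    cc <- oracle_components(sub)
    sizes <- tabulate(cc)
    big <- which.max(sizes)
    mem <- which(cc == big)
    mnc[v] <- length(mem)
    dmnc[v] <- sum(sub[mem, mem, drop = FALSE]) / 2 / length(mem)^dmnc_epsilon
  }

  # exact EPC expectation over all edge subsets (NA when too many edges)
  edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  m <- nrow(edges)
  epc <- rep(NA_real_, n)
  if (m <= epc_exact_max_edges) {
    epc <- numeric(n)
    for (mask in 0:(2^m - 1)) {
      keep <- if (m) bitwAnd(mask, 2^(seq_len(m) - 1)) > 0 else logical(0)
      sub <- matrix(0, n, n)
      if (any(keep)) {
        e <- edges[keep, , drop = FALSE]
        sub[e] <- 1
        sub[e[, c(2, 1), drop = FALSE]] <- 1
      }
      pr <- epc_retention^sum(keep) * (1 - epc_retention)^(m - sum(keep))
      cc <- oracle_components(sub)
      epc <- epc + pr * tabulate(cc)[cc]
    }
  }

  # BottleNeck: smallest-id-parent trees, paths counted by parent walks
  bottleneck <- numeric(n)
  for (s in seq_len(n)) {
    reach <- which(is.finite(D[s, ]))
    ns <- length(reach)
    if (ns <= 1) next
    parent <- rep(NA_integer_, n)
    for (u in reach) {
      if (u == s) next
      parent[u] <- min(which(adj[u, ] == 1 & D[s, ] == D[s, u] - 1))
    }
    paths_through <- numeric(n)
    for (u in reach) {
      if (u == s) next
      w <- u
      while (w != s) { paths_through[w] <- paths_through[w] + 1; w <- parent[w] }
    }
    paths_through[s] <- ns - 1
    hit <- reach[paths_through[reach] > ns / 4]
    bottleneck[hit] <- bottleneck[hit] + 1
  }

  ecc <- clo <- rad <- numeric(n)
  for (v in seq_len(n)) {
    dv <- D[v, ]
    fin <- which(is.finite(dv) & dv > 0)
    ecc[v] <- if (length(fin)) max(dv[fin]) else 0
    clo[v] <- sum(1 / dv[fin])
    mem <- which(comp == comp[v])
    if (length(mem) > 1) {
      diam <- max(D[mem, mem])
      rad[v] <- sum(diam + 1 - dv[fin]) / (length(mem) - 1)
    }
  }

  clust <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k >= 2) clust[v] <- sum(adj[nb, nb]) / (k * (k - 1))
  }

  data.frame(MCC = mcc, DMNC = dmnc, MNC = mnc, Degree = as.numeric(deg),
             EPC = epc, BottleNeck = bottleneck, Eccentricity = ecc,
             Closeness = clo, Radiality = rad, Betweenness = betw,
             Stress = stress, ClusteringCoefficient = clust)
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.numeric(stats::runif(length(up)) < p)
  adj + t(adj)
}

adjacency_to_igraph <- function(adj, names = letters[seq_len(nrow(adj))]) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- names
  g
}
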