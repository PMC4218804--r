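#' Build the undirected enzyme-centric network of a model
#'
#' Nodes are the genes appearing in any GPR rule.  Two genes are joined
#' when they catalyse the same reaction (isozymes and complex partners
#' alike) or when their reactions share at least one non-excluded
#' metabolite - the classic enzyme-centric projection in which ubiquitous
#' currency metabolites (ATP, NAD(H), water, protons, ...) would otherwise
#' connect everything to everything and are therefore dropped before
#' computing adjacency.  The graph is simple: no self-loops, no
#' multi-edges.
#'
#' @param model A [metabolic_model()].
#' @param excluded_metabolites Metabolite ids or names to ignore when two
#'   reactions are tested for a shared metabolite.  Matching is
#'   case-insensitive against both id and name;
#'   [currency_metabolites()] is a ready-made default list.
#' @return An [igraph::graph] with vertex attribute `name` (gene id).  A
#'   model without GPR annotations yields an empty graph with a warning.
#' @examples
#' g <- build_enzyme_network(make_toy_model("linear")$model)
#' igraph::ecount(g)
#' @export
build_enzyme_network <- function(model, excluded_metabolites = character(0)) {
  stopifnot(inherits(model, "metabolic_model"))
  genes <- model_genes(model)
  if (length(genes) == 0L) {
    warning("model has no GPR annotations; enzyme network is empty",
            call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  excl <- tolower(excluded_metabolites)
  met_ok <- !(tolower(model$metabolites$id) %in% excl |
              tolower(model$metabolites$name) %in% excl)

  # reaction x gene incidence from GPR leaves
  leaf_sets <- lapply(model$gpr, gpr_genes)
  nr <- nrow(model$reactions)
  RG <- Matrix::sparseMatrix(
    i = rep(seq_len(nr), lengths(leaf_sets)),
    j = match(unlist(leaf_sets, use.names = FALSE), genes),
    x = 1, dims = c(nr, length(genes)))

  # reactions adjacent iff they share a kept metabolite (or are identical)
  RM <- (Matrix::t(model$S[met_ok, , drop = FALSE]) != 0) * 1
  RR <- (RM %*% Matrix::t(RM)) > 0
  Matrix::diag(RR) <- TRUE                    # same-reaction rule
  GG <- (Matrix::t(RG) %*% RR %*% RG) > 0
  Matrix::diag(GG) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(as.matrix(GG), mode = "undirected")
  igraph::V(g)$name <- genes
  g
}

#' Default currency-metabolite exclusion list
#'
#' Name-matched (case-insensitively) against metabolite ids and names when
#' building the enzyme-centric network.
#'
#' @return Character vector of common currency metabolite names.
#' @export
currency_metabolites <- function() {
  c("ATP", "ADP", "AMP", "NAD", "NADH", "NADP", "NADPH", "coenzyme A",
    "CoA", "CO2", "carbon dioxide", "H2O", "water", "H+", "proton",
    "phosphate", "Pi", "diphosphate", "PPi")
}

#' Configuration for centrality computation
#'
#' Houses the constants of the neighbourhood-density and percolation
#' indices: the DMNC exponent `epsilon` (score is
#' `edges(M) / nodes(M)^epsilon` over the largest neighbourhood component
#' `M`), and the Monte-Carlo settings of the edge-percolated component
#' (number of realizations, per-edge retention probability, RNG seed).
#'
#' @param dmnc_epsilon Positive exponent, default 1.7.
#' @param epc_realizations Number of percolation realizations.
#' @param epc_retention_probability Per-edge keep probability in `(0, 1]`.
#' @param seed Integer seed for the percolation draws.
#' @return A list of class `centrality_config`.
#' @export
centrality_config <- function(dmnc_epsilon = 1.7, epc_realizations = 1000,
                              epc_retention_probability = 0.5, seed = 1L) {
  stopifnot(dmnc_epsilon > 0, epc_realizations >= 1,
            epc_retention_probability > 0, epc_retention_probability <= 1)
  structure(list(dmnc_epsilon = dmnc_epsilon,
                 epc_realizations = as.integer(epc_realizations),
                 epc_retention_probability = epc_retention_probability,
                 seed = as.integer(seed)),
            class = "centrality_config")
}

#' Twelve hub-centrality indices
#'
#' Computes, per node of a simple undirected graph, the twelve indices of
#' the CytoHubba family.  Distance-based indices are computed within
#' connected components; unreachable pairs contribute nothing (closeness is
#' the sum of reciprocal distances, so an unreachable pair contributes 0).
#' Degenerate cases (isolated nodes, singleton components) score 0 on every
#' index except EPC, which equals the expected reachable-set size and is at
#' least 1.
#'
#' Definitions, for node `v` with neighbourhood `N(v)` and `M` the largest
#' connected component of the subgraph induced by `N(v)`:
#'
#' * `Degree` - `|N(v)|`.
#' * `MCC` - sum over maximal cliques `C` containing `v` of `(|C|-1)!`;
#'   when `N(v)` has no internal edges this reduces to the degree.
#' * `MNC` - `|M|`.
#' * `DMNC` - `|E(M)| / |M|^epsilon`.
#' * `EPC` - Monte-Carlo mean (seeded) of the number of nodes reachable
#'   from `v` (including `v`) when each edge is retained independently with
#'   the configured probability.  Retention 1 gives the component size
#'   exactly.
#' * `BottleNeck` - over one breadth-first shortest-path tree per root `s`
#'   (parent = smallest-id neighbour one step closer to `s`), the number of
#'   roots for which `v` lies on more than a quarter of the tree's
#'   root-to-node paths; the subtree size of `v` counts the paths through
#'   it (for `v = s`, all `n_s - 1` paths).
#' * `Eccentricity` - max distance to any reachable node (smaller is more
#'   central; see [rank_and_flag()]).
#' * `Closeness` - `sum over u != v of 1 / d(v, u)`.
#' * `Radiality` - `sum over reachable u of (diam_C + 1 - d(v, u)) /
#'   (n_C - 1)` with `diam_C` and `n_C` the component diameter and order.
#' * `Betweenness` - standard shortest-path betweenness (unordered pairs).
#' * `Stress` - number of shortest paths (over unordered pairs) passing
#'   through `v` as an interior node.
#' * `ClusteringCoefficient` - `2 e_N / (k (k - 1))` for degree `k >= 2`,
#'   else 0.
#'
#' @param net An undirected [igraph::graph] with named vertices.
#' @param cfg A [centrality_config()].
#' @return data.frame, one row per node, columns `node` plus the twelve
#'   index names above.
#' @export
compute_centralities <- function(net, cfg = centrality_config()) {
  stopifnot(inherits(net, "igraph"), inherits(cfg, "centrality_config"))
  if (igraph::any_multiple(net) || any(igraph::which_loop(net))) {
    stop("enzyme network must be a simple graph", call. = FALSE)
  }
  n <- igraph::vcount(net)
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  empty <- data.frame(node = character(0))
  if (n == 0L) {
    for (idx in centrality_index_names()) empty[[idx]] <- numeric(0)
    return(empty)
  }
  D <- igraph::distances(net)           # Inf across components
  comp <- igraph::components(net)
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
  deg <- lengths(adj)

  # MCC via maximal cliques
  mcc <- numeric(n)
  for (cl in igraph::max_cliques(net, min = 2)) {
    sz <- length(cl)
    mcc[as.integer(cl)] <- mcc[as.integer(cl)] + factorial(sz - 1)
  }
  # fallback: neighbourhood without internal edges scores the degree
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) == 0L) { mcc[v] <- 0; next }
    internal <- sum(vapply(nb, function(u) length(intersect(adj[[u]], nb)),
                           integer(1))) / 2
    if (internal == 0) mcc[v] <- deg[v]
  }

  mnc <- dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) == 0L) next
    sub <- igraph::induced_subgraph(net, nb)
    cc <- igraph::components(sub)
    big <- which.max(cc$csize)
    members <- which(cc$membership == big)
    M <- igraph::induced_subgraph(sub, members)
    mnc[v] <- length(members)
    dmnc[v] <- igraph::ecount(M) / length(members)^cfg$dmnc_epsilon
  }

  # EPC: seeded Monte-Carlo edge percolation
  set.seed(cfg$seed)
  epc <- numeric(n)
  ne <- igraph::ecount(net)
  for (r in seq_len(cfg$epc_realizations)) {
    keep <- if (ne) stats::runif(ne) <= cfg$epc_retention_probability else logical(0)
    sub <- igraph::subgraph_from_edges(net, which(keep), delete.vertices = FALSE)
    cc <- igraph::components(sub)
    epc <- epc + cc$csize[cc$membership]
  }
  epc <- epc / cfg$epc_realizations

  # BottleNeck over deterministic BFS trees (smallest-id parent)
  bottleneck <- numeric(n)
  for (s in seq_len(n)) {
    reach <- which(is.finite(D[s, ]))
    ns <- length(reach)
    if (ns <= 1L) next
    parent <- rep(NA_integer_, n)
    for (u in reach) {
      if (u == s) next
      pred <- adj[[u]][D[s, adj[[u]]] == D[s, u] - 1]
      parent[u] <- min(pred)
    }
    subtree <- rep(1L, n)                 # paths through v = subtree size
    for (u in reach[order(D[s, reach], decreasing = TRUE)]) {
      if (u == s) next
      subtree[parent[u]] <- subtree[parent[u]] + subtree[u]
    }
    paths_through <- subtree
    paths_through[s] <- ns - 1L
    hit <- reach[paths_through[reach] > ns / 4]
    bottleneck[hit] <- bottleneck[hit] + 1
  }

  ecc <- numeric(n)
  closeness <- numeric(n)
  radiality <- numeric(n)
  for (v in seq_len(n)) {
    dv <- D[v, ]
    fin <- is.finite(dv) & dv > 0
    ecc[v] <- if (any(fin)) max(dv[fin]) else 0
    closeness[v] <- sum(1 / dv[fin])
    members <- which(comp$membership == comp$membership[v])
    nc <- length(members)
    if (nc > 1) {
      diam <- max(D[members, members])
      radiality[v] <- sum(diam + 1 - dv[fin]) / (nc - 1)
    }
  }

  betw <- igraph::betweenness(net, directed = FALSE)
  stress <- stress_centrality(D, adj)
  clust <- igraph::transitivity(net, type = "local", isolates = "zero")

  out <- data.frame(
    node = nodes, MCC = mcc, DMNC = dmnc, MNC = mnc, Degree = as.numeric(deg),
    EPC = epc, BottleNeck = bottleneck, Eccentricity = ecc,
    Closeness = closeness, Radiality = radiality,
    Betweenness = unname(betw), Stress = stress,
    ClusteringCoefficient = clust,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- cfg
  out
}

centrality_index_names <- function() {
  c("MCC", "DMNC", "MNC", "Degree", "EPC", "BottleNeck", "Eccentricity",
    "Closeness", "Radiality", "Betweenness", "Stress",
    "ClusteringCoefficient")
}

# number of shortest paths through each node as interior, from the distance
# matrix and adjacency lists (sigma by dynamic programming over BFS levels)
stress_centrality <- function(D, adj) {
  n <- nrow(D)
  sigma <- matrix(0, n, n)              # sigma[s, t]: # shortest s-t paths
  for (s in seq_len(n)) {
    reach <- which(is.finite(D[s, ]))
    sigma[s, s] <- 1
    for (u in reach[order(D[s, reach])]) {
      if (u == s) next
      pred <- adj[[u]][D[s, adj[[u]]] == D[s, u] - 1]
      sigma[s, u] <- sum(sigma[s, pred])
    }
  }
  stress <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      if (s == v || !is.finite(D[s, v])) next
      ts <- which(is.finite(D[v, ]) & seq_len(n) != v & seq_len(n) != s)
      on_path <- ts[D[s, ts] == D[s, v] + D[v, ts]]
      stress[v] <- stress[v] + sum(sigma[s, v] * sigma[v, on_path])
    }
  }
  stress / 2                            # each unordered pair counted twice
}

#' Rank nodes per centrality index and flag a gene set in the top k
#'
#' Scores are ranked descending (most central first) for every index
#' except `Eccentricity`, where smaller is more central and the ranking is
#' ascending.  Ties are broken by node id (lexicographically smaller id
#' ranks better), making ranks a deterministic permutation.
#'
#' @param table Output of [compute_centralities()].
#' @param gene_set Gene ids to flag (e.g. the down-regulated enzymes of a
#'   condition).
#' @param k Size of the top list.
#' @return List with `ranks` (data.frame of per-index ranks per node),
#'   `top_k` (named list: per index, the members of `gene_set` in the top
#'   `k`) and `k`.  A `gene_set` disjoint from the network yields empty
#'   flags and a warning.
#' @export
rank_and_flag <- function(table, gene_set, k = 100) {
  stopifnot(is.data.frame(table), k >= 1)
  idx_names <- centrality_index_names()
  stopifnot(all(idx_names %in% names(table)))
  present <- intersect(gene_set, table$node)
  if (length(gene_set) && length(present) == 0L) {
    warning("gene_set is disjoint from the network nodes", call. = FALSE)
  }
  ranks <- data.frame(node = table$node, stringsAsFactors = FALSE)
  top <- list()
  for (idx in idx_names) {
    s <- table[[idx]]
    if (idx == "Eccentricity") s <- -s
    ord <- order(-s, table$node)
    rk <- integer(nrow(table))
    rk[ord] <- seq_len(nrow(table))
    ranks[[idx]] <- rk
    topk <- table$node[ord][seq_len(min(k, nrow(table)))]
    top[[idx]] <- intersect(present, topk)
  }
  list(ranks = ranks, top_k = top, k = k)
}

#' Write an enzyme network as an edge-list TSV
#'
#' @param net An [igraph::graph].
#' @param path Output file (two columns, `from` and `to`).
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(net, path) {
  el <- igraph::as_edgelist(net)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an enzyme network as GraphML
#'
#' @param net An [igraph::graph].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
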