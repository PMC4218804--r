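#' Toy metabolic models with known optima
#'
#' Small analytic fixtures exercising every downstream analysis, each
#' returned together with its hand-derived optimal growth so tests never
#' have to trust the solver they are testing:
#'
#' * `"linear"` - uptake `EX_A` (cap `uptake_cap`, gene `gA`), conversion
#'   `R_AB: A -> B` (gene `gB`), biomass drain `BIO: B ->` (gene `gBIO`).
#'   Optimum = `uptake_cap`; every reaction is essential-by-wiring.
#' * `"parallel"` - two isozyme-like branches `R1`, `R2` (genes `g1`, `g2`)
#'   both converting A to B.  Optimum = `uptake_cap`; either branch alone
#'   can carry it.
#' * `"shortlong"` - a one-step route `SHORT: A -> B` (gene `gs`) competing
#'   with a two-step route `L1: A -> C`, `L2: C -> B` (genes `gl1`, `gl2`).
#'   Both reach the optimum, but parsimony routes everything through the
#'   short path.
#' * `"classify"` - shortlong plus a lossy route `ML: 2 A -> B` (gene `gm`,
#'   usable only below optimal growth) and a dead-end reaction
#'   `DEAD: A -> D` (gene `g_dead`, can never carry steady-state flux):
#'   one gene per pFBA category of [classify_genes_pfba()] other than the
#'   unavoidable essential overlap (`gA`, `gBIO`).
#' * `"random"` - a seeded branched network: a linear backbone
#'   `M1 -> ... -> Mk` guaranteeing feasibility with growth
#'   `= uptake_cap > 0`, plus random shortcut reactions (random
#'   directionality, bounds and 1- or 2-gene GPRs).  Same seed, same model.
#'
#' @param topology One of `"linear"`, `"parallel"`, `"shortlong"`,
#'   `"classify"`, `"random"`.
#' @param uptake_cap Uptake bound, mmol gDW^-1 h^-1.
#' @param n_reactions (random) Total reaction count, `>= 3`.
#' @param n_genes (random) Gene pool size.
#' @param subsystems Labels cycled over the non-exchange reactions.
#' @param seed (random) Integer seed.
#' @return List with `model` (a [metabolic_model()]), `optimum` (analytic
#'   optimal growth, `NA` when no closed form is claimed) and `notes`.
#' @export
make_toy_model <- function(topology = c("linear", "parallel", "shortlong",
                                        "classify", "random"),
                           uptake_cap = 10, n_reactions = 8, n_genes = 6,
                           subsystems = c("uptake", "conversion", "biomass"),
                           seed = 1L) {
  topology <- match.arg(topology)
  if (uptake_cap <= 0) stop("uptake_cap must be positive")
  switch(topology,
    linear = toy_linear(uptake_cap),
    parallel = toy_parallel(uptake_cap),
    shortlong = toy_shortlong(uptake_cap),
    classify = toy_classify(uptake_cap),
    random = toy_random(uptake_cap, n_reactions, n_genes, subsystems, seed)
  )
}

toy_linear <- function(cap) {
  m <- metabolic_model(
    "TOY-LIN",
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(
      id = c("EX_A", "R_AB", "BIO"),
      name = c("A uptake", "A to B", "biomass drain"),
      lower_bound = 0, upper_bound = c(cap, 1000, 1000),
      gpr = c("gA", "gB", "gBIO"),
      subsystem = c("uptake", "conversion", "biomass"),
      objective_coefficient = c(0, 0, 1)
    ),
    stoichiometry = list(EX_A = c(A = 1), R_AB = c(A = -1, B = 1),
                         BIO = c(B = -1))
  )
  list(model = m, optimum = cap,
       notes = "single path; optimum = uptake cap; every gene essential")
}

toy_parallel <- function(cap) {
  m <- metabolic_model(
    "TOY-PAR",
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(
      id = c("EX_A", "R1", "R2", "BIO"),
      lower_bound = 0, upper_bound = c(cap, 1000, 1000, 1000),
      gpr = c("gA", "g1", "g2", "gBIO"),
      subsystem = c("uptake", "conversion", "conversion", "biomass"),
      objective_coefficient = c(0, 0, 0, 1)
    ),
    stoichiometry = list(EX_A = c(A = 1), R1 = c(A = -1, B = 1),
                         R2 = c(A = -1, B = 1), BIO = c(B = -1))
  )
  list(model = m, optimum = cap,
       notes = "two redundant branches; v_R1 + v_R2 = cap at optimum")
}

toy_shortlong <- function(cap) {
  m <- metabolic_model(
    "TOY-SHORTLONG",
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(
      id = c("EX_A", "SHORT", "L1", "L2", "BIO"),
      lower_bound = 0, upper_bound = c(cap, 1000, 1000, 1000, 1000),
      gpr = c("gA", "gs", "gl1", "gl2", "gBIO"),
      subsystem = c("uptake", "conversion", "conversion", "conversion",
                    "biomass"),
      objective_coefficient = c(0, 0, 0, 0, 1)
    ),
    stoichiometry = list(EX_A = c(A = 1), SHORT = c(A = -1, B = 1),
                         L1 = c(A = -1, C = 1), L2 = c(C = -1, B = 1),
                         BIO = c(B = -1))
  )
  list(model = m, optimum = cap,
       notes = "pFBA routes all flux through SHORT (total flux cap vs 2 cap)")
}

toy_classify <- function(cap) {
  m <- metabolic_model(
    "TOY-CLASS",
    metabolites = data.frame(id = c("A", "B", "C", "D")),
    reactions = data.frame(
      id = c("EX_A", "SHORT", "L1", "L2", "ML", "DEAD", "BIO"),
      lower_bound = 0,
      upper_bound = c(cap, 1000, 1000, 1000, 1000, 1000, 1000),
      gpr = c("gA", "gs", "gl1", "gl2", "gm", "g_dead", "gBIO"),
      subsystem = c("uptake", "conversion", "conversion", "conversion",
                    "lossy", "dead-end", "biomass"),
      objective_coefficient = c(0, 0, 0, 0, 0, 0, 1)
    ),
    stoichiometry = list(
      EX_A = c(A = 1), SHORT = c(A = -1, B = 1), L1 = c(A = -1, C = 1),
      L2 = c(C = -1, B = 1), ML = c(A = -2, B = 1), DEAD = c(A = -1, D = 1),
      BIO = c(B = -1))
  )
  list(model = m, optimum = cap,
       notes = paste("designed categories: gs pFBA optima; gl1/gl2 ELE;",
                     "gm MLE (2:1 stoichiometry wastes A); g_dead blocked",
                     "(D has no consumer); gA/gBIO essential"))
}

toy_random <- function(cap, n_reactions, n_genes, subsystems, seed) {
  if (n_reactions < 3) stop("random toy models need n_reactions >= 3")
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(seed)
  n_extra <- n_reactions - 3L          # besides EX, one backbone step, BIO
  k <- max(2L, min(n_extra + 2L, 5L))  # backbone metabolites M1..Mk
  n_backbone <- k - 1L
  n_shortcut <- max(0L, n_extra - (n_backbone - 1L))
  mets <- paste0("M", seq_len(k))
  genes <- paste0("g", seq_len(n_genes))

  ids <- "EX"
  sto <- list(EX = stats::setNames(1, "M1"))
  lbs <- 0; ubs <- cap
  for (i in seq_len(n_backbone)) {
    id <- sprintf("B%d", i)
    ids <- c(ids, id)
    sto[[id]] <- stats::setNames(c(-1, 1), c(mets[i], mets[i + 1]))
    lbs <- c(lbs, 0); ubs <- c(ubs, 1000)
  }
  for (i in seq_len(n_shortcut)) {
    id <- sprintf("S%d", i)
    pair <- sort(sample.int(k, 2))
    rev <- stats::runif(1) < 0.4
    ids <- c(ids, id)
    sto[[id]] <- stats::setNames(c(-1, sample(1:2, 1)),
                                 c(mets[pair[1]], mets[pair[2]]))
    lbs <- c(lbs, if (rev) -round(stats::runif(1, 1, 1000)) else 0)
    ubs <- c(ubs, round(stats::runif(1, 1, 1000)))
  }
  ids <- c(ids, "BIO")
  sto$BIO <- stats::setNames(-1, mets[k])
  lbs <- c(lbs, 0); ubs <- c(ubs, 1000)

  gpr <- vapply(ids, function(id) {
    if (id %in% c("EX", "BIO")) return("")
    gs <- sample(genes, min(sample(1:2, 1), n_genes))
    if (length(gs) == 1) gs
    else paste(gs, collapse = if (stats::runif(1) < 0.5) " and " else " or ")
  }, character(1))

  m <- metabolic_model(
    sprintf("TOY-RND-%d", seed),
    metabolites = data.frame(id = mets),
    reactions = data.frame(
      id = ids, lower_bound = lbs, upper_bound = ubs, gpr = unname(gpr),
      subsystem = rep_len(subsystems, length(ids)),
      objective_coefficient = as.numeric(ids == "BIO")
    ),
    stoichiometry = sto
  )
  list(model = m, optimum = NA_real_,
       notes = "seeded branched network; backbone guarantees growth >= cap > 0")
}

#' Simulate a planted differential-expression data set
#'
#' Gaussian log2-scale model matching the interface the pipeline consumes
#' (already-normalized gene-level values): each gene draws a baseline mean
#' from `Normal(baseline_mean, baseline_sd)`; samples add
#' `Normal(0, noise_sd)` noise; mutant samples of planted genes are shifted
#' by `planted_lfc` (negative = down-regulated).
#'
#' @param genes Character vector of gene ids.
#' @param planted_genes Subset of `genes` carrying the shift.
#' @param planted_lfc Log2 fold change of planted genes (scalar or one per
#'   planted gene).
#' @param n_wt,n_mut Samples per group.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution (log2).
#' @param noise_sd Per-sample noise (log2).
#' @param paired_noise When `TRUE` (requires `n_wt == n_mut`), mutant
#'   samples reuse the wild-type noise draws, so the observed group-mean
#'   difference equals the planted fold change exactly while within-group
#'   variance stays at `noise_sd`; used by analytic fixtures whose expected
#'   downstream growth must have a closed form.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return List with `data` (an [expression_data()]) and `truth`
#'   (data.frame `gene`, `planted_lfc` for the planted set).
#' @export
simulate_expression <- function(genes, planted_genes = character(0),
                                planted_lfc = -2, n_wt = 4, n_mut = 4,
                                baseline_mean = 8, baseline_sd = 1,
                                noise_sd = 0.5, paired_noise = FALSE,
                                seed = 1L) {
  stopifnot(noise_sd > 0, baseline_sd >= 0)
  if (!all(planted_genes %in% genes)) {
    stop("planted genes must be a subset of 'genes'")
  }
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  if (paired_noise && n_wt != n_mut) {
    stop("paired_noise requires n_wt == n_mut")
  }
  set.seed(seed)
  ng <- length(genes)
  ns <- n_wt + n_mut
  base <- stats::rnorm(ng, baseline_mean, baseline_sd)
  noise <- matrix(stats::rnorm(ng * ns, 0, noise_sd), ng, ns)
  if (paired_noise) noise[, n_wt + seq_len(n_mut)] <- noise[, seq_len(n_wt)]
  vals <- noise + base
  lfc <- rep_len(planted_lfc, length(planted_genes))
  i <- match(planted_genes, genes)
  vals[i, n_wt + seq_len(n_mut)] <- vals[i, n_wt + seq_len(n_mut), drop = FALSE] + lfc
  colnames(vals) <- c(paste0("WT_", seq_len(n_wt)), paste0("MUT_", seq_len(n_mut)))
  rownames(vals) <- genes
  list(
    data = expression_data(vals, rep(c("WT", "MUT"), c(n_wt, n_mut))),
    truth = data.frame(gene = planted_genes, planted_lfc = lfc,
                       stringsAsFactors = FALSE)
  )
}

#' Write a complete end-to-end fixture bundle
#'
#' Emits a directory a new user (or an integration test) can run the whole
#' pipeline on: `model.xml` (SBML), `expression.tsv`, `samples.tsv` and
#' `truth.json` recording the planted fold changes, the reactions expected
#' to be valve-constrained, and - for the `"linear"` topology, where it has
#' a closed form - the expected post-valve growth
#' `cap * min(1, min 2^planted_lfc over genes on the chain)`.
#'
#' @param dir Output directory (created if missing).
#' @param topology Toy topology for [make_toy_model()].
#' @param planted_genes,planted_lfc Planted down-regulation passed to
#'   [simulate_expression()]; genes must exist in the toy model's GPRs (a
#'   planted gene outside the model is allowed but recorded as unmapped).
#' @param uptake_cap,n_wt,n_mut,noise_sd,seed Passed through to the
#'   generators.
#' @return List with the file paths and the `truth` list, invisibly usable
#'   as the bundle manifest.
#' @export
end_to_end_fixture <- function(dir, topology = "linear",
                               planted_genes = character(0),
                               planted_lfc = -1, uptake_cap = 10,
                               n_wt = 4, n_mut = 4, noise_sd = 0.2,
                               seed = 1L) {
  toy <- make_toy_model(topology, uptake_cap = uptake_cap, seed = seed)
  model <- toy$model
  genes <- model_genes(model)
  sim <- simulate_expression(genes, planted_genes = intersect(planted_genes, genes),
                             planted_lfc = planted_lfc, n_wt = n_wt,
                             n_mut = n_mut, noise_sd = noise_sd,
                             paired_noise = TRUE, seed = seed)
  unmapped <- setdiff(planted_genes, genes)
  if (length(unmapped)) {
    message("planted gene(s) not in model GPRs: ",
            paste(unmapped, collapse = ", "))
  }

  mapped <- intersect(planted_genes, genes)
  expected_rxns <- if (length(mapped)) {
    sort(unique(unlist(genes_to_reactions(model, mapped), use.names = FALSE)))
  } else character(0)
  expected_growth <- if (topology == "linear") {
    lfc <- rep_len(planted_lfc, length(planted_genes))
    phis <- 2^lfc[planted_genes %in% genes]
    uptake_cap * min(1, phis)
  } else NA_real_

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model_path <- file.path(dir, "model.xml")
  expr_path <- file.path(dir, "expression.tsv")
  samples_path <- file.path(dir, "samples.tsv")
  truth_path <- file.path(dir, "truth.json")

  write_sbml(model, model_path)
  vals <- sim$data$values
  utils::write.table(
    data.frame(gene = rownames(vals), vals, check.names = FALSE),
    expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(vals), group = sim$data$groups),
    samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    topology = topology,
    uptake_cap = uptake_cap,
    base_optimum = toy$optimum,
    planted = sim$truth,
    unmapped_planted_genes = unmapped,
    expected_constrained_reactions = expected_rxns,
    expected_growth = expected_growth,
    seed = seed
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(dir = dir, model = model_path, expression = expr_path,
                 samples = samples_path, truth_json = truth_path,
                 truth = truth))
}
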