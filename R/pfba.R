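#' Parsimonious FBA
#'
#' Two-stage solve: FBA fixes the optimal objective `f*`; a second LP then
#' holds the objective at `f* (1 - 1e-6)` or better and minimizes the total
#' absolute flux through the minimized reaction set (by default every
#' gene-associated reaction, the classic pFBA choice; pass all reaction ids
#' to obtain a fully parsimonious flux vector).  Absolute values are
#' linearized by splitting each minimized flux into positive and negative
#' parts.
#'
#' @param model A [metabolic_model()].
#' @param minimized_reactions Reaction ids whose total |flux| is minimized;
#'   default [gene_associated_reactions()] (all reactions if the model has
#'   no GPR annotations at all).
#' @param relative_tol Allowed relative slip of the objective below `f*`.
#' @return A `flux_solution` (see [fba()]) whose `objective` equals the FBA
#'   optimum within `relative_tol`, with an extra element `total_flux`: the
#'   minimized sum of absolute fluxes.
#' @examples
#' m <- make_toy_model("shortlong")$model
#' sol <- pfba(m)
#' sol$fluxes  # the two-step route is idle; the one-step route carries all
#' @export
pfba <- function(model, minimized_reactions = NULL, relative_tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(minimized_reactions)) {
    minimized_reactions <- gene_associated_reactions(model)
    if (length(minimized_reactions) == 0L) {
      minimized_reactions <- model$reactions$id
    }
  }
  midx <- rxn_index(model, minimized_reactions)

  base <- fba(model)
  if (!identical(base$status, "optimal")) {
    stop("pFBA requires a solvable model; FBA status: ", base$status,
         call. = FALSE)
  }
  fstar <- base$objective
  target <- fstar - relative_tol * max(1, abs(fstar))

  S <- as.matrix(model$S)
  m <- nrow(S)
  n <- ncol(S)
  k <- length(midx)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  big <- max(abs(c(lb, ub))) + 1

  # columns: v (n) | p (k) | q (k) | s (1); rows: S v = 0, v_i - p_i + q_i = 0,
  # c'v - s = target
  A <- matrix(0, m + k + 1, n + 2 * k + 1)
  A[seq_len(m), seq_len(n)] <- S
  for (j in seq_len(k)) {
    A[m + j, midx[j]] <- 1
    A[m + j, n + j] <- -1
    A[m + j, n + k + j] <- 1
  }
  A[m + k + 1, seq_len(n)] <- model$reactions$objective_coefficient
  A[m + k + 1, n + 2 * k + 1] <- -1
  b <- c(numeric(m + k), target)
  lb2 <- c(lb, numeric(2 * k), 0)
  ub2 <- c(ub, rep(big, 2 * k), abs(fstar) * relative_tol * 2 + 1)
  obj <- c(numeric(n), rep(1, 2 * k), 0)

  res <- solve_lp(obj, A, b, lb2, ub2, maximize = FALSE)
  if (!identical(res$status, "optimal")) {
    stop("pFBA stage 2 failed with status ", res$status, call. = FALSE)
  }
  v <- res$x[seq_len(n)]
  sol <- new_flux_solution(
    list(objective = sum(model$reactions$objective_coefficient * v),
         x = v,
         y = res$y[seq_len(m)],
         w = res$w[seq_len(n)],
         status = "optimal"),
    model
  )
  sol$total_flux <- res$objective
  sol
}

#' Six-way pFBA gene classification
#'
#' Every gene-associated gene is placed in exactly one category, assigned in
#' this priority order:
#'
#' 1. `essential` - deleting the gene drops growth below
#'    `essentiality_cutoff` times wild type ([single_gene_deletion()]);
#' 2. `blocked` - none of the gene's reactions can carry any flux even with
#'    the objective requirement removed ([fva()] at fraction 0);
#' 3. `pFBA optima` - at least one of its reactions carries flux in the
#'    parsimonious optimal solution;
#' 4. `ELE` (enzymatically less efficient) - some reaction could carry flux
#'    at optimal growth (nonzero FVA range at fraction 1) yet the
#'    parsimonious solution leaves them all idle;
#' 5. `MLE` (metabolically less efficient) - its reactions can carry flux
#'    only below optimal growth (nonzero range at fraction 0, zero range at
#'    fraction 1);
#' 6. `pFBA no-flux` - anything left.
#'
#' @param model A [metabolic_model()].
#' @param essentiality_cutoff Growth-ratio threshold for `essential`.
#' @param tol Flux magnitude treated as zero.
#' @return data.frame with columns `gene` and `category` (factor with the
#'   six levels above).
#' @export
classify_genes_pfba <- function(model, essentiality_cutoff = 0.01, tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  genes <- model_genes(model)
  if (length(genes) == 0L) {
    return(data.frame(gene = character(0),
                      category = factor(character(0), levels = pfba_categories())))
  }
  g2r <- genes_to_reactions(model, genes)
  del <- single_gene_deletion(model, genes = genes,
                              essentiality_cutoff = essentiality_cutoff)
  psol <- pfba(model)
  fva1 <- fva(model, fraction_of_optimum = 1)
  fva0 <- fva(model, fraction_of_optimum = 0)
  rng1 <- stats::setNames(pmax(abs(fva1$min), abs(fva1$max)), fva1$reaction)
  rng0 <- stats::setNames(pmax(abs(fva0$min), abs(fva0$max)), fva0$reaction)

  cat_of <- function(g) {
    rxns <- g2r[[g]]
    if (del$essential[del$gene == g]) return("essential")
    if (all(rng0[rxns] <= tol)) return("blocked")
    if (any(abs(psol$fluxes[rxns]) > tol)) return("pFBA optima")
    if (any(rng1[rxns] > tol)) return("ELE")
    if (any(rng0[rxns] > tol & rng1[rxns] <= tol)) return("MLE")
    "pFBA no-flux"
  }
  data.frame(
    gene = genes,
    category = factor(vapply(genes, cat_of, character(1)),
                      levels = pfba_categories()),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

pfba_categories <- function() {
  c("essential", "pFBA optima", "ELE", "MLE", "pFBA no-flux", "blocked")
}
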