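#' Construct a metabolic model
#'
#' The central container: a stoichiometric matrix over metabolites and
#' reactions, flux bounds in mmol gDW^-1 h^-1, GPR rules, subsystem labels
#' and an objective (biomass by convention).  All downstream analyses (FBA,
#' FVA, pFBA, deletions, valve integration, the enzyme network) consume this
#' class.
#'
#' @param id Model identifier.
#' @param metabolites data.frame with columns `id` (unique, non-empty),
#'   optional `name` and `compartment`.
#' @param reactions data.frame with columns `id` (unique), optional `name`,
#'   `lower_bound`, `upper_bound` (default `[-1000, 1000]` for reversible
#'   conventions; pass explicit values), `gpr` (rule string, `""` for none),
#'   `subsystem`, `objective_coefficient`.
#' @param stoichiometry named list, one element per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @return An object of class `metabolic_model`: a list with `id`,
#'   `metabolites`, `reactions`, sparse matrix `S` (metabolites x reactions)
#'   and `gpr`, a named list of parsed [parse_gpr()] expressions.
#' @examples
#' m <- metabolic_model(
#'   "mini",
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = data.frame(
#'     id = c("EX_A", "R_AB", "BIO"),
#'     lower_bound = 0, upper_bound = c(10, 1000, 1000),
#'     gpr = c("gA", "gB", ""),
#'     objective_coefficient = c(0, 0, 1)
#'   ),
#'   stoichiometry = list(EX_A = c(A = 1), R_AB = c(A = -1, B = 1),
#'                        BIO = c(B = -1))
#' )
#' model_stats(m)
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry) {
  stopifnot(is.character(id), length(id) == 1L)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!"id" %in% names(metabolites)) stop("metabolites need an 'id' column")
  if (!"id" %in% names(reactions)) stop("reactions need an 'id' column")
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  if (any(!nzchar(metabolites$id))) stop("empty metabolite id")
  if (any(!nzchar(reactions$id))) stop("empty reaction id")

  defaults <- list(name = "", lower_bound = -1000, upper_bound = 1000,
                   gpr = "", subsystem = "", objective_coefficient = 0)
  for (col in names(defaults)) {
    if (!col %in% names(reactions)) reactions[[col]] <- defaults[[col]]
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""

  bad <- reactions$lower_bound > reactions$upper_bound
  if (any(bad)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(reactions$id[bad], collapse = ", "))
  }

  canon <- c("id", "name", "lower_bound", "upper_bound", "gpr", "subsystem",
             "objective_coefficient")
  reactions <- reactions[, c(canon, setdiff(names(reactions), canon))]

  missing_rxn <- setdiff(reactions$id, names(stoichiometry))
  if (length(missing_rxn)) {
    stop("no stoichiometry for reaction(s): ", paste(missing_rxn, collapse = ", "))
  }
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  for (j in seq_len(nrow(reactions))) {
    sto <- stoichiometry[[reactions$id[j]]]
    if (length(sto) == 0) next
    unknown <- setdiff(names(sto), metabolites$id)
    if (length(unknown)) {
      stop("reaction ", reactions$id[j], " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    i <- match(names(sto), metabolites$id)
    trip$i <- c(trip$i, i)
    trip$j <- c(trip$j, rep.int(j, length(i)))
    trip$x <- c(trip$x, as.numeric(sto))
  }
  S <- Matrix::sparseMatrix(
    i = trip$i, j = trip$j, x = trip$x,
    dims = c(nrow(metabolites), nrow(reactions)),
    dimnames = list(metabolites$id, reactions$id)
  )

  gpr <- lapply(reactions$gpr, parse_gpr)
  names(gpr) <- reactions$id

  structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         S = S, gpr = gpr),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  st <- model_stats(x)
  cat(sprintf(
    "<metabolic_model> %s: %d metabolites, %d reactions (%d irreversible), %d genes, %d subsystems\n",
    x$id, st$metabolites, st$reactions, st$irreversible, st$genes, st$subsystems))
  obj <- x$reactions$id[x$reactions$objective_coefficient != 0]
  cat("  objective:", if (length(obj)) paste(obj, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Genes of a model
#'
#' The gene set is the union of all GPR leaves; a model may carry reactions
#' with no gene association (e.g. exchanges), which contribute nothing.
#'
#' @param model A [metabolic_model()].
#' @return Sorted character vector of gene ids.
#' @export
model_genes <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  sort(unique(unlist(lapply(model$gpr, gpr_genes), use.names = FALSE)))
}

#' Summary counts for a model
#'
#' A reaction is counted irreversible when its lower bound is non-negative
#' (it can only run forward).
#'
#' @param model A [metabolic_model()].
#' @return A list with `genes`, `reactions`, `irreversible`, `metabolites`
#'   and `subsystems` counts.
#' @export
model_stats <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  list(
    genes = length(model_genes(model)),
    reactions = nrow(model$reactions),
    irreversible = sum(model$reactions$lower_bound >= 0),
    metabolites = nrow(model$metabolites),
    subsystems = length(setdiff(unique(model$reactions$subsystem), ""))
  )
}

#' Map genes to the reactions they catalyse
#'
#' A gene maps to every reaction whose GPR mentions it as a leaf,
#' irrespective of AND/OR structure (this is the GPR expansion used to turn
#' down-regulated genes into down-regulated reactions).  Genes absent from
#' every rule map to the empty set with a warning.
#'
#' @param model A [metabolic_model()].
#' @param genes Character vector of gene ids (default: all model genes).
#' @return Named list, one character vector of reaction ids per queried gene.
#' @export
genes_to_reactions <- function(model, genes = model_genes(model)) {
  stopifnot(inherits(model, "metabolic_model"))
  leaf_sets <- lapply(model$gpr, gpr_genes)
  out <- lapply(genes, function(g) {
    hits <- names(leaf_sets)[vapply(leaf_sets, function(s) g %in% s, logical(1))]
    as.character(hits)
  })
  names(out) <- genes
  absent <- genes[lengths(out) == 0L]
  if (length(absent)) {
    warning("gene(s) not present in any GPR rule: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  out
}

#' Reactions with a gene association
#'
#' @param model A [metabolic_model()].
#' @return Character vector of reaction ids whose GPR is non-empty.
#' @export
gene_associated_reactions <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  model$reactions$id[vapply(model$gpr, function(e) e$op != "empty", logical(1))]
}

rxn_index <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (anyNA(i)) {
    stop("unknown reaction id(s): ",
         paste(reaction_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Replace the objective of a model
#'
#' @param model A [metabolic_model()].
#' @param reaction_id Reaction to optimize.
#' @param coefficient Objective coefficient (default 1).
#' @return A new model whose only objective reaction is `reaction_id`.
#' @export
set_objective <- function(model, reaction_id, coefficient = 1) {
  i <- rxn_index(model, reaction_id)
  model$reactions$objective_coefficient <- 0
  model$reactions$objective_coefficient[i] <- coefficient
  model
}

#' Change flux bounds of a reaction
#'
#' @param model A [metabolic_model()].
#' @param reaction_id Reaction to modify.
#' @param lower_bound,upper_bound New bounds; `NULL` keeps the current value.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_id, lower_bound = NULL, upper_bound = NULL) {
  i <- rxn_index(model, reaction_id)
  if (!is.null(lower_bound)) model$reactions$lower_bound[i] <- lower_bound
  if (!is.null(upper_bound)) model$reactions$upper_bound[i] <- upper_bound
  if (any(model$reactions$lower_bound[i] > model$reactions$upper_bound[i]))
    stop("lower_bound > upper_bound for ", reaction_id, call. = FALSE)
  model
}

objective_vector <- function(model) {
  stats::setNames(model$reactions$objective_coefficient, model$reactions$id)
}
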