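#' Flux balance analysis
#'
#' Maximizes the model objective `c'v` subject to steady-state mass balance
#' `S v = 0` and the flux bounds.  The solution mirrors the classic COBRA
#' output quartet: optimal objective `f`, flux vector `x`, shadow prices `y`
#' (one per metabolite: the marginal value of relaxing its mass balance) and
#' reduced costs `w` (one per reaction).
#'
#' @param model A [metabolic_model()] with at least one reaction of nonzero
#'   objective coefficient.
#' @return An object of class `flux_solution`: list with `objective`,
#'   `fluxes` (named), `shadow_prices` (named by metabolite),
#'   `reduced_costs` (named by reaction) and `status`.  An infeasible or
#'   unbounded model is reported in `status`, never silently.
#' @examples
#' m <- make_toy_model("linear")$model
#' sol <- fba(m)
#' sol$objective  # 10: the uptake cap limits growth
#' @export
fba <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  obj <- model$reactions$objective_coefficient
  if (all(obj == 0)) {
    stop("model '", model$id, "' has no objective reaction", call. = FALSE)
  }
  res <- solve_lp(obj, as.matrix(model$S),
                  lb = model$reactions$lower_bound,
                  ub = model$reactions$upper_bound,
                  maximize = TRUE)
  new_flux_solution(res, model)
}

new_flux_solution <- function(res, model) {
  structure(
    list(objective = res$objective,
         fluxes = stats::setNames(res$x, model$reactions$id),
         shadow_prices = stats::setNames(res$y[seq_len(nrow(model$metabolites))],
                                         model$metabolites$id),
         reduced_costs = stats::setNames(res$w[seq_len(nrow(model$reactions))],
                                         model$reactions$id),
         status = res$status),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status)
  if (identical(x$status, "optimal")) {
    cf <- count_carrying_flux(x)
    cat(sprintf(", objective f = %.6g, carrying-flux reactions: %d (%d+, %d-)",
                x$objective, cf$total, cf$positive, cf$negative))
  }
  cat("\n")
  invisible(x)
}

#' Count carrying-flux reactions
#'
#' A reaction carries flux when its optimal flux exceeds `tol` in magnitude;
#' positive and negative carriers are counted separately (the sign encodes
#' the direction a reversible reaction runs in).
#'
#' @param sol A [fba()] (or [pfba()]) solution with status `"optimal"`.
#' @param tol Magnitude below which a flux counts as zero.
#' @return List with `total`, `positive` and `negative` counts.
#' @export
count_carrying_flux <- function(sol, tol = 1e-9) {
  stopifnot(inherits(sol, "flux_solution"))
  if (!identical(sol$status, "optimal")) {
    stop("cannot count carrying flux: solution status is ", sol$status,
         call. = FALSE)
  }
  pos <- sum(sol$fluxes > tol)
  neg <- sum(sol$fluxes < -tol)
  list(total = pos + neg, positive = pos, negative = neg)
}

#' Maximal attainable flux through one reaction
#'
#' Re-points the objective at a single target reaction (coefficient 1),
#' forces the target's lower bound to zero so only forward production is
#' scored, and runs FBA.  Used for metabolite-turnover questions such as the
#' maximal acetyl-CoA synthetase / carboxylase fluxes of a condition model;
#' both of those reactions are irreversible, hence the zero lower bound.
#' The input model is not modified.
#'
#' @param model A [metabolic_model()].
#' @param reaction_id Target reaction id.
#' @return A `flux_solution` for the swapped objective, with attribute
#'   `"provenance"` recording the target and its original bounds.
#' @export
maximize_reaction_objective <- function(model, reaction_id) {
  i <- rxn_index(model, reaction_id)
  old <- model$reactions[i, c("lower_bound", "upper_bound")]
  if (model$reactions$upper_bound[i] < 0) {
    stop("reaction ", reaction_id,
         " has a negative upper bound; cannot force forward flux",
         call. = FALSE)
  }
  m2 <- set_objective(model, reaction_id)
  m2 <- set_bounds(m2, reaction_id, lower_bound = 0)
  sol <- fba(m2)
  attr(sol, "provenance") <- list(reaction = reaction_id,
                                  old_lower = old$lower_bound,
                                  old_upper = old$upper_bound)
  sol
}
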