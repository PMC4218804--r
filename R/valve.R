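#' Parsimonious wild-type reference flux state
#'
#' FBA optima are typically degenerate, so the raw FBA flux vector is not a
#' reproducible reference.  This solve fixes the objective at its optimum
#' and then minimizes the total absolute flux over *all* reactions, giving a
#' deterministic reference vector from which valve constraints are scaled.
#'
#' @param model A [metabolic_model()] with an objective.
#' @return Object of class `reference_flux_state`: list with `fluxes`
#'   (named, satisfies `S v = 0`), `objective` (the wild-type growth
#'   `f_WT`) and `model_id`.
#' @export
compute_reference_fluxes <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  sol <- pfba(model, minimized_reactions = model$reactions$id,
              relative_tol = 0)
  structure(
    list(fluxes = sol$fluxes, objective = sol$objective, model_id = model$id),
    class = "reference_flux_state"
  )
}

#' @export
print.reference_flux_state <- function(x, ...) {
  cat(sprintf("<reference_flux_state> model %s, f_WT = %.6g, %d reactions\n",
              x$model_id, x$objective, length(x$fluxes)))
  invisible(x)
}

#' Valve scaling factor from a log2 fold change
#'
#' The valve rule scales a reaction's reference flux by `2^fold_change`,
#' i.e. a fold change of -2 leaves one quarter of the wild-type flux and a
#' fold change of 0 leaves it untouched.  Up-regulation (positive fold
#' change) is excluded from valve integration - widening a bound cannot
#' change an FBA optimum - and is rejected here.
#'
#' @param fold_change Numeric log2 fold change(s), all `<= 0`.
#' @return `2^fold_change`, in `(0, 1]`.
#' @examples
#' scaling_factor(-2)  # 0.25
#' @export
scaling_factor <- function(fold_change) {
  if (any(fold_change > 0)) {
    stop("positive fold change(s) passed to scaling_factor(); ",
         "up-regulated genes are excluded from valve integration",
         call. = FALSE)
  }
  2^fold_change
}

#' Apply valve constraints to a model
#'
#' For each reaction `r` in `fc_map` with factor `phi = 2^FC` and reference
#' flux `v` from `ref`:
#'
#' * `mode = "cap"` (default): the reaction is confined to the sign of its
#'   reference flux and capped at the scaled magnitude - `v > 0` gives
#'   bounds `[0, phi v]`, `v < 0` gives `[phi v, 0]`, and `v = 0` scales the
#'   original bounds by `phi` so the valve still bites on reactions the
#'   reference solution does not use.
#' * `mode = "fixed"`: both bounds are set to `phi v` (the literal
#'   both-bounds reading).  Fixing many fluxes simultaneously generically
#'   renders a model infeasible, so this mode exists for fidelity
#'   experiments rather than as the default.
#'
#' All other reactions keep their bounds; in cap mode the constrained model's
#' feasible set is a subset of the base model's, so its growth can only drop.
#'
#' @param model The base [metabolic_model()].
#' @param ref [compute_reference_fluxes()] of the same model.
#' @param fc_map Named numeric vector, reaction id -> log2 fold change
#'   (all `<= 0`), e.g. from [assign_reaction_fold_changes()].
#' @param mode `"cap"` or `"fixed"`.
#' @return Object of class `constrained_model`: the derived
#'   `metabolic_model` plus `$provenance`, a data.frame recording per
#'   constrained reaction the reference flux, fold change, factor and old /
#'   new bounds.
#' @examples
#' toy <- make_toy_model("linear")
#' ref <- compute_reference_fluxes(toy$model)
#' cm <- apply_valve_constraints(toy$model, ref, c(R_AB = -1))
#' fba(cm)$objective  # 5: half the wild-type optimum of 10
#' @export
apply_valve_constraints <- function(model, ref, fc_map,
                                    mode = c("cap", "fixed")) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(ref, "reference_flux_state"))
  mode <- match.arg(mode)
  if (length(fc_map) > 0 && is.null(names(fc_map))) {
    stop("fc_map must be a named vector (reaction id -> fold change)")
  }
  if (any(fc_map > 0)) {
    stop("positive fold change(s) in fc_map: ",
         paste(names(fc_map)[fc_map > 0], collapse = ", "), call. = FALSE)
  }
  if (!all(names(fc_map) %in% model$reactions$id)) {
    stop("fc_map references unknown reaction(s): ",
         paste(setdiff(names(fc_map), model$reactions$id), collapse = ", "),
         call. = FALSE)
  }
  if (!all(model$reactions$id %in% names(ref$fluxes))) {
    stop("reference flux state does not cover this model", call. = FALSE)
  }

  prov <- data.frame(reaction = character(0), reference_flux = numeric(0),
                     fold_change = numeric(0), factor = numeric(0),
                     old_lb = numeric(0), old_ub = numeric(0),
                     new_lb = numeric(0), new_ub = numeric(0),
                     stringsAsFactors = FALSE)
  out <- model
  for (r in names(fc_map)) {
    i <- rxn_index(model, r)
    fc <- fc_map[[r]]
    phi <- scaling_factor(fc)
    v <- ref$fluxes[[r]]
    old_lb <- model$reactions$lower_bound[i]
    old_ub <- model$reactions$upper_bound[i]
    if (mode == "fixed") {
      new_lb <- new_ub <- phi * v
    } else if (v > 0) {
      new_lb <- 0; new_ub <- phi * v
    } else if (v < 0) {
      new_lb <- phi * v; new_ub <- 0
    } else {
      new_lb <- phi * old_lb; new_ub <- phi * old_ub
    }
    out$reactions$lower_bound[i] <- new_lb
    out$reactions$upper_bound[i] <- new_ub
    prov <- rbind(prov, data.frame(
      reaction = r, reference_flux = v, fold_change = fc, factor = phi,
      old_lb = old_lb, old_ub = old_ub, new_lb = new_lb, new_ub = new_ub,
      stringsAsFactors = FALSE))
  }
  out$id <- paste0(model$id, "_valve")
  out$provenance <- prov
  class(out) <- c("constrained_model", "metabolic_model")
  out
}

#' @export
print.constrained_model <- function(x, ...) {
  NextMethod()
  cat(sprintf("  valve-constrained reactions: %d\n", nrow(x$provenance)))
  invisible(x)
}

#' Write valve provenance as TSV
#'
#' @param cm A [apply_valve_constraints()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_provenance_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "constrained_model"))
  utils::write.table(cm$provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
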