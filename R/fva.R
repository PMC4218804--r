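#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux compatible with the
#' objective held at at least `fraction_of_optimum` times its FBA optimum.
#' The spread `max - min` is the reaction's flux capacity; comparing
#' capacities between a wild-type and a condition model locates where the
#' transcriptional constraint widened or narrowed the attainable flux range.
#'
#' With `fraction_of_optimum = 0` the objective requirement is dropped
#' entirely (not merely scaled to zero), which is the setting used to detect
#' blocked reactions: a reaction that cannot carry flux under mass balance
#' and bounds alone.
#'
#' @param model A [metabolic_model()].
#' @param fraction_of_optimum Required fraction of the optimal objective,
#'   in `[0, 1]`.
#' @param reactions Reactions to scan (default: all).
#' @return Object of class `fva_result`: data.frame with columns `reaction`,
#'   `min`, `max`, `capacity`; the enforced objective value is stored in
#'   attribute `"objective_floor"` (`NA` when the requirement was dropped).
#' @examples
#' m <- make_toy_model("parallel")$model
#' fva(m)   # each parallel branch alone spans [0, 10] at the optimum
#' @export
fva <- function(model, fraction_of_optimum = 1.0, reactions = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  if (is.null(reactions)) reactions <- model$reactions$id
  idx <- rxn_index(model, reactions)

  S <- as.matrix(model$S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- length(lb)

  if (fraction_of_optimum > 0) {
    base <- fba(model)
    if (!identical(base$status, "optimal")) {
      stop("FVA requires a solvable model; FBA status: ", base$status,
           call. = FALSE)
    }
    floor_val <- fraction_of_optimum * base$objective
    big <- sum(abs(c(lb, ub))) + abs(floor_val) + 1
    # c'v - s = floor, s >= 0  <=>  c'v >= floor
    A <- rbind(cbind(S, 0),
               c(model$reactions$objective_coefficient, -1))
    b <- c(numeric(nrow(S)), floor_val)
    lb2 <- c(lb, 0)
    ub2 <- c(ub, big)
  } else {
    floor_val <- NA_real_
    A <- S
    b <- numeric(nrow(S))
    lb2 <- lb
    ub2 <- ub
  }

  nvar <- ncol(A)
  mins <- maxs <- numeric(length(idx))
  for (k in seq_along(idx)) {
    e <- numeric(nvar)
    e[idx[k]] <- 1
    lo <- solve_lp(e, A, b, lb2, ub2, maximize = FALSE)
    hi <- solve_lp(e, A, b, lb2, ub2, maximize = TRUE)
    if (!identical(lo$status, "optimal") || !identical(hi$status, "optimal")) {
      stop("FVA subproblem failed for reaction ", reactions[k],
           " (status ", lo$status, "/", hi$status, ")", call. = FALSE)
    }
    mins[k] <- lo$objective
    maxs[k] <- hi$objective
  }
  out <- data.frame(reaction = reactions, min = mins, max = maxs,
                    capacity = maxs - mins, stringsAsFactors = FALSE)
  attr(out, "objective_floor") <- floor_val
  attr(out, "fraction_of_optimum") <- fraction_of_optimum
  class(out) <- c("fva_result", "data.frame")
  out
}

#' Compare flux capacities between two models
#'
#' Per reaction, `delta = capacity_mutant - capacity_wt`: positive values
#' mean the condition model gained flux capacity relative to wild type,
#' negative values mean it lost capacity.  Subsystems are then listed as
#' increased when at least one member reaction gained more than `tol`, and
#' decreased when at least one lost more than `tol`; a subsystem with
#' divergent members appears in both lists.
#'
#' @param wt,mut [fva()] results over the same reaction set.
#' @param model The model supplying subsystem annotations.
#' @param tol Capacity change below which a reaction is considered unchanged.
#' @return List with `per_reaction` (data.frame `reaction`, `subsystem`,
#'   `capacity_wt`, `capacity_mut`, `delta`), `increased_subsystems` and
#'   `decreased_subsystems` (character vectors, unlabeled subsystems
#'   excluded).
#' @export
compare_capacity <- function(wt, mut, model, tol = 1e-6) {
  stopifnot(inherits(wt, "data.frame"), inherits(mut, "data.frame"),
            inherits(model, "metabolic_model"))
  if (!identical(sort(wt$reaction), sort(mut$reaction))) {
    stop("FVA results cover different reaction sets", call. = FALSE)
  }
  mut <- mut[match(wt$reaction, mut$reaction), ]
  sub <- model$reactions$subsystem[rxn_index(model, wt$reaction)]
  per <- data.frame(
    reaction = wt$reaction,
    subsystem = sub,
    capacity_wt = wt$capacity,
    capacity_mut = mut$capacity,
    delta = mut$capacity - wt$capacity,
    stringsAsFactors = FALSE
  )
  lab <- nzchar(per$subsystem)
  list(
    per_reaction = per,
    increased_subsystems = sort(unique(per$subsystem[lab & per$delta > tol])),
    decreased_subsystems = sort(unique(per$subsystem[lab & per$delta < -tol]))
  )
}
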