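#' Run the full valve-integration workflow
#'
#' Orchestrates, against a single wild-type reference: differential
#' expression per condition, gene-to-reaction fold-change mapping, valve
#' constraint construction, and the downstream analyses - FBA growth and
#' carrying-flux counts, FVA capacity comparison per subsystem, pFBA
#' six-way classification and deletion scan of the down-regulated genes,
#' targeted reaction-objective maximization, and top-k centrality flags of
#' the down-regulated enzymes in the enzyme-centric network.
#'
#' @param model A [metabolic_model()] or a path to an SBML file.
#' @param conditions Named list (labels are condition names).  Each element
#'   is either an [expression_data()] object or a list with `expression`
#'   and `samples` TSV paths (see [read_expression_tsv()]).
#' @param alpha Significance level for down-regulation calls.
#' @param valve_mode `"cap"` or `"fixed"`; see [apply_valve_constraints()].
#' @param fva_fraction Fraction of optimum for the capacity comparison.
#' @param essentiality_cutoff Growth-ratio threshold for essentiality.
#' @param targets Reaction ids for objective-swap maximization (e.g. the
#'   acetyl-CoA synthetase / carboxylase proxies), or `NULL`.
#' @param excluded_metabolites Currency metabolites dropped when building
#'   the enzyme network; default [currency_metabolites()].
#' @param centrality_k Top-list size for centrality flagging.
#' @param seed Seed for the percolation index (and any other randomness).
#' @param out_dir If non-`NULL`, all intermediate artifacts and rendered
#'   tables are written under this directory.
#' @return Object of class `pipeline_report`: list with `wt` (reference
#'   growth, carrying-flux counts, FVA), `conditions` (one report per
#'   label) and `manifest` (versions, parameters, seed, warnings, LP
#'   statuses).
#' @examples
#' fx <- end_to_end_fixture(tempfile("bundle"), "linear",
#'                          planted_genes = "gB", planted_lfc = -1)
#' rep <- run_pipeline(fx$model,
#'                     conditions = list(mut1 = list(expression = fx$expression,
#'                                                   samples = fx$samples)))
#' rep$conditions$mut1$growth  # 5: half of the wild-type optimum
#' @export
run_pipeline <- function(model, conditions, alpha = 0.01,
                         valve_mode = c("cap", "fixed"), fva_fraction = 1.0,
                         essentiality_cutoff = 0.01, targets = NULL,
                         excluded_metabolites = currency_metabolites(),
                         centrality_k = 100, seed = 1L, out_dir = NULL) {
  valve_mode <- match.arg(valve_mode)
  if (is.character(model)) model <- read_sbml(model)
  stopifnot(inherits(model, "metabolic_model"))
  if (length(conditions) == 0L) stop("no conditions supplied")
  if (is.null(names(conditions)) || anyDuplicated(names(conditions))) {
    stop("conditions must carry unique labels")
  }
  if (!is.null(targets)) rxn_index(model, targets)   # validate early
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }

  wt_ref <- compute_reference_fluxes(model)
  wt_sol <- fba(model)
  wt_fva <- fva(model, fraction_of_optimum = fva_fraction)
  net <- withCallingHandlers(
    build_enzyme_network(model, excluded_metabolites),
    warning = function(w) {
      note("network: %s", conditionMessage(w)); invokeRestart("muffleWarning")
    })
  cent <- compute_centralities(net, centrality_config(seed = seed))
  wt_targets <- if (is.null(targets)) NULL else
    vapply(targets, function(t) maximize_reaction_objective(model, t)$objective,
           numeric(1))

  reports <- list()
  for (label in names(conditions)) {
    cond <- conditions[[label]]
    x <- if (inherits(cond, "expression_data")) cond else
      read_expression_tsv(cond$expression, cond$samples)
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop("pipeline stage '", what, "' failed for condition '", label,
             "': ", conditionMessage(e), call. = FALSE)
      })
    }
    de <- stage("differential_expression",
                differential_expression(x, alpha = alpha))
    down <- significant_down(de, alpha)
    fc_map <- withCallingHandlers(
      stage("map", assign_reaction_fold_changes(model, de, alpha)),
      warning = function(w) {
        note("%s: %s", label, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    cm <- stage("integrate",
                apply_valve_constraints(model, wt_ref, fc_map,
                                        mode = valve_mode))
    sol <- stage("fba", fba(cm))
    feasible <- identical(sol$status, "optimal")
    if (!feasible) note("%s: constrained model FBA status %s", label,
                        sol$status)
    growth <- if (feasible) sol$objective else 0
    carrying <- if (feasible) count_carrying_flux(sol) else
      list(total = NA_integer_, positive = NA_integer_,
           negative = NA_integer_)

    down_in_model <- intersect(down, model_genes(model))
    if (feasible && growth > 0) {
      mut_fva <- stage("fva", fva(cm, fraction_of_optimum = fva_fraction))
      cmp <- compare_capacity(wt_fva, mut_fva, model)
      cls <- stage("classify",
                   classify_genes_pfba(cm,
                                       essentiality_cutoff = essentiality_cutoff))
      del <- stage("deletions",
                   single_gene_deletion(cm, genes = down_in_model,
                                        essentiality_cutoff = essentiality_cutoff))
      cls_down <- cls[cls$gene %in% down_in_model, ]
      pct <- if (nrow(cls_down)) {
        100 * as.numeric(table(cls_down$category)) / nrow(cls_down)
      } else rep(NA_real_, length(pfba_categories()))
      names(pct) <- pfba_categories()
      strict_reduced <- if (nrow(del)) {
        100 * mean(del$growth_ratio < 1 - 1e-6)
      } else NA_real_
    } else {
      mut_fva <- NULL
      cmp <- list(per_reaction = NULL, increased_subsystems = character(0),
                  decreased_subsystems = character(0))
      cls_down <- NULL
      del <- NULL
      pct <- stats::setNames(rep(NA_real_, length(pfba_categories())),
                             pfba_categories())
      strict_reduced <- NA_real_
    }
    tgt <- if (is.null(targets) || !feasible) NULL else
      vapply(targets,
             function(t) maximize_reaction_objective(cm, t)$objective,
             numeric(1))
    flags <- if (length(down_in_model)) {
      withCallingHandlers(
        rank_and_flag(cent, down_in_model, k = centrality_k)$top_k,
        warning = function(w) {
          note("%s: %s", label, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    } else stats::setNames(vector("list", 0), character(0))

    reports[[label]] <- list(
      label = label,
      de = de,
      down_genes = down,
      fc_map = fc_map,
      constrained_model = cm,
      status = sol$status,
      growth = growth,
      growth_ratio = if (wt_sol$objective > 0) growth / wt_sol$objective else NA_real_,
      carrying_flux = carrying,
      fva = mut_fva,
      increased_subsystems = cmp$increased_subsystems,
      decreased_subsystems = cmp$decreased_subsystems,
      capacity = cmp$per_reaction,
      classification = cls_down,
      category_percent = pct,
      deletion = del,
      strict_growth_reduced_percent = strict_reduced,
      objective_swaps = tgt,
      centrality_top_k = flags
    )
  }

  manifest <- list(
    package = "fluxvalve",
    version = tryCatch(as.character(utils::packageVersion("fluxvalve")),
                       error = function(e) NA_character_),
    model_id = model$id,
    parameters = list(alpha = alpha, valve_mode = valve_mode,
                      fva_fraction = fva_fraction,
                      essentiality_cutoff = essentiality_cutoff,
                      centrality_k = centrality_k, seed = seed,
                      targets = targets,
                      excluded_metabolites = excluded_metabolites),
    wt_growth = wt_sol$objective,
    statuses = vapply(reports, `[[`, character(1), "status"),
    warnings = warnings_log,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  out <- structure(
    list(wt = list(growth = wt_sol$objective,
                   carrying_flux = count_carrying_flux(wt_sol),
                   fva = wt_fva, reference = wt_ref,
                   centrality = cent, objective_swaps = wt_targets),
         conditions = reports, manifest = manifest),
    class = "pipeline_report")
  if (!is.null(out_dir)) {
    render_tables(out, out_dir)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> model %s, WT growth %.6g, %d condition(s)\n",
              x$manifest$model_id, x$wt$growth, length(x$conditions)))
  for (r in x$conditions) {
    cat(sprintf("  %-12s growth %.6g (ratio %.3f), %d down gene(s)\n",
                r$label, r$growth, r$growth_ratio, length(r$down_genes)))
  }
  invisible(x)
}

#' Render a pipeline report as tables
#'
#' Produces the machine-readable twins of the study's report shapes: the
#' growth-per-condition table, the carrying-flux count table, the
#' subsystem-by-condition membership matrices for increased and decreased
#' flux capacity, the per-category gene percentages (formatted to one
#' decimal in the written TSV), and the objective-swap table with the
#' wild-type model as reference column.  When `dir` is given, each table is
#' written as TSV, plus a JSON mapping each condition to its
#' subsystem -> reaction lists and the run manifest.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory, or `NULL` to only return the tables.
#' @return Named list of data.frames, invisibly when writing.
#' @export
render_tables <- function(report, dir = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  conds <- report$conditions
  labels <- names(conds)

  growth <- data.frame(
    condition = c("WT", labels),
    growth = c(report$wt$growth, vapply(conds, `[[`, numeric(1), "growth")),
    growth_ratio = c(1, vapply(conds, `[[`, numeric(1), "growth_ratio")),
    row.names = NULL, stringsAsFactors = FALSE)

  carrying <- data.frame(
    condition = c("WT", labels),
    total = c(report$wt$carrying_flux$total,
              vapply(conds, function(r) r$carrying_flux$total, numeric(1))),
    positive = c(report$wt$carrying_flux$positive,
                 vapply(conds, function(r) r$carrying_flux$positive, numeric(1))),
    negative = c(report$wt$carrying_flux$negative,
                 vapply(conds, function(r) r$carrying_flux$negative, numeric(1))),
    row.names = NULL, stringsAsFactors = FALSE)

  member_table <- function(field) {
    subs <- sort(unique(unlist(lapply(conds, `[[`, field), use.names = FALSE)))
    if (length(subs) == 0L) {
      return(data.frame(subsystem = character(0), models = character(0)))
    }
    data.frame(
      subsystem = subs,
      models = vapply(subs, function(s) {
        paste(labels[vapply(conds, function(r) s %in% r[[field]], logical(1))],
              collapse = "- ")
      }, character(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  increased <- member_table("increased_subsystems")
  decreased <- member_table("decreased_subsystems")

  cats <- pfba_categories()
  categories <- cbind(
    data.frame(condition = labels, stringsAsFactors = FALSE),
    as.data.frame(do.call(rbind, lapply(conds, `[[`, "category_percent"))),
    data.frame(single_gene_deletion = vapply(
      conds, `[[`, numeric(1), "strict_growth_reduced_percent"))
  )
  rownames(categories) <- NULL

  objectives <- NULL
  if (!is.null(report$wt$objective_swaps)) {
    objectives <- cbind(
      data.frame(target = names(report$wt$objective_swaps),
                 WT = unname(report$wt$objective_swaps),
                 stringsAsFactors = FALSE),
      as.data.frame(lapply(conds, function(r) {
        if (is.null(r$objective_swaps)) rep(NA_real_, length(report$wt$objective_swaps))
        else unname(r$objective_swaps)
      }))
    )
    rownames(objectives) <- NULL
  }

  centrality <- do.call(rbind, lapply(labels, function(l) {
    fl <- conds[[l]]$centrality_top_k
    if (length(fl) == 0L) return(NULL)
    data.frame(condition = l, index = names(fl),
               flagged = vapply(fl, paste, character(1), collapse = ","),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  tabs <- list(growth = growth, carrying_flux = carrying,
               increased_subsystems = increased,
               decreased_subsystems = decreased,
               categories = categories, objectives = objectives,
               centrality_flags = centrality)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fmt_cat <- categories
    num <- vapply(fmt_cat, is.numeric, logical(1))
    fmt_cat[num] <- lapply(fmt_cat[num], function(x) sprintf("%.1f", x))
    write_one <- function(df, name) {
      if (is.null(df)) return(invisible(NULL))
      utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_one(growth, "growth")
    write_one(carrying, "carrying_flux")
    write_one(increased, "increased_subsystems")
    write_one(decreased, "decreased_subsystems")
    write_one(fmt_cat, "categories")
    write_one(objectives, "objectives")
    write_one(centrality, "centrality_flags")
    caps <- lapply(conds, function(r) {
      if (is.null(r$capacity)) return(NULL)
      per <- r$capacity[nzchar(r$capacity$subsystem), ]
      list(
        increased = split(per$reaction[per$delta > 1e-6],
                          per$subsystem[per$delta > 1e-6]),
        decreased = split(per$reaction[per$delta < -1e-6],
                          per$subsystem[per$delta < -1e-6])
      )
    })
    jsonlite::write_json(caps, file.path(dir, "capacity_subsystems.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(tabs))
  }
  tabs
}

#' Load a pipeline run configuration from YAML or JSON
#'
#' Fields mirror the arguments of [run_pipeline()]: `model` (SBML path),
#' `conditions` (named entries with `expression` and `samples` paths), and
#' optionally `alpha`, `valve_mode`, `fva_fraction`,
#' `essentiality_cutoff`, `targets`, `excluded_metabolites`,
#' `centrality_k`, `seed`, `out_dir`.  Relative paths are resolved against
#' the configuration file's directory.
#'
#' @param path Configuration file (`.yaml`/`.yml` needs the yaml package;
#'   `.json` uses jsonlite).
#' @return A named list ready to be spliced into [run_pipeline()] with
#'   `do.call()`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  if (!is.null(cfg$model)) cfg$model <- resolve(cfg$model)
  cfg$conditions <- lapply(cfg$conditions, function(cd) {
    list(expression = resolve(cd$expression), samples = resolve(cd$samples))
  })
  cfg
}
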