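#' Read a metabolic model from SBML
#'
#' Supports the two dialects the yeast consensus-model lineage has used:
#' Level 3 with the `fbc` extension (flux bounds as parameter references,
#' GPRs as `fbc:geneProductAssociation` trees, objective via
#' `fbc:listOfObjectives`) and the older COBRA convention (bounds as
#' `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters, GPRs and subsystems
#' as `GENE_ASSOCIATION:`/`SUBSYSTEM:` note lines).  When both are present
#' the fbc encoding wins.  Species flagged `boundaryCondition="true"` are
#' excluded from mass balance, and infinite bounds are capped at
#' `+/- infinite_bound` so downstream variability analyses always work on
#' finite ranges.  Metabolite ids are taken verbatim (no compartment-suffix
#' stripping); gene ids use the `fbc:label` when present, else the
#' `fbc:id`.
#'
#' A rule string that fails to parse is downgraded to an empty GPR with a
#' warning, keeping the reaction.  A model without any objective reaction is
#' a configuration error.
#'
#' @param path SBML file.
#' @param infinite_bound Cap applied to non-finite bounds (default 1000).
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path, infinite_bound = 1000) {
  if (!file.exists(path)) stop("SBML file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  fbc_uri <- grep("fbc", ns, value = TRUE)
  has_fbc <- length(fbc_uri) > 0
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_attr(mnode, "id")) && inherits(mnode, "xml_missing")) {
    stop("no <model> element in ", path, call. = FALSE)
  }
  model_id <- xml2::xml_attr(mnode, "id")
  if (is.na(model_id)) model_id <- basename(path)

  clamp <- function(x, default) {
    x[is.na(x)] <- default
    pmin(pmax(x, -infinite_bound), infinite_bound)
  }

  # --- gene products (fbc) ------------------------------------------------
  gp_nodes <- xml2::xml_find_all(mnode, ".//*[local-name()='geneProduct']")
  gp_id <- xml2::xml_attr(gp_nodes, "id")
  gp_label <- xml2::xml_attr(gp_nodes, "label")
  gene_name <- ifelse(is.na(gp_label) | !nzchar(gp_label), gp_id, gp_label)
  names(gene_name) <- gp_id

  # --- parameters ---------------------------------------------------------
  par_nodes <- xml2::xml_find_all(mnode, "./listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  # --- species ------------------------------------------------------------
  sp <- xml2::xml_find_all(mnode, "./listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_name <- xml2::xml_attr(sp, "name")
  sp_comp <- xml2::xml_attr(sp, "compartment")
  sp_bnd <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  keep <- !sp_bnd
  metabolites <- data.frame(
    id = sp_id[keep],
    name = ifelse(is.na(sp_name[keep]), sp_id[keep], sp_name[keep]),
    compartment = ifelse(is.na(sp_comp[keep]), "c", sp_comp[keep]),
    stringsAsFactors = FALSE
  )
  boundary_ids <- sp_id[sp_bnd]

  # --- fbc objective ------------------------------------------------------
  fo_nodes <- xml2::xml_find_all(mnode, ".//*[local-name()='fluxObjective']")
  obj_map <- numeric(0)
  if (length(fo_nodes)) {
    obj_map <- stats::setNames(
      as.numeric(xml2::xml_attr(fo_nodes, "coefficient")),
      xml2::xml_attr(fo_nodes, "reaction"))
    obj_map[is.na(obj_map)] <- 1
  }

  # --- reactions ----------------------------------------------------------
  rx <- xml2::xml_find_all(mnode, "./listOfReactions/reaction")
  if (length(rx) == 0L) stop("model has no reactions", call. = FALSE)
  n <- length(rx)
  rid <- xml2::xml_attr(rx, "id")
  rname <- xml2::xml_attr(rx, "name")
  rrev <- !(xml2::xml_attr(rx, "reversible") %in% "false")
  lb <- ub <- rep(NA_real_, n)
  gpr <- character(n)
  subsystem <- character(n)
  objective <- numeric(n)
  stoich <- vector("list", n)

  notes_field <- function(node, key) {
    # leaf elements only: a <body> wrapper concatenates its children's text
    txt <- xml2::xml_text(xml2::xml_find_all(node, "./notes//*[not(*)]"))
    hit <- grep(paste0("^\\s*", key, "\\s*:"), txt, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    trimws(sub(paste0("^\\s*", key, "\\s*:"), "", hit[1]))
  }

  for (j in seq_len(n)) {
    node <- rx[[j]]
    # stoichiometry
    reac <- xml2::xml_find_all(node, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(node, "./listOfProducts/speciesReference")
    sref <- function(nodes, sign) {
      if (length(nodes) == 0L) return(numeric(0))
      s <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      s[is.na(s)] <- 1
      stats::setNames(sign * s, xml2::xml_attr(nodes, "species"))
    }
    sto <- c(sref(reac, -1), sref(prod, 1))
    sto <- sto[!names(sto) %in% boundary_ids]
    sto <- tapply(sto, names(sto), sum)    # merge duplicate species refs
    stoich[[j]] <- stats::setNames(as.numeric(sto), names(sto))

    # bounds: fbc parameter refs first, then kinetic-law parameters
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lbref) || !is.na(ubref)) {
      lb[j] <- unname(par_val[lbref])
      ub[j] <- unname(par_val[ubref])
    } else {
      kl <- xml2::xml_find_all(node, "./kineticLaw//parameter")
      if (length(kl)) {
        kid <- xml2::xml_attr(kl, "id")
        kid[is.na(kid)] <- xml2::xml_attr(kl, "name")[is.na(kid)]
        kv <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")), kid)
        lb[j] <- unname(kv["LOWER_BOUND"])
        ub[j] <- unname(kv["UPPER_BOUND"])
        oc <- kv["OBJECTIVE_COEFFICIENT"]
        if (!is.na(oc)) objective[j] <- oc
      }
    }
    if (is.na(lb[j])) lb[j] <- if (rrev[j]) -infinite_bound else 0
    if (is.na(ub[j])) ub[j] <- infinite_bound

    # GPR: fbc geneProductAssociation wins over note strings
    gpa <- xml2::xml_find_first(node,
                                "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_find_all(gpa, "./*")
      ast <- if (length(kids)) fbc_gpa_to_ast(kids[[1]], gene_name) else gpr_empty()
      gpr[j] <- gpr_to_string(ast)
    } else {
      ga <- notes_field(node, "GENE[ _]ASSOCIATION")
      if (!is.na(ga)) {
        ok <- tryCatch({ parse_gpr(ga); TRUE }, error = function(e) {
          warning("reaction ", rid[j], ": unparseable GPR '", ga,
                  "' kept as empty (", conditionMessage(e), ")",
                  call. = FALSE)
          FALSE
        })
        gpr[j] <- if (ok) ga else ""
      }
    }
    ss <- notes_field(node, "SUBSYSTEM")
    subsystem[j] <- if (is.na(ss)) "" else ss
  }
  lb <- clamp(lb, -infinite_bound)
  ub <- clamp(ub, infinite_bound)
  if (length(obj_map)) {
    objective <- ifelse(rid %in% names(obj_map), obj_map[rid], 0)
  }
  if (all(objective == 0)) {
    stop("model '", model_id, "' declares no objective reaction",
         call. = FALSE)
  }

  metabolic_model(
    model_id,
    metabolites = metabolites,
    reactions = data.frame(
      id = rid, name = ifelse(is.na(rname), rid, rname),
      lower_bound = lb, upper_bound = ub, gpr = gpr, subsystem = subsystem,
      objective_coefficient = as.numeric(objective), stringsAsFactors = FALSE
    ),
    stoichiometry = stats::setNames(stoich, rid)
  )
}

fbc_gpa_to_ast <- function(node, gene_name) {
  tag <- sub("^.*:", "", xml2::xml_name(node))
  if (tag == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    g <- if (ref %in% names(gene_name)) gene_name[[ref]] else ref
    return(gpr_leaf(g))
  }
  if (tag %in% c("and", "or")) {
    kids <- xml2::xml_find_all(node, "./*")
    return(gpr_node(tag, lapply(kids, fbc_gpa_to_ast, gene_name = gene_name)))
  }
  stop("unsupported geneProductAssociation element: ", tag, call. = FALSE)
}

#' Write a metabolic model as SBML Level 3 + fbc version 2
#'
#' Bounds become shared model parameters, GPRs become
#' `fbc:geneProductAssociation` trees, the objective becomes the active
#' `fbc:objective`, and subsystem labels are stored as `SUBSYSTEM:` note
#' lines (the encoding [read_sbml()] understands).  Identifiers are written
#' verbatim and must be valid SBML SIds
#' (`[A-Za-z_][A-Za-z0-9_]*`).
#'
#' @param model A [metabolic_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  ids <- c(model$metabolites$id, model$reactions$id, model_genes(model))
  bad <- ids[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)]
  if (length(bad)) {
    stop("id(s) not valid SBML SIds: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc, level = "3", version = "1", "fbc:required" = "false")
  mn <- xml2::xml_add_child(doc, "model",
                            id = gsub("[^A-Za-z0-9_]", "_", model$id),
                            "fbc:strict" = "true")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mn, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }

  ls <- xml2::xml_add_child(mn, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    xml2::xml_add_child(
      ls, "species", id = model$metabolites$id[i],
      name = model$metabolites$name[i],
      compartment = model$metabolites$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }

  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  bkey <- function(v) sprintf("%.17g", v)
  bid <- stats::setNames(sprintf("fv_bound_%d", seq_along(bounds)),
                         bkey(bounds))
  lp <- xml2::xml_add_child(mn, "listOfParameters")
  for (k in seq_along(bounds)) {
    xml2::xml_add_child(lp, "parameter", id = unname(bid[k]),
                        value = bkey(bounds[k]), constant = "true")
  }
  bref <- function(v) unname(bid[bkey(v)])

  obj_rows <- which(model$reactions$objective_coefficient != 0)
  lo <- xml2::xml_add_child(mn, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  for (i in obj_rows) {
    xml2::xml_add_child(
      lfo, "fbc:fluxObjective",
      "fbc:reaction" = model$reactions$id[i],
      "fbc:coefficient" = format(model$reactions$objective_coefficient[i],
                                 digits = 17))
  }

  genes <- model_genes(model)
  if (length(genes)) {
    lg <- xml2::xml_add_child(mn, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = g,
                          "fbc:label" = g)
    }
  }

  lr <- xml2::xml_add_child(mn, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rn <- xml2::xml_add_child(
      lr, "reaction", id = r$id, name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bref(r$lower_bound),
      "fbc:upperFluxBound" = bref(r$upper_bound))
    if (nzchar(r$subsystem)) {
      nt <- xml2::xml_add_child(rn, "notes")
      bd <- xml2::xml_add_child(nt, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(bd, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    sto <- model$S[, i]
    sto <- sto[sto != 0]
    if (any(sto < 0)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (sid in names(sto)[sto < 0]) {
        xml2::xml_add_child(lre, "speciesReference", species = sid,
                            stoichiometry = format(-sto[[sid]], digits = 17),
                            constant = "true")
      }
    }
    if (any(sto > 0)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (sid in names(sto)[sto > 0]) {
        xml2::xml_add_child(lpr, "speciesReference", species = sid,
                            stoichiometry = format(sto[[sid]], digits = 17),
                            constant = "true")
      }
    }
    ast <- model$gpr[[r$id]]
    if (ast$op != "empty") {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      fbc_ast_to_xml(gpa, ast)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

fbc_ast_to_xml <- function(parent, ast) {
  if (ast$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = ast$gene)
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", ast$op))
    for (a in ast$args) fbc_ast_to_xml(node, a)
  }
  invisible(parent)
}

#' Dump / load a model as JSON
#'
#' A plain-text native serialization (ids, names, bounds, stoichiometry,
#' GPR strings, subsystems, objective) convenient for fixtures and diffing.
#'
#' @param model A [metabolic_model()].
#' @param path JSON file.
#' @return `model_to_json()` returns `path` invisibly; `model_from_json()`
#'   returns a [metabolic_model()].
#' @export
model_to_json <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  sto <- lapply(seq_len(nrow(model$reactions)), function(j) {
    v <- model$S[, j]
    as.list(v[v != 0])
  })
  names(sto) <- model$reactions$id
  payload <- list(
    id = model$id,
    metabolites = model$metabolites,
    reactions = model$reactions[, c("id", "name", "lower_bound",
                                    "upper_bound", "gpr", "subsystem",
                                    "objective_coefficient")],
    stoichiometry = sto
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  sto <- lapply(p$stoichiometry, function(x) unlist(x))
  metabolic_model(p$id, metabolites = p$metabolites,
                  reactions = p$reactions, stoichiometry = sto)
}
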