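#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers linking a
#' reaction to the genes whose products catalyse it.  `parse_gpr()` turns the
#' textual rule into an abstract syntax tree; `evaluate_gpr()` decides whether
#' the reaction remains available given a set of present genes (isozymes are
#' OR, complex subunits are AND); `gpr_genes()` lists the genes a rule
#' mentions.
#'
#' Grammar: `expr := term ("or" term)*`, `term := factor ("and" factor)*`,
#' `factor := "(" expr ")" | gene-id`.  `and` therefore binds tighter than
#' `or`.  Operator keywords are case-insensitive and `&`/`&&` and `|`/`||`
#' are accepted as synonyms.  An empty rule parses to the empty expression,
#' which evaluates `TRUE` under any gene set: a reaction with no gene
#' association is never disabled by a deletion (COBRA convention).
#'
#' @param rule Character scalar, e.g. `"g1 and (g2 or g3)"`.  `NA` or a
#'   blank/empty string yield the empty expression.
#' @return `parse_gpr()` returns an object of class `gpr_expression`: a nested
#'   list with element `op` in `"and"`, `"or"`, `"gene"` or `"empty"`, plus
#'   `args` (sub-expressions) or `gene` (leaf identifier).
#' @examples
#' e <- parse_gpr("g1 or g2 and g3")
#' evaluate_gpr(e, "g2")            # FALSE: needs g1, or both of g2,g3
#' evaluate_gpr(e, c("g2", "g3"))   # TRUE
#' gpr_genes(e)
#' @export
parse_gpr <- function(rule) {
  if (length(rule) != 1L) stop("'rule' must be a single string", call. = FALSE)
  if (is.na(rule) || !nzchar(trimws(rule))) return(gpr_empty())
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$tokens <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st)
  if (st$pos <= nrow(st$tokens)) {
    tok <- st$tokens[st$pos, ]
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 tok$at, tok$text), call. = FALSE)
  }
  expr
}

gpr_empty <- function() structure(list(op = "empty"), class = "gpr_expression")

gpr_node <- function(op, args) {
  # flatten nested same-operator nodes so "a and b and c" is one AND node
  flat <- list()
  for (a in args) {
    if (inherits(a, "gpr_expression") && identical(a$op, op)) {
      flat <- c(flat, a$args)
    } else {
      flat <- c(flat, list(a))
    }
  }
  structure(list(op = op, args = flat), class = "gpr_expression")
}

gpr_leaf <- function(gene) {
  structure(list(op = "gene", gene = gene), class = "gpr_expression")
}

gpr_tokenize <- function(rule) {
  n <- nchar(rule)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- data.frame(type = ch, text = ch, at = i)
      i <- i + 1L
      next
    }
    # a word runs to the next space or parenthesis
    j <- i
    while (j <= n && !grepl("^[\\s()]$", substr(rule, j, j), perl = TRUE)) j <- j + 1L
    word <- substr(rule, i, j - 1L)
    lw <- tolower(word)
    type <- if (lw %in% c("and", "&", "&&")) "and"
            else if (lw %in% c("or", "|", "||")) "or"
            else "gene"
    toks[[length(toks) + 1L]] <- data.frame(type = type, text = word, at = i)
    i <- j
  }
  if (length(toks) == 0L)
    stop("GPR parse error: empty rule after tokenization", call. = FALSE)
  do.call(rbind, toks)
}

gpr_peek <- function(st) {
  if (st$pos > nrow(st$tokens)) NULL else st$tokens[st$pos, ]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  repeat {
    tok <- gpr_peek(st)
    if (is.null(tok) || tok$type != "or") break
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st)
  }
  if (length(args) == 1L) args[[1L]] else gpr_node("or", args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_factor(st))
  repeat {
    tok <- gpr_peek(st)
    if (is.null(tok) || tok$type != "and") break
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_factor(st)
  }
  if (length(args) == 1L) args[[1L]] else gpr_node("and", args)
}

gpr_parse_factor <- function(st) {
  tok <- gpr_peek(st)
  if (is.null(tok))
    stop("GPR parse error at end of rule: missing operand", call. = FALSE)
  if (tok$type == "(") {
    open_at <- tok$at
    st$pos <- st$pos + 1L
    expr <- gpr_parse_or(st)
    tok <- gpr_peek(st)
    if (is.null(tok) || tok$type != ")")
      stop(sprintf("GPR parse error: unbalanced '(' opened at position %d",
                   open_at), call. = FALSE)
    st$pos <- st$pos + 1L
    return(expr)
  }
  if (tok$type == "gene") {
    st$pos <- st$pos + 1L
    return(gpr_leaf(tok$text))
  }
  stop(sprintf("GPR parse error at position %d: expected operand, found '%s'",
               tok$at, tok$text), call. = FALSE)
}

#' @rdname parse_gpr
#' @param expr A `gpr_expression`.
#' @param present_genes Character vector of gene ids considered present.
#' @return `evaluate_gpr()` returns a single logical.
#' @export
evaluate_gpr <- function(expr, present_genes) {
  stopifnot(inherits(expr, "gpr_expression"))
  switch(expr$op,
    empty = TRUE,
    gene  = expr$gene %in% present_genes,
    and   = all(vapply(expr$args, evaluate_gpr, logical(1), present_genes)),
    or    = any(vapply(expr$args, evaluate_gpr, logical(1), present_genes)),
    stop("corrupt GPR node: ", expr$op)
  )
}

#' @rdname parse_gpr
#' @return `gpr_genes()` returns the sorted unique gene ids appearing as
#'   leaves of the expression (empty character vector for the empty rule).
#' @export
gpr_genes <- function(expr) {
  stopifnot(inherits(expr, "gpr_expression"))
  leaves <- function(e) {
    switch(e$op,
      empty = character(0),
      gene  = e$gene,
      unlist(lapply(e$args, leaves), use.names = FALSE)
    )
  }
  sort(unique(leaves(expr)))
}

#' @rdname parse_gpr
#' @export
gpr_to_string <- function(expr) {
  stopifnot(inherits(expr, "gpr_expression"))
  fmt <- function(e, parent_op) {
    s <- switch(e$op,
      empty = "",
      gene  = e$gene,
      and   = paste(vapply(e$args, fmt, character(1), "and"), collapse = " and "),
      or    = paste(vapply(e$args, fmt, character(1), "or"), collapse = " or ")
    )
    if (e$op == "or" && identical(parent_op, "and")) s <- paste0("(", s, ")")
    s
  }
  fmt(expr, "")
}

#' @export
print.gpr_expression <- function(x, ...) {
  s <- gpr_to_string(x)
  cat("<GPR> ", if (nzchar(s)) s else "(empty)", "\n", sep = "")
  invisible(x)
}

#' @export
format.gpr_expression <- function(x, ...) gpr_to_string(x)
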