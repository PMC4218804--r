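#' Bundle a log2 expression matrix with group labels
#'
#' Inputs are gene-level, already log2-normalized values; no normalization,
#' background correction or count modelling happens here.  Samples belong to
#' either the wild-type (`"WT"`) or the mutant (`"MUT"`) group.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param groups Character/factor of length `ncol(values)` with levels
#'   `WT` and `MUT`.
#' @return Object of class `expression_data`.
#' @export
expression_data <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values need gene ids as rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (any(!is.finite(values))) stop("expression values must be finite")
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("one group label per sample required")
  }
  if (!all(groups %in% c("WT", "MUT"))) {
    stop("group labels must be 'WT' or 'MUT'")
  }
  structure(list(values = values, groups = groups), class = "expression_data")
}

#' @export
print.expression_data <- function(x, ...) {
  cat(sprintf("<expression_data> %d genes x %d samples (%d WT, %d MUT)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "WT"), sum(x$groups == "MUT")))
  invisible(x)
}

#' Read an expression bundle from TSV
#'
#' `expr_path`: first column gene id, remaining columns one per sample.
#' `samples_path`: two columns, `sample` and `group` (`WT`/`MUT`).
#'
#' @param expr_path,samples_path Paths to the two TSV files.
#' @return An [expression_data()] object.
#' @export
read_expression_tsv <- function(expr_path, samples_path) {
  ex <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(ex[[1]])
  values <- as.matrix(ex[, -1, drop = FALSE])
  rownames(values) <- genes
  ss <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(ss))) {
    stop("sample sheet needs 'sample' and 'group' columns")
  }
  i <- match(colnames(values), ss$sample)
  if (anyNA(i)) {
    stop("samples missing from sheet: ",
         paste(colnames(values)[is.na(i)], collapse = ", "))
  }
  expression_data(values, ss$group[i])
}

#' Per-gene differential expression on log2 data
#'
#' Two-sided two-sample t-test per gene, pooled variance by default (the
#' microarray-era standard; set `var_equal = FALSE` for Welch).  The fold
#' change is `mean(MUT) - mean(WT)` on the log2 scale, so down-regulation in
#' the mutant is negative.  Genes with zero pooled variance cannot be tested
#' by t; they get `p = 0` when the group means differ and `p = 1` when they
#' are equal, and are flagged in the `zero_variance` column.
#'
#' Raw p-values are thresholded (no multiple-testing correction) to match
#' the classic p < alpha convention; set `adjust = "BH"` to call
#' significance on Benjamini-Hochberg adjusted values instead.
#'
#' @param x An [expression_data()] with at least two samples per group.
#' @param alpha Significance level for the `significant_down` call.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `gene`, `fold_change`, `p_value`,
#'   `significant_down`, `zero_variance`.
#' @export
differential_expression <- function(x, alpha = 0.01, var_equal = TRUE,
                                    adjust = c("none", "BH")) {
  stopifnot(inherits(x, "expression_data"), alpha > 0, alpha < 1)
  adjust <- match.arg(adjust)
  wt <- x$values[, x$groups == "WT", drop = FALSE]
  mut <- x$values[, x$groups == "MUT", drop = FALSE]
  if (ncol(wt) < 2 || ncol(mut) < 2) {
    stop("each group needs at least 2 samples (found ", ncol(wt), " WT, ",
         ncol(mut), " MUT)", call. = FALSE)
  }
  fc <- rowMeans(mut) - rowMeans(wt)
  vw <- apply(wt, 1, stats::var)
  vm <- apply(mut, 1, stats::var)
  zerovar <- (vw + vm) == 0
  p <- rep(NA_real_, nrow(x$values))
  for (i in seq_len(nrow(x$values))) {
    if (zerovar[i]) {
      p[i] <- if (abs(fc[i]) > 0) 0 else 1
    } else {
      p[i] <- stats::t.test(mut[i, ], wt[i, ], var.equal = var_equal)$p.value
    }
  }
  p_eff <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  data.frame(
    gene = rownames(x$values),
    fold_change = unname(fc),
    p_value = unname(p),
    significant_down = unname(p_eff < alpha & fc < 0),
    zero_variance = unname(zerovar),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Significantly down-regulated genes
#'
#' Strict threshold: `p_value < alpha` and `fold_change < 0`.
#'
#' @param results Output of [differential_expression()].
#' @param alpha Significance level.
#' @return Character vector of gene ids.
#' @export
significant_down <- function(results, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1,
            all(c("gene", "fold_change", "p_value") %in% names(results)))
  results$gene[results$p_value < alpha & results$fold_change < 0]
}

#' Map down-regulated genes onto reaction fold changes
#'
#' Every reaction touched (via GPR leaves) by at least one significantly
#' down-regulated gene receives the minimum (most negative) log2 fold change
#' among those genes - the most conservative valve when several down genes
#' hit one reaction.  Reactions touched by no down gene are absent from the
#' map.  Down genes not present in any GPR are dropped with a warning.
#'
#' @param model A [metabolic_model()].
#' @param results Output of [differential_expression()].
#' @param alpha Significance level passed to [significant_down()].
#' @return Named numeric vector: reaction id -> assigned log2 fold change
#'   (all values negative).
#' @export
assign_reaction_fold_changes <- function(model, results, alpha = 0.01) {
  stopifnot(inherits(model, "metabolic_model"))
  down <- significant_down(results, alpha)
  if (length(down) == 0L) return(stats::setNames(numeric(0), character(0)))
  model_g <- model_genes(model)
  mapped <- intersect(down, model_g)
  dropped <- setdiff(down, model_g)
  if (length(dropped)) {
    warning("down-regulated gene(s) absent from model GPRs: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(mapped) == 0L) return(stats::setNames(numeric(0), character(0)))
  fc <- stats::setNames(results$fold_change, results$gene)[mapped]
  g2r <- genes_to_reactions(model, mapped)
  out <- list()
  for (g in mapped) {
    for (r in g2r[[g]]) {
      out[[r]] <- min(out[[r]] %||% Inf, fc[[g]])
    }
  }
  unlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a differential-expression table as TSV
#'
#' @param results Output of [differential_expression()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
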