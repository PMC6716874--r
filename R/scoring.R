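#' Per-gene mean expression
#'
#' Averages each gene's log2 expression over the selected samples. Genes
#' present in a model but absent from the matrix are treated as "not
#' expressed" (score 0) downstream; genes in the matrix but absent from
#' the model are simply never looked up.
#'
#' @param x an \code{expression_matrix}.
#' @param condition optional condition label to restrict the samples.
#' @return Named numeric vector, gene id -> mean log2 expression.
#' @export
summarize_gene_expression <- function(x, condition = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  sel <- if (is.null(condition)) rep(TRUE, length(x$samples))
         else x$condition == condition
  if (!any(sel)) stop("empty sample selection", call. = FALSE)
  rowMeans(x$values[, sel, drop = FALSE])
}

#' Map gene expression onto reactions through GPR rules
#'
#' Evaluates each reaction's GPR over the expression values with
#' \code{and} -> min (complex limited by its scarcest subunit) and
#' \code{or} -> max (isozymes are interchangeable). Reactions with an
#' empty GPR, or whose GPR genes are all absent from the expression
#' universe, are left unscored; genes in the model but missing from the
#' expression data contribute 0 ("not expressed").
#'
#' @param model a \code{metabolic_model}.
#' @param gene_expr named numeric vector, gene id -> expression.
#' @return Named numeric vector of reaction scores (scored reactions only).
#' @export
score_reactions <- function(model, gene_expr) {
  stopifnot(is.numeric(gene_expr))
  out <- numeric(0)
  for (r in model$reactions) {
    gg <- gpr_genes(r$gpr)
    if (!length(gg) || !any(gg %in% names(gene_expr))) next
    out[r$id] <- eval_gpr_score(r$gpr, gene_expr, missing_value = 0)
  }
  out
}

#' Assign confidence tiers to reactions
#'
#' Among scored reactions, the top \code{ceiling(high_frac * N)} by score
#' are \code{high} confidence, the bottom \code{ceiling(neg_frac * N)}
#' are \code{negative}, the rest \code{medium}. Unscored reactions (no
#' GPR evidence) are \code{medium}, letting network topology decide their
#' inclusion. Ties at a cutoff are broken by lexicographic reaction id,
#' so the assignment is deterministic.
#'
#' @param model a \code{metabolic_model}.
#' @param scores named numeric vector from [score_reactions()].
#' @param high_frac,neg_frac tier fractions (defaults 0.10 each, the
#'   standard cutoffs for expression-tiered extraction).
#' @return Named character vector over all model reactions with values
#'   \code{"high"}, \code{"medium"}, \code{"negative"}.
#' @export
assign_tiers <- function(model, scores, high_frac = 0.10, neg_frac = 0.10) {
  stopifnot(high_frac > 0, neg_frac > 0, high_frac + neg_frac < 1)
  scores <- scores[names(scores) %in% reaction_ids(model)]
  n <- length(scores)
  if (n < 3) stop("fewer than 3 scored reactions", call. = FALSE)
  n_high <- ceiling(high_frac * n)
  n_neg <- ceiling(neg_frac * n)
  if (n_high + n_neg > n) {
    stop("tier fractions leave no medium reactions at N = ", n, call. = FALSE)
  }
  ids <- names(scores)
  ord_desc <- ids[order(-scores, ids)]
  ord_asc <- ids[order(scores, ids)]
  high <- ord_desc[seq_len(n_high)]
  negative <- setdiff(ord_asc, high)[seq_len(n_neg)]
  tiers <- stats::setNames(rep("medium", length(model$reactions)),
                           reaction_ids(model))
  tiers[high] <- "high"
  tiers[negative] <- "negative"
  tiers
}

#' Write a tier table as TSV
#'
#' @param tiers named character vector from [assign_tiers()].
#' @param scores named numeric vector from [score_reactions()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_tier_table <- function(tiers, scores, path) {
  df <- data.frame(reaction = names(tiers),
                   score = unname(scores[names(tiers)]),
                   tier = unname(tiers), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
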