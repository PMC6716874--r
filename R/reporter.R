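#' Gene neighborhood of each metabolite
#'
#' For each metabolite, the union of genes appearing in the GPRs of the
#' reactions producing or consuming it (1-step network neighborhood,
#' compartment-specific). Metabolites touched only by GPR-less reactions
#' have no neighborhood and are excluded.
#'
#' @param model a \code{metabolic_model}.
#' @param exclude optional metabolite ids to drop (e.g. a currency
#'   metabolite list); empty by default, so highly connected species
#'   remain scorable.
#' @return Named list, metabolite id -> character vector of gene ids.
#' @export
metabolite_gene_neighborhood <- function(model, exclude = character(0)) {
  nb <- list()
  for (r in model$reactions) {
    gg <- gpr_genes(r$gpr)
    if (!length(gg)) next
    for (m in names(r$stoich)) {
      nb[[m]] <- union(nb[[m]], gg)
    }
  }
  nb[setdiff(names(nb), exclude)]
}

#' Reporter metabolite scores
#'
#' Aggregates differential-expression significance around each
#' metabolite: per gene \code{z_g = qnorm(1 - p_g)} (p clamped to
#' [1e-15, 1 - 1e-15]); per metabolite \code{Z_raw = sum(z_g) / sqrt(k)}
#' over its k neighborhood genes. Because highly connected metabolites
#' accumulate large sums by chance, \code{Z_raw} is corrected against a
#' sampled background: for each distinct k, \code{n_background} random
#' size-k gene sets are drawn from all genes with a DE p-value, and
#' \code{Z_corrected = (Z_raw - mu_k) / sigma_k}; \code{p = 1 -
#' pnorm(Z_corrected)}, BH-adjusted across metabolites. Direction is
#' reported separately as the mean sign of the neighborhood logFCs.
#'
#' @param neighborhood named list from [metabolite_gene_neighborhood()].
#' @param de a \code{de_result}.
#' @param n_background background samples per distinct neighborhood size
#'   (default 10000).
#' @param seed integer RNG seed for the background sampling.
#' @return data.frame of class \code{reporter_scores}:
#'   \code{metabolite, k, Z_raw, Z_corrected, p_value, adj_p,
#'   one_minus_p, direction}. Metabolites with a degenerate background
#'   (\code{sigma_k = 0}) are flagged in attribute \code{"degenerate"}
#'   and excluded; neighborhood genes lacking a DE p-value are dropped
#'   (attribute \code{"dropped_genes"}).
#' @export
reporter_scores <- function(neighborhood, de, n_background = 10000,
                            seed = 1) {
  stopifnot(inherits(de, "de_result"), n_background >= 100)
  nb_genes <- unique(unlist(neighborhood))
  dropped <- setdiff(nb_genes, de$gene)
  # the background universe is every gene with a DE p-value, so the
  # null moments reflect the whole dataset, not just metabolic genes
  scored_univ <- de$gene
  if (!length(intersect(nb_genes, scored_univ))) {
    stop("no neighborhood gene has a DE p-value", call. = FALSE)
  }
  p <- pmin(pmax(de$p_value, 1e-15), 1 - 1e-15)
  z <- stats::setNames(stats::qnorm(1 - p), scored_univ)
  lfc <- stats::setNames(de$logFC, scored_univ)

  nb <- lapply(neighborhood, function(gg) intersect(gg, scored_univ))
  nb <- nb[vapply(nb, length, integer(1)) >= 1L]
  k_all <- vapply(nb, length, integer(1))
  if (any(k_all > length(scored_univ))) {
    stop("neighborhood larger than the scored gene universe", call. = FALSE)
  }

  # background moments per distinct neighborhood size
  set.seed(seed)
  mu_k <- sd_k <- numeric(0)
  for (k in sort(unique(k_all))) {
    zr <- vapply(seq_len(n_background), function(i) {
      sum(z[sample.int(length(z), k)]) / sqrt(k)
    }, numeric(1))
    mu_k[as.character(k)] <- mean(zr)
    sd_k[as.character(k)] <- stats::sd(zr)
  }

  z_raw <- vapply(nb, function(gg) sum(z[gg]) / sqrt(length(gg)), numeric(1))
  mu <- mu_k[as.character(k_all)]
  sg <- sd_k[as.character(k_all)]
  degenerate <- names(nb)[sg == 0 | is.na(sg)]
  ok <- !(names(nb) %in% degenerate)
  z_corr <- (z_raw[ok] - mu[ok]) / sg[ok]
  pval <- 1 - stats::pnorm(z_corr)
  direction <- vapply(nb[ok], function(gg) mean(sign(lfc[gg])), numeric(1))

  out <- data.frame(metabolite = names(nb)[ok],
                    k = k_all[ok],
                    Z_raw = z_raw[ok],
                    Z_corrected = z_corr,
                    p_value = pval,
                    adj_p = stats::p.adjust(pval, method = "BH"),
                    one_minus_p = 1 - pval,
                    direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("reporter_scores", "data.frame")
  attr(out, "degenerate") <- degenerate
  attr(out, "dropped_genes") <- dropped
  out
}

#' Significant reporter metabolites
#'
#' @param scores a \code{reporter_scores} data.frame.
#' @param alpha significance cutoff (default 0.05).
#' @param use_adjusted use BH-adjusted p (default) or raw p for the cut.
#' @return The significant rows sorted by \code{Z_corrected} descending.
#' @export
significant_reporters <- function(scores, alpha = 0.05,
                                  use_adjusted = TRUE) {
  stopifnot(inherits(scores, "reporter_scores"))
  pc <- if (use_adjusted) scores$adj_p else scores$p_value
  out <- scores[pc < alpha, , drop = FALSE]
  out[order(-out$Z_corrected), , drop = FALSE]
}
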