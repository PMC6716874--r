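#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default.
#' All randomness flows from the single \code{seed}, split internally per
#' stage, so a config reproduces its outputs byte for byte.
#'
#' @param model a \code{metabolic_model}, or \code{NULL} to build the
#'   bundled toy network.
#' @param expression an \code{expression_matrix}, or \code{NULL} to
#'   simulate from \code{sim_spec}.
#' @param sim_spec an \code{expression_sim_spec} used when
#'   \code{expression} is \code{NULL}.
#' @param gene_sets named list of gene sets (default: the toy pathway
#'   collection).
#' @param markers optional marker data.frame for [marker_panel()].
#' @param medium named uptake bounds (default: the toy medium).
#' @param high_frac,neg_frac confidence-tier fractions.
#' @param extraction an \code{extraction_params}.
#' @param objective_fraction FVA objective floor fraction.
#' @param logfc_thresholds fold-change removal thresholds swept for the
#'   condition models.
#' @param padj_threshold adjusted-p cutoff for gene removal.
#' @param n_background reporter background samples.
#' @param seed root RNG seed.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(model = NULL, expression = NULL,
                            sim_spec = NULL, gene_sets = NULL,
                            markers = NULL, medium = NULL,
                            high_frac = 0.10, neg_frac = 0.10,
                            extraction = extraction_params(),
                            objective_fraction = 0.9,
                            logfc_thresholds = c(1.00, 0.85, 0.70),
                            padj_threshold = 0.05,
                            n_background = 10000, seed = 1) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1,
            all(logfc_thresholds > 0), padj_threshold > 0,
            padj_threshold <= 1)
  structure(list(model = model, expression = expression,
                 sim_spec = sim_spec, gene_sets = gene_sets,
                 markers = markers, medium = medium,
                 high_frac = high_frac, neg_frac = neg_frac,
                 extraction = extraction,
                 objective_fraction = objective_fraction,
                 logfc_thresholds = logfc_thresholds,
                 padj_threshold = padj_threshold,
                 n_background = n_background, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full differential flux-capacity pipeline
#'
#' Sequences the stages: median normalization, batch correction, PCA +
#' k-means heterogeneity report, differential expression, marker panel,
#' reaction scoring and tier assignment, context-specific extraction,
#' medium constraints, condition models at each fold-change threshold,
#' FVA, six-way status classification with consensus, gene-set
#' enrichment of the robust up/down gene lists, and reporter metabolite
#' analysis. Every stage table is written to \code{out_dir} as TSV,
#' along with the resolved parameters (\code{config.yaml}) and a run
#' log.
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with all stage results (\code{expression},
#'   \code{pca}, \code{heterogeneity}, \code{de}, \code{markers},
#'   \code{tiers}, \code{extraction}, \code{status}, \code{consensus},
#'   \code{enrichment_up_naive}, \code{enrichment_up_primed},
#'   \code{reporters}, ...).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  seed <- config$seed
  say("seed: %d", seed)

  model <- if (is.null(config$model)) make_toy_network() else config$model
  validate_model(model)
  gene_sets <- if (is.null(config$gene_sets)) toy_gene_sets() else config$gene_sets
  medium <- if (is.null(config$medium)) toy_medium() else config$medium

  x <- config$expression
  if (is.null(x)) {
    spec <- config$sim_spec
    if (is.null(spec)) spec <- expression_sim_spec(seed = seed + 1L)
    x <- simulate_expression(model$genes, spec)
    say("simulated expression: %d genes x %d samples", nrow(x$values),
        ncol(x$values))
  }

  x <- normalize_medians(x)
  x <- combat_correct(x)
  say("batch correction done over %d batches", length(unique(x$batch)))

  pca <- pca_scores(x, n_components = min(5L, length(x$samples) - 1L))
  het <- kmeans_heterogeneity(pca$scores, k = 2, labels = x$condition,
                              seed = seed + 2L)
  say("k=2 clustering: silhouette %.3f, ARI vs condition %.3f",
      het$silhouette_mean, het$ari)
  tsv(data.frame(sample = rownames(pca$scores), pca$scores,
                 batch = x$batch, condition = x$condition,
                 cluster = het$cluster), "pca_scores.tsv")

  de <- differential_expression(x)
  tsv(de, "differential_expression.tsv")
  say("DE: %d genes at BH < 0.05", sum(de$adj_p < 0.05))

  markers <- NULL
  if (!is.null(config$markers)) {
    markers <- marker_panel(de, config$markers)
    tsv(markers, "marker_panel.tsv")
  }

  gexpr <- summarize_gene_expression(x)
  scores <- score_reactions(model, gexpr)
  tiers <- assign_tiers(model, scores, config$high_frac, config$neg_frac)
  if (nzchar(model$objective_id)) tiers[model$objective_id] <- "high"
  write_tier_table(tiers, scores, file.path(out_dir, "reaction_tiers.tsv"))
  say("tiers: %d high / %d medium / %d negative",
      sum(tiers == "high"), sum(tiers == "medium"), sum(tiers == "negative"))

  extraction <- corda_extract(model, tiers, config$extraction)
  ex_present <- exchange_reactions(extraction$submodel)
  dropped_medium <- setdiff(names(medium), ex_present)
  if (length(dropped_medium)) {
    say("medium entries without a matching exchange dropped: %s",
        paste(dropped_medium, collapse = ", "))
  }
  context <- apply_medium(extraction$submodel,
                          medium[names(medium) %in% ex_present])
  write_model(context, file.path(out_dir, "context_model.json"))
  write_extraction_report(extraction, tiers,
                          file.path(out_dir, "extraction_report.tsv"))
  st <- model_stats(context)
  say("context model: %d reactions, %d metabolites, %d genes",
      st[["n_reactions"]], st[["n_metabolites"]], st[["n_genes"]])

  calls <- list()
  for (thr in config$logfc_thresholds) {
    m_n <- derive_condition_model(context, de, "naive", thr,
                                  config$padj_threshold)
    m_p <- derive_condition_model(context, de, "primed", thr,
                                  config$padj_threshold)
    say("threshold %.2f: silenced %d genes (naive), %d genes (primed)",
        thr, length(attr(m_n, "silenced_genes")),
        length(attr(m_p, "silenced_genes")))
    fv_n <- fva(m_n, config$objective_fraction)
    fv_p <- fva(m_p, config$objective_fraction)
    calls[[sprintf("%.2f", thr)]] <- classify_status(fv_n, fv_p)
  }
  status_tab <- Reduce(function(a, b) merge(a, b, by = "reaction"),
                       mapply(function(cl, nm) {
                         stats::setNames(cl[, c("reaction", "status")],
                                         c("reaction", paste0("status_at_", nm)))
                       }, calls, names(calls), SIMPLIFY = FALSE))
  cons <- consensus_status(calls)
  status_tab$robust_call <- ifelse(status_tab$reaction %in% cons$up_naive,
                                   "up_naive",
                            ifelse(status_tab$reaction %in% cons$up_primed,
                                   "up_primed", "none"))
  tsv(status_tab, "flux_status.tsv")
  say("robust calls: %d up-naive, %d up-primed reactions",
      length(cons$up_naive), length(cons$up_primed))

  universe <- de$gene
  genes_up_n <- genes_from_reactions(context,
                                     intersect(cons$up_naive,
                                               reaction_ids(context)))
  genes_up_p <- genes_from_reactions(context,
                                     intersect(cons$up_primed,
                                               reaction_ids(context)))
  enr_n <- enrich(genes_up_n, gene_sets, universe)
  enr_p <- enrich(genes_up_p, gene_sets, universe)
  tsv(enr_n, "enrichment_up_naive.tsv")
  tsv(enr_p, "enrichment_up_primed.tsv")

  nb <- metabolite_gene_neighborhood(context)
  reporters <- reporter_scores(nb, de, n_background = config$n_background,
                               seed = seed + 3L)
  tsv(reporters, "reporter_metabolites.tsv")
  sig_rep <- significant_reporters(reporters)
  say("reporter metabolites: %d significant of %d scored",
      nrow(sig_rep), nrow(reporters))

  resolved <- config[c("high_frac", "neg_frac", "objective_fraction",
                       "logfc_thresholds", "padj_threshold",
                       "n_background", "seed")]
  resolved$extraction <- unclass(config$extraction)
  yaml::write_yaml(resolved, file.path(out_dir, "config.yaml"))

  invisible(list(expression = x, pca = pca, heterogeneity = het, de = de,
                 markers = markers, scores = scores, tiers = tiers,
                 extraction = extraction, context_model = context,
                 status = status_tab, calls = calls, consensus = cons,
                 genes_up_naive = genes_up_n, genes_up_primed = genes_up_p,
                 enrichment_up_naive = enr_n, enrichment_up_primed = enr_p,
                 reporters = reporters, significant_reporters = sig_rep))
}
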