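# Synthetic-data module: a toy genome-scale network and a batch-structured
# expression simulator with planted condition effects. These stand in for
# the deposited stem-cell datasets so every downstream stage can be run
# and checked end to end.

#' Build the toy metabolic network
#'
#' A small, fully gene-annotated network with (a) glucose uptake feeding a
#' glycolysis-like chain to pyruvate, (b) a TCA-like cycle with an
#' anaplerotic entry regenerating its carrier, (c) an oxygen exchange plus
#' an OXPHOS-like ATP-producing reaction, (d) a tryptophan/kynurenine-like
#' branch gated by a dedicated gene set (with a rate-limiting IDO1-like
#' gene on the first committed step) ending in de novo NAD production, and
#' (e) a biomass objective consuming ATP, a precursor (pyruvate), and NAD.
#' Every enzymatic reaction carries a GPR; exchange and biomass
#' pseudo-reactions are GPR-less. The model grows (FBA optimum > 0) on its
#' default medium; construction is deterministic.
#'
#' @param include_trp_branch include the tryptophan/kynurenine branch
#'   (default \code{TRUE}). Without it, NAD is unreachable and the
#'   NAD-requiring biomass optimum is 0.
#' @param n_extra_reactions extra background reactions added as
#'   independent uptake-degradation chains (rounded up to whole chains of
#'   3); default 9.
#' @param seed integer, kept for interface symmetry with the stochastic
#'   generators; the network is deterministic.
#' @return A \code{metabolic_model} with objective \code{"biomass"}.
#' @export
make_toy_network <- function(include_trp_branch = TRUE,
                             n_extra_reactions = 9, seed = 1) {
  rxn <- function(id, stoich, gpr = NULL, lb = 0, ub = 1000,
                  subsystem = "") {
    list(id = id, name = id, subsystem = subsystem, lb = lb, ub = ub,
         stoich = stoich, gpr = gpr)
  }
  ex <- function(met, lb = 0) {
    rxn(paste0("EX_", sub("_e$", "", met)), stats::setNames(-1, met), lb = lb,
        subsystem = "exchange")
  }
  mets <- c("glc_e", "glc_c", "g6p_c", "pyr_c", "lac_c", "lac_e",
            "o2_e", "o2_c", "co2_c", "co2_e",
            "accoa_c", "oaa_c", "cit_c", "akg_c", "atp_c", "nad_c")
  rxns <- list(
    ex("glc_e", lb = -10),
    ex("o2_e", lb = -20),
    ex("co2_e"),
    ex("lac_e"),
    rxn("GLCt", c(glc_e = -1, glc_c = 1), "g_glct", subsystem = "transport"),
    rxn("O2t", c(o2_e = -1, o2_c = 1), "g_o2t", subsystem = "transport"),
    rxn("CO2t", c(co2_c = -1, co2_e = 1), "g_co2t", subsystem = "transport"),
    rxn("LACt", c(lac_c = -1, lac_e = 1), "g_lact", subsystem = "transport"),
    rxn("HEX", c(glc_c = -1, g6p_c = 1), "g_hex1 or g_hex2",
        subsystem = "glycolysis"),
    rxn("GLY", c(g6p_c = -1, pyr_c = 2, atp_c = 2), "g_gly1 and g_gly2",
        subsystem = "glycolysis"),
    rxn("LDH", c(pyr_c = -1, lac_c = 1), "g_ldh", lb = -1000,
        subsystem = "glycolysis"),
    rxn("PDH", c(pyr_c = -1, accoa_c = 1, co2_c = 1), "g_pdh",
        subsystem = "tca"),
    rxn("PC", c(pyr_c = -1, co2_c = -1, oaa_c = 1), "g_pc",
        subsystem = "tca"),
    rxn("CS", c(accoa_c = -1, oaa_c = -1, cit_c = 1), "g_cs",
        subsystem = "tca"),
    rxn("TCA1", c(cit_c = -1, akg_c = 1, co2_c = 1), "g_tca1",
        subsystem = "tca"),
    rxn("TCA2", c(akg_c = -1, oaa_c = 1, co2_c = 1), "g_tca2",
        subsystem = "tca"),
    rxn("OXPHOS", c(accoa_c = -1, o2_c = -2, atp_c = 10, co2_c = 2),
        "g_ox1 and g_ox2", subsystem = "oxphos"))

  if (include_trp_branch) {
    mets <- c(mets, "trp_e", "trp_c", "nfk_c", "kyn_c", "hkyn_c", "haa_c",
              "acms_c", "namn_c")
    rxns <- c(rxns, list(
      ex("trp_e", lb = -5),
      rxn("TRPt", c(trp_e = -1, trp_c = 1), "g_trpt",
          subsystem = "trp_kynurenine"),
      rxn("IDO", c(trp_c = -1, nfk_c = 1), "g_ido1",
          subsystem = "trp_kynurenine"),
      rxn("KYNF", c(nfk_c = -1, kyn_c = 1), "g_kynf",
          subsystem = "trp_kynurenine"),
      rxn("KMO", c(kyn_c = -1, hkyn_c = 1), "g_kmo",
          subsystem = "trp_kynurenine"),
      rxn("KYNU", c(hkyn_c = -1, haa_c = 1), "g_kynu",
          subsystem = "trp_kynurenine"),
      rxn("HAAO", c(haa_c = -1, acms_c = 1), "g_haao",
          subsystem = "trp_kynurenine"),
      rxn("QPRT", c(acms_c = -1, namn_c = 1), "g_qprt",
          subsystem = "trp_kynurenine"),
      rxn("NADS", c(namn_c = -1, atp_c = -1, nad_c = 1),
          "g_nmnat and g_nads", subsystem = "trp_kynurenine")))
  }

  n_chains <- ceiling(max(0, n_extra_reactions) / 3)
  for (i in seq_len(n_chains)) {
    me <- sprintf("x%d_e", i); mc <- sprintf("x%d_c", i)
    mets <- c(mets, me, mc)
    rxns <- c(rxns, list(
      ex(me, lb = -1),
      rxn(sprintf("Xt%d", i), stats::setNames(c(-1, 1), c(me, mc)),
          sprintf("g_xt%d", i), subsystem = "extra"),
      rxn(sprintf("XDEG%d", i), stats::setNames(c(-1, 1), c(mc, "co2_c")),
          sprintf("g_xd%d", i), subsystem = "extra")))
  }

  rxns <- c(rxns, list(
    rxn("biomass", c(atp_c = -10, pyr_c = -1, oaa_c = -0.1, nad_c = -0.2),
        subsystem = "biomass")))

  metabolic_model(data.frame(id = mets, stringsAsFactors = FALSE), rxns,
                  objective_id = "biomass")
}

#' Toy network bookkeeping: pathway gene and reaction sets
#'
#' @return \code{toy_trp_genes}/\code{toy_trp_reactions}: the gene and
#'   reaction ids of the tryptophan/kynurenine branch;
#'   \code{toy_gene_sets}: a small pathway collection (GMT-style named
#'   list) covering the toy network plus a dummy set outside it;
#'   \code{toy_biomass}: the biomass coefficients;
#'   \code{toy_medium}: the default uptake bounds.
#' @export
toy_trp_genes <- function() {
  c("g_trpt", "g_ido1", "g_kynf", "g_kmo", "g_kynu", "g_haao", "g_qprt",
    "g_nmnat", "g_nads")
}

#' @rdname toy_trp_genes
#' @export
toy_trp_reactions <- function() {
  c("TRPt", "IDO", "KYNF", "KMO", "KYNU", "HAAO", "QPRT", "NADS")
}

#' @rdname toy_trp_genes
#' @export
toy_gene_sets <- function() {
  list(
    trp_kynurenine = toy_trp_genes(),
    glycolysis_like = c("g_glct", "g_hex1", "g_hex2", "g_gly1", "g_gly2",
                        "g_ldh", "g_lact"),
    tca_like = c("g_pdh", "g_pc", "g_cs", "g_tca1", "g_tca2", "g_ox1",
                 "g_ox2"),
    adhesion_like = sprintf("g_adh%d", 1:6))
}

#' @rdname toy_trp_genes
#' @export
toy_biomass <- function() c(atp_c = -10, pyr_c = -1, oaa_c = -0.1,
                            nad_c = -0.2)

#' @rdname toy_trp_genes
#' @param n_extra_chains number of extra nutrient chains the toy network
#'   was built with (see \code{n_extra_reactions}; default 3 chains).
#' @export
toy_medium <- function(n_extra_chains = 3) {
  c(EX_glc = -10, EX_o2 = -20, EX_trp = -5,
    stats::setNames(rep(-1, n_extra_chains),
                    sprintf("EX_x%d", seq_len(n_extra_chains))))
}

#' Specify an expression simulation
#'
#' Parameters of the batch-structured log2 expression generator. Defaults
#' are the package's reference scenario: 3 batches with additive shifts of
#' SD 2 log2 units and mild multiplicative scale drift, 20 samples per
#' condition per batch, residual noise SD 0.5 log2 units - the magnitude
#' of cross-platform batch structure the merged stem-cell compendia show
#' relative to biological signal.
#'
#' @param n_genes total genes in the simulated universe.
#' @param n_batches number of batches (\code{>= 1}).
#' @param samples_per_condition_per_batch samples per condition in each
#'   batch.
#' @param batch_shift_sd SD (log2 units) of both the per-batch mean shift
#'   and the per-gene additive batch effect around it.
#' @param batch_scale_range range of the per-gene, per-batch
#'   multiplicative noise scale.
#' @param de_genes named numeric vector: gene id -> planted logFC
#'   (log2, naive - primed).
#' @param noise_sd residual noise SD (log2 units, \code{> 0}).
#' @param seed integer RNG seed; generation is a pure function of the
#'   spec.
#' @return An object of class \code{expression_sim_spec}.
#' @export
expression_sim_spec <- function(n_genes = 2000, n_batches = 3,
                                samples_per_condition_per_batch = 20,
                                batch_shift_sd = 2,
                                batch_scale_range = c(0.8, 1.25),
                                de_genes = numeric(0),
                                noise_sd = 0.5, seed = 1) {
  stopifnot(n_genes >= 1, n_batches >= 1,
            samples_per_condition_per_batch >= 1,
            batch_shift_sd >= 0, length(batch_scale_range) == 2,
            batch_scale_range[1] > 0,
            batch_scale_range[1] <= batch_scale_range[2],
            noise_sd > 0)
  if (length(de_genes) && is.null(names(de_genes))) {
    stop("de_genes must be a named numeric vector (gene -> logFC)",
         call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_batches = n_batches,
                 samples_per_condition_per_batch = samples_per_condition_per_batch,
                 batch_shift_sd = batch_shift_sd,
                 batch_scale_range = batch_scale_range,
                 de_genes = de_genes, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' Plant a whole-pathway downregulation into a simulation spec
#'
#' Extends the spec's planted differential genes with every pathway gene
#' at the given fold change (negative = down in naive). Replanting a gene
#' already planted at a different fold change is an error.
#'
#' @param spec an \code{expression_sim_spec}.
#' @param pathway_genes gene ids (must be within the spec's universe when
#'   simulated).
#' @param logfc planted log2 fold change (naive - primed).
#' @return The extended \code{expression_sim_spec}.
#' @export
plant_pathway_downregulation <- function(spec, pathway_genes, logfc) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  if (!length(pathway_genes)) return(spec)
  existing <- intersect(pathway_genes, names(spec$de_genes))
  clash <- existing[spec$de_genes[existing] != logfc]
  if (length(clash)) {
    stop("gene(s) already planted at a different logFC: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  add <- setdiff(pathway_genes, existing)
  spec$de_genes <- c(spec$de_genes, stats::setNames(rep(logfc, length(add)), add))
  spec
}

#' Simulate a batch-structured expression matrix
#'
#' Generates \code{x[g,s] = mu_g + Delta_g I(naive) + gamma_{g,b(s)} +
#' phi_{g,b(s)} eps_{g,s}} with per-gene baselines
#' \code{mu_g ~ N(7, 1.5)} (log2 microarray-like scale), per-batch mean
#' shifts \code{m_b ~ N(0, batch_shift_sd)}, additive batch effects
#' \code{gamma_{g,b} ~ N(m_b, batch_shift_sd)}, multiplicative scales
#' \code{phi_{g,b} ~ U(batch_scale_range)}, and noise
#' \code{eps ~ N(0, noise_sd)}. \code{Delta_g} is the planted logFC for
#' \code{de_genes} and 0 otherwise. Deterministic for a fixed spec.
#'
#' The gene universe is the model genes (in order) padded with filler ids
#' \code{gene0001, gene0002, ...} up to \code{n_genes}.
#'
#' @param model_genes gene ids to place at the head of the universe (may
#'   be empty).
#' @param spec an \code{expression_sim_spec}.
#' @return An \code{expression_matrix} with batch/condition metadata.
#' @export
simulate_expression <- function(model_genes = character(0), spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  model_genes <- unique(as.character(model_genes))
  if (length(model_genes) > spec$n_genes) {
    stop("n_genes smaller than the number of model genes", call. = FALSE)
  }
  n_fill <- spec$n_genes - length(model_genes)
  genes <- c(model_genes, sprintf("gene%04d", seq_len(n_fill)))
  bad <- setdiff(names(spec$de_genes), genes)
  if (length(bad)) {
    stop("de_genes outside the simulated universe: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  nb <- spec$n_batches
  spc <- spec$samples_per_condition_per_batch
  n_samples <- nb * 2L * spc
  batch <- rep(sprintf("b%d", seq_len(nb)), each = 2L * spc)
  condition <- rep(rep(c("naive", "primed"), each = spc), times = nb)
  samples <- sprintf("s%03d", seq_len(n_samples))

  set.seed(spec$seed)
  mu <- stats::rnorm(spec$n_genes, mean = 7, sd = 1.5)
  delta <- stats::setNames(rep(0, spec$n_genes), genes)
  delta[names(spec$de_genes)] <- spec$de_genes
  m_b <- stats::rnorm(nb, 0, spec$batch_shift_sd)
  gamma <- sapply(seq_len(nb), function(b) {
    stats::rnorm(spec$n_genes, m_b[b], spec$batch_shift_sd)
  })
  phi <- sapply(seq_len(nb), function(b) {
    stats::runif(spec$n_genes, spec$batch_scale_range[1],
                 spec$batch_scale_range[2])
  })
  gamma <- matrix(gamma, nrow = spec$n_genes)
  phi <- matrix(phi, nrow = spec$n_genes)

  bidx <- rep(seq_len(nb), each = 2L * spc)
  eps <- matrix(stats::rnorm(spec$n_genes * n_samples, 0, spec$noise_sd),
                nrow = spec$n_genes)
  vals <- mu + outer(delta, as.numeric(condition == "naive")) +
    gamma[, bidx, drop = FALSE] + phi[, bidx, drop = FALSE] * eps
  dimnames(vals) <- list(genes, samples)
  expression_matrix(vals, batch, condition)
}
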