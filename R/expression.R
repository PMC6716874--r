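#' Construct an expression matrix with sample metadata
#'
#' Log2-scale gene x sample values with per-sample batch and condition
#' labels (\code{"naive"}/\code{"primed"}).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); no missing values.
#' @param batch character/factor of per-sample batch labels.
#' @param condition character/factor of per-sample condition labels.
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, batch, condition) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stop("expression values contain missing entries", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids", call. = FALSE)
  batch <- as.character(batch); condition <- as.character(condition)
  if (length(batch) != ncol(values) || length(condition) != ncol(values)) {
    stop("batch and condition must label every sample", call. = FALSE)
  }
  if (anyNA(batch) || anyNA(condition)) {
    stop("batch/condition labels contain missing values", call. = FALSE)
  }
  structure(list(values = values,
                 genes = rownames(values),
                 samples = colnames(values),
                 batch = batch,
                 condition = condition),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d batches; conditions: %s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch)),
              paste(sort(unique(x$condition)), collapse = "/")))
  invisible(x)
}

#' Write / read an expression matrix as TSV
#'
#' Values go to \code{path} (genes x samples, first column \code{gene});
#' metadata to \code{metadata_path} (columns sample, batch, condition).
#'
#' @param x an \code{expression_matrix}.
#' @param path,metadata_path file paths.
#' @return \code{write_expression}: \code{path} invisibly;
#'   \code{read_expression}: an \code{expression_matrix}.
#' @export
write_expression <- function(x, path, metadata_path) {
  df <- data.frame(gene = x$genes, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- data.frame(sample = x$samples, batch = x$batch,
                   condition = x$condition, stringsAsFactors = FALSE)
  utils::write.table(md, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, metadata_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  md <- md[match(colnames(vals), md$sample), ]
  expression_matrix(vals, md$batch, md$condition)
}

#' Median-center samples to a common scale
#'
#' Shifts each sample so its median equals the global median of the input
#' per-sample medians; gene and sample order are preserved, and rank
#' order within each sample is unchanged. Constant-zero samples are left
#' unshifted with a warning.
#'
#' @param x an \code{expression_matrix}.
#' @return The normalized \code{expression_matrix}.
#' @export
normalize_medians <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  meds <- apply(x$values, 2, stats::median)
  target <- stats::median(meds)
  zero <- apply(x$values, 2, function(v) all(v == 0))
  if (any(zero)) {
    warning("constant-zero sample(s) left unshifted: ",
            paste(x$samples[zero], collapse = ", "), call. = FALSE)
  }
  shift <- target - meds
  shift[zero] <- 0
  x$values <- sweep(x$values, 2, shift, `+`)
  x
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Removes additive and multiplicative batch effects by the parametric
#' empirical-Bayes location/scale model, with the condition label
#' protected as a covariate in the design (condition effects are never
#' removed). Gene/sample ordering and metadata are untouched.
#'
#' @param x an \code{expression_matrix} with at least 2 batches and 2
#'   samples per batch.
#' @return The corrected \code{expression_matrix}.
#' @export
combat_correct <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  tb <- table(x$batch)
  if (length(tb) < 2L) stop("need at least 2 batches", call. = FALSE)
  if (any(tb < 2L)) {
    stop("need at least 2 samples per batch; too few in: ",
         paste(names(tb)[tb < 2L], collapse = ", "), call. = FALSE)
  }
  pure <- vapply(split(x$condition, x$batch),
                 function(cc) length(unique(cc)) == 1L, logical(1))
  if (any(pure)) {
    stop("batch(es) entirely confounded with one condition ",
         "(effect not estimable): ",
         paste(names(pure)[pure], collapse = ", "), call. = FALSE)
  }
  mod <- stats::model.matrix(~condition, data = data.frame(condition = x$condition))
  corrected <- suppressMessages(
    sva::ComBat(dat = x$values, batch = x$batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE))
  x$values <- corrected
  x
}

#' Principal component scores of samples
#'
#' Projects samples onto the top right-singular directions of the
#' gene-centered matrix.
#'
#' @param x an \code{expression_matrix}.
#' @param n_components number of components (\code{<= min(genes, samples)}).
#' @return List with \code{scores} (samples x n_components) and
#'   \code{explained} (non-increasing variance fractions).
#' @export
pca_scores <- function(x, n_components = 2) {
  stopifnot(inherits(x, "expression_matrix"))
  if (n_components <= 0) stop("n_components must be positive", call. = FALSE)
  maxc <- min(nrow(x$values), ncol(x$values))
  if (n_components > maxc) {
    stop("n_components exceeds min(genes, samples) = ", maxc, call. = FALSE)
  }
  pc <- stats::prcomp(t(x$values), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)])
}

#' Cluster samples and quantify heterogeneity
#'
#' Seeded k-means with 50 restarts on sample scores; reports the mean
#' silhouette width and the adjusted Rand index between the clustering
#' and a reference labelling (e.g., derivation protocol). A mean
#' silhouette below 0.25 is this module's "no major heterogeneity" call.
#'
#' @param scores numeric matrix of sample scores (samples in rows).
#' @param k number of clusters (\code{>= 2}, \code{<= n samples}).
#' @param labels reference labels per sample.
#' @param seed integer RNG seed.
#' @param nstart k-means restarts (default 50).
#' @return List with \code{cluster}, \code{silhouette_mean}, \code{ari}.
#' @export
kmeans_heterogeneity <- function(scores, k, labels, seed = 1, nstart = 50) {
  scores <- as.matrix(scores)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > nrow(scores)) stop("k exceeds number of samples", call. = FALSE)
  stopifnot(length(labels) == nrow(scores))
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = nstart)
  sil <- cluster::silhouette(km$cluster, stats::dist(scores))
  list(cluster = km$cluster,
       silhouette_mean = mean(sil[, "sil_width"]),
       ari = mclust::adjustedRandIndex(km$cluster, labels))
}

#' Two-group differential expression (Welch t-test)
#'
#' Per gene: \code{logFC = mean(naive) - mean(primed)} on the log2 scale,
#' Welch two-sample t-test p-value, Benjamini-Hochberg adjustment across
#' all tested genes. Genes with zero variance in both groups get
#' \code{p = 1} by convention and are flagged.
#'
#' @param x an \code{expression_matrix} with both conditions present
#'   (\code{>= 2} samples each).
#' @return data.frame of class \code{de_result} with columns \code{gene},
#'   \code{logFC}, \code{p_value}, \code{adj_p}, \code{zero_variance}.
#' @export
differential_expression <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  i_n <- x$condition == "naive"
  i_p <- x$condition == "primed"
  if (sum(i_n) < 2 || sum(i_p) < 2) {
    stop("need >= 2 samples per condition", call. = FALSE)
  }
  vn <- x$values[, i_n, drop = FALSE]
  vp <- x$values[, i_p, drop = FALSE]
  n1 <- ncol(vn); n2 <- ncol(vp)
  m1 <- rowMeans(vn); m2 <- rowMeans(vp)
  s1 <- rowSums((vn - m1)^2) / (n1 - 1)
  s2 <- rowSums((vp - m2)^2) / (n2 - 1)
  se2 <- s1 / n1 + s2 / n2
  zero_var <- se2 == 0
  tstat <- ifelse(zero_var, 0, (m1 - m2) / sqrt(pmax(se2, .Machine$double.xmin)))
  df <- ifelse(zero_var, 1,
               se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1)))
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(tstat), df))
  out <- data.frame(gene = x$genes,
                    logFC = m1 - m2,
                    p_value = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    zero_variance = zero_var,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Significance panel for marker genes
#'
#' Tabulates known condition markers with their fold change, adjusted
#' p-value, significance tier (\code{*} at adj_p < 1e-2, \code{**} at
#' < 1e-4, \code{***} at < 1e-6), and whether the sign of the fold change
#' matches the expected direction (\code{"naive"} = up in naive, i.e.
#' positive logFC; \code{"primed"} = negative).
#'
#' @param de a \code{de_result}.
#' @param markers data.frame with columns \code{gene} and
#'   \code{expected_direction} (\code{"naive"}/\code{"primed"}).
#' @return data.frame \code{(gene, logFC, adj_p, tier,
#'   direction_consistent)}; markers absent from the DE universe are
#'   reported in attribute \code{"missing"}.
#' @export
marker_panel <- function(de, markers) {
  stopifnot(inherits(de, "de_result"),
            all(c("gene", "expected_direction") %in% names(markers)))
  present <- markers$gene %in% de$gene
  missing <- markers$gene[!present]
  mk <- markers[present, , drop = FALSE]
  idx <- match(mk$gene, de$gene)
  adj <- de$adj_p[idx]
  tier <- ifelse(adj < 1e-6, "***",
          ifelse(adj < 1e-4, "**",
          ifelse(adj < 1e-2, "*", "ns")))
  expected_sign <- ifelse(mk$expected_direction == "naive", 1, -1)
  out <- data.frame(gene = mk$gene,
                    logFC = de$logFC[idx],
                    adj_p = adj,
                    tier = tier,
                    direction_consistent = sign(de$logFC[idx]) == expected_sign,
                    stringsAsFactors = FALSE)
  attr(out, "missing") <- missing
  out
}
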