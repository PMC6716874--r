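make_x <- function(vals, batch = rep("b1", ncol(vals)),
                   condition = rep(c("naive", "primed"), length.out = ncol(vals))) {
  rownames(vals) <- sprintf("g%02d", seq_len(nrow(vals)))
  colnames(vals) <- sprintf("s%02d", seq_len(ncol(vals)))
  expression_matrix(vals, batch, condition)
}

test_that("median normalization equalizes sample medians and preserves ranks", {
  set.seed(1)
  vals <- cbind(rnorm(99, 5), rnorm(99, 7))
  x <- make_x(vals)
  xn <- normalize_medians(x)
  meds <- apply(xn$values, 2, median)
  expect_equal(unname(meds), rep(median(apply(vals, 2, median)), 2))
  # idempotent
  xn2 <- normalize_medians(xn)
  expect_equal(xn2$values, xn$values, tolerance = 1e-12)
  # within-sample rank order preserved
  for (j in 1:2) {
    expect_identical(order(xn$values[, j]), order(vals[, j]))
  }
  # constant-zero sample warned and left alone
  vals0 <- cbind(rnorm(20, 5), rep(0, 20), rnorm(20, 6))
  expect_warning(x0 <- normalize_medians(make_x(vals0)), "constant-zero")
  expect_equal(unname(x0$values[, 2]), rep(0, 20))
})

test_that("batch correction leaves null-batch data nearly untouched", {
  spec <- expression_sim_spec(n_genes = 400, n_batches = 2,
                              samples_per_condition_per_batch = 10,
                              batch_shift_sd = 0, batch_scale_range = c(1, 1),
                              noise_sd = 0.5, seed = 71)
  x <- simulate_expression(character(0), spec)
  xc <- combat_correct(x)
  rms <- sqrt(rowMeans((xc$values - x$values)^2))
  expect_lt(median(rms), 0.5 / 4)
  expect_identical(xc$genes, x$genes)
  expect_identical(xc$samples, x$samples)
  expect_identical(xc$batch, x$batch)
})

test_that("batch correction removes planted shifts while keeping condition effects", {
  spec <- expression_sim_spec(n_genes = 500, n_batches = 3,
                              samples_per_condition_per_batch = 10,
                              batch_shift_sd = 2, seed = 72,
                              de_genes = stats::setNames(rep(2, 50), sprintf("gene%04d", 1:50)))
  x <- simulate_expression(character(0), spec)
  gap <- function(v) {
    bm <- tapply(v, x$batch, mean)
    max(bm) - min(bm)
  }
  gap_before <- apply(x$values, 1, gap)
  xc <- combat_correct(x)
  gap_after <- apply(xc$values, 1, gap)
  expect_gte(1 - median(gap_after) / median(gap_before), 0.90)
  # planted condition effect survives
  de <- differential_expression(xc)
  planted <- de$gene %in% sprintf("gene%04d", 1:50)
  expect_gt(median(de$logFC[planted]), 1.5)
})

test_that("symmetric opposite batch shifts cancel exactly up to noise", {
  set.seed(9)
  n <- 20
  base <- matrix(rnorm(10 * 2 * n, 6, 0.01), nrow = 10)
  shift <- matrix(rep(c(rep(3, n), rep(-3, n)), each = 10), nrow = 10)
  x <- make_x(base + shift, batch = rep(c("b1", "b2"), each = n),
              condition = rep(rep(c("naive", "primed"), each = n / 2), 2))
  xc <- combat_correct(x)
  bm <- apply(xc$values, 1, function(v) tapply(v, x$batch, mean))
  expect_lt(max(abs(bm[1, ] - bm[2, ])), 0.05)
})

test_that("confounded or undersized batch designs are rejected with names", {
  vals <- matrix(rnorm(40), nrow = 4)
  expect_error(combat_correct(make_x(vals, batch = rep("b1", 10))),
               "at least 2 batches")
  expect_error(combat_correct(make_x(vals, batch = c("b1", rep("b2", 9)))),
               "b1")
  x <- make_x(vals, batch = rep(c("b1", "b2"), each = 5),
              condition = rep(c("naive", "primed"), each = 5))
  expect_error(combat_correct(x), "confounded.*b1")
})

test_that("PCA scores match the SVD projection and flag planted structure", {
  set.seed(11)
  vals <- matrix(rnorm(50 * 8), nrow = 50)
  x <- make_x(vals)
  pc <- pca_scores(x, n_components = 3)
  # independent SVD oracle on the gene-centered matrix
  cen <- t(scale(t(vals), center = TRUE, scale = FALSE))
  sv <- svd(t(cen))
  proj <- t(cen) %*% sv$v[, 1:3]
  for (j in 1:3) {
    expect_lt(min(max(abs(pc$scores[, j] - proj[, j])),
                  max(abs(pc$scores[, j] + proj[, j]))), 1e-8)
  }
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  # identical samples get identical scores
  vals2 <- cbind(vals[, 1], vals[, 1], vals[, 2:4])
  pc2 <- pca_scores(make_x(vals2), 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-10)
  # one planted direction dominates
  dir_g <- rnorm(50)
  vals3 <- outer(dir_g, rnorm(12, 0, 4)) + matrix(rnorm(50 * 12, 0, 0.1), 50)
  pc3 <- pca_scores(make_x(vals3), 2)
  expect_gt(pc3$explained[1], 0.9)
  expect_error(pca_scores(x, 0), "positive")
  expect_error(pca_scores(x, 100), "exceeds")
})

test_that("k-means heterogeneity separates blobs and flags homogeneity", {
  set.seed(13)
  blob <- rbind(matrix(rnorm(30 * 2, 0), ncol = 2),
                matrix(rnorm(30 * 2, 8), ncol = 2))
  labs <- rep(c("x", "y"), each = 30)
  r <- kmeans_heterogeneity(blob, 2, labs, seed = 1)
  expect_equal(r$ari, 1)
  # homogeneous single Gaussian: low silhouette = "no major heterogeneity"
  homo <- matrix(rnorm(60 * 10), ncol = 10)
  r2 <- kmeans_heterogeneity(homo, 2, rep(c("x", "y"), 30), seed = 2)
  expect_lt(r2$silhouette_mean, 0.25)
  # deterministic under a fixed seed
  r3 <- kmeans_heterogeneity(homo, 2, rep(c("x", "y"), 30), seed = 2)
  expect_identical(r2$cluster, r3$cluster)
  expect_error(kmeans_heterogeneity(blob, 100, labs), "exceeds")
})

test_that("differential expression follows the Welch t + BH definition", {
  set.seed(21)
  vals <- matrix(rnorm(200 * 12, 5, 1), nrow = 200)
  x <- make_x(vals, condition = rep(c("naive", "primed"), each = 6))
  de <- differential_expression(x)
  expect_true(all(de$adj_p >= de$p_value - 1e-12))
  expect_true(all(de$adj_p >= 0 & de$adj_p <= 1))
  # per-gene oracle via stats::t.test
  for (i in c(1, 50, 200)) {
    tt <- t.test(vals[i, 1:6], vals[i, 7:12])
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-10)
    expect_equal(de$logFC[i], mean(vals[i, 1:6]) - mean(vals[i, 7:12]))
  }
  # identical group means give logFC 0; zero-variance genes flagged at p = 1
  vals2 <- rbind(rep(c(1, 2), 6), rep(3, 12))
  de2 <- differential_expression(make_x(matrix(vals2, nrow = 2),
                                        condition = rep(c("naive", "primed"), each = 6)))
  expect_true(de2$zero_variance[2])
  expect_equal(de2$p_value[2], 1)
  # BH equals the step-up definition on random p-vectors
  for (rep in 1:5) {
    p <- runif(50)
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("planted DE is recovered with controlled FDR", {
  planted <- sprintf("gene%04d", 1:200)
  spec <- expression_sim_spec(n_genes = 2200, n_batches = 1,
                              samples_per_condition_per_batch = 20,
                              batch_shift_sd = 0, batch_scale_range = c(1, 1),
                              noise_sd = 0.5, seed = 31,
                              de_genes = stats::setNames(rep(c(2, -2), 100), planted))
  x <- simulate_expression(character(0), spec)
  de <- differential_expression(x)
  called <- de$gene[de$adj_p < 0.05]
  sens <- mean(planted %in% called)
  fdr <- if (length(called)) mean(!called %in% planted) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("the marker panel tiers significance and checks direction", {
  planted <- c(up1 = 2, dn1 = -2)
  spec <- expression_sim_spec(n_genes = 500, n_batches = 1,
                              samples_per_condition_per_batch = 20,
                              batch_shift_sd = 0, batch_scale_range = c(1, 1),
                              noise_sd = 0.5, seed = 41, de_genes = planted)
  x <- simulate_expression(c("up1", "dn1", "null1"), spec)
  de <- differential_expression(x)
  markers <- data.frame(gene = c("up1", "dn1", "null1", "absent1"),
                        expected_direction = c("naive", "primed", "naive", "naive"))
  panel <- marker_panel(de, markers)
  expect_identical(attr(panel, "missing"), "absent1")
  expect_true(panel$direction_consistent[panel$gene == "up1"])
  expect_true(panel$direction_consistent[panel$gene == "dn1"])
  expect_true(panel$tier[panel$gene == "up1"] %in% c("*", "**", "***"))
  expect_identical(panel$tier[panel$gene == "null1"], "ns")
})
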