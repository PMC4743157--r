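test_that("boxplot stats follow the Tukey convention", {
  set.seed(1)
  vals <- matrix(rnorm(200), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  panel <- panel_boxplot(expression_matrix(vals))
  expect_equal(nrow(panel$stats), 10)
  x <- vals[, 3]
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  r <- panel$stats[3, ]
  expect_equal(c(r$lower, r$middle, r$upper), q)
  expect_equal(r$ymin, min(x[x >= q[1] - 1.5 * iqr]))
  expect_equal(r$ymax, max(x[x <= q[3] + 1.5 * iqr]))
  expect_error(panel_boxplot(expression_matrix(vals), c("g1", "nope")),
               "nope")
})

test_that("stacked histogram shares bin edges and stacks by first appearance", {
  v <- c(rnorm(30), rnorm(20, 3))
  cl <- c(rep("B", 30), rep("A", 20))
  panel <- panel_histogram(v, cl)
  expect_identical(panel$classes, c("B", "A"))   # first-appearance order
  expect_equal(nrow(panel$counts), 2)
  expect_equal(length(panel$breaks), grDevices::nclass.Sturges(v) + 1)
  expect_equal(sum(panel$counts), length(v))
  # per-class counts partition the pooled histogram in every bin
  pooled <- graphics::hist(v, breaks = panel$breaks, plot = FALSE)$counts
  expect_equal(unname(colSums(panel$counts)), pooled)
})

test_that("cluster producer yields one block per cluster in id order", {
  ex <- make_expression(n_genes = 200, seed = 13)
  model <- blocks_from_clusters(ex$exprs, ex$assignment)
  expect_length(model$blocks, 5)
  expect_identical(vapply(model$blocks, `[[`, character(1), "title"),
                   paste("Cluster", 1:5))
  expect_identical(model$panel_kind, "boxplot")
  counts <- vapply(model$blocks, function(b)
    length(b$gene_lists[[1]]$genes), integer(1))
  expect_equal(sum(counts), 200)
  expect_identical(model$blocks[[1]]$annotation,
                   paste(counts[1], "genes"))
})

test_that("single-cluster panel equals whole-matrix per-sample stats", {
  ex <- make_expression(n_genes = 50, seed = 14)
  one <- setNames(rep(1, 50), names(ex$assignment))
  model <- blocks_from_clusters(ex$exprs, one)
  expect_length(model$blocks, 1)
  expect_equal(model$blocks[[1]]$panel$stats,
               panel_boxplot(ex$exprs)$stats)
})

test_that("cluster producer rejects genes absent from the matrix", {
  ex <- make_expression(n_genes = 50, seed = 15)
  bad <- setNames(1, "ghost_gene")
  expect_error(blocks_from_clusters(ex$exprs, bad), "ghost_gene")
})

test_that("DE producer splits by effect sign at the threshold", {
  de <- data.frame(gene = paste0("g", 1:20),
                   effect = c(rep(2, 10), rep(-1, 3), rep(1.5, 4), 0, 0, 0),
                   p_adj = c(rep(0.01, 13), rep(0.5, 4), 0.01, 0.01, 0.01))
  model <- blocks_from_de(de)
  b <- model$blocks[[1]]
  expect_length(b$gene_lists, 2)
  expect_identical(b$annotation, c("3 genes", "10 genes"))
  expect_identical(b$gene_lists[[1]]$side, "down")
  expect_identical(b$gene_lists[[2]]$side, "up")
  # effect exactly 0 joins neither side even when significant
  expect_false(any(c("g18", "g19", "g20") %in%
                   unlist(lapply(b$gene_lists, `[[`, "genes"))))
})

test_that("DE producer emits a block even when nothing is significant", {
  de <- data.frame(gene = paste0("g", 1:6), effect = rnorm(6),
                   p_adj = rep(0.5, 6))
  model <- blocks_from_de(de, threshold = 0.05)
  b <- model$blocks[[1]]
  expect_length(b$gene_lists[[1]]$genes, 0)
  expect_length(b$gene_lists[[2]]$genes, 0)
  expect_identical(b$annotation, c("0 genes", "0 genes"))
})

test_that("PCA matches the closed-form 2-gene eigendecomposition", {
  # one high-variance gene, one low: PC1 aligns with the former
  vals <- rbind(big = c(-3, -1, 1, 3), small = c(0.5, -0.5, 0.5, -0.5))
  colnames(vals) <- paste0("s", 1:4)
  fit <- pca(expression_matrix(vals))
  expect_gt(abs(fit$loadings["big", 1]), abs(fit$loadings["small", 1]))
  expect_gt(fit$var_pct[1], fit$var_pct[2])
  # closed form: eigenvalues of the 2x2 covariance matrix
  ev <- eigen(stats::cov(t(vals)))$values
  expect_equal(fit$var_pct, 100 * ev / sum(ev), tolerance = 1e-10)
})

test_that("PCA output satisfies its structural invariants", {
  ex <- make_expression(n_genes = 80, n_samples = 18, seed = 16)
  fit <- pca(ex$exprs)
  L <- fit$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$var_pct) <= 1e-10))
  expect_lte(sum(fit$var_pct), 100 + 1e-8)
  # reconstruction: scores %*% t(loadings) recovers the centred matrix
  centred <- t(scale(t(ex$exprs$values), center = TRUE, scale = FALSE))
  expect_equal(t(fit$scores %*% t(L)), centred, tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading of each component is >= 0
  for (j in seq_len(ncol(L)))
    expect_gte(L[which.max(abs(L[, j])), j], 0)
})

test_that("PCA producer caps each loading side at n_genes", {
  pe <- make_planted_expression(n_genes = 2000, seed = 17)
  model <- blocks_from_pca(pe$exprs, n_comp = 2, n_genes = 500)
  for (b in model$blocks) {
    neg <- b$gene_lists[[1]]$genes
    pos <- b$gene_lists[[2]]$genes
    expect_length(pos, 500)
    expect_length(neg, 500)
    expect_length(intersect(pos, neg), 0)
  }
  expect_identical(model$panel_kind, "histogram")
  expect_match(model$blocks[[1]]$panel$note, "%$")
})

test_that("side lists hold min(n_genes, genes of that sign)", {
  vals <- matrix(rnorm(40), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  model <- blocks_from_pca(expression_matrix(vals), n_comp = 1,
                           n_genes = 500)
  l <- attr(model, "pca")$loadings[, 1]
  expect_length(model$blocks[[1]]$gene_lists[[2]]$genes, sum(l > 0))
  expect_length(model$blocks[[1]]$gene_lists[[1]]$genes, sum(l < 0))
})

test_that("excess components are clamped with a warning", {
  vals <- matrix(rnorm(40), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_warning(model <- blocks_from_pca(expression_matrix(vals),
                                          n_comp = 99),
                 "clamped")
  expect_lte(length(model$blocks), 4)
})

test_that("Bray-Curtis dissimilarity matches hand evaluation", {
  ab <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3),
              d = c(0, 0, 5))
  d <- bray_curtis(ab)
  expect_equal(d["a", "b"], 4 / 12)
  expect_equal(d["a", "c"], 0)              # identical rows
  expect_equal(d["a", "d"], (1 + 2 + 2) / (1 + 2 + 8))
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 4), rownames(ab)))
  expect_true(all(d >= 0 & d <= 1))
  # disjoint support
  dd <- bray_curtis(rbind(x = c(1, 0), y = c(0, 2)))
  expect_equal(dd["x", "y"], 1)
  expect_error(bray_curtis(rbind(c(-1, 2), c(0, 1))), "negative")
  expect_warning(z <- bray_curtis(rbind(a = c(0, 0), b = c(0, 0),
                                        c = c(1, 1))),
                 "all-zero")
  expect_equal(z["a", "b"], 0)
})

test_that("PCoA embeds Euclidean planar distances exactly", {
  set.seed(18)
  pts <- matrix(rnorm(10), ncol = 2)
  d <- as.matrix(dist(pts))
  fit <- pcoa(d, n_axes = 2)
  expect_equal(as.matrix(dist(fit$coords)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$eigenvalues) <= 1e-10))
  # two identical samples land on the same coordinates
  d2 <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  fit2 <- pcoa(d2, n_axes = 2)
  expect_equal(unname(fit2$coords[1, ]), unname(fit2$coords[2, ]),
               tolerance = 1e-8)
})

test_that("PCoA of Euclidean distances reproduces the PCA spectrum", {
  set.seed(19)
  pts <- matrix(rnorm(8 * 5), nrow = 8)   # 8 samples, 5 features
  d <- as.matrix(dist(pts))
  fit <- pcoa(d, n_axes = 4)
  pr <- prcomp(pts, center = TRUE, scale. = FALSE)
  pca_eig <- pr$sdev^2 * (nrow(pts) - 1)
  k <- length(fit$eigenvalues)
  expect_equal(fit$eigenvalues, pca_eig[seq_len(k)], tolerance = 1e-8)
})

test_that("feature association recovers an exact axis copy", {
  ab <- make_abundance(n_features = 20, n_samples = 20, seed = 20)
  fit <- pcoa(bray_curtis(ab$counts), n_axes = 2)
  ab2 <- cbind(ab$counts, mirror = rank(fit$coords[, 1]))
  assoc <- pcoa_feature_assoc(ab2, fit$coords)
  row <- assoc[assoc$axis == 1 & assoc$feature == "mirror", ]
  expect_equal(row$rho, 1)
  expect_equal(row$p, min(assoc$p[assoc$axis == 1]))
})

test_that("constant features are excluded with a warning", {
  ab <- make_abundance(n_features = 15, n_samples = 12, seed = 21)
  ab2 <- cbind(ab$counts, flat = 7)
  fit <- pcoa(bray_curtis(ab$counts), n_axes = 2)
  expect_warning(assoc <- pcoa_feature_assoc(ab2, fit$coords), "constant")
  expect_false("flat" %in% assoc$feature)
})

test_that("PCoA producer builds feature clouds without an enrichment step", {
  ab <- make_abundance(seed = 22)
  model <- blocks_from_pcoa(ab$counts, n_axes = 2,
                            sample_classes = ab$classes)
  expect_length(model$blocks, 2)
  b <- model$blocks[[1]]
  expect_false(is.null(b$clouds[[1]]))
  expect_identical(b$clouds[[2]]$text, b$gene_lists[[2]]$genes)
  expect_true(all(b$clouds[[2]]$p <= 0.05))
  expect_match(b$annotation[1], "features")
  expect_error(blocks_from_pcoa(ab$counts[1:3, ]), "4 samples")
})
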