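#' Per-sample boxplot statistics
#'
#' Tukey convention: median and quartiles by linear interpolation
#' ([stats::quantile] type 7), whiskers at the most extreme observation
#' within 1.5 IQR of the box.
#'
#' @param exprs an [expression_matrix()] (or plain matrix).
#' @param genes gene ids selecting the rows summarised per sample.
#' @return A list of kind `"boxplot"` whose `stats` data frame has one row
#'   per sample: `sample`, `ymin`, `lower`, `middle`, `upper`, `ymax`.
#' @export
panel_boxplot <- function(exprs, genes = NULL) {
  exprs <- as_expression_matrix(exprs)
  v <- exprs$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing) > 0)
      stop("gene(s) absent from expression matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  stats <- do.call(rbind, lapply(colnames(v), function(s) {
    x <- v[, s]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    data.frame(sample = s, ymin = lo, lower = q[1], middle = q[2],
               upper = q[3], ymax = hi, stringsAsFactors = FALSE)
  }))
  rownames(stats) <- NULL
  list(kind = "boxplot", stats = stats)
}

#' Stacked-histogram panel statistics
#'
#' Bin edges are shared by all classes of the block (bin count by Sturges'
#' rule over the pooled values); classes stack in order of first appearance.
#'
#' @param values numeric vector (e.g. PCA scores of samples along one
#'   component).
#' @param classes class label per value; a single pooled class when `NULL`.
#' @param note optional annotation (e.g. percent variance explained).
#' @return A list of kind `"histogram"`: `breaks`, `counts`
#'   (class x bin matrix), `classes`, `note`.
#' @export
panel_histogram <- function(values, classes = NULL, note = NULL) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (is.null(classes)) classes <- rep("all", length(values))
  stopifnot(length(classes) == length(values))
  classes <- as.character(classes)
  nb <- grDevices::nclass.Sturges(values)
  breaks <- seq(min(values), max(values), length.out = nb + 1)
  if (breaks[1] == breaks[length(breaks)])
    breaks <- breaks[1] + c(-0.5, 0.5)
  lev <- unique(classes)
  counts <- t(vapply(lev, function(cl) {
    graphics::hist(values[classes == cl], breaks = breaks,
                   plot = FALSE)$counts
  }, numeric(length(breaks) - 1)))
  rownames(counts) <- lev
  list(kind = "histogram", breaks = breaks, counts = counts,
       classes = lev, note = note)
}

#' Blocks from a gene clustering
#'
#' One block per cluster, ordered by cluster id: the cluster members as a
#' single gene list, a per-sample boxplot panel of the members' expression,
#' and the member count as annotation. Empty clusters are skipped with a
#' warning.
#'
#' @param exprs an [expression_matrix()] (or genes x samples matrix).
#' @param assignment named vector mapping gene id -> cluster id (e.g.
#'   `kmeans()$cluster`), or a two-column data frame (gene, cluster).
#' @return A [summary_model()] with boxplot panels.
#' @export
blocks_from_clusters <- function(exprs, assignment) {
  exprs <- as_expression_matrix(exprs)
  if (is.data.frame(assignment)) {
    stopifnot(ncol(assignment) >= 2)
    assignment <- stats::setNames(assignment[[2]], as.character(assignment[[1]]))
  }
  if (is.null(names(assignment)))
    stop("assignment must be named by gene id")
  absent <- setdiff(names(assignment), exprs$gene_ids)
  if (length(absent) > 0)
    stop("assigned gene(s) absent from expression matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  groups <- split(names(assignment), assignment)
  groups <- groups[order(names(groups))]
  blocks <- list()
  for (cl in names(groups)) {
    members <- groups[[cl]]
    if (length(members) == 0) {
      warning("cluster '", cl, "' has no genes; skipped")
      next
    }
    blocks[[length(blocks) + 1L]] <- block(
      title = paste("Cluster", cl),
      gene_lists = list(gene_list(members, label = paste("Cluster", cl))),
      panel = panel_boxplot(exprs, members),
      annotation = paste(length(members), "genes"))
  }
  summary_model(blocks, panel_kind = "boxplot")
}

#' Blocks from a differential-expression table
#'
#' One block per contrast with two gene lists: up-regulated (effect > 0,
#' `p_adj <= threshold`) and down-regulated (effect < 0). Genes with effect
#' exactly 0 join neither side. Both counts go into the annotation; an empty
#' side still renders (as an empty cloud annotated "0 genes"). The panel
#' shows per-sample boxplots of the significant genes when an expression
#' matrix is supplied, otherwise only the counts.
#'
#' @param de_table data frame with columns `gene`, `effect` (signed, e.g.
#'   log fold change), `p_adj`, and optionally `contrast`.
#' @param threshold adjusted-p cutoff (default 0.05).
#' @param exprs optional [expression_matrix()] for the panels.
#' @return A [summary_model()].
#' @export
blocks_from_de <- function(de_table, threshold = 0.05, exprs = NULL) {
  stopifnot(all(c("gene", "effect", "p_adj") %in% names(de_table)))
  if (is.null(de_table$contrast)) de_table$contrast <- "contrast"
  blocks <- lapply(unique(de_table$contrast), function(ct) {
    d <- de_table[de_table$contrast == ct, , drop = FALSE]
    sig <- !is.na(d$p_adj) & d$p_adj <= threshold
    up <- d$gene[sig & d$effect > 0]
    down <- d$gene[sig & d$effect < 0]
    panel <- if (is.null(exprs) || length(c(up, down)) == 0) {
      list(kind = "none")
    } else {
      panel_boxplot(exprs, intersect(c(up, down),
                                     as_expression_matrix(exprs)$gene_ids))
    }
    block(title = ct,
          gene_lists = list(
            gene_list(down, label = paste(ct, "down"), side = "down",
                      allow_empty = TRUE),
            gene_list(up, label = paste(ct, "up"), side = "up",
                      allow_empty = TRUE)),
          panel = panel,
          annotation = c(paste(length(down), "genes"),
                         paste(length(up), "genes")))
  })
  kinds <- vapply(blocks, function(b) b$panel$kind, character(1))
  if (length(unique(kinds)) > 1)
    blocks <- lapply(blocks, function(b) { b$panel <- list(kind = "none"); b })
  summary_model(blocks)
}

#' Principal component analysis of an expression matrix
#'
#' Samples are the observations, genes the variables; the matrix is centred
#' per gene before the singular value decomposition (no variance scaling by
#' default, appropriate for log-scale expression values; set `scale. = TRUE`
#' otherwise). The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making outputs reproducible.
#'
#' @param exprs an [expression_matrix()] or genes x samples matrix.
#' @param scale. divide genes by their standard deviation before the
#'   decomposition (default `FALSE`).
#' @return An object of class `pca_result`: `loadings` (genes x components,
#'   orthonormal columns), `scores` (samples x components), `var_pct`
#'   (percent variance per component, non-increasing).
#' @export
pca <- function(exprs, scale. = FALSE) {
  exprs <- as_expression_matrix(exprs)
  x <- t(exprs$values)
  pr <- stats::prcomp(x, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    l <- pr$rotation[, j]
    l[which.max(abs(l))] < 0
  }, logical(1))
  pr$rotation[, flip] <- -pr$rotation[, flip]
  pr$x[, flip] <- -pr$x[, flip]
  var_pct <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  structure(list(loadings = pr$rotation, scores = pr$x,
                 var_pct = var_pct,
                 sample_classes = exprs$sample_classes),
            class = "pca_result")
}

#' Blocks from PCA loadings
#'
#' For each of the first `n_comp` components, two gene lists are built from
#' the loadings: the genes with the largest positive loadings and the genes
#' with the largest negative loadings (at most `n_genes` each, default 500;
#' genes with a loading of exactly 0 join neither). The panel is a stacked
#' histogram of the samples' scores along the component, coloured by sample
#' class, annotated with the percent variance the component explains.
#'
#' @param exprs an [expression_matrix()] or genes x samples matrix.
#' @param n_comp number of leading components (clamped, with a warning, to
#'   the number available).
#' @param n_genes maximum genes per loading side (default 500).
#' @param scale. passed to [pca()].
#' @return A [summary_model()] with histogram panels; the `pca_result` is
#'   attached as attribute `"pca"`.
#' @export
blocks_from_pca <- function(exprs, n_comp = 3, n_genes = 500, scale. = FALSE) {
  exprs <- as_expression_matrix(exprs)
  fit <- pca(exprs, scale. = scale.)
  avail <- ncol(fit$loadings)
  if (n_comp > avail) {
    warning("n_comp = ", n_comp, " clamped to ", avail,
            " available component(s)")
    n_comp <- avail
  }
  blocks <- lapply(seq_len(n_comp), function(cmp) {
    l <- fit$loadings[, cmp]
    pos <- names(sort(l[l > 0], decreasing = TRUE))
    neg <- names(sort(l[l < 0], decreasing = FALSE))
    pos <- utils::head(pos, n_genes)
    neg <- utils::head(neg, n_genes)
    note <- sprintf("%.1f%%", fit$var_pct[cmp])
    block(
      title = paste0("PC", cmp),
      gene_lists = list(
        gene_list(neg, label = paste0("PC", cmp, " negative"),
                  side = "negative", allow_empty = TRUE),
        gene_list(pos, label = paste0("PC", cmp, " positive"),
                  side = "positive", allow_empty = TRUE)),
      panel = panel_histogram(fit$scores[, cmp], exprs$sample_classes,
                              note = note),
      annotation = c(paste(length(neg), "genes"),
                     paste(length(pos), "genes")))
  })
  model <- summary_model(blocks, panel_kind = "histogram")
  attr(model, "pca") <- fit
  model
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x_if - x_jf| / sum (x_if + x_jf)` over features `f`; the
#' standard ecological distance for nonnegative abundance data. A pair of
#' samples that are both all-zero has an undefined ratio and is defined here
#' as distance 0, with a warning.
#'
#' @param abundance samples x features matrix of nonnegative abundances.
#' @return Symmetric matrix with zero diagonal, values in `[0, 1]`.
#' @export
bray_curtis <- function(abundance) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0))
    stop("negative abundance value; Bray-Curtis requires nonnegative data")
  # vegdist warns about all-zero rows on its own; the NA substitution below
  # raises the package's single canonical warning instead
  d <- as.matrix(suppressWarnings(vegan::vegdist(abundance, method = "bray")))
  if (anyNA(d)) {
    warning("all-zero sample pair(s): Bray-Curtis distance set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of `-d^2 / 2`, then an
#' eigendecomposition; the coordinates are the eigenvectors scaled by the
#' square root of their (positive) eigenvalues. Axes with negative
#' eigenvalues (non-Euclidean distances) are dropped, with a message
#' summarising their magnitude.
#'
#' @param d distance matrix (symmetric, zero diagonal) or `dist` object.
#' @param n_axes number of leading axes to keep.
#' @return An object of class `pcoa_result`: `coords` (samples x axes),
#'   `eigenvalues` (positive, non-increasing), `neg_eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 3) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric with a zero diagonal")
  fit <- ape::pcoa(stats::as.dist(d))
  eig <- fit$values$Eigenvalues
  tol <- max(abs(eig)) * 1e-12
  pos <- eig[eig > tol]
  neg <- eig[eig < -tol]
  if (length(pos) == 0) stop("no positive eigenvalue; cannot embed distances")
  if (length(neg) > 0)
    message(length(neg), " negative eigenvalue(s) dropped (largest magnitude ",
            format(max(abs(neg)), digits = 3), ")")
  k <- min(n_axes, ncol(fit$vectors), length(pos))
  coords <- fit$vectors[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(coords = coords, eigenvalues = pos,
                 neg_eigenvalues = neg),
            class = "pcoa_result")
}

#' Feature-axis association by Spearman correlation
#'
#' For every feature, the Spearman correlation of its abundances with the
#' sample coordinates along each ordination axis, with a two-sided test
#' ([spearman_test()]: exact permutation p for small n) and
#' Benjamini-Hochberg correction across features within each axis. Constant
#' features are excluded with a warning.
#'
#' @param abundance samples x features matrix.
#' @param coords samples x axes coordinate matrix (e.g. `pcoa()$coords`).
#' @return A data frame: `axis`, `feature`, `rho`, `p`, `p_adj`.
#' @export
pcoa_feature_assoc <- function(abundance, coords) {
  abundance <- as.matrix(abundance)
  stopifnot(nrow(abundance) == nrow(coords))
  feats <- colnames(abundance)
  if (is.null(feats)) feats <- paste0("F", seq_len(ncol(abundance)))
  keep <- apply(abundance, 2, function(x) stats::sd(x) > 0)
  if (any(!keep))
    warning(sum(!keep), " constant feature(s) excluded from association tests")
  out <- do.call(rbind, lapply(seq_len(ncol(coords)), function(ax) {
    tests <- lapply(which(keep), function(f)
      spearman_test(abundance[, f], coords[, ax]))
    df <- data.frame(axis = ax, feature = feats[keep],
                     rho = vapply(tests, `[[`, numeric(1), "rho"),
                     p = vapply(tests, `[[`, numeric(1), "p"),
                     stringsAsFactors = FALSE)
    df$p_adj <- stats::p.adjust(df$p, method = "BH")
    df
  }))
  rownames(out) <- NULL
  out
}

#' Blocks from a PCoA of abundance data
#'
#' Ordination counterpart of [blocks_from_pca()] for data without loadings
#' (e.g. taxon abundances): samples are embedded by PCoA on Bray-Curtis
#' dissimilarities, and each axis gets a block whose word clouds show the
#' feature names significantly correlated (positively, right cloud) or
#' anti-correlated (negatively, left cloud) with the axis, sized by
#' `-log10` of the BH-adjusted Spearman test p-value. No enrichment step is
#' involved. The panel is a stacked histogram of the axis coordinates by
#' sample class, annotated with the axis' relative eigenvalue.
#'
#' @param abundance samples x features matrix of nonnegative abundances
#'   (at least 4 samples).
#' @param n_axes number of leading axes (default 3).
#' @param alpha threshold on the adjusted p (default 0.05).
#' @param sample_classes optional class label per sample.
#' @return A [summary_model()] with histogram panels; the `pcoa_result` and
#'   the full association table are attached as attributes `"pcoa"` and
#'   `"assoc"`.
#' @export
blocks_from_pcoa <- function(abundance, n_axes = 3, alpha = 0.05,
                             sample_classes = NULL) {
  abundance <- as.matrix(abundance)
  if (nrow(abundance) < 4)
    stop("need at least 4 samples for the Spearman association test")
  d <- bray_curtis(abundance)
  fit <- pcoa(d, n_axes = n_axes)
  assoc <- pcoa_feature_assoc(abundance, fit$coords)
  rel_eig <- 100 * fit$eigenvalues / sum(fit$eigenvalues)
  blocks <- lapply(seq_len(ncol(fit$coords)), function(ax) {
    a <- assoc[assoc$axis == ax, , drop = FALSE]
    sig <- a[a$p_adj <= alpha, , drop = FALSE]
    pos <- sig[sig$rho > 0, , drop = FALSE]
    neg <- sig[sig$rho < 0, , drop = FALSE]
    pos <- pos[order(pos$p_adj, pos$p, pos$feature), , drop = FALSE]
    neg <- neg[order(neg$p_adj, neg$p, neg$feature), , drop = FALSE]
    cloud_of <- function(s) data.frame(text = s$feature, p = s$p_adj,
                                       stringsAsFactors = FALSE)
    block(
      title = paste0("Axis", ax),
      gene_lists = list(
        gene_list(neg$feature, label = paste0("Axis", ax, " negative"),
                  side = "negative", allow_empty = TRUE),
        gene_list(pos$feature, label = paste0("Axis", ax, " positive"),
                  side = "positive", allow_empty = TRUE)),
      panel = panel_histogram(fit$coords[, ax], sample_classes,
                              note = sprintf("%.1f%%", rel_eig[ax])),
      annotation = c(paste(nrow(neg), "features"),
                     paste(nrow(pos), "features")),
      clouds = list(cloud_of(neg), cloud_of(pos)))
  })
  model <- summary_model(blocks, panel_kind = "histogram")
  attr(model, "pcoa") <- fit
  attr(model, "assoc") <- assoc
  model
}
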