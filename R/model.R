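#' Expression matrix container
#'
#' Thin wrapper around a genes x samples numeric matrix with an optional
#' per-sample class labelling. Row names are gene ids, column names sample
#' ids; both must be present and unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param sample_classes optional character vector of class labels, one per
#'   sample (named or in column order).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_classes = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate gene or sample ids")
  if (!is.null(sample_classes)) {
    if (!is.null(names(sample_classes)))
      sample_classes <- sample_classes[colnames(values)]
    if (length(sample_classes) != ncol(values) || anyNA(sample_classes))
      stop("sample_classes must label every sample")
    sample_classes <- as.character(sample_classes)
  }
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 sample_classes = sample_classes),
            class = "expression_matrix")
}

as_expression_matrix <- function(x, sample_classes = NULL) {
  if (inherits(x, "expression_matrix")) return(x)
  expression_matrix(as.matrix(x), sample_classes)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  if (!is.null(x$sample_classes))
    cat("  classes:", paste(unique(x$sample_classes), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a figure block
#'
#' A block is the figure unit: one or two gene lists, their word clouds, a
#' data panel (per-sample boxplots, a stacked histogram, or nothing), and an
#' annotation string (typically gene counts) printed next to the panel.
#' Two gene lists imply two clouds, negative/down on the left and
#' positive/up on the right.
#'
#' @param title block title.
#' @param gene_lists list of one or two [gene_list()] objects.
#' @param panel list with element `kind` in `c("boxplot", "histogram",
#'   "none")` plus the panel statistics (see [panel_boxplot()] /
#'   [panel_histogram()]).
#' @param annotation character annotation, one entry per gene list.
#' @param clouds optional list parallel to `gene_lists`; each element `NULL`
#'   or a data frame with columns `text` and `p` (word items).
#' @return An object of class `tc_block`.
#' @export
block <- function(title, gene_lists, panel = list(kind = "none"),
                  annotation = NULL, clouds = NULL) {
  stopifnot(length(gene_lists) %in% 1:2,
            all(vapply(gene_lists, inherits, logical(1), "gene_list")))
  stopifnot(panel$kind %in% c("boxplot", "histogram", "none"))
  if (is.null(annotation))
    annotation <- vapply(gene_lists, function(gl)
      paste(length(gl$genes), "genes"), character(1))
  if (is.null(clouds)) clouds <- vector("list", length(gene_lists))
  stopifnot(length(clouds) == length(gene_lists))
  structure(list(title = title, gene_lists = gene_lists, panel = panel,
                 annotation = annotation, clouds = clouds),
            class = "tc_block")
}

#' Construct a summary model
#'
#' The ordered sequence of blocks a figure is rendered from, plus global
#' display parameters. All blocks of one model share the same panel kind, so
#' the figure height grows linearly with the number of blocks.
#'
#' @param blocks list of [block()] objects.
#' @param panel_kind `"boxplot"`, `"histogram"` or `"none"`; defaults to the
#'   kind of the first block.
#' @param params named list of display parameters (merged over defaults):
#'   `block_width`, `cloud_height`, `panel_height`, `max_font`, `min_font`,
#'   `weight_cap`, `gray_range`.
#' @return An object of class `summary_model`.
#' @export
summary_model <- function(blocks, panel_kind = NULL, params = list()) {
  stopifnot(length(blocks) >= 1,
            all(vapply(blocks, inherits, logical(1), "tc_block")))
  kinds <- vapply(blocks, function(b) b$panel$kind, character(1))
  if (is.null(panel_kind)) panel_kind <- kinds[1]
  if (!all(kinds == panel_kind))
    stop("all blocks of a summary model must share one panel kind")
  defaults <- list(block_width = 800, cloud_height = 150, panel_height = 110,
                   max_font = 20, min_font = 4, weight_cap = 16,
                   gray_range = c(0.65, 0))
  params <- utils::modifyList(defaults, params)
  structure(list(blocks = blocks, panel_kind = panel_kind, params = params,
                 version = "1.0"),
            class = "summary_model")
}

#' @export
print.summary_model <- function(x, ...) {
  cat("summary_model: ", length(x$blocks), " block(s), panel kind '",
      x$panel_kind, "'\n", sep = "")
  for (b in x$blocks)
    cat("  -", b$title, "(", paste(x = vapply(b$gene_lists, function(g)
      length(g$genes), integer(1)), collapse = " / "), "genes )\n")
  invisible(x)
}

#' Attach enrichment word clouds to a model
#'
#' Runs the over-representation test and the display-filtering pipeline on
#' every gene list of every block, and stores the surviving terms as that
#' list's word-cloud items. Blocks whose clouds are already populated (e.g.
#' feature clouds from the PCoA producer) are left untouched. Empty gene
#' lists get an empty cloud.
#'
#' @param model a [summary_model()].
#' @param ann an [annotation_set()].
#' @param cfg a [filter_config()].
#' @param alpha significance threshold passed to [enrich()].
#' @param correction multiplicity correction method.
#' @param relation hierarchy-grouping relation for [filter_hierarchy()].
#' @return The model with `clouds` filled in.
#' @export
annotate_model <- function(model, ann, cfg = filter_config(), alpha = 0.05,
                           correction = "BH", relation = "direct") {
  stopifnot(inherits(model, "summary_model"))
  empty_cloud <- data.frame(text = character(0), p = numeric(0))
  model$blocks <- lapply(model$blocks, function(b) {
    for (i in seq_along(b$gene_lists)) {
      if (!is.null(b$clouds[[i]])) next
      gl <- b$gene_lists[[i]]
      if (length(gl$genes) == 0 ||
          length(intersect(gl$genes, ann$universe)) == 0) {
        b$clouds[[i]] <- empty_cloud
        next
      }
      terms <- enrich(gl, ann, alpha = alpha, correction = correction)
      terms <- filter_terms(terms, ann$parents, cfg, relation)
      b$clouds[[i]] <- data.frame(text = terms$term_name, p = terms$p_adj,
                                  stringsAsFactors = FALSE)
    }
    b
  })
  model
}

#' Write a summary model to JSON
#'
#' Versioned, lossless serialisation of the intermediate model file that the
#' analysis subcommands produce and the plot step consumes. Numbers are
#' written at full precision so a write/read round trip reproduces the model
#' exactly.
#'
#' @param model a [summary_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "summary_model"))
  ser <- list(
    format = "termclouds-model",
    version = model$version,
    panel_kind = model$panel_kind,
    params = model$params,
    blocks = lapply(model$blocks, function(b) list(
      title = b$title,
      gene_lists = lapply(b$gene_lists, unclass),
      panel = b$panel,
      annotation = b$annotation,
      clouds = b$clouds)))
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a summary model from JSON
#'
#' @param path path to a file written by [write_model()].
#' @return A [summary_model()].
#' @export
read_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(ser$format, "termclouds-model"))
    stop("'", path, "' is not a termclouds model file")
  blocks <- lapply(ser$blocks, function(rb) {
    gls <- lapply(rb$gene_lists, function(g)
      gene_list(unlist(g$genes), label = g$label, side = g$side,
                allow_empty = TRUE))
    panel <- simplify_panel(rb$panel)
    clouds <- lapply(rb$clouds, function(cl) {
      if (is.null(cl)) return(NULL)
      data.frame(text = vapply(cl, function(r) r$text, character(1)),
                 p = vapply(cl, function(r) as.numeric(r$p), numeric(1)),
                 stringsAsFactors = FALSE)
    })
    block(title = rb$title, gene_lists = gls, panel = panel,
          annotation = unlist(rb$annotation), clouds = clouds)
  })
  params <- lapply(ser$params, function(v)
    if (is.list(v)) unlist(v) else v)
  summary_model(blocks, panel_kind = ser$panel_kind, params = params)
}

simplify_panel <- function(p) {
  kind <- p$kind
  if (kind == "boxplot") {
    stats <- do.call(rbind, lapply(p$stats, function(r)
      data.frame(sample = r$sample, ymin = as.numeric(r$ymin),
                 lower = as.numeric(r$lower), middle = as.numeric(r$middle),
                 upper = as.numeric(r$upper), ymax = as.numeric(r$ymax),
                 stringsAsFactors = FALSE)))
    list(kind = "boxplot", stats = stats)
  } else if (kind == "histogram") {
    list(kind = "histogram",
         breaks = as.numeric(unlist(p$breaks)),
         counts = matrix(as.numeric(unlist(p$counts)),
                         nrow = length(p$classes), byrow = TRUE,
                         dimnames = list(unlist(p$classes), NULL)),
         classes = as.character(unlist(p$classes)),
         note = if (is.null(p$note)) NULL else p$note)
  } else {
    list(kind = "none")
  }
}
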