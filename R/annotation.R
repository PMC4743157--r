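#' Construct an annotation set
#'
#' An annotation set bundles term -> gene memberships with term names, term
#' sources (e.g. `"BP"`, `"KEGG"`, `"REAC"`) and the direct-parent structure of
#' the underlying ontology. It also fixes the gene universe used as the
#' background of over-representation tests; by default the universe is the
#' union of all annotated genes, which matches the implicit background of the
#' usual enrichment services. Supply `universe` explicitly to use an
#' array-specific background.
#'
#' Invariants enforced here: every annotated gene belongs to the universe,
#' every retained term annotates at least one gene, and parent edges may only
#' point at known terms (unknown parents are dropped with a warning).
#'
#' @param term_genes named list; per term, a character vector of gene ids.
#'   Gene ids are opaque, case-sensitive strings.
#' @param term_names named character; human-readable phrase per term.
#'   Defaults to the ids themselves.
#' @param parents named list; per term, character vector of direct parent term
#'   ids. Terms without an entry are treated as parentless.
#' @param source named character; annotation source label per term.
#'   Defaults to `"BP"`.
#' @param universe character vector of all background genes, or `NULL` for the
#'   union of annotated genes.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(term_genes, term_names = NULL, parents = NULL,
                           source = NULL, universe = NULL) {
  stopifnot(is.list(term_genes))
  ids <- names(term_genes)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every term must be named")
  if (anyDuplicated(ids))
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  term_genes <- lapply(term_genes, function(g) unique(as.character(g)))
  sizes <- lengths(term_genes)
  if (any(sizes < 1)) {
    empty <- ids[sizes < 1]
    warning("dropping ", length(empty), " term(s) with no genes: ",
            paste(utils::head(empty, 5), collapse = ", "))
    term_genes <- term_genes[sizes >= 1]
    ids <- names(term_genes)
  }
  all_genes <- unique(unlist(term_genes, use.names = FALSE))
  if (is.null(universe)) {
    universe <- all_genes
  } else {
    universe <- unique(as.character(universe))
    missing <- setdiff(all_genes, universe)
    if (length(missing) > 0) {
      # annotated genes outside a user universe are removed from the terms,
      # keeping the invariant term_genes subset-of universe
      warning(length(missing), " annotated gene(s) outside the supplied universe removed")
      term_genes <- lapply(term_genes, function(g) g[g %in% universe])
      keep <- lengths(term_genes) >= 1
      if (!all(keep)) {
        warning("dropping ", sum(!keep), " term(s) left empty by universe restriction")
        term_genes <- term_genes[keep]
      }
      ids <- names(term_genes)
    }
  }

  if (is.null(term_names)) term_names <- stats::setNames(ids, ids)
  term_names <- vapply(term_names, as.character, character(1))
  term_names <- term_names[intersect(names(term_names), ids)]
  absent <- setdiff(ids, names(term_names))
  if (length(absent) > 0)
    term_names[absent] <- absent

  if (is.null(source)) source <- stats::setNames(rep("BP", length(ids)), ids)
  if (length(source) == 1L && is.null(names(source)))
    source <- stats::setNames(rep(source, length(ids)), ids)
  source <- source[intersect(names(source), ids)]
  source[setdiff(ids, names(source))] <- "BP"

  if (is.null(parents)) parents <- list()
  parents <- parents[intersect(names(parents), ids)]
  parents <- lapply(parents, function(p) {
    p <- unique(as.character(p))
    unknown <- setdiff(p, ids)
    if (length(unknown) > 0)
      warning("dropping parent edge(s) to unknown term(s): ",
              paste(unknown, collapse = ", "))
    intersect(p, ids)
  })

  structure(
    list(term_ids = ids,
         term_names = term_names[ids],
         term_genes = term_genes[ids],
         parents = parents,
         source = source[ids],
         universe = universe),
    class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$term_ids), "terms,",
      length(x$universe), "genes in universe\n")
  cat("  sources:", paste(names(table(x$source)), collapse = ", "), "\n")
  cat("  terms with parents:", length(x$parents), "\n")
  invisible(x)
}

#' Number of genes annotated to a term
#'
#' @param ann an `annotation_set`
#' @param id term id(s)
#' @return integer vector of term sizes
#' @export
term_size <- function(ann, id) {
  stopifnot(inherits(ann, "annotation_set"))
  lengths(ann$term_genes[id])
}

#' Construct a gene list
#'
#' A gene list is one half (or the whole) of a figure block: a labelled,
#' ordered set of gene identifiers together with a side tag saying where its
#' word cloud goes (`"single"` for one-cloud blocks; `"positive"`/`"negative"`
#' for loading signs; `"up"`/`"down"` for differential expression).
#'
#' @param genes character vector, non-empty unless `allow_empty`; duplicates
#'   removed keeping first occurrence.
#' @param label display title fragment.
#' @param side one of `"single"`, `"positive"`, `"negative"`, `"up"`, `"down"`.
#' @param allow_empty permit an empty list (renders as an empty cloud
#'   annotated "0 genes").
#' @return An object of class `gene_list`.
#' @export
gene_list <- function(genes, label = "", side = "single", allow_empty = FALSE) {
  side <- match.arg(side, c("single", "positive", "negative", "up", "down"))
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0 && !allow_empty)
    stop("gene list '", label, "' is empty")
  structure(list(label = label, genes = genes, side = side),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat("gene_list '", x$label, "' (", x$side, "): ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Apply a gene identifier mapping
#'
#' Translates gene ids through a two-column mapping (old id -> new id), e.g.
#' probe ids to gene symbols. Unmapped ids are kept as-is; duplicates after
#' mapping are collapsed.
#'
#' @param genes character vector of ids.
#' @param map named character vector or two-column data frame (from, to).
#' @return character vector of translated ids.
#' @export
apply_gene_map <- function(genes, map) {
  if (is.data.frame(map)) {
    stopifnot(ncol(map) >= 2)
    map <- stats::setNames(as.character(map[[2]]), as.character(map[[1]]))
  }
  out <- ifelse(genes %in% names(map), unname(map[genes]), genes)
  out[!duplicated(out)]
}
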