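#' Term-filtering configuration
#'
#' Controls the display-filtering pipeline applied to enrichment results
#' before word-cloud construction. Defaults follow common practice for
#' lists of a few hundred genes: terms must have more than 50 and fewer
#' than 1000 annotated genes (very small terms are too specific, very large
#' ones too general), only the GO Biological Process branch and the KEGG and
#' Reactome pathway databases are shown, and at most the 30 most significant
#' terms survive.
#'
#' @param min_size exclusive lower bound on term size (default 50).
#' @param max_size exclusive upper bound on term size (default 1000).
#' @param max_terms cap on the number of displayed terms (default 30).
#' @param sources allowed source labels (default `c("BP", "KEGG", "REAC")`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_size = 50, max_size = 1000, max_terms = 30,
                          sources = c("BP", "KEGG", "REAC")) {
  stopifnot(min_size >= 0, min_size < max_size, max_terms >= 1)
  structure(list(min_size = min_size, max_size = max_size,
                 max_terms = max_terms, sources = as.character(sources)),
            class = "filter_config")
}

#' Size-window filter
#'
#' Keeps terms whose size `K` lies strictly inside `(min_size, max_size)`.
#' Terms without a known size (imported tables lacking a size column,
#' `K = NA`) are exempt and pass unchanged. Input order is preserved.
#'
#' @param terms an `enriched_terms` data frame.
#' @param cfg a [filter_config()].
#' @return The retained subset, same class and order.
#' @export
filter_size <- function(terms, cfg = filter_config()) {
  keep <- is.na(terms$K) | (terms$K > cfg$min_size & terms$K < cfg$max_size)
  terms[keep, , drop = FALSE]
}

#' Source filter
#'
#' Keeps terms whose source label is in `cfg$sources`. Terms with an unknown
#' source (`NA`, from tables without a source column) are exempt.
#'
#' @inheritParams filter_size
#' @return The retained subset, input order preserved.
#' @export
filter_sources <- function(terms, cfg = filter_config()) {
  keep <- is.na(terms$source) | terms$source %in% cfg$sources
  terms[keep, , drop = FALSE]
}

#' Redundancy reduction by shared parentage
#'
#' Ontology enrichment results typically contain clusters of closely related
#' terms. This filter groups the significant terms and keeps one
#' representative per group: terms are connected when they share at least one
#' direct parent, or when one is the direct parent of the other; groups are
#' the connected components of that graph, and the surviving term of each
#' group is the one with the smallest adjusted p (ties: smaller raw p, then
#' larger term size, then lexicographically smallest id). With
#' `relation = "ancestor"` the grouping instead uses the full ancestor
#' closure (terms sharing any ancestor, or one an ancestor of the other).
#'
#' Terms absent from the parent map form singleton groups and always survive.
#'
#' @param terms an `enriched_terms` data frame.
#' @param parents named list: term id -> character vector of direct parents
#'   (e.g. from [parse_dag()] or an [annotation_set()]).
#' @param relation `"direct"` (default) or `"ancestor"`.
#' @return The surviving subset, input order preserved.
#' @export
filter_hierarchy <- function(terms, parents, relation = c("direct", "ancestor")) {
  relation <- match.arg(relation)
  nt <- nrow(terms)
  if (nt <= 1) return(terms)
  ids <- terms$term_id
  par <- lapply(ids, function(id) {
    p <- parents[[id]]
    if (is.null(p)) character(0) else p
  })
  names(par) <- ids
  if (relation == "ancestor") par <- lapply(ids, ancestor_closure, parents = parents)

  # edges: shared (direct or ancestral) parent, or containment in the
  # other's parent set
  edges <- integer(0)
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      linked <- length(intersect(par[[i]], par[[j]])) > 0 ||
        ids[j] %in% par[[i]] || ids[i] %in% par[[j]]
      if (linked) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = nt, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership

  rank <- order_terms(terms)
  pos <- integer(nt); pos[rank] <- seq_len(nt)  # significance rank per row
  best <- tapply(seq_len(nt), comp, function(rows) rows[which.min(pos[rows])])
  keep <- sort(unlist(best))
  terms[keep, , drop = FALSE]
}

ancestor_closure <- function(id, parents) {
  seen <- character(0)
  frontier <- parents[[id]]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(parents[frontier], use.names = FALSE))
  }
  seen
}

#' Cap at the most significant terms
#'
#' Re-sorts defensively by significance (adjusted p, raw p, larger size,
#' term id) and returns at most `cfg$max_terms` terms.
#'
#' @inheritParams filter_size
#' @return The top terms in significance order.
#' @export
cap_top_n <- function(terms, cfg = filter_config()) {
  terms <- terms[order_terms(terms), , drop = FALSE]
  utils::head(terms, cfg$max_terms)
}

#' Full display-filtering pipeline
#'
#' Applies, in order: source restriction, size window, shared-parent
#' redundancy reduction, top-N cap. The cap runs last so that it counts only
#' terms that could actually be displayed. The composition is idempotent.
#'
#' @param terms an `enriched_terms` data frame.
#' @param parents named list of direct parents (may be empty).
#' @param cfg a [filter_config()].
#' @param relation grouping relation for [filter_hierarchy()].
#' @return The filtered `enriched_terms`, in significance order.
#' @export
filter_terms <- function(terms, parents = list(), cfg = filter_config(),
                         relation = "direct") {
  terms <- filter_sources(terms, cfg)
  terms <- filter_size(terms, cfg)
  terms <- filter_hierarchy(terms, parents, relation)
  cap_top_n(terms, cfg)
}
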