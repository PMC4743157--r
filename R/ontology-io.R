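#' Parse a GMT gene-set file
#'
#' Reads the standard tab-separated gene-set dialect: one set per line with
#' set id, description, then member gene ids. Duplicate gene ids within a line
#' are deduplicated; duplicate set ids across lines are an error.
#'
#' @param path path to a GMT file.
#' @return A list with `term_genes` (named list of gene id vectors) and
#'   `term_names` (named character), the annotation fragment a GMT carries.
#'   Pass through [annotation_set()] (optionally adding `parents` from
#'   [parse_dag()]) to obtain a full annotation set.
#' @seealso [write_gmt()], [annotation_set()]
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("GMT file '", path, "' is empty")
    return(list(term_genes = stats::setNames(list(), character(0)),
                term_names = stats::setNames(character(0), character(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2))
    stop("malformed GMT line ", which(nf < 2)[1], " in '", path,
         "': fewer than 2 tab-separated fields")
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  nms <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    unique(g)
  })
  list(term_genes = stats::setNames(genes, ids),
       term_names = stats::setNames(nms, ids))
}

#' Write an annotation set to GMT
#'
#' @param ann an `annotation_set` (or a `parse_gmt()`-style fragment).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(ann, path) {
  tg <- ann$term_genes
  tn <- ann$term_names
  lines <- vapply(names(tg), function(id) {
    paste(c(id, tn[[id]], tg[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse ontology parent structure
#'
#' Accepts either a two-column TSV edge list (child, parent; one edge per
#' line) or an OBO 1.2 file, from which only `id`, `name`, `is_a` and
#' `namespace` tags are read. Self-loops and cycles are structural errors;
#' for a cycle the error message lists one offending cycle.
#'
#' @param path path to a TSV edge list or OBO file.
#' @return A list with `parents` (named list: term id -> character vector of
#'   direct parents) and, for OBO input, `term_names` and `namespace`
#'   (named character vectors; empty for TSV input).
#' @export
parse_dag <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_obo <- any(grepl("^\\[Term\\]", lines)) || any(grepl("^format-version:", lines))
  res <- if (is_obo) parse_obo_lines(lines) else parse_edge_lines(lines, path)
  check_dag(res$parents)
  res
}

parse_edge_lines <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0)
    return(list(parents = list(), term_names = character(0),
                namespace = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2))
    stop("malformed edge line ", which(nf < 2)[1], " in '", path,
         "': expected child<TAB>parent")
  child <- vapply(fields, `[[`, character(1), 1L)
  parent <- vapply(fields, `[[`, character(1), 2L)
  if (any(child == parent))
    stop("self-loop edge on term '", child[child == parent][1], "'")
  parents <- lapply(split(parent, child), unique)
  list(parents = parents, term_names = character(0), namespace = character(0))
}

parse_obo_lines <- function(lines) {
  lines <- trimws(lines)
  starts <- which(lines == "[Term]")
  # any non-[Term] stanza ends the preceding term block too
  stanza_starts <- which(grepl("^\\[.*\\]$", lines))
  parents <- list()
  term_names <- character(0)
  namespace <- character(0)
  for (s in starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    tagval <- function(tag) sub(paste0("^", tag, ":\\s*"), "",
                                block[startsWith(block, paste0(tag, ":"))])
    id <- tagval("id")[1]
    if (is.na(id) || !nzchar(id)) next
    nm <- tagval("name")[1]
    ns <- tagval("namespace")[1]
    isa <- tagval("is_a")
    # "is_a: GO:0000001 ! name" -> keep only the id token
    isa <- sub("\\s*!.*$", "", isa)
    isa <- unique(isa[nzchar(isa)])
    if (any(isa == id)) stop("self-loop is_a on term '", id, "'")
    if (length(isa)) parents[[id]] <- isa
    if (!is.na(nm)) term_names[id] <- nm
    if (!is.na(ns)) namespace[id] <- ns
  }
  list(parents = parents, term_names = term_names, namespace = namespace)
}

# cycle detection by iterated leaf removal (Kahn); on failure, walk the
# residual graph to report one concrete cycle
check_dag <- function(parents) {
  if (length(parents) == 0) return(invisible(TRUE))
  nodes <- unique(c(names(parents), unlist(parents, use.names = FALSE)))
  deps <- parents[intersect(names(parents), nodes)]
  repeat {
    has_dep <- names(deps)[lengths(deps) > 0]
    resolvable <- setdiff(nodes, has_dep)
    if (length(resolvable) == 0) break
    nodes <- has_dep
    deps <- lapply(deps[nodes], setdiff, y = resolvable)
  }
  if (length(nodes) > 0) {
    cyc <- nodes[1]
    cur <- cyc
    repeat {
      nxt <- intersect(deps[[cur]], nodes)[1]
      if (nxt %in% cyc) {
        cyc <- c(cyc[which(cyc == nxt)[1]:length(cyc)], nxt)
        break
      }
      cyc <- c(cyc, nxt)
      cur <- nxt
    }
    stop("cycle in ontology structure: ", paste(cyc, collapse = " -> "))
  }
  invisible(TRUE)
}

#' Parse a pre-computed enrichment table
#'
#' Imports term tables produced upstream (g:Profiler, DAVID, GSEA exports and
#' the like) so the filtering and word-cloud stages can run on them directly.
#' Expected tab-separated columns: term id, term name, p-value, term size
#' (optional), source (optional). A header row is detected automatically. The
#' p-values are taken as already multiplicity-corrected (`p_adj = p_raw = p`).
#' A missing size marks the row as exempt from size filtering (`K = NA`).
#'
#' @param path path to the TSV file.
#' @return A `data.frame` of class `enriched_terms` with columns `term_id`,
#'   `term_name`, `source`, `K`, `p_raw`, `p_adj`.
#' @seealso [write_term_table()], [filter_terms()]
#' @export
parse_term_table <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(raw) < 3)
    stop("term table '", path, "' needs at least 3 columns: id, name, p")
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.numeric(raw[1, 3])))) {
    raw <- raw[-1, , drop = FALSE]   # header row
  }
  if (nrow(raw) == 0)
    return(enriched_terms(data.frame(term_id = character(0),
                                     term_name = character(0),
                                     source = character(0),
                                     K = numeric(0),
                                     p_raw = numeric(0), p_adj = numeric(0))))
  p <- as.numeric(raw[[3]])
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-value outside [0, 1] in term table row ",
         which(is.na(p) | p < 0 | p > 1)[1])
  K <- if (ncol(raw) >= 4) suppressWarnings(as.numeric(raw[[4]])) else NA_real_
  src <- if (ncol(raw) >= 5) as.character(raw[[5]]) else NA_character_
  enriched_terms(data.frame(
    term_id = raw[[1]], term_name = raw[[2]],
    source = src, K = K, p_raw = p, p_adj = p,
    stringsAsFactors = FALSE))
}

#' Write an enrichment table to TSV
#'
#' Emits the same dialect [parse_term_table()] reads (id, name, p_adj, size,
#' source), with a header.
#'
#' @param terms an `enriched_terms` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_table <- function(terms, path) {
  out <- data.frame(term_id = terms$term_id, term_name = terms$term_name,
                    p = terms$p_adj, size = terms$K, source = terms$source)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

enriched_terms <- function(df) {
  needed <- c("term_id", "term_name", "source", "K", "p_raw", "p_adj")
  stopifnot(all(needed %in% names(df)))
  rownames(df) <- NULL
  class(df) <- c("enriched_terms", "data.frame")
  df
}
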