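# shared helpers: tiny hand-built annotation sets and term tables

toy_annotation <- function() {
  annotation_set(
    term_genes = list(
      TA = c("g1", "g2", "g3", "g4"),
      TB = c("g3", "g4", "g5"),
      TC = c("g6", "g7"),
      TP = c("g1", "g2", "g3", "g4", "g5")),
    term_names = c(TA = "alpha process", TB = "beta process",
                   TC = "gamma pathway", TP = "parent process"),
    parents = list(TA = "TP", TB = "TP"),
    source = c(TA = "BP", TB = "BP", TC = "KEGG", TP = "BP"),
    universe = sprintf("g%d", 1:10))
}

# minimal enrichment-result table for the filter functions
mk_terms <- function(id, p_adj, K = NA_real_, p_raw = p_adj,
                     source = "BP", name = id) {
  data.frame(term_id = id, term_name = name, source = source,
             K = K, p_raw = p_raw, p_adj = p_adj, stringsAsFactors = FALSE)
}

# independent brute-force hypergeometric upper tail by direct enumeration
# of the probability mass (binomial-coefficient formula)
brute_upper_tail <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# O(n^2) rectangle oracle: any pair of open boxes intersecting?
count_overlaps <- function(words) {
  n <- nrow(words)
  if (n < 2) return(0L)
  bad <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- words[i, ]; b <- words[j, ]
    if (a$x < b$x + b$w && b$x < a$x + a$w &&
        a$y < b$y + b$h && b$y < a$y + a$h) bad <- bad + 1L
  }
  bad
}

all_inside <- function(words, canvas) {
  all(words$x >= -1e-9 & words$y >= -1e-9 &
      words$x + words$w <= canvas[1] + 1e-9 &
      words$y + words$h <= canvas[2] + 1e-9)
}
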