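test_that("size window is strict on both ends", {
  terms <- mk_terms(paste0("T", 1:4), p_adj = rep(0.01, 4),
                    K = c(50, 51, 999, 1000))
  kept <- filter_size(terms, filter_config())
  expect_equal(kept$K, c(51, 999))
  expect_equal(nrow(filter_size(terms[0, ], filter_config())), 0)
  # full sweep: exactly the integers strictly between the bounds survive
  sweep <- mk_terms(sprintf("T%04d", 1:2000), p_adj = rep(0.01, 2000),
                    K = 1:2000)
  kept <- filter_size(sweep, filter_config())
  expect_equal(nrow(kept), 949)
  expect_equal(range(kept$K), c(51, 999))
})

test_that("terms without a size are exempt from the window", {
  terms <- mk_terms(c("A", "B"), p_adj = c(0.01, 0.01), K = c(NA, 5))
  expect_identical(filter_size(terms, filter_config())$term_id, "A")
})

test_that("shared-parent groups keep only the most significant term", {
  parents <- list(A = "P", B = "P")
  terms <- mk_terms(c("A", "B"), p_adj = c(1e-5, 1e-3), K = c(100, 100))
  expect_identical(filter_hierarchy(terms, parents)$term_id, "A")

  # a term with no relatives survives untouched
  solo <- mk_terms("Z", 0.01, K = 100)
  expect_identical(filter_hierarchy(solo, parents)$term_id, "Z")

  # chain A-B via P1, B-C via P2: one component, minimum-p member C wins
  parents <- list(A = "P1", B = c("P1", "P2"), C = "P2")
  terms <- mk_terms(c("A", "B", "C"), p_adj = c(1e-3, 1e-4, 1e-6),
                    K = c(100, 100, 100))
  expect_identical(filter_hierarchy(terms, parents)$term_id, "C")
})

test_that("direct parent-child pairs are grouped too", {
  parents <- list(C = "P")
  terms <- mk_terms(c("P", "C"), p_adj = c(1e-2, 1e-4), K = c(500, 100))
  expect_identical(filter_hierarchy(terms, parents)$term_id, "C")
})

test_that("ancestor-closure grouping links grandparent chains", {
  parents <- list(C = "B", B = "A")
  terms <- mk_terms(c("A", "C"), p_adj = c(1e-2, 1e-5), K = c(500, 100))
  # not directly related: both survive under the default
  expect_equal(nrow(filter_hierarchy(terms, parents, "direct")), 2)
  # ancestrally related: one survives
  expect_identical(filter_hierarchy(terms, parents, "ancestor")$term_id, "C")
})

test_that("hierarchy filter keeps exactly one term per connected component", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    ids <- paste0("T", seq_len(n))
    pool <- paste0("P", 1:4)
    parents <- lapply(ids, function(i) sample(pool, sample(0:2, 1)))
    names(parents) <- ids
    terms <- mk_terms(ids, p_adj = runif(n), K = sample(60:900, n))
    kept <- filter_hierarchy(terms, parents)

    # independent BFS component count on the shared-parent graph
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      adj[i, j] <- length(intersect(parents[[i]], parents[[j]])) > 0 ||
        ids[j] %in% parents[[i]] || ids[i] %in% parents[[j]]
    }
    seen <- rep(FALSE, n); ncomp <- 0
    for (s in seq_len(n)) {
      if (seen[s]) next
      ncomp <- ncomp + 1
      queue <- s
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        if (seen[v]) next
        seen[v] <- TRUE
        queue <- c(queue, which(adj[v, ] & !seen))
      }
    }
    expect_equal(nrow(kept), ncomp)
  }
})

test_that("the cap keeps the most significant terms with the tie rule", {
  few <- mk_terms(paste0("T", 1:5), p_adj = (1:5) / 100, K = rep(100, 5))
  expect_equal(nrow(cap_top_n(few, filter_config())), 5)

  # ranks 30 and 31 tied on both p values: larger K survives
  p <- c(seq(1e-6, 1e-3, length.out = 29), 0.002, 0.002)
  terms <- mk_terms(paste0("T", sprintf("%02d", 1:31)), p_adj = p,
                    p_raw = p, K = c(rep(100, 29), 80, 300))
  kept <- cap_top_n(terms, filter_config())
  expect_equal(nrow(kept), 30)
  expect_true("T31" %in% kept$term_id)   # K = 300 wins the tie
  expect_false("T30" %in% kept$term_id)
})

test_that("sources filter keeps allowed labels and exempts unknown ones", {
  terms <- mk_terms(c("A", "B", "C", "D"), p_adj = rep(0.01, 4),
                    K = rep(100, 4),
                    source = c("BP", "MF", "KEGG", NA))
  kept <- filter_sources(terms, filter_config())
  expect_setequal(kept$term_id, c("A", "C", "D"))
})

test_that("full pipeline: stage outputs nest, cap applies last, idempotent", {
  ann <- make_annotation(n_terms = 120, n_genes = 4000, seed = 21)
  q <- make_spiked_query(ann, ann$term_ids[3], 1, n_background = 200,
                         seed = 22)
  res <- enrich(q, ann, alpha = 1)
  cfg <- filter_config()
  s1 <- filter_sources(res, cfg)
  s2 <- filter_size(s1, cfg)
  s3 <- filter_hierarchy(s2, ann$parents)
  s4 <- cap_top_n(s3, cfg)
  expect_true(all(s1$term_id %in% res$term_id))
  expect_true(all(s2$term_id %in% s1$term_id))
  expect_true(all(s3$term_id %in% s2$term_id))
  expect_true(all(s4$term_id %in% s3$term_id))
  once <- filter_terms(res, ann$parents, cfg)
  expect_identical(once$term_id, s4$term_id)
  twice <- filter_terms(once, ann$parents, cfg)
  expect_identical(twice$term_id, once$term_id)
})

test_that("100 eligible non-redundant terms are capped at 30", {
  terms <- mk_terms(sprintf("T%03d", 1:100),
                    p_adj = seq(1e-8, 1e-3, length.out = 100),
                    K = rep(200, 100))
  kept <- filter_terms(terms, parents = list(), filter_config())
  expect_equal(nrow(kept), 30)
  expect_identical(kept$term_id, sprintf("T%03d", 1:30))
})
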