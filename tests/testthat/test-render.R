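skip_if_not_installed("xml2")

render_cluster_model <- function(n_genes = 150, seed = 30) {
  ex <- make_expression(n_genes = n_genes, seed = seed)
  ann <- make_annotation(seed = seed)
  annotate_model(blocks_from_clusters(ex$exprs, ex$assignment), ann,
                 cfg = filter_config(min_size = 5, max_size = 2000))
}

test_that("model JSON round-trips losslessly", {
  model <- render_cluster_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_equal(unclass(back)[c("blocks", "panel_kind", "params")],
               unclass(model)[c("blocks", "panel_kind", "params")],
               tolerance = 0)
  # and a second round trip is byte-identical
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("a five-block boxplot model renders all structural parts", {
  model <- render_cluster_model()
  f <- withr::local_tempfile(fileext = ".svg")
  render(model, f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns(doc)
  titles <- xml2::xml_find_all(doc, "//d1:text[@class='block-title']", ns)
  expect_length(titles, 5)
  expect_identical(xml2::xml_text(titles), paste("Cluster", 1:5))
  annos <- xml2::xml_find_all(doc, "//d1:text[@class='panel-annotation']", ns)
  expect_length(annos, 5)
  expect_match(xml2::xml_text(annos)[1], "genes$")
})

test_that("empty clouds render as an annotation, not an error", {
  de <- data.frame(gene = paste0("g", 1:5), effect = rnorm(5),
                   p_adj = rep(0.9, 5))
  model <- blocks_from_de(de)
  ann <- make_annotation(seed = 31)
  model <- annotate_model(model, ann)
  f <- withr::local_tempfile(fileext = ".svg")
  render(model, f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns(doc)
  empties <- xml2::xml_find_all(doc, "//d1:text[@class='empty-cloud']", ns)
  expect_length(empties, 2)
  expect_identical(unique(xml2::xml_text(empties)), "0 terms")
})

test_that("figure height is linear in the block count", {
  ex <- make_expression(n_genes = 200, n_clusters = 4, seed = 32)
  m4 <- blocks_from_clusters(ex$exprs, ex$assignment)
  h4 <- model_dimensions(m4)["height"]
  ex20 <- make_expression(n_genes = 200, n_clusters = 20, seed = 32)
  m20 <- blocks_from_clusters(ex20$exprs, ex20$assignment)
  h20 <- model_dimensions(m20)["height"]
  expect_equal(unname(h20 / h4), 5)
  # a 20-block model actually renders
  ann <- make_annotation(seed = 32)
  f <- withr::local_tempfile(fileext = ".svg")
  render(annotate_model(m20, ann), f)
  svg <- xml2::read_xml(f)
  expect_equal(as.numeric(xml2::xml_attr(svg, "height")), unname(h20))
})

test_that("SVG output is byte-deterministic", {
  model <- render_cluster_model(seed = 33)
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render(model, f1)
  render(model, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("every text element lies inside the document viewBox", {
  ab <- make_abundance(seed = 34)
  model <- blocks_from_pcoa(ab$counts, sample_classes = ab$classes)
  f <- withr::local_tempfile(fileext = ".svg")
  render(model, f)
  doc <- xml2::read_xml(f)
  vb <- as.numeric(strsplit(xml2::xml_attr(doc, "viewBox"), " ")[[1]])
  ns <- xml2::xml_ns(doc)
  texts <- xml2::xml_find_all(doc, "//d1:text", ns)
  x <- as.numeric(xml2::xml_attr(texts, "x"))
  y <- as.numeric(xml2::xml_attr(texts, "y"))
  expect_true(all(x >= vb[1] & x <= vb[1] + vb[3]))
  expect_true(all(y >= vb[2] & y <= vb[2] + vb[4]))
})

test_that("PDF and PNG backends write non-empty files", {
  model <- render_cluster_model(n_genes = 60, seed = 35)
  fp <- withr::local_tempfile(fileext = ".pdf")
  render(model, fp)
  expect_gt(file.size(fp), 1000)
  fg <- withr::local_tempfile(fileext = ".png")
  render(model, fg, format = "png")
  expect_gt(file.size(fg), 1000)
})

test_that("two-cloud blocks place negative left and positive right", {
  pe <- make_planted_expression(n_genes = 300, n_samples = 12,
                                n_signal = 100, seed = 36)
  model <- blocks_from_pca(pe$exprs, n_comp = 1)
  ann <- make_annotation(n_genes = 300, seed = 36)
  # remap annotation universe onto the expression genes for a small test
  model <- annotate_model(model, ann,
                          cfg = filter_config(min_size = 5, max_size = 2000))
  b <- model$blocks[[1]]
  expect_identical(b$gene_lists[[1]]$side, "negative")
  expect_identical(b$gene_lists[[2]]$side, "positive")
})
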