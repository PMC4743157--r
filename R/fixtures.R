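# Seeded synthetic-data generators. Every generator calls set.seed(seed), so
# the same seed always reproduces the same object; pass different seeds for
# replicates. The generators emulate the structure of the real inputs the
# pipeline consumes (annotation DAGs with realistic term-size spread,
# spiked enriched queries, clustered time-course expression, grouped
# microbial abundance counts) without any download.

word_bank <- c(
  "cell", "cycle", "immune", "response", "signal", "transduction",
  "embryo", "development", "organ", "morphogenesis", "cardiovascular",
  "system", "adhesion", "muscle", "contraction", "lipid", "metabolic",
  "process", "regulation", "transcription", "DNA", "replication",
  "chromatin", "remodeling", "apoptotic", "pathway", "membrane",
  "transport", "protein", "folding", "oxidative", "stress", "nervous",
  "differentiation", "stem", "maintenance", "inflammatory", "vesicle",
  "mediated", "kinase")

#' Generate a synthetic annotation set
#'
#' Builds a tree-shaped ontology fragment of `depth` layers: terms in layer 1
#' are parentless, each deeper term has one parent in the layer above and its
#' gene set is a subset of the parent's. Term sizes are log-uniform in
#' `[5, 2000]` (truncated to the parent size for child terms), so at the
#' default parameters the generated sizes straddle the default (50, 1000)
#' display window from both sides. Term names are 2-5 word phrases, which
#' exercises the long-phrase packing path of the cloud layout. Sources are
#' drawn from BP/KEGG/REAC.
#'
#' @param n_terms number of terms (default 100).
#' @param n_genes universe size (default 5000).
#' @param depth number of tree layers (default 3); `depth = 1` makes every
#'   term parentless.
#' @param seed RNG seed.
#' @return An [annotation_set()].
#' @export
make_annotation <- function(n_terms = 100, n_genes = 5000, depth = 3,
                            seed = 1) {
  stopifnot(n_terms >= 1, n_genes >= 10, depth >= 1)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  ids <- sprintf("T%04d", seq_len(n_terms))
  layer <- rep(seq_len(depth), length.out = n_terms)
  layer <- sort(layer)
  sizes <- pmax(2L, round(exp(stats::runif(n_terms, log(5), log(2000)))))
  term_genes <- vector("list", n_terms)
  parents <- list()
  for (i in seq_len(n_terms)) {
    if (layer[i] == 1) {
      pool <- genes
    } else {
      cand <- which(layer == layer[i] - 1)
      par <- cand[sample.int(length(cand), 1)]
      parents[[ids[i]]] <- ids[par]
      pool <- term_genes[[par]]
    }
    sz <- min(sizes[i], length(pool))
    term_genes[[i]] <- sample(pool, sz)
  }
  names(term_genes) <- ids
  nm <- vapply(seq_len(n_terms), function(i)
    paste(sample(word_bank, sample(2:5, 1)), collapse = " "), character(1))
  src <- sample(c("BP", "KEGG", "REAC"), n_terms, replace = TRUE,
                prob = c(0.7, 0.15, 0.15))
  annotation_set(term_genes,
                 term_names = stats::setNames(nm, ids),
                 parents = parents,
                 source = stats::setNames(src, ids),
                 universe = genes)
}

#' Generate a spiked enriched query
#'
#' A gene list built as a fraction of one target term's genes plus uniform
#' background from the universe: `signal_frac = 1` with no background makes
#' the target maximally enriched; `signal_frac = 0` yields a pure background
#' query in which the target behaves like any random term (the null case for
#' type-I-error checks).
#'
#' @param ann an [annotation_set()].
#' @param target_term term id to spike.
#' @param signal_frac fraction of the target's genes included, in `[0, 1]`.
#' @param n_background background genes drawn uniformly from the universe
#'   outside the spiked genes (default 100).
#' @param seed RNG seed.
#' @return A [gene_list()].
#' @export
make_spiked_query <- function(ann, target_term, signal_frac,
                              n_background = 100, seed = 1) {
  stopifnot(inherits(ann, "annotation_set"),
            target_term %in% ann$term_ids,
            signal_frac >= 0, signal_frac <= 1)
  set.seed(seed)
  tg <- ann$term_genes[[target_term]]
  n_sig <- round(signal_frac * length(tg))
  signal <- if (n_sig > 0) sample(tg, n_sig) else character(0)
  bg_pool <- setdiff(ann$universe, signal)
  bg <- if (n_background > 0) sample(bg_pool, min(n_background, length(bg_pool)))
        else character(0)
  gene_list(c(signal, bg), label = paste0("spiked ", target_term))
}

#' Generate clustered time-course expression data
#'
#' Emulates a developmental time series: each cluster follows a distinct
#' smooth temporal profile (sigmoidal switches, transient peaks, a dip),
#' sampled at `n_timepoints` with `n_samples / n_timepoints` replicates per
#' time point, plus Gaussian noise. In the noiseless limit, reassigning each
#' gene to the nearest cluster profile recovers the true assignment exactly.
#'
#' @param n_genes number of genes (default 1000).
#' @param n_samples number of samples; should be a multiple of
#'   `n_timepoints` (default 27).
#' @param n_clusters number of temporal clusters (default 5).
#' @param n_timepoints time points spanning the course (default 9).
#' @param noise_sd standard deviation of the additive noise (default 0.5,
#'   about a quarter of the profile amplitude, typical of log-scale array
#'   replicates).
#' @param seed RNG seed.
#' @return A list: `exprs` (an [expression_matrix()] whose sample classes
#'   are the time points), `assignment` (named vector gene -> cluster id),
#'   `profiles` (cluster x timepoint matrix of noise-free means).
#' @export
make_expression <- function(n_genes = 1000, n_samples = 27, n_clusters = 5,
                            n_timepoints = 9, noise_sd = 0.5, seed = 1) {
  stopifnot(n_genes >= n_clusters, n_samples >= n_timepoints)
  set.seed(seed)
  t01 <- seq(0, 1, length.out = n_timepoints)
  profile_fun <- function(k) {
    switch((k - 1L) %% 5L + 1L,
           2 / (1 + exp(10 * (t01 - 0.3))),          # early shut-down
           2 / (1 + exp(-10 * (t01 - 0.6))),         # late switch-on
           2 * exp(-((t01 - 0.35) / 0.15)^2),        # early transient peak
           2 * exp(-((t01 - 0.75) / 0.15)^2),        # late transient peak
           1 - 1.5 * exp(-((t01 - 0.5) / 0.2)^2))    # mid-course dip
  }
  profiles <- t(vapply(seq_len(n_clusters), profile_fun,
                       numeric(n_timepoints)))
  rownames(profiles) <- as.character(seq_len(n_clusters))
  reps <- ceiling(n_samples / n_timepoints)
  tp_of_sample <- rep(seq_len(n_timepoints), each = reps)[seq_len(n_samples)]
  genes <- sprintf("g%05d", seq_len(n_genes))
  assignment <- stats::setNames(rep(seq_len(n_clusters),
                                    length.out = n_genes), genes)
  mu <- profiles[assignment, tp_of_sample, drop = FALSE]
  vals <- mu + stats::rnorm(length(mu), sd = noise_sd)
  dimnames(vals) <- list(genes, sprintf("s%03d", seq_len(n_samples)))
  exprs <- expression_matrix(vals,
                             sample_classes = paste0("t", tp_of_sample))
  list(exprs = exprs, assignment = assignment, profiles = profiles)
}

#' Generate expression with a planted class separation
#'
#' Two sample classes separated along a single latent direction: a block of
#' `n_signal` genes is shifted between the classes (half up, half down in
#' class B), everything else is noise. The leading principal component of
#' such a matrix separates the classes and loads on the planted genes, so
#' the top-loading gene lists of that component should recover the planted
#' set; used for parameter-recovery checks.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_samples number of samples, split into two equal classes
#'   (default 30).
#' @param n_signal number of planted genes (default 400).
#' @param effect between-class shift of a planted gene (default 2, i.e. two
#'   noise standard deviations).
#' @param noise_sd noise standard deviation (default 1).
#' @param seed RNG seed.
#' @return A list: `exprs` (an [expression_matrix()] with classes A/B),
#'   `signal_genes` (character vector of planted gene ids).
#' @export
make_planted_expression <- function(n_genes = 2000, n_samples = 30,
                                    n_signal = 400, effect = 2,
                                    noise_sd = 1, seed = 1) {
  stopifnot(n_signal <= n_genes, n_samples >= 4)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samples))
  classes <- rep(c("A", "B"), length.out = n_samples)
  vals <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                 nrow = n_genes, dimnames = list(genes, samples))
  sig <- sample(genes, n_signal)
  half <- n_signal %/% 2
  up <- sig[seq_len(half)]
  down <- sig[(half + 1):n_signal]
  vals[up, classes == "B"] <- vals[up, classes == "B"] + effect
  vals[down, classes == "B"] <- vals[down, classes == "B"] - effect
  list(exprs = expression_matrix(vals, sample_classes = classes),
       signal_genes = sig)
}

#' Generate grouped abundance counts
#'
#' Dirichlet-multinomial taxon counts for samples from `n_groups` habitats
#' (body-site style): all groups share a common base composition, and each
#' group has a planted block of features whose Dirichlet weight is boosted
#' `boost`-fold, giving clearly distinct communities. The planted features
#' drive the between-group ordination axes and should be recovered among the
#' significantly axis-correlated features.
#'
#' @param n_features number of taxa (default 60).
#' @param n_samples total samples, split evenly across groups (default 45).
#' @param n_groups number of habitats (default 3).
#' @param n_planted planted features per group (default 5).
#' @param boost fold-increase of planted Dirichlet weights (default 20).
#' @param depth sequencing depth per sample (default 10000 counts).
#' @param seed RNG seed.
#' @return A list: `counts` (samples x features matrix), `classes` (group
#'   label per sample), `planted` (named list: group -> planted feature
#'   ids).
#' @export
make_abundance <- function(n_features = 60, n_samples = 45, n_groups = 3,
                           n_planted = 5, boost = 20, depth = 10000,
                           seed = 1) {
  stopifnot(n_planted * n_groups <= n_features, n_samples >= 2 * n_groups)
  set.seed(seed)
  feats <- sprintf("Taxon%03d", seq_len(n_features))
  groups <- paste0("site", seq_len(n_groups))
  classes <- rep(groups, length.out = n_samples)
  classes <- sort(classes)
  base_alpha <- stats::runif(n_features, 0.2, 1)
  planted <- stats::setNames(lapply(seq_len(n_groups), function(g)
    feats[((g - 1) * n_planted + 1):(g * n_planted)]), groups)
  counts <- matrix(0L, nrow = n_samples, ncol = n_features,
                   dimnames = list(sprintf("m%03d", seq_len(n_samples)),
                                   feats))
  for (i in seq_len(n_samples)) {
    alpha <- base_alpha
    idx <- match(planted[[classes[i]]], feats)
    alpha[idx] <- alpha[idx] * boost
    w <- stats::rgamma(n_features, shape = alpha)
    counts[i, ] <- as.integer(stats::rmultinom(1, depth, prob = w / sum(w)))
  }
  list(counts = counts, classes = classes, planted = planted)
}
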