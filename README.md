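# termclouds

Word-cloud summary figures for collections of gene lists.

Most high-throughput analyses end with *many* gene lists, not one: the
clusters of a k-means run, the up- and down-regulated genes of each
contrast, the driving genes of each principal component, the taxa behind
each ordination axis. Characterising each list with ontology enrichment
produces hundreds of significant terms per list, and reading dozens of long
term tables side by side does not scale. `termclouds` compresses each list's
functional profile into a word cloud and stacks the clouds — together with a
panel of the underlying experimental data — into one figure that can be read
top to bottom.

## The method

For a query list of $n$ genes drawn from a universe of $N$ genes, a term
annotating $K$ genes with overlap $k$ is scored with the one-sided
hypergeometric (Fisher) tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

and Benjamini–Hochberg correction is applied across all terms with
$k \ge 1$. The significant terms then pass a three-stage display filter:

1. **size window** — only terms with more than 50 and fewer than 1000
   annotated genes are kept (smaller terms are too specific, larger ones
   too general; both bounds strict);
2. **redundancy reduction** — terms that share a direct parent in the
   ontology DAG (or are in a direct parent–child relation) are grouped by
   connected component and only the most significant member of each group
   survives;
3. **cap** — at most the 30 most significant terms remain.

Surviving term names are packed whole (never split or rotated) into a
cloud: font size within one cloud is proportional to $-\log_{10} p$, and a
single grayscale ramp computed over the *whole figure* encodes absolute
enrichment strength, because per-cloud font scaling makes sizes comparable
only within a cloud. Placement is a deterministic greedy spiral search
optimised for long multi-word phrases.

Producers build the figure blocks from standard upstream results:

| producer | gene lists per block | data panel |
|---|---|---|
| `blocks_from_clusters()` | cluster members | per-sample expression boxplots |
| `blocks_from_de()` | up / down regulated | boxplots or counts |
| `blocks_from_pca()` | 500 largest positive / negative loadings | stacked score histogram by class |
| `blocks_from_pcoa()` | features correlated / anti-correlated with the axis (Spearman test, BH) | stacked coordinate histogram |

The PCoA route (Bray–Curtis dissimilarity, Gower double-centering, exact
permutation Spearman p-values for small n) needs no annotation database at
all: the feature names themselves form the clouds, which is how abundance
data from microbiome studies is summarised.

## Worked example

Everything below runs offline on the package's seeded generators.

```r
library(termclouds)

ann <- make_annotation(seed = 42)          # 100 terms over 5000 genes
query <- make_spiked_query(ann, "T0004", signal_frac = 0.6,
                           n_background = 60, seed = 42)
query
#> gene_list 'spiked T0004' (single): 494 genes

terms <- enrich(query, ann)
head(as.data.frame(terms)[, c("term_id", "term_name", "K", "k", "p_adj")], 3)
#>   term_id         term_name   K   k     p_adj
#> 1   T0004 folding apoptotic 724 435 1.06e-306
#> 2   T0047       vesicle DNA 724 435 1.06e-306

shown <- filter_terms(terms, ann$parents)
nrow(shown)
#> [1] 1
```

The spiked term is found with overlap $k = 435$ of its $K = 724$ genes; a
second term with an identical gene set ties it exactly, and the hierarchy
filter collapses the redundant pair to one representative.

A full clustering summary, from matrix to figure:

```r
ex <- make_expression(seed = 42)           # 1000 genes, 9 time points
model <- blocks_from_clusters(ex$exprs, ex$assignment)
model <- annotate_model(model, ann)        # enrichment + filtering per block
model
#> summary_model: 5 block(s), panel kind 'boxplot'
#>   - Cluster 1 ( 200 genes )
#>   - Cluster 2 ( 200 genes )
#>   ...
render(model, "clusters.svg")
model_dimensions(model)
#>  width height
#>    800   1480
```

Each of the five blocks shows the cluster's per-sample expression boxplots
with the member count beside them, and the cluster's word cloud underneath.
The SVG is byte-deterministic: rendering the same model twice gives
identical files.

## Command line

The same flow as two shell commands (script in `inst/cli/`):

```sh
termclouds summarize-pca --exprs exprs.tsv --classes classes.tsv \
    --n-comp 3 --n-genes 500 --out model.json
termclouds plot model.json --gmt sets.gmt --dag dag.tsv -o figure.svg
```

All filter and layout parameters (`--min-size`, `--max-size`,
`--max-terms`, `--sources`, `--alpha`, ...) are exposed as flags.

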