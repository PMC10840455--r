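# microsig

Cancer-type classification and microbial signature discovery from
intratumoral microbiome abundance matrices with a heterogeneous graph
transformer.

## The problem

Tumor RNA-seq contains reads of intratumoral microbes. Once quantified into
a sparse species × sample count matrix with a cancer-type label per sample,
two questions remain: can the cancer type be predicted from the microbial
composition, and *which species* are associated with each cancer type?
`microsig` addresses both with one model. It is aimed at computational
microbiome/oncology researchers who have an abundance matrix, sample labels,
and (optionally) taxonomy and interspecies-metabolism tables, and want
attention-based, per-cancer-type species signatures with exact enrichment
p-values and visualization-ready exports.

## The method

A heterogeneous graph is built with species and sample nodes and three edge
types: abundance (species–sample, weight = relative abundance > 0),
metabolic (species sharing a compound in an NJS16-style interspecies table)
and phylogenetic (species sharing a genus). Two autoencoders compress the
normalized abundance rows and columns into 256-dimensional initial node
embeddings. A multi-head graph transformer (h = 8 heads, hidden width 128)
then computes, per head *i* and edge *s → t* of type *r*,

    score_i(s,t) = mu_r · k_i(s)ᵀ W_r q_i(t) / sqrt(d_h)  +  beta_r · log w_st
    alpha_i(s,t) = softmax over sources s' of t within edge type r

with node-type-dependent key/query/value projections and an
edge-type-dependent relation matrix, so per sample, head and edge type the
incident attentions sum to 1. Sample nodes are classified by cancer type
with focal loss (γ = 2) plus a small KL(attention ‖ uniform) regularizer
(coefficient 5e-5), trained with Adam (lr 0.003, 50 epochs, learning rate
halved after 5 epochs without improvement of validation macro-F1).

Signatures come from the final layer's species→sample attention averaged
over heads: species *s* is "high attention" in sample *t* when
alpha(s,t) > THRES/deg(t) (THRES = 3, i.e. three times the uniform
baseline), and each (species, cancer type) pair is tested for concentration
of high-attention samples in the type with the one-sided hypergeometric
upper tail, P(X ≥ k), X ~ Hypergeom(N, K, n). Pairs with p < 0.05 are
reported with a within-type max-rescaled mean attention weight. Performance
is summarized by accuracy and one-vs-rest macro precision/recall/F1.

See `vignettes/attention-signatures.Rmd` for the full model description,
the design decisions and their rationale, and known limitations.

## Worked example

Everything runs on a self-contained synthetic benchmark with planted
markers — 3 cancer types × 20 samples, 40 species, 5 marker species per
type elevated 8-fold in their own type:

```r
library(microsig)

ds  <- generate_dataset(synthetic_spec(seed = 1))
run <- run_pipeline(ds$abundance, ds$metadata, ds$taxonomy, ds$metabolic,
                    outdir = "demo", verbose = FALSE)
print(run)
#> microsig pipeline run
#> accuracy 0.9167 | macro precision 0.9333 | macro recall 0.9167 | macro F1 0.9153 (n = 12)
#>   signatures: 15 (species, cancer type) associations over 15 species
#>   artifacts: 11 files in demo

head(run$signatures, 6)
#>   cancer_type taxid species_name n_high_attention_samples      p_value
#> 1        COAD  1039 Species 1039                       12 9.001980e-08
#> 2        COAD  1004 Species 1004                        9 1.136159e-05
#> 3        COAD  1034 Species 1034                        6 7.742112e-04
#> 4        COAD  1001 Species 1001                        6 7.742112e-04
#> 5        COAD  1023 Species 1023                        6 7.742112e-04
#> 6        READ  1010 Species 1010                       13 1.500330e-08
#>   normalized_attention
#> 1            1.0000000
#> 2            0.7534194
#> 3            0.6315274
#> 4            0.6088791
#> 5            0.5851690
#> 6            1.0000000
```

The first line reports held-out classification on the stratified 20%
validation split (11/12 samples correctly typed here). Each signature row is
one (cancer type, species) association: `Species 1039` was high-attention in
12 of COAD's 20 samples and in no others, giving hypergeometric p = 9.0e-8;
its `normalized_attention` of 1.0 makes it COAD's top-ranked species. All 15
planted markers — and nothing else — are recovered in this run. The output
directory additionally holds the normalized matrix, both relation networks,
the full enrichment table, Cytoscape node/edge tables and SIF (edge
thickness = attention weight), an UpSet membership matrix, the training log,
and a checksum manifest (identical seeds give identical checksums).

A command-line wrapper covers the same flow from a shell:

```sh
Rscript inst/scripts/microsig-cli.R simulate --outdir data --seed 1
Rscript inst/scripts/microsig-cli.R run \
  --abundance data/abundance.tsv --metadata data/metadata.tsv \
  --taxonomy data/taxonomy.tsv --metabolic data/metabolic.tsv \
  --outdir results --seed 1
```

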