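# crossdex

Cross-species transcriptome subtyping and agreement of differential
expression.

`crossdex` implements, as one tested R pipeline, the comparative analysis
used to define rhabdoid-tumour entities across species from bulk log2
expression matrices: gene filtering, three unsupervised subgrouping methods
with explicit model-selection statistics, pairwise differential-expression
signatures, cross-species agreement of differential expression over
one-to-one orthologs, and centroid correlation against candidate
cell-of-origin profiles. A two-species synthetic data generator with planted
ground truth makes every stage testable end to end. It is aimed at
computational biologists comparing tumour cohorts between a mouse model and
human disease (or any two species linked by an ortholog table).

## The methods

**Filtering.** Genes are kept when expressed (max log2 value across samples
≥ 1.2) and variable by the relative interquartile range,
RIQR = max(Q3 − Q2, Q2 − Q1)/Q2 ≥ 0.75, with quartiles by type-7 linear
interpolation.

**Subgrouping, three ways.** (1) Average-linkage (UPGMA) hierarchical
clustering on Pearson correlation distance d = 1 − r. (2) Consensus
clustering: R subsamples of 80 % of the samples, each clustered by UPGMA at
every candidate k; the consensus matrix entry M(i, j) is the fraction of
co-sampled draws in which i and j co-cluster, and k is chosen by the lowest
proportion of ambiguous clustering, PAC = CDF(0.9) − CDF(0.1) over the
consensus entries. (3) Non-negative matrix factorization V ≈ WH by
multiplicative updates minimizing the Kullback–Leibler divergence, with
sample groups read from the argmax row of H; stability over random restarts
is summarized by the cophenetic correlation of the consensus connectivity
matrix, maximized over k.

**Differential expression and signatures.** Per-gene Welch t-tests with
Benjamini–Hochberg adjustment and a |log2 FC| ≥ 1.2 rule; the signature of a
group is the set of genes significantly higher in that group in *every*
pairwise comparison against the other groups.

**Cross-species agreement (AGDEX-style).** For a tumour group in each
species, the differential vector d = mean(tumour) − mean(reference cortex)
per gene; over the 1:1 ortholog pairing the agreement score is the cosine

    score = Σ dA·dB / sqrt(Σ dA² · Σ dB²)  ∈ [−1, 1],

with a permutation p-value from shuffling one vector over the ortholog index
(exhaustive enumeration when ≤ 8 genes, add-one rule so p > 0).

**Cell-of-origin correlation.** Pearson correlation between each tumour
group's centroid and reference progenitor-profile centroids over the
filtered gene universe.

A scalar `ddct()` utility implements 2^−ΔΔCt relative quantification for
qPCR follow-up.

## Worked example

```r
library(crossdex)

sim <- simulate_two_species(sim_params(), seed = 1)   # mouse-like + human-like
res <- run_pipeline(sim$a, sim$b, sim$annotation, sim$map,
                    config = list(resamplings = 250, nmf_runs = 10,
                                  n_perm = 200, seed = 2))
round(res$agdex$scores, 2)
```

The default simulation plants five mouse groups (Mb, Nb, lymph, mEIC, mIC)
and six human groups (MB, NB, hIC1, hIC3, hEC, hIC2) with four linked pairs
sharing programs at agreement ρ = 0.8. The AGDEX matrix printed above is

```
         MB    NB  hIC1  hIC3  hEC  hIC2
Mb     0.72  0.19  0.02  0.03 0.18  0.14
Nb     0.25  0.74 -0.04  0.01 0.16  0.10
lymph -0.03 -0.05 -0.02  0.01 0.05 -0.03
mEIC   0.15  0.11 -0.05 -0.01 0.69  0.07
mIC    0.19  0.16  0.02  0.04 0.18  0.75
```

Each linked mouse group scores highest with its planted human partner
(diagonal ≈ ρ = 0.8 minus estimation noise) — the row-wise argmax recovers
the full mouse→human correspondence, and the unlinked lymphoma group
matches nothing. Centroid correlation likewise ranks each group's planted
progenitor profile first (11/11 groups across both species).

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end and write plain
TSV tables under `results/`:

    Rscript analysis/01_simulate.R       # the two-species cohort + truth
    Rscript analysis/02_subgroup.R       # filter; 3 clustering routes; model selection
    Rscript analysis/03_signatures.R     # Welch/BH tables; group signatures
    Rscript analysis/04_cross_species.R  # AGDEX matrix; centroid correlations

On the seed-1 cohort, step 2 reports 76/740 mouse genes as expressed and
variable, PAC selecting k = 5 for mouse with all three methods in perfect
agreement (pairwise ARI = 1); step 3 finds group signatures of 6–12 genes
per group; step 4 prints the AGDEX matrix above.

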