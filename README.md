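# orthopan

Pan-genome inference for bacterial genome collections: which genes are
orthologs of which across dozens to hundreds of strains, which are core and
which accessory, where on the strain tree genes were gained and lost, and
which genes associate with a measured phenotype. It is aimed at
comparative / population genomicists working from annotated assemblies
(GenBank files) who want a reproducible, scriptable pipeline with a
built-in simulator for validating every step against known truth.

## Method

1. **Homology graph.** All-against-all protein comparison
   (Smith–Waterman, BLOSUM62, affine gaps 11/1) with Karlin–Altschul
   bitscores; pairs with e-value ≤ 0.001 become edges weighted by
   bitscore. A three-tier seeded search (exact 5-mers, reduced-alphabet
   seeds between cluster representatives, within-component densification)
   approximates the sensitivity of dedicated search tools; any external
   tool can be substituted through a tabular adapter.
2. **Markov Clustering** (inflation 1.5) of the graph, with a
   divide-and-conquer mode for large collections: batches of ≤ 50 strains
   are clustered, each cluster is reduced to a representative, and the
   representative "pseudo-genomes" are clustered again.
3. **Phylogeny-aware refinement** — the heart of the method. Each cluster
   gets a codon alignment and gene tree. Distant homologs are split at
   branches longer than the adaptive cutoff
   `b_c = (0.1 + 2 d_c) / (1 + 2 d_c)` (d_c = single-copy core
   diversity); close paralogs are split at the branch with maximal
   paralogy score φ (strains present on both sides) when
   `ℓ/b_c + φ_max/(1.5·#strains) > 1`; unclustered fragments surface as
   same-length singleton peaks and are merged, then re-examined.
4. **Gain/loss.** A core-genome SNP tree is built; gene presence/absence
   evolves as a two-state Markov chain whose gain and loss rates are
   fitted by maximum likelihood; joint ancestral states place gain/loss
   events on branches.
5. **Association.** Numeric phenotypes are scored against gene-tree
   branches (`b_a = |μ₁−μ₂|/√(σ₁²+σ₂²)`, max over branches) and against
   presence/absence (`p_a = √n (μ_a−μ_p)/σ`).

A coalescent simulator (gene gain at uniform branch points, loss at rate
2.1, HKY sequence evolution with ts/tv bias 1.1, optional transfer and
paralogous gene families) emits GenBank/FASTA genomes plus a truth table,
and `cluster_accuracy()` scores any clustering against it.

## Worked example

```r
library(orthopan)

# simulate a small pan-genome with known truth: 10 strains, 60 gene seeds,
# low diversity (constant substitution rate 0.01)
cfg <- sim_config(n_strains = 10, n_genes = 60, seed = 3,
                  rate_dist = rate_constant(0.01))
sim <- simulate_pangenome(cfg)

res <- run_pipeline(run_config(genomes = sim$genomes,
                               output_dir = "pan_out", seed = 7))
#> [01_extract] done in 0.1s
#> [02_cluster] done in 0.9s
#> [03_postprocess] done in 2.9s
#> ...

length(res$clusters)            # 48 ortholog clusters
res$post$d_c                    # 0.0044  (core diversity, subst/site)
res$post$b_c                    # 0.1078  (adaptive split cutoff)

acc <- cluster_accuracy(res$clusters, sim$truth)
acc$counts
#>      correct   incomplete contaminated         both
#>           48            0            0            0
acc$misclustered_gene_fraction
#> [1] 0
```

The numbers mean: the 199 simulated gene copies were grouped into 48
clusters, every one exactly matching a true ortholog group; the core
diversity of ~0.4% sets the branch-length cutoff (~0.11 substitutions/site)
above which post-processing would cut a gene tree apart. `pan_out/`
contains the cluster table, presence/absence matrix, gain/loss event
table, strain tree and a JSON bundle for visualization.

Real data enter the same way, one annotated GenBank file per strain:

```r
run_pipeline(run_config(input_dir = "genomes/", output_dir = "pan_out",
                        metadata_path = "strains.tsv",
                        phenotype_column = "mic"))
```

or from the shell: `Rscript inst/cli/orthopan.R run --input genomes/ --out pan_out`.

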