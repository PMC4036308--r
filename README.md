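# lactpath

Pathway-based GWAS enrichment and variance partitioning for quantitative
traits in pedigreed livestock populations.

## The problem

Most variants affecting milk-production traits in dairy cattle sit far
below genome-wide significance in a single-SNP scan. If a biological
pathway — say, the genes driving mammary development — truly matters for
a trait, its genes should collectively harbour more associated SNPs, and
capture more genetic variance, than arbitrary gene sets of the same
size. `lactpath` implements that test for quantitative-genetics
practitioners working with two-breed bull/cow populations:

1. **Annotation** — map each gene (1-based inclusive coordinates) plus
   100 kb of flank to SNPs; pathway SNP sets are deduplicated unions
   across member genes.
2. **Association** — a weighted single-SNP linear mixed model per trait,
   `y = Xβ + Wb + Zu + e` with `u ~ N(0, A σa²)` (pedigree numerator
   relationship matrix) and residual weights
   `w = (1−h²)/(1+(4−h²)/n)` for bulls (n daughters) and
   `w = (1−h²)/(1+r²(l−1)/l)` for cows (l lactations), records
   standardised within breed. REML is solved exactly by spectral
   profiling of the variance ratio; a fast GLS mode scans all SNPs from
   one decomposition, with an exact per-SNP REML refit as reference.
3. **Enrichment** — *PropSig*, the proportion of pathway SNPs with
   p ≤ 0.05, tested against a permutation null of random gene sets
   matched on gene count (default 10,000 permutations; the critical
   value is the 500th-largest null PropSig, i.e. experiment-wise 0.05).
4. **Variance partitioning** — a single-GRM REML fit
   (`g ~ N(0, G σg²)`, VanRaden method 1) of the pathway SNPs plus a
   4,000-SNP genome-wide augmentation, compared against five random
   near-gene SNP baselines of matched size: "additional variance
   explained" in percentage points, ± SD over replicates.

A synthetic-data generator (`sim_config()` / `simulate_dataset()`)
emulates the full study design — two breeds with divergent allele
frequencies, block LD, pedigree transmission, daughter-average bull
phenotypes and repeated-lactation cow phenotypes — so the entire
pipeline is testable without external data. Transcriptions of the three
curated lactation gene sets (mammary development, 64 genes; prolactin
signalling, 27; involution, 40) ship in `inst/extdata/`.

## Worked example

```r
library(lactpath)

# packaged gene sets
lp <- load_lactation_pathways()
sapply(lp$pathways, function(p) length(p$genes))
#>  mammary_development prolactin_signalling           involution
#>                   64                   27                   40

# a synthetic population whose causal variants all sit in one pathway
cfg <- sim_config(seed = 11, n_animals = 1000, n_snps = 5000,
                  n_genes = 500, pathway_size = 40,
                  traits = list(list(name = "milk", h2 = 0.33, r2 = 0.56,
                                     n_causal = 50, enrichment_frac = 1)))
sim <- simulate_dataset(cfg)

gw <- run_gwas(sim$phenotypes$milk, sim$genotypes, sim$pedigree,
               sim$snp_map, h2 = 0.33, r2 = 0.56)
gc_lambda(gw)
#> [1] 1.079228

en <- run_enrichment(gw, sim$pathways[[1]], sim$gene_table, sim$snp_map,
                     trait = "milk", n_perm = 2000, seed = 12)
print(en, digits = 3)
#>    pathway trait n_snps n_sig propsig threshold significant empirical_p
#> 1 pathway1  milk    251    33   0.131    0.0851        TRUE       5e-04

vp <- run_partitioning(sim$phenotypes$milk, sim$genotypes,
                       sim$pathways[[1]], sim$gene_table, sim$snp_map,
                       h2 = 0.33, r2 = 0.56, n_random = 400,
                       n_replicates = 5, seed = 13)
vp[, c("delta", "se", "prop_g_pathway", "prop_g_baseline_mean")]
#>   delta  se prop_g_pathway prop_g_baseline_mean
#> 1  21.2 3.3          0.542                 0.33
```

Reading the output: 13.1% of the pathway's 251 SNPs are associated at
p ≤ 0.05, against a permutation critical value of 8.5% — the pathway is
enriched (empirical p = 5e-4). The pathway SNP set also captures 21.2
percentage points more of the random-part variance than size-matched
near-gene baselines (54.2% vs 33.0%), consistent with the architecture
the generator planted. The genomic-control lambda near 1 shows the
polygenic model is calibrated despite pedigree structure.

## The analysis workflow

Numbered drivers under `analysis/` run the package end to end on a
simulated study and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # population, genotypes, 5 traits
Rscript analysis/02_gwas.R        # per-trait association TSVs + lambda
Rscript analysis/03_enrichment.R  # PropSig tests, chromosome-exclusion
                                  # re-analysis, gene spacing, effect
                                  # correlations
Rscript analysis/04_varcomp.R     # additional-variance table
```

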