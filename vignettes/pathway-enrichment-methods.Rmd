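---
title: "Methods: pathway-based GWAS enrichment and variance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-based GWAS enrichment and variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical methods it
implements, the choices made where the design was genuinely open, and
what the simulation-based tests do and do not establish.

## The scientific question

Candidate-gene GWAS in dairy cattle asks whether the genes of a curated
biological pathway — here, three gene sets covering mammary development,
prolactin signalling and post-lactation involution — are collectively
enriched for variants affecting milk-production traits, even when few
individual SNPs reach genome-wide significance. The package implements
the full chain: gene-to-SNP assignment, a weighted mixed-model
association scan, a permutation enrichment test, and a complementary
variance-partitioning comparison.

## Record preparation and weighting

Phenotypes are trait deviations: a cow record is the mean deviation over
her `l` lactations; a bull record is the mean deviation of his `n`
daughters. Records are standardised to mean 0, SD 1 *within breed*
(sample SD), so the two breeds share a scale and the breed fixed effect
absorbs only residual location differences.

Records differ in information content, which enters the model as
residual weights with `Var(e_i) = sigma_e2 / w_i`:

* bulls: `w = (1 - h2) / (1 + (4 - h2)/n)` — increasing in `n`, with
  limit `1 - h2`;
* cows: `w = (1 - h2) / (1 + r2 (l - 1)/l)` — equal to `1 - h2` at
  `l = 1` and decreasing in `l`, because repeated lactations share the
  permanent-environment component.

Both formulas are the standard de-regressed-proof weighting; the
typography of the printed sources is ambiguous about grouping, and this
reading (the only one consistent with de-regressed-proof theory and with
the stated limits) is adopted throughout. Heritabilities default to 0.33
for yield traits and 0.5 for percentage traits, repeatability to 0.56.
For high-heritability percentage traits, bull weighting is commonly
dropped for convergence reasons; `record_weights(weight_bulls = FALSE)`
reproduces that convention as a per-trait switch. Whether a bull's `n`
counts all daughters or daughters with records per trait is not
resolvable from the sources; the package treats `n` as the count
attached to the record.

## The association model

Each SNP is tested in

```
y = X beta + W b + Z u + e,   u ~ N(0, A sigma_a2),  Var(e_i) = sigma_e2 / w_i
```

with fixed effects mean, breed and sex, `W` the 0/1/2 dosage of the
counted allele, and `A` the pedigree numerator relationship matrix from
the tabular method. Two-sided p-values use the standard normal reference
for the Wald ratio (large-sample convention; the reference is not stated
in the sources).

**REML algorithm.** Both variance-component models in the package
(pedigree `A` and genomic `G`) have exactly two components, so the
restricted likelihood profiles to a one-dimensional function of the
variance ratio after a single eigendecomposition of the weighted
relationship matrix. The package optimises that profile exactly (a
log-scale grid of 81 points refined by `optimize()`, with the ratio-zero
boundary always a candidate) rather than iterating average-information or
EM updates: at desk scale the spectral approach finds the global REML
optimum, cannot diverge, and the same decomposition is what makes the
fast per-SNP scan and multi-trait reuse (`prep`/`rotate_genotypes`)
cheap. Convergence tolerance is `1e-8` on the log-ratio; variances are
non-negative by construction.

**Fast vs exact scan.** The reference behaviour refits REML per SNP with
the SNP as a fixed covariate (`mode = "exact"`). The default fast mode
fixes the variance ratio at the null fit and runs generalised least
squares per SNP, re-estimating the residual scale per SNP with REML
degrees of freedom `n - p - 1`. The acceptance suite verifies
`|difference in log10 p| <= 0.05` between modes at 200 SNPs x 500
animals; per-SNP re-estimation of the residual scale (not just reuse of
the null variance) is what keeps effect SNPs inside that band.

**Degenerate inputs.** With `A` proportional to the identity under the
given weights, the two variances are not separately identifiable; the
fitter detects the flat eigenvalue spectrum, warns, and reports total
variance instead of failing. Monomorphic SNPs and SNPs collinear with
the fixed effects are flagged (`status` column), never silently dropped.

## The enrichment test (PropSig)

A pathway's SNP set is the union of member-gene windows: gene body plus
100 kb each side, 1-based inclusive at both ends, truncated at position
1; SNPs in overlapping windows (e.g. STAT5A/STAT5B) count once. The
observed statistic is PropSig, the proportion of the set's SNPs with
`p <= 0.05`. The boundary is counted significant (`<=`, following the
methods wording over table captions that print `<`; ties are
measure-zero in practice).

The null distribution re-draws gene sets of the *same gene count* from
the annotated universe, maps them through the same windows, and
recomputes PropSig, 10,000 times by default. The experiment-wise
critical value is the `ceiling(0.05 * n_perm)`-th largest null value —
the 500th at 10,000 permutations — and a pathway is called significant
only if its PropSig *strictly exceeds* that value. The empirical p uses
the add-one estimator `(1 + #{null >= obs}) / (n_perm + 1)`, so it is
never zero.

Three deliberate properties of this scheme: random sets are matched on
gene count only (not SNP count, chromosome, or spacing — matching the
original design; `gene_pair_distances()` quantifies the spacing
difference but no correction is applied); permutation draws whose
windows contain no mapped SNP are redrawn and counted, since dropping
them would bias the null towards zero; and chromosome-exclusion
re-analysis removes the chromosome from the SNP map, the universe *and*
the tested pathway's gene count, so observed and null statistics stay
comparable. Alternative per-SNP thresholds (`alpha = 1e-3`, `1e-5`) are
supported but have no packaged reference values.

## Relationship matrices

`build_a_matrix()` implements the recursive tabular method
(`A_ii = 1 + 0.5 A_sd`, `A_ij = 0.5 (A_j,sire + A_j,dam)`), processed
parents-first with cycle detection; it is validated against a
Monte-Carlo gene-dropping oracle (10,000 drops, agreement within 0.02
elementwise on a 50-animal pedigree with inbreeding). `A` is stored
dense; the intended scale is a few thousand animals.

`build_grm()` is VanRaden method 1,
`G = ZZ' / (2 sum p_j (1 - p_j))`, with allele frequencies estimated
from the supplied genotypes by default (base-population frequencies can
be supplied). Monomorphic SNPs are dropped with a message. The cited
construction rule does not pin down the variant; method 1 with observed
frequencies is the conventional default.

## Variance partitioning

The genomic model drops the polygenic pedigree term, exactly as printed:

```
y = X beta + Z g + e,   g ~ N(0, G sigma_g2)
```

`G` is built from the pathway's windowed SNPs **plus 4,000 random
genome-wide SNPs** (one draw, reused for the pathway and every
baseline). The augmentation is the original remedy for singular GRMs
caused by genomically clustered pathway SNPs; it also means only the
*marginal* contribution of the pathway SNPs is assessed. The package
adds a configurable diagonal jitter only as a last resort; in practice
augmentation suffices, and eigendecomposition-based REML never inverts
`G` directly.

The headline quantity is `prop_g = sigma_g2 / (sigma_g2 + sigma_e2)`
(fixed effects excluded from the denominator — standard REML
convention). "Additional variance" is
`delta = 100 * (pathway prop_g - mean baseline prop_g)` percentage
points over five random near-gene baselines: sets of the same
pre-augmentation size drawn uniformly from the union of all gene
windows, excluding the shared augmentation SNPs so sizes stay exactly
matched. The reported `se` is the SD of the per-replicate differences
(not SD/sqrt(5)) — the sources do not state the formula, and the SD is
the conservative reading; an approximate REML-curvature SE of each
`prop_g` (`se_prop`, via the numerical Hessian in log-variances with the
delta method) is reported alongside. Fixed effects are mean, breed and
sex, as in the association model (the printed model reuses symbols
ambiguously).

## The synthetic-data generator

The generator emulates the structure of the two-breed study — not its
scale — so every stage is testable without external data:

* **Genome and annotation**: 5 chromosomes of 50 Mb, 5,000 uniform SNPs,
  500 genes of 10-200 kb placed around random cluster centres (allowing
  near-adjacent and overlapping genes, the feature that motivates the
  GRM augmentation), one 40-gene pathway.
* **Population**: founders of two breeds (70/30) are mosaics of 20
  breed-specific ancestral haplotypes (Balding-Nichols divergence
  Fst = 0.05, mean LD-block length 1 Mb), followed by within-breed
  random mating over 2 generations with Haldane recombination at
  1 cM/Mb; 2,000 animals, about 25% bulls. Dosages are
  Mendelian-consistent by construction and genomic relationships track
  the pedigree.
* **Phenotypes**: cow records are means over `l` lactation deviations
  (permanent environment variance `r2 - h2`, lactation noise `1 - r2`);
  bull records are means over `n` simulated daughter deviations (half
  the bull's breeding value plus daughter Mendelian-plus-residual
  noise), so the variance structure the weighting formulas assume is
  *emergent*, not imposed. Daughter counts are negative-binomial
  (mean 60), lactation counts 1-6 with decreasing probabilities —
  progeny-test-scale choices. A fixed breed shift (-0.5 SD for the
  minor breed) is added before within-breed standardisation. Causal
  SNP effects are Gaussian, rescaled so the breeding values have
  variance exactly `h2`; a configurable fraction of causal SNPs is
  forced inside the target pathway's windows.

What the generator does **not** model: coalescent-exact LD, selection or
genetic trend, genotyping/imputation error, herd-year-season structure,
and multi-generation pedigree depth beyond the configured generations.
Passing tests therefore demonstrate correctness of the statistical
machinery under a faithful but idealised data-generating process, not
performance on any real dataset.

## Simulation sizes used by the test suite

The acceptance-style tests run at sizes chosen to give stable Monte
Carlo answers in minutes on one core:

* type-I error: 200 null datasets as 8 independent populations (1,000
  animals, 5,000 independent-SNP genotypes) x 25 non-genetic traits,
  500 permutations each; the population's eigendecomposition and rotated
  genotypes are shared across its traits, which leaves the 200 null
  traits statistically independent draws;
* power: 50 datasets (5 populations x 10 traits) with all causal
  variants inside pathway windows and SNP-heritability 0.2;
* REML recovery: 30 replicates each for the pedigree model
  (`sigma_a2 = 0.3`, `sigma_e2 = 0.7`, 1,000 animals) and the GRM model
  (`prop_g = 0.3`), judged against two standard errors of the replicate
  mean;
* variance partitioning: 1,000 unrelated cows with one lactation each
  and independent SNPs, 400-SNP augmentation, 5 baseline replicates.
  With every causal variant inside pathway windows and none near the
  baselines, the expected pathway share has the closed form
  `h2 / (h2 + (1 - h2)^2)` (the constant cow weight `1 - h2` rescales
  the residual variance), and the expected baseline share is zero.

## Known limitations

* Single-trait models only; pleiotropy is summarised post hoc by
  correlating per-SNP effect estimates across traits.
* The permutation null matches gene count only; pathways whose genes
  are unusually clustered can differ from the null in SNP count and LD
  structure (the spacing diagnostic makes this visible, nothing
  corrects for it).
* `A` and `G` are dense; the package targets desk-scale problems
  (thousands of animals), not national evaluations.
* The GRM model has no polygenic pedigree term, following the printed
  model; background variance outside the SNP set inflates
  `sigma_e2` rather than being absorbed by a second component.
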