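#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study population.
#
# Emulates the two-breed dairy design: a pedigreed Holstein/Jersey
# population with block-LD genotypes, a 400-gene universe with two
# 40-gene pathways, and five milk-production traits (bull phenotypes are
# daughter averages, cow phenotypes repeated-lactation means).  Writes
# all standard inputs of the later stages plus a manifest of digests.

library(lactpath)
source("analysis/00_trait_config.R")

cfg <- dataset_config()
sim <- simulate_dataset(cfg)
paths <- write_dataset(sim, DATASET_DIR)

cat("Simulated", nrow(sim$pedigree), "animals (",
    sum(sim$pedigree$sex == "bull"), "bulls,",
    sum(sim$pedigree$sex == "cow"), "cows ) x",
    nrow(sim$snp_map), "SNPs\n")
cat("Gene universe:", nrow(sim$gene_table), "genes;",
    length(sim$pathways), "pathways of",
    paste(lengths(lapply(sim$pathways, `[[`, "genes")), collapse = "/"),
    "genes\n")
for (tr in names(sim$truth)) {
  tv <- sim$truth[[tr]]
  cat(sprintf("  trait %-9s h2 = %.2f, %d causal SNPs\n",
              tr, tv$h2, length(tv$causal_ids)))
}
cat("Wrote:\n"); print(unname(paths))
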