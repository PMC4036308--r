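# Shared settings for the analysis workflow.  Five milk-production
# traits: yield traits at heritability 0.33, percentage traits at 0.5,
# repeatability 0.56 throughout; percentage traits leave bulls
# unweighted.  The first trait carries a pathway-concentrated causal
# architecture so the workflow has a positive control; the others are
# polygenic genome-wide.

MASTER_SEED <- 2024L
DATASET_DIR <- "results/dataset"

TRAITS <- list(
  list(name = "milk",    h2 = 0.33, r2 = 0.56, n_causal = 50,
       enrichment_frac = 0.8, weight_bulls = TRUE),
  list(name = "fat",     h2 = 0.33, r2 = 0.56, n_causal = 100,
       enrichment_frac = 0,   weight_bulls = TRUE),
  list(name = "protein", h2 = 0.33, r2 = 0.56, n_causal = 100,
       enrichment_frac = 0,   weight_bulls = TRUE),
  list(name = "fat_pct",  h2 = 0.5, r2 = 0.56, n_causal = 100,
       enrichment_frac = 0,   weight_bulls = FALSE),
  list(name = "prot_pct", h2 = 0.5, r2 = 0.56, n_causal = 100,
       enrichment_frac = 0,   weight_bulls = FALSE))

trait_par <- function(name) TRAITS[[match(name, vapply(TRAITS, `[[`, "", "name"))]]

dataset_config <- function() {
  sim_config(seed = MASTER_SEED, n_animals = 1500, n_snps = 4000,
             n_genes = 400, n_pathways = 2, pathway_size = 40,
             n_chromosomes = 5,
             traits = lapply(TRAITS, function(t)
               t[c("name", "h2", "r2", "n_causal", "enrichment_frac")]))
}
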