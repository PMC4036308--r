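# Monte-Carlo gene-dropping estimate of the additive relationship matrix:
# founders get two unique alleles, each drop transmits one random allele
# per parent; A_ij = 2 * P(random alleles from i and j are IBD),
# A_ii = 1 + P(the two alleles of i are IBD).  Independent of the tabular
# recursion it checks.
gene_drop_A <- function(ped, n_drops = 10000, seed = 1) {
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  ord <- lactpath:::pedigree_order(ped)
  P <- matrix(0L, n_drops, n)
  M <- matrix(0L, n_drops, n)
  set.seed(seed)
  for (i in ord) {
    if (is.na(si[i])) P[, i] <- 2L * i - 1L else {
      u <- stats::runif(n_drops) < 0.5
      P[, i] <- ifelse(u, P[, si[i]], M[, si[i]])
    }
    if (is.na(di[i])) M[, i] <- 2L * i else {
      u <- stats::runif(n_drops) < 0.5
      M[, i] <- ifelse(u, P[, di[i]], M[, di[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + mean(P[, i] == M[, i])
    for (j in seq_len(i - 1L)) {
      f <- (mean(P[, i] == P[, j]) + mean(P[, i] == M[, j]) +
              mean(M[, i] == P[, j]) + mean(M[, i] == M[, j])) / 4
      A[i, j] <- A[j, i] <- 2 * f
    }
  }
  A
}

# A reproducible random pedigree: `n_founders` founders, then matings
# among all earlier animals (parent-offspring and full-sib matings can
# arise, so inbreeding is exercised).
make_test_pedigree <- function(n = 50, n_founders = 12, seed = 42) {
  set.seed(seed)
  animal <- sprintf("t%03d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    pair <- sample(i - 1L, 2L)
    sire[i] <- animal[pair[1L]]
    dam[i] <- animal[pair[2L]]
  }
  data.frame(animal = animal, sire = sire, dam = dam,
             stringsAsFactors = FALSE)
}

# Tiny deterministic annotation set used across annotation tests.
tiny_gene_table <- function() {
  data.frame(symbol = c("gA", "gB", "gC", "gD"),
             chrom = c("1", "1", "2", "2"),
             start = c(1000000L, 1050000L, 100L, 500L),
             stop = c(1050000L, 1200000L, 200L, 600L),
             stringsAsFactors = FALSE)
}

tiny_snp_map <- function() {
  pos1 <- c(899999, 900000, 1000000, 1100000, 1150000, 1300000, 1300001)
  pos2 <- c(50, 150, 550, 5000)
  validate_snp_map(data.frame(
    snp_id = c(sprintf("s1_%d", pos1), sprintf("s2_%d", pos2)),
    chrom = c(rep("1", length(pos1)), rep("2", length(pos2))),
    pos = c(pos1, pos2), stringsAsFactors = FALSE))
}

# Small simulated dataset shared by several files (fresh each call; seeds
# fixed inside the generator).
small_sim <- function(seed = 5, n_animals = 400, n_snps = 1500,
                      h2 = 0.33, r2 = 0.56, n_causal = 60,
                      enrichment_frac = 0, ...) {
  cfg <- sim_config(seed = seed, n_animals = n_animals, n_snps = n_snps,
                    n_genes = 150, pathway_size = 20, n_chromosomes = 3,
                    traits = list(list(name = "t", h2 = h2, r2 = r2,
                                       n_causal = n_causal,
                                       enrichment_frac = enrichment_frac)),
                    ...)
  simulate_dataset(cfg)
}
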