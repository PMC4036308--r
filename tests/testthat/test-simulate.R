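test_that("map and gene simulation respects the configuration", {
  cfg <- sim_config(seed = 61, n_chromosomes = 2, n_genes = 100,
                    n_snps = 600, pathway_size = 15)
  mg <- simulate_map_and_genes(cfg)
  expect_equal(nrow(mg$gene_table), 100L)
  expect_true(all(mg$gene_table$start <= mg$gene_table$stop))
  expect_true(all(mg$gene_table$start >= 1))
  expect_true(all(mg$gene_table$stop <= cfg$chrom_length))
  expect_equal(nrow(mg$snp_map), 600L)
  expect_length(mg$pathways[[1]]$genes, 15L)
  # deterministic under the same seed
  mg2 <- simulate_map_and_genes(cfg)
  expect_identical(mg, mg2)
  expect_error(simulate_map_and_genes(
    sim_config(n_genes = 1, n_snps = 10, pathway_size = 1,
               chrom_length = 1e5, gene_length_range = c(9e4, 9.9e4),
               n_chromosomes = 1)), "infeasible")
})

test_that("genotypes are Mendelian-consistent through the pedigree", {
  sim <- small_sim(seed = 62, n_animals = 300, n_snps = 800)
  ped <- sim$pedigree
  geno <- sim$genotypes
  kids <- which(!is.na(ped$sire))
  for (i in kids[1:30]) {
    gs <- geno[ped$sire[i], ]; gd <- geno[ped$dam[i], ]; gk <- geno[i, ]
    expect_true(all(gk[gs == 0 & gd == 0] == 0))
    expect_true(all(gk[gs == 2 & gd == 2] == 2))
    expect_true(all(gk[gs == 0 & gd == 2] == 1))
  }
  expect_true(all(geno %in% 0:2))
})

test_that("simulation is byte-identical under a fixed master seed", {
  s1 <- small_sim(seed = 63, n_animals = 120, n_snps = 400)
  s2 <- small_sim(seed = 63, n_animals = 120, n_snps = 400)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$pedigree, s2$pedigree)
  s3 <- small_sim(seed = 64, n_animals = 120, n_snps = 400)
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("founder allele frequencies track the ancestral distribution", {
  cfg <- sim_config(seed = 65, n_animals = 600, n_generations = 0,
                    n_snps = 1000, n_genes = 100, pathway_size = 10)
  mg <- simulate_map_and_genes(cfg)
  pop <- simulate_population(cfg, mg$snp_map)
  p_hat <- colMeans(pop$genotypes) / 2
  # ancestral p ~ U(0.05, 0.95): mean 0.5, few fixed alleles
  expect_equal(mean(p_hat), 0.5, tolerance = 0.03)
  expect_lt(mean(p_hat == 0 | p_hat == 1), 0.02)
})

test_that("genomic relationships track the pedigree", {
  sim <- small_sim(seed = 66, n_animals = 250, n_snps = 2000, fst = 0)
  A <- build_a_matrix(sim$pedigree)
  G <- suppressMessages(build_grm(sim$genotypes))$G
  lt <- lower.tri(A)
  expect_gt(cor(A[lt], G[lt]), 0.8)
})

test_that("phenotype construction matches the repeatability model", {
  cfg <- sim_config(seed = 67, n_animals = 5000, n_generations = 1,
                    n_snps = 1200, n_genes = 120, pathway_size = 15,
                    prop_bulls = 0.2,
                    traits = list(list(name = "t", h2 = 0.33, r2 = 0.56,
                                       n_causal = 100, enrichment_frac = 0)))
  sim <- simulate_dataset(cfg)
  tv <- sim$truth$t
  ph <- sim$phenotypes$t
  # realised heritability: variance of true breeding values
  expect_equal(var(tv$breeding_values), 0.33, tolerance = 0.05)
  # cow records regress on breeding values with slope ~1 (breed adjusted:
  # divergent allele frequencies correlate breed with breeding value)
  cows <- ph$sex == "cow"
  sl <- coef(lm(ph$value_raw[cows] ~ tv$breeding_values[cows] +
                  ph$breed[cows]))[2]
  expect_equal(unname(sl), 1, tolerance = 0.1)
  # cow record variance decreases with lactation count per closed form:
  # var = r2 + (1 - r2)/l   (h2 + pe = r2)
  for (l in c(1, 3)) {
    i <- cows & ph$n == l
    expect_equal(var(ph$value_raw[i] - cfg$breed_effects[ph$breed[i]]),
                 0.56 + (1 - 0.56) / l, tolerance = 0.12)
  }
  # bulls: mean daughter deviation shrinks towards 0.5 * BV
  bulls <- ph$sex == "bull" & ph$n >= 50
  slb <- coef(lm(ph$value_raw[bulls] ~ tv$breeding_values[bulls] +
                   ph$breed[bulls]))[2]
  expect_equal(unname(slb), 0.5, tolerance = 0.1)
})

test_that("full enrichment places every causal variant in pathway windows", {
  sim <- small_sim(seed = 68, n_animals = 100, n_snps = 1000,
                   enrichment_frac = 1, n_causal = 30)
  ss <- pathway_snp_set(sim$pathways[[1]], sim$gene_table, sim$snp_map)
  expect_true(all(sim$truth$t$causal_ids %in% ss$snp_ids))
  # h2 = 0: no genetic signal at all
  s0 <- small_sim(seed = 69, n_animals = 100, n_snps = 500, h2 = 0)
  expect_true(all(s0$truth$t$breeding_values == 0))
  expect_length(s0$truth$t$causal_ids, 0L)
})

test_that("datasets round-trip through the plain-text writers", {
  sim <- small_sim(seed = 70, n_animals = 60, n_snps = 300)
  dir <- withr::local_tempdir()
  paths <- write_dataset(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_dataset(dir)
  expect_equal(back$gene_table$symbol, sim$gene_table$symbol)
  expect_equal(back$snp_map$snp_id, sim$snp_map$snp_id)
  expect_equal(unname(back$genotypes), unname(sim$genotypes))
  expect_equal(back$pedigree$animal, sim$pedigree$animal)
  expect_equal(back$phenotypes$t$value, sim$phenotypes$t$value)
  expect_setequal(back$pathways[[1]]$genes, sim$pathways[[1]]$genes)
  # manifest digests are reproducible
  dir2 <- withr::local_tempdir()
  write_dataset(sim, dir2)
  m1 <- readLines(paths["manifest"])
  m2 <- readLines(file.path(dir2, "manifest.txt"))
  expect_identical(m1, m2)
})
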