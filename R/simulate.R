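#' Simulation configuration
#'
#' Builds the configuration list driving the synthetic-data generator.
#' Defaults give the desk-scale preset: a two-breed pedigreed population
#' of 2,000 animals (about 25% bulls), 5,000 SNPs with block LD over 5
#' chromosomes, a 500-gene universe and one 40-gene target pathway;
#' trait defaults follow dairy milk-production conventions (heritability
#' 0.33, repeatability 0.56).
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_chromosomes,chrom_length Genome layout (bp per chromosome).
#' @param n_genes,gene_length_range Gene universe size and length range
#'   (bp); genes are placed around random cluster centres so that, as in
#'   real annotations, some genes sit close together or overlap.
#' @param n_pathways,pathway_size Pathways drawn from the universe.
#' @param n_snps SNPs placed uniformly at random over the genome.
#' @param n_animals,n_generations,prop_bulls Population size and
#'   structure; animals are split evenly over generations 0..G.
#' @param breeds Named proportions of the two breeds.
#' @param fst Balding-Nichols divergence of breed allele frequencies.
#' @param n_anc_haplotypes,ld_block_bp Founder haplotypes are mosaics of
#'   this many ancestral haplotypes with mean block length `ld_block_bp`,
#'   producing distance-decaying LD.
#' @param recomb_rate Per-bp recombination rate at meiosis (default
#'   1e-8, i.e. 1 cM/Mb).
#' @param traits List of trait settings; each a list with `name`, `h2`,
#'   `r2`, `n_causal`, `enrichment_frac` (fraction of causal variants
#'   forced inside the target pathway's gene windows).
#' @param daughters_mu,daughters_size Negative-binomial daughter counts
#'   for bulls (progeny-test scale).
#' @param lactation_probs Distribution of cow lactation counts 1..length.
#' @param breed_effects Named fixed breed shifts (trait SD) added before
#'   within-breed standardisation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 5, chrom_length = 5e7,
                       n_genes = 500, gene_length_range = c(1e4, 2e5),
                       n_pathways = 1, pathway_size = 40,
                       n_snps = 5000,
                       n_animals = 2000, n_generations = 2,
                       prop_bulls = 0.25,
                       breeds = c(holstein = 0.7, jersey = 0.3),
                       fst = 0.05,
                       n_anc_haplotypes = 20, ld_block_bp = 1e6,
                       recomb_rate = 1e-8,
                       traits = list(list(name = "milk", h2 = 0.33,
                                          r2 = 0.56, n_causal = 100,
                                          enrichment_frac = 0)),
                       daughters_mu = 60, daughters_size = 2,
                       lactation_probs = c(0.30, 0.25, 0.20, 0.12, 0.08, 0.05),
                       breed_effects = c(holstein = 0, jersey = -0.5)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length > 0,
            cfg$n_snps >= 1, cfg$n_animals >= 4,
            cfg$pathway_size <= cfg$n_genes,
            abs(sum(cfg$breeds) - 1) < 1e-8)
  for (tr in cfg$traits) {
    stopifnot(tr$h2 >= 0, tr$h2 <= 1)
    if (!is.null(tr$r2)) stopifnot(tr$h2 <= tr$r2, tr$r2 <= 1)
    if (!is.null(tr$enrichment_frac))
      stopifnot(tr$enrichment_frac >= 0, tr$enrichment_frac <= 1)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the SNP map, gene universe and pathways
#'
#' Genes are placed around random cluster centres (so spacing mimics the
#' clustered annotation of real genomes), with lengths uniform in the
#' configured range; overlapping genes are allowed.  SNP positions are
#' uniform within chromosomes.  Pathways are disjoint random draws from
#' the gene universe.
#'
#' @param cfg A [sim_config()].
#' @return A list: `snp_map`, `gene_table`, `pathways` (list of
#'   `pathway`).
#' @export
simulate_map_and_genes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  mean_len <- mean(cfg$gene_length_range)
  if (cfg$n_genes * mean_len > 0.8 * cfg$n_chromosomes * cfg$chrom_length)
    stop("infeasible gene packing: universe does not fit the genome")
  with_seed(cfg$seed + 1L, {
    chroms <- as.character(seq_len(cfg$n_chromosomes))
    # genes spread over chromosomes proportionally
    gene_chr <- sort(rep_len(chroms, cfg$n_genes))
    tab <- lapply(chroms, function(ch) {
      ng <- sum(gene_chr == ch)
      if (ng == 0L) return(NULL)
      n_centres <- max(1L, ceiling(ng / 4))
      centres <- sort(stats::runif(n_centres, 1, cfg$chrom_length))
      len <- round(stats::runif(ng, cfg$gene_length_range[1],
                                cfg$gene_length_range[2]))
      start <- round(sample(centres, ng, replace = TRUE) +
                       stats::rnorm(ng, 0, 2e6))
      start <- pmin(pmax(start, 1), cfg$chrom_length - len)
      data.frame(chrom = ch, start = as.integer(start),
                 stop = as.integer(start + len), stringsAsFactors = FALSE)
    })
    gene_table <- do.call(rbind, tab)
    gene_table <- gene_table[order(gene_table$chrom, gene_table$start), ]
    gene_table <- data.frame(
      symbol = sprintf("g%04d", seq_len(nrow(gene_table))),
      gene_table, stringsAsFactors = FALSE)
    rownames(gene_table) <- NULL

    snp_chr <- sort(rep_len(chroms, cfg$n_snps))
    maps <- lapply(chroms, function(ch) {
      ns <- sum(snp_chr == ch)
      pos <- sort(sample.int(cfg$chrom_length, ns))
      data.frame(snp_id = sprintf("snp_%s_%d", ch, pos), chrom = ch,
                 pos = as.numeric(pos), stringsAsFactors = FALSE)
    })
    snp_map <- validate_snp_map(do.call(rbind, maps))

    pool <- gene_table$symbol
    pathways <- vector("list", cfg$n_pathways)
    for (i in seq_len(cfg$n_pathways)) {
      pick <- sample(pool, cfg$pathway_size)
      pool <- setdiff(pool, pick)
      pathways[[i]] <- new_pathway(sprintf("pathway%d", i), pick)
    }
    list(snp_map = snp_map, gene_table = gene_table, pathways = pathways)
  })
}

# Mosaic copy of ancestral haplotypes H (n_anc x m) with per-interval
# switch probabilities q (q[1] is the start, always a fresh draw).
#' @keywords internal
mosaic_haplotype <- function(H, q) {
  m <- ncol(H)
  switch_at <- c(TRUE, stats::runif(m - 1L) < q[-1L])
  seg <- cumsum(switch_at)
  templates <- sample.int(nrow(H), max(seg), replace = TRUE)
  H[cbind(templates[seg], seq_len(m))]
}

# One gamete from a pair of parental haplotypes with per-interval
# crossover probabilities r (r[1] = 0.5: chromosomes assort freely).
#' @keywords internal
meiosis <- function(hap1, hap2, r) {
  m <- length(hap1)
  cross <- c(stats::runif(1) < 0.5, stats::runif(m - 1L) < r[-1L])
  phase <- cumsum(cross) %% 2L
  ifelse(phase == 0L, hap1, hap2)
}

# Per-interval probabilities from inter-SNP distances; new chromosome
# resets to p_reset.
#' @keywords internal
interval_probs <- function(snp_map, scale, p_reset, haldane = FALSE) {
  m <- nrow(snp_map)
  d <- c(0, diff(snp_map$pos))
  new_chr <- c(TRUE, snp_map$chrom[-1L] != snp_map$chrom[-m])
  q <- if (haldane) 0.5 * (1 - exp(-2 * d * scale)) else 1 - exp(-d / scale)
  q[new_chr] <- p_reset
  q
}

#' Simulate the pedigree and LD-structured genotypes
#'
#' Founders of each breed are mosaics of breed-specific ancestral
#' haplotypes (Balding-Nichols divergent allele frequencies), giving
#' block-structured LD that decays with distance.  Later generations are
#' produced by within-breed random mating with Haldane recombination, so
#' offspring dosages are Mendelian-consistent and genomic relationships
#' track the pedigree.  Bull daughter counts and cow lactation counts are
#' drawn here (they are population attributes shared by all traits).
#'
#' @param cfg A [sim_config()].
#' @param snp_map SNP map from [simulate_map_and_genes()].
#' @return A list: `pedigree` (`animal`, `sire`, `dam`, `sex`, `breed`,
#'   `generation`, `n_records`) and `genotypes` (animals x SNPs dosage
#'   matrix).
#' @export
simulate_population <- function(cfg, snp_map) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- nrow(snp_map)
  with_seed(cfg$seed + 2L, {
    q_mosaic <- interval_probs(snp_map, cfg$ld_block_bp, 1)
    r_meiosis <- interval_probs(snp_map, cfg$recomb_rate, 0.5,
                                haldane = TRUE)
    G <- cfg$n_generations
    sizes <- rep(cfg$n_animals %/% (G + 1L), G + 1L)
    sizes[1L] <- sizes[1L] + cfg$n_animals - sum(sizes)
    n <- cfg$n_animals
    ids <- sprintf("a%05d", seq_len(n))
    breed <- character(n); sex <- character(n)
    sire <- rep(NA_character_, n); dam <- rep(NA_character_, n)
    generation <- rep(seq_along(sizes) - 1L, sizes)
    hapA <- matrix(0L, n, m); hapB <- matrix(0L, n, m)

    # breed-specific ancestral haplotypes
    p_anc <- stats::runif(m, 0.05, 0.95)
    a <- p_anc * (1 - cfg$fst) / cfg$fst
    b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
    anc <- lapply(names(cfg$breeds), function(br) {
      p_br <- stats::rbeta(m, a, b)
      matrix(stats::rbinom(cfg$n_anc_haplotypes * m, 1L,
                           rep(p_br, each = cfg$n_anc_haplotypes)),
             nrow = cfg$n_anc_haplotypes)
    })
    names(anc) <- names(cfg$breeds)

    for (g in seq_along(sizes)) {
      rows <- which(generation == g - 1L)
      breed[rows] <- rep(names(cfg$breeds),
                         round(cfg$breeds * length(rows)))[seq_along(rows)]
      sex[rows] <- ifelse(stats::runif(length(rows)) < cfg$prop_bulls,
                          "bull", "cow")
      # guarantee both sexes per breed while later generations still breed
      if (g < length(sizes)) {
        for (br in unique(breed[rows])) {
          br_rows <- rows[breed[rows] == br]
          if (length(br_rows) >= 2L) {
            if (!any(sex[br_rows] == "bull")) sex[br_rows[1L]] <- "bull"
            if (!any(sex[br_rows] == "cow"))
              sex[br_rows[length(br_rows)]] <- "cow"
          }
        }
      }
      for (i in rows) {
        if (g == 1L) {
          hapA[i, ] <- mosaic_haplotype(anc[[breed[i]]], q_mosaic)
          hapB[i, ] <- mosaic_haplotype(anc[[breed[i]]], q_mosaic)
        } else {
          prev <- which(generation < g - 1L & breed == breed[i])
          sires <- prev[sex[prev] == "bull"]
          dams <- prev[sex[prev] == "cow"]
          if (length(sires) == 0L || length(dams) == 0L)
            stop("breed '", breed[i], "' lacks parents of both sexes")
          s <- if (length(sires) == 1L) sires else sample(sires, 1L)
          d <- if (length(dams) == 1L) dams else sample(dams, 1L)
          sire[i] <- ids[s]; dam[i] <- ids[d]
          hapA[i, ] <- meiosis(hapA[s, ], hapB[s, ], r_meiosis)
          hapB[i, ] <- meiosis(hapA[d, ], hapB[d, ], r_meiosis)
        }
      }
    }
    n_records <- integer(n)
    is_bull <- sex == "bull"
    n_records[is_bull] <- pmax(1L, stats::rnbinom(sum(is_bull),
                                                  size = cfg$daughters_size,
                                                  mu = cfg$daughters_mu))
    n_records[!is_bull] <- sample(seq_along(cfg$lactation_probs),
                                  sum(!is_bull), replace = TRUE,
                                  prob = cfg$lactation_probs)
    geno <- hapA + hapB
    dimnames(geno) <- list(ids, snp_map$snp_id)
    ped <- data.frame(animal = ids, sire = sire, dam = dam, sex = sex,
                      breed = breed, generation = generation,
                      n_records = n_records, stringsAsFactors = FALSE)
    list(pedigree = ped, genotypes = geno)
  })
}

#' Simulate phenotypes for one trait
#'
#' Causal SNP effects are drawn and scaled so the true breeding values
#' have variance `h2` (phenotypic variance 1 before the breed shift).  A
#' configured fraction of causal variants is forced inside the target
#' pathway's gene windows.  Records are then built the way the study
#' phenotypes are built:
#' \itemize{
#'   \item cows: the mean over `l` lactation deviations of
#'     (breeding value + permanent environment + lactation noise), with
#'     variance ratios set by `h2` and `r2`;
#'   \item bulls: the mean daughter deviation over `n` simulated
#'     daughters (half the bull's breeding value plus daughter-specific
#'     Mendelian and residual noise), so the information structure the
#'     weighting formulas assume is emergent rather than imposed.
#' }
#' A fixed breed shift is added, then records are standardised within
#' breed.
#'
#' @param cfg A [sim_config()].
#' @param genotypes Dosage matrix from [simulate_population()].
#' @param pedigree Pedigree from [simulate_population()].
#' @param trait One element of `cfg$traits`.
#' @param pathway_snp_ids SNP ids of the enrichment target pathway's
#'   windows (required when `trait$enrichment_frac > 0`).
#' @param seed Stage seed.
#' @return A list: `pheno` (`animal`, `sex`, `breed`, `trait`, `value`
#'   standardised, `value_raw`, `n`) and `truth` (`causal_ids`,
#'   `effects`, `breeding_values`, `h2`, `r2`).
#' @export
simulate_phenotypes <- function(cfg, genotypes, pedigree, trait,
                                pathway_snp_ids = NULL, seed = cfg$seed + 10L) {
  h2 <- trait$h2
  r2 <- if (is.null(trait$r2)) max(h2, 0.56) else trait$r2
  n_causal <- if (is.null(trait$n_causal)) 100L else trait$n_causal
  enr <- if (is.null(trait$enrichment_frac)) 0 else trait$enrichment_frac
  n <- nrow(genotypes)
  with_seed(seed, {
    if (h2 > 0) {
      all_ids <- colnames(genotypes)
      n_in <- round(enr * n_causal)
      if (n_in > 0L) {
        if (is.null(pathway_snp_ids) || length(pathway_snp_ids) == 0L)
          stop("enrichment target pathway has no SNPs")
        inside <- sample(pathway_snp_ids, min(n_in, length(pathway_snp_ids)))
      } else inside <- character(0)
      outside_pool <- setdiff(all_ids,
                              if (enr > 0) pathway_snp_ids else character(0))
      outside <- sample(outside_pool, n_causal - length(inside))
      causal <- c(inside, outside)
      eff <- stats::rnorm(length(causal))
      Zc <- scale(genotypes[, causal, drop = FALSE], center = TRUE,
                  scale = FALSE)
      g_raw <- drop(Zc %*% eff)
      sc <- sqrt(h2 / stats::var(g_raw))
      g <- g_raw * sc
      eff <- eff * sc
    } else {
      causal <- character(0); eff <- numeric(0); g <- numeric(n)
    }
    value <- numeric(n)
    is_bull <- pedigree$sex == "bull"
    nb <- pedigree$n_records[is_bull]
    value[is_bull] <- 0.5 * g[is_bull] +
      stats::rnorm(sum(is_bull), 0,
                   sqrt((0.75 * h2 + (1 - h2)) / nb))
    nl <- pedigree$n_records[!is_bull]
    pe_sd <- sqrt(max(r2 - h2, 0))
    value[!is_bull] <- g[!is_bull] +
      stats::rnorm(sum(!is_bull), 0, pe_sd) +
      stats::rnorm(sum(!is_bull), 0, sqrt((1 - r2) / nl))
    value <- value + cfg$breed_effects[pedigree$breed]
    pheno <- data.frame(animal = pedigree$animal, sex = pedigree$sex,
                        breed = pedigree$breed, trait = trait$name,
                        value = standardise_records(value, pedigree$breed),
                        value_raw = value, n = pedigree$n_records,
                        stringsAsFactors = FALSE)
    list(pheno = pheno,
         truth = list(causal_ids = causal, effects = eff,
                      breeding_values = g, h2 = h2, r2 = r2))
  })
}

#' Simulate a complete dataset
#'
#' Runs the three simulation stages for every configured trait and
#' returns everything the downstream analyses need.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_dataset`: `cfg`, `snp_map`, `gene_table`,
#'   `pathways`, `pedigree`, `genotypes`, `phenotypes` (named list of
#'   per-trait tables) and `truth` (named list).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  mapg <- simulate_map_and_genes(cfg)
  pop <- simulate_population(cfg, mapg$snp_map)
  target <- mapg$pathways[[1L]]
  target_snps <- pathway_snp_set(target, mapg$gene_table, mapg$snp_map)$snp_ids
  phenos <- list(); truths <- list()
  for (i in seq_along(cfg$traits)) {
    tr <- cfg$traits[[i]]
    sim <- simulate_phenotypes(cfg, pop$genotypes, pop$pedigree, tr,
                               pathway_snp_ids = target_snps,
                               seed = cfg$seed + 10L + i)
    phenos[[tr$name]] <- sim$pheno
    truths[[tr$name]] <- sim$truth
  }
  structure(list(cfg = cfg, snp_map = mapg$snp_map,
                 gene_table = mapg$gene_table, pathways = mapg$pathways,
                 pedigree = pop$pedigree, genotypes = pop$genotypes,
                 phenotypes = phenos, truth = truths),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", nrow(x$pedigree), "animals,", nrow(x$snp_map),
      "SNPs,", nrow(x$gene_table), "genes,", length(x$phenotypes),
      "trait(s)\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the standard plain-text inputs of the analysis modules: gene
#' table TSV, pathway GMT, bim-like SNP map, dosage TSV, pedigree CSV,
#' phenotype CSV, plus a JSON-like truth/manifest file with the seed and
#' per-file digests.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(dir, "genes.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             map = file.path(dir, "snps.map"),
             dosages = file.path(dir, "dosages.tsv"),
             pedigree = file.path(dir, "pedigree.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             manifest = file.path(dir, "manifest.txt"))
  data.table::fwrite(sim$gene_table, paths["genes"], sep = "\t")
  writeLines(vapply(sim$pathways, function(p)
    paste(c(p$name, "simulated", p$genes), collapse = "\t"), character(1)),
    paths["pathways"])
  data.table::fwrite(sim$snp_map[, c("chrom", "snp_id", "pos")],
                     paths["map"], sep = "\t", col.names = FALSE)
  geno_df <- data.frame(animal = rownames(sim$genotypes), sim$genotypes,
                        check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(geno_df, paths["dosages"], sep = "\t")
  ped <- sim$pedigree
  ped$sire[is.na(ped$sire)] <- "0"; ped$dam[is.na(ped$dam)] <- "0"
  data.table::fwrite(ped, paths["pedigree"])
  data.table::fwrite(do.call(rbind, sim$phenotypes), paths["phenotypes"])
  digest <- tools::md5sum(paths[names(paths) != "manifest"])
  writeLines(c(sprintf("seed\t%d", sim$cfg$seed),
               sprintf("package_version\t%s",
                       as.character(utils::packageVersion("lactpath"))),
               sprintf("%s\t%s", basename(names(digest)), unname(digest))),
             paths["manifest"])
  invisible(paths)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A list with the same components as a `sim_dataset` except
#'   `cfg` and `truth`.
#' @export
read_dataset <- function(dir) {
  geno_df <- data.table::fread(file.path(dir, "dosages.tsv"),
                               data.table = FALSE)
  geno <- as.matrix(geno_df[, -1L, drop = FALSE])
  rownames(geno) <- as.character(geno_df[[1L]])
  ph <- data.table::fread(file.path(dir, "phenotypes.csv"),
                          data.table = FALSE)
  ph$animal <- as.character(ph$animal)
  list(gene_table = read_gene_table(file.path(dir, "genes.tsv")),
       pathways = read_gmt(file.path(dir, "pathways.gmt")),
       snp_map = read_snp_map(file.path(dir, "snps.map")),
       genotypes = geno,
       pedigree = read_pedigree(file.path(dir, "pedigree.csv")),
       phenotypes = split(ph, ph$trait))
}
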