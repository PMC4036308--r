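#' Sample random near-gene SNPs
#'
#' Draws `n_snps` distinct SNPs uniformly without replacement from the
#' union of all gene windows in the universe.  These sets are the
#' baseline for the "additional variance explained" comparison: they
#' match the pathway SNPs in being gene-proximal, but not in pathway
#' membership.
#'
#' @param n_snps Number of SNPs to draw.
#' @param gene_table Gene universe.
#' @param snp_map SNP map.
#' @param window_bp Gene window (default 100 kb).
#' @param seed Optional integer seed.
#' @param exclude Optional SNP ids removed from the eligible pool (e.g.
#'   a shared augmentation set, so set sizes stay exactly matched).
#' @return A `snp_set` named `"random_near_gene"`.
#' @export
sample_near_gene_snps <- function(n_snps, gene_table, snp_map,
                                  window_bp = 1e5, seed = NULL,
                                  exclude = NULL) {
  idx <- build_gene_snp_index(gene_table, snp_map, window_bp)
  eligible <- unique(unlist(idx, use.names = FALSE))
  if (!is.null(exclude))
    eligible <- eligible[!snp_map$snp_id[eligible] %in% exclude]
  if (length(eligible) < n_snps)
    stop("only ", length(eligible), " near-gene SNPs available; cannot sample ",
         n_snps)
  pick <- with_seed(seed, sample(eligible, n_snps))
  new_snp_set("random_near_gene", snp_map$snp_id[pick])
}

#' Additional variance explained by a pathway SNP set
#'
#' Difference, in percentage points, between the pathway fit's `prop_g`
#' and the mean `prop_g` of the random near-gene baseline fits.  The
#' reported `se` is the SD of the per-replicate differences across
#' baselines (a conservative dispersion measure; with a fixed pathway fit
#' it equals the SD of the baseline `prop_g` values).
#'
#' @param pathway_fit A `varcomp_fit` for the pathway (+ augmentation)
#'   SNP set.
#' @param baseline_fits List of >= 2 `varcomp_fit`s for size-matched
#'   random near-gene sets under the same augmentation scheme.
#' @param pathway_name,trait Labels carried into the result.
#' @return A one-row `data.frame`: `pathway`, `trait`, `prop_g_pathway`,
#'   `prop_g_baseline_mean`, `delta` (percentage points), `se`,
#'   `n_replicates`.
#' @export
additional_variance <- function(pathway_fit, baseline_fits,
                                pathway_name = NA_character_,
                                trait = NA_character_) {
  stopifnot(inherits(pathway_fit, "varcomp_fit"))
  if (length(baseline_fits) < 2L)
    stop("at least 2 baseline replicates are needed for a standard error")
  base <- vapply(baseline_fits, function(f) f$prop_g, numeric(1))
  if (!is.null(pathway_fit$snp_ids)) {
    n_path <- length(pathway_fit$snp_ids)
    for (f in baseline_fits) {
      if (!is.null(f$snp_ids) &&
          abs(length(f$snp_ids) - n_path) > 0.02 * n_path)
        stop("baseline SNP-set size (", length(f$snp_ids),
             ") does not match pathway set size (", n_path, ")")
    }
  }
  delta <- 100 * (pathway_fit$prop_g - mean(base))
  data.frame(pathway = pathway_name, trait = trait,
             prop_g_pathway = pathway_fit$prop_g,
             prop_g_baseline_mean = mean(base),
             delta = delta,
             se = 100 * stats::sd(pathway_fit$prop_g - base),
             n_replicates = length(base), stringsAsFactors = FALSE)
}

#' Variance partitioning of a pathway against near-gene baselines
#'
#' Orchestrates the full comparison for one trait and one pathway:
#' \enumerate{
#'   \item pathway windowed SNP set, augmented with `n_random` random
#'     genome-wide SNPs (one augmentation draw, reused across the pathway
#'     and every baseline);
#'   \item GRM + REML fit for the pathway set;
#'   \item `n_replicates` random near-gene SNP sets of the same
#'     (pre-augmentation) size, each augmented, fitted the same way;
#'   \item the additional-variance summary.
#' }
#'
#' @param pheno Phenotype table for one trait (`animal`, `sex`, `breed`,
#'   `value`, `n`), rows aligned with `genotypes`.
#' @param genotypes Animals x SNPs dosage matrix.
#' @param pathway A `pathway` object.
#' @param gene_table Gene universe table.
#' @param snp_map SNP map.
#' @param h2,r2 Trait parameters for the residual weights.
#' @param weight_bulls Passed to [record_weights()].
#' @param window_bp Gene window (default 100 kb).
#' @param n_random Augmentation SNPs (default 4000).
#' @param n_replicates Baseline replicates (default 5).
#' @param seed Master seed; stage seeds are derived from it.
#' @return The [additional_variance()] row, with the pathway and baseline
#'   fits attached as attributes `pathway_fit` and `baseline_fits`.
#' @export
run_partitioning <- function(pheno, genotypes, pathway, gene_table, snp_map,
                             h2, r2, weight_bulls = TRUE, window_bp = 1e5,
                             n_random = 4000, n_replicates = 5, seed = 1) {
  stopifnot(nrow(pheno) == nrow(genotypes))
  w <- record_weights(pheno, h2, r2, weight_bulls)
  X <- make_design(pheno)
  y <- pheno$value

  path_set <- pathway_snp_set(pathway, gene_table, snp_map, window_bp)
  if (path_set$n_snps == 0L)
    stop("run_partitioning: pathway '", pathway$name, "' maps to no SNPs")
  aug <- augment_snp_set(path_set, snp_map, n_random, seed = seed)
  aug_ids <- setdiff(aug$snp_ids, path_set$snp_ids)

  fit_set <- function(ids, label) {
    grm <- build_grm(genotypes, snp_ids = ids)
    fit <- tryCatch(fit_grm_model(y, X, grm, w),
                    error = function(e) stop("stage '", label, "' failed: ",
                                             conditionMessage(e)))
    fit
  }
  pathway_fit <- fit_set(aug$snp_ids, paste0("pathway:", pathway$name))

  baseline_fits <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    bs <- sample_near_gene_snps(path_set$n_snps, gene_table, snp_map,
                                window_bp, seed = seed + 1000 + r,
                                exclude = aug_ids)
    ids <- c(bs$snp_ids, aug_ids)
    baseline_fits[[r]] <- fit_set(ids, paste0("baseline:", r))
  }
  out <- additional_variance(pathway_fit, baseline_fits,
                             pathway_name = pathway$name,
                             trait = pheno$trait[1L])
  out$n_snps_pathway <- path_set$n_snps
  out$n_snps_augmentation <- length(aug_ids)
  attr(out, "pathway_fit") <- pathway_fit
  attr(out, "baseline_fits") <- baseline_fits
  out
}
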