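#' Proportion of significant SNPs
#'
#' Counts p-values at or below `alpha` and expresses the count as a
#' proportion of the set size (PropSig).  The boundary `p == alpha` is
#' counted significant.
#'
#' @param pvalues Numeric vector of per-SNP p-values in `[0, 1]` (`NA`s
#'   from monomorphic/collinear SNPs are dropped).
#' @param alpha Per-SNP significance level (default 0.05).
#' @return A list with `n_snps`, `n_sig` and `propsig`.
#' @export
prop_sig <- function(pvalues, alpha = 0.05) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) == 0L) stop("no p-values supplied")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  n_sig <- sum(pvalues <= alpha)
  list(n_snps = length(pvalues), n_sig = n_sig,
       propsig = n_sig / length(pvalues))
}

#' Draw a random gene set from a universe
#'
#' Samples `k` distinct genes uniformly without replacement, optionally
#' excluding chromosomes first.  Random gene sets are matched to a tested
#' pathway on gene count only (not SNP count or spacing), so the
#' permutation null reflects what an arbitrary same-sized gene list would
#' show.
#'
#' @param universe Gene coordinate table.
#' @param k Number of genes to draw.
#' @param seed Optional integer seed for reproducibility.
#' @param excluded_chroms Optional chromosome labels to remove before
#'   sampling.
#' @return A `pathway` object named `"random"`.
#' @export
sample_random_gene_set <- function(universe, k, seed = NULL,
                                   excluded_chroms = NULL) {
  if (!is.null(excluded_chroms))
    for (ch in excluded_chroms) universe <- exclude_chromosome(universe, ch)
  if (k > nrow(universe))
    stop("cannot sample ", k, " genes from a universe of ", nrow(universe))
  pick <- with_seed(seed, sample(nrow(universe), k))
  new_pathway("random", universe$symbol[pick])
}

#' Permutation null distribution of PropSig
#'
#' Repeatedly draws random gene sets of size `k` from the universe, forms
#' each set's windowed SNP union, and computes its PropSig from the
#' supplied per-SNP p-values.  The experiment-wise critical value is the
#' `ceiling(alpha_exp * n_perm)`-th largest null value (the 500th highest
#' at 10,000 permutations and level 0.05).  Draws whose windows contain
#' no mapped SNP are redrawn (dropping them would bias the null towards
#' zero); the redraw count is recorded.
#'
#' @param universe Gene coordinate table to sample from.
#' @param k Genes per random set (the tested pathway's gene count).
#' @param snp_map SNP map (defines the SNP universe).
#' @param pvalues Named numeric vector of per-SNP p-values (names =
#'   `snp_id`).
#' @param n_perm Number of permutations (default 10000).
#' @param alpha Per-SNP significance level inside PropSig (default 0.05).
#' @param alpha_exp Experiment-wise level setting the threshold rank
#'   (default 0.05).
#' @param window_bp Gene window (default 100 kb).
#' @param seed Integer seed.
#' @param excluded_chroms Optional chromosomes removed from both the
#'   universe and the SNP map before permuting.
#' @return An object of class `null_distribution`: sorted `values`
#'   (decreasing), `n_perm`, `alpha`, `alpha_exp`, `threshold`,
#'   `threshold_rank`, `n_redraws`, `seed`, `k`, `window_bp`.
#' @export
build_null_distribution <- function(universe, k, snp_map, pvalues,
                                    n_perm = 10000, alpha = 0.05,
                                    alpha_exp = 0.05, window_bp = 1e5,
                                    seed = NULL, excluded_chroms = NULL) {
  stopifnot(n_perm >= 1, k >= 1)
  if (is.null(names(pvalues))) stop("pvalues must be named by snp_id")
  if (!is.null(excluded_chroms)) {
    for (ch in excluded_chroms) {
      universe <- exclude_chromosome(universe, ch)
      snp_map <- snp_map[snp_map$chrom != ch, , drop = FALSE]
    }
  }
  if (k > nrow(universe))
    stop("k = ", k, " exceeds the post-exclusion universe size ",
         nrow(universe))
  p <- pvalues[match(snp_map$snp_id, names(pvalues))]
  idx <- build_gene_snp_index(universe, snp_map, window_bp)
  ng <- nrow(universe)
  vals <- numeric(n_perm)
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      repeat {
        snps <- unique(unlist(idx[sample.int(ng, k)], use.names = FALSE))
        pv <- p[snps]
        pv <- pv[!is.na(pv)]
        if (length(pv) > 0L) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > 100L * n_perm)
          stop("permutation gene sets persistently contain no mapped SNPs")
      }
      vals[b] <- mean(pv <= alpha)
    }
  })
  vals <- sort(vals, decreasing = TRUE)
  rank <- min(n_perm, ceiling(alpha_exp * n_perm))
  structure(list(values = vals, n_perm = n_perm, alpha = alpha,
                 alpha_exp = alpha_exp, threshold = vals[rank],
                 threshold_rank = rank, n_redraws = n_redraws,
                 seed = seed, k = k, window_bp = window_bp),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution>", x$n_perm, "permutations of", x$k,
      "genes; threshold", format(x$threshold, digits = 4),
      "( rank", x$threshold_rank, ")\n")
  invisible(x)
}

#' Experiment-wise enrichment test of a pathway
#'
#' Compares a pathway's observed PropSig with the permutation null: the
#' pathway is significant iff its PropSig strictly exceeds the critical
#' value.  The empirical p-value uses the add-one estimator
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param pathway_name Label for the tested pathway.
#' @param pvalues Named per-SNP p-values of the pathway SNP set.
#' @param null A `null_distribution` built with matching settings.
#' @param trait Optional trait label carried into the result.
#' @return A one-row `data.frame`: `pathway`, `trait`, `n_snps`, `n_sig`,
#'   `propsig`, `threshold`, `significant`, `empirical_p`.
#' @export
enrichment_test <- function(pathway_name, pvalues, null, trait = NA_character_) {
  stopifnot(inherits(null, "null_distribution"))
  obs <- prop_sig(pvalues, null$alpha)
  emp <- (1 + sum(null$values >= obs$propsig)) / (null$n_perm + 1)
  data.frame(pathway = pathway_name, trait = trait,
             n_snps = obs$n_snps, n_sig = obs$n_sig,
             propsig = obs$propsig, threshold = null$threshold,
             significant = obs$propsig > null$threshold,
             empirical_p = emp, stringsAsFactors = FALSE)
}

#' Pathway enrichment over association results
#'
#' End-to-end enrichment run: for each pathway, form the windowed SNP
#' union, compute observed PropSig from the association p-values, build a
#' size-matched permutation null and test at the experiment-wise level.
#'
#' @param assoc Association results (`snp_id`, `pvalue`, ... ) from
#'   [snp_association()] or [run_gwas()].
#' @param pathways A `pathway` or list of pathways.
#' @param universe Gene coordinate table used both to resolve pathway
#'   genes and as the random-sampling universe.
#' @param snp_map SNP map.
#' @param trait Optional trait label.
#' @inheritParams build_null_distribution
#' @return A `data.frame` with one row per pathway (see
#'   [enrichment_test()]), with the null distributions attached as the
#'   `nulls` attribute.
#' @export
run_enrichment <- function(assoc, pathways, universe, snp_map,
                           trait = NA_character_, n_perm = 10000,
                           alpha = 0.05, alpha_exp = 0.05, window_bp = 1e5,
                           seed = NULL, excluded_chroms = NULL) {
  if (inherits(pathways, "pathway")) pathways <- list(pathways)
  pvals <- stats::setNames(assoc$pvalue, assoc$snp_id)
  snp_map_used <- snp_map
  universe_used <- universe
  if (!is.null(excluded_chroms)) {
    for (ch in excluded_chroms) {
      snp_map_used <- snp_map_used[snp_map_used$chrom != ch, , drop = FALSE]
      universe_used <- exclude_chromosome(universe_used, ch)
    }
  }
  rows <- vector("list", length(pathways))
  nulls <- vector("list", length(pathways))
  for (i in seq_along(pathways)) {
    pw <- pathways[[i]]
    missing <- setdiff(pw$genes, universe$symbol)
    if (length(missing) > 0L)
      stop("pathway '", pw$name, "' has gene(s) absent from the gene table: ",
           paste(missing, collapse = ", "))
    genes_used <- intersect(pw$genes, universe_used$symbol)
    if (length(genes_used) == 0L)
      stop("pathway '", pw$name, "' has no genes left after exclusions")
    ss <- pathway_snp_set(new_pathway(pw$name, genes_used), universe_used,
                          snp_map_used, window_bp)
    if (ss$n_snps == 0L)
      stop("pathway '", pw$name, "' maps to no SNPs after exclusions")
    k_eff <- length(genes_used)
    null <- build_null_distribution(
      universe, k_eff, snp_map, pvals, n_perm = n_perm, alpha = alpha,
      alpha_exp = alpha_exp, window_bp = window_bp,
      seed = if (is.null(seed)) NULL else seed + i,
      excluded_chroms = excluded_chroms)
    rows[[i]] <- enrichment_test(pw$name, pvals[ss$snp_ids], null, trait)
    nulls[[i]] <- null
  }
  out <- do.call(rbind, rows)
  names(nulls) <- out$pathway
  attr(out, "nulls") <- nulls
  out
}
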