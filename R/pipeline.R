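#' Genome-wide association scan for one trait
#'
#' Prepares the records (within-breed standardisation is assumed done;
#' weights are computed from sex and record counts), fits the polygenic
#' null model against the pedigree A-matrix, and scans every SNP.
#'
#' @param pheno Phenotype table for one trait (`animal`, `sex`, `breed`,
#'   `value`, `n`), one record per animal.
#' @param genotypes Animals x SNPs dosage matrix; rows are matched to
#'   `pheno$animal` by rowname.
#' @param pedigree Pedigree covering at least the phenotyped animals.
#' @param snp_map SNP map (adds `chrom`/`pos` to the output).
#' @param h2,r2 Trait heritability and repeatability for the weights.
#' @param weight_bulls Passed to [record_weights()]; set `FALSE` for
#'   high-heritability percentage traits.
#' @param mode `"fast"` or `"exact"` (see [snp_association()]).
#' @return A `data.frame` with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `beta`, `se`, `pvalue`, `status`; the null model fit is attached as
#'   attribute `null_fit`.
#' @export
run_gwas <- function(pheno, genotypes, pedigree, snp_map, h2, r2,
                     weight_bulls = TRUE, mode = "fast") {
  rows <- match(pheno$animal, rownames(genotypes))
  if (anyNA(rows))
    stop("genotypes missing for animal(s): ",
         paste(utils::head(pheno$animal[is.na(rows)], 5L), collapse = ", "))
  geno <- genotypes[rows, , drop = FALSE]
  A_full <- build_a_matrix(pedigree)
  A <- A_full[pheno$animal, pheno$animal]
  w <- record_weights(pheno, h2, r2, weight_bulls)
  X <- make_design(pheno)
  null_fit <- fit_null_model(pheno$value, X, A, w)
  res <- snp_association(geno, null_fit, mode = mode)
  pos <- match(res$snp_id, snp_map$snp_id)
  out <- data.frame(snp_id = res$snp_id, chrom = snp_map$chrom[pos],
                    pos = snp_map$pos[pos], beta = res$beta, se = res$se,
                    pvalue = res$pvalue, status = res$status,
                    stringsAsFactors = FALSE)
  attr(out, "null_fit") <- null_fit
  out
}

#' Locations of the packaged lactation gene-set fixtures
#'
#' Paths to the transcribed gene coordinate tables of the three curated
#' lactation pathways (mammary development, prolactin signalling,
#' involution; UMD3.1 coordinates) and the GMT file tying them together.
#'
#' @return A named character vector of file paths.
#' @export
lactation_fixtures <- function() {
  f <- function(x) system.file("extdata", x, package = "lactpath",
                               mustWork = TRUE)
  c(mammary = f("mammary_development_genes.tsv"),
    prolactin = f("prolactin_signalling_genes.tsv"),
    involution = f("involution_genes.tsv"),
    gmt = f("lactation_pathways.gmt"))
}

#' Load the three packaged lactation pathways
#'
#' @return A list: `gene_table` (union of the three transcribed tables,
#'   deduplicated by symbol) and `pathways` (named list of `pathway`
#'   objects: mammary_development, prolactin_signalling, involution).
#' @export
load_lactation_pathways <- function() {
  fx <- lactation_fixtures()
  tabs <- lapply(fx[c("mammary", "prolactin", "involution")],
                 read_gene_table)
  union_tab <- do.call(rbind, tabs)
  union_tab <- union_tab[!duplicated(union_tab$symbol), , drop = FALSE]
  rownames(union_tab) <- NULL
  list(gene_table = validate_gene_table(union_tab),
       pathways = read_gmt(fx["gmt"]),
       tables = tabs)
}
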