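#' Within-breed standardisation of trait records
#'
#' Centers and scales trait values to mean 0, sample SD 1 separately
#' within each breed, so the two breeds are analysed on a common scale.
#'
#' @param values Numeric raw trait deviations.
#' @param breed Breed label per record (same length as `values`).
#' @return Numeric vector of standardised values.
#' @export
standardise_records <- function(values, breed) {
  stopifnot(length(values) == length(breed))
  out <- numeric(length(values))
  for (b in unique(breed)) {
    i <- which(breed == b)
    if (length(i) < 2L)
      stop("breed '", b, "' has fewer than 2 records; cannot standardise")
    s <- stats::sd(values[i])
    if (s == 0)
      stop("breed '", b, "' has zero within-breed variance")
    out[i] <- (values[i] - mean(values[i])) / s
  }
  out
}

#' Residual weight for a bull record
#'
#' A bull's phenotype is the average of his daughters' trait deviations;
#' its information content grows with the daughter count `n`.  The weight
#' is `w = (1 - h2) / (1 + (4 - h2) / n)`, increasing in `n` with limit
#' `1 - h2`.
#'
#' @param h2 Narrow-sense heritability in (0, 1).
#' @param n Number of daughters (>= 1); vectorised.
#' @return Weight(s) in (0, 1 - h2].
#' @export
bull_weight <- function(h2, n) {
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must be in (0, 1)")
  if (any(n < 1)) stop("daughter count n must be >= 1")
  (1 - h2) / (1 + (4 - h2) / n)
}

#' Residual weight for a cow record
#'
#' A cow's phenotype is the mean trait deviation over `l` lactations.
#' The weight is `w = (1 - h2) / (1 + r2 * (l - 1) / l)`, equal to
#' `1 - h2` at a single lactation and decreasing in `l` (repeated records
#' share the permanent-environment component, so extra lactations add
#' progressively less information relative to the residual scale).
#'
#' @param h2 Narrow-sense heritability in (0, 1).
#' @param r2 Repeatability in `[h2, 1]`.
#' @param l Number of lactations (>= 1); vectorised.
#' @return Weight(s) in (0, 1 - h2].
#' @export
cow_weight <- function(h2, r2, l) {
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must be in (0, 1)")
  if (any(r2 < 0 | r2 > 1)) stop("r2 must be in [0, 1]")
  if (any(l < 1)) stop("lactation count l must be >= 1")
  (1 - h2) / (1 + r2 * (l - 1) / l)
}

#' Compute residual weights for a phenotype table
#'
#' Applies [bull_weight()] to bull records and [cow_weight()] to cow
#' records.  For high-heritability percentage traits the bull weights can
#' be switched off (weight 1), matching analyses where weighted bull
#' records fail to converge.
#'
#' @param pheno Phenotype `data.frame` with columns `sex`
#'   (`"bull"`/`"cow"`), `n` (daughters for bulls, lactations for cows).
#' @param h2,r2 Trait heritability and repeatability.
#' @param weight_bulls If `FALSE`, bulls get weight 1 (percentage-trait
#'   convention).  Default `TRUE`.
#' @return Numeric weight vector aligned with `pheno` rows.
#' @export
record_weights <- function(pheno, h2, r2, weight_bulls = TRUE) {
  stopifnot(all(c("sex", "n") %in% names(pheno)),
            all(pheno$sex %in% c("bull", "cow")))
  w <- numeric(nrow(pheno))
  is_bull <- pheno$sex == "bull"
  w[is_bull] <- if (weight_bulls) bull_weight(h2, pheno$n[is_bull]) else 1
  w[!is_bull] <- cow_weight(h2, r2, pheno$n[!is_bull])
  w
}

#' Read a phenotype table
#'
#' CSV with header `animal,sex,breed,trait,value,n` (an optional `weight`
#' column overrides computed weights downstream).
#'
#' @param path Path to the CSV.
#' @return A `data.frame` with those columns; `value` and `n` numeric.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("animal", "sex", "breed", "trait", "value", "n")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  df$animal <- as.character(df$animal)
  df$value <- as.numeric(df$value)
  df$n <- as.numeric(df$n)
  if (any(!df$sex %in% c("bull", "cow")))
    stop("phenotype sex must be 'bull' or 'cow'")
  if (any(df$n < 1)) stop("record counts n must be >= 1")
  df
}

#' Fixed-effect design matrix for the association models
#'
#' Overall mean plus breed and sex contrasts, dropping factors with a
#' single level.
#'
#' @param pheno Phenotype `data.frame` with `breed` and `sex` columns.
#' @return A numeric design matrix with an intercept column.
#' @export
make_design <- function(pheno) {
  terms <- c()
  if (length(unique(pheno$breed)) > 1L) terms <- c(terms, "breed")
  if (length(unique(pheno$sex)) > 1L) terms <- c(terms, "sex")
  fml <- if (length(terms) == 0L) ~1 else
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(fml, data = pheno)
}

#' Cross-trait correlation of SNP effect estimates
#'
#' Pearson correlations between the per-SNP effect vectors of trait
#' pairs, over a given SNP set, as a pleiotropy summary.  SNPs with a
#' missing effect in either trait of a pair are dropped pairwise.
#'
#' @param results_by_trait Named list of association `data.frame`s (one
#'   per trait, from [snp_association()]).
#' @param snp_set Optional `snp_set` restricting the SNPs used (default:
#'   all shared SNPs).
#' @return A trait x trait correlation matrix with unit diagonal.
#' @export
effect_correlations <- function(results_by_trait, snp_set = NULL) {
  stopifnot(is.list(results_by_trait), length(results_by_trait) >= 1L)
  traits <- names(results_by_trait)
  if (is.null(traits)) stop("results_by_trait must be a named list")
  keep_ids <- Reduce(intersect, lapply(results_by_trait, `[[`, "snp_id"))
  if (!is.null(snp_set)) keep_ids <- intersect(keep_ids, snp_set$snp_ids)
  B <- vapply(results_by_trait, function(r)
    r$beta[match(keep_ids, r$snp_id)], numeric(length(keep_ids)))
  B <- matrix(B, nrow = length(keep_ids), dimnames = list(keep_ids, traits))
  if (sum(stats::complete.cases(B)) < 3L)
    stop("fewer than 3 SNPs with effects shared across all traits")
  C <- stats::cor(B, use = "pairwise.complete.obs")
  diag(C) <- 1
  C
}
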