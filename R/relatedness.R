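#' Read a pedigree file
#'
#' CSV with header `animal,sire,dam` (extra columns such as sex, breed or
#' generation are kept).  Unknown parents are coded `missing_code`.
#'
#' @param path Path to the CSV.
#' @param missing_code Code used for unknown parents (default `"0"`, the
#'   common livestock convention).
#' @return A `data.frame` with character `animal`, `sire`, `dam`; unknown
#'   parents are `NA`.
#' @export
read_pedigree <- function(path, missing_code = "0") {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE, colClasses = "character")
  names(df)[1:3] <- c("animal", "sire", "dam")
  for (f in c("sire", "dam"))
    df[[f]][df[[f]] %in% c(missing_code, "", "NA")] <- NA_character_
  validate_pedigree(df)
}

#' @keywords internal
validate_pedigree <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$animal))
    stop("duplicate animal id(s) in pedigree: ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  parents <- stats::na.omit(unique(c(ped$sire, ped$dam)))
  orphan <- setdiff(parents, ped$animal)
  if (length(orphan) > 0L)
    stop("parent(s) referenced without their own pedigree row: ",
         paste(orphan, collapse = ", "))
  ped
}

# Kahn topological sort; errors naming a member of any cycle.
#' @keywords internal
pedigree_order <- function(ped) {
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    cyc <- setdiff(seq_len(n), ord)
    stop("pedigree contains a cycle involving animal '", id[cyc[1L]], "'")
  }
  ord
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' Builds the expected additive (numerator) relationship matrix A by the
#' recursive tabular method: processing animals parents-first,
#' `A[i,i] = 1 + 0.5 A[sire, dam]` and
#' `A[i,j] = 0.5 (A[j, sire] + A[j, dam])`, with unknown parents
#' contributing zero.  A equals twice the kinship matrix; diagonal
#' elements are `1 + F` with F the inbreeding coefficient.
#'
#' @param ped Pedigree `data.frame` (`animal`, `sire`, `dam`; `NA` for
#'   unknown parents), e.g. from [read_pedigree()].
#' @return A dense symmetric matrix with dimnames set to animal ids, in
#'   the input row order.
#' @export
build_a_matrix <- function(ped) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  ord <- pedigree_order(ped)
  A <- matrix(0, n, n, dimnames = list(id, id))
  done <- integer(0)
  for (i in ord) {
    s <- si[i]; d <- di[i]
    if (length(done) > 0L) {
      row_s <- if (is.na(s)) 0 else A[done, s]
      row_d <- if (is.na(d)) 0 else A[done, d]
      v <- 0.5 * (row_s + row_d)
      A[done, i] <- v
      A[i, done] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    done <- c(done, i)
  }
  A
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = Z Z' / (2 * sum(p_j (1 - p_j)))` with `Z` the dosage matrix
#' centered by twice the allele frequency.  Monomorphic SNPs carry no
#' information and are dropped (with a message giving the count).
#'
#' @param genotypes Numeric animals x SNPs matrix of dosages in `[0, 2]`
#'   (column names are SNP ids, row names animal ids).
#' @param snp_ids Optional subset of SNP columns to use (default: all).
#' @param freqs `"estimate"` (default) to estimate allele frequencies as
#'   column means / 2 from the supplied genotypes, or a numeric vector of
#'   base-population frequencies aligned with the used SNPs.
#' @return A list of class `grm` with elements `G` (dense symmetric
#'   matrix), `animal_ids`, `snp_ids` (polymorphic SNPs used), `freqs`
#'   and `n_dropped` (monomorphic count).
#' @export
build_grm <- function(genotypes, snp_ids = NULL, freqs = "estimate") {
  stopifnot(is.matrix(genotypes))
  if (!is.null(snp_ids)) {
    miss <- setdiff(snp_ids, colnames(genotypes))
    if (length(miss) > 0L)
      stop("SNP id(s) absent from genotype matrix: ",
           paste(utils::head(miss, 5L), collapse = ", "),
           if (length(miss) > 5L) ", ..." else "")
    genotypes <- genotypes[, snp_ids, drop = FALSE]
  }
  if (identical(freqs, "estimate")) {
    p <- colMeans(genotypes) / 2
  } else {
    p <- as.numeric(freqs)
    if (length(p) != ncol(genotypes))
      stop("length of 'freqs' (", length(p), ") does not match SNP count (",
           ncol(genotypes), ")")
  }
  poly <- p > 0 & p < 1 & apply(genotypes, 2L, function(x) stats::var(x) > 0)
  n_dropped <- sum(!poly)
  if (!any(poly)) stop("all SNPs are monomorphic; cannot build a GRM")
  if (n_dropped > 0L)
    message("build_grm: dropped ", n_dropped, " monomorphic SNP(s)")
  Z <- sweep(genotypes[, poly, drop = FALSE], 2L, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  structure(list(G = G,
                 animal_ids = rownames(genotypes),
                 snp_ids = colnames(genotypes)[poly],
                 freqs = p[poly],
                 n_dropped = n_dropped),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm>", nrow(x$G), "animals,", length(x$snp_ids), "SNPs (",
      x$n_dropped, "monomorphic dropped )\n")
  invisible(x)
}

#' Augment a SNP set with random genome-wide SNPs
#'
#' Adds `n_random` distinct SNPs sampled uniformly without replacement
#' from the whole map, excluding SNPs already in the set.  Clustered
#' pathway SNPs can make a GRM singular (near-identical genomic
#' relationships); padding with random genome-wide SNPs restores
#' invertibility while leaving the pathway contribution assessable as a
#' marginal effect.
#'
#' @param pathway_snps A `snp_set`.
#' @param snp_map Full SNP map.
#' @param n_random Number of random SNPs to add (default 4000).
#' @param seed Integer seed making the draw reproducible.
#' @return A `snp_set` of size `n_snps + n_random`.
#' @export
augment_snp_set <- function(pathway_snps, snp_map, n_random = 4000, seed) {
  stopifnot(inherits(pathway_snps, "snp_set"), n_random >= 0)
  if (n_random == 0L) return(pathway_snps)
  pool <- setdiff(snp_map$snp_id, pathway_snps$snp_ids)
  if (length(pool) < n_random)
    stop("only ", length(pool), " non-pathway SNPs available; cannot sample ",
         n_random)
  extra <- with_seed(seed, sample(pool, n_random))
  new_snp_set(pathway_snps$pathway_name,
              c(pathway_snps$snp_ids, extra))
}

# Evaluate expr with a local RNG state seeded by `seed`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
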