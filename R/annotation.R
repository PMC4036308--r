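#' Read a gene coordinate table
#'
#' Parses a tab-separated gene table with columns `symbol`, `chrom`,
#' `start`, `stop` (1-based, inclusive, NCBI-style coordinates).  Summary
#' rows whose gene field is of the form `"N = 64"` are skipped, mirroring
#' the layout of printed pathway tables.
#'
#' @param path Path to a TSV file with a header line.  Extra columns are
#'   carried along untouched.
#' @return A `data.frame` with character `symbol`, character `chrom` and
#'   integer `start`/`stop` columns, one row per gene.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  if (file.size(path) == 0) stop("gene table has no gene rows: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (nrow(dt) == 0L) stop("gene table has no gene rows: ", path)
  cols <- tolower(names(dt))
  need <- c("symbol", "chrom", "start", "stop")
  alias <- list(symbol = c("symbol", "gene"), chrom = c("chrom", "chr"),
                start = "start", stop = c("stop", "end"))
  idx <- vapply(need, function(f) {
    hit <- which(cols %in% alias[[f]])
    if (length(hit) == 0L) stop("gene table lacks a '", f, "' column: ", path)
    hit[1L]
  }, integer(1))
  df <- data.frame(symbol = dt[[idx["symbol"]]], chrom = dt[[idx["chrom"]]],
                   start = dt[[idx["start"]]], stop = dt[[idx["stop"]]],
                   stringsAsFactors = FALSE)
  summary_row <- grepl("^\\s*N\\s*=", df$symbol)
  df <- df[!summary_row, , drop = FALSE]
  if (nrow(df) == 0L) stop("gene table has no gene rows: ", path)
  for (f in c("start", "stop")) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      stop("malformed ", f, " coordinate in gene table line ",
           bad[1L] + 1L, " (symbol '", df$symbol[bad[1L]], "')")
    df[[f]] <- as.integer(round(v))
  }
  validate_gene_table(df)
}

#' @keywords internal
validate_gene_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("symbol", "chrom", "start", "stop") %in% names(df)))
  dup <- unique(df$symbol[duplicated(df$symbol)])
  if (length(dup) > 0L)
    stop("duplicate gene symbol(s) in gene table: ",
         paste(dup, collapse = ", "))
  if (any(!nzchar(df$chrom))) stop("empty chromosome label in gene table")
  bad <- which(df$start > df$stop)
  if (length(bad) > 0L)
    stop("start > stop for gene(s): ",
         paste(df$symbol[bad], collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Read a SNP map
#'
#' Reads a bim-like tab-separated map: chromosome, SNP id, position.
#' A PLINK-style genetic-distance column (chrom, id, cM, pos) is detected
#' and ignored.  SNPs are sorted by chromosome and position.
#'
#' @param path Path to a headerless or headered TSV.
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos`.
#' @export
read_snp_map <- function(path) {
  if (!file.exists(path)) stop("SNP map not found: ", path)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 3L) stop("SNP map needs at least 3 columns (chrom, snp_id, pos)")
  pos_col <- if (ncol(dt) >= 4L) 4L else 3L  # bim: chrom id cM pos
  df <- data.frame(snp_id = dt[[2L]], chrom = dt[[1L]],
                   pos = suppressWarnings(as.numeric(dt[[pos_col]])),
                   stringsAsFactors = FALSE)
  if (anyNA(df$pos)) stop("non-numeric SNP position in map: ", path)
  validate_snp_map(df)
}

#' @keywords internal
validate_snp_map <- function(df) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(df)))
  if (anyDuplicated(df$snp_id)) stop("duplicate SNP ids in map")
  if (any(df$pos < 0)) stop("negative SNP position in map")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read pathways from a GMT-like file
#'
#' One line per pathway: name, description (may be empty), then gene
#' symbols, all tab-separated.
#'
#' @param path Path to the GMT file.
#' @return A named list of `pathway` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("pathway file is empty: ", path)
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line (need name, description, genes): ", ln)
    new_pathway(f[1L], f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(out) <- vapply(out, function(p) p$name, character(1))
  out
}

#' Construct a pathway object
#'
#' @param name Pathway name.
#' @param genes Character vector of member gene symbols (no duplicates).
#' @return An object of class `pathway`.
#' @export
new_pathway <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("pathway '", name, "' has no genes")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L)
    stop("duplicate gene symbol(s) in pathway '", name, "': ",
         paste(dup, collapse = ", "))
  structure(list(name = as.character(name), genes = genes),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway>", x$name, "-", length(x$genes), "genes\n")
  invisible(x)
}

#' @keywords internal
new_snp_set <- function(pathway_name, snp_ids) {
  snp_ids <- unique(as.character(snp_ids))
  structure(list(pathway_name = as.character(pathway_name),
                 snp_ids = snp_ids, n_snps = length(snp_ids)),
            class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat("<snp_set>", x$pathway_name, "-", x$n_snps, "SNPs\n")
  invisible(x)
}

#' SNPs inside a windowed gene interval
#'
#' Returns the SNPs lying on the gene's chromosome with position in
#' `[max(1, start - window_bp), stop + window_bp]`, both ends inclusive.
#'
#' @param gene One row of a gene table (list or single-row data.frame with
#'   `symbol`, `chrom`, `start`, `stop`).
#' @param snp_map SNP map data.frame (`snp_id`, `chrom`, `pos`).
#' @param window_bp Flanking window in base pairs (>= 0); default 100 kb,
#'   the conventional window capturing moderate-to-high LD around a gene.
#' @return A `snp_set` named after the gene.
#' @export
snps_in_window <- function(gene, snp_map, window_bp = 1e5) {
  if (is.data.frame(gene)) gene <- as.list(gene[1L, ])
  stopifnot(window_bp >= 0)
  lo <- max(1, gene$start - window_bp)
  hi <- gene$stop + window_bp
  on_chr <- snp_map$chrom == gene$chrom
  if (!any(on_chr)) {
    warning("chromosome '", gene$chrom, "' absent from SNP map (gene ",
            gene$symbol, ")")
    return(new_snp_set(gene$symbol, character(0)))
  }
  keep <- on_chr & snp_map$pos >= lo & snp_map$pos <= hi
  new_snp_set(gene$symbol, snp_map$snp_id[keep])
}

#' Windowed SNP set of a pathway
#'
#' Union of the member genes' windowed SNP sets; a SNP falling in several
#' overlapping gene windows (e.g. STAT5A/STAT5B) is counted once.
#'
#' @param pathway A `pathway` object.
#' @param gene_table Gene coordinate table resolving the pathway symbols.
#' @inheritParams snps_in_window
#' @return A `snp_set` named after the pathway.
#' @export
pathway_snp_set <- function(pathway, gene_table, snp_map, window_bp = 1e5) {
  stopifnot(inherits(pathway, "pathway"))
  missing <- setdiff(pathway$genes, gene_table$symbol)
  if (length(missing) > 0L)
    stop("pathway '", pathway$name, "' has gene(s) absent from the gene table: ",
         paste(missing, collapse = ", "))
  rows <- match(pathway$genes, gene_table$symbol)
  ids <- lapply(rows, function(i)
    snps_in_window(gene_table[i, ], snp_map, window_bp)$snp_ids)
  new_snp_set(pathway$name, unlist(ids, use.names = FALSE))
}

#' Pairwise same-chromosome gene distances
#'
#' For every unordered pair of distinct genes on the same chromosome,
#' reports the gap between their intervals in base pairs (0 for
#' overlapping genes).  Used as a clustering diagnostic when comparing a
#' curated pathway with random control gene sets.
#'
#' @param genes Gene coordinate table.
#' @return A `data.frame` with columns `chrom`, `gene1`, `gene2`,
#'   `distance`; zero rows if no pair shares a chromosome.
#' @export
gene_pair_distances <- function(genes) {
  stopifnot(nrow(genes) >= 1L)
  out <- list()
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    n <- nrow(g)
    if (n < 2L) next
    pr <- utils::combn(n, 2L)
    gap <- pmax(0, pmax(g$start[pr[1L, ]], g$start[pr[2L, ]]) -
                     pmin(g$stop[pr[1L, ]], g$stop[pr[2L, ]]) - 1L)
    out[[chr]] <- data.frame(chrom = chr,
                             gene1 = g$symbol[pr[1L, ]],
                             gene2 = g$symbol[pr[2L, ]],
                             distance = as.numeric(gap),
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), gene1 = character(0),
                      gene2 = character(0), distance = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Drop one chromosome from a gene table or SNP set
#'
#' Removes all entries on `chrom`; everything else is untouched.  Used for
#' sensitivity re-analyses excluding chromosomes that carry large known
#' QTL.
#'
#' @param items A gene table `data.frame` or a `snp_set`.
#' @param chrom Chromosome label to remove.
#' @param snp_map Required when `items` is a `snp_set` (SNP ids carry no
#'   chromosome themselves).
#' @return The same kind of object with the chromosome removed.
#' @export
exclude_chromosome <- function(items, chrom, snp_map = NULL) {
  if (is.data.frame(items)) {
    out <- items[items$chrom != chrom, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (inherits(items, "snp_set")) {
    if (is.null(snp_map))
      stop("snp_map is required to exclude a chromosome from a snp_set")
    drop_ids <- snp_map$snp_id[snp_map$chrom == chrom]
    return(new_snp_set(items$pathway_name,
                       setdiff(items$snp_ids, drop_ids)))
  }
  stop("exclude_chromosome: unsupported input of class ",
       paste(class(items), collapse = "/"))
}

#' Venn-style overlap of pathways
#'
#' Partitions the union of all member genes into intersection regions
#' (each gene assigned to the exact combination of pathways containing
#' it).
#'
#' @param pathways A list of two or more `pathway` objects.
#' @return A `data.frame` with one row per non-empty region: `region`
#'   (pathway names joined by `&`), `n_genes`, and `genes`
#'   (comma-separated).  Region counts sum to the size of the union.
#' @export
pathway_overlap <- function(pathways) {
  stopifnot(length(pathways) >= 2L)
  nm <- vapply(pathways, function(p) p$name, character(1))
  universe <- sort(unique(unlist(lapply(pathways, function(p) p$genes))))
  member <- vapply(pathways, function(p) universe %in% p$genes,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  region <- apply(member, 1L, function(m) paste(nm[m], collapse = "&"))
  sp <- split(universe, region)
  data.frame(region = names(sp),
             n_genes = lengths(sp),
             genes = vapply(sp, paste, character(1), collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Precompute the gene-to-SNP window index
#'
#' Maps every gene in a universe to the integer indices (into `snp_map`)
#' of the SNPs in its window.  Permutation tests draw thousands of random
#' gene sets; the index makes each draw an O(set size) union.
#'
#' @inheritParams pathway_snp_set
#' @return A named list (one element per gene symbol) of integer SNP
#'   indices, with `snp_map` row order as the indexing convention.
#' @export
build_gene_snp_index <- function(gene_table, snp_map, window_bp = 1e5) {
  by_chr <- split(seq_len(nrow(snp_map)), snp_map$chrom)
  idx <- vector("list", nrow(gene_table))
  names(idx) <- gene_table$symbol
  for (i in seq_len(nrow(gene_table))) {
    rows <- by_chr[[gene_table$chrom[i]]]
    if (is.null(rows)) { idx[[i]] <- integer(0); next }
    pos <- snp_map$pos[rows]
    lo <- max(1, gene_table$start[i] - window_bp)
    hi <- gene_table$stop[i] + window_bp
    idx[[i]] <- rows[pos >= lo & pos <= hi]
  }
  idx
}
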