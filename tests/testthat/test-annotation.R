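test_that("gene tables parse with exact coordinates and skip summary rows", {
  fx <- lactation_fixtures()
  mam <- read_gene_table(fx["mammary"])
  ghr <- mam[mam$symbol == "GHR", ]
  expect_equal(ghr$chrom, "20")
  expect_equal(ghr$start, 31790736L)
  expect_equal(ghr$stop, 32299996L)
  expect_equal(nrow(mam), 64L)
  expect_false(any(grepl("^N\\s*=", mam$symbol)))
})

test_that("gene table validation rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("symbol\tchrom\tstart\tstop", tmp)  # header only
  expect_error(read_gene_table(tmp), "no gene rows")
  writeLines(c("symbol\tchrom\tstart\tstop", "gX\t1\tabc\t200"), tmp)
  expect_error(read_gene_table(tmp), "malformed start coordinate")
  writeLines(c("symbol\tchrom\tstart\tstop", "gX\t1\t300\t200"), tmp)
  expect_error(read_gene_table(tmp), "start > stop.*gX")
  writeLines(c("symbol\tchrom\tstart\tstop",
               "gX\t1\t100\t200", "gX\t1\t150\t250"), tmp)
  expect_error(read_gene_table(tmp), "duplicate gene symbol")
  file.create(tmp2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_gene_table(tmp2))
})

test_that("gene windows are inclusive at both ends and truncate at 1", {
  genes <- tiny_gene_table()
  snps <- tiny_snp_map()
  ss <- snps_in_window(genes[1, ], snps, window_bp = 100000)
  expect_true("s1_900000" %in% ss$snp_ids)   # exactly start - window
  expect_false("s1_899999" %in% ss$snp_ids)  # one bp outside
  expect_true("s1_1150000" %in% ss$snp_ids)  # exactly stop + window
  # window 0 returns exactly in-gene SNPs
  ss0 <- snps_in_window(genes[1, ], snps, window_bp = 0)
  expect_setequal(ss0$snp_ids, c("s1_1000000"))
  # near-origin window truncates at position 1 without error
  g0 <- list(symbol = "g0", chrom = "2", start = 40L, stop = 60L)
  expect_equal(snps_in_window(g0, snps, window_bp = 1e6)$n_snps, 4L)
  # absent chromosome: warning, empty set
  gz <- list(symbol = "gz", chrom = "Z", start = 1L, stop = 10L)
  expect_warning(out <- snps_in_window(gz, snps), "absent")
  expect_equal(out$n_snps, 0L)
})

test_that("pathway SNP sets use union semantics and ignore gene order", {
  genes <- tiny_gene_table()
  snps <- tiny_snp_map()
  # gA and gB windows overlap on chromosome 1
  pw <- new_pathway("p", c("gA", "gB"))
  ss <- pathway_snp_set(pw, genes, snps, window_bp = 100000)
  nA <- snps_in_window(genes[1, ], snps, 100000)$n_snps
  nB <- snps_in_window(genes[2, ], snps, 100000)$n_snps
  expect_lt(ss$n_snps, nA + nB)               # shared SNPs counted once
  expect_equal(anyDuplicated(ss$snp_ids), 0L)
  pw_rev <- new_pathway("p", c("gB", "gA"))
  expect_setequal(ss$snp_ids,
                  pathway_snp_set(pw_rev, genes, snps, 100000)$snp_ids)
  # disjoint windows add up
  pw2 <- new_pathway("q", c("gA", "gC"))
  ss2 <- pathway_snp_set(pw2, genes, snps, 100000)
  nC <- snps_in_window(genes[3, ], snps, 100000)$n_snps
  expect_equal(ss2$n_snps, nA + nC)
  # single-gene pathway collapses to snps_in_window
  pw1 <- new_pathway("r", "gC")
  expect_setequal(pathway_snp_set(pw1, genes, snps, 100000)$snp_ids,
                  snps_in_window(genes[3, ], snps, 100000)$snp_ids)
  expect_error(pathway_snp_set(new_pathway("x", "nope"), genes, snps),
               "absent from the gene table: nope")
  expect_error(new_pathway("empty", character(0)), "no genes")
  expect_error(new_pathway("dup", c("gA", "gA")), "duplicate")
})

test_that("gene pair distances report same-chromosome gaps only", {
  genes <- data.frame(symbol = c("x", "y", "z"),
                      chrom = c("1", "1", "2"),
                      start = c(100L, 500L, 1L), stop = c(200L, 600L, 50L))
  d <- gene_pair_distances(genes)
  expect_equal(nrow(d), 1L)
  expect_equal(d$distance, 299)  # gap between [100,200] and [500,600]
  ov <- data.frame(symbol = c("x", "y"), chrom = "1",
                   start = c(100L, 150L), stop = c(200L, 300L))
  expect_equal(gene_pair_distances(ov)$distance, 0)
  cross <- data.frame(symbol = c("x", "y"), chrom = c("1", "2"),
                      start = c(1L, 1L), stop = c(10L, 10L))
  expect_equal(nrow(gene_pair_distances(cross)), 0L)
})

test_that("chromosome exclusion removes the documented QTL-region genes", {
  fx <- lactation_fixtures()
  mam <- read_gene_table(fx["mammary"])
  mam20 <- exclude_chromosome(mam, "20")
  expect_equal(nrow(mam20), 60L)
  expect_setequal(setdiff(mam$symbol, mam20$symbol),
                  c("FGF10", "MSX2", "PRLR", "GHR"))
  inv <- read_gene_table(fx["involution"])
  inv14 <- exclude_chromosome(inv, "14")
  expect_setequal(setdiff(inv$symbol, inv14$symbol),
                  c("CEBPD", "MYC", "PTK2"))
  # absent chromosome is a no-op
  expect_identical(exclude_chromosome(mam, "99"), mam)
})

test_that("excluding a chromosome commutes with building the SNP set", {
  genes <- tiny_gene_table()
  snps <- tiny_snp_map()
  pw <- new_pathway("p", genes$symbol)
  # filter genes first vs filter SNPs afterwards
  a <- pathway_snp_set(new_pathway("p", exclude_chromosome(genes, "1")$symbol),
                       genes, snps, 1000)
  b <- exclude_chromosome(pathway_snp_set(pw, genes, snps, 1000), "1",
                          snp_map = snps)
  expect_setequal(a$snp_ids, b$snp_ids)
})

test_that("pathway overlap partitions the union", {
  lp <- load_lactation_pathways()
  ov <- pathway_overlap(lp$pathways)
  triple <- ov$region[vapply(strsplit(ov$region, "&"), length, 1L) == 3L]
  expect_length(triple, 1L)
  expect_setequal(strsplit(ov$genes[ov$region == triple], ",")[[1]],
                  c("SOCS3", "STAT5A", "STAT5B"))
  union_size <- length(unique(unlist(lapply(lp$pathways, `[[`, "genes"))))
  expect_equal(sum(ov$n_genes), union_size)
  # disjoint and identical degenerate cases
  p1 <- new_pathway("a", c("x", "y")); p2 <- new_pathway("b", c("z"))
  ov2 <- pathway_overlap(list(p1, p2))
  expect_false(any(grepl("&", ov2$region)))
  ov3 <- pathway_overlap(list(p1, new_pathway("c", c("y", "x"))))
  expect_equal(ov3$region, "a&c")
  expect_equal(ov3$n_genes, 2L)
})

test_that("the gene-SNP index matches direct window queries", {
  genes <- tiny_gene_table()
  snps <- tiny_snp_map()
  idx <- build_gene_snp_index(genes, snps, 100000)
  for (i in seq_len(nrow(genes))) {
    expect_setequal(snps$snp_id[idx[[genes$symbol[i]]]],
                    snps_in_window(genes[i, ], snps, 100000)$snp_ids)
  }
})
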