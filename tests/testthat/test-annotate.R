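test_that("BED round-trips and rejects malformed input", {
  fx <- simulate_genome(n_genes = 20, n_peaks = 100, seed = 4)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(fx$peaks, path)
  back <- read_bed(path)
  expect_equal(back, fx$peaks)

  p2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2L\t100\t200\tp1\t0\t+", p2)
  one <- read_bed(p2)
  expect_equal(one$chrom, "chr2L")
  expect_equal(one$start, 100L)
  expect_equal(one$end, 200L)

  writeLines(c("chr2L\t100\t200\tp1\t0\t+", "chr2L\t300\t300\tp2\t0\t+"),
             p2)
  expect_error(read_bed(p2), "line 2")
  writeLines(c("chr2L\t100\t200\tp1", "chr2L\t300\t400\tp1"), p2)
  expect_error(read_bed(p2), "duplicate")
  writeLines("chr2L\tabc\t200\tp1", p2)
  expect_error(read_bed(p2), "non-integer")
})

test_that("read_bed agrees with an established BED importer", {
  skip_if_not_installed("rtracklayer")
  fx <- simulate_genome(n_genes = 10, n_peaks = 50, seed = 6)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(fx$peaks, path)
  ours <- read_bed(path)
  ref <- rtracklayer::import(path)
  expect_equal(ours$chrom, as.character(GenomicRanges::seqnames(ref)))
  # rtracklayer converts to 1-based closed; ours stays 0-based half-open
  expect_equal(ours$start, GenomicRanges::start(ref) - 1L)
  expect_equal(ours$end, GenomicRanges::end(ref))
  expect_equal(ours$name, ref$name)
})

test_that("gene tables round-trip and enforce the TSS/strand invariant", {
  fx <- simulate_genome(n_genes = 15, n_peaks = 0, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(fx$genes, path)
  expect_equal(read_gene_table(path), fx$genes)
  bad <- fx$genes
  bad$tss[1] <- bad$tss[1] + 1
  write_gene_table(bad, path)
  expect_error(read_gene_table(path), "TSS inconsistent")
})

test_that("tss_distance signs distances in gene orientation", {
  gene_plus <- data.frame(chrom = "c", strand = "+", tss = 1000)
  gene_minus <- data.frame(chrom = "c", strand = "-", tss = 1000)
  peak <- data.frame(chrom = "c", start = 850, end = 950)  # mid 900
  expect_equal(tss_distance(peak, gene_plus), -100)
  expect_equal(tss_distance(peak, gene_minus), 100)
  peak2 <- data.frame(chrom = "c", start = 1050, end = 1150) # mid 1100
  expect_equal(tss_distance(peak2, gene_plus), 100)
  expect_equal(tss_distance(peak2, gene_minus), -100)
  expect_error(tss_distance(data.frame(chrom = "d", start = 1, end = 9),
                            gene_plus), "cross-chromosome")
  # random pairs against the case-by-case oracle
  set.seed(3)
  for (i in 1:100) {
    st <- sample.int(10000, 1); en <- st + sample.int(500, 1)
    g <- data.frame(chrom = "c", strand = sample(c("+", "-"), 1),
                    tss = sample.int(10000, 1))
    mid <- (st + en) %/% 2
    want <- if (g$strand == "+") mid - g$tss else g$tss - mid
    expect_equal(tss_distance(data.frame(chrom = "c", start = st,
                                         end = en), g), want)
  }
})

test_that("annotate_peaks reproduces planted categories exactly", {
  fx <- simulate_genome(n_genes = 40, n_peaks = 1000,
                        mix = c(0.5, 0.15, 0.1, 0.1, 0.15), seed = 7)
  ann <- annotate_peaks(fx$peaks, fx$genes)
  expect_equal(ann$category, fx$truth$category)
  expect_equal(ann$gene, fx$truth$gene)
  expect_equal(ann$distance, fx$truth$distance)
  # categories partition the peaks
  expect_equal(nrow(ann), nrow(fx$peaks))
  expect_equal(sum(table(ann$category)), nrow(fx$peaks))
})

test_that("annotate_peaks handles TSS-coincident peaks and errors", {
  genes <- data.frame(gene_id = "g1", chrom = "c", strand = "+",
                      tss = 5000, start = 5000, end = 8000)
  atss <- data.frame(chrom = "c", start = 4900, end = 5100, name = "p")
  a <- annotate_peaks(atss, genes)
  expect_equal(a$distance, 0)
  expect_equal(a$category, "Promoter (<=1kb)")
  # 1500 upstream of the only TSS, outside the body
  up <- data.frame(chrom = "c", start = 3400, end = 3600, name = "p")
  a2 <- annotate_peaks(up, genes)
  expect_equal(a2$distance, -1500)
  expect_equal(a2$category, "Promoter (1-2kb)")
  expect_error(annotate_peaks(data.frame(chrom = "zz", start = 1, end = 9,
                                         name = "p"), genes),
               "no genes on chromosome")
})

test_that("annotation agrees with exhaustive search on random genomes", {
  set.seed(42)
  for (rep in 1:5) {
    genes <- random_gene_table(12, c(cA = 100000, cB = 80000))
    st <- sample.int(99000, 60, replace = TRUE)
    peaks <- data.frame(chrom = sample(c("cA", "cB"), 60, replace = TRUE),
                        start = st, end = st + 400,
                        name = sprintf("p%02d", 1:60),
                        stringsAsFactors = FALSE)
    peaks$start <- pmin(peaks$start, ifelse(peaks$chrom == "cA", 99000,
                                            79000))
    peaks$end <- peaks$start + 400
    ann <- annotate_peaks(peaks, genes)
    for (i in seq_len(nrow(peaks))) {
      want <- oracle_annotate_one(peaks$chrom[i], peaks$start[i],
                                  peaks$end[i], genes)
      expect_equal(ann$gene[i], want$gene)
      expect_equal(ann$distance[i], want$distance)
      expect_equal(ann$category[i], want$category)
    }
  }
})

test_that("annotation is invariant under chromosome renaming", {
  fx <- simulate_genome(n_genes = 20, n_peaks = 200, seed = 11)
  a1 <- annotate_peaks(fx$peaks, fx$genes)
  ren <- c(chr2L = "K9", chr2R = "K12")
  p2 <- fx$peaks; p2$chrom <- unname(ren[p2$chrom])
  g2 <- fx$genes; g2$chrom <- unname(ren[g2$chrom])
  a2 <- annotate_peaks(p2, g2)
  expect_equal(a2$category, a1$category)
  expect_equal(a2$gene, a1$gene)
})

test_that("overlap_counts is exact set algebra", {
  expect_equal(overlap_counts(c("g1", "g2", "g3"), c("g2", "g3", "g4")),
               c(both = 2L, only_a = 1L, only_b = 1L))
  a <- c("x", "y")
  expect_equal(overlap_counts(a, a), c(both = 2L, only_a = 0L,
                                       only_b = 0L))
  set.seed(14)
  for (i in 1:30) {
    u <- sprintf("g%02d", 1:40)
    a <- sample(u, sample.int(40, 1))
    b <- sample(u, sample.int(40, 1))
    got <- overlap_counts(a, b)
    expect_equal(got, oracle_overlap(a, b))
    # inclusion-exclusion
    expect_equal(sum(got), length(union(a, b)))
  }
})

test_that("tss_matrix bins strand-oriented signal around the TSS", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "c",
                      strand = c("+", "-"), tss = c(10000, 20999),
                      start = c(10000, 16000), end = c(15000, 21000))
  sizes <- c(c = 50000)
  # uniform signal 1.0 everywhere -> all entries 1
  blanket <- data.frame(chrom = "c", start = 0, end = 50000, name = "all",
                        score = 1)
  m <- tss_matrix(blanket, genes, sizes, flank = 1000, bin = 50)
  expect_true(all(m == 1))
  expect_equal(dim(m), c(2L, 40L))
  # zero peaks -> all-zero matrix
  m0 <- tss_matrix(blanket[0, ], genes, sizes, flank = 1000, bin = 50)
  expect_true(all(m0 == 0))
  # a minus-strand gene sees the mirrored profile of a plus-strand gene
  # with the mirrored peak placement
  pk_plus <- data.frame(chrom = "c", start = 10100, end = 10300,
                        name = "a", score = 2)   # downstream of gp TSS
  pk_minus <- data.frame(chrom = "c", start = 20699, end = 20899,
                         name = "b", score = 2)  # downstream of gm TSS
  mp <- tss_matrix(pk_plus, genes, sizes, flank = 1000, bin = 50)
  mm <- tss_matrix(pk_minus, genes, sizes, flank = 1000, bin = 50)
  expect_equal(unname(mm["gm", ]), unname(mp["gp", ]))
  # rows ordered by descending row sum
  both <- tss_matrix(rbind(pk_plus, pk_plus, pk_minus), genes, sizes,
                     flank = 1000, bin = 50)
  expect_equal(rownames(both)[1], "gp")
  # edge genes are flagged and zero-padded
  edge_gene <- data.frame(gene_id = "ge", chrom = "c", strand = "+",
                          tss = 300, start = 300, end = 4000)
  me <- tss_matrix(pk_plus, edge_gene, sizes, flank = 1000, bin = 50)
  expect_equal(attr(me, "edge_genes"), "ge")
  expect_error(tss_matrix(pk_plus, genes, sizes, flank = 1030, bin = 50),
               "flank")
})

test_that("chip_qpcr_enrichment computes IP/control ratios", {
  r <- chip_qpcr_enrichment(c("psq", "IR1"), ip = c(10, 2),
                            control = c(2, 2))
  expect_equal(r$ratio, c(5, 1))
  expect_equal(r$enriched, c(TRUE, FALSE))
  r0 <- chip_qpcr_enrichment(c("a", "b"), c(1, 1), c(1, 0))
  expect_equal(attr(r0, "excluded"), "b")
  expect_equal(nrow(r0), 1)
  expect_error(chip_qpcr_enrichment("a", -1, 1), "negative signal")
})
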