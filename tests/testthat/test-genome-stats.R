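test_that("gc_content handles the textbook cases and excludes N", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGTN"), 50)
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("NNN"), "no A/C/G/T")
})

test_that("gc_content equals a base-by-base counting oracle", {
  set.seed(41)
  seq <- paste(sample(c("A", "C", "G", "T", "N"), 10000, replace = TRUE,
                      prob = c(0.24, 0.25, 0.26, 0.24, 0.01)),
               collapse = "")
  chars <- strsplit(seq, "")[[1L]]
  oracle <- 100 * sum(chars %in% c("G", "C")) /
    sum(chars %in% c("A", "C", "G", "T"))
  expect_equal(gc_content(seq), oracle)
})

test_that("occupancy merges overlaps and conserves total length", {
  set.seed(43)
  total <- 50000L
  n <- 200L
  starts <- sample.int(total - 400L, n)
  ends <- pmin(starts + sample.int(400L, n, replace = TRUE), total)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:n), start = starts,
                      end = ends,
                      strand = sample(c("+", "-"), n, replace = TRUE))
  ann <- genome_annotation("c1", total, genes)
  seq <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
               collapse = "")
  st <- occupancy(ann, seq)
  expect_equal(st$gene_length, mask_union_length(starts, ends, total))
  expect_equal(st$gene_length + st$intergenic_length, st$total_bases)
  expect_equal(st$gene_fraction_percent + st$intergenic_fraction_percent,
               100)
})

test_that("published-scale occupancy reproduces the printed gene fraction", {
  total <- 4119979L
  gene_len <- 3673824L
  seq <- strrep("ACGT", ceiling(total / 4))
  seq <- substr(seq, 1L, total)
  ann <- genome_annotation("chr", total, data.frame(
    gene_id = "all_genes", start = 1L, end = gene_len, strand = "+"))
  st <- occupancy(ann, seq)
  expect_equal(cogevo:::format_percent(st$gene_fraction_percent), "89.17")
  # conservation makes the intergenic complement exact
  expect_equal(st$intergenic_length, total - gene_len)
})

test_that("occupancy on an empty gene list gives a fully intergenic genome", {
  ann <- genome_annotation("c1", 1000L,
                           data.frame(gene_id = character(0),
                                      start = integer(0), end = integer(0),
                                      strand = character(0)))
  st <- occupancy(ann, strrep("ACGT", 250))
  expect_equal(st$gene_length, 0L)
  expect_equal(st$intergenic_length, 1000L)
  expect_equal(st$intergenic_fraction_percent, 100)
})

test_that("merging already-disjoint intervals changes nothing", {
  genes <- data.frame(gene_id = c("a", "b"), start = c(10L, 100L),
                      end = c(50L, 150L), strand = c("+", "-"))
  ann <- genome_annotation("c1", 200L, genes)
  st <- occupancy(ann, strrep("ACGT", 50))
  expect_equal(st$gene_length, 41L + 51L)
})

test_that("annotation validation rejects out-of-bounds and duplicates", {
  expect_error(genome_annotation("c", 100L, data.frame(
    gene_id = "g", start = 50L, end = 150L, strand = "+")), "bounds")
  expect_error(genome_annotation("c", 100L, data.frame(
    gene_id = c("g", "g"), start = c(1L, 10L), end = c(5L, 20L),
    strand = c("+", "+"))), "unique")
})

test_that("simulated genomes meet the GC target and are reproducible", {
  g0 <- simulate_genome(1000L, 0L, gc_target = 0.5, seed = 1)
  expect_equal(nrow(g0$annotation$genes), 0L)
  st0 <- occupancy(g0$annotation, g0$sequence)
  expect_equal(st0$intergenic_length, 1000L)

  g <- simulate_genome(100000L, 60L, gc_target = 0.5469, seed = 2)
  expect_lt(abs(gc_content(g$sequence) / 100 - 0.5469), 0.01)

  p1 <- withr::local_tempfile(fileext = ".fasta")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(simulate_genome(5000L, 5L, seed = 9)$sequence, p1)
  write_genome_fasta(simulate_genome(5000L, 5L, seed = 9)$sequence, p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_error(simulate_genome(1000L, 10L), "infeasible")
})

test_that("gene tables round-trip through TSV and minimal GFF3", {
  g <- simulate_genome(20000L, 12L, seed = 5)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(g$annotation, tsv)
  back <- read_gene_table(tsv, 20000L)
  expect_equal(back$genes, g$annotation$genes)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("contig1\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$annotation$genes$start, g$annotation$genes$end,
                       g$annotation$genes$strand,
                       g$annotation$genes$gene_id)), gff)
  back2 <- read_gene_table(gff, 20000L)
  expect_equal(back2$genes$start, g$annotation$genes$start)
  expect_equal(back2$genes$end, g$annotation$genes$end)
})
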