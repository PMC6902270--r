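# Interval data model, file I/O, and the gap / nearest-TSS / context
# operations against brute-force oracles.

test_that("BED reading preserves coordinates and validates input", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpk1", "chr2\t0\t50", "chr1\t300\t400\tpk2\t7\t-"),
             path)
  x <- read_bed(path)
  expect_equal(x$chrom, c("chr1", "chr2", "chr1"))
  expect_equal(x$start, c(100, 0, 300))
  expect_equal(x$end, c(200, 50, 400))
  expect_equal(x$name, c("pk1", ".", "pk2"))
  expect_equal(x$strand, c(".", ".", "-"))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), bad)
  expect_error(read_bed(bad), "line 2")
  writeLines("chr1\tx\t200", bad)
  expect_error(read_bed(bad), "line 1")
})

test_that("BED round-trip is lossless for columns 1-6", {
  x <- genomic_intervals(c("chr1", "chr1", "chr2"), c(0, 150, 7),
                         c(100, 300, 9), name = c("a", "b", "c"),
                         score = c(1, 2.5, 0), strand = c("+", "-", "."))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$name, x$name)
  expect_equal(y$score, x$score)
  expect_equal(y$strand, x$strand)
  # byte-identical on rewrite
  path2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(y, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("bedGraph parsing builds validated signal tracks", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t10\t2.5", path)
  tr <- read_bedgraph(path)
  expect_equal(tr$chr1$value, 2.5)
  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"), path)
  expect_error(read_bedgraph(path), "overlap")
  writeLines("chr1\t0\t10\t-1", path)
  expect_error(read_bedgraph(path), "negative")
  writeLines(character(0), path)
  expect_length(read_bedgraph(path), 0)
})

test_that("annotation readers compute strand-aware TSSs", {
  path <- withr::local_tempfile(fileext = ".bed")
  bed12 <- function(chrom, s, e, id, strand) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d\t0",
            chrom, s, e, id, strand, s, e, e - s)
  }
  writeLines(c(bed12("chr1", 1000, 2000, "gMinus", "-"),
               bed12("chr1", 1000, 2000, "gPlus", "+")), path)
  ann <- read_annotation(path, "bed12")
  expect_equal(ann$genes$tss[ann$genes$gene_id == "gMinus"], 1999)
  expect_equal(ann$genes$tss[ann$genes$gene_id == "gPlus"], 1000)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
               "chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tParent=g1",
               "chr2\tsrc\tgene\t501\t900\t.\t-\t.\tID=g2"), gff)
  ann2 <- read_annotation(gff, "gff3")
  expect_equal(sort(ann2$genes$gene_id), c("g1", "g2"))
  # 1-based closed GFF3 converted to 0-based half-open
  expect_equal(ann2$genes$start[ann2$genes$gene_id == "g1"], 1000)
  expect_equal(ann2$genes$tss[ann2$genes$gene_id == "g2"], 899)
  expect_equal(nrow(ann2$exons), 1)
})

test_that("gap matches stated examples, symmetry, and the base-set oracle", {
  g <- function(s1, e1, s2, e2) {
    interval_gap(genomic_intervals("chr1", s1, e1),
                 genomic_intervals("chr1", s2, e2))
  }
  expect_equal(g(100, 200, 200, 300), 0)
  expect_equal(g(100, 200, 150, 300), -50)
  expect_equal(g(100, 200, 250, 300), 50)
  expect_true(is.na(interval_gap(genomic_intervals("chr1", 0, 10),
                                 genomic_intervals("chr2", 0, 10))))
  set.seed(11)
  for (r in 1:200) {
    ab <- rand_intervals(2, n_chrom = 2, max_pos = 400, max_len = 80)
    a <- ab[1, ]; b <- ab[2, ]
    expect_identical(interval_gap(a, b), interval_gap(b, a))
    expect_equal(interval_gap(a, b), oracle_gap(a, b))
  }
})

test_that("nearest_tss follows midpoint distance with deterministic ties", {
  ann <- gene_annotation(data.frame(
    gene_id = c("far", "near"), chrom = "chr1", start = c(700, 400),
    end = c(1200, 900), strand = "+"))
  hit <- nearest_tss(genomic_intervals("chr1", 450, 550), ann)
  expect_equal(hit$gene_id, "near")
  expect_equal(hit$distance, -100)
  # tie at equal |distance| goes to the smaller TSS coordinate
  ann2 <- gene_annotation(data.frame(
    gene_id = c("right", "left"), chrom = "chr1", start = c(600, 400),
    end = c(1100, 900), strand = "+"))
  expect_equal(nearest_tss(genomic_intervals("chr1", 450, 550), ann2)$gene_id,
               "left")
  expect_equal(nearest_tss(genomic_intervals("chr2", 0, 10), ann)$gene_id,
               NA_character_)
})

test_that("nearest_tss and classify_context agree with exhaustive oracles", {
  set.seed(21)
  for (r in 1:25) {
    n_genes <- sample(3:20, 1)
    gs <- sort(sample.int(50000, n_genes))
    ann <- gene_annotation(data.frame(
      gene_id = sprintf("g%02d", seq_len(n_genes)),
      chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
      start = gs, end = gs + sample(500:3000, n_genes, TRUE),
      strand = sample(c("+", "-"), n_genes, TRUE)))
    regions <- rand_intervals(40, n_chrom = 2, max_pos = 52000)
    for (i in seq_len(nrow(regions))) {
      got <- nearest_tss(regions[i, ], ann)
      want <- oracle_nearest(regions[i, ], ann)
      expect_identical(got$gene_id, want$gene_id)
      expect_equal(got$distance, want$distance)
      expect_identical(classify_context(regions[i, ], ann),
                       oracle_context(regions[i, ], ann))
    }
  }
})

test_that("context classes partition any region set", {
  ann <- toy_annotation()
  set.seed(5)
  regions <- rand_intervals(120, n_chrom = 2, max_pos = 12000)
  ctx <- vapply(seq_len(nrow(regions)), function(i) {
    classify_context(regions[i, ], ann)
  }, "")
  expect_true(all(ctx %in% c("promoter", "exonic", "intronic", "intergenic")))
  expect_equal(length(ctx), nrow(regions))
})

test_that("promoter precedence and strand orientation are honoured", {
  ann <- toy_annotation()  # gA + strand TSS 1000; gB - strand TSS 9499
  # midpoint 1 bp upstream of the + TSS
  expect_equal(classify_context(genomic_intervals("chr1", 998, 1000), ann),
               "promoter")
  # inside gA's first exon but also in gA's downstream promoter window
  expect_equal(classify_context(genomic_intervals("chr1", 1100, 1102), ann),
               "promoter")
  # exonic once past the promoter window
  expect_equal(classify_context(genomic_intervals("chr1", 2600, 2700), ann),
               "exonic")
  # upstream of the minus-strand TSS means larger coordinates
  expect_equal(classify_context(genomic_intervals("chr1", 9600, 9602), ann),
               "promoter")
  expect_equal(classify_context(genomic_intervals("chr1", 5000, 5002), ann),
               "intergenic")
})
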