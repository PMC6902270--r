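# Synthetic-data generators: determinism, planted structure, and
# round-trips through the file readers.

test_that("genome generation is seed-deterministic with the stated GC", {
  g1 <- generate_genome(9, n_chrom = 2, chrom_length = 1e5)
  g2 <- generate_genome(9, n_chrom = 2, chrom_length = 1e5)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$annotation$genes, g2$annotation$genes)
  expect_length(g1$genome, 2)
  # observed GC within 3 sd of the target (binomial)
  g3 <- generate_genome(10, n_chrom = 1, chrom_length = 2e5, gc = 0.5)
  gc_obs <- mean(strsplit(g3$genome[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 2e5))
  expect_error(generate_genome(1, chrom_length = 1e4), "50 kb")
})

test_that("gene models satisfy the annotation invariants", {
  g <- generate_genome(12, chrom_length = 1e5)
  genes <- g$annotation$genes
  expect_true(all(genes$tss == ifelse(genes$strand == "+", genes$start,
                                      genes$end - 1)))
  ex <- g$annotation$exons
  idx <- match(ex$gene_id, genes$gene_id)
  expect_true(all(ex$start >= genes$start[idx] & ex$end <= genes$end[idx]))
  # exons within a gene are disjoint
  by_gene <- split(ex, ex$gene_id)
  ok <- vapply(by_gene, function(d) {
    d <- d[order(d$start), ]
    nrow(d) < 2 || all(d$start[-1] >= d$end[-nrow(d)])
  }, logical(1))
  expect_true(all(ok))
})

test_that("noiseless planting is recovered exactly", {
  sim <- plant_enhancers(generate_genome(13, chrom_length = 2e5),
                         n_per_condition = 6, jitter_sd = 0, n_decoys = 2)
  for (cond in c("CNT", "FGF")) {
    enh <- call_enhancers(sim$peaks[[cond]]$ac, sim$peaks[[cond]]$me3,
                          condition = cond)
    r <- score_enhancer_recovery(enh, sim, cond)
    expect_equal(r$sensitivity, 1)
    expect_equal(r$fdr, 0)
    # with zero jitter the called valleys equal the truth spans
    truth <- sim$enhancers_truth
    truth <- truth[!truth$decoy & truth$condition %in% c(cond, "both"), ]
    expect_setequal(paste(enh$chrom, enh$start, enh$end),
                    paste(truth$chrom, truth$start, truth$end))
  }
  expect_error(plant_enhancers(generate_genome(13, chrom_length = 2e5),
                               jitter_sd = -1), "jitter_sd")
})

test_that("condition-specific planting lands in the right comparison set", {
  sim <- plant_enhancers(generate_genome(14, chrom_length = 3e5),
                         n_per_condition = 8, fraction_common = 0.25)
  ea <- call_enhancers(sim$peaks$CNT$ac, sim$peaks$CNT$me3, condition = "CNT")
  eb <- call_enhancers(sim$peaks$FGF$ac, sim$peaks$FGF$me3, condition = "FGF")
  cmp <- compare_conditions(ea, eb)
  truth <- sim$enhancers_truth[!sim$enhancers_truth$decoy, ]
  expect_equal(cmp$counts[["common"]], sum(truth$condition == "both"))
  expect_equal(cmp$counts[["unique_a"]], sum(truth$condition == "CNT"))
  expect_equal(cmp$counts[["unique_b"]], sum(truth$condition == "FGF"))
  # an FGF-only truth valley overlaps a unique_b call
  fgf <- truth[truth$condition == "FGF", ][1, ]
  expect_true(any(cmp$unique_b$chrom == fgf$chrom &
                    cmp$unique_b$start < fgf$end &
                    cmp$unique_b$end > fgf$start))
})

test_that("decoy valleys are removed by the repressive filter", {
  sim <- plant_enhancers(generate_genome(15, chrom_length = 2e5),
                         n_per_condition = 5, n_decoys = 4)
  truth <- sim$enhancers_truth
  for (cond in c("CNT", "FGF")) {
    cands <- call_valleys(sim$peaks[[cond]]$ac)
    kept <- filter_repressive(cands, sim$peaks[[cond]]$me3)
    decoys <- truth[truth$decoy & truth$condition == cond, ]
    expect_gt(nrow(cands), nrow(kept))
    for (i in seq_len(nrow(decoys))) {
      expect_false(any(kept$chrom == decoys$chrom[i] &
                         kept$start < decoys$end[i] &
                         kept$end > decoys$start[i]))
    }
  }
})

test_that("motif planting covers the stated fraction and only FGF valleys", {
  sim <- plant_enhancers(generate_genome(16, chrom_length = 3e5),
                         n_per_condition = 10, fraction_common = 0.2)
  full <- plant_motifs(sim, fraction_fgf = 1)
  truth <- full$enhancers_truth
  fgf <- truth[!truth$decoy & truth$condition == "FGF", ]
  ap1 <- ap1_fixture_pwm()
  thr <- suppressWarnings(score_threshold(ap1, 1e-4))
  hits_per <- vapply(seq_len(nrow(fgf)), function(i) {
    s <- interval_sequences(full$genome, fgf[i, c("chrom", "start", "end")])
    nrow(scan_pwm(s, ap1, thr))
  }, 0L)
  expect_true(all(hits_per >= 1))
  expect_true(all(truth$has_motif[!truth$decoy & truth$condition == "FGF"]))
  expect_false(any(truth$has_motif[truth$condition != "FGF"]))
  none <- plant_motifs(sim, fraction_fgf = 0)
  expect_equal(nrow(none$motif_sites), 0)
  # recorded sites carry the planted word on the recorded strand
  expect_true(all(interval_sequences(full$genome, full$motif_sites) ==
                    "TGACTCA"))
})

test_that("ortholog simulation honours divergence settings", {
  # divergence 0: all species identical, full support everywhere
  o0 <- make_orthologs(per_species_divergence = 0, element_divergence = 0,
                       seed = 22)
  expect_true(all(unlist(o0$orthologs$others) == o0$orthologs$reference$seq))
  b0 <- find_conserved_blocks(o0$orthologs)
  expect_equal(nrow(b0), 1)
  expect_equal(b0$n_species, 9)
  # determinism
  o1 <- make_orthologs(seed = 23)
  o2 <- make_orthologs(seed = 23)
  expect_identical(o1$orthologs$others, o2$orthologs$others)
  expect_identical(o1$truth, o2$truth)
})

test_that("count simulation is deterministic and near-noiseless limits are exact", {
  c1 <- simulate_counts(31)
  c2 <- simulate_counts(31)
  expect_identical(c1$counts$counts, c2$counts$counts)
  expect_identical(c1$truth, c2$truth)
  expect_equal(nrow(c1$counts$counts), 216)
  expect_equal(table(factor(c1$truth))[["direct_up"]], 5)
  # vanishing dispersion and no lane effects: calls equal the planted truth
  c3 <- simulate_counts(32, dispersion = 1e-6, lane_sd = 0)
  norm <- normalize_counts(c3$counts, background = FALSE)
  plain <- respond(norm, "FGF", "CNT", preset = "methods")
  chx <- respond(norm, "FGF_CHX", "CHX", preset = "methods")
  cls <- classify_direct(plain, chx)
  expect_equal(classification_accuracy(cls, c3$truth), 1)
  expect_error(simulate_counts(1, conditions = c("A", "B")), "4 conditions")
})

test_that("generated files parse cleanly back through the readers", {
  sim <- plant_enhancers(generate_genome(33, chrom_length = 1e5),
                         n_per_condition = 4, n_decoys = 0, coverage = TRUE)
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "ac.bed")
  write_bed(sim$peaks$CNT$ac, bed)
  back <- read_bed(bed)
  expect_equal(back$start, sim$peaks$CNT$ac$start)
  expect_equal(back$end, sim$peaks$CNT$ac$end)
  bg <- file.path(dir, "ac.bedGraph")
  write_bedgraph(sim$tracks$CNT$ac, bg)
  tr <- read_bedgraph(bg)
  expect_equal(tr$chr1$value, sim$tracks$CNT$ac$chr1$value)
  fa <- file.path(dir, "genome.fa")
  write_genome_fasta(sim$genome, fa)
  expect_identical(read_genome_fasta(fa), sim$genome)
  cs <- simulate_counts(34)
  tsv <- file.path(dir, "counts.tsv")
  write_count_table(cs$counts, tsv)
  back_ct <- read_count_table(tsv)
  expect_equal(back_ct$counts, cs$counts$counts)
  expect_identical(back_ct$condition, cs$counts$condition)
})
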