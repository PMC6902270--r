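# PWM construction, exact thresholds, scanning and shuffle-null
# enrichment.

test_that("PWM normalisation and score bounds are consistent", {
  p <- pwm(matrix(c(8, 0, 0, 0,  0, 4, 4, 0), 4, 2), name = "toy")
  expect_equal(colSums(p$probs), c(1, 1))
  expect_equal(p$max_score, sum(apply(p$log_odds, 2, max)))
  expect_lt(p$min_score, 0)
  expect_error(pwm(matrix(-1, 4, 2)), "non-negative")
})

test_that("JASPAR pfm files parse in both common layouts", {
  path <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TOY",
               "A [ 10  0 ]", "C [  0 10 ]", "G [  0  0 ]", "T [  0  0 ]",
               ">plain second",
               "1 2", "3 4", "5 6", "7 8"), path)
  ps <- read_jaspar(path)
  expect_length(ps, 2)
  expect_equal(ps[[1]]$width, 2)
  expect_equal(unname(ps[[2]]$counts[, 1]), c(1, 3, 5, 7))
})

test_that("score thresholds match exhaustive enumeration", {
  # width-1: p = 0.25 forces the single best base
  set.seed(81)
  p1 <- random_pwm(1)
  expect_equal(score_threshold(p1, 0.25), max(p1$log_odds), tolerance = 2e-3)
  # p = 1 returns the minimum attainable score
  expect_equal(score_threshold(p1, 1), p1$min_score)
  # width-3 against all 64 words, plus random widths
  for (r in 1:15) {
    w <- sample(2:6, 1)
    p <- random_pwm(w)
    pv <- stats::runif(1, 1e-4, 0.3)
    expect_equal(suppressWarnings(score_threshold(p, pv)),
                 enum_threshold(p, pv), tolerance = 1e-9)
  }
  wide <- pwm(matrix(stats::runif(4 * 26), 4, 26))
  expect_error(score_threshold(wide, 0.01), "wider than 25")
})

test_that("threshold semantics: tail probability at threshold is <= p", {
  set.seed(82)
  for (r in 1:10) {
    p <- random_pwm(4)
    pv <- stats::runif(1, 0.02, 0.2)  # above the minimum attainable tail
    thr <- score_threshold(p, pv)
    # evaluated on the same score grid the threshold lives on; the
    # returned value carries half a grid unit per column of slack
    q <- round(p$log_odds / 1e-3) * 1e-3
    words <- as.matrix(expand.grid(rep(list(1:4), 4)))
    scores <- apply(words, 1, function(v) sum(q[cbind(v, 1:4)]))
    probs <- apply(words, 1, function(v) prod(p$background[v]))
    expect_lte(sum(probs[scores >= thr + 4 * 5e-4 - 1e-9]), pv + 1e-12)
  }
})

test_that("scanning finds the consensus and respects strand symmetry", {
  ap1 <- ap1_fixture_pwm()
  hits <- scan_pwm("TGACTCA", ap1, threshold = 5)
  expect_true(any(hits$start == 0 & hits$strand == "+"))
  expect_equal(max(hits$score), ap1$max_score)
  # the AP1 core is near-palindromic: its reverse complement also scores
  rc_hits <- scan_pwm("TGAGTCA", ap1, threshold = 5)
  expect_true(nrow(rc_hits) >= 1)
  # N windows are skipped
  expect_equal(nrow(scan_pwm("TGANTCA", ap1, threshold = -100)), 0)
})

test_that("scanning matches the all-windows oracle and mirrors under revcomp", {
  set.seed(91)
  p <- random_pwm(5)
  seq <- random_dna(1000)
  thr <- score_threshold(p, 0.01)
  got <- scan_pwm(seq, p, thr)
  want <- oracle_scan(seq, p, thr)
  want <- want[order(want$start, want$strand), ]
  expect_equal(nrow(got), if (is.null(want)) 0 else nrow(want))
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$score, want$score, tolerance = 1e-9)
  # revcomp invariance up to coordinate/strand mirroring
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  got_rc <- scan_pwm(rc, p, thr)
  expect_equal(nrow(got_rc), nrow(got))
  expect_equal(sort(nchar(seq) - got_rc$end), sort(got$start))
  expect_equal(sort(got_rc$score), sort(got$score), tolerance = 1e-9)
})

test_that("shuffle enrichment obeys the add-one p-value rule", {
  ap1 <- ap1_fixture_pwm()
  # shuffle-invariant sequences make every null equal the observed: p = 1
  seqs <- c(strrep("A", 60), strrep("A", 80))
  r <- shuffle_enrichment(seqs, ap1, n_shuffles = 99, seed = 3)
  expect_equal(r$p_value, 1)
  expect_error(shuffle_enrichment(seqs, ap1, n_shuffles = 10, seed = 1),
               "at least 99")
  expect_error(shuffle_enrichment(c("ACG"), ap1, n_shuffles = 99, seed = 1),
               "shorter than the PWM")
})

test_that("planted motifs are detected against the shuffle null", {
  set.seed(101)
  ap1 <- ap1_fixture_pwm()
  seqs <- replicate(12, random_dna(200))
  for (i in 1:6) {  # plant once per sequence in half the set
    pos <- sample(1:(200 - 7), 1)
    substr(seqs[i], pos, pos + 6) <- "TGACTCA"
  }
  r <- shuffle_enrichment(seqs, ap1, n_shuffles = 100, seed = 4)
  expect_lte(r$p_value, 0.05)
  expect_gt(r$observed_stat, mean(r$null_stats))
})

test_that("differential enrichment flags planted asymmetry only", {
  set.seed(111)
  ap1 <- ap1_fixture_pwm()
  decoy <- pwm(matrix(c(0, 0, 20, 0,  0, 20, 0, 0,  20, 0, 0, 0,
                        0, 0, 0, 20,  0, 20, 0, 0,  0, 0, 20, 0,
                        20, 0, 0, 0), 4, 7), name = "decoy")
  set_a <- replicate(20, random_dna(300))
  set_b <- replicate(20, random_dna(300))
  for (i in 1:12) {
    pos <- sample(1:(300 - 7), 1)
    substr(set_a[i], pos, pos + 6) <- "TGACTCA"
  }
  tab <- differential_motif_enrichment(set_a, set_b, list(ap1, decoy),
                                       n_shuffles = 400, seed = 9)
  expect_true(tab$significant[tab$pwm == "AP1_fixture"])
  expect_false(tab$significant[tab$pwm == "decoy"])
  # e-value is Bonferroni over the tested PWMs
  expect_equal(tab$e_value, pmin(tab$p_value * 2, Inf))
  # single PWM: e-value equals p-value
  tab1 <- differential_motif_enrichment(set_a, set_b, list(ap1),
                                        n_shuffles = 200, seed = 9)
  expect_equal(tab1$e_value, tab1$p_value)
  # identical sets give a zero statistic
  tab0 <- differential_motif_enrichment(set_a, set_a, list(ap1),
                                        n_shuffles = 100, seed = 9)
  expect_equal(tab0$statistic, 0)
  expect_gt(tab0$p_value, 0.05)
})
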