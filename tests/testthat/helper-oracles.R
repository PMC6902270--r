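# Independent brute-force oracles used across the suite. These go
# through different code paths than the implementation (per-base set
# algebra, exhaustive loops, GenomicRanges/IRanges, igraph components)
# so agreement is evidence, not tautology.

rand_intervals <- function(n, n_chrom = 2, max_pos = 10000, min_len = 10,
                           max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(min_len:max_len, n, replace = TRUE)
  genomic_intervals(sample(sprintf("chr%d", seq_len(n_chrom)), n, TRUE),
                    start, start + len)
}

# gap via explicit base sets
oracle_gap <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(NA_real_)
  ba <- seq(a$start[1], a$end[1] - 1)
  bb <- seq(b$start[1], b$end[1] - 1)
  ov <- length(intersect(ba, bb))
  if (ov > 0) return(-ov)
  if (a$end[1] <= b$start[1]) b$start[1] - a$end[1] else a$start[1] - b$end[1]
}

# exhaustive nearest-TSS search with explicit tie-breaking loop
oracle_nearest <- function(region, annotation) {
  g <- annotation$genes
  mid <- floor((region$start[1] + region$end[1]) / 2)
  best <- NULL
  for (i in seq_len(nrow(g))) {
    if (g$chrom[i] != region$chrom[1]) next
    d <- g$tss[i] - mid
    better <- is.null(best) || abs(d) < abs(best$d) ||
      (abs(d) == abs(best$d) && g$tss[i] < best$tss) ||
      (abs(d) == abs(best$d) && g$tss[i] == best$tss &&
         g$gene_id[i] < best$id)
    if (better) best <- list(id = g$gene_id[i], d = d, tss = g$tss[i])
  }
  if (is.null(best)) list(gene_id = NA_character_, distance = NA_real_) else
    list(gene_id = best$id, distance = best$d)
}

# context by testing each category membership independently
oracle_context <- function(region, annotation, promoter_up = 2000,
                           promoter_down = 500) {
  g <- annotation$genes
  e <- annotation$exons
  mid <- floor((region$start[1] + region$end[1]) / 2)
  in_prom <- FALSE
  for (i in seq_len(nrow(g))) {
    if (g$chrom[i] != region$chrom[1]) next
    win <- if (g$strand[i] == "+") {
      c(g$tss[i] - promoter_up, g$tss[i] + promoter_down)
    } else {
      c(g$tss[i] + 1 - promoter_down, g$tss[i] + 1 + promoter_up)
    }
    if (mid >= win[1] && mid < win[2]) in_prom <- TRUE
  }
  in_exon <- any(e$chrom == region$chrom[1] & mid >= e$start & mid < e$end)
  in_gene <- any(g$chrom == region$chrom[1] & mid >= g$start & mid < g$end)
  if (in_prom) "promoter" else if (in_exon) "exonic" else
    if (in_gene) "intronic" else "intergenic"
}

# full enhancer call via GenomicRanges reduce + exhaustive pair loops
oracle_enhancer_call <- function(ac, me3, max_inner_gap = 3000) {
  gr <- GenomicRanges::GRanges(ac$chrom,
                               IRanges::IRanges(ac$start + 1, ac$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1)
  m <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                  start = GenomicRanges::start(merged) - 1,
                  end = GenomicRanges::end(merged))
  m <- m[order(m$chrom, m$start), ]
  valleys <- NULL
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (i == j || m$chrom[i] != m$chrom[j]) next
      if (m$end[i] >= m$start[j]) next
      gapw <- m$start[j] - m$end[i]
      if (gapw <= 0 || gapw > max_inner_gap) next
      # adjacency: no third merged peak in between
      between <- any(m$chrom == m$chrom[i] & m$start >= m$end[i] &
                       m$end <= m$start[j] &
                       seq_len(nrow(m)) != i & seq_len(nrow(m)) != j)
      if (between) next
      valleys <- rbind(valleys, data.frame(chrom = m$chrom[i],
                                           start = m$end[i],
                                           end = m$start[j]))
    }
  }
  if (is.null(valleys)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  # repressive filter: >= 1 bp base overlap via IRanges
  if (nrow(me3)) {
    vgr <- GenomicRanges::GRanges(valleys$chrom,
                                  IRanges::IRanges(valleys$start + 1,
                                                   valleys$end))
    mgr <- GenomicRanges::GRanges(me3$chrom,
                                  IRanges::IRanges(me3$start + 1, me3$end))
    valleys <- valleys[!suppressWarnings(IRanges::overlapsAny(vgr, mgr)), ,
                       drop = FALSE]
  }
  rownames(valleys) <- NULL
  valleys[order(valleys$chrom, valleys$start), , drop = FALSE]
}

# per-base profile extraction
oracle_extract <- function(track, anchors, window, bin_size) {
  nbins <- 2 * window / bin_size
  out <- matrix(0, nrow(anchors), nbins)
  for (i in seq_len(nrow(anchors))) {
    runs <- track[[anchors$chrom[i]]]
    lo <- anchors$start[i] - window
    for (b in seq_len(nbins)) {
      vals <- numeric(bin_size)
      for (k in seq_len(bin_size)) {
        pos <- lo + (b - 1) * bin_size + k - 1
        v <- 0
        if (pos >= 0 && !is.null(runs)) {
          hit <- which(runs$start <= pos & runs$end > pos)
          if (length(hit)) v <- runs$value[hit[1]]
        }
        vals[k] <- v
      }
      out[i, b] <- mean(vals)
    }
    if (anchors$strand[i] == "-") out[i, ] <- rev(out[i, ])
  }
  out
}

# exhaustive word enumeration for PWM score thresholds, on the same
# 1e-3-bit grid the DP uses, so agreement is exact
enum_threshold <- function(pwm, p, scale = 1e-3) {
  w <- pwm$width
  q <- round(pwm$log_odds / scale) * scale
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- apply(words, 1, function(v) sum(q[cbind(v, seq_len(w))]))
  probs <- apply(words, 1, function(v) prod(pwm$background[v]))
  cand <- sort(unique(scores))
  tails <- vapply(cand, function(s) sum(probs[scores >= s - scale / 2]), 0)
  ok <- which(tails <= p)
  margin <- w * scale / 2
  if (!length(ok)) return(max(cand) - margin)  # strictest-threshold fallback
  cand[min(ok)] - margin
}

random_pwm <- function(width, name = "rand") {
  pwm(matrix(stats::runif(4 * width, 0, 20), 4, width), name = name)
}

# naive all-windows scan using Biostrings reverse complement
oracle_scan <- function(seq, p, threshold) {
  w <- p$width
  n <- nchar(seq) - w + 1
  hits <- NULL
  score_word <- function(word) {
    v <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
    if (anyNA(v)) return(NA_real_)
    sum(p$log_odds[cbind(v, seq_len(w))])
  }
  for (i in seq_len(max(n, 0))) {
    word <- substr(seq, i, i + w - 1)
    sf <- score_word(word)
    sr <- score_word(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(word))))
    if (!is.na(sf) && sf >= threshold) {
      hits <- rbind(hits, data.frame(start = i - 1, strand = "+", score = sf))
    }
    if (!is.na(sr) && sr >= threshold) {
      hits <- rbind(hits, data.frame(start = i - 1, strand = "-", score = sr))
    }
  }
  hits
}

# connected-component condition comparison via igraph on exhaustive
# pairwise gap tests
oracle_compare <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  edges <- NULL
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (a$chrom[i] != b$chrom[j]) next
      if (max(a$start[i], b$start[j]) - min(a$end[i], b$end[j]) <= 0) {
        edges <- rbind(edges, c(i, na + j))
      }
    }
  }
  if (is.null(edges)) {
    return(list(unique_a = na, unique_b = nb, common = 0,
                common_a = 0, common_b = 0))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, na + nb - igraph::vcount(g)))
  comp <- igraph::components(g)
  linked <- unique(as.vector(edges))
  comp_ids <- unique(comp$membership[linked])
  in_comp_a <- sum(seq_len(na) %in% linked)
  in_comp_b <- sum((na + seq_len(nb)) %in% linked)
  list(unique_a = na - in_comp_a, unique_b = nb - in_comp_b,
       common = length(comp_ids), common_a = in_comp_a,
       common_b = in_comp_b)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small deterministic annotation used by several files
toy_annotation <- function() {
  gene_annotation(
    data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
               start = c(1000, 8000), end = c(3000, 9500),
               strand = c("+", "-")),
    data.frame(gene_id = c("gA", "gA", "gB"), chrom = "chr1",
               start = c(1000, 2500, 8000), end = c(1400, 3000, 8400))
  )
}
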