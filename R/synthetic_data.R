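# Synthetic-data generators with recorded ground truth: a random genome
# with genes, planted bimodal-acetylation enhancer structures per
# condition, motif insertions, ortholog sets with conserved elements,
# and multiplexed negative-binomial count tables. Every generator is
# fully deterministic under its seed.

#' Generate a random genome with non-overlapping genes
#'
#' Chromosomes are i.i.d. base sequences at the requested GC content,
#' partitioned into fixed-size slots; each slot holds one gene whose
#' TSS sits at a fixed slot offset (strand chosen at random, body
#' extending downstream), leaving a defined upstream zone where
#' enhancer structures can later be planted with a guaranteed
#' nearest-TSS assignment.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_length Chromosome length in bp (default 5e5, giving a
#'   1 Mb genome at the defaults); must be at least 50 kb.
#' @param gc GC fraction (default 0.42).
#' @param slot_size Gene slot size in bp (default 12500); must be at
#'   least 9000 to fit a gene plus an enhancer zone.
#' @return A `synthetic_truth` list: `genome` (named character vector),
#'   `annotation` ([gene_annotation()]), `slots` (slot bookkeeping),
#'   `seed`, plus empty truth slots filled by later generators.
#' @export
generate_genome <- function(seed, n_chrom = 2, chrom_length = 5e5,
                            gc = 0.42, slot_size = 12500) {
  if (chrom_length < 5e4) stop("chrom_length must be at least 50 kb")
  if (slot_size < 9000) {
    stop("slot_size too small to place genes without overlap")
  }
  with_seed(seed, {
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    chroms <- sprintf("chr%d", seq_len(n_chrom))
    genome <- vapply(chroms, function(ch) {
      paste(sample(DNA_BASES, chrom_length, TRUE, probs), collapse = "")
    }, "")
    tss_offset <- 7000  # upstream enhancer zone is [1200, 6300) per slot
    slots <- do.call(rbind, lapply(chroms, function(ch) {
      s <- seq(0, chrom_length - slot_size, by = slot_size)
      data.frame(chrom = ch, slot_start = s)
    }))
    n <- nrow(slots)
    strand <- sample(c("+", "-"), n, TRUE)
    glen <- round(stats::runif(n, 2000, 4500))
    # TSS anchored near slot_start + tss_offset for both strands
    gstart <- ifelse(strand == "+", slots$slot_start + tss_offset,
                     slots$slot_start + tss_offset - glen)
    genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                        chrom = slots$chrom, start = gstart,
                        end = gstart + glen, strand = strand)
    exons <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- sample(2:4, 1)
      len <- glen[i]
      bounds <- sort(sample(seq(150, len - 150, by = 10), 2 * k - 2))
      es <- c(0, bounds[seq(2, length(bounds), by = 2)])
      ee <- c(bounds[seq(1, length(bounds), by = 2)], len)
      if (strand[i] == "-") { tmp <- len - rev(ee); ee <- len - rev(es); es <- tmp }
      data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                 start = genes$start[i] + es, end = genes$start[i] + ee)
    }))
    slots$gene_id <- genes$gene_id
    slots$tss <- ifelse(strand == "+", gstart, gstart + glen - 1)
    structure(list(genome = genome, annotation = gene_annotation(genes, exons),
                   slots = slots, slot_size = slot_size, seed = seed,
                   enhancers_truth = NULL, me3_domains = NULL,
                   motif_sites = NULL, peaks = NULL, tracks = NULL),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d chromosome(s) (%s bp), %d gene(s), seed %d\n",
              length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ","),
              nrow(x$annotation$genes), x$seed))
  if (!is.null(x$enhancers_truth)) {
    cat(sprintf("  planted enhancers: %d (%s)\n", nrow(x$enhancers_truth),
                paste(sprintf("%s=%d", names(table(x$enhancers_truth$condition)),
                              table(x$enhancers_truth$condition)),
                      collapse = ", ")))
  }
  if (!is.null(x$motif_sites)) {
    cat(sprintf("  planted motif sites: %d\n", nrow(x$motif_sites)))
  }
  invisible(x)
}

#' @keywords internal
jitter_edge <- function(x, sd, lower = -Inf, upper = Inf) {
  round(min(max(x + stats::rnorm(1, 0, sd), lower), upper))
}

#' Plant bimodal-acetylation enhancer structures
#'
#' Each planted structure is a left H3K27ac flank peak, a valley, and a
#' right flank, positioned in the enhancer zone upstream of a slot's
#' gene so the valley's nearest TSS is the designated target gene by
#' construction. A fraction of structures is shared between the two
#' conditions; the rest are condition-specific. Peak BED records are
#' the true flanks with Gaussian edge jitter, truncated so a flank
#' never invades more than 25% of the valley. Decoy bimodal pairs whose
#' valley is covered by an H3K27me3 domain exercise the repressive
#' filter; extra H3K27me3 domains are planted over a few gene loci in
#' the FGF condition. With `coverage = TRUE`, per-condition bedGraph
#' tracks are simulated: Poisson noise around flank plateaus, valley
#' background, and a peak-dip-peak acetylation shape at every TSS.
#'
#' @param sim A `synthetic_truth` from [generate_genome()].
#' @param n_per_condition Enhancers per condition (default 40).
#' @param fraction_common Fraction of each condition's enhancers shared
#'   with the other (default 0.2).
#' @param jitter_sd Peak-edge jitter sd in bp (default 30; 0 gives
#'   noiseless peaks).
#' @param n_decoys Number of H3K27me3-covered decoy structures
#'   (default 4, alternating conditions).
#' @param coverage Also simulate bedGraph signal tracks (default
#'   `FALSE`; they are only needed for profile work).
#' @param conditions Condition labels (default `c("CNT", "FGF")`).
#' @param seed Seed; defaults to a child of the genome seed.
#' @return The `synthetic_truth` with `peaks` (per condition: `ac`,
#'   `me3` interval sets), `enhancers_truth` (valley spans, flanks,
#'   target gene, condition in {CNT, FGF, both}), `me3_domains`, and
#'   optionally `tracks` (per condition: `ac`, `me3` signal tracks).
#' @export
plant_enhancers <- function(sim, n_per_condition = 40,
                            fraction_common = 0.2, jitter_sd = 30,
                            n_decoys = 4, coverage = FALSE,
                            conditions = c("CNT", "FGF"),
                            seed = child_seed(sim$seed, "enhancers")) {
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  stopifnot(length(conditions) == 2)
  n_common <- round(fraction_common * n_per_condition)
  n_unique <- n_per_condition - n_common
  n_struct <- 2 * n_unique + n_common + n_decoys
  if (n_struct > nrow(sim$slots)) {
    stop(sprintf("not enough slots (%d) for %d structures",
                 nrow(sim$slots), n_struct))
  }
  with_seed(seed, {
    slot_idx <- sample.int(nrow(sim$slots), n_struct)
    role <- rep(c(conditions[1], conditions[2], "both", "decoy"),
                c(n_unique, n_unique, n_common, n_decoys))
    zone_lo <- sim$slots$slot_start[slot_idx] + 1200
    zone_hi <- sim$slots$slot_start[slot_idx] + 6300
    lf <- round(stats::runif(n_struct, 500, 1200))
    rf <- round(stats::runif(n_struct, 500, 1200))
    vl <- round(stats::runif(n_struct, 200, 2500))
    total <- lf + vl + rf
    start <- round(zone_lo + stats::runif(n_struct) * (zone_hi - zone_lo - total))
    truth <- data.frame(
      chrom = sim$slots$chrom[slot_idx],
      start = start + lf, end = start + lf + vl,
      left_start = start, left_end = start + lf,
      right_start = start + lf + vl, right_end = start + total,
      gene_id = sim$slots$gene_id[slot_idx],
      condition = role
    )
    decoy <- truth$condition == "decoy"
    truth$condition[decoy] <- rep_len(conditions, sum(decoy))
    truth$decoy <- decoy
    # jittered peak BEDs per condition
    jit <- function(rows, cond) {
      if (!nrow(rows)) {
        return(genomic_intervals(character(0), numeric(0), numeric(0)))
      }
      out <- lapply(seq_len(nrow(rows)), function(i) {
        v <- rows$end[i] - rows$start[i]
        inv <- 0.25 * v
        le <- jitter_edge(rows$left_end[i], jitter_sd,
                          upper = rows$start[i] + inv)
        ls <- jitter_edge(rows$left_start[i], jitter_sd, upper = le - 50,
                          lower = 0)
        rs <- jitter_edge(rows$right_start[i], jitter_sd,
                          lower = rows$end[i] - inv)
        re <- jitter_edge(rows$right_end[i], jitter_sd, lower = rs + 50)
        data.frame(chrom = rows$chrom[i], start = c(ls, rs), end = c(le, re))
      })
      out <- do.call(rbind, out)
      genomic_intervals(out$chrom, out$start, out$end,
                        name = sprintf("%s_pk%d", cond, seq_len(nrow(out))))
    }
    peaks <- list()
    me3_dom <- list()
    # repressive domains over a few unused gene loci, FGF condition only
    free <- setdiff(seq_len(nrow(sim$slots)), slot_idx)
    rep_slots <- free[seq_len(min(3, length(free)))]
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      rows <- truth[!truth$decoy & truth$condition %in% c(cond, "both"), ]
      peaks_ac <- jit(rows, cond)
      drows <- truth[truth$decoy & truth$condition == cond, ]
      if (nrow(drows)) {
        peaks_ac <- genomic_intervals(
          c(peaks_ac$chrom, jit(drows, cond)$chrom),
          c(peaks_ac$start, jit(drows, cond)$start),
          c(peaks_ac$end, jit(drows, cond)$end))
      }
      dm <- if (nrow(drows)) {
        data.frame(chrom = drows$chrom, start = drows$start - 200,
                   end = drows$end + 200)
      } else NULL
      if (cond == conditions[2] && length(rep_slots)) {
        g <- sim$annotation$genes[
          match(sim$slots$gene_id[rep_slots], sim$annotation$genes$gene_id), ]
        dm <- rbind(dm, data.frame(chrom = g$chrom, start = g$start - 2000,
                                   end = g$end + 2000))
      }
      me3 <- if (is.null(dm)) {
        genomic_intervals(character(0), numeric(0), numeric(0))
      } else {
        genomic_intervals(dm$chrom, pmax(dm$start, 0), dm$end,
                          name = sprintf("%s_me3_%d", cond, seq_len(nrow(dm))))
      }
      peaks[[cond]] <- list(ac = peaks_ac, me3 = me3)
      me3_dom[[cond]] <- me3
    }
    sim$peaks <- peaks
    sim$me3_domains <- me3_dom
    sim$enhancers_truth <- truth
    if (coverage) sim$tracks <- simulate_tracks(sim, conditions)
    sim
  })
}

# Poisson-noise coverage tracks: flank plateaus, valley background, and
# peak-dip-peak acetylation around every TSS. 25 bp bins.
#' @keywords internal
simulate_tracks <- function(sim, conditions, bin = 25,
                            rate_bg = 1, rate_peak = 20, rate_dip = 3,
                            rate_tss = 15, rate_me3 = 10, rate_me3_bg = 0.3) {
  truth <- sim$enhancers_truth
  tss <- sim$slots$tss
  tss_chrom <- sim$slots$chrom
  out <- list()
  for (cond in conditions) {
    ac_rate <- me3_rate <- list()
    for (ch in names(sim$genome)) {
      n_bins <- nchar(sim$genome[[ch]]) %/% bin
      mids <- (seq_len(n_bins) - 0.5) * bin
      r_ac <- rep(rate_bg, n_bins)
      r_me <- rep(rate_me3_bg, n_bins)
      rows <- truth[truth$chrom == ch &
                      (truth$condition %in% c(cond, "both") | truth$decoy), ]
      rows <- rows[!rows$decoy | rows$condition == cond, ]
      for (i in seq_len(nrow(rows))) {
        r_ac[mids >= rows$left_start[i] & mids < rows$left_end[i]] <- rate_peak
        r_ac[mids >= rows$right_start[i] & mids < rows$right_end[i]] <- rate_peak
      }
      ts <- tss[tss_chrom == ch]
      for (t in ts) {
        r_ac[abs(mids - t) >= 100 & abs(mids - t) < 400] <- rate_tss
        r_ac[abs(mids - t) < 100] <- rate_dip
      }
      me3 <- sim$me3_domains[[cond]]
      me3 <- me3[me3$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(me3))) {
        r_me[mids >= me3$start[i] & mids < me3$end[i]] <- rate_me3
      }
      starts <- (seq_len(n_bins) - 1) * bin
      ac_rate[[ch]] <- data.frame(start = starts, end = starts + bin,
                                  value = stats::rpois(n_bins, r_ac))
      me3_rate[[ch]] <- data.frame(start = starts, end = starts + bin,
                                   value = stats::rpois(n_bins, r_me))
    }
    mk <- function(l) {
      signal_track(rep(names(l), vapply(l, nrow, 0L)),
                   unlist(lapply(l, `[[`, "start")),
                   unlist(lapply(l, `[[`, "end")),
                   unlist(lapply(l, `[[`, "value")))
    }
    out[[cond]] <- list(ac = mk(ac_rate), me3 = mk(me3_rate))
  }
  out
}

#' Plant motif instances into condition-specific valleys
#'
#' Writes the PWM's maximum-score word into a fraction of the valleys
#' unique to the second (treated) condition, at a random offset and
#' strand; control valleys receive none. Positions are recorded in the
#' truth.
#'
#' @param sim A `synthetic_truth` after [plant_enhancers()].
#' @param pwm A [pwm()]; default the synthetic AP1 fixture.
#' @param fraction_fgf Fraction of treated-condition valleys receiving
#'   a site (default 0.6).
#' @param condition Condition whose unique valleys receive sites
#'   (default `"FGF"`).
#' @param seed Seed; defaults to a child of the genome seed.
#' @return The `synthetic_truth` with updated `genome`, `motif_sites`
#'   (interval + strand per planted site) and a `has_motif` column in
#'   `enhancers_truth`.
#' @export
plant_motifs <- function(sim, pwm = ap1_fixture_pwm(), fraction_fgf = 0.6,
                         condition = "FGF",
                         seed = child_seed(sim$seed, "motifs")) {
  stopifnot(fraction_fgf >= 0, fraction_fgf <= 1)
  if (is.null(sim$enhancers_truth)) stop("plant_enhancers() first")
  word <- paste(DNA_BASES[apply(pwm$log_odds, 2, which.max)], collapse = "")
  w <- nchar(word)
  truth <- sim$enhancers_truth
  truth$has_motif <- FALSE
  cand <- which(!truth$decoy & truth$condition == condition)
  with_seed(seed, {
    n_plant <- round(fraction_fgf * length(cand))
    chosen <- if (n_plant) sample(cand, n_plant) else integer(0)
    sites <- list()
    for (i in chosen) {
      vlen <- truth$end[i] - truth$start[i]
      if (vlen < w) next  # motif wider than valley: skip
      off <- sample.int(vlen - w + 1, 1) - 1
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") word else revcomp(word)
      pos <- truth$start[i] + off
      substr(sim$genome[[truth$chrom[i]]], pos + 1, pos + w) <- ins
      truth$has_motif[i] <- TRUE
      sites[[length(sites) + 1]] <- data.frame(
        chrom = truth$chrom[i], start = pos, end = pos + w,
        strand = strand, enhancer = i)
    }
    sim$motif_sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 strand = character(0), enhancer = integer(0))
    sim$enhancers_truth <- truth
    sim
  })
}

#' Fetch the sequence of a genomic interval
#'
#' @param genome Named character vector of chromosome sequences.
#' @param regions A `genomic_intervals` data frame.
#' @return Character vector of sequences (minus-strand records are
#'   reverse-complemented).
#' @export
interval_sequences <- function(genome, regions) {
  strand <- if (is.null(regions$strand)) rep(".", nrow(regions)) else
    regions$strand
  vapply(seq_len(nrow(regions)), function(i) {
    s <- substr(genome[[regions$chrom[i]]], regions$start[i] + 1,
                regions$end[i])
    if (!is.na(strand[i]) && strand[i] == "-") revcomp(s) else s
  }, "")
}

#' Default species panel for ortholog simulation
#' @return Character vector of 9 species names, reference first.
#' @export
ortholog_species <- function() {
  c("chick", "human", "horse", "cow", "rabbit", "mouse", "opossum",
    "platypus", "lizard")
}

#' @keywords internal
mutate_seq <- function(v, rate) {
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    # substitute with one of the three other bases
    v[hit] <- ((v[hit] - 1L + sample.int(3, length(hit), TRUE)) %% 4L) + 1L
  }
  v
}

#' Simulate an ortholog set with planted conserved elements
#'
#' Non-reference sequences are copies of the reference with i.i.d.
#' point substitutions at `per_species_divergence`; inside each planted
#' element, a subset of species instead mutates at
#' `element_divergence`. The default background divergence (0.5, the
#' maximum) emulates unalignable diverged sequence so only planted
#' elements remain detectable.
#'
#' @param reference_seq Reference DNA string, or `NULL` to generate a
#'   random `ref_length`-bp sequence.
#' @param species Species names, reference first (default
#'   [ortholog_species()]).
#' @param n_elements Number of planted conserved elements (default 1).
#' @param element_length Element length in bp (default 60).
#' @param n_species_with_element Species carrying the element including
#'   the reference (default 8 of 9).
#' @param element_divergence Substitution rate inside elements
#'   (default 0.01).
#' @param per_species_divergence Background substitution rate in
#'   [0, 0.5] (default 0.5).
#' @param ref_length Length of a generated reference (default 2000).
#' @param origin Optional `genomic_intervals` origin of the reference.
#' @param seed Integer seed.
#' @return List with `orthologs` (an [ortholog_set()]) and `truth`
#'   (data frame of planted element spans, reference-local 0-based,
#'   with carrier species).
#' @export
make_orthologs <- function(reference_seq = NULL,
                           species = ortholog_species(), n_elements = 1,
                           element_length = 60,
                           n_species_with_element = 8,
                           element_divergence = 0.01,
                           per_species_divergence = 0.5,
                           ref_length = 2000, origin = NULL, seed) {
  stopifnot(per_species_divergence >= 0, per_species_divergence <= 0.5,
            length(species) >= 2,
            n_species_with_element <= length(species))
  with_seed(seed, {
    if (is.null(reference_seq)) {
      reference_seq <- paste(sample(DNA_BASES, ref_length, TRUE),
                             collapse = "")
    }
    n <- nchar(reference_seq)
    ref_int <- dna_to_int(reference_seq)
    # non-overlapping element placements
    spots <- seq(0, n - element_length, by = element_length * 3)
    if (length(spots) < n_elements) stop("reference too short for elements")
    el_start <- sort(sample(spots, n_elements))
    carriers <- lapply(seq_len(n_elements), function(e) {
      c(species[1], sample(species[-1], n_species_with_element - 1))
    })
    truth <- data.frame(start = el_start, end = el_start + element_length,
                        species = vapply(carriers, paste, "",
                                         collapse = ","))
    others <- lapply(species[-1], function(sp) {
      rate <- rep(per_species_divergence, n)
      for (e in seq_len(n_elements)) {
        if (sp %in% carriers[[e]]) {
          rate[(el_start[e] + 1):(el_start[e] + element_length)] <-
            element_divergence
        }
      }
      v <- ref_int
      hit <- which(stats::runif(n) < rate)
      if (length(hit)) {
        v[hit] <- ((v[hit] - 1L + sample.int(3, length(hit), TRUE)) %% 4L) + 1L
      }
      int_to_dna(v)
    })
    names(others) <- species[-1]
    list(orthologs = ortholog_set(species[1], reference_seq, others,
                                  origin = origin),
         truth = truth)
  })
}

#' Simulate a multiplexed count table with planted responses
#'
#' Negative-binomial counts for a four-condition design (control,
#' treated, treated+CHX, CHX vehicle), three replicates each by
#' default. Direct targets carry the planted fold change in both the
#' plain and the CHX contrast; indirect targets only in the plain
#' contrast; repressed classes are mirrored. Per-sample lane-effect
#' multipliers plus positive, negative and housekeeping control probes
#' give [normalize_counts()] real work.
#'
#' @param seed Integer seed.
#' @param n_endogenous Endogenous probes (default 192, giving 216 total
#'   with the control probes).
#' @param n_direct,n_indirect Planted direct/indirect targets (default
#'   10 each, split evenly up/down).
#' @param log2fc Planted absolute log2 fold change (default 2).
#' @param dispersion NB dispersion for endogenous probes (default 0.1).
#' @param replicates Replicates per condition (default 3, minimum 3).
#' @param lane_sd Log-normal sd of per-sample lane effects
#'   (default 0.15).
#' @param baseline_range Range of endogenous baseline means
#'   (log-uniform; default 200-2000).
#' @param conditions Condition labels, in the order control, treated,
#'   treated+CHX, CHX vehicle.
#' @return List with `counts` (a [count_table()]) and `truth` (named
#'   character vector of planted classes per endogenous probe).
#' @export
simulate_counts <- function(seed, n_endogenous = 192, n_direct = 10,
                            n_indirect = 10, log2fc = 2, dispersion = 0.1,
                            replicates = 3, lane_sd = 0.15,
                            baseline_range = c(200, 2000),
                            conditions = c("CNT", "FGF", "FGF_CHX", "CHX")) {
  if (length(conditions) != 4) {
    stop("design must name 4 conditions: control, treated, treated+CHX, CHX")
  }
  if (replicates < 3) stop("need at least 3 replicates per condition")
  with_seed(seed, {
    half <- function(k) c(rep("up", ceiling(k / 2)), rep("down", floor(k / 2)))
    truth <- rep("unresponsive", n_endogenous)
    truth[seq_len(n_direct)] <- paste0("direct_", half(n_direct))
    truth[n_direct + seq_len(n_indirect)] <- paste0("indirect_", half(n_indirect))
    probes <- sprintf("probe%03d", seq_len(n_endogenous))
    names(truth) <- probes
    base <- exp(stats::runif(n_endogenous, log(baseline_range[1]),
                             log(baseline_range[2])))
    eff <- function(cls, active) {
      ifelse(cls %in% paste0(active, "_up"), 2^log2fc,
             ifelse(cls %in% paste0(active, "_down"), 2^(-log2fc), 1))
    }
    fc_by_cond <- list(1, eff(truth, c("direct", "indirect")),
                       eff(truth, "direct"), 1)
    names(fc_by_cond) <- conditions
    pos_mu <- c(12800, 3200, 800, 200, 50, 12.5) * 8
    hk_mu <- exp(stats::runif(10, log(500), log(3000)))
    neg_mu <- rep(2, 8)
    size_ctrl <- 100  # technical control probes: near-Poisson
    cond_vec <- rep(conditions, each = replicates)
    rep_vec <- rep(seq_len(replicates), times = length(conditions))
    cols <- lapply(seq_along(cond_vec), function(j) {
      lane <- exp(stats::rnorm(1, 0, lane_sd))
      mu <- base * fc_by_cond[[cond_vec[j]]] * lane
      c(stats::rnbinom(n_endogenous, size = 1 / dispersion, mu = mu),
        stats::rnbinom(6, size = size_ctrl, mu = pos_mu * lane),
        stats::rpois(8, neg_mu),
        stats::rnbinom(10, size = size_ctrl, mu = hk_mu * lane))
    })
    m <- do.call(cbind, cols)
    rownames(m) <- c(probes, sprintf("POS_%s", LETTERS[1:6]),
                     sprintf("NEG_%s", LETTERS[1:8]),
                     sprintf("HK_%02d", 1:10))
    ct <- count_table(m, rep(c("endogenous", "positive", "negative",
                               "housekeeping"), c(n_endogenous, 6, 8, 10)),
                      cond_vec, rep_vec)
    list(counts = ct, truth = truth)
  })
}

#' Score called enhancers against the planted truth
#'
#' A planted valley counts as recovered when a called valley covers at
#' least half of it; a called valley counts as a false discovery when
#' it overlaps no planted valley of its condition.
#'
#' @param called An `enhancer_set` for one condition.
#' @param sim A `synthetic_truth` after [plant_enhancers()].
#' @param condition Condition label matching the truth (`"CNT"` or
#'   `"FGF"`; `"both"` rows count for either).
#' @return List with `sensitivity`, `fdr`, `n_true`, `n_called`,
#'   `recovered` (logical per truth row).
#' @export
score_enhancer_recovery <- function(called, sim, condition) {
  truth <- sim$enhancers_truth
  truth <- truth[!truth$decoy & truth$condition %in% c(condition, "both"), ]
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    j <- called$chrom == truth$chrom[i]
    ov <- pmin(called$end[j], truth$end[i]) - pmax(called$start[j], truth$start[i])
    any(ov >= 0.5 * (truth$end[i] - truth$start[i]))
  }, logical(1))
  false_pos <- vapply(seq_len(nrow(called)), function(k) {
    i <- truth$chrom == called$chrom[k]
    ov <- pmin(called$end[k], truth$end[i]) - pmax(called$start[k], truth$start[i])
    !any(ov > 0)
  }, logical(1))
  list(sensitivity = mean(recovered),
       fdr = if (nrow(called)) mean(false_pos) else 0,
       n_true = nrow(truth), n_called = nrow(called),
       recovered = recovered)
}

#' Accuracy of a direct/indirect classification against planted truth
#'
#' Multi-class accuracy over all endogenous probes.
#'
#' @param classification A [classify_direct()] table.
#' @param truth Named truth vector from [simulate_counts()].
#' @return Fraction of probes whose class matches the truth.
#' @export
classification_accuracy <- function(classification, truth) {
  got <- classification$class[match(names(truth), classification$probe)]
  mean(got == truth)
}
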