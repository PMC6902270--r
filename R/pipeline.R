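# End-to-end orchestration: a single config drives simulation (or file
# inputs), enhancer calling, condition comparison, profiles and
# clustering, motif enrichment, conservation and response
# classification, writing a run directory with a manifest of file
# hashes so reruns are verifiable.

#' Write a genome as FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1)
  out
}

#' Build a run configuration
#'
#' All tunable parameters of the pipeline with their default values
#' (3 kb maximum valley, -2000/+500 promoter window, +/-5 kb profile
#' window with 50 bp bins, 5 clusters, scan p-value 1e-4, 1000
#' shuffles, e-value gate 0.05, 8 bp words in 300 bp windows with a
#' 7-species gate, alpha 0.05).
#'
#' @param seed Integer master seed.
#' @param out_dir Run directory.
#' @param ... Overrides for any default listed above (see the returned
#'   object for names).
#' @return A `run_config` list.
#' @export
run_config <- function(seed, out_dir, ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    # enhancer calling
    max_inner_gap = 3000, promoter_up = 2000, promoter_down = 500,
    # profiles
    profile_window = 5000, tss_window = 2000, bin_size = 50, k = 5,
    # motifs
    pwm_p = 1e-4, n_shuffles = 1000, e_threshold = 0.05,
    # conservation
    word = 8, cons_window = 300, cons_step = 50, min_shared = 8,
    min_species = 7,
    # expression
    preset = "figure", alpha = 0.05,
    # synthetic inputs
    simulate = TRUE, n_chrom = 2, chrom_length = 5e5,
    n_per_condition = 40, fraction_common = 0.2, jitter_sd = 30,
    fraction_fgf = 0.6, conditions = c("CNT", "FGF"),
    # file inputs (used when simulate = FALSE)
    ac_beds = NULL, me3_beds = NULL, annotation = NULL,
    annotation_format = "gff3", genome_fasta = NULL, counts_tsv = NULL,
    pwm_file = NULL, ortholog_fasta = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read / write run configurations as YAML
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(run_config, v)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  v <- unclass(config)
  v <- v[!vapply(v, is.null, logical(1))]
  yaml::write_yaml(v, path)
  invisible(path)
}

#' @keywords internal
write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) {
    ifelse(v == round(v) & abs(v) < 1e15, format(v, scientific = FALSE,
                                                 trim = TRUE),
           fmt_num(v, digits = 8))
  })
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate the full synthetic study
#'
#' Genome + genes, planted two-condition enhancer structures with
#' coverage tracks, planted motif sites, an ortholog set anchored on a
#' planted enhancer, and a multiplexed count table whose planted
#' direct/indirect targets are the genes nearest the treated-condition
#' enhancers in spirit (probe labels are independent of the genome).
#'
#' @param seed Integer master seed.
#' @param config Optional `run_config` supplying generator parameters.
#' @param coverage Simulate signal tracks (default `TRUE`).
#' @return A list: `sim` (`synthetic_truth`), `counts_sim`
#'   (simulate_counts output), `ortho` (make_orthologs output).
#' @export
synthetic_study <- function(seed, config = run_config(seed, tempfile()),
                            coverage = TRUE) {
  sim <- generate_genome(child_seed(seed, "genome"),
                         n_chrom = config$n_chrom,
                         chrom_length = config$chrom_length)
  sim <- plant_enhancers(sim, n_per_condition = config$n_per_condition,
                         fraction_common = config$fraction_common,
                         jitter_sd = config$jitter_sd, coverage = coverage,
                         conditions = config$conditions,
                         seed = child_seed(seed, "enhancers"))
  sim <- plant_motifs(sim, fraction_fgf = config$fraction_fgf,
                      condition = config$conditions[2],
                      seed = child_seed(seed, "motifs"))
  truth <- sim$enhancers_truth
  anchor <- truth[!truth$decoy & truth$condition == config$conditions[2], ][1, ]
  locus <- genomic_intervals(anchor$chrom, max(anchor$left_start - 500, 0),
                             anchor$right_end + 500)
  ref_seq <- interval_sequences(sim$genome, locus)
  ortho <- make_orthologs(reference_seq = ref_seq, origin = locus,
                          seed = child_seed(seed, "orthologs"))
  counts_sim <- simulate_counts(child_seed(seed, "counts"))
  list(sim = sim, counts_sim = counts_sim, ortho = ortho)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order and writes every output
#' into `config$out_dir`: per-condition enhancer BEDs, the comparison
#' table, context distributions, TSS metaprofiles, motif-centred
#' cluster assignments, the motif-enrichment table, conservation
#' blocks, response and classification tables, a markdown report, the
#' round-trippable config, and a `MANIFEST.tsv` of md5 hashes. Reruns
#' with the same config and seed reproduce identical hashes.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  conds <- config$conditions

  inputs <- stage("inputs", {
    if (isTRUE(config$simulate)) {
      study <- synthetic_study(config$seed, config)
      sim <- study$sim
      dir.create(out("inputs"), showWarnings = FALSE)
      for (cond in conds) {
        write_bed(sim$peaks[[cond]]$ac, out(sprintf("inputs/%s_ac.bed", cond)))
        write_bed(sim$peaks[[cond]]$me3, out(sprintf("inputs/%s_me3.bed", cond)))
        write_bedgraph(sim$tracks[[cond]]$ac,
                       out(sprintf("inputs/%s_ac.bedGraph", cond)))
      }
      write_genome_fasta(sim$genome, out("inputs/genome.fa"))
      write_count_table(study$counts_sim$counts, out("inputs/counts.tsv"))
      write_ortholog_fasta(study$ortho$orthologs, out("inputs/orthologs.fa"))
      list(ac = lapply(conds, function(c) read_bed(out(sprintf("inputs/%s_ac.bed", c)))),
           me3 = lapply(conds, function(c) read_bed(out(sprintf("inputs/%s_me3.bed", c)))),
           annotation = sim$annotation, genome = sim$genome,
           tracks = sim$tracks, counts = study$counts_sim$counts,
           orthologs = study$ortho$orthologs, study = study)
    } else {
      if (is.null(config$ac_beds) || is.null(config$me3_beds)) {
        stop("enhancer_calling inputs missing: ac_beds/me3_beds required")
      }
      list(ac = lapply(config$ac_beds, read_bed),
           me3 = lapply(config$me3_beds, read_bed),
           annotation = if (!is.null(config$annotation)) {
             read_annotation(config$annotation, config$annotation_format)
           },
           genome = if (!is.null(config$genome_fasta)) {
             read_genome_fasta(config$genome_fasta)
           },
           tracks = NULL,
           counts = if (!is.null(config$counts_tsv)) {
             read_count_table(config$counts_tsv)
           },
           orthologs = if (!is.null(config$ortholog_fasta)) {
             read_ortholog_fasta(config$ortholog_fasta)
           },
           study = NULL)
    }
  })
  names(inputs$ac) <- names(inputs$me3) <- conds

  enh <- stage("enhancer_calling", {
    lapply(conds, function(cond) {
      e <- call_enhancers(inputs$ac[[cond]], inputs$me3[[cond]],
                          inputs$annotation,
                          max_inner_gap = config$max_inner_gap,
                          condition = cond,
                          promoter_up = config$promoter_up,
                          promoter_down = config$promoter_down)
      write_bed(genomic_intervals(e$chrom, e$start, e$end,
                                  name = sprintf("%s|%s|%s", e$gene_id,
                                                 e$context, cond),
                                  score = e$end - e$start),
                out(sprintf("enhancers_%s.bed", cond)))
      e
    })
  })
  names(enh) <- conds

  comparison <- stage("compare", {
    cmp <- compare_conditions(enh[[1]], enh[[2]])
    write_tsv(data.frame(set = c(sprintf("unique_%s", conds), "common"),
                         count = c(cmp$counts[["unique_a"]],
                                   cmp$counts[["unique_b"]],
                                   cmp$counts[["common"]])),
              out("comparison_counts.tsv"))
    write_tsv(cmp$common, out("common_components.tsv"))
    ctx <- do.call(rbind, lapply(conds, function(cond) {
      as.data.frame(t(context_distribution(enh[[cond]])))
    }))
    ctx <- cbind(condition = conds, ctx)
    write_tsv(ctx, out("context_distribution.tsv"))
    cmp
  })

  profiles <- stage("profiles", {
    if (is.null(inputs$tracks)) return(NULL)
    g <- inputs$annotation$genes
    tss_anchors <- genomic_intervals(g$chrom, g$tss, g$tss + 1,
                                     name = g$gene_id, strand = g$strand)
    meta <- lapply(conds, function(cond) {
      m <- extract_matrix(inputs$tracks[[cond]]$ac, tss_anchors,
                          window = config$tss_window,
                          bin_size = config$bin_size)
      metaprofile(m)
    })
    nb <- length(meta[[1]])
    write_tsv(data.frame(
      bin_center = seq(-config$tss_window + config$bin_size / 2,
                       config$tss_window - config$bin_size / 2,
                       by = config$bin_size),
      stats::setNames(as.data.frame(meta), conds), check.names = FALSE),
      out("tss_metaprofile.tsv"))
    # motif-centred heatmap matrix + clusters (treated-condition track)
    pwms <- if (!is.null(config$pwm_file)) read_jaspar(config$pwm_file) else
      list(AP1_fixture = ap1_fixture_pwm())
    m1 <- pwms[[1]]
    thr <- suppressWarnings(score_threshold(m1, config$pwm_p))
    hits <- do.call(rbind, lapply(seq_len(nrow(enh[[2]])), function(i) {
      s <- interval_sequences(inputs$genome, enh[[2]][i, ])
      h <- scan_pwm(s, m1, thr)
      if (!nrow(h)) return(NULL)
      h$chrom <- enh[[2]]$chrom[i]
      h$start <- h$start + enh[[2]]$start[i]
      h$end <- h$end + enh[[2]]$start[i]
      h
    }))
    clu <- NULL
    if (!is.null(hits) && nrow(hits) >= config$k) {
      centers <- floor((hits$start + hits$end) / 2)
      anchors <- genomic_intervals(hits$chrom, centers, centers + 1,
                                   strand = hits$strand)
      pm <- extract_matrix(inputs$tracks[[2]]$ac, anchors,
                           window = config$profile_window,
                           bin_size = config$bin_size)
      clu <- cluster_profiles(pm, k = config$k,
                              seed = child_seed(config$seed, "kmeans"))
      write_tsv(data.frame(anchor = seq_along(clu$labels),
                           chrom = anchors$chrom, center = centers,
                           cluster = clu$labels),
                out("motif_clusters.tsv"))
    }
    list(metaprofiles = meta, clusters = clu, motif_hits = hits)
  })

  motifs <- stage("motifs", {
    if (is.null(inputs$genome)) return(NULL)
    pwms <- if (!is.null(config$pwm_file)) read_jaspar(config$pwm_file) else
      list(AP1_fixture = ap1_fixture_pwm())
    cmp <- comparison
    seq_b <- interval_sequences(inputs$genome, cmp$unique_b)
    seq_a <- interval_sequences(inputs$genome, cmp$unique_a)
    tab <- differential_motif_enrichment(seq_b, seq_a, pwms,
                                         n_shuffles = config$n_shuffles,
                                         seed = child_seed(config$seed, "motif_null"),
                                         e_threshold = config$e_threshold)
    write_tsv(tab, out("motif_enrichment.tsv"))
    tab
  })

  conservation <- stage("conservation", {
    if (is.null(inputs$orthologs)) return(NULL)
    blocks <- find_conserved_blocks(inputs$orthologs, word = config$word,
                                    window = config$cons_window,
                                    step = config$cons_step,
                                    min_shared = config$min_shared,
                                    min_species = config$min_species)
    write_tsv(blocks, out("conserved_blocks.tsv"))
    if (nrow(blocks) && "genome_start" %in% names(blocks)) {
      flagged <- annotate_blocks(blocks, enh[[2]])
      write_tsv(data.frame(chrom = flagged$chrom, start = flagged$start,
                           end = flagged$end, conserved = flagged$conserved),
                out("enhancer_conservation.tsv"))
    }
    blocks
  })

  response <- stage("response", {
    if (is.null(inputs$counts)) return(NULL)
    norm <- normalize_counts(inputs$counts)
    plain <- respond(norm, "FGF", "CNT", preset = config$preset,
                     alpha = config$alpha)
    chx <- respond(norm, "FGF_CHX", "CHX", preset = config$preset,
                   alpha = config$alpha)
    cls <- classify_direct(plain, chx)
    write_tsv(plain, out("response_plain.tsv"))
    write_tsv(chx, out("response_chx.tsv"))
    write_tsv(cls, out("target_classification.tsv"))
    jsonlite::write_json(as.list(venn_overlap(plain, chx)),
                         out("venn_counts.json"), auto_unbox = TRUE)
    list(plain = plain, chx = chx, classification = cls)
  })

  stage("report", {
    write_run_config(config, out("config.yaml"))
    lines <- c("# valleycall run report", "",
               sprintf("- seed: %d", config$seed),
               sprintf("- conditions: %s", paste(conds, collapse = " vs ")),
               sprintf("- enhancers called: %s",
                       paste(sprintf("%s=%d", conds,
                                     vapply(enh, nrow, 0L)), collapse = ", ")),
               sprintf("- unique %s: %d, unique %s: %d, common: %d",
                       conds[1], comparison$counts[["unique_a"]],
                       conds[2], comparison$counts[["unique_b"]],
                       comparison$counts[["common"]]))
    if (!is.null(inputs$study)) {
      rec <- lapply(conds, function(cond) {
        score_enhancer_recovery(enh[[cond]], inputs$study$sim, cond)
      })
      lines <- c(lines, sprintf("- recovery %s: sensitivity %.3f, FDR %.3f",
                                conds, vapply(rec, `[[`, 0, "sensitivity"),
                                vapply(rec, `[[`, 0, "fdr")))
      if (!is.null(response)) {
        acc <- classification_accuracy(response$classification,
                                       inputs$study$counts_sim$truth)
        lines <- c(lines, sprintf("- classification accuracy vs truth: %.3f",
                                  acc))
      }
    }
    if (!is.null(motifs)) {
      lines <- c(lines, sprintf("- motif '%s': e-value %.4g%s", motifs$pwm,
                                motifs$e_value,
                                ifelse(motifs$significant, " (significant)", "")))
    }
    writeLines(lines, out("report.md"))
    # manifest: sorted relative paths + md5, written last
    files <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                          "MANIFEST.tsv"))
    md5 <- tools::md5sum(file.path(config$out_dir, files))
    write_tsv(data.frame(file = files, md5 = unname(md5),
                         seed = config$seed),
              out("MANIFEST.tsv"))
  })

  invisible(list(enhancers = enh, comparison = comparison,
                 profiles = profiles, motifs = motifs,
                 conservation = conservation, response = response,
                 inputs = inputs))
}
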