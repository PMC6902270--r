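# Alignment-free conservation scan: sliding 300 bp windows along a
# reference locus are called conserved when enough species share a
# cluster of the window's 8-mers, independent of word order (tolerant of
# rearrangements, as in motif-cluster phylogenetic footprinting).

#' Construct an ortholog sequence set
#'
#' One reference locus plus orthologous sequences from other species.
#'
#' @param reference_name Reference species name.
#' @param reference_seq Reference DNA string.
#' @param others Named character vector/list of DNA strings, one per
#'   non-reference species.
#' @param origin Optional `genomic_intervals` row giving the genomic
#'   origin of the reference locus (used to place blocks in genome
#'   coordinates).
#' @return An `ortholog_set`.
#' @export
ortholog_set <- function(reference_name, reference_seq, others,
                         origin = NULL) {
  others <- as.list(others)
  if (length(others) < 1) stop("need at least 2 species in total")
  if (is.null(names(others)) || any(!nzchar(names(others)))) {
    stop("non-reference sequences must be named by species")
  }
  structure(list(reference = list(species = reference_name,
                                  seq = toupper(reference_seq),
                                  origin = origin),
                 others = lapply(others, toupper)),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("ortholog_set: reference '%s' (%d bp) + %d species\n",
              x$reference$species, nchar(x$reference$seq),
              length(x$others)))
  invisible(x)
}

#' Read an ortholog set from a multi-FASTA file
#'
#' Record ids are species names; the first record is the reference and
#' may carry `chrom:start-end` in its description to anchor the locus.
#'
#' @param path Multi-FASTA path.
#' @return An [ortholog_set()].
#' @export
read_ortholog_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 2) stop("ortholog FASTA needs at least 2 records")
  ids <- names(ss)
  first <- strsplit(ids[1], "\\s+")[[1]]
  origin <- NULL
  loc <- grep("^[^:]+:[0-9]+-[0-9]+$", first[-1], value = TRUE)
  if (length(loc)) {
    parts <- strsplit(loc[1], "[:-]")[[1]]
    origin <- genomic_intervals(parts[1], as.numeric(parts[2]),
                                as.numeric(parts[3]))
  }
  others <- unname(as.character(ss[-1]))
  names(others) <- vapply(strsplit(ids[-1], "\\s+"), `[`, "", 1)
  ortholog_set(first[1], unname(as.character(ss[1])), others,
               origin = origin)
}

#' Write an ortholog set as multi-FASTA
#' @param orthologs An [ortholog_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_fasta <- function(orthologs, path) {
  ref <- orthologs$reference
  id <- ref$species
  if (!is.null(ref$origin)) {
    id <- sprintf("%s %s:%d-%d", id, ref$origin$chrom[1],
                  as.integer(ref$origin$start[1]),
                  as.integer(ref$origin$end[1]))
  }
  seqs <- Biostrings::DNAStringSet(c(ref$seq, unlist(orthologs$others)))
  names(seqs) <- c(id, names(orthologs$others))
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

# reverse-complement codes for all base-4 k-mer codes 0..4^k-1
#' @keywords internal
rc_code_table <- function(k) {
  codes <- 0:(4^k - 1)
  rc <- numeric(length(codes))
  rem <- codes
  for (j in seq_len(k)) {       # digit j from the right
    d <- rem %% 4
    rem <- rem %/% 4
    rc <- rc + (3 - d) * 4^(k - j)
  }
  rc
}

# Does any `window`-bp span of the species sequence contain >=
# min_shared distinct words from the reference word set?
#' @keywords internal
count_clustered_shared <- function(sp_pos, sp_word_idx, window, word) {
  if (!length(sp_pos)) return(0L)
  ord <- order(sp_pos)
  pos <- sp_pos[ord]; widx <- sp_word_idx[ord]
  best <- 0L
  counts <- integer(max(widx))
  distinct <- 0L
  left <- 1L
  for (right in seq_along(pos)) {
    w <- widx[right]
    if (counts[w] == 0L) distinct <- distinct + 1L
    counts[w] <- counts[w] + 1L
    while (pos[right] + word - pos[left] > window) {
      wl <- widx[left]
      counts[wl] <- counts[wl] - 1L
      if (counts[wl] == 0L) distinct <- distinct - 1L
      left <- left + 1L
    }
    if (distinct > best) best <- distinct
  }
  best
}

#' Find conserved blocks across an ortholog set
#'
#' A `window`-bp window slides along the reference at `step`-bp
#' intervals. A non-reference species supports a window when some
#' `window`-bp span of its sequence contains at least `min_shared`
#' distinct `word`-mers of the reference window, matched on either
#' strand and regardless of order. Windows supported by at least
#' `min_species` species (the reference counts as one) are reported;
#' overlapping reported windows are merged into blocks.
#'
#' @param orthologs An [ortholog_set()].
#' @param word Word size in bp (default 8).
#' @param window Window size in bp (default 300).
#' @param step Window step in bp (default 50).
#' @param min_shared Minimum distinct shared words per supporting
#'   species (default 8).
#' @param min_species Minimum supporting species including the
#'   reference (default 7, i.e. 7-of-9 when 9 species are supplied).
#' @return Data frame of blocks: `start`, `end` (reference-local,
#'   0-based half-open), `n_species`, `species` (comma-separated,
#'   union over merged windows), `max_shared_words`; plus genome
#'   coordinates `chrom`, `genome_start`, `genome_end` when the
#'   reference has an origin.
#' @export
find_conserved_blocks <- function(orthologs, word = 8, window = 300,
                                  step = 50, min_shared = 8,
                                  min_species = 7) {
  if (word > window) stop("word size must not exceed window size")
  ref <- orthologs$reference$seq
  n <- nchar(ref)
  if (n < window) stop("reference shorter than one window")
  rc <- rc_code_table(word)
  ref_codes <- kmer_codes(dna_to_int(ref), word)
  sp_names <- names(orthologs$others)
  # per species: forward-word positions and codes (NA windows dropped)
  sp_index <- lapply(orthologs$others, function(s) {
    codes <- kmer_codes(dna_to_int(s), word)
    keep <- !is.na(codes)
    list(pos = which(keep), codes = codes[keep])
  })
  starts <- seq(0, n - window, by = step)
  supported <- matrix(FALSE, length(starts), length(sp_names))
  shared_counts <- matrix(0L, length(starts), length(sp_names))
  for (wi in seq_along(starts)) {
    s0 <- starts[wi]
    wcodes <- ref_codes[(s0 + 1):(s0 + window - word + 1)]
    wcodes <- unique(wcodes[!is.na(wcodes)])
    if (length(wcodes) < min_shared) next
    for (si in seq_along(sp_names)) {
      idx <- sp_index[[si]]
      m_f <- match(idx$codes, wcodes)
      m_r <- match(rc[idx$codes + 1], wcodes)
      m <- ifelse(is.na(m_f), m_r, m_f)
      hit <- !is.na(m)
      cnt <- count_clustered_shared(idx$pos[hit], m[hit], window, word)
      shared_counts[wi, si] <- cnt
      supported[wi, si] <- cnt >= min_shared
    }
  }
  n_support <- rowSums(supported) + 1L  # reference supports itself
  called <- which(n_support >= min_species)
  if (!length(called)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_species = integer(0), species = character(0),
                      max_shared_words = integer(0)))
  }
  # merge overlapping called windows
  ws <- starts[called]; we <- ws + window
  grp <- cumsum(c(TRUE, ws[-1] > cummax(we)[-length(we)]))
  blocks <- lapply(split(seq_along(called), grp), function(ii) {
    rows <- called[ii]
    sp <- sp_names[colSums(supported[rows, , drop = FALSE]) > 0]
    data.frame(start = min(ws[ii]), end = max(we[ii]),
               n_species = max(n_support[rows]),
               species = paste(c(orthologs$reference$species, sp),
                               collapse = ","),
               max_shared_words = max(shared_counts[rows, , drop = FALSE]))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  origin <- orthologs$reference$origin
  if (!is.null(origin)) {
    out$chrom <- origin$chrom[1]
    out$genome_start <- origin$start[1] + out$start
    out$genome_end <- origin$start[1] + out$end
  }
  out
}

#' Flag enhancers overlapping conserved blocks
#'
#' Joins conserved blocks onto an enhancer set with the same 0 bp gap
#' rule used for the condition comparison (overlap or book-ended =>
#' conserved).
#'
#' @param blocks Block table from [find_conserved_blocks()] with genome
#'   coordinates (`chrom`, `genome_start`, `genome_end`), or local
#'   coordinates plus a `chrom` column.
#' @param enhancers An `enhancer_set`.
#' @return The enhancer set with a logical `conserved` column.
#' @export
annotate_blocks <- function(blocks, enhancers) {
  bs <- if ("genome_start" %in% names(blocks)) blocks$genome_start else blocks$start
  be <- if ("genome_end" %in% names(blocks)) blocks$genome_end else blocks$end
  bc <- if ("chrom" %in% names(blocks)) blocks$chrom else rep(NA_character_, nrow(blocks))
  enhancers$conserved <- vapply(seq_len(nrow(enhancers)), function(i) {
    any(bc == enhancers$chrom[i] &
          pmax(enhancers$start[i], bs) - pmin(enhancers$end[i], be) <= 0)
  }, logical(1))
  enhancers
}
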