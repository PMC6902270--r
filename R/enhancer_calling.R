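# Bimodal-valley enhancer calling: putative enhancers are the low-signal
# valleys between adjacent H3K27ac peak pairs separated by at most
# max_inner_gap (default 3 kb), kept only when no H3K27me3 peak overlaps
# the valley.

#' Merge touching or overlapping peaks
#'
#' Normalisation before valley pairing: peaks whose gap is <= 0
#' (overlapping or book-ended) are unioned into single intervals.
#'
#' @param peaks A `genomic_intervals` data frame.
#' @return Merged peaks sorted by (chrom, start).
#' @export
merge_touching_peaks <- function(peaks) {
  if (!nrow(peaks)) return(peaks)
  out <- lapply(split(as.data.frame(peaks), peaks$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    run_end <- cummax(d$end)
    new_run <- c(TRUE, d$start[-1] > run_end[-nrow(d)])
    grp <- cumsum(new_run)
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, grp, min),
               end = tapply(d$end, grp, max))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  genomic_intervals(out$chrom, out$start, out$end)
}

#' @keywords internal
empty_enhancers <- function(condition = NA_character_) {
  df <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                   left_start = numeric(0), left_end = numeric(0),
                   right_start = numeric(0), right_end = numeric(0),
                   gene_id = character(0), distance_to_tss = numeric(0),
                   context = character(0), condition = character(0))
  class(df) <- c("enhancer_set", "data.frame")
  df
}

#' Call candidate valleys between adjacent acetylation peaks
#'
#' For every pair of adjacent merged H3K27ac peaks on the same
#' chromosome with `0 < gap <= max_inner_gap`, the inter-peak valley is
#' emitted as a candidate enhancer. A peak can serve as right flank of
#' one valley and left flank of the next.
#'
#' @param ac_peaks Merged, sorted H3K27ac peaks (see
#'   [merge_touching_peaks()]; applied internally if needed).
#' @param max_inner_gap Maximum valley width in bp (default 3000).
#' @param condition Optional condition label stored on each call.
#' @return An `enhancer_set` data frame: valley span (`chrom`, `start`,
#'   `end`), flank peaks (`left_*`, `right_*`), and annotation columns
#'   initialised to `NA`.
#' @export
call_valleys <- function(ac_peaks, max_inner_gap = 3000,
                         condition = NA_character_) {
  if (max_inner_gap <= 0) stop("max_inner_gap must be positive")
  peaks <- merge_touching_peaks(ac_peaks)
  if (nrow(peaks) < 2) return(empty_enhancers(condition))
  same <- peaks$chrom[-1] == peaks$chrom[-nrow(peaks)]
  gapw <- peaks$start[-1] - peaks$end[-nrow(peaks)]
  keep <- which(same & gapw > 0 & gapw <= max_inner_gap)
  if (!length(keep)) return(empty_enhancers(condition))
  df <- data.frame(
    chrom = peaks$chrom[keep],
    start = peaks$end[keep],
    end = peaks$start[keep + 1],
    left_start = peaks$start[keep], left_end = peaks$end[keep],
    right_start = peaks$start[keep + 1], right_end = peaks$end[keep + 1],
    gene_id = NA_character_, distance_to_tss = NA_real_,
    context = NA_character_, condition = condition
  )
  rownames(df) <- NULL
  class(df) <- c("enhancer_set", "data.frame")
  df
}

#' Remove valleys overlapping repressive H3K27me3 peaks
#'
#' A candidate is retained iff no H3K27me3 peak overlaps its valley by
#' at least one base; a book-ended repressive peak does not disqualify.
#' The optional ratio mode instead drops valleys whose me3 base coverage
#' exceeds `max_me3_fraction` of the valley length.
#'
#' @param cands An `enhancer_set` of candidates.
#' @param me3_peaks H3K27me3 peaks (`genomic_intervals`).
#' @param max_me3_fraction `0` (default) for strict absence; a value in
#'   (0, 1] switches to the coverage-ratio rule.
#' @return The retained `enhancer_set`.
#' @export
filter_repressive <- function(cands, me3_peaks, max_me3_fraction = 0) {
  if (!nrow(cands) || !nrow(me3_peaks)) return(cands)
  me3 <- merge_touching_peaks(me3_peaks)
  covered <- vapply(seq_len(nrow(cands)), function(i) {
    m <- me3[me3$chrom == cands$chrom[i], , drop = FALSE]
    if (!nrow(m)) return(0)
    ov <- pmin(m$end, cands$end[i]) - pmax(m$start, cands$start[i])
    sum(pmax(ov, 0))
  }, 0)
  if (max_me3_fraction <= 0) {
    keep <- covered == 0
  } else {
    keep <- covered / (cands$end - cands$start) <= max_me3_fraction
  }
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate enhancers with nearest gene and genomic context
#'
#' Each valley is assigned to the closest TSS (signed midpoint distance)
#' and classified as promoter/exonic/intronic/intergenic.
#'
#' @param enh An `enhancer_set`.
#' @param annotation A [gene_annotation()].
#' @param promoter_up,promoter_down Promoter window passed to
#'   [classify_context()].
#' @return The `enhancer_set` with `gene_id`, `distance_to_tss` and
#'   `context` filled in (chromosomes without genes get `NA` gene and
#'   `"intergenic"` context).
#' @export
annotate_enhancers <- function(enh, annotation, promoter_up = 2000,
                               promoter_down = 500) {
  if (!nrow(enh)) return(enh)
  for (i in seq_len(nrow(enh))) {
    region <- enh[i, c("chrom", "start", "end")]
    hit <- nearest_tss(region, annotation)
    enh$gene_id[i] <- hit$gene_id
    enh$distance_to_tss[i] <- hit$distance
    enh$context[i] <- classify_context(region, annotation,
                                       promoter_up, promoter_down)
  }
  enh
}

#' Full enhancer call for one condition
#'
#' Convenience wrapper: merge H3K27ac peaks, call <=`max_inner_gap`
#' valleys, drop H3K27me3-overlapping candidates, annotate.
#'
#' @inheritParams call_valleys
#' @param me3_peaks H3K27me3 peaks.
#' @param annotation Optional [gene_annotation()]; skipped if `NULL`.
#' @inheritParams annotate_enhancers
#' @return An annotated `enhancer_set`.
#' @export
call_enhancers <- function(ac_peaks, me3_peaks, annotation = NULL,
                           max_inner_gap = 3000, condition = NA_character_,
                           promoter_up = 2000, promoter_down = 500) {
  enh <- call_valleys(ac_peaks, max_inner_gap, condition)
  enh <- filter_repressive(enh, me3_peaks)
  if (!is.null(annotation)) {
    enh <- annotate_enhancers(enh, annotation, promoter_up, promoter_down)
  }
  enh
}

#' @export
print.enhancer_set <- function(x, ...) {
  cat(sprintf("enhancer_set: %d putative enhancer(s)\n", nrow(x)))
  if (!all(is.na(x$context))) {
    print(context_distribution(x))
  }
  invisible(x)
}

#' Compare enhancer repertoires between two conditions
#'
#' An enhancer in one condition is common iff some enhancer of the other
#' condition overlaps or book-ends its valley (gap <= 0 bp). Chains of
#' touching valleys are collapsed into connected components; each
#' component contributes one matched entry.
#'
#' @param a,b `enhancer_set`s for the two conditions.
#' @return A `condition_comparison`: list with `unique_a`, `unique_b`
#'   (enhancer_sets), `common` (data frame of components with member
#'   counts), and `counts`.
#' @export
compare_conditions <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  # cross-condition overlap edges under the 0-gap rule
  edges <- NULL
  if (na && nb) {
    hits <- lapply(seq_len(na), function(i) {
      j <- which(b$chrom == a$chrom[i] &
                   pmax(a$start[i], b$start) - pmin(a$end[i], b$end) <= 0)
      if (length(j)) cbind(i, j) else NULL
    })
    edges <- do.call(rbind, hits)
  }
  if (is.null(edges)) {
    comp_a <- rep(NA_integer_, na); comp_b <- rep(NA_integer_, nb)
  } else {
    # union-find over nodes 1..na (a) and na+1..na+nb (b)
    parent <- seq_len(na + nb)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges[r, 1]); rb <- find(edges[r, 2] + na)
      if (ra != rb) parent[rb] <- ra
    }
    roots_a <- vapply(seq_len(na), find, 0L)
    roots_b <- vapply(seq_len(nb), function(j) find(j + na), 0L)
    linked_a <- seq_len(na) %in% edges[, 1]
    linked_b <- seq_len(nb) %in% edges[, 2]
    comp_ids <- sort(unique(c(roots_a[linked_a], roots_b[linked_b])))
    comp_a <- ifelse(linked_a, match(roots_a, comp_ids), NA_integer_)
    comp_b <- ifelse(linked_b, match(roots_b, comp_ids), NA_integer_)
  }
  unique_a <- a[is.na(comp_a), , drop = FALSE]
  unique_b <- b[is.na(comp_b), , drop = FALSE]
  rownames(unique_a) <- rownames(unique_b) <- NULL
  n_comp <- length(stats::na.omit(unique(c(comp_a, comp_b))))
  common <- if (n_comp) {
    data.frame(
      component = seq_len(n_comp),
      n_a = as.integer(table(factor(comp_a, levels = seq_len(n_comp)))),
      n_b = as.integer(table(factor(comp_b, levels = seq_len(n_comp)))),
      chrom = vapply(seq_len(n_comp), function(k) {
        c(a$chrom[which(comp_a == k)], b$chrom[which(comp_b == k)])[1]
      }, ""),
      start = vapply(seq_len(n_comp), function(k) {
        min(c(a$start[which(comp_a == k)], b$start[which(comp_b == k)]))
      }, 0),
      end = vapply(seq_len(n_comp), function(k) {
        max(c(a$end[which(comp_a == k)], b$end[which(comp_b == k)]))
      }, 0)
    )
  } else {
    data.frame(component = integer(0), n_a = integer(0), n_b = integer(0),
               chrom = character(0), start = numeric(0), end = numeric(0))
  }
  structure(list(
    unique_a = unique_a, unique_b = unique_b, common = common,
    membership_a = comp_a, membership_b = comp_b,
    counts = c(unique_a = nrow(unique_a), unique_b = nrow(unique_b),
               common = n_comp)
  ), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("condition_comparison\n")
  cat(sprintf("  unique to A: %d\n  unique to B: %d\n  common components: %d\n",
              x$counts[["unique_a"]], x$counts[["unique_b"]],
              x$counts[["common"]]))
  invisible(x)
}

#' Genomic-context distribution of an enhancer set
#'
#' @param enh An annotated `enhancer_set`.
#' @return Named integer vector over promoter, exonic, intronic,
#'   intergenic, summing to `nrow(enh)`.
#' @export
context_distribution <- function(enh) {
  lv <- c("promoter", "exonic", "intronic", "intergenic")
  if (nrow(enh) && anyNA(enh$context)) {
    stop("enhancer set contains unannotated enhancers")
  }
  tab <- table(factor(enh$context, levels = lv))
  out <- as.integer(tab)
  names(out) <- lv
  out
}
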