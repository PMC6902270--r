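# Genomic intervals: 0-based half-open spans, stored as plain data frames
# with columns chrom, start, end, name, score, strand. BED is the native
# convention; GFF3 (1-based closed) is converted at the parser boundary.

#' Construct a set of genomic intervals
#'
#' Intervals are 0-based, half-open `[start, end)` spans on named
#' chromosomes, the atom of all peak, enhancer and annotation work in
#' this package.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end` per record.
#' @param name Optional feature names (default `"."`).
#' @param score Optional numeric scores (default `NA`).
#' @param strand Strand per record, one of `"+"`, `"-"`, `"."`.
#' @return A `genomic_intervals` data frame with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`.
#' @examples
#' gi <- genomic_intervals("chr1", c(100, 400), c(200, 600))
#' interval_width(gi)
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = NA_real_,
                              strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' @keywords internal
validate_intervals <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("interval %d: start (%s) must be < end (%s)",
                 bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

#' Interval widths
#' @param x A `genomic_intervals` data frame.
#' @return Integer vector of `end - start`.
#' @export
interval_width <- function(x) x$end - x$start

#' Interval midpoints
#'
#' The anchor used for nearest-TSS assignment and genomic-context
#' classification; `floor((start + end) / 2)`.
#' @param x A `genomic_intervals` data frame.
#' @return Integer vector of midpoint base positions.
#' @export
interval_midpoint <- function(x) floor((x$start + x$end) / 2)

#' @export
print.genomic_intervals <- function(x, ...) {
  cat(sprintf("genomic_intervals: %d interval(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

# ---- BED ----

#' Read a BED file (3-6 columns)
#'
#' Coordinates are kept verbatim (BED is already 0-based half-open).
#' Missing name/score/strand columns are filled with `"."`, `NA`, `"."`.
#'
#' @param path Path to a tab-separated BED3-BED6 file without header.
#' @return A `genomic_intervals` data frame in file order.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 which(nf < 3)[1]))
  }
  get <- function(i, default) {
    vapply(fields, function(f) {
      if (length(f) >= i) f[i] else default
    }, NA_character_)
  }
  start <- suppressWarnings(as.numeric(get(2, NA_character_)))
  end <- suppressWarnings(as.numeric(get(3, NA_character_)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("BED parse error at line %d: non-numeric coordinate", bad))
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("BED validation error at line %d: start >= end", bad))
  }
  score <- suppressWarnings(as.numeric(get(5, NA_character_)))
  strand <- get(6, ".")
  strand[!strand %in% c("+", "-")] <- "."
  genomic_intervals(get(1, NA_character_), start, end, name = get(4, "."),
                    score = score, strand = strand)
}

#' Write intervals as BED6
#'
#' Plain-integer coordinates, LF line endings; lossless round-trip with
#' [read_bed()] for columns 1-6.
#'
#' @param x A `genomic_intervals` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  score <- ifelse(is.na(x$score), "0", fmt_num(x$score))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), x$name, score, x$strand)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# ---- bedGraph / signal tracks ----

#' Construct a signal track
#'
#' A per-chromosome run-length coverage representation: sorted,
#' non-overlapping `[start, end)` runs each carrying a non-negative read
#' density.
#'
#' @param chrom,start,end,value Parallel vectors of runs.
#' @return A `signal_track`: a named list (one element per chromosome) of
#'   data frames with columns `start`, `end`, `value`, sorted by `start`.
#' @export
signal_track <- function(chrom = character(0), start = numeric(0),
                         end = numeric(0), value = numeric(0)) {
  if (any(start >= end)) stop("signal run with start >= end")
  if (any(value < 0)) stop("signal value must be non-negative")
  track <- lapply(split(data.frame(start = as.numeric(start),
                                   end = as.numeric(end),
                                   value = as.numeric(value)),
                        as.character(chrom)),
                  function(d) {
                    d <- d[order(d$start, d$end), , drop = FALSE]
                    rownames(d) <- NULL
                    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
                      stop("overlapping runs in signal track")
                    }
                    d
                  })
  structure(track, class = "signal_track")
}

#' Read a 4-column bedGraph file into a signal track
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @return A [signal_track()]. Overlapping runs or negative values are
#'   validation errors.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (!length(lines)) return(signal_track())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    stop(sprintf("bedGraph parse error at line %d: fewer than 4 columns",
                 which(lengths(fields) < 4)[1]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4, byrow = TRUE)
  value <- as.numeric(m[, 4])
  if (any(value < 0)) {
    stop(sprintf("bedGraph validation error at line %d: negative value",
                 which(value < 0)[1]))
  }
  signal_track(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]), value)
}

#' Write a signal track as bedGraph
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- unlist(lapply(names(track), function(ch) {
    d <- track[[ch]]
    sprintf("%s\t%d\t%d\t%s", ch, as.integer(d$start), as.integer(d$end),
            fmt_num(d$value))
  }))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), %d run(s)\n",
              length(x), sum(vapply(x, nrow, 0L))))
  invisible(x)
}

# ---- gene annotation ----

#' Construct a gene annotation
#'
#' Holds gene bodies with strand-aware transcription start sites and an
#' exon table. The TSS sits at `start` for `+` genes and at `end - 1`
#' for `-` genes (0-based).
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (strand must be `+` or `-`).
#' @param exons Optional data frame with columns `gene_id`, `chrom`,
#'   `start`, `end`; exons must lie within their gene body.
#' @return A `gene_annotation` object: list with elements `genes`
#'   (including a computed `tss` column) and `exons`.
#' @export
gene_annotation <- function(genes, exons = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene without strand: TSS undefined")
  }
  if (any(genes$start >= genes$end)) stop("gene body with start >= end")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  rownames(genes) <- NULL
  if (is.null(exons)) {
    exons <- data.frame(gene_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0))
  } else {
    exons <- as.data.frame(exons, stringsAsFactors = FALSE)
    idx <- match(exons$gene_id, genes$gene_id)
    if (anyNA(idx)) stop("exon with unknown gene_id")
    if (any(exons$start < genes$start[idx] | exons$end > genes$end[idx])) {
      stop("exon outside its gene body")
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d gene(s), %d exon(s)\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Read gene annotations from BED12 or GFF3
#'
#' BED12 blocks become exons; GFF3 `gene` and `exon` features are used
#' (exons are tied to genes via the `Parent`/`ID` chain or gene_id
#' attribute), with 1-based closed GFF3 coordinates converted to 0-based
#' half-open on input.
#'
#' @param path Annotation file path.
#' @param format `"bed12"` or `"gff3"`.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path, format = c("bed12", "gff3")) {
  format <- match.arg(format)
  if (format == "bed12") {
    read_annotation_bed12(path)
  } else {
    read_annotation_gff3(path)
  }
}

#' @keywords internal
read_annotation_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12)) {
    stop(sprintf("BED12 parse error at line %d: fewer than 12 columns",
                 which(lengths(fields) < 12)[1]))
  }
  genes <- exons <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    start <- as.numeric(f[2]); end <- as.numeric(f[3])
    if (!f[6] %in% c("+", "-")) {
      stop(sprintf("BED12 line %d: gene without strand, TSS undefined", i))
    }
    genes[[i]] <- data.frame(gene_id = f[4], chrom = f[1], start = start,
                             end = end, strand = f[6])
    sizes <- as.numeric(strsplit(f[11], ",")[[1]])
    offs <- as.numeric(strsplit(f[12], ",")[[1]])
    exons[[i]] <- data.frame(gene_id = f[4], chrom = f[1],
                             start = start + offs, end = start + offs + sizes)
  }
  gene_annotation(do.call(rbind, genes), do.call(rbind, exons))
}

#' @keywords internal
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(gr)
  is_gene <- tolower(meta$type) == "gene"
  if (!any(is_gene)) stop("GFF3 contains no gene features")
  gid <- function(d) {
    id <- if ("ID" %in% names(d)) d$ID else NA
    if ("gene_id" %in% names(d)) id <- ifelse(is.na(id), d$gene_id, id)
    if ("Name" %in% names(d)) id <- ifelse(is.na(id), d$Name, id)
    as.character(id)
  }
  g <- meta[is_gene, , drop = FALSE]
  if (any(!as.character(g$strand) %in% c("+", "-"))) {
    stop("GFF3 gene without strand: TSS undefined")
  }
  genes <- data.frame(gene_id = gid(g), chrom = as.character(g$seqnames),
                      start = g$start - 1, end = g$end,
                      strand = as.character(g$strand))
  is_exon <- tolower(meta$type) == "exon"
  exons <- NULL
  if (any(is_exon)) {
    e <- meta[is_exon, , drop = FALSE]
    parent <- if ("Parent" %in% names(e)) {
      vapply(e$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
    } else gid(e)
    keep <- parent %in% genes$gene_id
    if (any(keep)) {
      exons <- data.frame(gene_id = parent[keep],
                          chrom = as.character(e$seqnames)[keep],
                          start = e$start[keep] - 1, end = e$end[keep])
    }
  }
  gene_annotation(genes, exons)
}

# ---- interval algebra ----

#' Gap between two intervals
#'
#' `max(a.start, b.start) - min(a.end, b.end)`: negative when the
#' intervals share bases, zero when book-ended, positive when separated,
#' `NA` on different chromosomes. A 0 bp gap is the overlap rule used
#' for the common-enhancer comparison.
#'
#' @param a,b Single-row `genomic_intervals` (or lists with `chrom`,
#'   `start`, `end`).
#' @return Signed gap in bp, or `NA` if the chromosomes differ.
#' @examples
#' a <- genomic_intervals("chr1", 100, 200)
#' b <- genomic_intervals("chr1", 200, 300)
#' interval_gap(a, b)  # 0: book-ended
#' @export
interval_gap <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(NA_real_)
  max(a$start[1], b$start[1]) - min(a$end[1], b$end[1])
}

#' Nearest transcription start site
#'
#' Assigns a region to the gene whose TSS is closest to the region's
#' midpoint on the same chromosome. Ties go to the smaller TSS
#' coordinate, then the lexicographically smaller `gene_id`, so output
#' is deterministic.
#'
#' @param region Single-row `genomic_intervals`.
#' @param annotation A [gene_annotation()].
#' @param anchor `"midpoint"` (default) or `"edge"`: distance measured
#'   from the region midpoint or from its nearest edge.
#' @return List with `gene_id` (NA if no gene on the chromosome) and
#'   `distance` (signed bp; negative when the TSS lies left of the
#'   anchor).
#' @export
nearest_tss <- function(region, annotation, anchor = c("midpoint", "edge")) {
  anchor <- match.arg(anchor)
  g <- annotation$genes
  g <- g[g$chrom == region$chrom[1], , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance = NA_real_))
  if (anchor == "midpoint") {
    mid <- floor((region$start[1] + region$end[1]) / 2)
    d <- g$tss - mid
  } else {
    d <- ifelse(g$tss < region$start[1], g$tss - region$start[1],
                ifelse(g$tss >= region$end[1], g$tss - (region$end[1] - 1), 0))
  }
  ord <- order(abs(d), g$tss, g$gene_id)
  list(gene_id = g$gene_id[ord[1]], distance = d[ord[1]])
}

#' Classify the genomic context of a region
#'
#' The region midpoint decides membership with precedence
#' promoter > exonic > intronic > intergenic. The promoter window spans
#' `promoter_up` bp upstream to `promoter_down` bp downstream of a TSS,
#' oriented by gene strand.
#'
#' @param region Single-row `genomic_intervals`.
#' @param annotation A [gene_annotation()].
#' @param promoter_up,promoter_down Promoter window extent in bp
#'   (defaults 2000 upstream / 500 downstream).
#' @return One of `"promoter"`, `"exonic"`, `"intronic"`, `"intergenic"`.
#' @export
classify_context <- function(region, annotation, promoter_up = 2000,
                             promoter_down = 500) {
  stopifnot(promoter_up >= 0, promoter_down >= 0)
  g <- annotation$genes
  g <- g[g$chrom == region$chrom[1], , drop = FALSE]
  mid <- floor((region$start[1] + region$end[1]) / 2)
  if (nrow(g)) {
    pstart <- ifelse(g$strand == "+", g$tss - promoter_up,
                     g$tss + 1 - promoter_down)
    pend <- ifelse(g$strand == "+", g$tss + promoter_down,
                   g$tss + 1 + promoter_up)
    if (any(mid >= pstart & mid < pend)) return("promoter")
    e <- annotation$exons
    e <- e[e$chrom == region$chrom[1], , drop = FALSE]
    if (nrow(e) && any(mid >= e$start & mid < e$end)) return("exonic")
    if (any(mid >= g$start & mid < g$end)) return("intronic")
  }
  "intergenic"
}
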