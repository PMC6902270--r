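# Position weight matrices: log-odds scoring, exact score-distribution
# thresholds via dynamic programming, sequence scanning, and empirical
# motif-enrichment tests against shuffled-sequence nulls.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Counts are converted to probabilities with a pseudocount spread
#' according to the background, then to log2 odds against the
#' background:
#' `log2((counts + pseudocount * background) / (column_total + pseudocount) / background)`.
#'
#' @param counts 4 x width numeric matrix of base counts, rows in
#'   A, C, G, T order (a width x 4 matrix is transposed automatically).
#' @param name Motif name.
#' @param background Background base probabilities (length 4, sums
#'   to 1); default uniform.
#' @param pseudocount Positive smoothing mass (default 1).
#' @return A `pwm` object with elements `name`, `counts`, `probs`,
#'   `log_odds` (4 x width, bits), `background`, `width`, `max_score`,
#'   `min_score`.
#' @export
pwm <- function(counts, name = "motif", background = rep(0.25, 4),
                pseudocount = 1) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 4 && nrow(counts) != 4) counts <- t(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  rownames(counts) <- DNA_BASES
  totals <- colSums(counts)
  probs <- sweep(counts + pseudocount * background, 2,
                 totals + pseudocount, "/")
  lo <- log2(probs / background)
  structure(list(name = name, counts = counts, probs = probs,
                 log_odds = lo, background = background,
                 width = ncol(counts),
                 max_score = sum(apply(lo, 2, max)),
                 min_score = sum(apply(lo, 2, min))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, score range [%.3f, %.3f] bits\n",
              x$name, x$width, x$min_score, x$max_score))
  cat("consensus:", paste(DNA_BASES[apply(x$counts, 2, which.max)],
                          collapse = ""), "\n")
  invisible(x)
}

#' Read JASPAR-style pfm count matrices
#'
#' Accepts the JASPAR pfm layout: a `>name` header followed by four
#' rows, either bare numbers or `A [ 1 2 3 ]` style; multiple records
#' per file.
#'
#' @param path Path to a pfm file.
#' @param background,pseudocount Passed to [pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) stop("no '>' headers found in pfm file")
  ends <- c(starts[-1] - 1, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    name <- strsplit(header, "\\s+")[[1]]
    name <- paste(name[name != ""], collapse = "_")
    body <- lines[(starts[i] + 1):ends[i]]
    if (length(body) < 4) stop(sprintf("matrix '%s': expected 4 rows", name))
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      stop(sprintf("matrix '%s': ragged rows", name))
    }
    out[[name]] <- pwm(do.call(rbind, rows), name = name,
                       background = background, pseudocount = pseudocount)
  }
  out
}

#' Synthetic AP1 (Jun/Fos) test-fixture matrix
#'
#' A consensus-built TGA(C/G)TCA count matrix used by the test suite and
#' the synthetic-data generator. It is a synthetic fixture shaped like
#' the canonical AP1 TPA-response element, not a measured matrix; supply
#' JASPAR matrices via [read_jaspar()] for real analyses.
#'
#' @inheritParams pwm
#' @return A `pwm` named `"AP1_fixture"`.
#' @export
ap1_fixture_pwm <- function(background = rep(0.25, 4), pseudocount = 1) {
  cons <- c("T", "G", "A", "S", "T", "C", "A")  # S = C or G
  counts <- matrix(1, 4, length(cons), dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(cons)) {
    if (cons[j] == "S") {
      counts[c("C", "G"), j] <- 48.5
    } else {
      counts[cons[j], j] <- 97
    }
  }
  pwm(counts, name = "AP1_fixture", background = background,
      pseudocount = pseudocount)
}

#' Exact score threshold for a scan p-value
#'
#' Computes the full distribution of the log-odds score of a random
#' background-distributed word by dynamic programming over the score
#' values rescaled to an integer grid (1e-3 bits per unit), and returns
#' the smallest attainable score `s` with `P(score >= s) <= p`. When
#' even the top-scoring words jointly exceed `p` (possible for short or
#' degenerate motifs), the maximum attainable score is returned with a
#' warning — the strictest threshold the matrix admits. Exact up to the
#' grid resolution for widths up to 25.
#'
#' @param pwm A [pwm()].
#' @param p Target p-value in (0, 1).
#' @param scale Grid resolution in bits per unit (default 1e-3).
#' @return Threshold in bits.
#' @export
score_threshold <- function(pwm, p, scale = 1e-3) {
  if (p <= 0 || p >= 1) {
    if (p == 1) return(pwm$min_score)
    stop("p must be in (0, 1]")
  }
  if (pwm$width > 25) {
    stop("PWM wider than 25: exact score distribution too wide; ",
         "scan with an explicit bit threshold instead")
  }
  q <- round(pwm$log_odds / scale)
  colmin <- apply(q, 2, min)
  range_total <- sum(apply(q, 2, max) - colmin)
  dist <- c(1, numeric(range_total))
  filled <- 0L
  for (j in seq_len(pwm$width)) {
    newd <- numeric(range_total + 1)
    for (b in 1:4) {
      off <- q[b, j] - colmin[j]
      idx <- seq_len(filled + 1L)
      newd[idx + off] <- newd[idx + off] + dist[idx] * pwm$background[b]
    }
    dist <- newd
    filled <- filled + max(q[, j]) - colmin[j]
  }
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(dist > 0 & tail_p <= p)  # attainable scores only
  if (!length(ok)) {
    ok <- max(which(dist > 0))
    warning(sprintf(
      "requested p (%g) below the matrix's minimum attainable tail (%g); using the maximum attainable score",
      p, tail_p[ok]))
  }
  # half a grid unit per column of slack so boundary words whose exact
  # (unquantised) score sits just below the grid value are admitted
  (min(ok) - 1L + sum(colmin)) * scale - pwm$width * scale / 2
}

# Log-odds scores of every window of an integer-coded sequence on one
# strand; NA where the window contains an ambiguous base.
#' @keywords internal
window_scores <- function(vint, lo) {
  w <- ncol(lo)
  n <- length(vint) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    sc <- sc + lo[j * 4L - 4L + vint[j:(j + n - 1L)]]
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Reports every window position and strand whose log-odds score
#' reaches the threshold. The reverse strand is scored on the reverse
#' complement; all coordinates are 0-based on the forward strand.
#' Windows containing non-ACGT bases are skipped.
#'
#' @param seq A DNA string (A/C/G/T/N).
#' @param pwm A [pwm()].
#' @param threshold Score threshold in bits (e.g. from
#'   [score_threshold()]).
#' @return Data frame of hits: `start`, `end` (0-based half-open),
#'   `strand`, `score`.
#' @export
scan_pwm <- function(seq, pwm, threshold) {
  vint <- dna_to_int(seq)
  lo <- pwm$log_odds
  lo_rc <- lo[4:1, ncol(lo):1, drop = FALSE]
  fwd <- window_scores(vint, lo)
  rev_ <- window_scores(vint, lo_rc)
  hit_f <- which(!is.na(fwd) & fwd >= threshold)
  hit_r <- which(!is.na(rev_) & rev_ >= threshold)
  out <- data.frame(
    start = c(hit_f, hit_r) - 1L,
    end = c(hit_f, hit_r) - 1L + pwm$width,
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rev_[hit_r])
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

# Per-sequence Clover-style raw statistic: log of the average likelihood
# ratio (2^score) over all windows on both strands.
#' @keywords internal
sequence_lr_stat <- function(seq, pwm) {
  vint <- dna_to_int(seq)
  lo <- pwm$log_odds
  sc <- c(window_scores(vint, lo),
          window_scores(vint, lo[4:1, ncol(lo):1, drop = FALSE]))
  sc <- sc[!is.na(sc)]
  if (!length(sc)) return(NA_real_)
  m <- max(sc)
  m * log(2) + log(mean(2^(sc - m)))
}

#' @keywords internal
shuffle_seq <- function(seq, method = c("mono", "di")) {
  method <- match.arg(method)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (method == "mono") return(paste(sample(v), collapse = ""))
  # dinucleotide-preserving shuffle by rejection-sampled Euler walk
  n <- length(v)
  if (n < 3) return(seq)
  for (attempt in 1:200) {
    edges <- split(v[-1], v[-n])
    edges <- lapply(edges, sample)
    ptr <- lapply(edges, function(e) 1L)
    out <- character(n)
    out[1] <- v[1]
    ok <- TRUE
    for (i in 2:n) {
      cur <- out[i - 1]
      k <- ptr[[cur]]
      if (is.null(edges[[cur]]) || k > length(edges[[cur]])) { ok <- FALSE; break }
      out[i] <- edges[[cur]][k]
      ptr[[cur]] <- k + 1L
    }
    if (ok) return(paste(out, collapse = ""))
  }
  paste(sample(v), collapse = "")
}

#' Shuffle-null motif enrichment of a sequence set
#'
#' The observed statistic is the mean over sequences of the log average
#' likelihood ratio under the PWM (all windows, both strands). The null
#' is built by shuffling each sequence independently
#' (composition-preserving mononucleotide shuffle by default) in each of
#' `n_shuffles` replicates; the empirical p-value uses the add-one rule
#' `(1 + #{null >= observed}) / (1 + n_shuffles)` and is therefore never
#' exactly 0.
#'
#' @param seqs Character vector of DNA sequences.
#' @param pwm A [pwm()].
#' @param n_shuffles Number of shuffle replicates (>= 99; default 1000).
#' @param seed Integer RNG seed.
#' @param method Shuffle model: `"mono"` (default) or `"di"`
#'   (dinucleotide-preserving).
#' @return An `enrichment_result`: list with `pwm_name`,
#'   `observed_stat`, `null_stats`, `p_value`.
#' @export
shuffle_enrichment <- function(seqs, pwm, n_shuffles = 1000, seed,
                               method = c("mono", "di")) {
  method <- match.arg(method)
  if (n_shuffles < 99) stop("n_shuffles must be at least 99")
  if (!length(seqs)) stop("empty sequence set")
  obs_each <- vapply(seqs, sequence_lr_stat, 0, pwm = pwm,
                     USE.NAMES = FALSE)
  if (all(is.na(obs_each))) {
    stop("all sequences shorter than the PWM width")
  }
  observed <- mean(obs_each, na.rm = TRUE)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(r) {
      mean(vapply(seqs, function(s) {
        sequence_lr_stat(shuffle_seq(s, method), pwm)
      }, 0, USE.NAMES = FALSE), na.rm = TRUE)
    }, 0)
  })
  structure(list(pwm_name = pwm$name, observed_stat = observed,
                 null_stats = null_stats,
                 p_value = (1 + sum(null_stats >= observed)) /
                   (1 + n_shuffles)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result '%s': observed %.4f, p = %.4g (%d nulls)\n",
              x$pwm_name, x$observed_stat, x$p_value, length(x$null_stats)))
  invisible(x)
}

#' Differential motif enrichment between two sequence sets
#'
#' For each PWM the statistic is the difference of mean per-sequence log
#' average likelihood ratios, set A minus set B. The null re-splits the
#' pooled sequences at random into the original set sizes `n_shuffles`
#' times (per-sequence statistics are computed once, so re-splitting is
#' exact and cheap). One-sided p-values (A enriched over B) get a
#' Bonferroni-style e-value `p * #PWMs`, flagged at `e <= 0.05`.
#'
#' @param set_a,set_b Character vectors of DNA sequences.
#' @param pwms List of [pwm()] objects.
#' @param n_shuffles Number of null re-splits (default 1000).
#' @param seed Integer RNG seed.
#' @param e_threshold Significance gate on the e-value (default 0.05).
#' @return Data frame with one row per PWM: `pwm`, `stat_a`, `stat_b`,
#'   `statistic`, `p_value`, `e_value`, `significant`.
#' @export
differential_motif_enrichment <- function(set_a, set_b, pwms,
                                          n_shuffles = 1000, seed,
                                          e_threshold = 0.05) {
  if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
  if (!is.list(pwms) || inherits(pwms, "pwm")) pwms <- list(pwms)
  na <- length(set_a)
  splits <- with_seed(seed, {
    lapply(seq_len(n_shuffles), function(r) sample.int(na + length(set_b), na))
  })
  rows <- lapply(pwms, function(m) {
    sa <- vapply(set_a, sequence_lr_stat, 0, pwm = m, USE.NAMES = FALSE)
    sb <- vapply(set_b, sequence_lr_stat, 0, pwm = m, USE.NAMES = FALSE)
    obs <- mean(sa, na.rm = TRUE) - mean(sb, na.rm = TRUE)
    pooled <- c(sa, sb)
    nulls <- vapply(splits, function(idx) {
      mean(pooled[idx], na.rm = TRUE) - mean(pooled[-idx], na.rm = TRUE)
    }, 0)
    p <- (1 + sum(nulls >= obs)) / (1 + n_shuffles)
    data.frame(pwm = m$name, stat_a = mean(sa, na.rm = TRUE),
               stat_b = mean(sb, na.rm = TRUE), statistic = obs,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$e_value <- pmin(out$p_value * length(pwms), Inf)
  out$significant <- out$e_value <= e_threshold
  rownames(out) <- NULL
  out
}
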