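# Read-density aggregation around anchors (TSSs, enhancer centres, motif
# sites) and k-means clustering of motif-centred signal matrices.

#' Extract an anchor-by-bin signal matrix
#'
#' For each length-1 anchor, the window `[anchor - window, anchor +
#' window)` is cut into `2 * window / bin_size` bins and each bin gets
#' the length-weighted mean track value over its bases (uncovered bases
#' count as 0). Minus-strand anchors have their bins reversed so that
#' "downstream" is always to the right. Anchors whose window leaves the
#' covered part of the chromosome are zero-padded and flagged.
#'
#' @param track A [signal_track()].
#' @param anchors `genomic_intervals` of width 1 (anchor points with
#'   strand).
#' @param window Half-width in bp (default 5000).
#' @param bin_size Bin width in bp (default 50); must divide `window`.
#' @return A `profile_matrix`: list with `values` (anchors x bins),
#'   `anchors`, `window`, `bin_size`, and `clipped` (logical per anchor).
#' @export
extract_matrix <- function(track, anchors, window = 5000, bin_size = 50) {
  if (window %% bin_size != 0) stop("window must be divisible by bin_size")
  if (nrow(anchors) && any(anchors$end - anchors$start != 1)) {
    stop("anchors must be length-1 intervals")
  }
  nbins <- as.integer(2 * window / bin_size)
  vals <- matrix(0, nrow(anchors), nbins)
  clipped <- logical(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    lo <- anchors$start[i] - window
    hi <- anchors$start[i] + window
    clipped[i] <- lo < 0
    runs <- track[[ch]]
    row <- numeric(nbins)
    if (!is.null(runs) && nrow(runs)) {
      sel <- runs[runs$end > lo & runs$start < hi, , drop = FALSE]
      for (r in seq_len(nrow(sel))) {
        s <- max(sel$start[r], lo, 0); e <- min(sel$end[r], hi)
        if (e <= s) next
        b0 <- floor((s - lo) / bin_size) + 1L
        b1 <- floor((e - 1 - lo) / bin_size) + 1L
        for (b in b0:b1) {
          bs <- lo + (b - 1L) * bin_size; be <- bs + bin_size
          row[b] <- row[b] + (min(e, be) - max(s, bs)) * sel$value[r]
        }
      }
    }
    row <- row / bin_size
    if (anchors$strand[i] == "-") row <- rev(row)
    vals[i, ] <- row
  }
  structure(list(values = vals, anchors = anchors, window = window,
                 bin_size = bin_size, clipped = clipped),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d anchor(s) x %d bin(s) (+/- %d bp, %d bp bins)\n",
              nrow(x$values), ncol(x$values), x$window, x$bin_size))
  invisible(x)
}

#' Average signal profile across anchors
#'
#' Column means of a profile matrix: the metagene/metaprofile curve
#' (e.g. the peak-dip-peak acetylation shape around active TSSs).
#'
#' @param matrix A `profile_matrix`.
#' @return Numeric vector of per-bin mean densities.
#' @export
metaprofile <- function(matrix) {
  if (!nrow(matrix$values)) stop("empty profile matrix")
  colMeans(matrix$values)
}

#' @keywords internal
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

#' Cluster anchor profiles with seeded k-means
#'
#' Lloyd k-means with k-means++ initialisation, 10 restarts, up to 300
#' iterations; deterministic given `seed`. Rows are ordered within
#' clusters by row sum (descending) for heatmap output.
#'
#' @param matrix A `profile_matrix`.
#' @param k Number of clusters (default 5).
#' @param seed Integer RNG seed (required for reproducibility).
#' @param nstart Restarts (default 10).
#' @param normalize Per-row max-normalisation before clustering
#'   (default `FALSE`).
#' @return A `cluster_result`: list with `labels` (1..k per anchor),
#'   `centroids` (k x bins), `inertia` (within-cluster sum of squares),
#'   `order` (row order for heatmaps), `k`, `seed`.
#' @export
cluster_profiles <- function(matrix, k = 5, seed, nstart = 10,
                             normalize = FALSE) {
  x <- matrix$values
  if (k < 1 || k > nrow(x)) stop("k must be between 1 and the anchor count")
  if (normalize) {
    mx <- apply(x, 1, max)
    x <- x / ifelse(mx > 0, mx, 1)
  }
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      init <- kmeanspp_centers(x, k)
      f <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = 300,
                      algorithm = "Lloyd")
      )
      if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
    }
    best
  })
  ord <- order(fit$cluster, -rowSums(matrix$values))
  structure(list(labels = fit$cluster, centroids = fit$centers,
                 inertia = fit$tot.withinss, order = ord, k = k,
                 seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d, inertia = %.4g\n", x$k, x$inertia))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Plot a metaprofile curve
#'
#' @param x A `profile_matrix`.
#' @param ... Passed to [graphics::plot()].
#' @return The per-bin means, invisibly.
#' @export
plot.profile_matrix <- function(x, ...) {
  mp <- metaprofile(x)
  pos <- seq(-x$window + x$bin_size / 2, x$window - x$bin_size / 2,
             by = x$bin_size)
  graphics::plot(pos, mp, type = "l", xlab = "position relative to anchor (bp)",
                 ylab = "mean read density", ...)
  invisible(mp)
}
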