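# Multiplexed count analysis: nCounter-style normalisation, fold-change
# / t-test response calls, cycloheximide direct-target classification,
# and the enhancer-associated expression comparison.

#' Construct a count table
#'
#' @param counts Numeric probes x samples matrix with probe rownames.
#' @param probe_class Character vector per probe, one of `endogenous`,
#'   `positive`, `negative`, `housekeeping`.
#' @param condition Condition label per sample.
#' @param replicate Replicate index per sample.
#' @return A `count_table`: list with `counts`, `probe_class`,
#'   `condition`, `replicate`, `normalized` flag.
#' @export
count_table <- function(counts, probe_class, condition, replicate) {
  counts <- as.matrix(counts)
  stopifnot(length(probe_class) == nrow(counts),
            length(condition) == ncol(counts),
            length(replicate) == ncol(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  ok <- c("endogenous", "positive", "negative", "housekeeping")
  if (any(!probe_class %in% ok)) stop("unknown probe class")
  colnames(counts) <- sprintf("%s:%d", condition, as.integer(replicate))
  structure(list(counts = counts, probe_class = as.character(probe_class),
                 condition = as.character(condition),
                 replicate = as.integer(replicate), normalized = FALSE),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d probes x %d samples (%s)%s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", "),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Read a count table from TSV
#'
#' First column probe name, second column probe class, remaining
#' columns samples with `condition:replicate` headers.
#'
#' @param path TSV path.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- colnames(d)[-(1:2)]
  parts <- strsplit(hdr, ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("sample headers must be condition:replicate")
  }
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(m) <- d[[1]]
  count_table(m, d[[2]],
              vapply(parts, `[`, "", 1),
              as.integer(vapply(parts, `[`, "", 2)))
}

#' Write a count table as TSV
#' @param ct A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(ct, path) {
  d <- data.frame(probe = rownames(ct$counts), class = ct$probe_class,
                  ct$counts, check.names = FALSE)
  colnames(d)[-(1:2)] <- sprintf("%s:%d", ct$condition, ct$replicate)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalise a count table
#'
#' Vendor-style three-step scheme, each step toggleable: (1) per-sample
#' lane scaling by the ratio of the grand geometric mean of positive
#' probes to the sample's positive geometric mean; (2) content scaling
#' likewise from housekeeping probes; (3) background subtraction of
#' `mean + 2*sd` of the sample's negative probes, floored at 1.
#'
#' @param ct A [count_table()].
#' @param positive,housekeeping,background Logical toggles for the three
#'   steps (all `TRUE` by default).
#' @return The normalised (real-valued) `count_table`.
#' @export
normalize_counts <- function(ct, positive = TRUE, housekeeping = TRUE,
                             background = TRUE) {
  counts <- ct$counts
  if (positive) {
    if (!any(ct$probe_class == "positive")) {
      stop("missing probe class: positive")
    }
    gm <- apply(counts[ct$probe_class == "positive", , drop = FALSE],
                2, geomean)
    counts <- sweep(counts, 2, geomean(gm) / gm, "*")
  }
  if (housekeeping) {
    if (!any(ct$probe_class == "housekeeping")) {
      stop("missing probe class: housekeeping")
    }
    gm <- apply(counts[ct$probe_class == "housekeeping", , drop = FALSE],
                2, geomean)
    counts <- sweep(counts, 2, geomean(gm) / gm, "*")
  }
  if (background) {
    if (!any(ct$probe_class == "negative")) {
      stop("missing probe class: negative")
    }
    neg <- counts[ct$probe_class == "negative", , drop = FALSE]
    bg <- apply(neg, 2, function(v) mean(v) + 2 * stats::sd(v))
    counts <- pmax(sweep(counts, 2, bg, "-"), 1)
  }
  out <- ct
  out$counts <- counts
  out$normalized <- TRUE
  out
}

#' Threshold presets for response calling
#'
#' `"figure"`: fold change >= 1.5 up, <= 0.25 down (figure-legend
#' thresholds); `"methods"`: >= 1.25 up, <= 0.75 down (methods-section
#' thresholds). Both pair with p <= 0.05.
#'
#' @param preset `"figure"` or `"methods"`.
#' @return Named vector `c(up = ..., down = ...)`.
#' @export
threshold_preset <- function(preset = c("figure", "methods")) {
  preset <- match.arg(preset)
  if (preset == "figure") c(up = 1.5, down = 0.25) else c(up = 1.25, down = 0.75)
}

#' Call per-probe responses between two conditions
#'
#' Fold change is the treated/control ratio of means on the linear
#' scale; the p-value is an unpaired t-test on log2 counts (pooled
#' variance by default, which is well calibrated at 3 replicates;
#' `var_equal = FALSE` switches to Welch). A probe
#' is `up` when `fold_change >= up` and `p <= alpha` (thresholds
#' inclusive), `down` when `fold_change <= down` and `p <= alpha`,
#' otherwise `unchanged`. Only endogenous probes are tested.
#'
#' @param ct A normalised [count_table()].
#' @param treated,control Condition labels.
#' @param preset Threshold preset name (see [threshold_preset()];
#'   default `"figure"`), ignored when `up`/`down` given.
#' @param up,down Explicit fold-change thresholds.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance t-test (default `TRUE`); `FALSE`
#'   for Welch.
#' @return A `response_table` data frame: `probe`, `fold_change`,
#'   `log2_fc`, `p_value`, `call`.
#' @export
respond <- function(ct, treated, control, preset = "figure",
                    up = NULL, down = NULL, alpha = 0.05,
                    var_equal = TRUE) {
  thr <- threshold_preset(preset)
  if (is.null(up)) up <- thr[["up"]]
  if (is.null(down)) down <- thr[["down"]]
  it <- which(ct$condition == treated)
  ic <- which(ct$condition == control)
  if (length(it) < 2 || length(ic) < 2) {
    stop("both conditions need at least 2 replicates")
  }
  endo <- which(ct$probe_class == "endogenous")
  m <- ct$counts
  fc <- rowMeans(m[endo, it, drop = FALSE]) /
    rowMeans(m[endo, ic, drop = FALSE])
  lt <- log2(pmax(m[endo, it, drop = FALSE], 1e-9))
  lc <- log2(pmax(m[endo, ic, drop = FALSE], 1e-9))
  p <- vapply(seq_along(endo), function(i) {
    a <- lt[i, ]; b <- lc[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b, var.equal = var_equal)$p.value
  }, 0)
  call <- ifelse(p <= alpha & fc >= up, "up",
                 ifelse(p <= alpha & fc <= down, "down", "unchanged"))
  out <- data.frame(probe = rownames(m)[endo], fold_change = fc,
                    log2_fc = log2(fc), p_value = p, call = call,
                    row.names = NULL)
  attr(out, "thresholds") <- c(up = up, down = down, alpha = alpha)
  class(out) <- c("response_table", "data.frame")
  out
}

#' @export
print.response_table <- function(x, ...) {
  tab <- table(factor(x$call, levels = c("up", "down", "unchanged")))
  cat(sprintf("response_table: %d probes (%d up, %d down, %d unchanged)\n",
              nrow(x), tab[["up"]], tab[["down"]], tab[["unchanged"]]))
  invisible(x)
}

#' Classify direct vs indirect signalling targets
#'
#' A probe responding in the same direction both with and without
#' translation blocked (cycloheximide) is a direct transcriptional
#' target; a response seen only in the plain contrast is indirect.
#' Probes responding only under CHX are reported separately, not
#' classified.
#'
#' @param plain [respond()] table for the plain contrast (e.g. FGF vs
#'   control).
#' @param chx [respond()] table for the CHX contrast (e.g. FGF+CHX vs
#'   CHX), same probe universe.
#' @return A `target_classification` data frame: `probe`, `class` in
#'   {direct_up, direct_down, indirect_up, indirect_down,
#'   unresponsive}; attribute `chx_only` lists probes called only under
#'   CHX.
#' @export
classify_direct <- function(plain, chx) {
  if (!identical(sort(plain$probe), sort(chx$probe))) {
    stop("plain and chx tables must share the same probe universe")
  }
  chx <- chx[match(plain$probe, chx$probe), ]
  cls <- ifelse(plain$call == "up" & chx$call == "up", "direct_up",
         ifelse(plain$call == "down" & chx$call == "down", "direct_down",
         ifelse(plain$call == "up", "indirect_up",
         ifelse(plain$call == "down", "indirect_down", "unresponsive"))))
  out <- data.frame(probe = plain$probe, class = cls, row.names = NULL)
  attr(out, "chx_only") <- plain$probe[plain$call == "unchanged" &
                                         chx$call != "unchanged"]
  class(out) <- c("target_classification", "data.frame")
  out
}

#' @export
print.target_classification <- function(x, ...) {
  cat("target_classification:\n")
  print(table(factor(x$class, levels = c("direct_up", "direct_down",
                                         "indirect_up", "indirect_down",
                                         "unresponsive"))))
  invisible(x)
}

#' Overlap of response calls between two contrasts
#'
#' Venn-style set algebra on the up and down call sets of two response
#' tables (e.g. 3 h vs 6 h of treatment).
#'
#' @param r1,r2 [respond()] tables over the same probe universe.
#' @return Named integer vector: `up_both`, `up_only_1`, `up_only_2`,
#'   `down_both`, `down_only_1`, `down_only_2`.
#' @export
venn_overlap <- function(r1, r2) {
  one <- function(dir) {
    s1 <- r1$probe[r1$call == dir]
    s2 <- r2$probe[r2$call == dir]
    c(both = length(intersect(s1, s2)),
      only_1 = length(setdiff(s1, s2)),
      only_2 = length(setdiff(s2, s1)))
  }
  u <- one("up"); d <- one("down")
  c(up_both = u[["both"]], up_only_1 = u[["only_1"]],
    up_only_2 = u[["only_2"]], down_both = d[["both"]],
    down_only_1 = d[["only_1"]], down_only_2 = d[["only_2"]])
}

#' Test whether enhancer-associated genes are higher expressed
#'
#' One-sided Mann-Whitney test that transcripts with a putative active
#' enhancer have higher expression than the remaining transcripts
#' (normal approximation with tie correction; exact enumeration with a
#' warning when a group has fewer than 3 members).
#'
#' @param expression Named numeric vector: expression level per probe.
#' @param with_enhancer Character vector of probes carrying an enhancer.
#' @return List with `p_value`, `median_with`, `median_without`,
#'   `n_with`, `n_without`.
#' @export
enhancer_expression_test <- function(expression, with_enhancer) {
  grp <- names(expression) %in% with_enhancer
  x <- expression[grp]; y <- expression[!grp]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    p <- 0.5  # fully tied: no evidence either way
  } else if (min(length(x), length(y)) < 3) {
    warning("group with fewer than 3 members: exact enumeration used")
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater",
                         exact = TRUE)$p.value)
  } else {
    p <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                            correct = TRUE)$p.value
  }
  list(p_value = p, median_with = stats::median(x),
       median_without = stats::median(y),
       n_with = length(x), n_without = length(y))
}
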