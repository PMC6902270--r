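# Count normalisation, response calling, direct-target logic and the
# enhancer expression comparison.

toy_counts <- function(m, conds = rep(c("CNT", "FGF"), each = 3)) {
  count_table(m, c(rep("endogenous", nrow(m) - 6),
                   rep("positive", 2), rep("negative", 2),
                   rep("housekeeping", 2)),
              conds, rep(1:3, length(conds) / 3))
}

test_that("normalisation restores uniformly scaled samples", {
  set.seed(181)
  base <- matrix(rep(c(500, 800, 200, 1000, 3, 2, 600, 900), 6), ncol = 6)
  rownames(base) <- sprintf("p%d", 1:8)
  ct <- toy_counts(base)
  norm <- normalize_counts(ct, background = FALSE)
  expect_equal(norm$counts, ct$counts)  # identical samples: factors 1
  doubled <- base
  doubled[, 3] <- doubled[, 3] * 2
  norm2 <- normalize_counts(toy_counts(doubled), background = FALSE)
  expect_equal(norm2$counts[, 3], norm2$counts[, 1], tolerance = 1e-9)
  expect_error(normalize_counts(count_table(base[1:2, , drop = FALSE],
                                            rep("endogenous", 2),
                                            ct$condition, ct$replicate)),
               "positive")
})

test_that("normalisation shrinks housekeeping variation across lanes", {
  set.seed(191)
  improved <- 0
  for (r in 1:20) {
    cs <- simulate_counts(300 + r, n_direct = 0, n_indirect = 0,
                          lane_sd = 0.4)
    hk <- cs$counts$probe_class == "housekeeping"
    cv <- function(m) mean(apply(m, 1, function(v) stats::sd(v) / mean(v)))
    pre <- cv(cs$counts$counts[hk, ])
    post <- cv(normalize_counts(cs$counts, housekeeping = FALSE)$counts[hk, ])
    improved <- improved + (post < pre)
  }
  expect_gte(improved, 18)
})

test_that("response calls honour inclusive thresholds and degenerate input", {
  # zero variance, different means: fold change exactly at threshold -> up
  m <- rbind(flat = rep(c(100, 150), each = 3),
             same = rep(80, 6),
             ctrl = rep(c(500, 500), each = 3))
  m <- rbind(m, pos1 = 1000, pos2 = 1000, neg1 = 0, neg2 = 0,
             hk1 = 500, hk2 = 500)
  ct <- toy_counts(m)
  ct$normalized <- TRUE
  r <- respond(ct, "FGF", "CNT", up = 1.5, down = 0.25)
  expect_equal(r$call[r$probe == "flat"], "up")      # FC exactly 1.5
  expect_equal(r$fold_change[r$probe == "flat"], 1.5)
  expect_equal(r$p_value[r$probe == "same"], 1)      # no variance, no change
  expect_equal(r$call[r$probe == "same"], "unchanged")
})

test_that("response calling is antisymmetric under condition swap", {
  set.seed(201)
  cs <- simulate_counts(11)
  norm <- normalize_counts(cs$counts)
  fwd <- respond(norm, "FGF", "CNT", up = 1.5, down = 1 / 1.5)
  rev_ <- respond(norm, "CNT", "FGF", up = 1.5, down = 1 / 1.5)
  expect_equal(fwd$fold_change, 1 / rev_$fold_change, tolerance = 1e-9)
  expect_equal(fwd$p_value, rev_$p_value, tolerance = 1e-9)
  map <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_identical(unname(map[fwd$call]), rev_$call)
})

test_that("planted inductions are called at the stated strength", {
  set.seed(211)
  called_up <- replicate(20, {
    # 4-fold induction, n = 3, CV 20% (NB size 25)
    a <- stats::rnbinom(3, size = 25, mu = 800)
    b <- stats::rnbinom(3, size = 25, mu = 200)
    m <- rbind(gene = c(a, b), ctrl = rep(300, 6), pos1 = 1000, pos2 = 1000,
               neg1 = 0, neg2 = 0, hk1 = 500, hk2 = 500)
    ct <- toy_counts(m, conds = rep(c("FGF", "CNT"), each = 3))
    ct$normalized <- TRUE
    respond(ct, "FGF", "CNT")$call[1] == "up"
  })
  expect_gte(mean(called_up), 0.9)
})

test_that("direct/indirect classification follows the CHX logic", {
  mk <- function(calls) {
    structure(data.frame(probe = sprintf("p%d", seq_along(calls)),
                         fold_change = 1, log2_fc = 0, p_value = 1,
                         call = calls),
              class = c("response_table", "data.frame"))
  }
  plain <- mk(c("up", "up", "down", "unchanged", "unchanged"))
  chx <- mk(c("up", "unchanged", "down", "up", "unchanged"))
  cls <- classify_direct(plain, chx)
  expect_equal(cls$class,
               c("direct_up", "indirect_up", "direct_down",
                 "unresponsive", "unresponsive"))
  expect_equal(attr(cls, "chx_only"), "p4")
  expect_error(classify_direct(plain, mk(c("up", "up", "down"))[1:3, ]),
               "probe universe")
})

test_that("venn overlap counts conserve set sizes", {
  mk <- function(calls) {
    structure(data.frame(probe = sprintf("p%d", seq_along(calls)),
                         fold_change = 1, log2_fc = 0, p_value = 1,
                         call = calls),
              class = c("response_table", "data.frame"))
  }
  r1 <- mk(c("up", "up", "down", "unchanged"))
  expect_equal(unname(venn_overlap(r1, r1)),
               c(2L, 0L, 0L, 1L, 0L, 0L))
  r2 <- mk(c("unchanged", "down", "up", "up"))
  v <- venn_overlap(r1, r2)
  expect_equal(v[["up_both"]] + v[["up_only_1"]], sum(r1$call == "up"))
  expect_equal(v[["up_both"]] + v[["up_only_2"]], sum(r2$call == "up"))
  expect_equal(v[["down_both"]] + v[["down_only_1"]], sum(r1$call == "down"))
  set.seed(221)
  for (r in 1:25) {
    c1 <- mk(sample(c("up", "down", "unchanged"), 30, TRUE))
    c2 <- mk(sample(c("up", "down", "unchanged"), 30, TRUE))
    v <- venn_overlap(c1, c2)
    for (dir in c("up", "down")) {
      expect_equal(v[[paste0(dir, "_both")]] + v[[paste0(dir, "_only_1")]],
                   sum(c1$call == dir))
      expect_equal(v[[paste0(dir, "_both")]] + v[[paste0(dir, "_only_2")]],
                   sum(c2$call == dir))
    }
  }
})

test_that("enhancer-associated expression test behaves across regimes", {
  # fully tied values: no evidence either way
  x <- stats::setNames(rep(5, 20), sprintf("p%d", 1:20))
  expect_equal(enhancer_expression_test(x, names(x)[1:10])$p_value, 0.5)
  # planted shift is detected
  set.seed(231)
  expr <- stats::setNames(c(stats::rnorm(50, 8), stats::rnorm(200, 6)),
                          sprintf("p%d", 1:250))
  res <- enhancer_expression_test(expr, sprintf("p%d", 1:50))
  expect_lt(res$p_value, 0.01)
  expect_gt(res$median_with, res$median_without)
  # identical distributions: p has no systematic direction
  ps <- replicate(60, {
    e <- stats::setNames(stats::rnorm(60), sprintf("p%d", 1:60))
    enhancer_expression_test(e, sprintf("p%d", 1:20))$p_value
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  # tiny group: exact enumeration with a warning
  expect_warning(
    res2 <- enhancer_expression_test(
      stats::setNames(c(10, 9, 1:6), sprintf("p%d", 1:8)), c("p1", "p2")),
    "fewer than 3")
  expect_lt(res2$p_value, 0.2)
})
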