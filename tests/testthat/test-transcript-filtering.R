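test_that("expression filter cuts at 1% of the dataset-mean RPKM", {
  # 3 genes x 6 samples built so the overall mean RPKM is exactly 2.0
  vals <- rbind(
    c(4, 4, 4, 4, 4, 4),            # clearly expressed
    c(0.015, 0.01, 0, 0, 0.005, 0), # MAX 0.015 < 0.02 -> removed
    c(0.02, 0, 0, 0, 0, 0)          # MAX exactly at the cutoff -> retained
  )
  vals[1, 1] <- 4 + (2.0 * 18 - sum(vals))  # pad to mean exactly 2.0
  em <- make_em(vals, rep(c("V", "E2"), each = 3))
  res <- filter_low_expression(em)
  expect_equal(res$threshold, 0.02)
  expect_equal(rownames(res$matrix$values), c("g1", "g3"))
  expect_false(res$summaries$passed_filter[res$summaries$gene_id == "g2"])
  # an all-zero gene is removed whenever the threshold is positive
  em0 <- make_em(rbind(vals, c(0, 0, 0, 0, 0, 0)),
                 rep(c("V", "E2"), each = 3))
  expect_false(filter_low_expression(em0)$summaries$passed_filter[4])
  # degenerate dataset: everything below the (here inflated) cutoff
  em_bad <- make_em(matrix(1, 2, 4), c("V", "V", "E2", "E2"))
  expect_error(filter_low_expression(em_bad, threshold_fraction = 2),
               "all genes")
})

test_that("filtering twice equals filtering once", {
  set.seed(42)
  em <- sim_two_group(100, lfc = 0)
  em$values[1:30, ] <- em$values[1:30, ] / 1e4   # a low-expressed block
  once <- filter_low_expression(em)
  twice <- filter_low_expression(once$matrix)
  expect_equal(twice$matrix$values, once$matrix$values)
  expect_equal(twice$threshold, once$threshold)
})

test_that("baseline zeros are replaced by 0.05% of the per-gene MAX", {
  vals <- rbind(c(0, 0.3, 2, 100, 90, 80),
                c(0, 1, 1, 5, 5, 5))
  em <- make_em(vals, rep(c("V", "E2"), each = 3))
  out <- replace_vehicle_zeros(em, "V")
  expect_equal(out$values[1, 1], 0.05)        # MAX 100 -> 0.0005 * 100
  expect_equal(out$values[1, 2], 0.3)         # nonzero baseline untouched
  expect_equal(out$values[2, 1], 0.0025)      # MAX 5
  # zeros outside the baseline group stay
  vals2 <- rbind(c(1, 1, 1, 0, 4, 4))
  em2 <- make_em(vals2, rep(c("V", "E2"), each = 3))
  expect_equal(replace_vehicle_zeros(em2, "V")$values[1, 4], 0)
  # a MAX = 0 gene must have been filtered before this stage
  em3 <- make_em(rbind(c(0, 0, 0, 0, 0, 0), c(1, 1, 1, 2, 2, 2)),
                 rep(c("V", "E2"), each = 3))
  expect_error(replace_vehicle_zeros(em3, "V"), "MAX = 0")
  expect_error(replace_vehicle_zeros(em, "W"), "not present")
})

test_that("the DEG gate is literally 2-fold AND FDR < 0.05", {
  # g1: fold 4 with tiny variance -> DEG up; g2: fold 1.9 highly significant
  # but below the fold gate -> not DEG; g3: flat -> not DEG; g4: fold 4 down
  vals <- rbind(
    c(8.0, 8.1, 7.9, 2.0, 2.1, 1.9),
    c(1.9, 1.9, 1.9, 1.0, 1.0, 1.0) * 10,
    c(5, 5.1, 4.9, 5, 5.05, 4.95),
    c(3.0, 3.1, 2.9, 12.0, 12.1, 11.9)
  )
  em <- make_em(vals, rep(c("E2", "V"), each = 3))
  deg <- call_deg(em, c("E2", "V"))
  expect_equal(deg$fold_change[1], mean(vals[1, 1:3]) / mean(vals[1, 4:6]))
  expect_true(deg$is_deg[1])
  expect_equal(deg$direction[1], "up")
  expect_false(deg$is_deg[2])
  expect_true(deg$fdr_p[2] < 0.05)           # it fails only on fold
  expect_false(deg$is_deg[3])
  expect_true(deg$is_deg[4])
  expect_equal(deg$direction[4], "down")
  expect_true(all(deg$fdr_p >= deg$p_value))
  expect_error(call_deg(em, c("E2", "V"), exclude_samples = c("s4", "s5")),
               "fewer than 2")
})

test_that("vectorized contrast tests agree with the stats oracles", {
  set.seed(7)
  em <- sim_two_group(25, lfc = rep(c(0, 2), length.out = 25))
  deg <- call_deg(em, c("A", "B"), epsilon = 1e-3)
  deg_w <- call_deg(em, c("A", "B"), epsilon = 1e-3, method = "welch")
  logv <- log2(em$values + 1e-3)
  groups <- em$design$group
  for (i in c(1, 7, 13, 25)) {
    # pooled contrast = equal-variance t-test when only two groups exist
    p_pool <- stats::t.test(logv[i, groups == "A"],
                            logv[i, groups == "B"],
                            var.equal = TRUE)$p.value
    expect_equal(deg$p_value[i], p_pool, tolerance = 1e-12)
    p_welch <- stats::t.test(logv[i, groups == "A"],
                             logv[i, groups == "B"])$p.value
    expect_equal(deg_w$p_value[i], p_welch, tolerance = 1e-12)
    f_ref <- stats::oneway.test(v ~ g,
                                data.frame(v = logv[i, ], g = groups),
                                var.equal = TRUE)$p.value
    expect_equal(deg$anova_p[i], f_ref, tolerance = 1e-12)
  }
  # with three groups the error term pools across all of them
  set.seed(8)
  mu <- stats::rnorm(10, 3, 1)
  v3 <- 2^(mu + matrix(stats::rnorm(10 * 9, 0, 0.3), 10))
  em3 <- make_em(v3, rep(c("V", "E2", "M"), each = 3))
  deg3 <- call_deg(em3, c("E2", "V"))
  l3 <- log2(v3 + 1e-3)
  for (i in c(2, 9)) {
    fit <- stats::aov(y ~ g, data.frame(y = l3[i, ],
                                        g = factor(rep(c("V", "E2", "M"),
                                                       each = 3))))
    mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
    tt <- (mean(l3[i, 4:6]) - mean(l3[i, 1:3])) / sqrt(mse * (2 / 3))
    p_ref <- 2 * stats::pt(abs(tt), 6, lower.tail = FALSE)
    expect_equal(deg3$p_value[i], p_ref, tolerance = 1e-10)
  }
})

test_that("call_deg is invariant to sample and gene order and BH is monotone", {
  set.seed(11)
  em <- sim_two_group(40, lfc = rep(c(0, 1.5), 20))
  deg <- call_deg(em, c("A", "B"))
  perm_s <- sample(ncol(em$values))
  perm_g <- sample(nrow(em$values))
  em2 <- expression_matrix(em$values[perm_g, perm_s],
                           em$design[perm_s, , drop = FALSE])
  deg2 <- call_deg(em2, c("A", "B"))
  deg2 <- deg2[match(deg$gene_id, deg2$gene_id), ]
  rownames(deg2) <- NULL
  expect_equal(deg2$p_value, deg$p_value)
  expect_equal(deg2$fdr_p, deg$fdr_p)
  expect_equal(deg2$is_deg, deg$is_deg)
  ord <- order(deg$p_value)
  expect_true(all(diff(deg$fdr_p[ord]) >= -1e-12))
})

test_that("union_deg pools DEG across donors and keeps per-donor folds", {
  mk <- function(ids, deg_ids, fold = 3) {
    structure(data.frame(gene_id = ids, fold_change = fold,
                         is_deg = ids %in% deg_ids,
                         stringsAsFactors = FALSE),
              class = c("deg_table", "data.frame"))
  }
  u <- union_deg(list(d1 = mk(c("a", "b", "c"), c("a", "b")),
                      d2 = mk(c("b", "c", "d"), c("b", "c"))))
  expect_equal(u$gene_id, c("a", "b", "c"))
  expect_true(is.na(u$fold_d2[u$gene_id == "a"]))  # absent from donor 2
  expect_equal(union_deg(list(only = mk("x", "x")))$gene_id, "x")
  u2 <- union_deg(list(d1 = mk(paste0("a", 1:10), paste0("a", 1:10)),
                       d2 = mk(paste0("b", 1:7), paste0("b", 1:7))))
  expect_equal(nrow(u2), 17)
})
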