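#' Filter genes expressed below 1% of the dataset-mean RPKM
#'
#' For each gene the maximum RPKM over all samples ("MAX") is computed; genes
#' with MAX strictly below `threshold_fraction` times the mean of the entire
#' RPKM matrix (all genes x all samples, taken before filtering) are removed.
#' With the default 1% a dataset whose mean RPKM is 2.0 yields a cutoff of
#' 0.02. The applied threshold is stored as attribute `low_expr_threshold` on
#' the returned matrix and is reused if the result is filtered again, so the
#' operation is idempotent.
#'
#' @param em an [expression_matrix()].
#' @param threshold_fraction fraction of the dataset-mean RPKM (default 0.01).
#' @return a list with `matrix` (the filtered [expression_matrix()]),
#'   `summaries` (data frame `gene_id`, `max_rpkm`, `passed_filter`), and
#'   `threshold` (the absolute RPKM cutoff applied).
#' @export
filter_low_expression <- function(em, threshold_fraction = 0.01) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!nrow(em$values)) stop("empty expression matrix")
  threshold <- attr(em$values, "low_expr_threshold")
  if (is.null(threshold)) {
    threshold <- threshold_fraction * mean(em$values)
  }
  max_rpkm <- apply(em$values, 1, max)
  passed <- max_rpkm >= threshold   # strict "<" removes
  summaries <- data.frame(
    gene_id = rownames(em$values),
    max_rpkm = unname(max_rpkm),
    passed_filter = unname(passed),
    stringsAsFactors = FALSE
  )
  if (!any(passed)) stop("all genes fall below the expression filter")
  values <- em$values[passed, , drop = FALSE]
  attr(values, "low_expr_threshold") <- threshold
  out <- expression_matrix(values, em$design)
  attr(out$values, "low_expr_threshold") <- threshold
  list(matrix = out, summaries = summaries, threshold = threshold)
}

#' Replace baseline-group zeros by 0.05% of the per-gene MAX
#'
#' Zero RPKM values in baseline (vehicle) samples would make treatment/vehicle
#' fold changes undefined; each such zero is replaced by
#' `0.0005 * MAX(gene)`, where MAX is the gene's maximum RPKM over all
#' samples. Zeros in non-baseline groups are left untouched.
#'
#' @param em an [expression_matrix()].
#' @param baseline_group the group label of the vehicle/control samples.
#' @return the modified [expression_matrix()].
#' @export
replace_vehicle_zeros <- function(em, baseline_group) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!baseline_group %in% em$design$group) {
    stop("baseline group not present in design: ", baseline_group)
  }
  max_rpkm <- apply(em$values, 1, max)
  base_cols <- which(em$design$group == baseline_group)
  zero <- em$values[, base_cols, drop = FALSE] == 0
  if (any(zero & max_rpkm == 0)) {
    stop("gene with MAX = 0 reached zero replacement; filter first")
  }
  repl <- matrix(0.0005 * max_rpkm, nrow = nrow(em$values),
                 ncol = length(base_cols))
  vals <- em$values
  vals[, base_cols][zero] <- repl[zero]
  out <- expression_matrix(vals, em$design)
  attr(out$values, "low_expr_threshold") <- attr(em$values, "low_expr_threshold")
  out
}

#' Call differentially expressed genes for one contrast
#'
#' Per gene, the fold change is the ratio of arithmetic group means of
#' (zero-replaced) RPKM, `mean(A)/mean(B)`. Testing happens on
#' `log2(RPKM + epsilon)`: a one-way ANOVA is fitted across all design
#' groups, its F-test is reported as `anova_p`, and the per-contrast p-value
#' (`method = "anova"`, the default) is the pooled-variance contrast t-test
#' from that fit — the difference of the two group means over the
#' within-group mean square, on `N - k` degrees of freedom. Pooling the
#' within-group variance across all groups is what gives the test usable
#' power at typical replicate numbers (n = 3 per group leaves a Welch test
#' with as few as 2 df); `method = "welch"` is available when
#' group variances cannot be assumed equal. Contrast p-values are
#' Benjamini-Hochberg adjusted across the retained genes, and a gene is a
#' DEG when `|log2 fold| >= log2(fold_cutoff)` and the adjusted p is below
#' `fdr_cutoff` — the classic "2-fold, FDR p < 0.05" gate at the defaults.
#'
#' @param em an [expression_matrix()] (filtered and zero-replaced).
#' @param contrast character pair `c(A, B)`: fold change and test compare
#'   group A over group B.
#' @param fold_cutoff fold-change gate as a ratio (default 2).
#' @param fdr_cutoff BH-adjusted p-value gate (default 0.05).
#' @param epsilon offset added before the log2 transform (default 1e-3).
#' @param exclude_samples optional sample ids dropped before testing (e.g.
#'   PCA outliers identified upstream).
#' @param method `"anova"` (pooled-variance contrast, default) or `"welch"`.
#' @return a `deg_table` data frame: `gene_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `log2_fold`, `p_value`, `anova_p`, `fdr_p`, `is_deg`,
#'   `direction`, with the contrast stored in attribute `contrast`.
#' @export
call_deg <- function(em, contrast, fold_cutoff = 2, fdr_cutoff = 0.05,
                     epsilon = 1e-3, exclude_samples = NULL,
                     method = c("anova", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(em, "expression_matrix"), length(contrast) == 2)
  keep <- !(em$design$sample_id %in% exclude_samples)
  values <- em$values[, keep, drop = FALSE]
  design <- em$design[keep, , drop = FALSE]
  groups <- design$group
  for (g in contrast) {
    if (sum(groups == g) < 2) {
      stop("group ", g, " has fewer than 2 samples")
    }
  }
  a_cols <- groups == contrast[1]
  b_cols <- groups == contrast[2]
  mean_a <- rowMeans(values[, a_cols, drop = FALSE])
  mean_b <- rowMeans(values[, b_cols, drop = FALSE])
  fold <- mean_a / mean_b
  logv <- log2(values + epsilon)
  fit <- oneway_fit_rows(logv, groups)
  anova_p <- fit$p
  p <- if (method == "welch") {
    welch_t_rows(logv[, a_cols, drop = FALSE], logv[, b_cols, drop = FALSE])
  } else {
    contrast_t_rows(logv, fit, a_cols, b_cols)
  }
  fdr <- stats::p.adjust(p, method = "BH")
  log2_fold <- log2(fold)
  is_deg <- abs(log2_fold) >= log2(fold_cutoff) & fdr < fdr_cutoff
  is_deg[is.na(is_deg)] <- FALSE
  out <- data.frame(
    gene_id = rownames(values),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    fold_change = unname(fold), log2_fold = unname(log2_fold),
    p_value = unname(p), anova_p = unname(anova_p), fdr_p = unname(fdr),
    is_deg = unname(is_deg),
    direction = ifelse(log2_fold >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- contrast
  class(out) <- c("deg_table", class(out))
  out
}

# Row-wise Welch two-sample t-test p-values (two-sided).
welch_t_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero within-group variance: the data decide by the mean difference alone
  degen <- se2 == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  p[is.nan(p)] <- 1
  p
}

# Row-wise one-way fixed-effects ANOVA fit: F-test p plus the pooled
# within-group mean square reused by the contrast t-test.
oneway_fit_rows <- function(x, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups); n <- ncol(x)
  gm <- rowMeans(x)
  ss_between <- 0; ss_within <- 0
  for (lev in levels(groups)) {
    cols <- groups == lev
    ni <- sum(cols)
    mi <- rowMeans(x[, cols, drop = FALSE])
    ss_between <- ss_between + ni * (mi - gm)^2
    ss_within <- ss_within + rowSums((x[, cols, drop = FALSE] - mi)^2)
  }
  df_within <- n - k
  mse <- ss_within / df_within
  fstat <- (ss_between / (k - 1)) / mse
  p <- stats::pf(fstat, k - 1, df_within, lower.tail = FALSE)
  p[is.nan(p)] <- 1
  list(p = p, mse = mse, df_within = df_within)
}

# Pooled-variance contrast t-test between two groups, using the ANOVA
# within-group mean square (all groups) as the error term.
contrast_t_rows <- function(x, fit, a_cols, b_cols) {
  ma <- rowMeans(x[, a_cols, drop = FALSE])
  mb <- rowMeans(x[, b_cols, drop = FALSE])
  se <- sqrt(fit$mse * (1 / sum(a_cols) + 1 / sum(b_cols)))
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), fit$df_within, lower.tail = FALSE)
  degen <- se == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  p
}

#' Combine per-donor DEG tables into a cross-donor union
#'
#' Donors are analyzed separately (each relative to its own vehicle control);
#' this step unions the genes called DEG in any donor and carries each
#' donor's fold change alongside (`NA` where a donor did not quantify the
#' gene).
#'
#' @param per_donor named list of `deg_table` objects from [call_deg()], one
#'   per donor.
#' @return data frame `gene_id`, one `fold_<donor>` and `is_deg_<donor>`
#'   column pair per donor, and `deg_any`.
#' @export
union_deg <- function(per_donor) {
  stopifnot(is.list(per_donor), length(per_donor) >= 1)
  if (is.null(names(per_donor)) || any(!nzchar(names(per_donor)))) {
    names(per_donor) <- paste0("donor", seq_along(per_donor))
  }
  deg_ids <- sort(unique(unlist(lapply(per_donor, function(d) d$gene_id[d$is_deg]))))
  out <- data.frame(gene_id = deg_ids, stringsAsFactors = FALSE)
  for (dn in names(per_donor)) {
    d <- per_donor[[dn]]
    idx <- match(deg_ids, d$gene_id)
    out[[paste0("fold_", dn)]] <- d$fold_change[idx]
    out[[paste0("is_deg_", dn)]] <- ifelse(is.na(idx), FALSE, d$is_deg[idx])
  }
  out$deg_any <- rep(TRUE, nrow(out))
  out
}
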