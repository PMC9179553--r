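#' Derive loop anatomy: anchors and span
#'
#' A loop's span is the region between the end of the left anchor and the
#' start of the right anchor, `[end1, start2)`. Adjacent anchors yield a
#' zero-width span, flagged in `zero_span`.
#'
#' @param loops loop data frame.
#' @return data frame `loop_id`, `chrom`, anchor coordinates, `span_start`,
#'   `span_end`, `zero_span`.
#' @export
derive_loop_parts <- function(loops) {
  loops <- validate_loops(loops)
  data.frame(
    loop_id = loops$loop_id, chrom = loops$chrom,
    left_start = loops$start1, left_end = loops$end1,
    right_start = loops$start2, right_end = loops$end2,
    span_start = loops$end1, span_end = loops$start2,
    zero_span = loops$start2 == loops$end1,
    stringsAsFactors = FALSE
  )
}

#' Loops shared across donors by reciprocal anchor overlap
#'
#' A loop is shared when, across every donor set, both its left anchors and
#' its right anchors overlap by at least `anchor_overlap_bp`. Shared loops
#' take the union (default) or intersection of the matched anchors. With
#' more than two sets the sharing is folded left to right, so a shared loop
#' must have a partner in every donor.
#'
#' @param donor_loop_sets list (length >= 2) of loop data frames.
#' @param anchor_overlap_bp minimum overlap per anchor in bp (default 1).
#' @param coords `"union"` (default) or `"intersection"` anchor coordinates
#'   for the output.
#' @return a loop data frame of shared loops.
#' @export
shared_loops <- function(donor_loop_sets, anchor_overlap_bp = 1L,
                         coords = c("union", "intersection")) {
  coords <- match.arg(coords)
  stopifnot(is.list(donor_loop_sets), length(donor_loop_sets) >= 2)
  acc <- validate_loops(donor_loop_sets[[1]])
  for (k in 2:length(donor_loop_sets)) {
    acc <- shared_loops_pair(acc, validate_loops(donor_loop_sets[[k]]),
                             anchor_overlap_bp, coords)
  }
  acc
}

shared_loops_pair <- function(x, y, min_bp, coords) {
  rows <- list()
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(y))) {
      if (x$chrom[i] != y$chrom[j]) next
      l_ov <- min(x$end1[i], y$end1[j]) - max(x$start1[i], y$start1[j])
      r_ov <- min(x$end2[i], y$end2[j]) - max(x$start2[i], y$start2[j])
      if (l_ov < min_bp || r_ov < min_bp) next
      if (coords == "union") {
        s1 <- min(x$start1[i], y$start1[j]); e1 <- max(x$end1[i], y$end1[j])
        s2 <- min(x$start2[i], y$start2[j]); e2 <- max(x$end2[i], y$end2[j])
      } else {
        s1 <- max(x$start1[i], y$start1[j]); e1 <- min(x$end1[i], y$end1[j])
        s2 <- max(x$start2[i], y$start2[j]); e2 <- min(x$end2[i], y$end2[j])
      }
      if (e1 > s2) {
        warning("shared loop ", x$loop_id[i], "/", y$loop_id[j],
                " has touching anchors after merging; dropped")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        loop_id = paste0(x$loop_id[i], "|", y$loop_id[j]),
        chrom = x$chrom[i], start1 = s1, end1 = e1, start2 = s2, end2 = e2,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    new_loops(character(), character(), integer(), integer(), integer(), integer())
  if (anyDuplicated(out$loop_id)) out$loop_id <- make.unique(out$loop_id, "_")
  validate_loops(out)
}

#' Classify peak-gene interactions through chromatin loops
#'
#' Emits one record per qualifying (peak, gene, category, loop) tuple:
#'
#' * **direct** — the peak interval intersects the gene's promoter window
#'   `[TSS - promoter_halfwidth, TSS + promoter_halfwidth)`; no loop
#'   involved (`loop_id` is `NA`).
#' * **anchor_anchor** — the peak overlaps one anchor of a loop and the
#'   gene's TSS falls within the *opposite* anchor of that loop.
#' * **anchor_span** — the peak overlaps an anchor and the gene's TSS falls
#'   strictly inside that loop's span.
#' * **span_anchor** — the peak lies in the span (overlapping the span but
#'   neither anchor of that loop: anchor membership takes precedence) and
#'   the gene's TSS falls within either anchor.
#'
#' Peak membership in anchors/spans is any-overlap (>= 1 bp); gene membership
#' is TSS containment (genes are "within loop ends" when their TSS falls in
#' an anchor). A peak and a TSS sharing one anchor produce no anchor_anchor
#' record; these pairs are tabulated in the `same_anchor` attribute as a
#' diagnostic. A pair may hold several categories across loops; each tuple is
#' emitted once.
#'
#' @param peaks peak data frame.
#' @param loop_parts output of [derive_loop_parts()].
#' @param genes gene-model data frame.
#' @param promoter_halfwidth promoter half-window around the TSS in bp
#'   (default 2500).
#' @return data frame `peak_id`, `gene_id`, `category`, `loop_id`,
#'   `peak_location`, `gene_location`, sorted deterministically; attribute
#'   `same_anchor` holds the diagnostic pair table.
#' @export
classify_interactions <- function(peaks, loop_parts, genes,
                                  promoter_halfwidth = 2500L) {
  peaks <- validate_peaks(peaks); genes <- validate_genes(genes)
  recs <- list(); same_anchor <- list()
  add <- function(peak_id, gene_id, category, loop_id, ploc, gloc) {
    recs[[length(recs) + 1L]] <<- data.frame(
      peak_id = peak_id, gene_id = gene_id, category = category,
      loop_id = loop_id, peak_location = ploc, gene_location = gloc,
      stringsAsFactors = FALSE)
  }
  # direct: peak overlaps the promoter window of a gene
  for (i in seq_len(nrow(peaks))) {
    g_idx <- which(genes$chrom == peaks$chrom[i] &
                     genes$tss - promoter_halfwidth < peaks$end[i] &
                     genes$tss + promoter_halfwidth > peaks$start[i])
    for (j in g_idx) {
      add(peaks$peak_id[i], genes$gene_id[j], "direct", NA_character_,
          "promoter", "promoter")
    }
  }
  # loop-mediated categories
  if (!is.null(loop_parts) && nrow(loop_parts)) {
    for (l in seq_len(nrow(loop_parts))) {
      lp <- loop_parts[l, ]
      p_idx <- which(peaks$chrom == lp$chrom &
                       peaks$start < lp$right_end & peaks$end > lp$left_start)
      if (!length(p_idx)) next
      g_idx <- which(genes$chrom == lp$chrom &
                       genes$tss >= lp$left_start & genes$tss < lp$right_end)
      if (!length(g_idx)) next
      tss <- genes$tss[g_idx]
      g_left <- tss >= lp$left_start & tss < lp$left_end
      g_right <- tss >= lp$right_start & tss < lp$right_end
      g_span <- tss >= lp$span_start & tss < lp$span_end
      for (i in p_idx) {
        in_left <- peaks$start[i] < lp$left_end & peaks$end[i] > lp$left_start
        in_right <- peaks$start[i] < lp$right_end & peaks$end[i] > lp$right_start
        in_span <- !in_left && !in_right &&
          peaks$start[i] < lp$span_end & peaks$end[i] > lp$span_start
        for (k in seq_along(g_idx)) {
          gid <- genes$gene_id[g_idx[k]]
          if (in_left && g_right[k]) {
            add(peaks$peak_id[i], gid, "anchor_anchor", lp$loop_id,
                "left_anchor", "right_anchor")
          }
          if (in_right && g_left[k]) {
            add(peaks$peak_id[i], gid, "anchor_anchor", lp$loop_id,
                "right_anchor", "left_anchor")
          }
          if ((in_left && g_left[k]) || (in_right && g_right[k])) {
            same_anchor[[length(same_anchor) + 1L]] <- data.frame(
              peak_id = peaks$peak_id[i], gene_id = gid,
              loop_id = lp$loop_id,
              anchor = if (in_left && g_left[k]) "left_anchor" else "right_anchor",
              stringsAsFactors = FALSE)
          }
          if ((in_left || in_right) && g_span[k]) {
            add(peaks$peak_id[i], gid, "anchor_span", lp$loop_id,
                if (in_left) "left_anchor" else "right_anchor", "span")
          }
          if (in_span && (g_left[k] || g_right[k])) {
            add(peaks$peak_id[i], gid, "span_anchor", lp$loop_id, "span",
                if (g_left[k]) "left_anchor" else "right_anchor")
          }
        }
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else data.frame(
    peak_id = character(), gene_id = character(), category = character(),
    loop_id = character(), peak_location = character(),
    gene_location = character(), stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$peak_id, out$gene_id, out$category, out$loop_id,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "same_anchor") <- if (length(same_anchor))
    unique(do.call(rbind, same_anchor)) else NULL
  out
}

#' Tally expressed and differentially expressed genes per category
#'
#' For each interaction category, counts the deduplicated expressed genes
#' with at least one assignment, and how many of those are DEG; also reports
#' the cross-category union of DEG genes (a gene in several categories is
#' counted once in the union, mirroring "some genes have more than one type
#' of interaction").
#'
#' @param assignments output of [classify_interactions()].
#' @param deg a DEG table: either a `deg_table` from [call_deg()] or a
#'   [union_deg()] result (any data frame with `gene_id` and a logical DEG
#'   indicator; for `deg_table` the `is_deg` column is used, otherwise all
#'   listed genes count as DEG).
#' @param expressed_genes character vector of expressed gene ids.
#' @return list with `per_category` (data frame `category`, `genes_total`,
#'   `genes_deg`), `deg_union` (character vector), `genes_by_category`
#'   and `deg_by_category` (named lists of gene-id vectors).
#' @export
integrate_with_deg <- function(assignments, deg, expressed_genes) {
  deg_genes <- deg_gene_ids(deg)
  assigned <- unique(assignments$gene_id)
  if (length(assigned)) {
    known <- union(expressed_genes, deg_genes)
    mismatch <- mean(!assigned %in% known)
    if (mismatch > 0.5) {
      stop(sprintf(
        "gene namespace mismatch: %.0f%% of assigned genes unknown to the expression data",
        100 * mismatch))
    }
  }
  cats <- c("direct", "anchor_anchor", "anchor_span", "span_anchor")
  genes_by_cat <- lapply(cats, function(cc) {
    sort(intersect(unique(assignments$gene_id[assignments$category == cc]),
                   expressed_genes))
  })
  names(genes_by_cat) <- cats
  deg_by_cat <- lapply(genes_by_cat, intersect, y = deg_genes)
  per_category <- data.frame(
    category = cats,
    genes_total = vapply(genes_by_cat, length, integer(1)),
    genes_deg = vapply(deg_by_cat, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_category) <- NULL
  list(per_category = per_category,
       deg_union = sort(unique(unlist(deg_by_cat))),
       genes_by_category = genes_by_cat,
       deg_by_category = deg_by_cat)
}

deg_gene_ids <- function(deg) {
  if (is.data.frame(deg)) {
    if (!is.null(deg$is_deg)) deg$gene_id[deg$is_deg]
    else if (!is.null(deg$deg_any)) deg$gene_id[deg$deg_any]
    else deg$gene_id
  } else as.character(deg)
}

#' Compare loop-mediated DEG capture against the closest-gene baseline
#'
#' The baseline gene set contains every gene that is the nearest gene
#' (by TSS/TES distance) to at least one peak within the distance cap. For
#' each loop category the DEG genes also present in the baseline set are
#' "captured"; the direct category is captured in full by construction
#' whenever the promoter window is within the cap.
#'
#' @param integration output of [integrate_with_deg()].
#' @param closest_assignments output of [closest_gene_within()].
#' @return list with `per_category` (data frame `category`, `genes_deg`,
#'   `captured_by_closest`, `capture_fraction`), `union_deg`,
#'   `union_captured`, `baseline_genes`.
#' @export
compare_with_closest_gene <- function(integration, closest_assignments) {
  baseline <- sort(unique(closest_assignments$gene_id[
    closest_assignments$within_100kb & !is.na(closest_assignments$gene_id)]))
  deg_by_cat <- integration$deg_by_category
  per_category <- data.frame(
    category = names(deg_by_cat),
    genes_deg = vapply(deg_by_cat, length, integer(1)),
    captured_by_closest = vapply(deg_by_cat, function(g)
      length(intersect(g, baseline)), integer(1)),
    stringsAsFactors = FALSE
  )
  per_category$capture_fraction <- ifelse(
    per_category$genes_deg > 0,
    per_category$captured_by_closest / per_category$genes_deg, NA_real_)
  rownames(per_category) <- NULL
  u <- integration$deg_union
  list(per_category = per_category,
       union_deg = u,
       union_captured = intersect(u, baseline),
       baseline_genes = baseline)
}
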