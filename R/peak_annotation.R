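#' Classify peak locations relative to gene models
#'
#' Each peak is reduced to a reference point (its midpoint by default) and
#' classified against the gene models in priority order: 5' UTR > exon >
#' 3' UTR > intron of any gene whose body contains the point ("exon" means
#' exonic bases outside both UTRs, so every base in a gene body has exactly
#' one class). Points inside no gene body are binned strand-aware by distance
#' to the nearest gene: upstream/downstream within (0, 5 kb] and (5 kb,
#' 25 kb], and distal beyond 25 kb. Ties between genes are broken toward the
#' higher-priority feature, then the smaller `gene_id`.
#'
#' `distance_bp` is 0 inside a gene body, negative upstream and positive
#' downstream of the assigned gene (relative to its strand).
#'
#' @param peaks peak data frame.
#' @param genes gene-model data frame.
#' @param overlap_mode `"midpoint"` (default; guarantees exactly one category
#'   per peak) or `"any"` (the peak is classified by the best-priority class
#'   of any base it covers).
#' @return data frame `peak_id`, `category`, `assigned_gene`, `distance_bp`.
#' @export
annotate_peak_location <- function(peaks, genes,
                                   overlap_mode = c("midpoint", "any")) {
  overlap_mode <- match.arg(overlap_mode)
  peaks <- validate_peaks(peaks); genes <- validate_genes(genes)
  if (!nrow(genes)) {
    warning("empty gene set: all peaks classified distal")
    return(data.frame(peak_id = peaks$peak_id,
                      category = rep("distal_gt_25kb", nrow(peaks)),
                      assigned_gene = NA_character_,
                      distance_bp = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  n <- nrow(peaks)
  category <- character(n); gene <- rep(NA_character_, n)
  dist <- integer(n)
  mids <- peak_midpoints(peaks)
  body_classes <- c("5utr", "exon", "3utr", "intron")
  for (i in seq_len(n)) {
    hit <- classify_point_in_genes(peaks$chrom[i], mids[i], genes,
                                   range_lo = if (overlap_mode == "any") peaks$start[i] else mids[i],
                                   range_hi = if (overlap_mode == "any") peaks$end[i] - 1L else mids[i])
    if (!is.na(hit$class)) {
      category[i] <- hit$class; gene[i] <- hit$gene_id; dist[i] <- 0L
      next
    }
    # outside every gene body: nearest gene by strand-aware flank distance
    nb <- nearest_flank_gene(peaks$chrom[i], mids[i], genes)
    if (is.na(nb$gene_id)) {
      category[i] <- "distal_gt_25kb"; dist[i] <- NA_integer_
      next
    }
    gene[i] <- nb$gene_id
    d <- nb$distance
    side <- nb$side   # "upstream" / "downstream"
    category[i] <- if (d > 25000) "distal_gt_25kb"
      else if (d <= 5000) paste0(side, "_0_5kb")
      else paste0(side, "_5_25kb")
    dist[i] <- if (side == "upstream") -d else d
  }
  data.frame(peak_id = peaks$peak_id, category = category,
             assigned_gene = gene, distance_bp = dist,
             stringsAsFactors = FALSE)
}

# Best-priority gene-body class over positions [range_lo, range_hi] on chrom;
# NA class when no gene body covers any position in the range.
classify_point_in_genes <- function(chrom, mid, genes, range_lo, range_hi) {
  cand <- which(genes$chrom == chrom & genes$start <= range_hi &
                  genes$end > range_lo)
  best_rank <- 5L; best_gene <- NA_character_
  ranks <- c("5utr" = 1L, "exon" = 2L, "3utr" = 3L, "intron" = 4L)
  for (j in cand) {
    cls <- gene_body_class(genes[j, ], range_lo, range_hi)
    if (is.na(cls)) next
    r <- ranks[[cls]]
    if (r < best_rank ||
        (r == best_rank && !is.na(best_gene) && genes$gene_id[j] < best_gene)) {
      best_rank <- r; best_gene <- genes$gene_id[j]
    }
  }
  list(class = if (best_rank <= 4L) names(ranks)[best_rank] else NA_character_,
       gene_id = best_gene)
}

# Best class of any base of [lo, hi] within one gene's body.
gene_body_class <- function(g, lo, hi) {
  lo2 <- max(lo, g$start); hi2 <- min(hi, g$end - 1L)
  if (lo2 > hi2) return(NA_character_)
  in_blocks <- function(blocks) {
    nrow(blocks) > 0 && any(blocks$start <= hi2 & blocks$end > lo2)
  }
  u5 <- g$utr5[[1]]; u3 <- g$utr3[[1]]; ex <- g$exons[[1]]
  if (in_blocks(u5)) return("5utr")
  # exon = exonic bases not in either UTR
  if (nrow(ex)) {
    for (k in seq_len(nrow(ex))) {
      s <- max(ex$start[k], lo2); e <- min(ex$end[k], hi2 + 1L)
      if (e <= s) next
      covered <- rep(TRUE, e - s)
      pos0 <- s
      for (blocks in list(u5, u3)) {
        if (!nrow(blocks)) next
        for (b in seq_len(nrow(blocks))) {
          bs <- max(blocks$start[b], s); be <- min(blocks$end[b], e)
          if (be > bs) covered[(bs - pos0 + 1L):(be - pos0)] <- FALSE
        }
      }
      if (any(covered)) return("exon")
    }
  }
  if (in_blocks(u3)) return("3utr")
  "intron"
}

# Nearest gene for a point outside all gene bodies (strand-aware side).
nearest_flank_gene <- function(chrom, mid, genes) {
  cand <- which(genes$chrom == chrom)
  if (!length(cand)) {
    return(list(gene_id = NA_character_, distance = NA_integer_, side = NA))
  }
  best <- list(gene_id = NA_character_, distance = Inf, side = NA)
  for (j in cand) {
    s <- genes$start[j]; e <- genes$end[j]; strand <- genes$strand[j]
    if (mid >= s && mid < e) next
    if (mid < s) { d <- s - mid; side5 <- TRUE } else { d <- mid - (e - 1L); side5 <- FALSE }
    side <- if ((strand == "+") == side5) "upstream" else "downstream"
    if (d < best$distance ||
        (d == best$distance && genes$gene_id[j] < best$gene_id)) {
      best <- list(gene_id = genes$gene_id[j], distance = d, side = side)
    }
  }
  best$distance <- as.integer(best$distance)
  best
}

#' Summarize peak location calls
#'
#' @param calls output of [annotate_peak_location()].
#' @return data frame `category`, `count`, `fraction` covering all nine
#'   categories plus an aggregate `gene_body` row (5utr + exon + 3utr +
#'   intron; its count is excluded from the fraction-sum invariant).
#' @export
summarize_locations <- function(calls) {
  if (!nrow(calls)) stop("no location calls to summarize")
  cats <- c("5utr", "exon", "3utr", "intron",
            "upstream_0_5kb", "upstream_5_25kb",
            "downstream_0_5kb", "downstream_5_25kb", "distal_gt_25kb")
  counts <- vapply(cats, function(cc) sum(calls$category == cc), integer(1))
  total <- nrow(calls)
  out <- data.frame(category = cats, count = unname(counts),
                    fraction = unname(counts) / total,
                    stringsAsFactors = FALSE)
  gb <- sum(counts[c("5utr", "exon", "3utr", "intron")])
  rbind(out, data.frame(category = "gene_body", count = gb,
                        fraction = gb / total, stringsAsFactors = FALSE))
}
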