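#' Overlap two peak sets and report the shared/unique partition
#'
#' Two peaks overlap when their intersection is at least `min_overlap_bp`.
#' `shared` contains the merged union coordinates of every connected cluster
#' of overlapping A and B peaks (so the output shared intervals are maximal
#' and mutually disjoint); `only_a`/`only_b` are the input peaks with no
#' cross-set partner. `fraction_of_b_overlapped` is the proportion of
#' original B peaks intersected by at least one A peak — the Venn-style
#' quantity behind statements like "the PGR peaks overlap 70% of the ESR1
#' peaks".
#'
#' @param a,b peak data frames.
#' @param min_overlap_bp minimum intersection width in bp (default 1).
#' @return a list of class `overlap_result`: `shared`, `only_a`, `only_b`,
#'   `n_a_overlapping`, `n_b_overlapped`, `fraction_of_a_overlapped`,
#'   `fraction_of_b_overlapped`, `venn` (counts `only_a`, `shared_a`,
#'   `shared_b`, `only_b`, `shared_merged`).
#' @export
overlap_peak_sets <- function(a, b, min_overlap_bp = 1L) {
  a <- validate_peaks(a); b <- validate_peaks(b)
  if (nrow(a) && nrow(b)) {
    hits <- GenomicRanges::findOverlaps(peaks_to_gr(a), peaks_to_gr(b),
                                        minoverlap = min_overlap_bp)
    a_hit <- unique(S4Vectors::queryHits(hits))
    b_hit <- unique(S4Vectors::subjectHits(hits))
  } else {
    hits <- NULL; a_hit <- integer(); b_hit <- integer()
  }
  shared <- merge_overlapping_pairs(a, b, hits, a_hit, b_hit)
  res <- list(
    shared = shared,
    only_a = a[setdiff(seq_len(nrow(a)), a_hit), , drop = FALSE],
    only_b = b[setdiff(seq_len(nrow(b)), b_hit), , drop = FALSE],
    n_a_overlapping = length(a_hit),
    n_b_overlapped = length(b_hit),
    fraction_of_a_overlapped = if (nrow(a)) length(a_hit) / nrow(a) else NA_real_,
    fraction_of_b_overlapped = if (nrow(b)) length(b_hit) / nrow(b) else NA_real_,
    venn = list(only_a = nrow(a) - length(a_hit),
                shared_a = length(a_hit), shared_b = length(b_hit),
                shared_merged = nrow(shared),
                only_b = nrow(b) - length(b_hit))
  )
  class(res) <- "overlap_result"
  res
}

# Union-merge every connected cluster of overlapping peaks (A side + B side).
merge_overlapping_pairs <- function(a, b, hits, a_hit, b_hit) {
  if (is.null(hits) || !length(a_hit)) return(empty_peaks())
  sel <- rbind(
    a[a_hit, c("chrom", "start", "end"), drop = FALSE],
    b[b_hit, c("chrom", "start", "end"), drop = FALSE]
  )
  gr <- GenomicRanges::reduce(intervals_to_gr(sel$chrom, sel$start, sel$end))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  new_peaks(df$chrom, df$start, df$end)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap_result: shared(merged) =", nrow(x$shared),
      "| only_a =", nrow(x$only_a), "| only_b =", nrow(x$only_b),
      sprintf("| fraction of B overlapped = %.3f\n", x$fraction_of_b_overlapped))
  invisible(x)
}

#' Assign each peak to the closest gene by TSS/TES distance
#'
#' The distance from a peak to a gene is 0 when the peak interval contains
#' the gene's TSS or TES; otherwise it is the minimum gap (in bp) from either
#' peak edge to the TSS and to the TES. Each peak takes the gene minimizing
#' this distance (ties toward the smaller `gene_id`), and `within_100kb`
#' flags distances at or below `max_distance` (inclusive). This is the
#' closest-gene baseline the loop-aware assignment is compared against.
#'
#' @param peaks peak data frame.
#' @param genes gene-model data frame.
#' @param max_distance inclusive distance cap in bp (default 100000).
#' @return data frame `peak_id`, `gene_id`, `distance_bp`, `within_100kb`.
#' @export
closest_gene_within <- function(peaks, genes, max_distance = 100000L) {
  peaks <- validate_peaks(peaks); genes <- validate_genes(genes)
  if (!nrow(genes)) stop("gene set is empty")
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n); dist <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- which(genes$chrom == peaks$chrom[i])
    if (!length(cand)) next
    d <- pmin(point_gap(peaks$start[i], peaks$end[i], genes$tss[cand]),
              point_gap(peaks$start[i], peaks$end[i], genes$tes[cand]))
    ord <- order(d, genes$gene_id[cand])
    gene_id[i] <- genes$gene_id[cand][ord[1]]
    dist[i] <- d[ord[1]]
  }
  data.frame(peak_id = peaks$peak_id, gene_id = gene_id, distance_bp = dist,
             within_100kb = !is.na(dist) & dist <= max_distance,
             stringsAsFactors = FALSE)
}

# Gap from interval [start, end) to point p: 0 when contained.
point_gap <- function(start, end, p) {
  ifelse(p < start, start - p, ifelse(p >= end, p - (end - 1L), 0L))
}
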