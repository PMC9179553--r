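# Naive brute-force oracles, written directly from the interaction and
# distance definitions. They deliberately share no code with the package
# internals: everything is an explicit loop over pairs/positions.

# All-pairs peak overlap: indices of A and B peaks with an intersection of
# at least min_bp.
oracle_overlap_pairs <- function(a, b, min_bp = 1L) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_bp) pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (!length(pairs)) return(matrix(integer(), ncol = 2))
  do.call(rbind, pairs)
}

# Exhaustive closest gene by min distance to TSS/TES (0 when contained).
oracle_closest <- function(peaks, genes, max_distance = 100000L) {
  point_dist <- function(s, e, p) {
    if (p >= s && p < e) 0L else if (p < s) s - p else p - (e - 1L)
  }
  out <- data.frame(peak_id = peaks$peak_id, gene_id = NA_character_,
                    distance_bp = NA_integer_, within_100kb = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    best_d <- Inf; best_g <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      d <- min(point_dist(peaks$start[i], peaks$end[i], genes$tss[j]),
               point_dist(peaks$start[i], peaks$end[i], genes$tes[j]))
      if (d < best_d || (d == best_d && genes$gene_id[j] < best_g)) {
        best_d <- d; best_g <- genes$gene_id[j]
      }
    }
    if (is.finite(best_d)) {
      out$gene_id[i] <- best_g
      out$distance_bp[i] <- as.integer(best_d)
      out$within_100kb[i] <- best_d <= max_distance
    }
  }
  out
}

# Per-position location classifier: class of a single base within one gene,
# evaluated block by block.
oracle_base_class <- function(g, pos) {
  if (pos < g$start || pos >= g$end) return(NA_character_)
  in_any <- function(blocks) {
    if (!nrow(blocks)) return(FALSE)
    any(pos >= blocks$start & pos < blocks$end)
  }
  if (in_any(g$utr5[[1]])) return("5utr")
  if (in_any(g$utr3[[1]])) return("3utr")
  if (in_any(g$exons[[1]])) return("exon")
  "intron"
}

# Midpoint-based location call for every peak, scanning all genes.
oracle_annotate <- function(peaks, genes) {
  rank_of <- c("5utr" = 1, "exon" = 2, "3utr" = 3, "intron" = 4)
  out <- data.frame(peak_id = peaks$peak_id, category = NA_character_,
                    assigned_gene = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[i] + peaks$end[i] - 1) / 2)
    best_rank <- Inf; best_g <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      cls <- oracle_base_class(genes[j, ], mid)
      if (is.na(cls)) next
      r <- rank_of[[cls]]
      if (r < best_rank || (r == best_rank && genes$gene_id[j] < best_g)) {
        best_rank <- r; best_g <- genes$gene_id[j]
      }
    }
    if (is.finite(best_rank)) {
      out$category[i] <- names(rank_of)[best_rank]
      out$assigned_gene[i] <- best_g
      next
    }
    # flanking: nearest gene edge, side relative to gene strand
    best_d <- Inf; best_g <- NA_character_; best_side <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      if (mid < genes$start[j]) {
        d <- genes$start[j] - mid
        side <- if (genes$strand[j] == "+") "upstream" else "downstream"
      } else {
        d <- mid - (genes$end[j] - 1)
        side <- if (genes$strand[j] == "+") "downstream" else "upstream"
      }
      if (d < best_d || (d == best_d && genes$gene_id[j] < best_g)) {
        best_d <- d; best_g <- genes$gene_id[j]; best_side <- side
      }
    }
    if (!is.finite(best_d)) {
      out$category[i] <- "distal_gt_25kb"
    } else if (best_d > 25000) {
      out$category[i] <- "distal_gt_25kb"; out$assigned_gene[i] <- best_g
    } else {
      bin <- if (best_d <= 5000) "_0_5kb" else "_5_25kb"
      out$category[i] <- paste0(best_side, bin)
      out$assigned_gene[i] <- best_g
    }
  }
  out
}

# Triple loop over (peak, loop, gene) applying the category definitions
# literally; direct is a plain (peak, gene) scan.
oracle_classify <- function(peaks, loops, genes, ph = 2500L) {
  recs <- list()
  emit <- function(p, g, cat, l) {
    recs[[length(recs) + 1L]] <<- data.frame(
      peak_id = p, gene_id = g, category = cat, loop_id = l,
      stringsAsFactors = FALSE)
  }
  ovl <- function(s1, e1, s2, e2) min(e1, e2) - max(s1, s2) >= 1
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      if (ovl(peaks$start[i], peaks$end[i], genes$tss[j] - ph,
              genes$tss[j] + ph)) {
        emit(peaks$peak_id[i], genes$gene_id[j], "direct", NA_character_)
      }
    }
  }
  for (l in seq_len(nrow(loops))) {
    la <- c(loops$start1[l], loops$end1[l])
    ra <- c(loops$start2[l], loops$end2[l])
    sp <- c(loops$end1[l], loops$start2[l])
    for (i in seq_len(nrow(peaks))) {
      if (peaks$chrom[i] != loops$chrom[l]) next
      p <- c(peaks$start[i], peaks$end[i])
      p_left <- ovl(p[1], p[2], la[1], la[2])
      p_right <- ovl(p[1], p[2], ra[1], ra[2])
      p_span <- !p_left && !p_right && sp[2] > sp[1] &&
        ovl(p[1], p[2], sp[1], sp[2])
      if (!p_left && !p_right && !p_span) next
      for (j in seq_len(nrow(genes))) {
        if (genes$chrom[j] != loops$chrom[l]) next
        tss <- genes$tss[j]
        g_left <- tss >= la[1] && tss < la[2]
        g_right <- tss >= ra[1] && tss < ra[2]
        g_span <- tss >= sp[1] && tss < sp[2]
        if ((p_left && g_right) || (p_right && g_left)) {
          emit(peaks$peak_id[i], genes$gene_id[j], "anchor_anchor",
               loops$loop_id[l])
        }
        if ((p_left || p_right) && g_span) {
          emit(peaks$peak_id[i], genes$gene_id[j], "anchor_span",
               loops$loop_id[l])
        }
        if (p_span && (g_left || g_right)) {
          emit(peaks$peak_id[i], genes$gene_id[j], "span_anchor",
               loops$loop_id[l])
        }
      }
    }
  }
  out <- if (length(recs)) unique(do.call(rbind, recs)) else data.frame(
    peak_id = character(), gene_id = character(), category = character(),
    loop_id = character(), stringsAsFactors = FALSE)
  sort_records(out)
}

# Pairwise shared-loop oracle: brute force over all loop pairs.
oracle_shared_loops <- function(x, y, min_bp = 1L) {
  keep <- list()
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(y))) {
      if (x$chrom[i] != y$chrom[j]) next
      l_ov <- min(x$end1[i], y$end1[j]) - max(x$start1[i], y$start1[j])
      r_ov <- min(x$end2[i], y$end2[j]) - max(x$start2[i], y$start2[j])
      if (l_ov >= min_bp && r_ov >= min_bp) {
        keep[[length(keep) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(keep)) return(matrix(integer(), ncol = 2))
  do.call(rbind, keep)
}

sort_records <- function(df) {
  if (!nrow(df)) return(df)
  df <- df[order(df$peak_id, df$gene_id, df$category, df$loop_id,
                 method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}
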