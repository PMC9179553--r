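#' Specification of a synthetic regulatory landscape
#'
#' Describes a toy genome with gene models, chromatin loops, ChIP peaks, a
#' compartment eigenvector track, and a treatment expression design, with
#' planted ground truth for every downstream statistic. Defaults emulate the
#' structure of a two-donor hormone-treated organoid study: loops tens of kb
#' to hundreds of kb in extent with 5-15 kb anchors, peaks planted in the
#' four interaction geometries, 68% of peaks in the B compartment, and an
#' estrogen-like induction (fold 4) attenuated (factor 0.5 on the log scale)
#' in a progestin co-treatment group, 3 replicates per group with lognormal
#' noise of 0.25 on log2.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_genes total gene models (planted partners plus background).
#' @param n_loops total loops (planted plus empty).
#' @param loop_extent_range numeric pair: min/max loop extent (outer edge to
#'   outer edge) in bp.
#' @param anchor_width_range numeric pair: min/max anchor width in bp.
#' @param n_peaks total peaks.
#' @param category_mix named integer vector with entries `direct`,
#'   `anchor_anchor`, `anchor_span`, `span_anchor`; remaining peaks are
#'   planted unassigned (outside loops and promoters).
#' @param fraction_peaks_in_B target proportion of peaks whose midpoint falls
#'   in a B-compartment bin.
#' @param deg_spec list: `n_up`, `n_down`, `true_fold`, `noise_sigma_log2`,
#'   `n_replicates`, `attenuation_factor` (0..1 exponent on the fold for the
#'   co-treatment group), `zero_fraction` (baseline zeros injected into
#'   unplanted genes).
#' @param bin_size compartment bin width in bp.
#' @param promoter_halfwidth promoter half-window used when planting direct
#'   peaks and exclusion zones, in bp.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   outputs.
#' @return a `landscape_spec` list.
#' @export
landscape_spec <- function(n_chromosomes = 6L,
                           chrom_length = 10000000L,
                           n_genes = 160L,
                           n_loops = 100L,
                           loop_extent_range = c(30000L, 250000L),
                           anchor_width_range = c(5000L, 15000L),
                           n_peaks = 300L,
                           category_mix = c(direct = 30L, anchor_anchor = 20L,
                                            anchor_span = 25L,
                                            span_anchor = 40L),
                           fraction_peaks_in_B = 0.68,
                           deg_spec = list(n_up = 40L, n_down = 20L,
                                           true_fold = 4,
                                           noise_sigma_log2 = 0.25,
                                           n_replicates = 3L,
                                           attenuation_factor = 0.5,
                                           zero_fraction = 0.02),
                           bin_size = 100000L,
                           promoter_halfwidth = 2500L,
                           seed = 1L) {
  spec <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes), n_loops = as.integer(n_loops),
    loop_extent_range = as.numeric(loop_extent_range),
    anchor_width_range = as.numeric(anchor_width_range),
    n_peaks = as.integer(n_peaks),
    category_mix = category_mix, fraction_peaks_in_B = fraction_peaks_in_B,
    deg_spec = utils::modifyList(
      list(n_up = 40L, n_down = 20L, true_fold = 4, noise_sigma_log2 = 0.25,
           n_replicates = 3L, attenuation_factor = 0.5, zero_fraction = 0.02),
      deg_spec),
    bin_size = as.integer(bin_size),
    promoter_halfwidth = as.integer(promoter_halfwidth),
    seed = as.integer(seed)
  )
  class(spec) <- "landscape_spec"
  validate_landscape_spec(spec)
}

validate_landscape_spec <- function(spec) {
  cm <- spec$category_mix
  needed <- c("direct", "anchor_anchor", "anchor_span", "span_anchor")
  missing <- setdiff(needed, names(cm))
  if (length(missing)) {
    stop("category_mix lacks: ", paste(missing, collapse = ", "))
  }
  cm <- vapply(needed, function(x) as.integer(cm[[x]]), integer(1))
  if (any(cm < 0)) stop("negative category count")
  if (sum(cm) > spec$n_peaks) {
    stop("infeasible spec: planted category counts exceed n_peaks")
  }
  n_loop_planted <- sum(cm[c("anchor_anchor", "anchor_span", "span_anchor")])
  if (n_loop_planted > spec$n_loops) {
    stop("infeasible spec: more loop-planted peaks than loops")
  }
  if (sum(cm) > 0 && spec$n_genes < sum(cm)) {
    stop("infeasible spec: fewer genes than planted peak partners")
  }
  if (spec$fraction_peaks_in_B < 0 || spec$fraction_peaks_in_B > 1) {
    stop("fraction_peaks_in_B must be in [0, 1]")
  }
  if (spec$deg_spec$true_fold < 1) stop("true_fold must be >= 1")
  if (spec$deg_spec$attenuation_factor < 0 || spec$deg_spec$attenuation_factor > 1) {
    stop("attenuation_factor must be in [0, 1]")
  }
  if (spec$loop_extent_range[2] < 2 * spec$anchor_width_range[2] + 25000) {
    stop("loop extent range too small for anchors plus a usable span")
  }
  # worst-case packing check: loops plus inter-loop gaps must fit
  per_chrom <- ceiling(spec$n_loops / spec$n_chromosomes)
  worst <- per_chrom * (spec$loop_extent_range[2] + 200000) + 400000
  if (worst > spec$chrom_length) {
    stop("infeasible spec: loops cannot be packed into chrom_length ",
         "(worst-case need ", worst, " bp per chromosome)")
  }
  spec$category_mix <- cm
  spec
}

#' Generate a synthetic landscape with planted ground truth
#'
#' Places loops non-overlapping and non-nested along each chromosome, then
#' plants each category peak with its own dedicated loop (or promoter) and
#' partner gene, enforcing exclusion zones so that
#' [classify_interactions()] on the emitted files recovers exactly the
#' planted (peak, gene, category) tuples and nothing else: planted loop
#' peaks sit at least 2 kb inside their anchor (or mid-span), background
#' genes and unassigned peaks stay at least 3 kb away from every loop and
#' 6 kb from every other element, and no peak other than a planted direct
#' peak touches a promoter window.
#'
#' Compartment labels are planted at bin level: an exact subset-sum over the
#' peak-occupied bins selects B bins so that the B fraction of peak midpoints
#' matches `fraction_peaks_in_B` (exactly when an integral solution exists;
#' the achieved fraction is recorded in the ground truth either way).
#'
#' @param spec a [landscape_spec()].
#' @param outdir optional directory: when given, writes `genes.bed12`,
#'   `loops.bedpe`, `peaks.bed`, `eigenvector.bedgraph`,
#'   `truth_assignments.tsv`, and `truth.json`.
#' @return list with `genes`, `loops`, `peaks`, `eigen` (labeled track) and
#'   `truth` (list: `assignments`, `peak_compartments`, `fraction_B`,
#'   `bin_labels`).
#' @export
generate_landscape <- function(spec, outdir = NULL) {
  spec <- validate_landscape_spec(spec)
  set.seed(spec$seed)
  cm <- spec$category_mix
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))

  loops <- place_loops(spec, chroms)
  alloc <- free_zone_allocator(spec, chroms, loops)

  genes <- list(); peaks <- list(); truth <- list()
  gene_n <- 0L; peak_n <- 0L
  new_gene_id <- function() { gene_n <<- gene_n + 1L; sprintf("gene%04d", gene_n) }
  new_peak_id <- function() { peak_n <<- peak_n + 1L; sprintf("peak%04d", peak_n) }

  # assign planted roles to loop slots
  roles <- rep("empty", nrow(loops))
  n_aa <- cm[["anchor_anchor"]]; n_as <- cm[["anchor_span"]]
  n_sa <- cm[["span_anchor"]]
  roles[seq_len(n_aa + n_as + n_sa)] <- c(rep("anchor_anchor", n_aa),
                                          rep("anchor_span", n_as),
                                          rep("span_anchor", n_sa))

  ph <- spec$promoter_halfwidth
  for (l in seq_len(nrow(loops))) {
    role <- roles[l]
    if (role == "empty") next
    lp <- loops[l, ]
    pid <- new_peak_id(); gid <- new_gene_id()
    pw <- sample(300:900, 1)
    # anchor-planted genes are confined to their anchor so no gene end spills
    # into the free zones and perturbs the closest-gene baseline
    if (role %in% c("anchor_anchor", "anchor_span")) {
      # peak >= 2 kb inside the left anchor
      ps <- sample_pos(lp$start1 + 2000, lp$end1 - 2000 - pw)
      if (role == "anchor_anchor") {
        tss <- sample_pos(lp$start2 + 500, lp$end2 - 3500)
        max_len <- min(10000L, lp$end2 - 500L - tss)
      } else {
        tss <- sample_pos(lp$end1 + 5000, lp$start2 - 15000)
        max_len <- 10000L
      }
    } else {  # span_anchor: peak mid-span, gene TSS in the left anchor
      mid_lo <- lp$end1 + 5000; mid_hi <- lp$start2 - 5000 - pw
      ps <- sample_pos(mid_lo, mid_hi)
      tss <- sample_pos(lp$start1 + 500, lp$end1 - 3500)
      max_len <- min(10000L, lp$end1 - 500L - tss)
    }
    peaks[[length(peaks) + 1L]] <- list(chrom = lp$chrom, start = ps,
                                        end = ps + pw, peak_id = pid)
    genes[[length(genes) + 1L]] <- plant_gene(gid, lp$chrom, tss,
                                              max_len = max_len)
    truth[[length(truth) + 1L]] <- data.frame(
      peak_id = pid, gene_id = gid, category = role, loop_id = lp$loop_id,
      stringsAsFactors = FALSE)
  }

  # direct pairs: outside all loops, peak overlapping the partner promoter
  for (k in seq_len(cm[["direct"]])) {
    slot <- alloc(16000L)
    pid <- new_peak_id(); gid <- new_gene_id()
    tss <- slot$start + 3000L
    pw <- sample(300:900, 1)
    off <- sample(seq(-ph + 50L, ph - pw - 50L), 1)   # peak inside the window
    peaks[[length(peaks) + 1L]] <- list(chrom = slot$chrom, start = tss + off,
                                        end = tss + off + pw, peak_id = pid)
    genes[[length(genes) + 1L]] <- plant_gene(gid, slot$chrom, tss,
                                              max_len = 10000L)
    truth[[length(truth) + 1L]] <- data.frame(
      peak_id = pid, gene_id = gid, category = "direct",
      loop_id = NA_character_, stringsAsFactors = FALSE)
  }

  # background genes
  n_background <- spec$n_genes - gene_n
  for (k in seq_len(max(0L, n_background))) {
    slot <- alloc(13000L)
    genes[[length(genes) + 1L]] <- plant_gene(new_gene_id(), slot$chrom,
                                              slot$start + 3000L,
                                              max_len = 9000L)
  }

  # unassigned peaks: outside loops and away from every promoter
  n_unassigned <- spec$n_peaks - peak_n
  for (k in seq_len(max(0L, n_unassigned))) {
    slot <- alloc(1200L)
    pw <- sample(300:900, 1)
    peaks[[length(peaks) + 1L]] <- list(chrom = slot$chrom,
                                        start = slot$start,
                                        end = slot$start + pw,
                                        peak_id = new_peak_id())
  }

  genes_df <- if (length(genes)) do.call(rbind_gene_rows, list(genes)) else
    new_genes(character(), character(), integer(), integer(), character())
  peaks_df <- if (length(peaks)) new_peaks(
    chrom = vapply(peaks, `[[`, "", "chrom"),
    start = vapply(peaks, function(p) as.integer(p$start), integer(1)),
    end = vapply(peaks, function(p) as.integer(p$end), integer(1)),
    peak_id = vapply(peaks, `[[`, "", "peak_id")) else empty_peaks()
  truth_df <- if (length(truth)) do.call(rbind, truth) else data.frame(
    peak_id = character(), gene_id = character(), category = character(),
    loop_id = character(), stringsAsFactors = FALSE)

  peaks_df <- rebalance_peak_bins(spec, peaks_df, truth_df, alloc)
  comp <- plant_compartments(spec, chroms, peaks_df)

  out <- list(genes = genes_df, loops = loops, peaks = peaks_df,
              eigen = comp$track,
              truth = list(assignments = truth_df,
                           peak_compartments = comp$per_peak,
                           fraction_B = comp$fraction_B,
                           bin_labels = comp$track$label))
  if (!is.null(outdir)) write_landscape(out, outdir)
  out
}

sample_pos <- function(lo, hi) {
  lo <- as.integer(ceiling(lo)); hi <- as.integer(floor(hi))
  if (hi < lo) stop("infeasible placement: empty interval for planting")
  if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# A plus-strand gene with 2-4 exons and a CDS, TSS at the stated position.
plant_gene <- function(gene_id, chrom, tss, max_len = 10000L) {
  len <- if (max_len <= 3000L) 3000L else
    3000L + sample.int(max_len - 3000L + 1L, 1L) - 1L
  n_ex <- sample(2:4, 1)
  cuts <- sort(sample(seq(200L, len - 200L, by = 50L), 2L * (n_ex - 1L)))
  bounds <- c(0L, cuts, len)
  ex <- data.frame(start = tss + bounds[seq(1, length(bounds), 2)],
                   end = tss + bounds[seq(2, length(bounds), 2)])
  cds_s <- ex$start[1] + min(150L, (ex$end[1] - ex$start[1]) %/% 2L)
  last <- nrow(ex)
  cds_e <- ex$end[last] - min(150L, (ex$end[last] - ex$start[last]) %/% 2L)
  utrs <- derive_utrs(ex, cds_s, cds_e, "+")
  list(gene_id = gene_id, gene_name = gene_id, chrom = chrom, start = tss,
       end = tss + len, strand = "+", exons = ex, utr5 = utrs$utr5,
       utr3 = utrs$utr3)
}

rbind_gene_rows <- function(rows) {
  assemble_genes(rows)
}

place_loops <- function(spec, chroms) {
  if (spec$n_loops == 0L) {
    return(new_loops(character(), character(), integer(), integer(),
                     integer(), integer()))
  }
  per_chrom <- rep(spec$n_loops %/% spec$n_chromosomes, spec$n_chromosomes)
  extra <- spec$n_loops %% spec$n_chromosomes
  if (extra) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  rows <- list()
  idx <- 0L
  for (ci in seq_along(chroms)) {
    cursor <- 200000L
    for (k in seq_len(per_chrom[ci])) {
      aw1 <- round(stats::runif(1, spec$anchor_width_range[1],
                                spec$anchor_width_range[2]))
      aw2 <- round(stats::runif(1, spec$anchor_width_range[1],
                                spec$anchor_width_range[2]))
      ext_lo <- max(spec$loop_extent_range[1], aw1 + aw2 + 25000)
      ext <- round(stats::runif(1, ext_lo, spec$loop_extent_range[2]))
      if (cursor + ext + 200000 > spec$chrom_length) {
        stop("infeasible spec: ran out of chromosome while placing loops")
      }
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        loop_id = sprintf("loop%03d", idx), chrom = chroms[ci],
        start1 = cursor, end1 = cursor + as.integer(aw1),
        start2 = cursor + as.integer(ext) - as.integer(aw2),
        end2 = cursor + as.integer(ext), stringsAsFactors = FALSE)
      cursor <- cursor + as.integer(ext) +
        as.integer(round(stats::runif(1, 80000, 200000)))
    }
  }
  validate_loops(do.call(rbind, rows))
}

# Sequential allocator over the regions outside loops (3 kb margins), with
# 6 kb spacing between allocations so promoters and peaks cannot collide.
free_zone_allocator <- function(spec, chroms, loops) {
  zones <- list()
  for (cm in chroms) {
    ls <- loops[loops$chrom == cm, , drop = FALSE]
    ls <- ls[order(ls$start1), , drop = FALSE]
    edges_lo <- c(20000L, ls$end2 + 3000L)
    edges_hi <- c(ls$start1 - 3000L, spec$chrom_length - 20000L)
    for (z in seq_along(edges_lo)) {
      if (edges_hi[z] - edges_lo[z] > 20000L) {
        zones[[length(zones) + 1L]] <- list(chrom = cm, lo = edges_lo[z],
                                            hi = edges_hi[z])
      }
    }
  }
  zi <- 1L
  cursor <- if (length(zones)) zones[[1]]$lo else NA_integer_
  function(width, spacing = 6000L) {
    repeat {
      if (zi > length(zones)) {
        stop("infeasible spec: free space exhausted while planting elements")
      }
      z <- zones[[zi]]
      if (cursor + width <= z$hi) {
        out <- list(chrom = z$chrom, start = cursor)
        cursor <<- cursor + as.integer(width) + as.integer(spacing)
        return(out)
      }
      zi <<- zi + 1L
      if (zi <= length(zones)) cursor <<- zones[[zi]]$lo
    }
  }
}

# The planted B fraction is a bin-level subset sum over peak counts; when
# peaks cluster so no exact integral solution exists, relocate unassigned
# peaks (never planted ones) into fresh bin-sized slots until it does.
rebalance_peak_bins <- function(spec, peaks, truth, alloc) {
  if (!nrow(peaks)) return(peaks)
  bs <- spec$bin_size
  target <- as.integer(round(spec$fraction_peaks_in_B * nrow(peaks)))
  movable <- setdiff(peaks$peak_id, truth$peak_id)
  for (iter in seq_len(60L)) {
    mids <- peak_midpoints(peaks)
    keys <- paste0(peaks$chrom, ":", (mids %/% bs) * bs)
    occ <- table(keys)
    counts <- as.integer(occ)
    pick <- subset_sum_pick(counts, target)
    if (sum(counts[pick]) == target) break
    multi <- names(occ)[occ >= 2L]
    cand <- which(peaks$peak_id %in% movable & keys %in% multi)
    if (!length(cand)) break
    i <- cand[length(cand)]
    slot <- tryCatch(alloc(1200L, spacing = bs),
                     error = function(e) NULL)
    if (is.null(slot)) break
    w <- peaks$end[i] - peaks$start[i]
    peaks$start[i] <- slot$start
    peaks$end[i] <- slot$start + w
  }
  peaks
}

plant_compartments <- function(spec, chroms, peaks) {
  bs <- spec$bin_size
  n_bins <- as.integer(ceiling(spec$chrom_length / bs))
  bins <- data.frame(
    chrom = rep(chroms, each = n_bins),
    start = rep(as.integer((seq_len(n_bins) - 1L) * bs), length(chroms)),
    stringsAsFactors = FALSE)
  bins$end <- pmin(bins$start + as.integer(bs), spec$chrom_length)
  key <- paste0(bins$chrom, ":", bins$start)
  label <- rep(NA_character_, nrow(bins))
  n_B_achieved <- 0L
  if (nrow(peaks)) {
    mids <- peak_midpoints(peaks)
    peak_key <- paste0(peaks$chrom, ":", (mids %/% bs) * bs)
    occ <- table(peak_key)
    occ_keys <- names(occ)
    counts <- as.integer(occ)
    target <- as.integer(round(spec$fraction_peaks_in_B * nrow(peaks)))
    pick <- subset_sum_pick(counts, target)
    b_keys <- occ_keys[pick]
    n_B_achieved <- sum(counts[pick])
    label[key %in% b_keys] <- "B"
    label[key %in% setdiff(occ_keys, b_keys)] <- "A"
  }
  empty <- is.na(label)
  label[empty] <- sample(c("A", "B"), sum(empty), replace = TRUE)
  mag <- stats::runif(nrow(bins), 0.2, 1)
  eig <- ifelse(label == "A", mag, -mag)
  track <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                      eigen = eig, stringsAsFactors = FALSE)
  attr(track, "bin_size") <- as.integer(bs)
  track <- label_compartments(track, orientation = "as_is")
  per_peak <- if (nrow(peaks)) {
    mids <- peak_midpoints(peaks)
    peak_key <- paste0(peaks$chrom, ":", (mids %/% bs) * bs)
    data.frame(peak_id = peaks$peak_id,
               label = track$label[match(peak_key, key)],
               stringsAsFactors = FALSE)
  } else data.frame(peak_id = character(), label = character(),
                    stringsAsFactors = FALSE)
  list(track = track,
       per_peak = per_peak,
       fraction_B = if (nrow(peaks)) n_B_achieved / nrow(peaks) else NA_real_)
}

# Exact 0/1 subset-sum over small positive counts; returns a logical pick
# whose sum is the closest achievable value to target (ties: smaller sum).
subset_sum_pick <- function(counts, target) {
  n <- length(counts)
  if (!n) return(logical(0))
  total <- sum(counts)
  target <- max(0L, min(target, total))
  reach <- matrix(FALSE, nrow = n + 1L, ncol = total + 1L)
  reach[1, 1] <- TRUE
  for (i in seq_len(n)) {
    reach[i + 1L, ] <- reach[i, ]
    c_i <- counts[i]
    if (c_i < total + 1L) {
      shifted <- c(rep(FALSE, c_i), reach[i, seq_len(total + 1L - c_i)])
      reach[i + 1L, ] <- reach[i + 1L, ] | shifted
    }
  }
  sums <- which(reach[n + 1L, ]) - 1L
  best <- sums[order(abs(sums - target), sums)][1]
  pick <- logical(n)
  s <- best
  for (i in n:1) {
    if (s - counts[i] >= 0 && reach[i, s - counts[i] + 1L]) {
      pick[i] <- TRUE
      s <- s - counts[i]
    }
  }
  pick
}

#' Simulate a treatment-group expression matrix with planted fold changes
#'
#' Baseline (vehicle) expression is lognormal per gene; an estrogen-like
#' group multiplies planted up-genes by `true_fold` (down-genes by
#' `1/true_fold`), and a co-treatment group applies
#' `true_fold^attenuation_factor`, reproducing the attenuation of the
#' estrogen response when the factor is below 1 (1 leaves the two treatment
#' groups identically distributed; 0 makes the third group baseline-like).
#' A `zero_fraction` of baseline values in unplanted genes is set to 0 to
#' exercise the zero-replacement rule.
#'
#' @param spec a [landscape_spec()] (its `deg_spec` and `seed` are used).
#' @param genes gene-model data frame giving the gene namespace.
#' @param groups labels for (baseline, treatment, attenuated co-treatment).
#' @param donor donor label stored in the design.
#' @param seed optional seed override (default `spec$seed + 1`).
#' @return list with `matrix` (an [expression_matrix()]) and `truth` (data
#'   frame `gene_id`, `planted` in `up`/`down`/`null`, `true_fold_e2`).
#' @export
simulate_expression <- function(spec, genes,
                                groups = c("V", "E2", "E2+MPA"),
                                donor = "donor1", seed = NULL) {
  ds <- spec$deg_spec
  if (ds$n_replicates < 2) stop("n_replicates must be >= 2")
  set.seed(if (is.null(seed)) spec$seed + 1L else as.integer(seed))
  gene_ids <- genes$gene_id
  n <- length(gene_ids)
  if (ds$n_up + ds$n_down > n) stop("more planted DEG than genes")
  planted <- rep("null", n)
  sel <- sample.int(n, ds$n_up + ds$n_down)
  planted[sel[seq_len(ds$n_up)]] <- "up"
  if (ds$n_down > 0) planted[sel[ds$n_up + seq_len(ds$n_down)]] <- "down"
  lfc <- ifelse(planted == "up", log2(ds$true_fold),
                ifelse(planted == "down", -log2(ds$true_fold), 0))
  mu <- stats::rnorm(n, mean = 3, sd = 1.5)
  nr <- ds$n_replicates
  shift <- cbind(matrix(0, n, nr),                       # baseline
                 matrix(lfc, n, nr),                     # treatment
                 matrix(lfc * ds$attenuation_factor, n, nr))
  noise <- matrix(stats::rnorm(n * 3L * nr, 0, ds$noise_sigma_log2), n, 3L * nr)
  values <- 2^(mu + shift + noise)
  if (ds$zero_fraction > 0) {
    base_cols <- seq_len(nr)
    for (j in base_cols) {
      z <- stats::runif(n) < ds$zero_fraction & planted == "null"
      values[z, j] <- 0
    }
  }
  sample_ids <- paste(rep(groups, each = nr), rep(seq_len(nr), 3L), sep = "_")
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  design <- data.frame(sample_id = sample_ids,
                       group = rep(groups, each = nr),
                       donor = donor, stringsAsFactors = FALSE)
  list(matrix = expression_matrix(values, design),
       truth = data.frame(gene_id = gene_ids, planted = planted,
                          true_fold_e2 = 2^lfc, stringsAsFactors = FALSE))
}

# ---- writers for generated landscapes --------------------------------------

#' Write landscape files
#'
#' Serializes a generated landscape as plain-text genomics formats plus the
#' ground truth (TSV + JSON). All writers are deterministic.
#'
#' @param landscape output of [generate_landscape()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_landscape <- function(landscape, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_bed12(landscape$genes, file.path(outdir, "genes.bed12"))
  write_bedpe(landscape$loops, file.path(outdir, "loops.bedpe"))
  write_peaks_bed(landscape$peaks, file.path(outdir, "peaks.bed"))
  write_bedgraph(landscape$eigen, file.path(outdir, "eigenvector.bedgraph"))
  write_table(landscape$truth$assignments,
              file.path(outdir, "truth_assignments.tsv"))
  jsonlite::write_json(
    list(fraction_B = landscape$truth$fraction_B,
         peak_compartments = landscape$truth$peak_compartments),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @rdname write_landscape
#' @param genes,path gene models and destination for the BED12 writer.
#' @export
write_bed12 <- function(genes, path) {
  genes <- validate_genes(genes)
  lines <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    ex <- ex[order(ex$start), , drop = FALSE]
    u5 <- genes$utr5[[i]]; u3 <- genes$utr3[[i]]
    left_utr <- if (genes$strand[i] == "+") u5 else u3
    right_utr <- if (genes$strand[i] == "+") u3 else u5
    thick_s <- if (nrow(left_utr)) max(left_utr$end) else genes$start[i]
    thick_e <- if (nrow(right_utr)) min(right_utr$start) else genes$end[i]
    if (!nrow(u5) && !nrow(u3)) { thick_s <- genes$start[i]; thick_e <- genes$end[i] }
    lines[i] <- paste(
      genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i], 0,
      genes$strand[i], thick_s, thick_e, "0",
      nrow(ex),
      paste0(paste(ex$end - ex$start, collapse = ","), ","),
      paste0(paste(ex$start - genes$start[i], collapse = ","), ","),
      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_landscape
#' @param loops loop table for the BEDPE writer.
#' @export
write_bedpe <- function(loops, path) {
  loops <- validate_loops(loops)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s", loops$chrom, loops$start1,
                   loops$end1, loops$chrom, loops$start2, loops$end2,
                   loops$loop_id)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_landscape
#' @param peaks peak table for the BED6 writer.
#' @export
write_peaks_bed <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  score <- ifelse(is.na(peaks$score), "0", format(peaks$score, trim = TRUE))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", peaks$chrom, peaks$start,
                   peaks$end, peaks$peak_id, score, peaks$strand)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_landscape
#' @param track eigenvector track for the bedGraph writer.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                   format(track$eigen, trim = TRUE, digits = 15))
  writeLines(lines, path)
  invisible(path)
}
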