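#' @title Core genomic containers
#'
#' @description
#' All interval containers in loopweaver are plain data frames with documented
#' columns, using the BED convention throughout: 0-based half-open
#' `[start, end)` coordinates. GTF input (1-based inclusive) is translated at
#' the I/O boundary.
#'
#' * **Peaks**: `chrom`, `start`, `end`, `peak_id`, `score`, `strand`,
#'   `summit_offset`.
#' * **Gene models** (one row per gene): `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand`, `tss`, `tes`, plus list-columns `exons`,
#'   `utr5`, `utr3` (each a data frame of `start`/`end` pairs). `tss` and
#'   `tes` are single base positions: on `+`, `tss = start` and
#'   `tes = end - 1`; on `-`, `tss = end - 1` and `tes = start`.
#' * **Loops**: `loop_id`, `chrom`, `start1`, `end1`, `start2`, `end2` with
#'   `end1 <= start2` (left anchor strictly precedes the right anchor).
#'
#' @name loopweaver-types
NULL

new_peaks <- function(chrom = character(), start = integer(), end = integer(),
                      peak_id = NULL, score = NA_real_, strand = ".",
                      summit_offset = NA_integer_) {
  n <- length(chrom)
  if (is.null(peak_id)) peak_id <- sprintf("%s:%d-%d", chrom, start, end)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    peak_id = as.character(peak_id),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    summit_offset = rep_len(as.integer(summit_offset), n),
    stringsAsFactors = FALSE
  )
  validate_peaks(df)
}

validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  req <- c("chrom", "start", "end", "peak_id")
  missing <- setdiff(req, names(peaks))
  if (length(missing)) {
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(peaks)) {
    if (any(peaks$start < 0)) stop("peak start < 0")
    if (any(peaks$end <= peaks$start)) stop("peak end <= start")
    if (anyDuplicated(peaks$peak_id)) stop("duplicate peak_id in peak set")
    if (any(!nzchar(peaks$chrom))) stop("empty chromosome name")
  }
  if (is.null(peaks$score)) peaks$score <- NA_real_
  if (is.null(peaks$strand)) peaks$strand <- "."
  if (is.null(peaks$summit_offset)) peaks$summit_offset <- NA_integer_
  peaks
}

empty_peaks <- function() {
  new_peaks(character(), integer(), integer())
}

validate_genes <- function(genes) {
  stopifnot(is.data.frame(genes))
  req <- c("gene_id", "chrom", "start", "end", "strand", "tss", "tes")
  missing <- setdiff(req, names(genes))
  if (length(missing)) {
    stop("gene table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(genes)) {
    if (any(genes$end <= genes$start)) stop("gene end <= start")
    if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
    plus <- genes$strand == "+"
    if (any(genes$tss[plus] != genes$start[plus]) ||
        any(genes$tss[!plus] != genes$end[!plus] - 1L)) {
      stop("tss inconsistent with strand and gene extent")
    }
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  }
  if (is.null(genes$gene_name)) genes$gene_name <- genes$gene_id
  for (col in c("exons", "utr5", "utr3")) {
    if (is.null(genes[[col]])) {
      genes[[col]] <- replicate(nrow(genes), empty_blocks(), simplify = FALSE)
    }
  }
  genes
}

empty_blocks <- function() data.frame(start = integer(), end = integer())

#' Build a one-row-per-gene model table
#'
#' Convenience constructor used by the synthetic generator and tests. TSS and
#' TES are derived strand-aware from the gene extent; `exons` defaults to a
#' single exon covering the gene body.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome of each gene.
#' @param start,end 0-based half-open gene body extent.
#' @param strand `"+"` or `"-"` per gene.
#' @param gene_name optional display names (default: `gene_id`).
#' @param exons,utr5,utr3 optional list-columns of `start`/`end` block data
#'   frames, one element per gene.
#' @return a validated gene-model data frame (see [loopweaver-types]).
#' @export
new_genes <- function(gene_id, chrom, start, end, strand,
                      gene_name = gene_id, exons = NULL, utr5 = NULL,
                      utr3 = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  tss <- ifelse(strand == "+", start, end - 1L)
  tes <- ifelse(strand == "+", end - 1L, start)
  df <- data.frame(
    gene_id = as.character(gene_id), gene_name = as.character(gene_name),
    chrom = as.character(chrom), start = start, end = end,
    strand = as.character(strand), tss = as.integer(tss),
    tes = as.integer(tes), stringsAsFactors = FALSE
  )
  n <- nrow(df)
  df$exons <- if (is.null(exons)) {
    lapply(seq_len(n), function(i) data.frame(start = start[i], end = end[i]))
  } else exons
  df$utr5 <- if (is.null(utr5)) replicate(n, empty_blocks(), simplify = FALSE) else utr5
  df$utr3 <- if (is.null(utr3)) replicate(n, empty_blocks(), simplify = FALSE) else utr3
  validate_genes(df)
}

validate_loops <- function(loops) {
  stopifnot(is.data.frame(loops))
  req <- c("loop_id", "chrom", "start1", "end1", "start2", "end2")
  missing <- setdiff(req, names(loops))
  if (length(missing)) {
    stop("loop table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(loops)) {
    if (any(loops$end1 <= loops$start1) || any(loops$end2 <= loops$start2)) {
      stop("degenerate loop anchor (end <= start)")
    }
    if (any(loops$end1 > loops$start2)) {
      stop("left anchor must end at or before the right anchor starts")
    }
    if (anyDuplicated(loops$loop_id)) stop("duplicate loop_id")
  }
  loops
}

new_loops <- function(loop_id, chrom, start1, end1, start2, end2) {
  validate_loops(data.frame(
    loop_id = as.character(loop_id), chrom = as.character(chrom),
    start1 = as.integer(start1), end1 = as.integer(end1),
    start2 = as.integer(start2), end2 = as.integer(end2),
    stringsAsFactors = FALSE
  ))
}

#' Construct an expression matrix with an attached design
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids); RPKM-scale, non-negative.
#' @param design data frame with columns `sample_id`, `group` and optionally
#'   `donor`, one row per sample.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values` and `design`.
#' @export
expression_matrix <- function(values, design) {
  stopifnot(is.matrix(values), is.data.frame(design))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene id")
  if (any(values < 0)) stop("negative expression value")
  if (!all(c("sample_id", "group") %in% names(design))) {
    stop("design needs sample_id and group columns")
  }
  absent <- setdiff(colnames(values), design$sample_id)
  if (length(absent)) {
    stop("sample(s) missing from design: ", paste(absent, collapse = ", "))
  }
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  if (length(unique(design$group)) < 2) stop("design must contain >= 2 groups")
  structure(list(values = values, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples;", length(unique(x$design$group)), "groups\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# ---- GRanges bridges (internal) --------------------------------------------

intervals_to_gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
}

peaks_to_gr <- function(peaks) {
  gr <- intervals_to_gr(peaks$chrom, peaks$start, peaks$end)
  names(gr) <- peaks$peak_id
  gr
}

peak_midpoints <- function(peaks) {
  as.integer(floor((as.numeric(peaks$start) + as.numeric(peaks$end) - 1) / 2))
}

points_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos + 1L, width = 1L))
}
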