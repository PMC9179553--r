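#' Read ChIP-seq peak calls from a BED file
#'
#' Supports plain BED3/BED6 and ENCODE narrowPeak. Coordinates are kept
#' 0-based half-open exactly as in the file. Peaks lacking a name field (or
#' named `"."`) receive generated ids of the form `"<chrom>:<start>-<end>"`.
#' For narrowPeak input the 10th field (summit offset from peak start, in bp)
#' is stored as `summit_offset`; a value of -1 is treated as absent.
#'
#' @param path path to a tab-separated BED file; lines starting with `#`,
#'   `track` or `browser` are skipped.
#' @param dialect one of `"bed6"` (default, tolerates 3-6 columns), `"bed3"`,
#'   `"narrowPeak"`.
#' @param chr_normalize if `TRUE`, add a `"chr"` prefix to bare chromosome
#'   names (`"1"` becomes `"chr1"`). Chromosome matching elsewhere is
#'   exact-string, so inputs must agree on the convention.
#' @return a peak data frame (see [loopweaver-types]).
#' @export
read_bed <- function(path, dialect = c("bed6", "bed3", "narrowPeak"),
                     chr_normalize = FALSE) {
  dialect <- match.arg(dialect)
  lines <- read_data_lines(path)
  if (!length(lines)) return(empty_peaks())
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  ncol_min <- switch(dialect, bed3 = 3L, bed6 = 3L, narrowPeak = 10L)
  n <- length(fields)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  name <- character(n); score <- rep(NA_real_, n)
  strand <- rep(".", n); summit <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < ncol_min) {
      stop(sprintf("%s line %d: expected >= %d tab-separated fields, got %d",
                   path, lines$lineno[i], ncol_min, length(f)))
    }
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("%s line %d: non-numeric coordinates", path, lines$lineno[i]))
    }
    if (e <= s) {
      stop(sprintf("%s line %d: end (%d) <= start (%d)", path,
                   lines$lineno[i], e, s))
    }
    chrom[i] <- f[1]; start[i] <- s; end[i] <- e
    if (dialect != "bed3" && length(f) >= 4 && nzchar(f[4]) && f[4] != ".") {
      name[i] <- f[4]
    }
    if (dialect != "bed3" && length(f) >= 5 && f[5] != ".") {
      score[i] <- suppressWarnings(as.numeric(f[5]))
    }
    if (dialect != "bed3" && length(f) >= 6) strand[i] <- f[6]
    if (dialect == "narrowPeak") {
      sm <- suppressWarnings(as.integer(f[10]))
      if (!is.na(sm) && sm >= 0) summit[i] <- sm
    }
  }
  if (chr_normalize) chrom <- normalize_chrom(chrom)
  blank <- !nzchar(name)
  name[blank] <- sprintf("%s:%d-%d", chrom[blank], start[blank], end[blank])
  new_peaks(chrom, start, end, peak_id = name, score = score,
            strand = strand, summit_offset = summit)
}

#' Read chromatin loops from a BEDPE file
#'
#' Each record pairs two anchor intervals. Inter-chromosomal records are
#' dropped (a message reports the count, also available as attribute
#' `n_interchrom_dropped`). Anchors are reordered so the left anchor precedes
#' the right one; records whose anchors overlap after ordering are rejected
#' with a warning (attribute `n_overlapping_rejected`).
#'
#' @param path path to a tab-separated BEDPE file (>= 6 columns:
#'   chrom1,start1,end1,chrom2,start2,end2; optional 7th column = loop id).
#' @param chr_normalize as in [read_bed()].
#' @return a loop data frame (see [loopweaver-types]).
#' @export
read_bedpe <- function(path, chr_normalize = FALSE) {
  lines <- read_data_lines(path)
  out <- list(); dropped <- 0L; rejected <- 0L
  for (i in seq_along(lines$text)) {
    f <- strsplit(lines$text[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) {
      stop(sprintf("%s line %d: expected >= 6 fields", path, lines$lineno[i]))
    }
    co <- suppressWarnings(as.integer(f[c(2, 3, 5, 6)]))
    if (anyNA(co)) {
      stop(sprintf("%s line %d: non-numeric coordinates", path, lines$lineno[i]))
    }
    c1 <- f[1]; c2 <- f[4]
    if (chr_normalize) { c1 <- normalize_chrom(c1); c2 <- normalize_chrom(c2) }
    if (c1 != c2) { dropped <- dropped + 1L; next }
    s1 <- co[1]; e1 <- co[2]; s2 <- co[3]; e2 <- co[4]
    if (e1 <= s1 || e2 <= s2) {
      stop(sprintf("%s line %d: anchor end <= start", path, lines$lineno[i]))
    }
    if (s1 > s2) { tmp <- c(s1, e1); s1 <- s2; e1 <- e2; s2 <- tmp[1]; e2 <- tmp[2] }
    if (e1 > s2) {
      warning(sprintf("%s line %d: overlapping anchors, record rejected",
                      path, lines$lineno[i]))
      rejected <- rejected + 1L
      next
    }
    id <- if (length(f) >= 7 && nzchar(f[7]) && f[7] != ".") f[7] else
      sprintf("loop_%s:%d-%d", c1, s1, e2)
    out[[length(out) + 1L]] <- data.frame(
      loop_id = id, chrom = c1, start1 = s1, end1 = e1, start2 = s2,
      end2 = e2, stringsAsFactors = FALSE)
  }
  loops <- if (length(out)) do.call(rbind, out) else
    new_loops(character(), character(), integer(), integer(), integer(), integer())
  if (anyDuplicated(loops$loop_id)) {
    loops$loop_id <- make.unique(loops$loop_id, sep = "_")
  }
  loops <- validate_loops(loops)
  if (dropped > 0) {
    message(dropped, " inter-chromosomal BEDPE record(s) dropped")
  }
  attr(loops, "n_interchrom_dropped") <- dropped
  attr(loops, "n_overlapping_rejected") <- rejected
  loops
}

#' Read gene models from BED12 or GTF
#'
#' Produces one model per gene. BED12 blocks become exons; when a CDS is
#' present (BED12 `thickStart < thickEnd`, or GTF `CDS` features) the exonic
#' bases outside the CDS are split strand-aware into 5' and 3' UTR blocks;
#' without a CDS the UTR lists are empty. GTF coordinates (1-based inclusive)
#' are converted to 0-based half-open on read. When a GTF gene has several
#' transcripts the longest transcript (tie: lexicographically smallest
#' transcript id) defines the model, since all downstream rules operate per
#' gene, not per transcript.
#'
#' @param path input file.
#' @param format `"bed12"` or `"gtf"` (default: guessed from the extension).
#' @param chr_normalize as in [read_bed()].
#' @return a gene-model data frame (see [loopweaver-types]).
#' @export
read_gene_models <- function(path, format = NULL, chr_normalize = FALSE) {
  if (is.null(format)) {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed12"
  }
  format <- match.arg(format, c("bed12", "gtf"))
  genes <- if (format == "bed12") read_bed12_genes(path) else read_gtf_genes(path)
  if (chr_normalize) genes$chrom <- normalize_chrom(genes$chrom)
  validate_genes(genes)
}

read_bed12_genes <- function(path) {
  lines <- read_data_lines(path)
  if (!length(lines$text)) {
    return(new_genes(character(), character(), integer(), integer(), character()))
  }
  rows <- vector("list", length(lines$text))
  for (i in seq_along(lines$text)) {
    f <- strsplit(lines$text[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) {
      stop(sprintf("%s line %d: BED12 requires 12 fields", path, lines$lineno[i]))
    }
    start <- as.integer(f[2]); end <- as.integer(f[3]); strand <- f[6]
    thick_s <- as.integer(f[7]); thick_e <- as.integer(f[8])
    n_blocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks) {
      stop(sprintf("%s line %d: blockCount disagrees with blockSizes/blockStarts",
                   path, lines$lineno[i]))
    }
    ex_start <- start + offs
    ex_end <- ex_start + sizes
    if (offs[1] != 0L || ex_end[n_blocks] != end) {
      stop(sprintf("%s line %d: blocks inconsistent with chromStart/chromEnd",
                   path, lines$lineno[i]))
    }
    if (n_blocks > 1 && any(ex_start[-1] < ex_end[-n_blocks])) {
      stop(sprintf("%s line %d: exon blocks overlap or are unsorted",
                   path, lines$lineno[i]))
    }
    exons <- data.frame(start = ex_start, end = ex_end)
    utrs <- derive_utrs(exons, thick_s, thick_e, strand)
    rows[[i]] <- list(gene_id = f[4], chrom = f[1], start = start, end = end,
                      strand = strand, exons = exons, utr5 = utrs$utr5,
                      utr3 = utrs$utr3)
  }
  assemble_genes(rows)
}

# Exonic bases outside [cds_start, cds_end) split strand-aware into UTRs.
derive_utrs <- function(exons, cds_start, cds_end, strand) {
  if (is.na(cds_start) || is.na(cds_end) || cds_end <= cds_start) {
    return(list(utr5 = empty_blocks(), utr3 = empty_blocks()))
  }
  clip <- function(lo, hi) {
    s <- pmax(exons$start, lo); e <- pmin(exons$end, hi)
    keep <- e > s
    data.frame(start = s[keep], end = e[keep])
  }
  left <- clip(-Inf, cds_start)
  right <- clip(cds_end, Inf)
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]; meta <- meta[keep, , drop = FALSE]; type <- type[keep]
  if (!length(gr)) {
    return(assemble_genes(list()))
  }
  tx <- as.character(meta$transcript_id)
  gid <- as.character(meta$gene_id)
  gname <- if ("gene_name" %in% names(meta)) as.character(meta$gene_name) else gid
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type, tx = tx, gid = gid, gname = gname,
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (g in unique(df$gid)) {
    sub <- df[df$gid == g, , drop = FALSE]
    # longest transcript; tie -> lexicographically smallest transcript id
    tx_len <- vapply(split(sub, sub$tx), function(d) {
      ex <- d[d$type == "exon", , drop = FALSE]
      if (!nrow(ex)) ex <- d
      sum(ex$end - ex$start)
    }, numeric(1))
    ord <- order(-tx_len, names(tx_len))
    chosen <- names(tx_len)[ord[1]]
    sub <- sub[sub$tx == chosen, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (!nrow(ex)) ex <- sub
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    exons <- data.frame(start = ex$start, end = ex$end)
    utrs <- if (nrow(cds)) {
      derive_utrs(exons, min(cds$start), max(cds$end), ex$strand[1])
    } else list(utr5 = empty_blocks(), utr3 = empty_blocks())
    rows[[length(rows) + 1L]] <- list(
      gene_id = g, gene_name = sub$gname[1], chrom = ex$chrom[1],
      start = min(ex$start), end = max(ex$end), strand = ex$strand[1],
      exons = exons, utr5 = utrs$utr5, utr3 = utrs$utr3)
  }
  assemble_genes(rows)
}

assemble_genes <- function(rows) {
  if (!length(rows)) {
    return(new_genes(character(), character(), integer(), integer(), character()))
  }
  df <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    gene_name = vapply(rows, function(r) r$gene_name %||% r$gene_id, ""),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    strand = vapply(rows, `[[`, "", "strand"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id)) {
    # one model per gene id: keep the longest extent (tie: first occurrence)
    len <- df$end - df$start
    ord <- order(df$gene_id, -len)
    keep <- ord[!duplicated(df$gene_id[ord])]
    keep <- sort(keep)
    df <- df[keep, , drop = FALSE]; rows <- rows[keep]
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tes <- ifelse(df$strand == "+", df$end - 1L, df$start)
  df$exons <- lapply(rows, `[[`, "exons")
  df$utr5 <- lapply(rows, `[[`, "utr5")
  df$utr3 <- lapply(rows, `[[`, "utr3")
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a signed compartment eigenvector from bedGraph
#'
#' The track must be a fixed-step binning: every bin has width `bin_size`,
#' except that the last bin of a chromosome may be shorter. Gaps (missing
#' bins) are allowed. Bins are returned sorted within chromosome.
#'
#' @param path bedGraph path (`chrom  start  end  value`).
#' @param bin_size expected bin width in bp (the track resolution).
#' @param chr_normalize as in [read_bed()].
#' @return data frame `chrom`, `start`, `end`, `eigen` with attribute
#'   `bin_size`.
#' @export
read_bedgraph_eigenvector <- function(path, bin_size = 100000L,
                                      chr_normalize = FALSE) {
  lines <- read_data_lines(path)
  n <- length(lines$text)
  chrom <- character(n); start <- integer(n); end <- integer(n); val <- numeric(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines$text[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4) {
      stop(sprintf("%s line %d: bedGraph requires 4 fields", path, lines$lineno[i]))
    }
    chrom[i] <- f[1]; start[i] <- as.integer(f[2]); end[i] <- as.integer(f[3])
    val[i] <- as.numeric(f[4])
  }
  if (chr_normalize) chrom <- normalize_chrom(chrom)
  df <- data.frame(chrom = chrom, start = start, end = end, eigen = val,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (cm in unique(df$chrom)) {
    sub <- df[df$chrom == cm, , drop = FALSE]
    if (any(sub$start %% bin_size != 0)) {
      stop("bin start not a multiple of bin_size on ", cm)
    }
    w <- sub$end - sub$start
    bad <- w != bin_size
    # only the terminal (max-start) bin of a chromosome may be short
    bad[which.max(sub$start)] <- bad[which.max(sub$start)] && w[which.max(sub$start)] > bin_size
    if (any(bad)) {
      stop("bin of width != bin_size not at chromosome end on ", cm)
    }
  }
  attr(df, "bin_size") <- as.integer(bin_size)
  df
}

#' Read an RPKM expression table with its sample design
#'
#' @param path TSV with a gene-id first column and one column per sample.
#' @param design_path TSV mapping `sample_id` to `group` (and optionally
#'   `donor`).
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, design_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs gene ids plus >= 1 sample")
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) stop("duplicate gene id in expression table")
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("non-numeric or missing expression value")
  if (any(values < 0)) stop("negative expression value")
  rownames(values) <- gene_ids
  design <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                              comment.char = "#", stringsAsFactors = FALSE)
  expression_matrix(values, design)
}

#' Write a result table as deterministic TSV
#'
#' Rows are sorted lexicographically over all columns left to right and
#' written tab-separated with a header, so identical inputs always yield
#' byte-identical files; an empty table yields a header-only file.
#' [read_table()] reads the file back.
#'
#' @param records a data frame (list-columns are not supported).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.null(records)) stop("records must be non-null")
  stopifnot(is.data.frame(records))
  if (any(vapply(records, is.list, logical(1)))) {
    stop("list-columns cannot be serialized; flatten first")
  }
  if (nrow(records) > 1) {
    ord <- do.call(order, lapply(unname(as.list(records)), function(x) {
      if (is.numeric(x)) x else as.character(x)
    }))
    records <- records[ord, , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

# ---- shared parsing helpers ------------------------------------------------

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  lineno <- seq_along(raw)
  keep <- nzchar(raw) & !grepl("^(#|track\\b|browser\\b)", raw)
  list(text = raw[keep], lineno = lineno[keep])
}

normalize_chrom <- function(x) {
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}
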