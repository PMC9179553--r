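# Random-instance generators and tiny hand-built fixtures used across tests.

rand_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                       width_range = c(100, 2000)) {
  if (n == 0) return(loopweaver:::empty_peaks())
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  loopweaver:::new_peaks(sample(chroms, n, replace = TRUE), start,
                         start + width, peak_id = sprintf("p%04d", seq_len(n)))
}

# Genes with random exon/UTR structure (some minus strand, some UTR-less).
rand_genes <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6) {
  if (n == 0) {
    return(new_genes(character(), character(), integer(), integer(), character()))
  }
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(1000:30000, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  exons <- vector("list", n); utr5 <- vector("list", n); utr3 <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(1:4, 1)
    cuts <- sort(sample(seq(50, len[i] - 50, by = 25), 2 * (k - 1)))
    b <- c(0, cuts, len[i])
    ex <- data.frame(start = start[i] + b[seq(1, length(b), 2)],
                     end = start[i] + b[seq(2, length(b), 2)])
    exons[[i]] <- ex
    if (stats::runif(1) < 0.7) {
      cds_s <- ex$start[1] + sample.int(max(1, ex$end[1] - ex$start[1] - 1), 1)
      last <- nrow(ex)
      cds_e <- ex$end[last] - sample.int(max(1, ex$end[last] - ex$start[last] - 1), 1)
      if (cds_e > cds_s) {
        u <- loopweaver:::derive_utrs(ex, cds_s, cds_e, strand[i])
        utr5[[i]] <- u$utr5; utr3[[i]] <- u$utr3
      } else {
        utr5[[i]] <- loopweaver:::empty_blocks(); utr3[[i]] <- loopweaver:::empty_blocks()
      }
    } else {
      utr5[[i]] <- loopweaver:::empty_blocks(); utr3[[i]] <- loopweaver:::empty_blocks()
    }
  }
  new_genes(sprintf("g%04d", seq_len(n)), sample(chroms, n, replace = TRUE),
            start, start + len, strand, exons = exons, utr5 = utr5,
            utr3 = utr3)
}

rand_loops <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6) {
  if (n == 0) {
    return(loopweaver:::new_loops(character(), character(), integer(),
                                  integer(), integer(), integer()))
  }
  start1 <- sample.int(max_pos, n, replace = TRUE)
  aw1 <- sample(2000:10000, n, replace = TRUE)
  gap <- sample(0:200000, n, replace = TRUE)
  aw2 <- sample(2000:10000, n, replace = TRUE)
  loopweaver:::new_loops(sprintf("L%03d", seq_len(n)),
                         sample(chroms, n, replace = TRUE),
                         start1, start1 + aw1, start1 + aw1 + gap,
                         start1 + aw1 + gap + aw2)
}

# Expression matrix from a plain gene x sample value matrix.
make_em <- function(values, groups, donor = "d1") {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  expression_matrix(values, data.frame(sample_id = colnames(values),
                                       group = groups, donor = donor,
                                       stringsAsFactors = FALSE))
}

# Two-group lognormal matrix with planted log2 fold changes.
sim_two_group <- function(n_genes, n_per_group = 3, lfc = 0, sigma = 0.25,
                          groups = c("A", "B")) {
  mu <- stats::rnorm(n_genes, 3, 1.5)
  lfc <- rep_len(lfc, n_genes)
  a <- 2^(mu + lfc + matrix(stats::rnorm(n_genes * n_per_group, 0, sigma),
                            n_genes))
  b <- 2^(mu + matrix(stats::rnorm(n_genes * n_per_group, 0, sigma), n_genes))
  make_em(cbind(a, b), rep(groups, each = n_per_group))
}

tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
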