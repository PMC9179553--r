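test_that("loop spans run from left-anchor end to right-anchor start", {
  loops <- loopweaver:::new_loops(c("L1", "L2"), "chr1",
                                  c(100000L, 700000L), c(110000L, 710000L),
                                  c(495000L, 710000L), c(505000L, 720000L))
  parts <- derive_loop_parts(loops)
  expect_equal(parts$span_start[1], 110000L)
  expect_equal(parts$span_end[1], 495000L)
  expect_false(parts$zero_span[1])
  expect_true(parts$zero_span[2])       # adjacent anchors
  # definition equality on random loops
  set.seed(501)
  rl <- rand_loops(100)
  rp <- derive_loop_parts(rl)
  expect_equal(rp$span_start, rl$end1)
  expect_equal(rp$span_end, rl$start2)
})

test_that("shared loops require both anchors to overlap in every donor", {
  l1 <- loopweaver:::new_loops("A", "chr1", 100, 200, 1000, 1100)
  expect_equal(nrow(shared_loops(list(l1, l1))), 1)
  sh <- shared_loops(list(l1, l1))
  expect_equal(sh$start1, 100L)
  expect_equal(sh$end2, 1100L)
  # left anchors overlap, right anchors disjoint -> not shared
  l2 <- loopweaver:::new_loops("B", "chr1", 150, 250, 2000, 2100)
  expect_equal(nrow(shared_loops(list(l1, l2))), 0)
  # intersection coordinates mode
  l3 <- loopweaver:::new_loops("C", "chr1", 150, 250, 950, 1050)
  shi <- shared_loops(list(l1, l3), coords = "intersection")
  expect_equal(shi$start1, 150L)
  expect_equal(shi$end1, 200L)
  expect_equal(shi$start2, 1000L)
  expect_equal(shi$end2, 1050L)
})

test_that("jittered donor loop sets share exactly the brute-force pairs", {
  set.seed(502)
  for (rep in 1:8) {
    base <- rand_loops(40, chroms = "chr1", max_pos = 2e6)
    jitter <- function(l) {
      d <- sample(-3000:3000, nrow(l), replace = TRUE)
      keep <- l$end1 + d < l$start2 + d  # always true; jitter whole loop
      loopweaver:::new_loops(paste0(l$loop_id, "j"), l$chrom,
                             l$start1 + d, l$end1 + d,
                             l$start2 + d, l$end2 + d)
    }
    other <- jitter(base)
    pairs <- oracle_shared_loops(base, other)
    # pairs whose merged anchors would touch are dropped by the union rule
    ok <- if (!nrow(pairs)) logical(0) else apply(pairs, 1, function(ij) {
      i <- ij[1]; j <- ij[2]
      max(base$end1[i], other$end1[j]) <= min(base$start2[i], other$start2[j])
    })
    want_ids <- sort(paste0(base$loop_id[pairs[ok, 1]], "|",
                            other$loop_id[pairs[ok, 2]]))
    got <- suppressWarnings(shared_loops(list(base, other)))
    expect_equal(sort(got$loop_id), want_ids)
  }
})

test_that("the four interaction categories follow the stated geometry", {
  loops <- loopweaver:::new_loops("L1", "chr1", 100000, 110000, 495000, 505000)
  parts <- derive_loop_parts(loops)
  gene <- new_genes("gR", "chr1", 500000, 508000, "+")   # TSS in right anchor
  p_anchor <- loopweaver:::new_peaks("chr1", 102000, 102500, "pk")
  rec <- classify_interactions(p_anchor, parts, gene)
  expect_equal(rec$category, "anchor_anchor")
  expect_equal(rec$peak_location, "left_anchor")
  expect_equal(rec$gene_location, "right_anchor")

  p_span <- loopweaver:::new_peaks("chr1", 300000, 300200, "pk2")
  rec2 <- classify_interactions(p_span, parts, gene)
  expect_equal(rec2$category, "span_anchor")

  g_span <- new_genes("gS", "chr1", 200000, 205000, "+")
  rec3 <- classify_interactions(p_anchor, parts, g_span)
  expect_equal(rec3$category, "anchor_span")

  # direct is independent of loops
  p_prom <- loopweaver:::new_peaks("chr1", 499000, 499500, "pk3")
  rec4 <- classify_interactions(p_prom, parts, gene)
  expect_true("direct" %in% rec4$category)
  rec5 <- classify_interactions(p_prom, NULL, gene)
  expect_equal(rec5$category, "direct")
  expect_true(is.na(rec5$loop_id))

  # peak and TSS in the same anchor: diagnostic only, no anchor_anchor
  p_same <- loopweaver:::new_peaks("chr1", 496000, 496400, "pk4")
  rec6 <- classify_interactions(p_same, parts, gene)
  expect_false("anchor_anchor" %in% rec6$category)
  expect_equal(attr(rec6, "same_anchor")$anchor, "right_anchor")
})

test_that("classification matches the brute-force triple loop on random data", {
  set.seed(503)
  for (rep in 1:10) {
    peaks <- rand_peaks(60, max_pos = 8e5)
    genes <- rand_genes(30, max_pos = 8e5)
    loops <- rand_loops(12, max_pos = 8e5)
    got <- classify_interactions(peaks, derive_loop_parts(loops), genes)
    want <- oracle_classify(peaks, loops, genes)
    expect_equal(got[, c("peak_id", "gene_id", "category", "loop_id")],
                 want, ignore_attr = TRUE)
  }
})

test_that("classification is order-invariant and monotone in its windows", {
  set.seed(504)
  peaks <- rand_peaks(50, max_pos = 6e5)
  genes <- rand_genes(25, max_pos = 6e5)
  loops <- rand_loops(10, max_pos = 6e5)
  parts <- derive_loop_parts(loops)
  base <- classify_interactions(peaks, parts, genes)
  perm <- classify_interactions(peaks[sample(nrow(peaks)), ],
                                parts[sample(nrow(parts)), ],
                                genes[sample(nrow(genes)), ])
  expect_equal(base, perm, ignore_attr = TRUE)

  # a larger promoter window never loses a direct record
  wide <- classify_interactions(peaks, parts, genes,
                                promoter_halfwidth = 5000)
  key <- function(df) {
    d <- df[df$category == "direct", ]
    paste(d$peak_id, d$gene_id)
  }
  expect_true(all(key(base) %in% key(wide)))

  # widening anchors never loses an anchor-based record
  grown <- loops
  grown$start1 <- grown$start1 - 1000L
  grown$end2 <- grown$end2 + 1000L
  grown$end1 <- grown$end1 + pmin(1000L, (grown$start2 - grown$end1) %/% 2L)
  rec_g <- classify_interactions(peaks, derive_loop_parts(grown), genes)
  akey <- function(df) {
    d <- df[df$category == "anchor_anchor", ]
    paste(d$peak_id, d$gene_id, d$loop_id)
  }
  expect_true(all(akey(base) %in% akey(rec_g)))
})

test_that("per-category tallies count deduplicated genes and a single union", {
  asn <- data.frame(
    peak_id = c("p1", "p2", "p3", "p4", "p5"),
    gene_id = c("a", "b", "c", "b", "b"),
    category = c("direct", "direct", "anchor_anchor", "anchor_anchor",
                 "span_anchor"),
    loop_id = c(NA, NA, "L1", "L2", "L3"),
    stringsAsFactors = FALSE)
  res <- integrate_with_deg(asn, deg = c("b"),
                            expressed_genes = c("a", "b", "c"))
  pc <- res$per_category
  expect_equal(pc$genes_total[pc$category == "direct"], 2L)
  expect_equal(pc$genes_deg[pc$category == "direct"], 1L)
  expect_equal(pc$genes_deg[pc$category == "anchor_anchor"], 1L)
  expect_equal(pc$genes_deg[pc$category == "span_anchor"], 1L)
  # gene b sits in three categories but once in the union
  expect_equal(res$deg_union, "b")
  # namespace sanity check
  expect_error(
    integrate_with_deg(asn, deg = "zz", expressed_genes = c("x1", "x2")),
    "namespace mismatch")
})

test_that("loop-aware capture strictly exceeds the baseline on loop-only targets", {
  # DEG gene on the far anchor 400 kb from the peak; a non-DEG gene 10 kb away
  loops <- loopweaver:::new_loops("L1", "chr1", 100000, 110000, 500000, 510000)
  peaks <- loopweaver:::new_peaks("chr1", 102000, 102600, "pk")
  genes <- new_genes(c("far_deg", "near_bystander"), "chr1",
                     c(505000, 112000), c(507000, 114000), c("+", "+"))
  asn <- classify_interactions(peaks, derive_loop_parts(loops), genes)
  expect_true(any(asn$gene_id == "far_deg" & asn$category == "anchor_anchor"))
  integ <- integrate_with_deg(asn, deg = "far_deg",
                              expressed_genes = genes$gene_id)
  cmp <- compare_with_closest_gene(integ, closest_gene_within(peaks, genes))
  expect_equal(cmp$baseline_genes, "near_bystander")
  expect_equal(cmp$union_deg, "far_deg")
  expect_equal(length(cmp$union_captured), 0)
  pc <- cmp$per_category
  expect_equal(pc$captured_by_closest[pc$category == "anchor_anchor"], 0L)
})
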