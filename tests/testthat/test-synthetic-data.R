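small_spec <- function(...) {
  landscape_spec(n_chromosomes = 2, n_loops = 14, n_peaks = 50, n_genes = 40,
                 category_mix = c(direct = 5, anchor_anchor = 4,
                                  anchor_span = 4, span_anchor = 4),
                 ...)
}

test_that("generated landscapes are recovered exactly by the classifier", {
  land <- generate_landscape(small_spec(seed = 21))
  asn <- classify_interactions(land$peaks, derive_loop_parts(land$loops),
                               land$genes)
  got <- sort_records(asn[, c("peak_id", "gene_id", "category", "loop_id")])
  want <- sort_records(land$truth$assignments)
  expect_equal(got, want, ignore_attr = TRUE)
  expect_equal(nrow(want), 17)   # the planted mix
})

test_that("identical spec and seed give byte-identical files", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_landscape(small_spec(seed = 33), outdir = d1)
  generate_landscape(small_spec(seed = 33), outdir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  # a different seed must move something
  d3 <- file.path(tempdir(), "det3")
  generate_landscape(small_spec(seed = 34), outdir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "peaks.bed"))),
                         unname(tools::md5sum(file.path(d3, "peaks.bed")))))
})

test_that("degenerate and infeasible specs are handled up front", {
  empty <- landscape_spec(n_peaks = 0,
                          category_mix = c(direct = 0, anchor_anchor = 0,
                                           anchor_span = 0, span_anchor = 0),
                          n_loops = 10, n_genes = 10, n_chromosomes = 2,
                          seed = 1)
  land <- generate_landscape(empty)
  expect_equal(nrow(land$peaks), 0)
  expect_equal(nrow(land$truth$assignments), 0)

  expect_error(landscape_spec(n_peaks = 3,
                              category_mix = c(direct = 2, anchor_anchor = 2,
                                               anchor_span = 0,
                                               span_anchor = 0)),
               "exceed n_peaks")
  expect_error(landscape_spec(n_loops = 2,
                              category_mix = c(direct = 0, anchor_anchor = 2,
                                               anchor_span = 1,
                                               span_anchor = 0)),
               "more loop-planted")
  expect_error(landscape_spec(n_chromosomes = 1, chrom_length = 1e6,
                              n_loops = 30,
                              category_mix = c(direct = 0, anchor_anchor = 0,
                                               anchor_span = 0,
                                               span_anchor = 0)),
               "packed")
})

test_that("planted compartment fractions are achieved exactly", {
  for (s in c(5, 6)) {
    land <- generate_landscape(small_spec(seed = s,
                                          fraction_peaks_in_B = 0.68))
    fr <- peaks_in_compartments(land$peaks, land$eigen)
    expect_equal(fr$fraction_B, land$truth$fraction_B)
    expect_equal(fr$fraction_B, 0.68)   # 34 of 50 peaks
    expect_equal(fr$per_peak$label, land$truth$peak_compartments$label)
  }
})

test_that("expression simulation plants folds and the attenuation limits hold", {
  spec <- small_spec(seed = 41,
                     deg_spec = list(n_up = 6, n_down = 3,
                                     noise_sigma_log2 = 0,
                                     zero_fraction = 0))
  genes <- generate_landscape(spec)$genes
  sim <- simulate_expression(spec, genes)
  v <- sim$matrix$values
  des <- sim$matrix$design
  up <- sim$truth$gene_id[sim$truth$planted == "up"]
  dn <- sim$truth$gene_id[sim$truth$planted == "down"]
  mv <- rowMeans(v[, des$group == "V"])
  me <- rowMeans(v[, des$group == "E2"])
  mm <- rowMeans(v[, des$group == "E2+MPA"])
  # with zero noise the planted ratios are exact
  expect_equal(unname(me[up] / mv[up]), rep(4, 6))
  expect_equal(unname(me[dn] / mv[dn]), rep(0.25, 3))
  expect_equal(unname(mm[up] / mv[up]), rep(2, 6))   # fold^0.5
  # attenuation limits: 1 -> same as treatment, 0 -> same as baseline
  s1 <- simulate_expression(small_spec(
    seed = 41, deg_spec = list(n_up = 6, n_down = 3, noise_sigma_log2 = 0,
                               attenuation_factor = 1, zero_fraction = 0)),
    genes)
  v1 <- s1$matrix$values
  expect_equal(v1[, s1$matrix$design$group == "E2+MPA"][, 1],
               v1[, s1$matrix$design$group == "E2"][, 1])
  s0 <- simulate_expression(small_spec(
    seed = 41, deg_spec = list(n_up = 6, n_down = 3, noise_sigma_log2 = 0,
                               attenuation_factor = 0, zero_fraction = 0)),
    genes)
  v0 <- s0$matrix$values
  expect_equal(v0[, s0$matrix$design$group == "E2+MPA"][, 1],
               v0[, s0$matrix$design$group == "V"][, 1])
  expect_error(
    simulate_expression(small_spec(
      seed = 1, deg_spec = list(n_replicates = 1)), genes),
    "n_replicates")
})

test_that("baseline zero injection feeds the zero-replacement rule", {
  spec <- small_spec(seed = 51,
                     deg_spec = list(n_up = 8, n_down = 4,
                                     zero_fraction = 0.2))
  genes <- generate_landscape(spec)$genes
  sim <- simulate_expression(spec, genes)
  v <- sim$matrix$values
  base_cols <- sim$matrix$design$group == "V"
  expect_true(any(v[, base_cols] == 0))
  expect_true(all(v[, !base_cols] > 0))
  repl <- replace_vehicle_zeros(sim$matrix, "V")
  expect_true(all(repl$values > 0))
  z <- which(v[, base_cols] == 0, arr.ind = TRUE)[1, ]
  gmax <- max(v[z[1], ])
  expect_equal(repl$values[, base_cols][z[1], z[2]], 0.0005 * gmax)
})
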