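test_that("build_table joins expression onto the protein-call universe", {
  calls <- u2os_fixture()$calls[1:3, ]
  expr <- tibble::tibble(gene_id = calls$gene_id[1:2], reads = c(4L, 0L),
                         rpkm = c(2.5, 0), present = c(TRUE, FALSE))
  expect_message(rec <- build_table(expr, calls), "without expression")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$rpkm[3], 0)
  expect_false(rec$rna_present[3])

  expect_equal(nrow(build_table(expr, calls[0, ])), 0)
  dup <- dplyr::bind_rows(calls, calls[1, ])
  expect_error(build_table(expr, dup), "duplicate gene_id")
})

test_that("venn partitions genes exactly and conserves the total", {
  rec <- make_records(ihc = c(TRUE, TRUE, FALSE, FALSE),
                      if_ = c(TRUE, FALSE, TRUE, FALSE),
                      rna = c(TRUE, FALSE, FALSE, FALSE))
  v <- venn(rec)
  expect_equal(as.integer(v[c("ABC", "A", "B", "none")]), rep(1L, 4))
  expect_equal(sum(as.integer(v)), attr(v, "total"))

  all_false <- make_records(rep(FALSE, 5), rep(FALSE, 5), rep(FALSE, 5))
  expect_equal(as.integer(venn(all_false)["none"]), 5L)

  set.seed(9)
  r <- make_records(sample(c(TRUE, FALSE), 200, TRUE),
                    sample(c(TRUE, FALSE), 200, TRUE),
                    sample(c(TRUE, FALSE), 200, TRUE))
  expect_equal(sum(as.integer(venn(r))), 200L)
})

test_that("overlap summary agrees with percentages computed directly from records", {
  set.seed(17)
  rec <- make_records(sample(c(TRUE, FALSE), 300, TRUE),
                      sample(c(TRUE, FALSE), 300, TRUE),
                      sample(c(TRUE, FALSE), 300, TRUE))
  ov <- overlap_summary(venn(rec))
  gf <- function(m) ov$fraction[ov$metric == m]
  expect_equal(gf("rna_presence"), mean(rec$rna_present))
  expect_equal(gf("ihc_presence"), mean(rec$ihc_present))
  expect_equal(gf("rna_coverage_of_ihc"),
               sum(rec$rna_present & rec$ihc_present) / sum(rec$ihc_present))
  expect_equal(gf("transcript_not_if"),
               sum(rec$rna_present & !rec$if_present) / sum(rec$rna_present))
  expect_equal(gf("either_protein_to_both"),
               sum(rec$ihc_present & rec$if_present) /
                 sum(rec$ihc_present | rec$if_present))

  # single-group edge: everything in ABC -> all coverages 100%
  solo <- make_records(rep(TRUE, 10), rep(TRUE, 10), rep(TRUE, 10))
  ovs <- overlap_summary(venn(solo))
  expect_equal(ovs$percent[ovs$metric == "rna_coverage_of_ihc"], 100)
  # zero denominator reported as NA, not 0
  none <- make_records(rep(FALSE, 4), rep(FALSE, 4), rep(FALSE, 4))
  ovn <- overlap_summary(venn(none))
  expect_true(is.na(ovn$percent[ovn$metric == "rna_coverage_of_ihc"]))
})

test_that("chi-square association matches the closed form and handles correction", {
  ind <- matrix(c(50, 50, 50, 50), 2)
  res <- association_test(ind, correction = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  m <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(association_test(m, correction = FALSE)$statistic,
               oracle_chisq_2x2(m))
  expect_equal(association_test(m, correction = FALSE)$statistic, 20)

  set.seed(5)
  for (i in 1:20) {
    t <- matrix(sample(1:80, 4, TRUE), 2)
    expect_equal(association_test(t, correction = FALSE)$statistic,
                 oracle_chisq_2x2(t), tolerance = 1e-10)
  }
  degenerate <- matrix(c(0, 0, 5, 5), 2)
  expect_error(association_test(degenerate), "exact test")
})

test_that("2x2 presence tables are oriented rna x protein", {
  rec <- make_records(ihc = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                      if_ = c(TRUE, FALSE, FALSE, TRUE, TRUE),
                      rna = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  tab <- contingency_2x2(rec, "ihc")
  expect_equal(unname(tab), matrix(c(2, 1, 1, 1), 2, byrow = TRUE))
  expect_equal(sum(tab), 5)
})

test_that("one-sided KS statistic matches brute-force evaluation", {
  same <- ks_one_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  disjoint <- ks_one_sided(c(1, 2), c(3, 4), alternative = "lower")
  expect_equal(disjoint$statistic, 1)

  set.seed(31)
  for (i in 1:25) {
    x <- round(stats::rlnorm(20), 2)
    y <- round(stats::rlnorm(50), 2)
    for (alt in c("lower", "greater")) {
      expect_equal(ks_one_sided(x, y, alt)$statistic,
                   oracle_ks_one_sided(x, y, alt), tolerance = 1e-12)
    }
  }
  expect_error(ks_one_sided(1, c(1, 2)), "at least 2")
})

test_that("one-sided KS agrees with stats::ks.test on tie-free data", {
  set.seed(12)
  x <- stats::rnorm(40)
  y <- stats::rnorm(60, 0.5)
  ours <- ks_one_sided(x, y, "lower")
  ref <- suppressWarnings(stats::ks.test(x, y, alternative = "greater",
                                         exact = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("per-group CDFs are step functions anchored to the reference", {
  rec <- make_records(ihc = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
                      if_ = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
                      rna = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
                      rpkm = c(5, 6, 1, 2, 3, 7))
  cdfs <- expression_cdf_by_group(rec, groups = c("C", "ABC"))
  expect_equal(cdfs$C(2), 2 / 3)
  expect_equal(cdfs$reference(max(rec$rpkm)), 1)
  # group sampled from the low tail dominates the reference everywhere
  grid <- sort(unique(rec$rpkm))
  expect_true(all(cdfs$C(grid) >= cdfs$reference(grid)))
  expect_warning(expression_cdf_by_group(rec, groups = c("AB", "ABC")),
                 "empty")
})

test_that("expression bins are equal-size quantiles with deterministic ties", {
  rec <- make_records(rep(TRUE, 100), rep(TRUE, 100), rep(TRUE, 100),
                      rpkm = rep(c(0, 2), 50))
  bo <- bin_overlap(rec, n_bins = 25)
  expect_equal(bo$bins$n_genes, rep(4L, 25))
  expect_equal(sum(bo$bins$n_genes), 100)
  expect_true(all(bo$bins$pct_ihc_present == 100))
  expect_equal(bo$halves$pct_if_present, c(100, 100))

  # weighted mean of per-bin percentages equals the overall percentage
  set.seed(23)
  r2 <- make_records(sample(c(TRUE, FALSE), 203, TRUE),
                     sample(c(TRUE, FALSE), 203, TRUE),
                     rep(TRUE, 203),
                     rpkm = stats::rlnorm(203))
  b2 <- bin_overlap(r2, n_bins = 25)
  expect_equal(sum(b2$bins$n_genes), 203)
  expect_equal(sum(b2$bins$n_genes * b2$bins$pct_ihc_present) / 203,
               100 * mean(r2$ihc_present), tolerance = 1e-10)
  expect_equal(sum(b2$bins$n_genes * b2$bins$pct_if_present) / 203,
               100 * mean(r2$if_present), tolerance = 1e-10)

  # ties broken by gene id: row order must not matter
  shuffled <- r2[sample(nrow(r2)), ]
  b3 <- bin_overlap(shuffled, n_bins = 25)
  expect_equal(b3$bins, b2$bins)

  expect_error(bin_overlap(r2[1:10, ], n_bins = 25), "fewer genes")
})

test_that("supportive-WB restriction filters the binned denominator", {
  rec <- make_records(rep(c(TRUE, FALSE), 30), rep(TRUE, 60),
                      rep(TRUE, 60), rpkm = seq_len(60),
                      wb_score = rep(c(1L, 7L, 4L), 20))
  bo <- bin_overlap(rec, n_bins = 4, restrict_supportive_wb = TRUE)
  expect_equal(sum(bo$bins$n_genes), 20)  # only wb_score 1 is supportive
})
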