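mk_aln <- function(mismatches) {
  n <- length(mismatches)
  list(read_id = "r",
       hits = if (n == 0) NULL else
         data.frame(chrom = "chr1", start = seq_len(n) * 1000L,
                    end = seq_len(n) * 1000L + 35L, strand = "+",
                    mismatches = mismatches))
}

test_that("clear-zone uniqueness rule classifies the canonical cases", {
  cfg <- quant_config()
  expect_equal(classify_read(mk_aln(0L), cfg)$status, "unique")
  # competitor inside the clear zone
  expect_equal(classify_read(mk_aln(c(1L, 2L)), cfg)$status, "ambiguous")
  # competitor beyond the zone: 3 > 0 + 2
  dec <- classify_read(mk_aln(c(0L, 3L)), cfg)
  expect_equal(dec$status, "unique")
  expect_equal(dec$chosen_hit$mismatches, 0L)
  # best hit above the mismatch cap
  expect_equal(classify_read(mk_aln(4L), cfg)$status, "discarded_mismatch")
  expect_equal(classify_read(mk_aln(integer(0)), cfg)$status, "unmapped")
  # tie at the minimum
  expect_equal(classify_read(mk_aln(c(2L, 2L)), cfg)$status, "ambiguous")
})

test_that("single-read and vectorised classifiers agree on random hit lists", {
  cfg <- quant_config()
  set.seed(11)
  hits <- NULL
  expected <- character(0)
  ids <- sprintf("r%03d", 1:150)
  for (i in seq_along(ids)) {
    k <- sample(0:4, 1)
    m <- if (k > 0) sample(0:5, k, replace = TRUE) else integer(0)
    expected[i] <- classify_read(mk_aln(m), cfg)$status
    if (k > 0) {
      hits <- rbind(hits, data.frame(read_id = ids[i], chrom = "c",
                                     start = 1:k, end = 1:k + 35,
                                     strand = "+", mismatches = m))
    }
  }
  aln <- structure(list(
    reads = tibble::tibble(read_id = ids, read_length = 35L,
                           n_hits = tabulate(match(hits$read_id, ids),
                                             length(ids))),
    hits = tibble::as_tibble(hits)), class = "read_alignments")
  dec <- txpconcord:::classify_reads(aln, cfg)
  expect_equal(dec$status[match(ids, dec$read_id)], unname(expected))
})

test_that("read assignment requires full containment within an exon", {
  gm <- gene_models(data.frame(gene_id = c("g1", "g1", "g2"),
                               chrom = "chr1",
                               start = c(100, 200, 105),
                               end = c(200, 300, 150)))
  hit <- data.frame(chrom = "chr1", start = 110, end = 145, strand = "+")
  expect_setequal(assign_read_to_genes(hit, gm), c("g1", "g2"))
  # straddles the exon boundary: no assignment in single-exon mode
  straddle <- data.frame(chrom = "chr1", start = 195, end = 230,
                         strand = "+")
  expect_length(assign_read_to_genes(straddle, gm), 0)
  # ...but g1's exons [100,200)+[200,300) merge to [100,300)
  expect_equal(assign_read_to_genes(straddle, gm,
                                    containment = "merged_exons"), "g1")
  intergenic <- data.frame(chrom = "chr1", start = 5000, end = 5035,
                           strand = "+")
  expect_length(assign_read_to_genes(intergenic, gm), 0)
})

test_that("quantify counts hand-placed reads and computes RPKM", {
  gm <- gene_models(data.frame(gene_id = c("gA", "gB", "gC"),
                               chrom = "chr1",
                               start = c(0, 10000, 20000),
                               end = c(1000, 11000, 22000)))
  # gA: 2 contained reads, gB: 0, gC: 5
  starts <- c(10, 500, 20000, 20500, 21000, 21500, 21900)
  hits <- tibble::tibble(read_id = sprintf("r%d", 1:7), chrom = "chr1",
                         start = as.integer(starts),
                         end = as.integer(starts + 35), strand = "+",
                         mismatches = 0L)
  aln <- structure(list(reads = tibble::tibble(read_id = hits$read_id,
                                               read_length = 35L,
                                               n_hits = 1L),
                        hits = hits), class = "read_alignments")
  expr <- quantify(aln, gm)
  expect_equal(expr$reads[match(c("gA", "gB", "gC"), expr$gene_id)],
               c(2L, 0L, 5L))
  expect_equal(attr(expr, "library_size"), 7)
  expect_equal(expr$present, expr$reads >= 1)
  # closed form: C = 2, L = 1000, N = 7
  expect_equal(expr$rpkm[expr$gene_id == "gA"], 1e9 * 2 / (1000 * 7))

  cfg <- quant_config(library_size = 1e6)
  expr2 <- quantify(aln, gm, cfg)
  # C = 2, L = 1000, N = 1e6 -> RPKM = 2000... scaled: C=10,L=1000,N=1e6 -> 10
  expect_equal(expr2$rpkm[expr2$gene_id == "gA"] * 5, 10)
})

test_that("counts are conserved on overlap-free models and RPKM is scale-invariant", {
  set.seed(3)
  ds <- simulate_dataset(sim_config(n_genes = 120, depth = 5000,
                                    multimap_rate = 0, unmapped_rate = 0,
                                    seed = 5))
  expr <- quantify(ds$alignments, ds$genes)
  # simulated gene models never overlap: every assigned read counts once
  expect_equal(sum(expr$reads), attr(expr, "n_assigned"))
  expect_equal(sum(expr$reads), attr(expr, "n_unique"))

  # duplicate every read and double the library size: RPKM unchanged
  aln <- ds$alignments
  dup <- aln$hits
  dup$read_id <- paste0(dup$read_id, "_copy")
  aln2 <- structure(list(
    reads = dplyr::bind_rows(aln$reads,
                             dplyr::mutate(aln$reads,
                                           read_id = paste0(read_id,
                                                            "_copy"))),
    hits = dplyr::bind_rows(aln$hits, dup)), class = "read_alignments")
  expr2 <- quantify(aln2, ds$genes)
  expect_equal(expr2$reads, 2L * expr$reads)
  expect_equal(attr(expr2, "library_size"), 2 * attr(expr, "library_size"))
  expect_equal(expr2$rpkm, expr$rpkm, tolerance = 1e-12)
})

test_that("shared reads can be counted per gene or discarded", {
  gm <- gene_models(data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                               start = c(100, 120), end = c(300, 320)))
  hits <- tibble::tibble(read_id = c("r1", "r2"), chrom = "chr1",
                         start = c(150L, 101L), end = c(185L, 136L),
                         strand = "+", mismatches = 0L)
  aln <- structure(list(reads = tibble::tibble(read_id = c("r1", "r2"),
                                               read_length = 35L,
                                               n_hits = 1L),
                        hits = hits), class = "read_alignments")
  expr <- quantify(aln, gm)  # r1 inside both genes, r2 only g1
  expect_equal(sum(expr$reads), 3L)          # shared read counted twice
  expect_equal(attr(expr, "n_assigned"), 2L) # but library size counts reads
  expr2 <- quantify(aln, gm, quant_config(multi_gene = "discard_shared"))
  expect_equal(expr2$reads[expr2$gene_id == "g1"], 1L)
  expect_equal(expr2$reads[expr2$gene_id == "g2"], 0L)
})

test_that("presence rate reports fractions of detected transcripts", {
  expect_equal(presence_rate(c(TRUE, FALSE, FALSE))$percent, 33.3)
  expect_equal(presence_rate(rep(TRUE, 10))$percent, 100)
  pr <- presence_rate(transcriptome_fixture(21146, 15536))
  expect_equal(pr$n_present, 15536)
  expect_equal(pr$fraction, 15536 / 21146)
  expect_error(presence_rate(logical(0)), "no genes")
})

test_that("quantification recovers expression ranks from simulated reads", {
  ds <- simulate_dataset(sim_config(n_genes = 150, depth = 150 * 60,
                                    seed = 21))
  expr <- quantify(ds$alignments, ds$genes)
  j <- dplyr::inner_join(expr, ds$truth, by = "gene_id")
  j <- j[j$true_rpkm > 0, ]
  expect_gt(cor(j$rpkm, j$true_rpkm, method = "spearman"), 0.9)
})
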