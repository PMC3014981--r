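# Shared fixture builders and independent brute-force oracles.

# --- file fixtures ---------------------------------------------------------

write_gtf_fixture <- function(exons, path = tempfile(fileext = ".gtf")) {
  # exons: data.frame gene_id, chrom, start, end (0-based half-open), strand
  if (is.null(exons$strand)) exons$strand <- "+"
  lines <- sprintf(
    "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t\";",
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$gene_id)
  writeLines(lines, path)
  path
}

write_sam_fixture <- function(hits, unmapped = character(),
                              chrom_len = 100000L,
                              path = tempfile(fileext = ".sam")) {
  # hits: data.frame read_id, chrom, start (0-based), len, mismatches
  chroms <- unique(hits$chrom)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, chrom_len))
  sec <- duplicated(hits$read_id)
  flag <- ifelse(sec, 256L, 0L)
  seq_field <- ifelse(sec, "*", strrep("A", hits$len))
  qual <- ifelse(sec, "*", strrep("I", hits$len))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  hits$read_id, flag, hits$chrom, hits$start + 1L,
                  hits$len, seq_field, qual, hits$mismatches)
  unm <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                 unmapped, strrep("A", 35L), strrep("I", 35L))
  writeLines(c(header, body, unm), path)
  path
}

write_alignment_tsv_fixture <- function(hits,
                                        path = tempfile(fileext = ".tsv")) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

write_antibody_tsv_fixture <- function(df,
                                       path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

# minimal concordance record table from presence flags
make_records <- function(ihc, if_, rna, rpkm = NULL, wb_score = NA_integer_,
                         if_score = NA_integer_) {
  n <- length(ihc)
  if (is.null(rpkm)) rpkm <- ifelse(rna, seq_len(n), 0)
  tibble::tibble(
    gene_id = sprintf("G%03d", seq_len(n)),
    ihc_present = ihc, if_present = if_, rna_present = rna, rpkm = rpkm,
    wb_score = rep_len(wb_score, n), if_score = rep_len(if_score, n),
    wb_category = wb_validation_category(rep_len(wb_score, n)),
    if_category = if_validation_category(rep_len(if_score, n)),
    venn_group = txpconcord:::venn_label(ihc, if_, rna))
}

# --- oracles ---------------------------------------------------------------

# Literal restatement of the uniqueness rule: a hit wins iff every other hit
# needs more than m + z mismatches; independent of the min-based implementation.
oracle_classify <- function(mismatches, max_mm = 3L, z = 2L) {
  if (length(mismatches) == 0) return("unmapped")
  if (min(mismatches) > max_mm) return("discarded_mismatch")
  winners <- vapply(seq_along(mismatches), function(i) {
    all(mismatches[-i] > mismatches[i] + z)
  }, logical(1))
  if (sum(winners) == 1) "unique" else "ambiguous"
}

# Per-base occupancy count of an exon set (brute-force exonic length).
oracle_exonic_length <- function(starts, ends) {
  length(unique(unlist(Map(function(s, e) seq.int(s, e - 1L), starts, ends))))
}

# Brute-force one-sided KS statistic by explicit counting at every pooled
# observation point.
oracle_ks_one_sided <- function(sample, reference, alternative = "lower") {
  pts <- c(sample, reference)
  d <- vapply(pts, function(t) {
    fs <- sum(sample <= t) / length(sample)
    fr <- sum(reference <= t) / length(reference)
    if (alternative == "lower") fs - fr else fr - fs
  }, numeric(1))
  max(c(d, 0))
}

oracle_ks_two_sided <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) {
    abs(sum(x <= t) / length(x) - sum(y <= t) / length(y))
  }, numeric(1)))
}

# Exact permutation p-value for the two-sided KS statistic by full
# enumeration of all splits of the pooled sample.
oracle_ks_permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  d_obs <- oracle_ks_two_sided(x, y)
  splits <- utils::combn(length(pooled), n1)
  ge <- apply(splits, 2, function(idx) {
    oracle_ks_two_sided(pooled[idx], pooled[-idx]) >= d_obs - 1e-12
  })
  mean(ge)
}

# Direct hypergeometric upper-tail summation.
oracle_hyper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# closed-form Pearson chi-square for a 2x2 table
oracle_chisq_2x2 <- function(m) {
  n <- sum(m)
  n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
}
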