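.VENN_LEVELS <- c("A", "B", "C", "AB", "AC", "BC", "ABC", "none")

# A = IHC, B = IF, C = RNA-seq
venn_label <- function(ihc, if_, rna) {
  lab <- paste0(ifelse(ihc, "A", ""), ifelse(if_, "B", ""),
                ifelse(rna, "C", ""))
  lab[lab == ""] <- "none"
  factor(lab, levels = .VENN_LEVELS)
}

#' Join expression and protein calls into a concordance table
#'
#' One record per gene in the protein-call set (the dual-platform antibody
#' subset defines the universe). Genes without expression data are kept with
#' `rna_present = FALSE` and `rpkm = 0` (a message reports how many).
#'
#' @param expr Expression tibble from [quantify()] (`gene_id`, `reads`,
#'   `rpkm`, `present`).
#' @param calls Protein-call tibble from [build_hpa_subset()].
#' @return Tibble with `gene_id`, `ihc_present`, `if_present`, `rna_present`,
#'   `rpkm`, `wb_score`, `if_score`, `wb_category`, `if_category`,
#'   `venn_group`.
#' @export
build_table <- function(expr, calls) {
  expr <- as_tibble(expr); calls <- as_tibble(calls)
  if (anyDuplicated(expr$gene_id)) {
    stop("duplicate gene_id in expression table: ",
         expr$gene_id[duplicated(expr$gene_id)][1])
  }
  if (anyDuplicated(calls$gene_id)) {
    stop("duplicate gene_id in protein calls: ",
         calls$gene_id[duplicated(calls$gene_id)][1])
  }
  out <- calls %>%
    left_join(expr %>% select("gene_id", "rpkm", rna_present = "present"),
              by = "gene_id")
  n_missing <- sum(is.na(out$rna_present))
  if (n_missing > 0) {
    message(n_missing, " gene(s) without expression data: rna_present set ",
            "to FALSE")
    out$rna_present[is.na(out$rna_present)] <- FALSE
    out$rpkm[is.na(out$rpkm)] <- 0
  }
  out %>%
    mutate(venn_group = venn_label(.data$ihc_present, .data$if_present,
                                   .data$rna_present)) %>%
    select("gene_id", "ihc_present", "if_present", "rna_present", "rpkm",
           "wb_score", "if_score", "wb_category", "if_category",
           "venn_group")
}

#' Three-platform Venn partition
#'
#' Partitions genes into the 8 groups defined by presence in IHC (A), IF (B)
#' and RNA-seq (C).
#'
#' @param records Concordance tibble from [build_table()].
#' @return Object of class `venn_counts`: named integer vector over
#'   `A, B, C, AB, AC, BC, ABC, none` with attribute `total`.
#' @export
venn <- function(records) {
  counts <- table(venn_label(records$ihc_present, records$if_present,
                             records$rna_present))
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "total") <- nrow(records)
  class(out) <- "venn_counts"
  out
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Venn partition (A = IHC, B = IF, C = RNA-seq),",
      attr(x, "total"), "genes:\n")
  print(stats::setNames(as.integer(x), names(unclass(x))))
  invisible(x)
}

venn_total <- function(v) attr(v, "total")

#' Overlap summary percentages from Venn counts
#'
#' Derives the standard cross-platform summary rates: per-platform presence,
#' all-three and none rates, RNA coverage of the IHC- and IF-detected
#' proteins, the both-protein rate among either-protein detections, and the
#' transcript-without-protein rates. Percentages are rounded to 1 decimal; a
#' zero denominator yields `NA`, never 0.
#'
#' @param v A `venn_counts` object from [venn()].
#' @return Tibble with `metric`, `numerator`, `denominator`, `fraction`,
#'   `percent`.
#' @export
overlap_summary <- function(v) {
  stopifnot(inherits(v, "venn_counts"))
  g <- function(nm) as.integer(v[nm])
  total <- venn_total(v)
  ihc <- g("A") + g("AB") + g("AC") + g("ABC")
  if_ <- g("B") + g("AB") + g("BC") + g("ABC")
  rna <- g("C") + g("AC") + g("BC") + g("ABC")
  either_protein <- g("A") + g("B") + g("AB") + g("AC") + g("BC") + g("ABC")
  rows <- list(
    c("rna_presence", rna, total),
    c("ihc_presence", ihc, total),
    c("if_presence", if_, total),
    c("all_three", g("ABC"), total),
    c("none", g("none"), total),
    c("rna_coverage_of_ihc", g("AC") + g("ABC"), ihc),
    c("rna_coverage_of_if", g("BC") + g("ABC"), if_),
    c("either_protein_to_both", g("AB") + g("ABC"), either_protein),
    c("transcript_not_ihc", g("C") + g("BC"), rna),
    c("transcript_not_if", g("C") + g("AC"), rna)
  )
  out <- tibble(
    metric = vapply(rows, `[`, character(1), 1),
    numerator = as.integer(vapply(rows, `[`, character(1), 2)),
    denominator = as.integer(vapply(rows, `[`, character(1), 3))
  )
  out$fraction <- ifelse(out$denominator > 0,
                         out$numerator / out$denominator, NA_real_)
  out$percent <- round(100 * out$fraction, 1)
  out
}

#' Build a 2x2 presence contingency table
#'
#' Cross-tabulates RNA presence against one protein platform, oriented as the
#' printed tables: rows = RNA present/absent, columns = protein
#' present/absent.
#'
#' @param records Concordance tibble from [build_table()].
#' @param platform `"ihc"` or `"if"`.
#' @return 2x2 integer matrix with dimnames.
#' @export
contingency_2x2 <- function(records, platform = c("ihc", "if")) {
  platform <- match.arg(platform)
  prot <- if (platform == "ihc") records$ihc_present else records$if_present
  m <- matrix(c(sum(records$rna_present & prot),
                sum(records$rna_present & !prot),
                sum(!records$rna_present & prot),
                sum(!records$rna_present & !prot)),
              nrow = 2, byrow = TRUE,
              dimnames = list(rna = c("present", "absent"),
                              protein = c("present", "absent")))
  m
}

new_test_result <- function(method, statistic, p_value, sidedness,
                            df = NULL, replicates = NULL) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), sidedness = sidedness,
                 df = df, replicates = replicates),
            class = "concord_test")
}

#' @export
print.concord_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 5),
      if (!is.null(x$df)) paste0("(df = ", x$df, ")"),
      "\n  p =", format(x$p_value, digits = 3),
      paste0("(", x$sidedness,
             if (!is.null(x$replicates))
               paste0(", ", x$replicates, " replicates"), ")"), "\n")
  invisible(x)
}

#' Chi-square association test on a 2x2 presence table
#'
#' Pearson chi-square with 1 degree of freedom; the Yates continuity
#' correction is applied by default.
#'
#' @param tab 2x2 matrix of observed counts (see [contingency_2x2()]).
#' @param correction Apply the continuity correction (default `TRUE`).
#' @return A `concord_test` result (statistic, p-value, df = 1).
#' @examples
#' tab <- matrix(c(2123, 222, 315, 89), 2, 2, byrow = TRUE)
#' association_test(tab)$p_value  # ~3.4e-13
#' @export
association_test <- function(tab, correction = TRUE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (sum(tab) == 0) stop("empty table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("expected cell count of zero: use an exact test instead")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correction))
  new_test_result(
    method = paste0("Pearson chi-square",
                    if (correction) " (continuity-corrected)"),
    statistic = res$statistic, p_value = res$p.value,
    sidedness = "two_sided", df = 1L)
}

#' Per-group empirical CDFs of expression
#'
#' Step-function empirical CDFs of RPKM for selected Venn groups, plus the
#' reference CDF over the full record set. A left-shifted (higher) curve
#' marks a group containing more lowly transcribed genes.
#'
#' @param records Concordance tibble from [build_table()].
#' @param groups Venn group labels to include; defaults to the groups with
#'   RNA data plus AB as in the published comparison.
#' @return Named list of `ecdf` functions, including `reference`. Empty
#'   groups are omitted with a warning.
#' @export
expression_cdf_by_group <- function(records,
                                    groups = c("C", "AB", "BC", "ABC")) {
  out <- list()
  for (gp in groups) {
    x <- records$rpkm[records$venn_group == gp]
    if (length(x) == 0) {
      warning("group ", gp, " is empty; omitted")
      next
    }
    out[[gp]] <- stats::ecdf(x)
  }
  out$reference <- stats::ecdf(records$rpkm)
  out
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether `sample` is stochastically lower (its CDF lies above the
#' reference CDF) or greater than `reference`. The statistic is the maximal
#' signed CDF difference over the pooled observation points (tie-aware); the
#' p-value is the asymptotic one-sided tail
#' \eqn{\exp(-2 D^2 nm/(n+m))}.
#'
#' @param sample,reference Numeric vectors (each of length >= 2).
#' @param alternative `"lower"`: sample stochastically lower than reference
#'   (default); `"greater"`: sample stochastically greater.
#' @return A `concord_test` result.
#' @export
ks_one_sided <- function(sample, reference,
                         alternative = c("lower", "greater")) {
  alternative <- match.arg(alternative)
  if (length(sample) < 2 || length(reference) < 2) {
    stop("need at least 2 observations in each sample")
  }
  pts <- sort(unique(c(sample, reference)))
  fs <- stats::ecdf(sample)(pts)
  fr <- stats::ecdf(reference)(pts)
  d <- if (alternative == "lower") max(fs - fr) else max(fr - fs)
  d <- max(d, 0)
  n <- length(sample); m <- length(reference)
  p <- exp(-2 * d^2 * n * m / (n + m))
  new_test_result(
    method = sprintf("two-sample KS (one-sided, sample %s)", alternative),
    statistic = d, p_value = min(1, p), sidedness = "one_sided")
}

#' Quantile-binned RNA-protein overlap
#'
#' Ranks genes by RPKM (descending; ties broken by gene id for
#' reproducibility), splits them into `n_bins` equal-size quantile bins (any
#' remainder spread over the top bins) and reports the percentage of
#' IHC-present and IF-present genes per bin, together with upper/lower 50%
#' and top/bottom 5% summaries. Optionally the analysis is restricted to
#' genes whose antibody holds a supportive Western-blot category.
#'
#' @param records Concordance tibble from [build_table()].
#' @param n_bins Number of expression bins (default 25, i.e. 4% steps).
#' @param restrict_supportive_wb Keep only genes with
#'   `wb_category == "supportive"` before ranking.
#' @return List of class `binned_overlap` with tibbles `bins` (per-bin
#'   percentages), `halves` (upper/lower 50%) and `tails` (top/bottom 5%).
#' @export
bin_overlap <- function(records, n_bins = 25,
                        restrict_supportive_wb = FALSE) {
  stopifnot(n_bins >= 2)
  df <- as_tibble(records)
  if (restrict_supportive_wb) {
    df <- df[!is.na(df$wb_category) & df$wb_category == "supportive", ]
  }
  n <- nrow(df)
  if (n < n_bins) stop("fewer genes (", n, ") than bins (", n_bins, ")")
  df <- df[order(-df$rpkm, df$gene_id), ]
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  df$bin <- rep(seq_len(n_bins), times = sizes)
  cum_hi <- cumsum(sizes)
  cum_lo <- c(0, cum_hi[-n_bins])
  bins <- df %>% group_by(.data$bin) %>%
    summarise(n_genes = n(),
              pct_ihc_present = 100 * mean(.data$ihc_present),
              pct_if_present = 100 * mean(.data$if_present),
              .groups = "drop") %>%
    mutate(quantile_range = sprintf("top %.1f%%-%.1f%%",
                                    100 * cum_lo / n, 100 * cum_hi / n)) %>%
    select("bin", "quantile_range", "n_genes", "pct_ihc_present",
           "pct_if_present")
  slice_stats <- function(idx, label) {
    tibble(level = label, n_genes = length(idx),
           pct_ihc_present = 100 * mean(df$ihc_present[idx]),
           pct_if_present = 100 * mean(df$if_present[idx]))
  }
  upper <- seq_len(ceiling(n / 2))
  lower <- setdiff(seq_len(n), upper)
  halves <- bind_rows(slice_stats(upper, "upper_50"),
                      slice_stats(lower, "lower_50"))
  k5 <- max(1L, round(0.05 * n))
  tails <- bind_rows(slice_stats(seq_len(k5), "top_5"),
                     slice_stats(seq.int(n - k5 + 1L, n), "bottom_5"))
  structure(list(bins = bins, halves = halves, tails = tails,
                 n_genes = n,
                 restricted = restrict_supportive_wb),
            class = "binned_overlap")
}

#' @export
print.binned_overlap <- function(x, ...) {
  cat("Expression-binned overlap over", x$n_genes, "genes",
      if (x$restricted) "(supportive-WB antibodies only)", "\n")
  print(as.data.frame(x$halves), row.names = FALSE)
  cat("(", nrow(x$bins), "quantile bins in $bins; top/bottom 5% in $tails)\n")
  invisible(x)
}
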