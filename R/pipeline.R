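#' Run the full concordance analysis and write a report directory
#'
#' Orchestrates the stages end to end: read quantification (clear-zone
#' uniqueness filter, exon containment, RPKM), protein presence calls on the
#' dual-platform antibody subset, three-platform Venn/overlap/association
#' statistics, expression-binned overlap, and validation-score group
#' comparisons. Inputs are either a [synthetic_dataset] (raw alignments are
#' quantified) or the deterministic [u2os_fixture()] tables.
#'
#' @param out_dir Output directory (created if needed). Files written:
#'   `expr.tsv`, `calls.tsv`, `records.tsv`, `venn.tsv`, `overlap.tsv`,
#'   `bins.tsv`, `tests.tsv`, `summary.md`.
#' @param data A `synthetic_dataset` from [simulate_dataset()], or `NULL`
#'   (default) to analyse the deterministic fixture.
#' @param quant A [quant_config()], used when `data` carries raw alignments.
#' @param n_bins Expression bins for [bin_overlap()].
#' @param ks_replicates Replicates for the permutation KS tests.
#' @param seed Seed driving every stochastic stage (per-stage seeds are
#'   derived from it).
#' @return Invisibly, a list with all computed objects (`expr`, `calls`,
#'   `records`, `venn`, `overlap`, `bins`, `tests`).
#' @export
run_pipeline <- function(out_dir, data = NULL, quant = quant_config(),
                         n_bins = 25, ks_replicates = 2000, seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(...) message("[", format(Sys.time(), "%H:%M:%S"),
                                     "] ", ...)
  if (is.null(data)) {
    log_stage("stage fixture: deterministic U-2 OS tables")
    fx <- u2os_fixture()
    expr <- fx$expr
    calls <- fx$calls
  } else {
    stopifnot(inherits(data, "synthetic_dataset"))
    log_stage("stage quantify: ", nrow(data$alignments$reads), " reads, ",
              nrow(data$genes$genes), " genes")
    expr <- quantify(data$alignments, data$genes, quant)
    log_stage("stage call-proteins: ", nrow(data$antibodies), " antibodies")
    calls <- build_hpa_subset(data$antibodies)
  }
  utils::write.table(expr, file.path(out_dir, "expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_protein_calls(calls, file.path(out_dir, "calls.tsv"))

  log_stage("stage concord: ", nrow(calls), " genes in protein-call set")
  records <- suppressMessages(build_table(expr, calls))
  utils::write.table(records, file.path(out_dir, "records.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  v <- venn(records)
  venn_df <- tibble(group = names(unclass(v)), n = as.integer(v),
                    percent = round(100 * as.integer(v) / venn_total(v), 1))
  utils::write.table(venn_df, file.path(out_dir, "venn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ov <- overlap_summary(v)
  utils::write.table(ov, file.path(out_dir, "overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  bo <- bin_overlap(records, n_bins = n_bins)
  bins_df <- bo$bins
  utils::write.table(bins_df, file.path(out_dir, "bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  log_stage("stage scores: association and KS tests")
  tests <- list()
  for (pf in c("ihc", "if")) {
    tr <- association_test(contingency_2x2(records, pf))
    tests[[paste0("chisq_rna_", pf)]] <- tr
  }
  for (gp in c("C", "BC")) {
    x <- records$rpkm[records$venn_group == gp]
    if (length(x) >= 2) {
      tests[[paste0("ks_", gp, "_vs_all")]] <-
        ks_one_sided(x, records$rpkm, alternative = "lower")
    }
  }
  ks_seed <- seed + 1000L
  wb_a <- records$wb_score[records$venn_group == "A" &
                             !is.na(records$wb_score)]
  wb_abc <- records$wb_score[records$venn_group == "ABC" &
                               !is.na(records$wb_score)]
  if (length(wb_a) > 0 && length(wb_abc) > 0) {
    tests$ks_bootstrap_wb_A_vs_ABC <-
      ks_bootstrap(wb_a, wb_abc, replicates = ks_replicates, seed = ks_seed)
  }
  if_b <- records$if_score[records$venn_group == "B" &
                             !is.na(records$if_score)]
  if_abc <- records$if_score[records$venn_group == "ABC" &
                               !is.na(records$if_score)]
  if (length(if_b) > 0 && length(if_abc) > 0) {
    tests$ks_bootstrap_if_B_vs_ABC <-
      ks_bootstrap(if_b, if_abc, replicates = ks_replicates,
                   seed = ks_seed + 1L)
  }
  tests_df <- bind_rows(lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    tibble(name = nm, method = t$method, statistic = t$statistic,
           p_value = t$p_value, sidedness = t$sidedness)
  }))
  utils::write.table(tests_df, file.path(out_dir, "tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pr <- presence_rate(expr)
  summary_lines <- c(
    "# Transcript-protein concordance summary", "",
    sprintf("- genes quantified: %d; RNA presence %.1f%% (%d/%d)",
            pr$n_total, 100 * pr$fraction, pr$n_present, pr$n_total),
    sprintf("- protein-call set: %d genes", nrow(records)),
    "",
    "## Venn partition (A = IHC, B = IF, C = RNA-seq)", "",
    sprintf("- %s: %d (%.1f%%)", venn_df$group, venn_df$n, venn_df$percent),
    "",
    "## Overlap summary", "",
    sprintf("- %s: %d/%d = %.1f%%", ov$metric, ov$numerator,
            ov$denominator, ov$percent),
    "",
    "## Tests", "",
    sprintf("- %s [%s]: statistic %.4g, p = %.3g", tests_df$name,
            tests_df$method, tests_df$statistic, tests_df$p_value),
    "",
    sprintf("run time: %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  )
  writeLines(summary_lines, file.path(out_dir, "summary.md"))
  log_stage("done: ", out_dir)
  invisible(list(expr = expr, calls = calls, records = records, venn = v,
                 overlap = ov, bins = bo, tests = tests))
}
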