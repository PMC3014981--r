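# Deterministic fixtures reproducing the published U-2 OS concordance
# counts. All presence flags and validation scores are assigned by integer
# arithmetic; only the RPKM magnitudes of RNA-present genes use a fixed
# internal seed, so repeated calls are identical.

.U2OS_VENN <- c(A = 110L, B = 55L, C = 102L, AB = 205L, AC = 472L,
                BC = 120L, ABC = 1651L, none = 34L)

# deterministic per-group score assignment: the first round(f_s * n) genes
# get supportive scores (cycled), the next round(f_u * n) uncertain, the
# rest non-supportive
cycle_scores <- function(n, f_supportive, f_uncertain,
                         supportive, uncertain, nonsupportive) {
  ns <- round(f_supportive * n)
  nu <- round(f_uncertain * n)
  nn <- n - ns - nu
  c(rep_len(supportive, ns), rep_len(uncertain, nu),
    rep_len(nonsupportive, max(0, nn)))[seq_len(n)]
}

#' Deterministic U-2 OS concordance fixture
#'
#' Builds an expression table and a protein-call table for exactly 2749
#' genes whose three presence flags partition into the published Venn
#' groups: A = 110, B = 55, C = 102, AB = 205, AC = 472, BC = 120,
#' ABC = 1651, none = 34 (A = IHC, B = IF, C = RNA-seq). RNA-present genes
#' carry positive read counts and log-normal RPKM values; the RNA-only (C)
#' and IF+RNA (BC) groups are drawn from the lower expression tail, so their
#' cumulative expression curves sit left of the full set. Western-blot and
#' IF validation scores are laid out so that groups A and AB are rich in
#' low-scoring antibodies and the supportive IF fraction in ABC is about
#' three times that of B.
#'
#' @return List with tibbles `expr` (`gene_id`, `reads`, `rpkm`, `present`)
#'   and `calls` (the [build_hpa_subset()] schema).
#' @examples
#' fx <- u2os_fixture()
#' venn(build_table(fx$expr, fx$calls))
#' @export
u2os_fixture <- function() {
  sizes <- .U2OS_VENN
  group <- factor(rep(names(sizes), sizes), levels = .VENN_LEVELS)
  n <- sum(sizes)
  gene_id <- sprintf("G%04d", seq_len(n))
  ihc <- group %in% c("A", "AB", "AC", "ABC")
  if_ <- group %in% c("B", "AB", "BC", "ABC")
  rna <- group %in% c("C", "AC", "BC", "ABC")

  rpkm <- numeric(n)
  with_seed(20101202L, {
    low <- rna & group %in% c("C", "BC")     # lower expression tail
    hi <- rna & !low
    rpkm[low] <- stats::qlnorm(stats::runif(sum(low)) / 3,
                               meanlog = 1.5, sdlog = 1.2)
    rpkm[hi] <- stats::qlnorm(stats::runif(sum(hi)),
                              meanlog = 1.5, sdlog = 1.2)
  })
  reads <- ifelse(rna, pmax(1L, as.integer(round(rpkm * 5))), 0L)
  expr <- tibble(gene_id = gene_id, reads = reads, rpkm = rpkm,
                 present = rna)

  # WB scores: groups detected by RNA score well, the protein-only groups
  # A and AB are enriched for low-scoring (non-supportive) antibodies
  wb_frac <- list(A = c(0.25, 0.25), B = c(0.30, 0.30), C = c(0.45, 0.30),
                  AB = c(0.25, 0.25), AC = c(0.55, 0.25),
                  BC = c(0.50, 0.30), ABC = c(0.60, 0.25),
                  none = c(0.30, 0.30))
  wb_score <- integer(n)
  for (g in names(sizes)) {
    idx <- which(group == g)
    fr <- wb_frac[[g]]
    wb_score[idx] <- cycle_scores(length(idx), fr[1], fr[2],
                                  1:3, 4:5, 6:7)
  }

  # IF scores: absent platforms score 7; present genes split so that the
  # supportive fraction in ABC (~0.45) is ~3x that of B (~0.145)
  if_frac <- list(B = c(8 / 55, 0.35), AB = c(0.25, 0.35),
                  BC = c(0.40, 0.35), ABC = c(0.45, 0.35))
  if_score <- rep(7L, n)
  for (g in names(if_frac)) {
    idx <- which(group == g)
    fr <- if_frac[[g]]
    if_score[idx] <- cycle_scores(length(idx), fr[1], fr[2],
                                  1:3, 4:6, 8:9)
  }

  intensity <- ifelse(ihc, rep_len(c("weak", "moderate", "strong"), n),
                      "negative")
  calls <- tibble(
    gene_id = gene_id,
    antibody_id = sprintf("AB%04d", seq_len(n)),
    ihc_present = call_ihc(intensity),
    if_present = call_if(if_score),
    wb_score = wb_score,
    if_score = if_score,
    wb_category = wb_validation_category(wb_score),
    if_category = if_validation_category(if_score)
  )
  stopifnot(identical(unname(calls$ihc_present), unname(ihc)),
            identical(unname(calls$if_present), unname(if_)))
  list(expr = expr, calls = calls)
}

#' Genome-wide transcript presence fixture
#'
#' Expression table at the scale of the full gene annotation: `n_present` of
#' `n_genes` genes carry at least one uniquely mapped exonic read. Defaults
#' reproduce the published genome-wide detection (15536 of 21146 Ensembl
#' genes).
#'
#' @param n_genes Total genes.
#' @param n_present Genes with a detected transcript.
#' @return Expression tibble (`gene_id`, `reads`, `rpkm`, `present`).
#' @export
transcriptome_fixture <- function(n_genes = 21146L, n_present = 15536L) {
  stopifnot(n_present <= n_genes)
  present <- seq_len(n_genes) <= n_present
  tibble(gene_id = sprintf("ENSG%08d", seq_len(n_genes)),
         reads = ifelse(present, 1L, 0L),
         rpkm = ifelse(present, 1, 0),
         present = present)
}
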