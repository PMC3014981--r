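#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' statistical structure the concordance analysis assumes: per-gene
#' expression from a zero-inflated log-normal, 35-bp reads placed uniformly
#' inside exons with decoy multi-mapping hits and per-hit mismatch counts,
#' and antibody panels whose true detection probability rises with expression
#' (a logistic in log10 RPKM, separate intercept/slope per platform) while
#' false-positive calls concentrate in antibodies with poor validation
#' scores. IF is configured more sensitive than IHC at low expression
#' (higher intercept, flatter slope).
#'
#' @param n_genes Number of genes.
#' @param mean_exons Mean exons per gene (count is 1 + Poisson).
#' @param exon_length_meanlog,exon_length_sdlog Log-normal exon lengths (bp).
#' @param min_exon_length Floor on exon length; must be >= `read_length`.
#' @param intron_length,intergenic_gap Fixed intron and inter-gene spacing.
#' @param pi0 Zero-inflation: fraction of transcriptionally silent genes.
#' @param expr_meanlog,expr_sdlog Log-normal expression (RPKM scale) of the
#'   expressed genes.
#' @param depth Total mapped reads to generate.
#' @param read_length Read length in bp (default 35).
#' @param multimap_rate Fraction of reads given 1-3 decoy hits.
#' @param clear_zone_violation_rate Among multi-mapped reads, the fraction
#'   whose decoy falls inside the mismatch clear zone (these become
#'   ambiguous under the uniqueness filter; the rest stay unique).
#' @param clear_zone Clear-zone width assumed when placing decoys.
#' @param mismatch_probs Distribution of the true hit's mismatch count over
#'   0..(length-1).
#' @param unmapped_rate Extra unmapped reads, as a fraction of `depth`.
#' @param ihc_alpha,ihc_beta,if_alpha,if_beta Logistic detection parameters:
#'   P(detected) = plogis(alpha + beta * log10(true RPKM)).
#' @param antibody_quality_probs Mix of good/medium/poor antibodies.
#' @param false_positive_rate Per-quality probability that an antibody calls
#'   a protein present despite no true detection.
#' @param n_antibody_probs Distribution of antibodies per gene (1..3).
#' @param ihc_missing_rate,if_missing_rate,wb_missing_rate Per-antibody
#'   probability of lacking data on that platform.
#' @param seed Integer seed; all randomness in [simulate_dataset()] flows
#'   from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       mean_exons = 4,
                       exon_length_meanlog = log(250),
                       exon_length_sdlog = 0.45,
                       min_exon_length = 80L,
                       intron_length = 300L,
                       intergenic_gap = 2000L,
                       pi0 = 0.265,
                       expr_meanlog = 1.0,
                       expr_sdlog = 1.5,
                       depth = 2e5,
                       read_length = 35L,
                       multimap_rate = 0.15,
                       clear_zone_violation_rate = 0.5,
                       clear_zone = 2L,
                       mismatch_probs = c(0.65, 0.25, 0.08, 0.02),
                       unmapped_rate = 0.02,
                       ihc_alpha = 0.6, ihc_beta = 0.9,
                       if_alpha = 0.9, if_beta = 0.45,
                       antibody_quality_probs =
                         c(good = 0.5, medium = 0.3, poor = 0.2),
                       false_positive_rate =
                         c(good = 0.02, medium = 0.08, poor = 0.25),
                       n_antibody_probs = c(0.6, 0.3, 0.1),
                       ihc_missing_rate = 0.15,
                       if_missing_rate = 0.3,
                       wb_missing_rate = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(pi0 >= 0, pi0 <= 1, multimap_rate >= 0, multimap_rate <= 1,
            clear_zone_violation_rate >= 0, clear_zone_violation_rate <= 1,
            ihc_beta >= 0, if_beta >= 0,
            abs(sum(mismatch_probs) - 1) < 1e-8)
  if (read_length > min_exon_length) {
    stop("infeasible config: read_length (", read_length,
         ") exceeds the minimum exon length (", min_exon_length, ")")
  }
  structure(cfg, class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

# Build random gene models laid head-to-tail along synthetic chromosomes.
simulate_gene_models <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  n_exons <- 1L + stats::rpois(n, cfg$mean_exons - 1)
  per_chrom <- 500L
  chrom <- paste0("chrS", (seq_len(n) - 1L) %/% per_chrom + 1L)
  ex_gene <- rep(gene_id, n_exons)
  ex_chrom <- rep(chrom, n_exons)
  ex_len <- pmax(cfg$min_exon_length,
                 round(stats::rlnorm(sum(n_exons), cfg$exon_length_meanlog,
                                     cfg$exon_length_sdlog)))
  # lay out exons: introns within a gene, gaps between genes, fresh origin
  # per chromosome
  step <- ex_len + cfg$intron_length
  first_of_gene <- !duplicated(ex_gene)
  extra <- ifelse(first_of_gene, cfg$intergenic_gap - cfg$intron_length, 0)
  start <- stats::ave(step + extra, ex_chrom, FUN = function(s) {
    cumsum(c(0, utils::head(s, -1)))
  }) + extra
  start <- as.integer(start)
  strand <- rep(sample(c("+", "-"), n, replace = TRUE), n_exons)
  gene_models(tibble(gene_id = ex_gene, chrom = ex_chrom,
                     start = start, end = start + as.integer(ex_len),
                     strand = strand))
}

#' Simulate a full synthetic dataset
#'
#' Generates gene models, true expression, a multi-hit read alignment stream
#' and an antibody annotation panel under one seed, with complete ground
#' truth. Reads are placed uniformly within exons of their origin gene (so
#' every true hit is containable in single-exon mode); decoy hits of
#' multi-mapped reads land on an unannotated decoy chromosome, keeping truth
#' labels unambiguous, and their mismatch counts either violate the clear
#' zone (making the read ambiguous) or fall safely outside it.
#'
#' @param cfg A [sim_config()].
#' @return List of class `synthetic_dataset` with elements `genes`
#'   ([gene_models]), `truth` (per-gene tibble: expression, detection
#'   probabilities and outcomes), `alignments` (`read_alignments`),
#'   `read_truth` (per-read origin and clear-zone bookkeeping), `antibodies`
#'   (annotation tibble) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genes <- simulate_gene_models(cfg)
    n <- cfg$n_genes
    gm <- genes$genes

    expressed <- stats::runif(n) >= cfg$pi0
    true_rpkm <- ifelse(expressed,
                        stats::rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog),
                        0)

    # ---- reads -----------------------------------------------------------
    w <- true_rpkm * gm$exonic_length
    counts <- if (sum(w) > 0)
      as.integer(stats::rmultinom(1, cfg$depth, w)) else integer(n)
    rl <- cfg$read_length
    exbl <- genes$exons
    origin <- rep(gm$gene_id, counts)
    n_reads <- length(origin)
    hit_chrom <- character(n_reads); hit_start <- integer(n_reads)
    if (n_reads > 0) {
      idx_by_gene <- split(seq_len(n_reads), origin)
      for (g in names(idx_by_gene)) {
        rows <- which(exbl$gene_id == g)
        len <- exbl$end[rows] - exbl$start[rows]
        ok <- rows[len >= rl]
        wex <- (exbl$end[ok] - exbl$start[ok]) - rl + 1
        ridx <- idx_by_gene[[g]]
        pick <- ok[sample.int(length(ok), length(ridx), replace = TRUE,
                              prob = wex)]
        hit_chrom[ridx] <- exbl$chrom[pick]
        span <- (exbl$end[pick] - exbl$start[pick]) - rl
        hit_start[ridx] <- exbl$start[pick] +
          as.integer(floor(stats::runif(length(ridx)) * (span + 1)))
      }
    }
    read_id <- sprintf("r%07d", seq_len(n_reads))
    mm_support <- seq_along(cfg$mismatch_probs) - 1L
    true_mm <- sample(mm_support, n_reads, replace = TRUE,
                      prob = cfg$mismatch_probs)
    hits <- tibble(read_id = read_id, chrom = hit_chrom,
                   start = hit_start, end = hit_start + rl,
                   strand = sample(c("+", "-"), n_reads, replace = TRUE),
                   mismatches = true_mm)

    # decoy hits on an unannotated chromosome
    is_multi <- stats::runif(n_reads) < cfg$multimap_rate
    violates <- is_multi & stats::runif(n_reads) <
      cfg$clear_zone_violation_rate
    midx <- which(is_multi)
    decoys <- NULL
    if (length(midx) > 0) {
      k <- sample.int(3, length(midx), replace = TRUE,
                      prob = c(0.6, 0.3, 0.1))
      dread <- rep(read_id[midx], k)
      dm_base <- rep(true_mm[midx], k)
      dviol <- rep(violates[midx], k)
      first <- !duplicated(dread)
      # violating reads: first decoy inside [m, m+z]; everything else well
      # beyond the clear zone
      dmm <- dm_base + cfg$clear_zone + 1L +
        sample(0:2, length(dread), replace = TRUE)
      inzone <- dviol & first
      dmm[inzone] <- dm_base[inzone] +
        sample(0:cfg$clear_zone, sum(inzone), replace = TRUE)
      dstart <- as.integer(floor(stats::runif(length(dread)) * (1e7 - rl)))
      decoys <- tibble(read_id = dread, chrom = "chrDecoy",
                       start = dstart, end = dstart + rl,
                       strand = sample(c("+", "-"), length(dread),
                                       replace = TRUE),
                       mismatches = as.integer(dmm))
    }
    n_unm <- round(cfg$unmapped_rate * cfg$depth)
    unm_ids <- if (n_unm > 0) sprintf("u%07d", seq_len(n_unm)) else character()
    all_hits <- bind_rows(hits, decoys) %>% arrange(.data$read_id)
    reads <- tibble(read_id = c(read_id, unm_ids),
                    read_length = rl) %>% arrange(.data$read_id)
    nh <- all_hits %>% group_by(.data$read_id) %>%
      summarise(n_hits = n(), .groups = "drop")
    reads <- left_join(reads, nh, by = "read_id")
    reads$n_hits[is.na(reads$n_hits)] <- 0L
    aln <- structure(list(reads = reads, hits = all_hits),
                     class = "read_alignments")
    read_truth <- tibble(read_id = read_id, gene_id = origin,
                         multimapped = is_multi,
                         violates_clear_zone = violates)

    # ---- protein detection ----------------------------------------------
    lg <- ifelse(expressed, log10(true_rpkm), NA_real_)
    p_ihc <- ifelse(expressed, stats::plogis(cfg$ihc_alpha +
                                               cfg$ihc_beta * lg), 0)
    p_if <- ifelse(expressed, stats::plogis(cfg$if_alpha +
                                              cfg$if_beta * lg), 0)
    ihc_detected <- stats::runif(n) < p_ihc
    if_detected <- stats::runif(n) < p_if
    truth <- tibble(gene_id = gm$gene_id, expressed = expressed,
                    true_rpkm = true_rpkm, n_reads = counts,
                    p_ihc = p_ihc, p_if = p_if,
                    ihc_detected = ihc_detected, if_detected = if_detected)

    # ---- antibody panel --------------------------------------------------
    n_ab <- sample.int(3, n, replace = TRUE, prob = cfg$n_antibody_probs)
    ab_gene <- rep(gm$gene_id, n_ab)
    m <- length(ab_gene)
    ab_id <- sprintf("AB%05d", seq_len(m))
    quality <- sample(names(cfg$antibody_quality_probs), m, replace = TRUE,
                      prob = cfg$antibody_quality_probs)
    fp <- cfg$false_positive_rate[quality]
    gdet_ihc <- rep(ihc_detected, n_ab)
    gdet_if <- rep(if_detected, n_ab)
    ab_ihc_pos <- gdet_ihc | (stats::runif(m) < fp)
    ab_if_pos <- gdet_if | (stats::runif(m) < fp)
    intensity <- ifelse(ab_ihc_pos,
                        sample(c("weak", "moderate", "strong"), m,
                               replace = TRUE, prob = c(0.35, 0.4, 0.25)),
                        "negative")
    if_score <- integer(m)
    if_score[!ab_if_pos] <- 7L
    pos <- which(ab_if_pos)
    score_pool <- list(good = 1:3, medium = 4:6, poor = 8:9)
    for (q in names(score_pool)) {
      sel <- pos[quality[pos] == q]
      if (length(sel) > 0)
        if_score[sel] <- sample(score_pool[[q]], length(sel), replace = TRUE)
    }
    wb_pool <- list(good = 1:3, medium = 4:5, poor = 6:7)
    wb_score <- integer(m)
    for (q in names(wb_pool)) {
      sel <- which(quality == q)
      wb_score[sel] <- sample(wb_pool[[q]], length(sel), replace = TRUE)
    }
    ihc_intensity <- intensity
    ihc_intensity[stats::runif(m) < cfg$ihc_missing_rate] <- NA
    if_score[stats::runif(m) < cfg$if_missing_rate] <- NA
    wb_score[stats::runif(m) < cfg$wb_missing_rate] <- NA
    antibodies <- tibble(antibody_id = ab_id, gene_id = ab_gene,
                         ihc_intensity = ihc_intensity,
                         if_score = as.integer(if_score),
                         wb_score = as.integer(wb_score))

    structure(list(genes = genes, truth = truth, alignments = aln,
                   read_truth = read_truth, antibodies = antibodies,
                   config = cfg),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$truth), "genes,",
      nrow(x$alignments$reads), "reads,", nrow(x$antibodies),
      "antibodies (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Two null score samples from one discrete distribution
#'
#' Calibration input for [ks_bootstrap()]: two independent i.i.d. samples
#' drawn from the same discrete score distribution.
#'
#' @param n1,n2 Sample sizes.
#' @param support Score support (default 1..7).
#' @param probs Probabilities over `support` (default uniform).
#' @param seed Optional seed.
#' @return List with integer vectors `x` and `y`.
#' @export
simulate_null_scores <- function(n1, n2, support = 1:7, probs = NULL,
                                 seed = NULL) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (length(support) == 0) stop("empty score support")
  draw <- function() {
    list(x = sample(support, n1, replace = TRUE, prob = probs),
         y = sample(support, n2, replace = TRUE, prob = probs))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
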