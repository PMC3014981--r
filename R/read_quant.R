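#' Quantification configuration
#'
#' Parameters for the uniqueness filter and RPKM computation.
#'
#' A read is *unique* when its best hit (minimal mismatch count `N*`) is the
#' only hit with `N*` mismatches and no other hit has between `N*+1` and
#' `N*+clear_zone` mismatches — the mismatch "clear zone". Reads whose best
#' hit exceeds `max_mismatches` are discarded.
#'
#' @param max_mismatches Maximum mismatches allowed on the chosen hit
#'   (default 3).
#' @param clear_zone Width of the uniqueness clear zone in mismatches
#'   (default 2).
#' @param library_size RPKM denominator N. `NULL` (default) means "total
#'   unique exonic reads assigned to genes", computed from the data.
#' @param containment `"single_exon"` (default): a read is assigned to a gene
#'   only if it falls entirely inside one annotated exon. `"merged_exons"`:
#'   containment is tested against the merged exon union, so a read may span
#'   the junction of two overlapping exons.
#' @param multi_gene `"count_all"` (default): a read contained in exons of
#'   several overlapping genes counts once per gene. `"discard_shared"`:
#'   such reads are dropped.
#' @param stranded If `TRUE`, a hit is only assigned to genes on its own
#'   strand. Default `FALSE` (random-primed libraries are unstranded).
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(max_mismatches = 3L, clear_zone = 2L,
                         library_size = NULL,
                         containment = c("single_exon", "merged_exons"),
                         multi_gene = c("count_all", "discard_shared"),
                         stranded = FALSE) {
  containment <- match.arg(containment)
  multi_gene <- match.arg(multi_gene)
  stopifnot(max_mismatches >= 0, clear_zone >= 0,
            is.null(library_size) || library_size > 0)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 clear_zone = as.integer(clear_zone),
                 library_size = library_size,
                 containment = containment,
                 multi_gene = multi_gene,
                 stranded = stranded),
            class = "quant_config")
}

#' Classify one read under the clear-zone uniqueness rule
#'
#' @param aln A list with elements `read_id` and `hits` (a data frame with at
#'   least `mismatches`; typically also `chrom`, `start`, `end`, `strand`),
#'   or a one-read `read_alignments` object.
#' @param cfg A [quant_config()].
#' @return A list of class `uniqueness_decision` with `read_id`, `status`
#'   (one of `"unique"`, `"ambiguous"`, `"discarded_mismatch"`,
#'   `"unmapped"`) and `chosen_hit` (a one-row data frame when unique,
#'   otherwise `NULL`).
#' @examples
#' cfg <- quant_config()
#' h <- data.frame(chrom = "c", start = c(0, 100), end = c(35, 135),
#'                 strand = "+", mismatches = c(0, 3))
#' classify_read(list(read_id = "r", hits = h), cfg)$status  # "unique"
#' @export
classify_read <- function(aln, cfg = quant_config()) {
  if (inherits(aln, "read_alignments")) {
    stopifnot(nrow(aln$reads) == 1)
    aln <- list(read_id = aln$reads$read_id, hits = aln$hits)
  }
  hits <- aln$hits
  status <- "ambiguous"
  chosen <- NULL
  if (is.null(hits) || nrow(hits) == 0) {
    status <- "unmapped"
  } else {
    m <- hits$mismatches
    nstar <- min(m)
    if (nstar > cfg$max_mismatches) {
      status <- "discarded_mismatch"
    } else {
      at_best <- sum(m == nstar)
      in_zone <- sum(m > nstar & m <= nstar + cfg$clear_zone)
      if (at_best == 1 && in_zone == 0) {
        status <- "unique"
        chosen <- hits[which.min(m), , drop = FALSE]
      }
    }
  }
  structure(list(read_id = aln$read_id, status = status,
                 chosen_hit = chosen),
            class = "uniqueness_decision")
}

# Vectorised classifier over a read_alignments object.
# Returns a tibble: read_id, status, and the chosen hit columns for uniques.
classify_reads <- function(aln, cfg = quant_config()) {
  stopifnot(is(aln, "read_alignments"))
  hits <- aln$hits
  if (nrow(hits) > 0) {
    f <- factor(hits$read_id)
    m <- hits$mismatches
    nstar <- tapply(m, f, min)
    idx_levels <- as.integer(f)
    best_of_read <- nstar[idx_levels]
    n_at_best <- tapply(m == best_of_read, f, sum)
    in_zone <- tapply(m > best_of_read &
                        m <= best_of_read + cfg$clear_zone, f, sum)
    status <- ifelse(nstar > cfg$max_mismatches, "discarded_mismatch",
                     ifelse(n_at_best == 1 & in_zone == 0,
                            "unique", "ambiguous"))
    per_read <- tibble(read_id = levels(f), status = as.vector(status))
    # chosen hit = the (single) best hit of each unique read
    is_best <- m == best_of_read
    ord <- order(idx_levels, !is_best)  # best hits first within read
    hb <- hits[ord, ][!duplicated(f[ord]), ]
    per_read <- left_join(per_read, hb, by = "read_id")
    per_read[per_read$status != "unique",
             c("chrom", "start", "end", "strand", "mismatches")] <- NA
  } else {
    per_read <- tibble(read_id = character(), status = character(),
                       chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       mismatches = integer())
  }
  unmapped <- setdiff(aln$reads$read_id, per_read$read_id)
  if (length(unmapped) > 0) {
    per_read <- bind_rows(per_read, tibble(
      read_id = unmapped, status = "unmapped", chrom = NA_character_,
      start = NA_integer_, end = NA_integer_, strand = NA_character_,
      mismatches = NA_integer_))
  }
  per_read
}

# Containment lookup: which genes fully contain each hit.
# Returns tibble(read_id, gene_id), one row per (read, gene) assignment.
assign_hits <- function(hits, genes, containment = "single_exon",
                        stranded = FALSE) {
  stopifnot(is(genes, "gene_models"))
  if (nrow(hits) == 0) {
    return(tibble(read_id = character(), gene_id = character()))
  }
  target <- if (containment == "single_exon") genes$exons else genes$merged
  tgt_strand <- if (stranded && "strand" %in% names(target))
    ifelse(target$strand %in% c("+", "-"), target$strand, "*") else "*"
  tgt <- GenomicRanges::GRanges(
    seqnames = target$chrom,
    ranges = IRanges::IRanges(start = target$start + 1L, end = target$end),
    strand = tgt_strand
  )
  qry <- GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = if (stranded) hits$strand else "*"
  )
  ov <- GenomicRanges::findOverlaps(qry, tgt, type = "within",
                                    ignore.strand = !stranded)
  tibble(read_id = hits$read_id[S4Vectors::queryHits(ov)],
         gene_id = target$gene_id[S4Vectors::subjectHits(ov)]) %>%
    distinct()
}

#' Assign one uniquely mapped hit to genes by exon containment
#'
#' A gene receives the read only if the read span lies entirely inside one of
#' its exons (`single_exon` mode) or inside one block of its merged exon
#' union (`merged_exons` mode). Partial overlap never counts.
#'
#' @param hit A one-row data frame with `chrom`, `start`, `end`, `strand`.
#' @param genes A [gene_models] object.
#' @param containment `"single_exon"` or `"merged_exons"`.
#' @param stranded Restrict to genes on the hit's strand.
#' @return Character vector of gene ids (possibly empty).
#' @export
assign_read_to_genes <- function(hit, genes,
                                 containment = c("single_exon",
                                                 "merged_exons"),
                                 stranded = FALSE) {
  containment <- match.arg(containment)
  hit <- as_tibble(hit)
  if (!"read_id" %in% names(hit)) hit$read_id <- "query"
  sort(unique(assign_hits(hit, genes, containment, stranded)$gene_id))
}

#' Quantify gene expression from alignments
#'
#' Runs the full quantification: clear-zone uniqueness filtering, exon
#' containment assignment, per-gene read counting, and RPKM
#' \deqn{RPKM_g = 10^9 \, C_g / (L_g N)}
#' where \eqn{C_g} is the unique exonic read count of gene g, \eqn{L_g} its
#' merged exonic length, and N the library size (by default the total number
#' of assigned unique exonic reads). A gene is called RNA-present when at
#' least one uniquely mapped read fell entirely inside one of its exons
#' (\eqn{C_g \ge 1}).
#'
#' @param aln A `read_alignments` object.
#' @param genes A [gene_models] object.
#' @param cfg A [quant_config()].
#' @return A tibble with columns `gene_id`, `reads`, `rpkm`, `present`, one
#'   row per gene in `genes` (zero counts included). Attributes:
#'   `library_size`, `n_unique`, `n_assigned`, `status_counts`.
#' @export
quantify <- function(aln, genes, cfg = quant_config()) {
  stopifnot(is(aln, "read_alignments"), is(genes, "gene_models"))
  decisions <- classify_reads(aln, cfg)
  uniq <- decisions[decisions$status == "unique", ]
  assignments <- assign_hits(
    uniq[, c("read_id", "chrom", "start", "end", "strand")],
    genes, cfg$containment, cfg$stranded)
  if (cfg$multi_gene == "discard_shared" && nrow(assignments) > 0) {
    k <- table(assignments$read_id)
    shared <- names(k)[k > 1]
    assignments <- assignments[!assignments$read_id %in% shared, ]
  }
  n_assigned <- length(unique(assignments$read_id))
  lib <- if (is.null(cfg$library_size)) n_assigned else cfg$library_size
  if (lib == 0) stop("empty library: no reads assigned and no library_size")
  counts <- assignments %>% group_by(.data$gene_id) %>%
    summarise(reads = n(), .groups = "drop")
  expr <- genes$genes %>%
    select("gene_id", "exonic_length") %>%
    left_join(counts, by = "gene_id") %>%
    mutate(reads = ifelse(is.na(.data$reads), 0L, .data$reads),
           rpkm = 1e9 * .data$reads / (.data$exonic_length * lib),
           present = .data$reads >= 1L) %>%
    select("gene_id", "reads", "rpkm", "present")
  attr(expr, "library_size") <- lib
  attr(expr, "n_unique") <- nrow(uniq)
  attr(expr, "n_assigned") <- n_assigned
  attr(expr, "status_counts") <- table(decisions$status)
  expr
}

#' Fraction of genes with a detected transcript
#'
#' A transcript counts as present when the gene is represented by at least
#' one uniquely mapped exonic read.
#'
#' @param expr Expression tibble from [quantify()] (needs a logical
#'   `present` column), or a logical vector of presence flags.
#' @return A list of class `presence_rate`: `fraction`, `percent` (1
#'   decimal), `n_present`, `n_total`.
#' @examples
#' pr <- presence_rate(c(rep(TRUE, 15536), rep(FALSE, 21146 - 15536)))
#' pr$percent  # 73.5
#' @export
presence_rate <- function(expr) {
  p <- if (is.logical(expr)) expr else expr$present
  if (length(p) == 0) stop("no genes: presence rate undefined")
  structure(list(fraction = mean(p),
                 percent = round(100 * mean(p), 1),
                 n_present = sum(p),
                 n_total = length(p)),
            class = "presence_rate")
}

#' @export
print.presence_rate <- function(x, ...) {
  cat(sprintf("RNA presence: %.1f%% (%d/%d genes)\n",
              100 * x$fraction, x$n_present, x$n_total))
  invisible(x)
}
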