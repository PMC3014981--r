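#' @importFrom dplyr %>% arrange group_by summarise mutate filter select ungroup
#'   left_join n distinct bind_rows across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom methods is
NULL

# Internal coordinate convention: 0-based, half-open [start, end), like BED.
# GTF input/output converts (GTF is 1-based, closed).

#' Construct a set of gene models from an exon table
#'
#' Builds the package's gene-model container from a table of exon intervals.
#' Exons of a gene are merged into their non-overlapping sorted union; the
#' total length of that union is the exonic gene length \eqn{L_g} used as the
#' "length of the gene" in RPKM.
#'
#' @param exons A data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (`+`, `-` or `.`). Coordinates are 0-based,
#'   half-open.
#' @return An object of class `gene_models`: a list with elements
#'   \describe{
#'     \item{genes}{tibble with `gene_id`, `chrom`, `strand`, `exonic_length`}
#'     \item{exons}{the validated input exon tibble}
#'     \item{merged}{tibble of the merged (disjoint, sorted) exon union}
#'   }
#' @examples
#' gm <- gene_models(data.frame(gene_id = "g1", chrom = "chr1",
#'                              start = c(100, 150), end = c(200, 300)))
#' gm$genes$exonic_length  # 200: union of [100,200) and [150,300)
#' @export
gene_models <- function(exons) {
  exons <- as_tibble(exons)
  required <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    stop("exon table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"strand" %in% names(exons)) exons$strand <- "."
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  bad <- which(exons$start < 0 | exons$end <= exons$start)
  if (length(bad) > 0) {
    stop("invalid exon interval at row ", bad[1],
         ": need start >= 0 and end > start")
  }
  if (nrow(exons) == 0) stop("no exons supplied")

  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = ifelse(exons$strand %in% c("+", "-"), exons$strand, "*")
  )
  by_gene <- S4Vectors::split(gr, exons$gene_id)
  merged_grl <- GenomicRanges::reduce(by_gene, ignore.strand = TRUE)
  merged_flat <- unlist(merged_grl, use.names = TRUE)
  merged <- tibble(
    gene_id = names(merged_flat),
    chrom = as.character(GenomicRanges::seqnames(merged_flat)),
    start = GenomicRanges::start(merged_flat) - 1L,
    end = GenomicRanges::end(merged_flat)
  ) %>% arrange(.data$gene_id, .data$chrom, .data$start)

  lens <- merged %>%
    group_by(.data$gene_id) %>%
    summarise(exonic_length = sum(.data$end - .data$start), .groups = "drop")

  meta <- exons %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              .groups = "drop")

  genes <- left_join(meta, lens, by = "gene_id") %>% arrange(.data$gene_id)
  stopifnot(all(genes$exonic_length > 0))

  structure(list(genes = genes, exons = exons, merged = merged),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons (",
      nrow(x$merged), "merged blocks )\n")
  cat("  exonic length: median", stats::median(x$genes$exonic_length),
      "bp, total", sum(x$genes$exonic_length), "bp\n")
  invisible(x)
}

#' Read gene models from a GTF or BED12 file
#'
#' GTF exon features (Ensembl dialect, 1-based closed coordinates) or BED12
#' blocks are converted to the internal 0-based half-open convention and
#' assembled into a [gene_models] object. Genes with zero exon features are
#' dropped with a warning.
#'
#' @param path Path to a `.gtf` or `.bed` file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return A [gene_models] object.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed12" else "gtf"
  }
  if (format == "gtf") {
    gr <- tryCatch(
      rtracklayer::import(path, format = "gtf"),
      error = function(e) stop("failed to parse GTF '", path, "': ",
                               conditionMessage(e))
    )
    gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
               S4Vectors::mcols(gr)$type == "exon"]
    if (length(gr) == 0) stop("no exon features found in ", path)
    gid <- S4Vectors::mcols(gr)$gene_id
    if (is.null(gid) || anyNA(gid)) stop("GTF exon without gene_id in ", path)
    exons <- tibble(
      gene_id = as.character(gid),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # GTF 1-based -> internal 0-based
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    gr <- tryCatch(
      rtracklayer::import(path, format = "bed"),
      error = function(e) stop("failed to parse BED '", path, "': ",
                               conditionMessage(e))
    )
    name <- S4Vectors::mcols(gr)$name
    if (is.null(name)) name <- paste0("bed_", seq_along(gr))
    blocks <- S4Vectors::mcols(gr)$blocks
    ex_list <- lapply(seq_along(gr), function(i) {
      chrom_start <- GenomicRanges::start(gr[i]) - 1L  # back to 0-based
      if (!is.null(blocks) && length(blocks[[i]]) > 0) {
        b <- blocks[[i]]  # 1-based, relative to range start
        tibble(
          gene_id = name[i],
          chrom = as.character(GenomicRanges::seqnames(gr[i])),
          start = chrom_start + IRanges::start(b) - 1L,
          end = chrom_start + IRanges::end(b),
          strand = as.character(GenomicRanges::strand(gr[i]))
        )
      } else {
        tibble(
          gene_id = name[i],
          chrom = as.character(GenomicRanges::seqnames(gr[i])),
          start = chrom_start,
          end = GenomicRanges::end(gr[i]),
          strand = as.character(GenomicRanges::strand(gr[i]))
        )
      }
    })
    exons <- bind_rows(ex_list)
  }
  exons$strand[!exons$strand %in% c("+", "-")] <- "."
  gene_models(exons)
}

#' Write gene models to GTF
#'
#' Inverse of [read_gene_models()] for the GTF dialect: internal 0-based
#' half-open exons are converted back to 1-based closed GTF coordinates.
#'
#' @param gm A [gene_models] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(gm, path) {
  stopifnot(is(gm, "gene_models"))
  ex <- gm$exons
  lines <- sprintf(
    "%s\ttxpconcord\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
    ex$chrom, ex$start + 1L, ex$end,
    ifelse(ex$strand %in% c("+", "-"), ex$strand, "."),
    ex$gene_id, ex$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read multi-hit read alignments
#'
#' Reads alignment records carrying per-hit mismatch counts, either from
#' SAM/BAM (mismatches from the `NM` tag; secondary alignments are kept, so a
#' multi-mapping read contributes one hit per record) or from a plain
#' tab-separated dialect with header
#' `read_id  chrom  start  end  strand  mismatches` (coordinates 0-based
#' half-open, one row per hit). Unmapped reads are retained with zero hits.
#'
#' @param path Path to a `.sam`, `.bam` or `.tsv` file.
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"tsv"`.
#' @return An object of class `read_alignments`: a list with
#'   \describe{
#'     \item{reads}{tibble `read_id`, `read_length`, `n_hits`}
#'     \item{hits}{tibble `read_id`, `chrom`, `start`, `end`, `strand`,
#'       `mismatches`, input order preserved within each read}
#'   }
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, sam = "sam", bam = "bam", "tsv")
  }
  if (format %in% c("sam", "bam")) {
    bam <- path
    if (format == "sam") {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    param <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "strand", "qwidth", "cigar"),
      tag = "NM"
    )
    res <- Rsamtools::scanBam(bam, param = param)[[1]]
    flag <- res$flag
    mapped <- !bitwAnd(flag, 4L)
    nm <- res$tag$NM
    if (any(mapped & is.na(nm))) {
      bad <- res$qname[mapped & is.na(nm)][1]
      stop("alignment record without NM tag: read '", bad, "'")
    }
    ref_width <- rep(NA_integer_, length(flag))
    if (any(mapped)) {
      ref_width[mapped] <-
        GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[mapped])
    }
    hits <- tibble(
      read_id = res$qname[mapped],
      chrom = as.character(res$rname[mapped]),
      start = res$pos[mapped] - 1L,
      end = res$pos[mapped] - 1L + ref_width[mapped],
      strand = as.character(res$strand[mapped]),
      mismatches = as.integer(nm[mapped])
    )
    reads <- tibble(read_id = res$qname,
                    read_length = as.integer(res$qwidth)) %>%
      group_by(.data$read_id) %>%
      summarise(read_length = .data$read_length[1], .groups = "drop")
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    required <- c("read_id", "chrom", "start", "end", "strand", "mismatches")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols) > 0) {
      stop("alignment TSV lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    mapped <- !is.na(df$chrom) & df$chrom != ""
    if (any(mapped & (is.na(df$mismatches)))) {
      stop("missing mismatch count for read '",
           df$read_id[mapped & is.na(df$mismatches)][1], "'")
    }
    if (any(mapped & (df$start < 0))) {
      stop("negative coordinate for read '",
           df$read_id[mapped & df$start < 0][1], "'")
    }
    hits <- as_tibble(df[mapped, required])
    hits$start <- as.integer(hits$start)
    hits$end <- as.integer(hits$end)
    hits$mismatches <- as.integer(hits$mismatches)
    reads <- tibble(read_id = unique(df$read_id))
    rl <- hits %>% group_by(.data$read_id) %>%
      summarise(read_length = as.integer(.data$end[1] - .data$start[1]),
                .groups = "drop")
    reads <- left_join(reads, rl, by = "read_id")
  }
  nh <- hits %>% group_by(.data$read_id) %>%
    summarise(n_hits = n(), .groups = "drop")
  reads <- left_join(reads, nh, by = "read_id")
  reads$n_hits[is.na(reads$n_hits)] <- 0L
  structure(list(reads = reads, hits = hits), class = "read_alignments")
}

#' Write alignments in the multi-hit TSV dialect
#'
#' @param aln A `read_alignments` object (see [read_alignments()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(aln, path) {
  stopifnot(is(aln, "read_alignments"))
  hits <- aln$hits
  unmapped <- setdiff(aln$reads$read_id, hits$read_id)
  if (length(unmapped) > 0) {
    hits <- bind_rows(hits, tibble(
      read_id = unmapped, chrom = NA_character_, start = NA_integer_,
      end = NA_integer_, strand = NA_character_, mismatches = NA_integer_
    ))
  }
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.read_alignments <- function(x, ...) {
  cat("read_alignments:", nrow(x$reads), "reads,", nrow(x$hits), "hits;",
      sum(x$reads$n_hits == 0), "unmapped\n")
  invisible(x)
}

.IHC_LEVELS <- c("negative", "weak", "moderate", "strong")

#' Read an antibody annotation table
#'
#' Expects a TSV with header `antibody_id`, `gene_id`, `ihc_intensity`,
#' `if_score`, `wb_score`. IHC intensity is one of negative / weak / moderate /
#' strong; the IF validation score is an integer 1..9 (7 = no staining); the
#' Western-blot validation score is 1..7. Empty cells encode missing values;
#' out-of-range values are rejected with their row number.
#'
#' @param path Path to the TSV file.
#' @return A tibble of validated antibody records.
#' @export
read_antibody_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  required <- c("antibody_id", "gene_id", "ihc_intensity", "if_score",
                "wb_score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("antibody table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as_tibble(df[required])
  df$ihc_intensity <- ifelse(is.na(df$ihc_intensity), NA_character_,
                             tolower(trimws(df$ihc_intensity)))
  bad <- which(!is.na(df$ihc_intensity) &
                 !df$ihc_intensity %in% .IHC_LEVELS)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": unknown IHC intensity '",
         df$ihc_intensity[bad[1]], "'")
  }
  df$if_score <- suppressWarnings(as.integer(df$if_score))
  df$wb_score <- suppressWarnings(as.integer(df$wb_score))
  bad <- which(!is.na(df$if_score) & (df$if_score < 1 | df$if_score > 9))
  if (length(bad) > 0) {
    stop("row ", bad[1], ": IF validation score out of range 1..9: ",
         df$if_score[bad[1]])
  }
  bad <- which(!is.na(df$wb_score) & (df$wb_score < 1 | df$wb_score > 7))
  if (length(bad) > 0) {
    stop("row ", bad[1], ": WB validation score out of range 1..7: ",
         df$wb_score[bad[1]])
  }
  df
}

#' Write an antibody annotation table
#' @param ab Antibody tibble as returned by [read_antibody_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_antibody_table <- function(ab, path) {
  utils::write.table(ab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
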