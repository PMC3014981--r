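#' Protein presence from IHC staining intensity
#'
#' A protein is absent when the immunohistochemistry staining intensity is
#' `negative`, and present when it is `weak`, `moderate` or `strong`.
#'
#' @param intensity Character vector of IHC grades.
#' @return Logical vector of presence calls.
#' @export
call_ihc <- function(intensity) {
  if (anyNA(intensity)) {
    stop("missing IHC intensity: exclude genes without IHC data upstream")
  }
  intensity <- tolower(intensity)
  bad <- setdiff(unique(intensity), .IHC_LEVELS)
  if (length(bad) > 0) stop("unknown IHC intensity: ", bad[1])
  intensity != "negative"
}

#' Protein presence from the IF validation score
#'
#' A protein is absent when the immunofluorescence validation score is 7 (no
#' staining) and present for any other score on the nine-grade scale.
#'
#' @param if_score Integer vector of IF validation scores (1..9).
#' @return Logical vector of presence calls.
#' @export
call_if <- function(if_score) {
  if (anyNA(if_score)) {
    stop("missing IF score: exclude genes without IF data upstream")
  }
  if (any(if_score < 1 | if_score > 9)) {
    stop("IF validation score out of range 1..9")
  }
  if_score != 7
}

#' Western-blot validation category
#'
#' Maps the seven-grade WB validation score onto the three main categories:
#' grades 1-3 supportive, 4-5 uncertain, 6-7 non-supportive.
#'
#' @param wb_score Integer vector of WB scores (1..7), `NA` allowed.
#' @return Factor with levels supportive / uncertain / non_supportive.
#' @export
wb_validation_category <- function(wb_score) {
  if (any(!is.na(wb_score) & (wb_score < 1 | wb_score > 7))) {
    stop("WB validation score out of range 1..7")
  }
  out <- rep(NA_character_, length(wb_score))
  out[!is.na(wb_score) & wb_score <= 3] <- "supportive"
  out[!is.na(wb_score) & wb_score %in% 4:5] <- "uncertain"
  out[!is.na(wb_score) & wb_score >= 6] <- "non_supportive"
  factor(out, levels = c("supportive", "uncertain", "non_supportive"))
}

#' Default IF score-to-category map
#'
#' The nine-grade IF validation scale merged into the three main categories:
#' 1-3 supportive, 4-6 uncertain, 8-9 non-supportive; 7 denotes absence (no
#' staining) and maps to no category. The map is a named character vector and
#' can be replaced wholesale in [if_validation_category()].
#'
#' @return Named character vector indexed by score "1".."9".
#' @export
default_if_category_map <- function() {
  c(`1` = "supportive", `2` = "supportive", `3` = "supportive",
    `4` = "uncertain", `5` = "uncertain", `6` = "uncertain",
    `7` = NA, `8` = "non_supportive", `9` = "non_supportive")
}

#' IF validation category
#'
#' @param if_score Integer vector of IF scores (1..9), `NA` allowed.
#' @param map Score-to-category map; see [default_if_category_map()].
#' @return Factor with levels supportive / uncertain / non_supportive.
#' @export
if_validation_category <- function(if_score,
                                   map = default_if_category_map()) {
  if (any(!is.na(if_score) & (if_score < 1 | if_score > 9))) {
    stop("IF validation score out of range 1..9")
  }
  out <- unname(map[as.character(if_score)])
  factor(out, levels = c("supportive", "uncertain", "non_supportive"))
}

#' Select the best antibody for a gene
#'
#' Among a gene's candidate antibodies the best-scoring IF antibody is
#' selected: numerically lowest IF validation score (lower grades are
#' better), ties broken by lowest WB score (missing WB ranks worst), then by
#' antibody id.
#'
#' @param candidates Data frame of antibody records for one gene with columns
#'   `antibody_id`, `if_score`, `wb_score`.
#' @return The selected row (one-row tibble).
#' @export
select_antibody <- function(candidates) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) stop("no candidate antibodies")
  wb <- ifelse(is.na(candidates$wb_score), 8L,
               as.integer(candidates$wb_score))
  ord <- order(candidates$if_score, wb, candidates$antibody_id)
  candidates[ord[1], , drop = FALSE]
}

#' Assemble the non-redundant dual-platform antibody subset
#'
#' Keeps the genes having at least one antibody with protein expression data
#' from both IHC and IF, selects one antibody per gene via
#' [select_antibody()], and derives all presence calls and validation
#' categories from that single antibody. Genes whose selected antibody lacks
#' WB data keep a missing WB category (no fallback to another antibody).
#'
#' @param ab Antibody tibble (see [read_antibody_table()]).
#' @param if_map IF category map for [if_validation_category()].
#' @return Tibble of per-gene protein calls: `gene_id`, `antibody_id`,
#'   `ihc_present`, `if_present`, `wb_score`, `if_score`, `wb_category`,
#'   `if_category`; one row per gene, ordered by `gene_id`.
#' @export
build_hpa_subset <- function(ab, if_map = default_if_category_map()) {
  ab <- as_tibble(ab)
  dual <- ab[!is.na(ab$ihc_intensity) & !is.na(ab$if_score), ]
  if (nrow(dual) == 0) {
    return(tibble(gene_id = character(), antibody_id = character(),
                  ihc_present = logical(), if_present = logical(),
                  wb_score = integer(), if_score = integer(),
                  wb_category = factor(levels = levels(
                    wb_validation_category(integer()))),
                  if_category = factor(levels = levels(
                    wb_validation_category(integer())))))
  }
  sel <- dual %>%
    group_by(.data$gene_id) %>%
    dplyr::group_modify(~ select_antibody(.x)) %>%
    ungroup() %>%
    arrange(.data$gene_id)
  tibble(
    gene_id = sel$gene_id,
    antibody_id = sel$antibody_id,
    ihc_present = call_ihc(sel$ihc_intensity),
    if_present = call_if(sel$if_score),
    wb_score = sel$wb_score,
    if_score = sel$if_score,
    wb_category = wb_validation_category(sel$wb_score),
    if_category = if_validation_category(sel$if_score, if_map)
  )
}

#' Write protein calls to TSV
#' @param calls Tibble from [build_hpa_subset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
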