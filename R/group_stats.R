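#' Validation-score distribution of a Venn group
#'
#' Empirical distribution of Western-blot scores (1..7) or IF validation
#' scores (1..9) for the antibodies of one Venn group, with the fraction of
#' antibodies holding a supportive category. Records with a missing score are
#' excluded and counted.
#'
#' @param records Concordance tibble from [build_table()].
#' @param group One Venn group label (`"A"`, ..., `"ABC"`, `"none"`).
#' @param score_kind `"wb"` or `"if"`.
#' @return List of class `score_distribution`: `group`, `score_kind`,
#'   `values` (sorted score vector), `counts` (named table over the score
#'   support), `supportive_fraction`, `n`, `n_missing`.
#' @export
score_distribution <- function(records, group, score_kind = c("wb", "if")) {
  score_kind <- match.arg(score_kind)
  stopifnot(group %in% .VENN_LEVELS)
  sel <- records[records$venn_group == group, ]
  scores <- if (score_kind == "wb") sel$wb_score else sel$if_score
  cats <- if (score_kind == "wb") sel$wb_category else sel$if_category
  keep <- !is.na(scores)
  n_missing <- sum(!keep)
  scores <- scores[keep]; cats <- cats[keep]
  if (length(scores) == 0) {
    stop("group ", group, " has no ", score_kind, " scores after exclusions")
  }
  support <- if (score_kind == "wb") 1:7 else 1:9
  counts <- table(factor(scores, levels = support))
  structure(list(
    group = group, score_kind = score_kind,
    values = sort(scores), counts = counts,
    supportive_fraction = mean(cats == "supportive", na.rm = FALSE),
    n = length(scores), n_missing = n_missing
  ), class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("%s score distribution, group %s (n = %d, %d missing)\n",
              toupper(x$score_kind), x$group, x$n, x$n_missing))
  print(x$counts)
  cat(sprintf("supportive fraction: %.3f\n", x$supportive_fraction))
  invisible(x)
}

# Two-sided two-sample KS statistic for ordinal scores with heavy ties.
ks_stat_discrete <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
}

#' Permutation (KS-bootstrap) test on ordinal validation scores
#'
#' Two-sample KS test whose null distribution is built by resampling: the
#' observed two-sided KS statistic on the (tied, ordinal) scores is compared
#' with `replicates` label permutations of the pooled scores (default), or
#' with bootstrap resamples drawn with replacement. The p-value uses the
#' add-one estimator \eqn{(1 + \#\{D^* \ge D\})/(B+1)}, so it can never be
#' zero.
#'
#' @param group1_scores,group2_scores Numeric/integer score vectors.
#' @param replicates Number of resamples B (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param method `"permutation"` (exchangeable-null label shuffles, default)
#'   or `"resample"` (bootstrap with replacement from the pooled scores).
#' @return A `concord_test` result with the observed statistic and the
#'   resampling p-value.
#' @export
ks_bootstrap <- function(group1_scores, group2_scores, replicates = 10000,
                         seed = NULL, method = c("permutation", "resample")) {
  method <- match.arg(method)
  if (replicates < 1) stop("replicates must be >= 1")
  if (length(group1_scores) == 0 || length(group2_scores) == 0) {
    stop("both score samples must be non-empty")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pooled <- c(group1_scores, group2_scores)
  n1 <- length(group1_scores); n <- length(pooled)
  # map scores to small integer codes so the permuted CDFs reduce to
  # cumulative count vectors (tabulate), fast enough for many replicates
  codes <- match(pooled, sort(unique(pooled)))
  k <- max(codes)
  tot_counts <- tabulate(codes, k)
  cum_tot <- cumsum(tot_counts)
  d_from_counts <- function(c1) {
    f1 <- cumsum(c1) / n1
    f2 <- (cum_tot - cumsum(c1)) / (n - n1)
    max(abs(f1 - f2))
  }
  d_obs <- d_from_counts(tabulate(codes[seq_len(n1)], k))
  exceed <- 0L
  for (b in seq_len(replicates)) {
    c1 <- if (method == "permutation") {
      tabulate(codes[sample.int(n, n1)], k)
    } else {
      tabulate(sample(codes, n1, replace = TRUE), k)
    }
    if (method == "resample") {
      # independent second bootstrap sample; recompute both CDFs
      c2 <- tabulate(sample(codes, n - n1, replace = TRUE), k)
      d <- max(abs(cumsum(c1) / n1 - cumsum(c2) / (n - n1)))
    } else {
      d <- d_from_counts(c1)
    }
    if (d >= d_obs - 1e-12) exceed <- exceed + 1L
  }
  new_test_result(
    method = sprintf("two-sample KS, %s null on ordinal scores", method),
    statistic = d_obs,
    p_value = (1 + exceed) / (replicates + 1),
    sidedness = "two_sided", replicates = as.integer(replicates))
}

#' Ratio of supportive-antibody fractions between two groups
#'
#' @param g1,g2 `score_distribution` objects (see [score_distribution()]).
#' @return The ratio `g1$supportive_fraction / g2$supportive_fraction`;
#'   `NaN` with a warning when the denominator fraction is zero.
#' @export
supportive_ratio <- function(g1, g2) {
  stopifnot(inherits(g1, "score_distribution"),
            inherits(g2, "score_distribution"))
  if (g2$supportive_fraction == 0) {
    warning("reference group has supportive fraction 0: ratio undefined")
    return(NaN)
  }
  g1$supportive_fraction / g2$supportive_fraction
}

#' Hypergeometric over-representation test
#'
#' One-sided over-representation p-value for a gene category within a group
#' of genes drawn from a background: \eqn{p = P(X \ge k)} with
#' \eqn{X \sim} Hypergeometric(background, set, group).
#'
#' @param background_size Number of genes in the background universe.
#' @param set_size Number of background genes annotated to the category (K).
#' @param group_size Size of the gene group tested (n).
#' @param overlap Number of annotated genes inside the group (k).
#' @return A `concord_test` result; the statistic is the observed overlap.
#' @examples
#' enrichment(2749, 69, 205, 33)$p_value  # far below 1e-7
#' @export
enrichment <- function(background_size, set_size, group_size, overlap) {
  if (set_size > background_size || group_size > background_size) {
    stop("set and group must be subsets of the background")
  }
  if (overlap > min(set_size, group_size)) {
    stop("overlap cannot exceed set or group size")
  }
  if (overlap < 0) stop("overlap must be non-negative")
  p <- stats::phyper(overlap - 1, set_size, background_size - set_size,
                     group_size, lower.tail = FALSE)
  new_test_result(method = "hypergeometric over-representation",
                  statistic = overlap, p_value = p,
                  sidedness = "one_sided")
}

#' Batch over-representation with Benjamini-Hochberg adjustment
#'
#' @param categories Data frame with columns `category`, `set_size`,
#'   `overlap`.
#' @param background_size,group_size As in [enrichment()].
#' @return Tibble with per-category p-values and BH-adjusted q-values,
#'   ordered by p-value.
#' @export
enrichment_batch <- function(categories, background_size, group_size) {
  categories <- as_tibble(categories)
  p <- vapply(seq_len(nrow(categories)), function(i) {
    enrichment(background_size, categories$set_size[i], group_size,
               categories$overlap[i])$p_value
  }, numeric(1))
  categories$p_value <- p
  categories$q_value <- stats::p.adjust(p, method = "BH")
  categories[order(categories$p_value), ]
}
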