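---
title: "Methods: transcript-protein presence concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-protein presence concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txpconcord)
```

# The problem

How well does the set of genes with a detectable transcript agree with the
set of genes whose protein is detectable *in situ*? `txpconcord` answers
this at the presence/absence level for three platforms applied to one cell
line: RNA-seq of the transcriptome, and two antibody-based protein assays —
immunohistochemistry (IHC, chromogenic staining graded
negative/weak/moderate/strong) and immunofluorescence confocal microscopy
(IF, annotated with a nine-grade validation score in which grade 7 means no
staining). Because IHC and IF are semi-quantitative, the comparison is made
on presence calls, with the quantitative RNA-seq signal (RPKM) used to
stratify the comparison by expression level.

# RNA side: quantification model

## Uniqueness by mismatch clear zone

Short reads (35 bp) may align to several genomic locations with different
numbers of mismatches. A read is kept as **unique** only when its best hit,
with $N^{*}$ mismatches, is unambiguous in a strong sense: no other hit has
$N^{*}$, $N^{*}+1$, ..., $N^{*}+z$ mismatches, with clear-zone width
$z = 2$ by default. A competitor inside that zone — including a tie at
$N^{*}$, since presence requires "a single location" — makes the read
**ambiguous**; reads whose best hit needs more than 3 mismatches are
**discarded**. Both parameters live in `quant_config()`. The implementation
(a vectorised min/count formulation) is tested against an independent
literal restatement of the rule, enumerating every hit list of length up to
4 with mismatch counts 0..5.

## Exon containment and counting

A unique read is assigned to a gene when it falls *entirely inside* an exon
of that gene; partial overlap never counts. Two containment modes exist
because annotation practice leaves an ambiguity:

* `single_exon` (default): containment within one annotated exon interval.
  This is the literal reading of the presence rule and is the conservative
  choice for 35-bp reads, which rarely need junctions.
* `merged_exons`: containment within one block of the merged exon union,
  which admits reads spanning the junction of two overlapping exons.

A read contained in exons of several overlapping genes counts once for each
gene (presence is defined per gene); `multi_gene = "discard_shared"`
switches to dropping such reads. Counting is unstranded by default — the
library protocol here is random-primed, and strandedness is genuinely
unknowable from the inputs — with `stranded = TRUE` available.

## RPKM and presence

For gene $g$ with $C_g$ unique exonic reads, merged-exon length $L_g$ and
library size $N$:

$$\mathrm{RPKM}_g = \frac{10^9 \, C_g}{L_g \, N}.$$

$L_g$ is the length of the *merged* exon union (the natural reading of
"length of the gene" for exonic counting, and standard RPKM practice). $N$
defaults to the total number of assigned unique exonic reads; a fixed
denominator (e.g. all uniquely mapped reads) can be supplied via
`quant_config(library_size =)`. A gene is RNA-present iff $C_g \ge 1$.

# Protein side: presence calls and validation categories

* IHC: absent iff staining intensity is `negative`.
* IF: absent iff validation score is 7; any other score (including 8-9)
  means present. This is deliberately the literal rule; whether 8-9 should
  also denote absence is a judgement the data model leaves to the category
  map.
* WB categories: scores 1-3 supportive, 4-5 uncertain, 6-7 non-supportive.
* IF categories: the full score-to-category table is not part of the
  public record, so the default map (1-3 supportive, 4-6 uncertain, 8-9
  non-supportive, 7 = absent) is an assumption, exposed as a replaceable
  argument (`default_if_category_map()`).

The analysis universe is the **dual-platform subset**: genes with at least
one antibody carrying both IHC and IF data. For multi-antibody genes the
best-scoring IF antibody is selected (lowest score; ties by lowest WB
score with missing ranked worst, then antibody id — a deterministic,
documented ordering). That single antibody carries *all* of the gene's
calls; if it lacks WB data the WB category stays missing rather than
borrowing from a different antibody, keeping a strict one-gene-one-antibody
correspondence.

# Joint statistics

* **Venn partition**: presence by IHC (A), IF (B), RNA-seq (C) defines 8
  groups (A, B, C, AB, AC, BC, ABC, none).
* **Overlap summary**: coverage and presence rates as count/denominator
  with percentages at 1 decimal; an empty denominator yields `NA`, never 0.
* **Association**: Pearson chi-square (df = 1) on the RNA x protein 2x2
  table, Yates continuity correction on by default (this is what
  reproduces the published p-value on the recorded counts; the uncorrected
  statistic is also available and is verified against the closed form).
  A zero expected cell raises an error directing users to an exact test.
* **Expression shift per group**: one-sided two-sample KS test with a
  tie-aware statistic (max signed ECDF difference over pooled points) and
  the asymptotic one-sided tail $e^{-2D^2 nm/(n+m)}$. The default
  direction is "group stochastically lower", matching the question of
  whether a group contains lowly transcribed genes, and the group is
  compared against the full subset including itself (the natural reference
  curve in a cumulative-density display), not the complement; both are
  choices the caller can invert by passing other vectors.
* **Quantile-binned overlap**: genes ranked by RPKM descending (ties by
  gene id, so binning is reproducible regardless of row order), split into
  25 equal-size bins (remainder spread over the top bins). Since 25 equal
  bins are 4% each while the headline slices are "top/bottom 5%", both the
  25-bin table and explicit top/bottom-5% slices are emitted, plus the
  upper/lower-50% split. Restricting to supportive-WB antibodies filters
  *before* ranking.
* **Permutation KS on validation scores** (`ks_bootstrap()`): the WB/IF
  scores are heavily tied ordinal grades, so the null distribution of the
  two-sided KS statistic is built by pooled label permutation
  (exchangeable null) — the standard resampling choice for tied scores —
  with bootstrap-with-replacement available as an alternative mode. The
  p-value uses the add-one estimator $(1+\#\{D^* \ge D\})/(B+1)$, which
  cannot return zero; with the default $B = 10^4$ the smallest reportable
  p is $10^{-4}$.
* **Over-representation**: one-sided hypergeometric tail
  ($P(X \ge k)$) with Benjamini-Hochberg adjustment across categories.
  This is a generic substitute for database-backed enrichment tools: tools
  built on the EASE-adjusted Fisher statistic report systematically more
  conservative p-values, so published values from such tools are not
  directly comparable. The background defaults to whatever gene universe
  the caller supplies; for subgroup analyses the dual-platform subset is
  the natural background.

# Synthetic data

`simulate_dataset()` generates every input the pipeline consumes, under a
single seed:

* **Gene models**: ~4 exons per gene (1 + Poisson), log-normal exon
  lengths (median 250 bp, floor 80 bp), genes laid head-to-tail so models
  never overlap and truth stays unambiguous.
* **Expression**: zero-inflated log-normal. The default silent fraction
  $\pi_0 = 0.265$ mirrors the observed genome-wide transcript detection of
  roughly 73-74%; the log-normal shape mimics the skewed RPKM frequency
  distribution typical of bulk RNA-seq.
* **Reads**: 35 bp, placed uniformly inside exons of the origin gene
  (guaranteeing single-exon containment), mismatches drawn from a
  decreasing distribution over 0..3. A configurable fraction of reads gets
  1-3 decoy hits on an unannotated decoy chromosome; a configured share of
  those decoys lands *inside* the clear zone. This makes ambiguity
  deterministic given the bookkeeping, and the generator's
  `violates_clear_zone` flags are required (and tested) to coincide
  exactly with the filter's ambiguous set.
* **Protein detection**: gene-level Bernoulli with
  $P(\text{detected}) = \mathrm{logit}^{-1}(\alpha_p + \beta_p \log_{10}
  \mathrm{RPKM})$ per platform. Defaults
  ($\alpha_{IHC}=0.6, \beta_{IHC}=0.9$;
  $\alpha_{IF}=0.9, \beta_{IF}=0.45$) encode the two qualitative facts the
  analysis rests on: detection rises with expression, and IF is the more
  sensitive platform at low expression (flatter slope, higher intercept)
  while IHC detects more overall at the top end. Silent genes have zero
  true detection probability; apparent detections there come only from the
  antibody false-positive layer, whose rate grows as antibody quality
  (and hence WB/IF validation scores) worsens. This is the structure that
  makes groups A and AB fill with low-scoring antibodies.
* **What it does not emulate**: sequencing error profiles, colorspace,
  junction reads, gene-model overlap, batch effects, or any biological
  covariance between expression and antibody quality. Passing tests
  therefore demonstrate the statistical machinery and the stated
  qualitative structure, not performance on real tissue data.

`u2os_fixture()` is a separate, deterministic construction: 2749 genes
whose presence flags reproduce the recorded three-platform partition
(A=110, B=55, C=102, AB=205, AC=472, BC=120, ABC=1651, none=34) by integer
arithmetic. RPKM magnitudes for RNA-present genes come from a log-normal
under a fixed internal seed, with groups C and BC drawn from the lower
third of the quantile range so their cumulative curves sit left of the
full set — a qualitative, not quantitative, reproduction of the published
expression curves. Validation scores are laid out deterministically per
group (supportive fractions: ABC highest, A/AB lowest; IF supportive
fraction in ABC ≈ 3x that of B). Venn counts, overlap percentages and the
2x2 association tables derived from the fixture are *exact* consequences
of the printed counts; everything involving score or RPKM magnitudes is
engineered and only its direction is meaningful.

# Numerical and design notes

* Internal coordinates are 0-based half-open everywhere; GTF conversion
  happens at the boundary (read/write), preventing off-by-one drift.
* Percentages are reported at 1 decimal next to their raw fractions.
  Published reports sometimes truncate rather than round (e.g. 222/2345 =
  9.47% printed as 9.4%), so comparisons at the last decimal should allow
  one unit of disagreement.
* KS p-values: the one-sided asymptotic tail is used for expression
  comparisons (sample sizes in the hundreds-thousands); for ordinal scores
  the permutation null is preferred over the asymptotic formula because of
  ties. The permutation p converges to the exact enumeration value
  (verified by full enumeration at pooled $n \le 8$), and its type-I error
  at $\alpha = 0.05$ is calibrated on null score pairs.
* Problem sizes in the test-suite simulations (hundreds to 5000 genes,
  $10^4$-$2\times 10^5$ reads, 500 calibration pairs at $B = 999$) were
  chosen as the smallest scales at which the stochastic assertions are
  stable under their stated tolerances.
* Degenerate inputs fail loudly: empty libraries, empty score groups,
  zero expected cells, fewer genes than bins, out-of-range scores and
  infeasible read lengths all raise errors rather than returning NA-laden
  results.

# Worked example

```{r example, eval = FALSE}
fx <- u2os_fixture()
records <- build_table(fx$expr, fx$calls)
venn(records)
overlap_summary(venn(records))
association_test(contingency_2x2(records, "ihc"))
bin_overlap(records, n_bins = 25)

# or the whole pipeline, writing TSVs and a summary:
res <- run_pipeline(tempfile("concord-"), seed = 1)
```

# Known limitations

* The IF score-to-category map and the "best scoring" ordering are
  assumptions where the underlying scheme is not public; both are
  replaceable arguments.
* Junction-spanning reads are only assignable in `merged_exons` mode and
  only within a merged block; true splice-junction assignment is out of
  scope.
* The hypergeometric enrichment is not a reimplementation of
  database-backed tools (no EASE score, no category clustering); category
  membership must be supplied by the user.
* Real antibody panels have structured missingness and per-tissue
  variability that the independent-dropout model here does not capture.
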