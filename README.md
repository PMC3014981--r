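# txpconcord

Transcript–protein presence concordance for a cell line: compare which
genes have a detectable transcript (RNA-seq) with which genes have a
detectable protein (antibody-based immunohistochemistry, IHC, and
immunofluorescence microscopy, IF), and use antibody validation scores
(Western blot and IF reliability grades) to separate genuine discordance
from antibody artefacts.

The package is aimed at people analysing antibody-resource data (such as
cell-line annotations from large antibody atlases) alongside RNA-seq, and
at anyone who needs the underlying statistical pieces: a strict
unique-mapping filter, presence-level concordance statistics, and
permutation tests on tied ordinal scores.

## What it computes

**RNA side.** A read is *uniquely mapped* only if its best hit (N\*
mismatches, N\* ≤ 3) has no competitor within the mismatch *clear zone*
[N\*, N\*+2]. A gene is RNA-present when at least one unique read falls
entirely inside one of its exons. Expression is

RPKM_g = 10^9 · C_g / (L_g · N)

with C_g the unique exonic read count, L_g the merged exonic length and N
the library size (total assigned unique exonic reads by default).

**Protein side.** IHC: absent iff staining intensity is negative. IF:
absent iff validation score is 7 (no staining). One best-scoring IF
antibody per gene is selected among those with data on both platforms (the
non-redundant dual-platform subset); its Western-blot score maps to
supportive (1–3) / uncertain (4–5) / non-supportive (6–7).

**Joint statistics.** Venn partition over presence by IHC (A), IF (B) and
RNA-seq (C); overlap/coverage percentages; continuity-corrected chi-square
association between RNA and protein presence; one-sided two-sample
Kolmogorov–Smirnov tests for expression shifts of Venn groups;
expression-quantile-binned detection rates (25 bins plus 50% and 5%
slices); permutation-null KS tests on ordinal validation scores; and
hypergeometric over-representation with BH adjustment.

**Synthetic data.** `simulate_dataset()` generates gene models, reads with
decoy multi-mapping hits and mismatch counts, and antibody panels whose
detection probability is logistic in log10 RPKM and whose false positives
concentrate in low-validation antibodies — with full ground truth.
`u2os_fixture()` is a deterministic 2749-gene table reproducing the
recorded three-platform partition of the U-2 OS osteosarcoma cell line.

## Worked example

```r
library(txpconcord)

fx <- u2os_fixture()
records <- build_table(fx$expr, fx$calls)
venn(records)
#> Venn partition (A = IHC, B = IF, C = RNA-seq), 2749 genes:
#>    A    B    C   AB   AC   BC  ABC none
#>  110   55  102  205  472  120 1651   34

association_test(contingency_2x2(records, "ihc"))
#> Pearson chi-square (continuity-corrected)
#>   statistic = 52.965 (df = 1)
#>   p = 3.4e-13 (two_sided)

bin_overlap(records, n_bins = 25)
#> Expression-binned overlap over 2749 genes
#>     level n_genes pct_ihc_present pct_if_present
#>  upper_50    1375       100.00000       77.81818
#>  lower_50    1374        77.36536       69.94178
#> ( 25 quantile bins in $bins; top/bottom 5% in $tails)
```

Reading the output: 60.1% of the 2749 genes (ABC = 1651) are detected on
all three platforms and only 34 genes on none; RNA presence is strongly
associated with IHC protein presence (p ≈ 3.4 × 10⁻¹³); and protein
detection rates fall from the upper to the lower expression half on both
platforms. `run_pipeline(out_dir)` runs every stage and writes the TSV
tables plus a markdown summary; pass it a `simulate_dataset()` result to
analyse synthetic raw data end to end (quantification included).

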