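---
title: "CATG-anchored DGE tag profiling: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CATG-anchored DGE tag profiling: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgetag)
```

## The assay and its quantitative model

Digital gene expression (DGE) tag profiling counts transcripts by
sequencing a single short signature per cDNA molecule: the 21-bp fragment
beginning at an NlaIII restriction site (`CATG`) plus the 17 following
nucleotides. A library is therefore a multiset of 21-mers, and a gene's
expression is estimated by the number of tag copies that can be traced back
to its transcript. `dgetag` implements the complete analysis chain for this
assay:

1. **Tag extraction** — each 35-bp read contributes the 21-mer starting at
   its first `CATG` with at least 17 nt following; reads without a usable
   anchor are "empty".
2. **Clean-tag filtering** — adaptor-matching tags, tags containing `N`,
   and singleton tags (copy number 1) are removed, in that fixed order.
3. **Virtual-tag mapping** — tags are looked up in a database of all
   CATG-anchored 21-mers of the annotated transcripts (both strands) with
   at most one mismatch; the genome-wide tag set catches transcripts the
   annotation misses.
4. **Normalization** — unambiguous per-gene counts are scaled to TPM
   (tags per million clean tags).
5. **Differential expression** — the Audic–Claverie conditional count test
   per gene, Benjamini–Hochberg FDR across each comparison, significance at
   FDR ≤ 0.001 and |log2 ratio| ≥ 1.
6. **Non-additivity** — a hybrid library is compared against an in-silico
   mid-parent library (pooled parental counts) with the same machinery.
7. **Descriptive summaries** — category accounting, abundance and
   fold-change distributions, saturation curves, overlap partitions,
   hierarchical clustering of DEGs, hypergeometric term enrichment.

## The significance model

For a gene with `x` tags in library A (total `n_a`) and `y` in library B
(total `n_b`), equal relative abundance implies the conditional law

$$P(y \mid x) \;=\; \Big(\tfrac{n_b}{n_a}\Big)^{y}
  \frac{(x+y)!}{x!\,y!\,\big(1+\tfrac{n_b}{n_a}\big)^{x+y+1}},$$

a negative binomial with size $x+1$ and success probability
$n_a/(n_a+n_b)$. The two-sided p-value doubles the smaller of the tails
$P(Y \le y \mid x)$ and $P(X \le x \mid y)$, capped at 1.

**Tail convention.** The two tails satisfy the exact identity
$P(X \le x \mid y) = P(Y > y \mid x)$. Taking these two as the tails (rather
than the inclusive pair $P(Y\le y), P(Y\ge y)$) buys two properties at once:
the p-value is exactly symmetric in the two libraries, so every pairwise
screen is antisymmetric under exchanging control and experimental roles, and
$x = y$ with equal totals gives exactly $p = 1$. The cost is that the
observed point's mass is excluded from the upper tail — a discrepancy of at
most one pmf value, analogous in spirit to a mid-p correction. Tails are
accumulated in log space, always summing the numerically smaller tail
directly, so the test is stable at library totals of millions and counts of
tens of thousands.

Genes with zero counts in both libraries are excluded before FDR adjustment
(they carry no information and would only inflate the test count `m`). When
one library has zero expression, TPM 0.001 stands in for 0 when forming
log2 ratios, keeping them finite; the affected genes are flagged by their
zero raw counts in the output tables.

No dispersion-aware (negative binomial with overdispersion) model is fitted:
the design has one library per condition and no replicates, which is exactly
the regime the conditional count test was devised for. This is a known
limitation — biological variability beyond sampling noise is not captured,
so p-values should be read as evidence of count differences, not of
population-level effects.

## Mapping policy

* All CATG-anchored sites per transcript are indexed, not only the
  canonical 3'-most one, on both strands. Internal and antisense tags are
  real and informative in this assay (run-off reverse transcription,
  antisense transcription); `site_rank` records the 3'→5' order so a
  canonical-only view can be recovered by filtering `site_rank == 1`.
* Resolution is strictly stratified: exact beats one-mismatch; the genome
  tag set is consulted only when no gene matches at ≤ 1 mismatch, and
  likewise exact-first. This mirrors the mutually exclusive categories of
  the standard accounting table (gene / genome / unknown), whose totals
  partition the clean-tag total exactly — an identity asserted on every run.
* `N` never matches any base, in references or in tags (conservative).
* A tag hitting one gene at several sites is credited once; a tag hitting
  one gene in both orientations at the same stratum is credited as sense,
  the parsimonious origin (cases are logged in the assignment attributes).
* "Tag-mapped genes" counts genes reachable through ambiguous tags as well;
  the unambiguous gene count is reported separately and is never larger.
* The TPM denominator is the library's total clean-tag count, not its
  mapped count, so mapping efficiency differences between libraries do not
  silently rescale expression values.
* Coordinates are 0-based half-open internally; GFF3 I/O is 1-based
  inclusive, as the format requires.

## Mid-parent value (MPV)

The MPV library models an equal RNA mixture of the two parents sequenced at
their combined depth: per-gene raw counts are pooled and the clean totals
added. Pooling counts (rather than averaging TPM) keeps the MPV a proper
count library so the same conditional test applies; with near-equal parental
totals, MPV TPM equals the parental TPM mean to first order. Genes whose
hybrid expression differs significantly from MPV (same thresholds as the DEG
screen — no separate threshold is defined for this contrast) are
non-additive, split by direction and cross-tabulated by parental bias. Genes
with exactly equal parental TPM form their own `Br=Bo` row rather than being
silently merged into either bias class.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fdr_threshold` | 0.001 | FDR cutoff for DEG / non-additivity calls |
| `lfc_threshold` | 1 | minimum |log2 ratio| for significance |
| TPM floor | 0.001 | stand-in for zero when forming ratios |
| mismatch budget | 1 | maximum Hamming distance in tag lookup (fixed) |
| `bin_lower` | 2,6,11,21,51,101 | abundance distribution bins (copy numbers) |
| `linkage` | average | DEG clustering linkage (Euclidean distance) |
| `n_clusters` | 12 | flat clusters cut from the DEG tree |
| `q_threshold` | 0.05 | enrichment significance on BH-adjusted values |

Average linkage on Euclidean distance reproduces the defaults of the
hierarchical-clustering tools of the assay's era; both are arguments.
Untested cells of the DEG log2-ratio matrix are imputed as 0 before
clustering — untested means no evidence of change, and 0 is the neutral
value of the log-ratio scale. Twelve flat clusters mirror the A–L cluster
granularity conventional for this kind of six-comparison design; the cut is
an argument, not a constant. The enrichment background defaults to whatever
universe the caller supplies; for DEG enrichment the natural choice is the
tag-mapped genes of the compared libraries, since genes invisible to the
assay cannot be drawn into the foreground.

## What the simulator emulates — and what it does not

`sim_config()` encodes the seven-library study design: parents `Br` and
`Bo`, hybrid generations `F1`–`F4`, and a natural allopolyploid `N`.
The generator:

* draws parental abundances from a log-normal (sdlog 1.5) — a few
  high-abundance genes, a long low-abundance tail, matching the abundance
  profile typical of these libraries;
* makes a configurable fraction of genes parent-specific (default 5% per
  parent);
* builds F1 as the mid-parent mixture with non-additive log2 deviations of
  magnitude 1–3 planted on 30% of expressed genes, 60.7% of them above MPV
  (the direction balance characteristic of this design), attenuated
  geometrically (default 50% per generation) in F2–F4, so later generations
  drift back toward additivity;
* plants exact shared 21-mers between 5% of gene pairs (mapping ambiguity),
  flags 36% of genes as antisense-transcribed (30% of their reads from the
  antisense strand), and guarantees every gene at least one usable CATG
  site;
* generates 35-bp reads anchored at CATG sites (3'-most with probability
  0.7), with per-base substitution errors (0.005), N masking (0.002) and
  whole-read adaptor contamination (0.005), all multinomially sampled from
  the truth and fully determined by the seed.

Default depth is 1e6 reads per library. Real libraries of this design run
around 6e6 tags; 1e6 keeps a full seven-library run to desk-scale minutes
while preserving the counting regime (hundreds of tags for a mid-abundance
gene). Routine unit tests run smaller configurations (50–500 genes, 1e3–3e5
reads); the deep validation tests and the acceptance script use 2000 genes
at 1e6 and 5e5 reads respectively.

One compositional subtlety is worth stating: relative abundances must sum
to one, so planting up-biased deviations on 30% of genes necessarily
shrinks every *additive* gene's relative abundance by the renormalization
factor (about −0.5 to −0.8 log2 units at the defaults). This is not an
artifact to be removed — the same composition effect exists in real
sequencing of a reprogrammed transcriptome — but it means "additive" genes
sit slightly below MPV in relative terms, and the |log2 ratio| ≥ 1
significance threshold is what keeps them from being called non-additive.
At study-scale depth the planted deviations remain recoverable because
they are measured relative to the same shifted baseline.

The simulator does **not** model: realistic quality-score profiles, indels,
PCR duplication, splice isoforms, homeolog sequence divergence between the
parental genomes, or chromosome-scale rearrangement. Consequently, passing
the recovery tests demonstrates that the pipeline's accounting, mapping and
statistics are correct under sampling noise, sequencing error and planted
regulation structure — it does not certify performance on real allopolyploid
data, where homeologous cross-mapping and biological replication structure
add difficulty the synthetic truth does not contain.

## Numerical and degeneracy choices

* Tag tallying sorts and run-length-encodes, so library construction is
  deterministic and order-independent; the virtual tag table is kept in
  canonical (tag, gene, orientation) order, making index construction
  invariant to gene input order.
* Filter attribution is first-match in the fixed order adaptor → N →
  singleton, which makes the copy-conservation identity
  `reads = clean + empty + adaptor + N + singleton` exact on every run.
* `top_k` breaks |log2 ratio| ties by smaller FDR, then lexicographic gene
  id; genes expressed in only one sample are excluded from the top tables
  (their ratios are floor artifacts).
* Empty inputs: empty read sets give empty libraries; an empty clean
  library summarizes to zeros; `compute_profile` refuses a zero clean
  total; clustering refuses an empty matrix.
* The saturation curve subsamples without replacement via one permutation
  and first-occurrence positions, so a single pass yields every depth.

## Known limitations

* One library per condition: no replicate-aware inference.
* Ambiguous tags are counted in the accounting but never rescued
  (no expectation-sharing across genes).
* The 1-mismatch budget is fixed; indels are out of scope.
* Enrichment is a generic hypergeometric over a user-supplied annotation
  table; no ontology structure (term propagation) is applied.
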