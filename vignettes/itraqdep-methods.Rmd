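---
title: "Methods: reporter-ion quantitation, DEP calling and enrichment in itraqdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporter-ion quantitation, DEP calling and enrichment in itraqdep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraqdep)
```

## The experimental design the pipeline models

`itraqdep` analyzes multiplexed isobaric-label (iTRAQ/TMT) proteomics
experiments in which several samples are chemically tagged, pooled, and
fragmented together, so that each peptide-spectrum match (PSM) carries one
reporter-ion intensity per sample. The motivating design compares endometrial
tissue of two pig breeds (prolific Meishan, MS; commercial Duroc, DU) at two
mid-gestation stages (days 49 and 72), one reporter channel per breed/stage
group (MSD72:127, MSD49:128, DUD49:129, DUD72:130), with two replicate pools
each analyzed in an independent LC-MS/MS run. The pipeline starts from PSM
tables (Mascot-style search output with ion scores and PSM-level q-values);
database searching itself is out of scope.

Because both reporter ions of a contrast are released from the *same*
fragmentation spectrum, their ratio cancels peptide ionization efficiency and
spectrum-level effects. All inference is therefore built on within-spectrum
channel ratios.

## Quantitation model

For a contrast "case vs control" (e.g. MSD49 vs DUD49):

1. **Identification filters.** PSMs are kept when ion score > 20 and
   q-value < 0.01, both strict. The filter is idempotent and
   order-preserving.
2. **Unique peptides.** A peptide sequence is *unique* iff it maps to exactly
   one protein accession across the entire experiment (all pools jointly);
   only unique peptides quantify proteins. Shared peptides measure the sum of
   their parents and would bias ratios toward 1. Uniqueness is computed on
   the bare sequence; modification-aware identity is out of scope. We chose
   the experiment-wide rule (rather than per pool) because the combined fold
   change is only defined for proteins quantified in *every* pool, so a
   peptide ambiguous in any pool should not contribute anywhere.
3. **Rollup.** Per protein and pool, the fold change `FC_r` is the **median**
   of its unique-peptide within-spectrum ratios; even counts use midpoint
   interpolation (the `stats::median` convention, stated explicitly for
   reproducibility).
4. **Combination.** The combined fold change is the geometric mean over the
   `R` pools, `FC = (prod FC_r)^(1/R)`, computed as `2^mean(log2 FC_r)`.
   Working on the log2 scale makes the reciprocal-pair and power-of-two
   identities exact in floating point and matches the package-wide log2
   convention. Proteins missing any pool have no combined FC and are
   ineligible for DEP calling (the commonly-quantified-set rule); they are
   reported with an `eligible = FALSE` flag, never dropped silently.
5. **Significance.** The p-value is a two-tailed one-sample t-test of the
   protein's pooled log2 ratios against 0. The design has one channel per
   group per pool, so a two-sample test "between groups" is inoperable at
   the protein level; treating the within-spectrum log2 ratio as a paired
   observation of the log fold change is the package's main interpretive
   choice, and peptide-level ratios (not per-pool summaries) are the test
   unit. Degenerate inputs follow stated conventions: fewer than 2 ratios
   give `NA` (ineligible); zero variance gives p = 1 at mean 0 and p = 0
   otherwise. No multiple-testing correction is applied to protein p-values
   because DEP calling thresholds raw p.

No between-channel normalization is applied by default; reporter-loading
normalization is deliberately left to the caller since the ratio design
already cancels spectrum-level effects.

## DEP calling

A protein is `increased` when `FC >= 1.3` and `p < 0.05`, `decreased` when
`FC <= 0.70` and `p < 0.05`, otherwise `unchanged`. The FC boundaries are
inclusive (thresholds read as attainable cutoffs) while the p boundary is
strict. The window is deliberately asymmetric: `0.70 < 1/1.3 = 0.769`, so the
down-call is stricter than the mirror of the up-call and the caller must not
symmetrize — a protein at FC 0.75 mirrors an increased call at 1.33 yet stays
`unchanged`. Raising `alpha` or loosening either threshold can only add DEPs
(monotonicity, property-tested).

## Enrichment

Each contrast's DEP set is tested per annotation term against the background
of commonly quantified proteins (not the full search database) with a
**two-tailed Fisher exact test** on the 2x2 table (DEP membership x term
annotation, fixed margins). The two-tailed rule is the probability-mass
definition — the p-value sums hypergeometric probabilities of all tables no
more probable than the observed one — stated explicitly because the
tail-doubling alternative differs. Ties are detected with a relative
tolerance of 1e-7 so mathematically equal probabilities are not split by
floating-point rounding; the implementation is verified against exhaustive
enumeration on every table with total at most 40 and against
`stats::fisher.test`. Unannotated background proteins count in the
without-term cells, preserving fixed margins. Benjamini-Hochberg adjusted
p-values are reported alongside, but top-term selection follows the original
analysis and uses raw p < 0.05 with odds ratio > 1, sorted by p (ties:
larger DEP count, then term id), truncated to the top 15 biological
processes and top 5 pathways. GO annotations are used as given — no
propagation up the ontology graph — which is the main comparability caveat
against tools that propagate.

## Overlap and concordance

Cross-contrast analysis computes exclusive Venn region counts for 2-4 DEP
sets (regions named by sorted set-name tuples for deterministic output) and
classifies DEPs shared by two contrasts as `both_increased`,
`both_decreased` or `reverse` — the last being the biologically interesting
"reverse expression pattern" case. Orthogonal validation mirrors the wet-lab
checks: western-blot band intensities normalized per lane by housekeeping
actin and anchored so the first-listed (reference) group has mean 1 — the
anchor choice is arbitrary for ratios and is recorded in the output; a
one-way ANOVA per protein with `*`/`**` star conventions at p < 0.05 / 0.01;
Pearson correlation between blot-derived and reporter-derived fold changes
paired by (protein, contrast), on raw fold changes by default (a `log2`
option is provided for sensitivity). Fetal-loss arithmetic is
`100 * (mean_early - mean_late) / mean_early` from per-sow viable-fetus
counts; group SDs use the population convention (divisor n), which
reproduces the recorded 16.3 +/- 0.47 for counts {16, 16, 17}. Note the
recorded Duroc loss (11 -> 8.67) computes to 21.2%, while the Meishan loss
(16.3 -> 14.3) computes to 12.2% rather than the sometimes-quoted ~13%; the
package reports the arithmetic value.

## The synthetic-data generator

Raw mass-spectrometry data for the motivating study are not publicly
deposited, so the package ships a spike-in simulator whose defaults define
the benchmark study conditions used by the recovery tests: 200 proteins,
log-normal baseline abundances, 4-6 peptides per protein, 10% shared
peptides, two replicate pools, 20% of proteins spiked in one randomly chosen
group at a fold change drawn from {1.5, 2.0} (up) or {0.5, 0.67} (down) —
values straddling the 1.3/0.70 calling window on both sides — and 5%
multiplicative reporter noise.

The noise model is log-normal multiplicative on reporter intensities (SD on
the log scale derived from the CV), standard for MS intensities and
guaranteeing positivity. Peptide ionization factors are drawn log-normally
per peptide and held constant across channels and pools, so ratios cancel
them exactly — matching the ratio-based design. Shared peptides receive the
summed contribution of their parents, which is precisely why the rollup
restricts to unique peptides. A small fraction (5%) of junk PSM rows with
failing ion scores or q-values exercises the identification filters.
Annotation terms are planted: 25% of terms (emitted in the BP namespace)
draw ~80% of their member proteins from the spiked set, the rest annotate
proteins at random.

What the simulator does *not* emulate: chromatographic missingness, reporter
isotope-impurity cross-talk, compositional channel biases, interference from
co-isolated precursors, or protein-inference ambiguity beyond simple shared
peptides. Passing recovery tests therefore demonstrates correctness of the
statistical machinery under the stated generative model, not robustness to
every artifact of real reporter-ion data.

Determinism is part of the contract: a fixed seed and config reproduce every
output byte-for-byte, and the run manifest deliberately omits timestamps so
whole result bundles are diffable.

## Problem sizes and numerical choices

The recovery benchmarks run 20 independent seeds of the 200-protein,
two-pool design (about 1,800 PSM rows per seed), which gives roughly 1,600
spiked (protein, contrast) estimates and 14,000 null estimates — enough to
bound power above 0.95 and the false-positive rate below 0.05 with little
Monte-Carlo uncertainty, while keeping a full run under a minute. Under
these conditions measured power is ~0.99, the null false-positive rate ~0
(a null protein must both clear the 1.3/0.70 window and reach p < 0.05,
which 5% reporter noise essentially never produces), and the mean relative
error of combined FC estimates ~2%; individual estimates occasionally exceed
10% relative error (~0.1% of them, tail of the sampling distribution), so
accuracy is asserted distributionally. Fisher p-values are validated
exhaustively over all 2x2 tables with total <= 40 (135,751 tables) to 1e-12
against an independent log-binomial enumeration.

## Known limitations

- Two replicate pools give protein t-tests low power for subtle changes;
  the pipeline reproduces this property of the design rather than fixing it.
- Protein accessions are taken verbatim; no isoform/group collapsing.
- Missing reporter intensities exclude a record from the affected contrast's
  ratios only; no imputation is offered.
- Whether "unique peptide" should be sequence- or PSM-level, and whether the
  original t-test operated on peptide ratios or replicate summaries, are
  underdetermined by the source analysis; the sequence-level and
  peptide-level choices implemented here are flagged for sensitivity
  analysis.
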