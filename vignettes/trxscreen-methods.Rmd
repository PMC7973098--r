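---
title: "Methods: dual-reporter screen scoring and companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-reporter screen scoring and companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trxscreen)
```

This vignette is the package's account of its statistical methods: the
models behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic-data generators do and do not emulate, and
the design choices made where the conventions of this assay family leave
room.

## Primary screen model

A dual-reporter RNAi screen measures, per well, the activity of an
experimental Firefly luciferase under trxG-dependent control (channel F) and
a constitutive Renilla co-reporter (channel R). The analysis assumes:

* plate effects are multiplicative and common to all wells of one
  plate/channel (dispensing, incubation, reader gain);
* well noise is multiplicative and roughly log-normal, as is typical for
  luminescence;
* most library genes are inert, so the library itself provides a stable
  empirical null;
* a gene that depresses both channels acts on general transcription,
  translation or viability and is uninformative about trxG function.

The pipeline in `screen_zscore()` is, in order:

1. **Plate-median correction.** Each plate/channel is divided by the median
   intensity of its *test* wells; controls are excluded from the median but
   corrected with it. The corrected test-well median is exactly 1, removing
   plate effects without assuming any control behaviour. Using all wells
   instead would let plates with many controls shift the normalizer; the
   test-only convention is the default and the invariant "median of
   corrected test wells = 1" is tested.
2. **Relative activity** `F/R` per well. Wells with nonpositive or missing
   Renilla are excluded with a logged reason, never silently NaN — a
   dead-cell well must not enter averages with an undefined ratio.
3. **Replicate averaging**: mean over a gene's replicate wells within each
   experiment, then the mean of experiment means. This weights experiments,
   not wells, so an experiment with a lost well is not down-weighted;
   genes observed in only one experiment are flagged rather than dropped.
4. **Dual-effect masking.** The per-gene aggregated Renilla activity is
   Z-scored the same way as the ratio; genes with a Renilla reduction
   Z ≥ 3 are masked. The threshold 3 is the conventional screening cut-off
   for "clearly off-null" behaviour and is fully configurable
   (`mask_cutoff`); the assay itself defines no numeric rule, only the
   principle that dual-channel genes leave the analysis.
5. **Robust Z-scoring.**
   `Z = (median(ref) − value) / (1.4826 × MAD(ref))`. Median/MAD rather
   than mean/SD because hit tails are heavy — candidate scores range up to
   ~16 while the null scale is a few percent — and the estimate must not be
   dragged by the very hits it is meant to flag. The sign convention makes
   *reduction* positive so trxG-like candidates and positive controls score
   high. If the MAD degenerates to zero (possible only in noiseless or
   constant data) the scale falls back to the sample SD with a warning;
   this is what lets a zero-noise simulation still separate planted effects
   exactly.
6. **Reference population.** The default null is all unmasked test genes
   (a ~400-gene library gives a stable empirical null; masked genes are
   excluded in a second pass so artifacts do not inflate the scale). A
   `reference = "neg_controls"` mode scores against the per-well ratios of
   the LacZ/GFP wells instead, for designs whose libraries are expected to
   be effect-rich.
7. **Cut-off derivation**: `floor(min(Z of trx-type positive controls))`.
   The floor of the published control scores 6.13 and 6.15 is 6, and the
   floor is conservative (it can only lower the bar relative to the
   controls, never raise it). The reporter-ablating `pos_fluc` control is
   deliberately not part of the cut-off: it measures assay dynamic range,
   not trxG biology. An explicit `cutoff` always overrides.
8. **Calling**: unmasked genes with Z at or above the cut-off, ranked by Z
   descending, ties broken by gene id so output order is total and
   reproducible.

## Secondary screen

Validation tests each retested gene's per-well relative activities against
the negative-control (LacZ) wells with a Welch unequal-variance t-test —
the safer default when "independent t-tests" is all the assay convention
specifies; a pooled-variance flag exists. The test is two-sided, but
validation additionally requires the candidate mean to be *below* the
control mean: a significant increase is not a validation. `alpha` defaults
to 0.05 and no multiple-testing correction is applied by default (the
shortlist is small and star annotations conventionally report raw p);
Benjamini–Hochberg is available via `adjust = "BH"`. Calibration is checked
by simulation: 2000 independent null genes (triplicate wells vs a 6-well
control, each with its own control draw) must be called significant at
0.05 in 3.5–6.5% of cases. Each null gene gets an independent control draw
because a single shared control sample correlates all the tests and the
realized rate then reflects that one draw rather than the test's size.

## ΔΔCT expression

`expression_report()` implements the classic Livak method with a fixed
amplification efficiency of 2 (the `efficiency` parameter exists but
standard-curve estimation is out of scope): per-replicate
ΔCT = Ct_target − Ct_reference within each sample, ΔΔCT of a test sample
against the *mean* control ΔCT (replicates are not paired across samples,
so pairing them would invent structure), fold change 2^−ΔΔCT, and a Welch
t-test of test vs control ΔCT replicates. Standard errors are propagated on
the log2 (cycle) scale, where the noise is additive. The control sample
reports exactly 1 by construction. The reference gene is a **required**
argument with no default: different experiments legitimately normalize to
different genes (e.g. Actin for embryos, with rp49 used as a negative
control gene elsewhere), and a silent default would be a trap. A plate
shift — adding a constant to every Ct of a sample — cancels through the
reference gene; this is tested.

## Peak annotation

`annotate_peaks()` assigns each peak its nearest gene by absolute signed
distance from the peak midpoint (floor of (start+end)/2) to the TSS, signed
in gene orientation (upstream negative; minus-strand genes flip). Category
bins are symmetric promoter windows with half-open upper edges — |d| ≤ 1 kb,
1–2 kb, 2–3 kb — then *Genic* if the midpoint lies in any gene body, else
*Distal Intergenic*; the five categories partition every peak set. Midpoint
anchoring (not summit) is used because summits are not guaranteed in input
BED. The genic check ignores exon/intron structure deliberately: the
analysis aggregates sub-genic categories anyway. Symmetric windows follow
the defaults of the standard annotators this mirrors; the exact windows of
any given published pie chart depend on upstream tool settings, which is
why genome-wide published counts are checked by oracle equivalence on
synthetic genomes rather than by re-deriving accession-dependent numbers.
Ties in |d| are broken by gene id ascending. `tss_matrix()` computes the
strand-oriented binned coverage matrix around TSSs (mean per-base summed
peak score per bin; rows sorted by total signal; off-chromosome windows
zero-padded and flagged), and `overlap_counts()` provides exact set algebra
for Venn-style co-occupancy counts. ChIP-qPCR enrichment is an IP/control
ratio on already-normalized signals with a default calling threshold of 2;
the formula is configurable because assay write-ups rarely state it.

## Phenotype scoring

Ordinal severity tables (extra-sex-comb classes `-` to `++++`, or the
two-class A5→A4 penetrance table) are converted to per-replicate
proportions and compared cross-vs-cross with per-category Welch t-tests on
replicate-level proportions — matching how such figures are analyzed —
rather than a chi-square on pooled counts, which ignores replicate
structure; the pooled chi-square is still reported as a secondary line. A
*suppression* call requires a severe category (`+++`/`++++`) significantly
lower; an *enhancement* call requires the `transformed` penetrance category
significantly higher. Zero-variance equal categories report t = 0, p = 1
rather than erroring.

## What the generators emulate — and what they do not

`simulate_screen()` reproduces the screen's statistical structure: 400
genes in triplicate on six 384-well plates, the whole experiment twice;
per-plate positive (trx-like, ash1-like, reporter dsRNA) and negative
(LacZ, GFP) controls; multiplicative log-normal plate factors (log-SD 0.2)
and well noise (CV 0.15); planted hits reducing only F by 70% and planted
"general" genes reducing both channels by 50%. Defaults that the assay
family does not fix are declared conventions chosen once: baselines
10 000/5 000 luminescence units for F/R, three wells per control role per
plate placed column-major at the head of each plate, genes in consecutive
triplicate blocks split evenly across plates, reporter-control reduction
95%, and sub-seeds derived as master seed + fixed offset per artifact so
any fixture regenerates independently. Ct noise is additive Gaussian in
cycles; phenotype counts are exact multinomials; genome fixtures place
genes on a regular 20-kb grid with 5-kb bodies and plant peaks at known
TSS offsets.

What they do *not* emulate: spatial/edge plate effects, dispensing
drift, dose–response, cross-well contamination, PCR efficiency differences
between amplicons, irregular gene density, overlapping genes, or read-level
sequencing noise. Passing recovery tests therefore demonstrates that the
analysis inverts its own generative assumptions exactly and robustly at
realistic noise — not that real screens are free of the artifacts above
(edge-effect correction is a logged possible extension).

## Numerical choices and problem sizes

All statistics are double precision; no iterative optimization is involved.
Determinism contracts (fixed seed ⇒ bit-identical outputs, identical
pipeline digests) are tested. The test suite runs the screen at its native
scale (400 genes, 2 580 wells), oracle equivalence at ≥ 100 random
instances per primitive, the null calibration at 2 000 simulated genes, and
multinomial moment checks at 10 000 replicates — sizes chosen so the whole
suite completes in well under a minute while estimates are tight.
`run_pipeline()` on the default configuration runs all six stages in a few
seconds.

## Known limitations

* The masking threshold (Renilla Z ≥ 3) and the Z reference population are
  conventions, not assay-derived facts; both are configurable and both
  choices are visible in the run manifest.
* Ratio noise is assumed symmetric enough on the raw scale for median/MAD
  scoring; extremely skewed wells are handled only through robustness, not
  modeling.
* Annotation is midpoint-based and exon-blind; peaks spanning multiple
  TSSs are assigned to the single nearest gene.
* Only penetrance (not expressivity) of the A5→A4 transformation is
  modeled, as expressivity lacks a categorical scale here.
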