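---
title: "riboseek: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboseek: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboseek)
```

This vignette is the package's own account of what each stage
computes, which assumptions it makes, which parameters matter, and
where the design was genuinely open.  Everything numerical shown here
is computed by the package at build time; the test suite and
`scripts/acceptance.R` recompute the same quantities independently.

## 1. The tissue-specificity screen

A gene is called specific to a target tissue when its expression
there exceeds every other sample by a fold threshold.  With
replicated target samples the phrase "k-fold above any other sample"
admits several readings; `compute_specificity()` uses the strictest:

$$\frac{\min_{s \in \text{target}} x_{gs}}{\max_{s \notin \text{target}} x_{gs}} \ge k,$$

so a single noisy replicate on either side can veto a call.  The
alternatives (mean or max over target replicates) are strictly more
permissive; the minimum was chosen because a specificity claim that
survives its own worst replicate is the one worth following up, and
replicate counts in multi-organ panels are too small (often 2) for a
mean to add robustness.

Two guards handle degenerate input:

* an **expression floor** (`floor = 0.5` FPKM on the target minimum)
  prevents near-silent genes from passing on ratios between noise
  values, and deliberately also blocks the `0/0` case;
* a **zero denominator** with the floor met is a pass — expression in
  the target tissue and literally none anywhere else is the strongest
  possible specificity, not an error.

The fold boundary is inclusive (`ratio >= fold`).  Downstream,
candidates flow through annotation and ortholog filters into a
cross-species re-screen of the ortholog partners (same fold and
floor); a multi-mapped candidate is validated if *any* partner
validates, because one conserved specific ortholog is sufficient
evidence of conserved regulation.  `build_funnel_report()` enforces
the telescoping invariant (`n_out = n_in - n_excluded`, stages chain
exactly) so a report cannot silently drop or double-count genes.

## 2. Ribosome association from polysome fractions

Polysome profiling separates lysate on a sucrose gradient into
ribosome-free, 40S, 60S, monosome and polysome fractions; RNA
recovered from polysome fractions was ribosome-associated in the
cell.  `classify_polysome_association()` reduces this to a detection
question: a transcript is `associated` when its polysome-fraction
level reaches the detection threshold (default 1 FPKM), `free` when
only the free fraction does, `undetected` otherwise.  The association
strength `log2((poly + c) / (free + c))` uses a pseudocount
`c = 0.5` FPKM so that zeros stay finite.

"Strongest association" is ranked by polysome-fraction level rather
than by the strength ratio — fraction-wise expression is what the
underlying experiment displays — but both orderings are reported
(`rank_by_strength`) since a low-expressed transcript can have a
higher ratio than a high-expressed one.

Fraction profiles are compared with total-variation distance,
$\tfrac12\sum_i |a_i - b_i|/100 \in [0, 1]$: a proper metric, directly
interpretable as the fraction of probability mass that would have to
move to turn one gradient distribution into the other.

## 3. Nuclear/cytoplasmic localization

Two independent assays are supported.

**smFISH spot counts.**  Per-cell cytoplasmic percentage
`100 * cyto / (nuc + cyto)` over cells with at least one spot,
aggregated by the **median**.  Whether published "percent
cytoplasmic" figures are per-cell medians or pooled-spot proportions
is usually unstated; the median was chosen as the headline because it
is robust to segmentation outliers (a single mis-segmented cell with
hundreds of spurious spots barely moves it), and the pooled estimate
is reported alongside.  Zero-spot cells are excluded from the
statistic but counted in QC; fewer than `min_cells = 100` informative
cells raises a `low_n` flag, following the common practice of scoring
at least 100 cells.

**Fractionation qPCR.**  Relative target abundance between the
cytosolic and nuclear fractions via ΔΔCt
(`fold = E^(ΔCt_nuc - ΔCt_cyto)`, efficiency default 2.0, i.e.
perfect doubling), converted to `percent_cyto = 100 r / (1 + r)`.
This assumes the reference transcript normalizes recovery between
fractions.  Fractionation quality is checked with transcripts of
known localization: a nuclear control (a Neat1-like transcript)
computing > 50% cytoplasmic, or a cytosolic control < 50%, fails QC —
if the controls are not in their expected fractions, the target's
number is meaningless.

Both methods satisfy the swap symmetry: exchanging the nuclear and
cytoplasmic inputs maps `p` to `100 - p`.

## 4. Conserved promoter windows and motif scanning

Conservation detection is deliberately self-contained: an **ungapped,
TSS-anchored sliding window** (default 50 nt) compares the two
promoters at identical TSS-relative offsets and reports maximal
merged runs with identity at or above 70%.  Random sequence averages
25% identity, so 70% over 50 nt is a ~10⁻¹⁰ event by chance, and
the planted-block recovery tests show the detector returns exactly
the planted regions.  This replaces browser-derived conservation
tracks (PhyloP) with something computable from two FASTA records; the
trade-off is that indels between species shift the frame and can
break a genuinely conserved block — acceptable near the TSS, where
alignments are typically colinear, and documented as a limitation.
The promoter window default is [TSS−2000, TSS+200), 0-based
half-open.

PWMs are position probability matrices with additive pseudocounts.
Scanning scores each window in log2-odds bits against the background;
the **p-value null is exact**: per-position score contributions are
discretized to 0.01-bit bins and convolved under the background by
dynamic programming, so `score_pvalue()` is the true tail probability
of the discretized score of a random window (discretization error is
bounded by width × bin).  The test suite verifies the DP against
brute-force enumeration of all 4^w windows for widths up to 6.  The
default report threshold is `p <= 1e-4`, the usual motif-occurrence
convention; note a width-w motif cannot beat `4^-w`, so motifs
shorter than 8 nt cannot clear 1e-4 at all — the shipped example
matrices are 10 and 8 nt wide for this reason.  Reverse-strand hits
are scored with the reverse-complement matrix on the forward
sequence and reported in forward coordinates; palindromic motifs
legitimately appear on both strands and are not deduplicated.

A **conserved site pair** requires same-named hits in both species,
both inside the same conserved window, with TSS-relative intervals
overlapping by at least 1 nt — the operational meaning of
"overlapping and conserved binding site" under an ungapped positional
alignment.

## 5. Translatome dynamics and stall sites

Time courses are replicate-mean profiles on a shared grid (hours
internally; labels like "2 d"/"2 w" map to 48/336 h).  The peak is
the argmax of replicate means with ties broken toward the *earliest*
tied timepoint — when two timepoints are indistinguishable, the
biologically conservative statement is that the response had already
peaked by the earlier one.  `translational_shift()` reports the lag
(ribosome-series peak minus RNA-series peak); a positive lag —
e.g. +288 h when transcript abundance peaks at 2 days but ribosome
association at 2 weeks — is the signature of regulation acting on
translation rather than transcript supply.

Stall-site detection uses a robust z-score per position:
`z = (count - median(win)) / max(1.4826 * MAD(win), 1)` over a ±25 nt
window.  The 1.4826 constant makes the MAD a consistent estimator of
the standard deviation, so `z = 5` means five (robust) standard
deviations above the local context; the MAD floor of 1 count keeps
flat windows finite and makes perfectly flat tracks return zero
calls.  Calls within 3 nt merge to the maximal-z position, since a
pile-up spread over adjacent footprint 5' ends is one event.  The
caller also reports a start-proximal ratio (mean coverage over the
first 50 codons after the start codon vs the remainder), which
quantifies initiation-region enrichment separately from discrete
stall peaks.  The z-statistic is scale-invariant whenever the local
MAD is at least 1 count; on locally constant tracks (MAD = 0) the
floor breaks exact invariance — a documented degenerate case.

## 6. Stalling-motif enrichment

Motif occurrences are counted at **every offset**, so overlapping
matches count (`PPP` twice in `APPPPK`); this maximizes sensitivity
for run-type motifs whose biological signal scales with run length.
`X` never matches.  Two complementary contrasts compare a protein
group against the rest:

* the distribution of `categories_present` (0..K motif categories per
  protein), compared with a chi-square test on the 2×(K+1) table
  (no continuity correction; the 2×2 example [[10,0],[0,10]] gives
  statistic 20).  When any expected cell is below 5, the p-value
  comes from Monte-Carlo resampling of tables with both margins
  fixed, which the tests validate against exhaustive hypergeometric
  enumeration;
* per-protein total counts, compared with the package's Mann-Whitney
  U: exact enumeration for tie-free `n + m <= 12`, otherwise the
  tie-corrected normal approximation with continuity correction.
  The exact path is validated against the Wilcoxon distribution
  (`pwilcox`) and both paths against `wilcox.test`.  The two-sided p
  is the default headline value; the one-sided ("group carries more
  motifs") p is what the power analyses use.

The catalogue of stalling-motif categories is a **required user
input**: which motifs stall ribosomes is an empirical, evolving list,
and no canonical set ships with the package.
`example_stalling_motifs()` (and
`inst/extdata/example_stalling_motifs.yaml`) provide a clearly
labeled synthetic four-category example — poly-proline,
proline–glycine, poly-basic, poly-acidic — for tests and demos only.

## 7. What the synthetic data emulates — and what it does not

Every generator is a pure function of its arguments; the seed is
expanded into per-generator substreams so modules regenerate
independently.  Defaults are the package's study conditions:

| generator | emulates | key defaults |
|---|---|---|
| `generate_expression()` | multi-organ FPKM panels, two species | 7 tissues × 2 replicates; planted fold 10; noise SD 0.3 on log2 |
| `generate_funnel_fixture()` | the canonical screening funnel | 96 planted; 70/18/3 dropout; planted fold 50 |
| `generate_polysome()` | 5-candidate polysome screen | polysome means 8/3/2/1.5/0 FPKM |
| `generate_fish()` | smFISH spot counts | 100 cells, 50 spots/cell, 60% cytoplasmic |
| `generate_promoters()` | TSS-anchored promoter pair | 2200 nt; two 80-nt conserved blocks near the TSS; 2% mismatch |
| `generate_dynamics_and_coverage()` | disease-model time course + footprints | RNA peak 48 h, ribo peak 336 h; Poisson(20) coverage, fold-10 stall |
| `generate_proteome()` | labeled proteome | 200/group, length 300; planted motif rates 6 vs 3 |

Noise choices: expression replicates scatter lognormally with SD 0.3
on the log2 scale (±23%, typical of bulk RNA-seq replicates of the
same tissue); organ-to-organ means for planted genes spread with
natural-log SD 1, so organs differ several-fold as real organs do.
Planted genes put their target-tissue mean at `fold` × the maximum
other-tissue mean, which is exactly the quantity the screen
thresholds.  The funnel fixture plants at fold 50 so that all 96
candidates survive the fold-5 screen with probability
indistinguishable from 1 and the funnel counts are exact by
construction; the parameter-recovery experiments plant at fold 10,
where the fold-5 screen operates at ~0.97 sensitivity and ~0
false-discovery proportion.  Planted promoter motif instances are
exempt from the conserved-block mismatch process (binding sites under
purifying selection); otherwise a 2% mismatch rate would destroy a
planted site in a noticeable fraction of runs and the emitted truth
table would be wrong.  Time-course peak means exceed the runner-up by
5/3 so replicate noise cannot move the argmax.

What passing tests on these conditions do **not** show: the
generators have no length or GC biases, no codon-level structure, no
batch effects, no correlated replicates, no indels between species,
and binomial (not overdispersed) FISH spot splitting.  Results on
real data depend on upstream processing (alignment, FPKM
computation, P-site offsetting) that is explicitly out of scope.

## 8. Numerical choices and degenerate inputs

* PWM score bin 0.01 bits; p-value queries round the score to the
  same grid, so DP and enumeration agree to 1e-6.
* All-zero fraction vectors, zero library sizes, empty groups,
  all-tied Mann-Whitney samples, motif-free proteomes, and tracks
  shorter than the stall window raise errors or flags rather than
  returning numbers; degenerate statistics (`U` with zero variance)
  report p = 1 with a `degenerate` flag.
* Problem sizes in the validation suite — 300-gene screens × 20
  replicates, 1 kb scan oracles, 50 power simulations and 200 null
  replicates at 100–200 proteins per group — were chosen to estimate
  each property with comfortable Monte-Carlo margin (e.g. the null
  Kolmogorov–Smirnov distance estimates at ~0.06–0.09 against a 0.1
  bound backed by ~1/sqrt(200) resolution).

## 9. Known limitations

* The conservation detector is positional and ungapped; indels
  between promoters break it (use a real aligner upstream if that
  matters).
* The polysome classifier is threshold-based; it does not model
  gradient physics or absorbance traces.
* The stall caller reports local pile-ups; it does not P-site-offset
  reads or test codon periodicity, and a hard edge in coverage (e.g.
  the boundary of an elevated initiation region) can produce boundary
  calls.
* Chi-square Monte-Carlo p-values have resolution 1/(B+1)
  (B = 10000 by default).
* The example PWMs and stalling-motif set are synthetic stand-ins;
  swap in curated matrices/catalogues for real analyses.
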