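---
title: "Screening and evaluating methylation markers of pCR: methods"
author: "methmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and evaluating methylation markers of pCR: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmarker)
```

## The problem

Some HER2-positive breast cancers disappear completely under neoadjuvant
HER2-directed therapy (trastuzumab plus chemotherapy): at surgery no
invasive or intraductal tumor cells remain. This *pathological complete
response* (pCR) predicts excellent survival, and patients who could be
identified as future pCR cases *before* surgery might eventually be spared
the operation. methmarker implements the computational side of a
multi-omics marker hunt for this setting: somatic-mutation and copy-number
screens from targeted panel sequencing, a differential-expression screen
from microarrays, a DNA-methylation marker screen from Infinium-450K-style
beta values, combined-marker performance evaluation, and on-treatment
response monitoring. Cohorts are organized as fixed, disjoint screening,
validation and re-validation sets assigned in the sample sheet; discovery
statistics only ever see the screening set.

## The methylation screen

The core procedure treats every CpG probe as a one-dimensional threshold
classifier of outcome:

1. **Universe.** Keep probes with beta < 0.2 in *every* normal reference
   profile (a mammary epithelial profile and two leukocyte profiles in the
   emulated design). Tumor hypermethylation is only interpretable where
   normal tissue is unmethylated; leukocyte profiles also guard against
   immune-cell contamination of biopsies.
2. **Per-site classifier.** A sample is called methylated at a probe when
   beta > 0.3. For direction "hyper in pCR" the call predicts pCR;
   accuracy is the fraction of correctly classified samples and
   specificity the fraction of the negative class (non-pCR) called
   unmethylated. Both directions are evaluated; a site passes when
   accuracy > 0.67 and specificity > 0.85 in at least one. If both pass
   (possible only in degenerate small-n situations) the higher-accuracy
   direction is kept, ties breaking toward hyper-in-pCR.
3. **Annotation filter.** Keep sites in CpG islands or genic regions,
   where methylation has a defensible regulatory interpretation.
4. **Region aggregation.** Within each annotated region, order the
   region's probes by genomic position and emit a candidate marker for
   every maximal run of at least 3 passing probes that are adjacent in
   that ordering and agree in direction. Adjacency is relative to the
   region's own probe list, not the whole-array order: a non-passing probe
   of the same region breaks a run (configurable via `max_gap`), and a
   direction flip always breaks a run. Requiring consecutive probes
   suppresses single-probe artifacts, which dominate any array-scale
   screen at these gates.

A candidate region's *marker level* in any sample is the mean beta of its
member probes; `predict()` on the screen object computes levels or
dichotomized calls for new cohorts. Validation and re-validation compare
marker levels between outcome groups with the two-sided Mann–Whitney test
at alpha 0.05.

```{r screen}
bundle <- simulate_cohort(simulation_config(seed = 1))
screen <- screen_methylation_markers(
  bundle$beta, bundle$annotation, bundle$reference,
  setNames(bundle$samples$pcr, bundle$samples$sample_id))
screen
```

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `beta_max` | 0.2 | universe gate: max reference beta (strict <) |
| `beta_cut` | 0.3 | per-sample methylation call (strict >) |
| `acc_threshold` | 0.67 | per-site accuracy gate (strict >) |
| `spec_threshold` | 0.85 | per-site specificity gate (strict >) |
| `min_consecutive` | 3 | probes per candidate region |
| `max_gap` | 0 | non-passing probes tolerated inside a run |

All comparisons honor the strict/inclusive boundaries exactly as stated;
unit tests pin each boundary (a beta value exactly 0.3 is unmethylated, a
reference beta exactly 0.2 leaves the universe, a site with accuracy
exactly 0.67 fails).

## The genomic and transcriptomic screens

**Variant filter.** A variant is kept as a functional somatic mutation iff
tumor VAF > 10%, matched-normal VAF < 1%, homopolymer context < 3, at
least 5 alternate reads on each strand, coverage > 100 reads, and a
protein-altering or splice consequence. "Found in both strands in 5 reads
or more" is read as >= 5 per strand (the standard strand-support reading);
a total-with-representation alternative (>= 5 overall, >= 1 per strand) is
selectable via `strand_rule` because the phrasing admits both. The filter
is a pure monotone predicate: weakening any evidence field can never turn
a rejected variant into an accepted one, and a property test checks this.

**Copy number.** Region depths are normalized to depth fractions
(depth / total reads per sample); the fold change is the tumor:normal
ratio of fractions, with gain > 2 and loss < 0.5. Zero normal depth with
tumor signal is an infinite-fold gain; zero in both is neutral with
undefined fold change. No segmentation is attempted — inputs are
pre-summarized panel regions.

**Expression.** Raw intensities are log2-transformed and each sample is
shifted so its 75th percentile (linear-interpolation quantile, R type 7)
is exactly 0 — the convention under which "average intensity > 0.5" is a
meaningful abundance gate. The volcano screen selects genes with
p < 0.001 and linear fold change > 4, with the fold change computed as the
difference of group means on the log2 scale, exponentiated. The
two-sample test is Welch's t by default; the microarray suite that
produced the published gene lists does not document its test, so
Mann–Whitney is selectable and published lists may differ by test choice.
No multiple-testing correction is applied: the raw-p gate *is* the screen,
and the validation cohorts are the error control.

## Marker performance and response monitoring

`evaluate_marker()` fixes the orientation once for the whole package:
positive class = pCR, marker-positive = predicted pCR, so sensitivity is
tp/(tp+fn) over pCR samples and specificity tn/(tn+fp) over non-pCR
samples. Any metric with a zero denominator is undefined (`NA`), never
0-divided. `stratified_report()` evaluates methylation, ER-negative
status and their AND combination overall and in age strata <45, 45–55
(inclusive both ends) and >55, which partition all ages. Exact fractions
are kept internally; rendered percentages round half-up to one decimal
(base `round()` is round-half-even and would print 40/128 as 31.2%).

The dichotomization cutoff for continuous methylation levels deliberately
has **no default**: the clinically calibrated cutoff is assay-specific and
absent from the modeled study's main text. The example config ships 0.15
as an explicitly non-canonical placeholder.

`her2_reference_cohort()` reconstructs a 128-patient cohort from published
per-stratum marker-by-outcome counts. The published table gives only the
margins of methylation, ER and the combined marker; because the combined
marker is the AND of the other two, the joint (methylation x ER) cell
counts are determined up to one free cell, and the deterministic
assignment used (combined-positive patients are methylation-high and
ER-negative; the remaining margins fill in) is consistent in every
stratum-by-outcome cell and reproduces every published rate exactly. The
rows are synthetic reconstructions, not original patient records.

**Response monitoring.** For paired baseline/on-treatment biopsies the
change in marker level is reported under two conventions, because a
published "delta-beta >= 50%" gate is ambiguous: absolute percentage
points of the methylation fraction (default — beta is already a fraction,
so a >= 50-point drop is the natural reading) and decrease relative to
baseline. Both are carried in the output; classification uses the
configured one with an inclusive >= threshold. The Wilcoxon signed-rank
test (zero differences dropped, warning and p = 1 if all are zero)
quantifies the on-treatment change, and `compare_response_markers()`
contrasts the outcome-selectivity of the methylation marker's decrease
with comparators such as the Ki-67 index, which decrease in most samples
regardless of outcome.

## The synthetic cohort generator

`simulate_cohort()` emulates the data structures above at desk scale with
one master seed; every sub-generator derives its own seed from
(seed, cohort set, stage label), so the three cohort sets are disjoint,
independently reproducible draws.

* **Beta values** come from two beta distributions with concentration 20:
  background mean 0.05 (so reference profiles fall below the 0.2 universe
  gate with probability ~0.99 per probe) and methylated mean 0.6 (above
  the 0.3 call threshold with probability 0.997). The two modes straddle
  the 0.2/0.3 thresholds, which is all the screen's logic depends on; no
  distributional model is published. Draws are inherently in (0,1); the
  paired on-treatment levels add Gaussian noise and are clipped to [0,1],
  a simplification that cannot bias threshold logic.
* **The planted marker** is a run of 4 consecutive probes in one CpG-island
  region. A sample is methylated there with probability 0.8 (pCR) or 0.02
  (non-pCR), and the methylated state is shared by the run's probes, as
  it would be for a contiguous DMR. The non-pCR penetrance is calibrated
  to the screen's specificity gate: with 20 non-pCR screening samples,
  specificity > 0.85 tolerates at most 2 methylated non-pCR samples, an
  event of probability `pbinom(2, 20, p)` — 0.993 at p = 0.02 but only
  0.68 at p = 0.1. A cohort-wide methylation-high rate of ~12% in
  non-responders, as published for the full 128-patient cohort, is
  therefore *not* survivable by this screen design at n = 20 in most
  replicates; users can raise `penetrance_nonpcr` to explore exactly that
  regime.
* **ER status** is drawn with P(ER-negative) = 0.8 in pCR and 0.35 in
  non-pCR samples, matching the published margins (81.4% / 35.3%).
* **Expression** is log-normal with 10 planted genes at log2 fold change
  2.5 (fold 5.7, comfortably past the volcano's fold-4 gate at noise sd
  0.3) and elevated abundance so they clear the intensity gate.
* **Variants** are the fixed 14-record boundary table: one record failing
  each of the six rules at its boundary value, one failing each clearly,
  one all-pass and one all-fail. Exactly one record survives the filter.
* **Copy number** plants two fold-3 gains and two fold-0.3 losses among 50
  neutral regions.
* **Paired levels** decay by 80% of baseline in pCR samples and stay flat
  (Gaussian noise, sd 0.02) otherwise; the Ki-67-like comparator decays
  in every sample.

What the generator does *not* emulate: Infinium type-I/type-II probe
chemistry, batch effects, probe cross-reactivity, missing beta values
(disallowed by the IO contract in this version), tumor purity gradients,
and correlated background methylation. Passing tests on synthetic data
therefore demonstrate the correctness of the screening *logic* under the
assumed signal structure, not the power of the design on real arrays; the
published array-scale funnel counts (hundreds of thousands of universe
sites narrowing to a handful of regions) require the original arrays,
which were never deposited, and are not reproduced here.

## Problem sizes and numerical choices

The default simulated screen uses 10,000 probes x 34 samples (14 pCR / 20
non-pCR), 2,000 genes, and 47/55-sample validation sets — sizes chosen so
a full multi-replicate screen runs in seconds while every pipeline branch
is exercised. The statistical tests delegate to R's `fisher.test` and
`wilcox.test` (exact distributions where sizes and ties permit,
tie-corrected normal approximation otherwise); the test suite checks them
against independent exhaustive enumerations — all group assignments for
Mann–Whitney, all 2^n sign assignments for the signed-rank test, and the
hypergeometric tail sum for Fisher's exact test — across hundreds of random
small instances. Quantiles are R type 7 (linear interpolation), pinned by
a worked example. Percentile normalization is idempotent by construction:
an input that already satisfies the 75th-percentile-zero convention is
returned unchanged.

## Known limitations

* The dichotomization cutoff and the real arrays behind the published
  funnel are unavailable; related quantities are exercised on synthetic or
  reconstructed data only.
* "Consecutive probes" is interpreted within the annotated region's own
  probe ordering; a genome-wide sliding interpretation would need the full
  manifest and is not implemented.
* Missing beta values are a validation error rather than being imputed;
  relaxing this is future work.
* The VCF dialect for variant input is not implemented; the TSV contract
  covers the fields the six rules test.
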