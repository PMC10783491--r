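---
title: "Methods: scoring difficulty-to-sequence at single-base resolution"
author: "unmetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring difficulty-to-sequence at single-base resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unmetr)
```

## The problem and the model

Short-read resequencing calls variants by mapping reads onto a reference
genome. In repetitive, low-complexity or otherwise awkward sequence the
mapping itself — not the base calling — becomes the dominant error source,
and whole neighbourhoods of calls fail a caller's quality filters. A large
population variant catalog with per-variant PASS/filtered flags therefore
carries an empirical record of *where* short-read calling breaks down.
`unmetr` turns that record into a per-nucleotide difficulty score for
protein-coding positions.

The procedure has four stages.

**1. Windowed filter statistics define ground truth.** For a focal position
and flank $N$ (default 12, i.e. a $2N+1 = 25$-bp window), two statistics are
computed over the variant records whose positions fall in the closed window:

$$\mathrm{VD} = \frac{\#\text{variants in window}}{2N+1}, \qquad
  \mathrm{VFR} = \frac{\#\text{filtered variants in window}}{\#\text{variants in window}},$$

with VFR undefined on variant-free windows. A window of 25 bp holding 8
variants, 2 filtered, has VD $= 8/25 = 0.32$ and VFR $= 2/8 = 0.25$.
An SNV site inside the CDS is labeled **unreliable** (positive) when its
window has VFR $= 1.0$ and VD $\ge 0.12$ — with a 25-bp window the density
floor demands at least three observed variants, so a lone filtered variant
never creates a positive — and **reliable** (negative) when VFR $= 0.0$ and
VD $\ge 0.12$. Everything in between stays unlabeled; the extremes are
deliberately stringent so the training classes are clean.

**2. Ten per-base features.** Each candidate position is described by:
standardized coverage depth (absolute per-chromosome z-value),
$(K,E)$-mappability, homopolymer mask, tandem-repeat mask,
interspersed-repeat mask, segmental-duplication mask, low-complexity mask,
structural-variant mask, windowed GC content, and windowed Shannon entropy.
Sequence-derived features come from the genome alone; the three
database-style masks are supplied as BED interval sets; coverage is an
external track.

**3. A boosted-tree classifier.** Negatives are down-sampled to the
positive count, the balanced set is split 8:2, and an XGBoost model is
fitted with a grid search over `max_depth` {3,4,5,6}, `learning_rate`
{0.1, 0.01, 0.001}, `gamma` {0, 0.1, 0.01}, `subsample` {0.5, 0.8, 1} and
`colsample_bytree` {0.5, 0.8, 1}, selected by 5-fold cross-validated
accuracy at the 0.5 threshold. Held-out performance is reported as AUC
(midrank statistic) and the Matthews correlation coefficient
$$\mathrm{MCC} = \frac{CPU \cdot CPR - PU \cdot PR}
 {\sqrt{(CPU+PU)(CPU+PR)(CPR+PU)(CPR+PR)}},$$
where the four counts are correctly-predicted-unreliable,
correctly-predicted-reliable, and the two corresponding error cells. An
optional leakage check re-evaluates the test set after removing sites whose
centered 25-mer matches a training-site 25-mer at $\ge 80\%$ of positions
(20 of 25; ungapped, either strand).

**4. Percentile normalization and banding.** The model scores every CDS
position with defined features; raw scores become percentile ranks,
$\mathrm{score}(p) = \#\{q : \mathrm{raw}(q) \le \mathrm{raw}(p)\}/n$, so
the score is uniform on $(0,1]$ up to ties and the $\ge 0.97$ band is
literally the top 3% when scores are distinct. Bands are *reliable*
($< 0.93$), *error-prone* ($[0.93, 0.97)$) and *difficult* ($\ge 0.97$);
runs of at least 50 consecutive scored bases at $\ge 0.97$ are exported as
difficult regions.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| flank $N$ | 12 | bp | window $2N+1 = 25$ bp for VD/VFR, GC, entropy |
| `vd_min` | 0.12 | — | density floor for labels ($\ge 3$ variants / 25 bp) |
| mappability $K$, $E$ | 100, 2 | bp, mismatches | word length and error budget |
| homopolymer run | 7 | bp | minimum tract length |
| mask flank | 12 | bp | extension of homopolymer/tandem masks |
| DUST level | 30 | — | low-complexity stringency |
| tandem period / array | ≤ 25 / ≥ 12 | bp | built-in detector caps |
| similarity threshold | 0.80 | — | leakage filter (20/25 positions) |
| band thresholds | 0.93, 0.97 | percentile | error-prone / difficult cutpoints |
| difficult-region length | 50 | nt | minimum exported run |

## Definitional and numerical choices

Several points are genuinely open in the underlying procedure; the package
fixes each one explicitly.

* **One coordinate convention.** Everything internal is 0-based half-open;
  VCF positions are shifted exactly once at the reader boundary, BED and
  bedGraph pass through unshifted. `FILTER` values `PASS` and `.` map to
  *passed*; any other value maps to *filtered*.
* **Per-allele counting.** Multi-allelic VCF records are split per
  alternate allele and VD counts records, so a biallelic position
  contributes 2. Labels, in contrast, attach to positions: all alleles at
  one position share one window, hence one label.
* **The focal variant counts in its own window.** This makes the criteria
  self-consistent: VFR $= 1.0$ implies the focal variant itself is
  filtered, VFR $= 0.0$ that it passed.
* **Window truncation.** Windows overhanging a chromosome end are truncated
  for counting but VD keeps the fixed denominator $2N+1$.
* **Centered windows.** GC, entropy and the leakage 25-mers are centered on
  the scored position ($\pm N$), the same convention as the VD/VFR window;
  a trailing-window convention would be equally defensible but mixing
  conventions invites off-by-one drift.
* **Mappability semantics.** The value at $p$ is $1/\mathrm{occ}(p)$ where
  $\mathrm{occ}$ counts length-$K$ windows on either strand of the whole
  genome within Hamming distance $E$; `N` mismatches everything (including
  `N`). The implementation seeds candidate matches with $E+1$ exact chunks
  (pigeonhole principle) before full verification, which is exact, and is
  cross-checked in the tests against an all-pairs oracle at small $K$.
* **Low-complexity score.** Within sliding 64-bp windows the symmetric
  DUST score $\sum_t c_t(c_t-1)/2$ over triplet counts is normalized by
  $(k-1)$ for $k$ triplets and a window is masked when the score exceeds
  level/10. At level 30 this masks homopolymeric and short-motif sequence
  while leaving random 50%-GC sequence untouched; a per-window-length
  normalization was rejected because it would mask random sequence (its
  expected normalized score already sits above the threshold).
* **Built-in repeat detectors.** The tandem and low-complexity detectors
  are deliberately simple exact-arithmetic detectors (maximal exact tandem
  arrays with $\ge 2$ copies; triplet-count DUST) with an override path for
  interval sets produced by external tools, since downstream only binary
  masks are consumed — interval fidelity, not repeat scores, is what
  matters.
* **Ties and degenerate cases.** AUC uses midranks (constant scores give
  0.5); MCC returns 0 with a warning when a denominator factor vanishes;
  percentile ties share their highest member's value so the maximum is
  exactly 1.0; the error-prone band is half-open so the three bands
  partition; "longer than 50 nt" is implemented as run length $\ge 50$ and
  exposed as an argument; grid-search ties resolve to the first grid point
  in a fixed enumeration order.
* **Dropped, not imputed.** Positions where any feature is undefined
  (within $N$ of a chromosome end, within $K-1$ of the 3' end, missing
  coverage) are dropped from the matrix and counted, never imputed.
* **Percentile scope.** Percentile ranks are computed globally over all
  scored CDS positions, not per chromosome.

## What the synthetic generator emulates

`simulate_unmet_data()` builds the complete input bundle from one seed:
random ~50%-GC background with planted exact segmental duplications
(mappability 0.5 by construction), exact tandem arrays, homopolymer runs,
GC-extreme windows and annotation-only structural-variant regions; a CDS
tiling of 300-bp exons / 200-bp gaps (60% coverage); a Poisson variant
catalog at 0.2 records/bp (so a 25-bp window typically holds ~5 records,
the density regime in which the labeling rule is meaningful) with 10%
short indels; and 30x Gaussian coverage halved inside planted regions.
Filter flags are drawn with probability `p_diff` = 0.95 inside planted
regions and `p_bg` = 0.02 outside — the standard bundle on which the
end-to-end tests demand held-out AUC $\ge$ 0.9 and higher median scores
inside plants than outside. Sub-seeds for the genome, CDS, variant and
coverage stages are derived from the one configuration seed by fixed
offsets, so each generator is individually reproducible and the whole
bundle is byte-identical under a fixed seed.

The generator is a caricature in useful ways and a caricature nonetheless:
duplications are exact copies rather than diverged paralogs, filter flags
are conditionally independent given region membership (real filters fail in
correlated bursts), coverage is Gaussian rather than overdispersed, there
is no allele-frequency structure, and GC-extreme windows are treated as
difficult even though in real exomes extreme-GC regions depress coverage
more than they corrupt calls. Passing tests on this bundle therefore
demonstrates that the machinery — labeling, features, training, ranking —
recovers a planted signal faithfully; it does not certify performance on
any real genome, where class boundaries are far noisier.

On the standard bundle the coverage z-value and the duplication/SV masks
carry most of the gain importance, because the generator couples depth
depression tightly to every planted region; in catalogs built from real
population data, mappability dominates instead. This difference is a
property of the synthetic signal, not of the method.

## Problem sizes

The test suite and the worked examples run entirely at desk scale, chosen
so the full suite completes in well under a minute of compute per stage:
the standard bundle is two 50-kb chromosomes (~20k variant records, ~9k
labeled sites, 60k scored positions), oracle-equivalence suites use 200
random instances per operation with genomes up to a few hundred bases for
the quadratic mappability oracle, and grid searches in tests use the
2-point reduced grid. The full 324-point grid is available via
`train_control(grid = "full")` and is the default of `unmet()` itself.

## Known limitations

* Labels derive from one catalog's filter flags; systematic filter biases
  propagate into the score. The score ranks positions within the scored
  set — it is a percentile, not a calibrated error probability.
* Coverage is consumed as a track, not computed from alignments; CRAM/BAM
  pileup is out of scope.
* Pseudo-autosomal special-casing for sex chromosomes is not implemented;
  on real data, supply PAR-aware inputs if that distinction matters.
* The built-in detectors are not drop-in replacements for TRF or
  DustMasker interval boundaries; use the override arguments when exact
  tool output is required.
* Logistic-regression and random-forest baselines are not bundled; the
  boosted ensemble is the deliverable, and `univariate_analysis()` covers
  the per-feature comparison.
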