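---
title: "Detecting single-position polymorphisms on overlapping tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single-position polymorphisms on overlapping tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement model

A 2 bp overlapping tiling path places 25-mer probes at every other position
of each unigene, alternating strands, so that a typical interior base is
covered by twelve to thirteen probes. Hybridizing fragmented, end-labeled
genomic DNA makes both strands informative, and a single-base difference
between the hybridized genotype and the probe sequence weakens binding of
every covering probe — strongly when the mismatch falls among the sixteen
most central bases, weakly near the probe ends. `spptools` works entirely
from this signature. Because one target sequence polymorphism manifests as
a coordinated dip across overlapping features, calls are reported as
*single-position polymorphisms* (SPPs): contiguous 2 bp-grid ranges, rather
than single-feature (per-probe) events.

All coordinates in the package are 0-based and half-open; VCF input/output
converts to and from the 1-based convention at the boundary.

## Background, normalization and informative probes

Anti-genomic (AG) probes — sequences with no genomic target — estimate
nonspecific background per GC bin. Arrays are background-corrected with the
standard normal + exponential convolution model (limma's `normexp`; the
package also offers a pass-through `"none"` mode as a fully reproducible
path) and quantile-normalized across arrays with tied values receiving the
mean of their tied ranks. A probe is *informative* on an array iff its
intensity strictly exceeds the 90th percentile (type-7 interpolated
quantile) of the AG probes of its GC bin on that array. Bins with fewer
than 20 AG probes give no threshold and their probes are treated as
globally non-informative — a conservative rule for the sparsely covered
GC extremes. Only informative probes enter any downstream statistic.

## Deviation statistics

With `R(Y_i)` the mean of informative genomic probes in the same GC bin on
the same array,

$$\mathrm{SFPdev}_{ig} = \frac{Y_i - R(Y_i)}{Y_i},$$

and for every 2 bp window the position deviation is the weighted mean of
the covering probes' SFPdev, weights taken from a position profile at the
offset of the window midpoint from each probe center and renormalized to
sum to one per window, so windows with different coverage are comparable.
The profile defaults to a symmetric trapezoid (full weight for offsets
within ±8, decaying to 0.1 at ±12) and can be calibrated from training
SNPs with `estimate_weight_profile()` (below).

# The three callers

## Pair-wise ratio test (SFPdev caller)

For two genotypes with replicate arrays, each window's statistic is the
ratio of replicate-mean SPPdev, $R_s$. Its null distribution is estimated
per unigene by permuting the array columns and pooling the permuted ratios
across all windows of the unigene (the null is assumed exchangeable along
the unigene). Two numerical choices here are deliberate:

* **Extremity.** The two-sided p-value is twice the smaller pooled-ECDF
  tail at $R_s$ (`tails = "ecdf"`). The alternative reading — count
  permuted ratios beyond $R_s$ *or beyond its reciprocal*
  (`tails = "reflect"`) — presumes positive ratios; deviation ratios are
  negative whenever the reference genotype's window mean is positive, and
  the reciprocal rule then assigns such windows p ≈ 1 regardless of how
  extreme they are.
* **Identity exclusion.** Sampled permutations reject the observed
  grouping and its mirror (`exclude_identity = TRUE`). Pooling across
  windows means a single permutation that reproduces the observed grouping
  re-injects the observed extreme ratios into the null *at every window*
  of the unigene, inflating the p-values of exactly the true
  polymorphisms. Exhaustive enumeration (used by the oracle tests) keeps
  every permutation.

P-values are Benjamini–Hochberg adjusted within each unigene
(`fdr_scope = "unigene"`), matching the inference procedure's per-unigene
structure; chip-wide adjustment is available. Significant windows merge
into maximal ranges; ranges are kept when at least `min_width = 4` bp wide,
supported by `min_probes = 2` informative probes at their best-covered
window, and oriented with ratio < 1 (the direction in which the non-
reference genotype loses signal; the opposite orientation is empirically
false-positive-rich).

## Moderated positional D-statistic (MSA caller)

Per window, with replicate log weighted-mean intensities per genotype,

$$S_i = a\,(SS_A + SS_B), \qquad
  a = \frac{1/n_A + 1/n_B}{n_A + n_B - 2},$$

and the statistic is $D = (\bar x_A - \bar x_B)/(s_i + S_0)$ with $S_0$
the chip-wide median of the spreads. Three numerical decisions:

* **Spread scale.** By default $s_i = \sqrt{S_i}$ — exactly the pooled
  standard error, the scale on which the moderated-statistic literature
  operates and on which delta thresholds of 0.2–1.6 are meaningful. The
  literal product form ($s_i = S_i$, `spread = "ss"`) is retained; it
  carries units of variance and makes the statistic scale-dependent.
* **Denominator sign.** Subtracting the median ($s_i - S_0$) leaves half
  of all denominators non-positive; the default adds it
  (`denominator = "plus"`), the standard moderation; `"minus"` is guarded
  by a 10⁻⁸ floor.
* **Centering.** Quantile normalization transfers the variant genotype's
  lost signal mass to its non-variant probes, which shifts the D-stat null
  slightly off zero — amplified by the small moderated denominator.
  The delta rule is therefore applied to median-centered statistics,
  observed and permuted alike (`center = TRUE`).

Significance at a delta uses the permutation rank-deviation rule
(`delta_rule = "sam"`): observed order statistics are compared with their
permutation averages, and the outermost observed values whose deviation
reaches delta become the cutoffs; the FDR estimate at that delta is the
permutation-mean count of windows beyond the cutoffs over the observed
count. A literal `|D| >= delta` rule (`delta_rule = "dstat"`) is kept for
comparison but is scale-free under the null — roughly two thirds of null
windows exceed 0.2 at any noise level — so it cannot control error at the
conventional delta grid. Merging and range filtering match the SFPdev
caller.

## Diversity-panel genotyper

Each window's SPPdev values across all panel arrays are split at the
largest gap among cuts leaving at least `min_side = 2` arrays per side.
Arrays inside the central 20% (`ambiguity_band`) of the interval between
the two mode means are set missing. Since SFPdev = 1 − R/Y increases with
signal, the high-deviation mode is the high-signal allele A. The
between-mode separation is summarized on the implied-signal scale:
S ∝ 1/(1 − SPPdev) inverts the deviation definition exactly, so
`cluster_ratio` is the ratio of implied hybridization signals of the two
modes — well-defined where raw mode-mean ratios are not (mode means can be
negative or zero) — and must reach `min_ratio = 1.2`.

Replicate triples then summarize to marker codes (A iff A/A/A; B iff
B/B/B; C = B/B/−; D = A/A/−; "−" iff all missing; anything containing both
alleles, or two missings and a call, is inconsistent, I). Panel filters
default to zero missing, zero inconsistent, ≥ 2 probes, ≥ 4 bp and ratio
≥ 1.2. Adjacent windows with identical call patterns merge into ranges
before width filtering, bridging a single failed window (`max_gap = 2`):
adjacent windows share 11 of 12 probes, so isolated window failures are
artifacts of one noisy array value, not evidence of a marker boundary.
Haplotype collapse keeps one representative per distinct pattern per
unigene; C/D participate as their own symbols by default, or fold into
B/A with `permissive = TRUE` for allele-level analyses (the right choice
when comparing against allele-level truth). Marker levels
(`private` to a species, `interspecific_only`, `intraspecific`,
`monomorphic`) partition the markers, with single-member species treated
as monomorphic within.

## Weight-profile calibration

`estimate_weight_profile()` reverses the deviation model: for each probe
covering a training SNP, the oriented genotype difference
$d = (\mathrm{dev}_{hi} - \mathrm{dev}_{lo})/(1 - \mathrm{dev}_{hi})$
equals loss/(1 − loss) for a fractional signal loss, so loss = d/(1 + d)
recovers the per-offset mismatch sensitivity directly. Each SNP's
orientation is inferred from its central probes (a signed estimator has no
noise floor, unlike a mean of absolute differences), and a residual
reference-ratio bias is estimated from the same unigenes' non-covering
probes and removed. Offset means are symmetrized and normalized to a
maximum of one. Profiles built from fewer than 50 SNPs are flagged
low-confidence.

# The synthetic hybridization model

`simulate_panel()` draws log-normal intensities:

$$\ln Y_{pa} = \mu(\mathrm{gc}_p) + \alpha_p +
  \sum_v \ln(1 - \mathrm{loss}(o_{pv})) + \varepsilon_{pa}.$$

| parameter | default | meaning |
|---|---|---|
| `baseline_by_gc` | ln 500 + 0.04 (gc − 12.5) | mild GC slope around a median signal of ~500 units |
| `probe_effect_sd` | 0.8 (ln scale) | per-probe affinity, shared across arrays |
| `noise_sd` | 0.1 (ln scale) | replicate noise, ~10% CV (replicate correlation ≈ 97%) |
| `dim_fraction` | 0.05 | AG background ≈ 20× below genomic signal |
| `sensitivity_curve` | trapezoid: 0.5 for \|o\| ≤ 8 → 0.05 at \|o\| = 12 | fractional loss per mismatch offset |
| `replicate_count` | 3 | arrays per genotype |

The affinity spread matters: at small spreads the SFPdev window means
straddle zero and the ratio statistic degenerates into sign-flipping; at
0.8, ~97% of window means are negative — the regime the ratio < 1
orientation filter presupposes — and the simulator reproduces it. The
background level keeps probes carrying a 50%-loss mismatch above the AG
90th percentile most of the time, as on bright real bins. Variants are
biallelic and homozygous (inbred lines); the simulator does **not** model
heterozygosity, cross-hybridizing paralogs as sequences (duplicate-locus
behavior is tested with constructed duplicated references instead),
spatial artifacts, or amplification bias. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
signal model, not robustness to every failure mode of physical chips.

# Study sizes and operating characteristics

The test-suite and `scripts/acceptance.R` studies use: a two-genotype
comparison with 200 planted SNPs on 200 unigenes of 200 bp (matching the
chip's typical contiguous tiling stretch and an interspecific SNP density
of roughly one per few hundred bases), 3 + 3 replicate arrays, B = 300
ratio-test permutations and 100 label permutations; a matched null panel
of ~2,000 windows at B = 1,000; a 120-unigene calibration panel with 300
training SNPs; and a 12-genotype, 3-species diversity panel with 24
private and 6 intraspecific variants. All run in a few minutes on one CPU.

Two honest limitations, both measured by the acceptance suite rather than
hidden by it:

* The pair-wise ratio test is specific but insensitive: its pooled null
  inherits heavy tails from windows whose mean deviation is near zero
  (where permuted ratios are unstable), so moderate planted SNPs — those
  sitting on bright, high-affinity probes whose *relative* deviation is
  small — do not reach FDR 0.1. Roughly half of planted SNPs are
  recovered at that cutoff with observed FDR near 0.1.
* At delta 0.2 the D-statistic caller recovers essentially all planted
  SNPs, but its own permutation FDR estimate (and the observed FDR on a
  clean, fully covered truth set) is far above 0.2; the estimate falls
  monotonically along the delta grid and reaches well below 1% at 1.6.
  On real chips the observed FDR at liberal deltas comes out below the
  permuted estimate when validation excludes calls without sequence
  coverage and removes duplicated loci — deflators a clean synthetic panel
  does not have.

The diversity-panel genotyper recovers planted species structure almost
exactly; the residual few percent at zero replicate noise comes from a
real mechanism, not noise: per-array informative masking drops 50%-loss
probes on carrier arrays, and losing exactly the most deviant probes can
shrink a window's between-mode ratio below 1.2. This is the panel method's
characteristic higher false-negative rate.
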