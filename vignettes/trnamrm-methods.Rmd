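---
title: "Methods: scheduled-MRM quantification of tRNA modifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scheduled-MRM quantification of tRNA modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnamrm)
```

This vignette explains the statistical and numerical machinery in
`trnamrm`: what each stage assumes, why the defaults are what they are, and
what the synthetic-data generator does and does not emulate.

## The acquisition model

A scheduled MRM experiment on a triple quadrupole monitors, for each
analyte, a fixed parent→product m/z transition inside a retention-time
window. The registry (`default_registry()`) holds the 25 transitions used
for yeast cytoplasmic tRNA ribonucleosides: 23 quantified modification
analytes, ncm5Um (kept but flagged *tentative*, since its identification
rests on a correct molecular transition with weak signal rather than a
confirmed fragmentation match), and the [15N5]-2′-deoxyadenosine internal
standard. Five acquisition segments (1–4, 4–7, 7–10, 10–30, 30–40 min)
partition the run; with a 200 ms dwell per transition, the sampling cadence
of a trace is `0.2 s × (number of co-scheduled transitions)`.

The parent−product mass shift is a structural checksum: 132 u (ribose
loss) for ordinary ribonucleosides, 146 u for the 2′-O-methylated set
{Cm, Um, Gm, Am, ncm5Um}, 116 u (deoxyribose) for the internal standard,
and 120 u for pseudouridine, whose C–C glycosidic bond forces
quantification on a ribose ring fragment (m/z 125). `validate_registry()`
enforces these invariants and returns violations as data, so a custom
registry can be audited rather than rejected wholesale. m/z values are
stored and matched as integers — MRM on this instrument class is specified
at unit resolution, and fractional matching would invent precision the
method does not have. Ar(p), undetectable in positive-ion mode, is excluded
by default but can be supplied via a custom registry.

Segment boundaries are half-open `[start, end)` except the last segment,
closed at 40 min. This makes `segment_for()` total on boundary times — a
retention time of exactly 4 min belongs to the second window — at the cost
of an arbitrary but documented convention.

## Peak integration

Vendor software performs integration opaquely; here the contract is
explicit so results are reproducible and testable:

1. extraction window = expected RT ± `rt_tolerance` (default **0.5 min**:
   half the smallest retention-time gap between confusable isobaric
   neighbours, m5C at 3.3 min vs m3C at 4.4 min, both 258→126);
2. baseline = median of the outer 10% of the window; noise = SD of those
   edge points;
3. apex = window maximum; bounds extend from the apex to the first
   baseline crossing or valley;
4. area = trapezoidal integral of (intensity − baseline) between bounds,
   floored at 0;
5. a peak is `not_detected` when its apex rises less than 3× the noise
   estimate above baseline — the conventional S/N = 3 detection floor.

Isobaric transitions (the 258→126 pair, the parent-298 family) are never
deconvolved: they are resolved purely chromatographically, each searched
only within its own window, as in the underlying assay. Peaks whose bounds
hit the window edge while still well above baseline are flagged
`saturated_edge`; apexes more than half a tolerance from the expected RT
are flagged `rt_shifted`.

## Normalization

The normalized intensity is

```
intensity = analyte area / internal-standard area / tRNA mass (µg)
```

a dimensionless ratio per microgram of hydrolyzed tRNA. The
internal-standard ratio cancels injection-to-injection and
ionization-efficiency drift (any per-sample multiplicative factor common to
all traces divides out exactly); the mass term puts different tRNA inputs
on one footing. The denominator order is definitional — any strictly
monotone variant would preserve the fold-changes that downstream stages
consume, which is why the exact arithmetic is declared rather than treated
as a tunable. Undetected analytes propagate as 0 with their flag retained.
Blank subtraction (for analytes like i6A with a measurable no-matrix
background) is available but off by default, since a correction procedure
is a policy choice the analyst should make explicitly.

Intensity tiers (`summarize_intensities()`) default to decade cuts below
the strongest mean signal. Tier membership reflects abundance *times*
mass-spectrometric response; the boundaries are configuration, not
science.

## Calibration

`fit_calibration()` is unweighted OLS of area ratio on concentration, not
forced through zero; the zero-concentration standard is an ordinary level.
The default level series for m7G is 0, 5, 50, 300, 600, 1000, 2000 nM
against 40 nM internal standard. Weighted fits are exposed through the
`weights` argument; inverse prediction floors negative concentrations at 0
with a `below_curve` flag.

## Exposure-signature statistics

**Fold-changes and t-tests.** Per condition and analyte,
`FC = mean(treated)/mean(control)` with a two-sided, unpaired,
equal-variance Student's t-test — the classical pooled form, which is what
"Student's t-test" denotes and what an N = 3 design supports. A
summary-statistic entry point (`ttest_from_summary()`) exists because
replicate tables are published as mean ± SD with N. No multiple-testing
correction is applied by default (raw p < 0.05 / p < 0.1 are the
conventional reporting thresholds for these panels); `p.adjust` can be
applied downstream by the analyst. Cells undetected in the control give
`NA` with a flag (a ratio with a zero denominator is not data); cells
undetected only in the treated group carry the sentinel 0.00001 used by
ratio tables to mean "undetectable", and sentinel-bearing columns are
excluded from clustering and PCA rather than imputed.

**Clustering.** `hierarchical_cluster()` implements agglomerative centroid
linkage with the Pearson distance `d = 1 − r` on the log₂ fold-change
matrix after mean-centering. Cluster centroids are coordinate-wise means,
and all inter-cluster distances are recomputed against centroids after
every merge — the scheme of the classical gene-expression clustering
programs. This cannot be expressed as `stats::hclust()` on a static
distance matrix (hclust's centroid method is defined for squared-Euclidean
input), so the agglomeration is implemented directly; the test suite checks
it against an independently coded exhaustive oracle. Centroid linkage can
produce height inversions; they are preserved, not repaired. The *centered*
Pearson form is used, consistent with the explicit mean-centering step; the
uncentered variant exists in legacy tools but mixes offset and shape.

**PCA.** `pca_signature()` eigendecomposes the correlation matrix of the
*linear* fold-change variables (each variable mean-centered and scaled to
unit SD). The clustering input (log₂) and the PCA input (linear,
standardized) are deliberately different transforms, because the two
analyses are specified separately in the workflow this package implements.
Variance shares are eigenvalues as percentages of their total; with n
observations and p > n − 1 variables the trailing eigenvalues are zero, so
the retained `min(n − 1, p)` components still sum to 100%. Signs are fixed
by making the largest-magnitude loading of each component positive.
Observation contributions follow the squared-score convention standard in
PCA software, `100·s²ᵢₖ/Σⱼ s²ⱼₖ`; agent-level contributions are sums over
that agent's doses. The contribution convention is a declared choice — the
quantity is not uniquely defined by "contribution to variance" alone.

**Profile correlations.** Plain Pearson coefficients between row profiles
with pairwise-complete values; constant profiles yield flagged undefined
entries rather than silent zeros.

## Mutant-panel rules

`classify_ratios()` applies strict inequalities exactly as the ratio-table
legend states them — `< 0.02` undetectable, `< 0.6` decreased, `> 1.5`
increased — so boundary values fall to the milder label. Enzyme→product
links gate on per-cell t-test significance when flags are provided and
degrade to ungated with a warning otherwise (whether published "abolished"
calls were significance-gated is not stated, so gating is configurable).
Redundancy candidates tier profile correlations at > 0.8 (strong) and
0.5–0.8 (moderate). The shipped `modification_positions()` table (wobble
34, position 37, 26, 44, 46, …) is reference decoration for reports;
nothing is computed from it.

## The synthetic-data generator

`simulate_chromatograms()` emulates: Gaussian elution peaks (σ default
**0.05 min**, narrow enough that the closest scheduled neighbours — m7G
5.1 vs m1A 5.7 min — resolve cleanly) centred at registry RT plus Gaussian
jitter (default 0.02 min); a constant baseline with additive Gaussian noise
truncated at zero; sampling only inside the scheduled segment at the
dwell-derived cadence. `simulate_experiment()` adds the replicate design:
6 µg tRNA and 6 pmol internal standard per sample, three biological
replicates per group, a per-sample *injection scale* (log-normal, CV 3%,
applied to every trace including the internal standard — this is the
variation the internal standard exists to cancel, at the low-percent level
typical of intra-day instrument precision) and per-analyte *biological*
variation (log-normal, CV 10%, not applied to the internal standard, so it
survives normalization and drives the t-tests — chosen as a realistic
replicate CV for biological material). Control abundances span three
decades across high/medium/low tiers, mirroring the dynamic range of real
hydrolysates. The 12-condition exposure panel applies per-agent
fold-change signatures (all within 0.2×–4×), scaled geometrically with
dose, with the hypochlorite agent inverse-dosed; the mutant panel encodes
known enzyme→product relationships, including a near-identical profile
pair for the two subunits of the m7G methyltransferase and a shared-Um
triplet.

What it does **not** emulate: chromatographic drift and carryover, peak
tailing/fronting, detector saturation, shot-noise scaling of counting
statistics (the true instrument noise structure is unknown; additive
Gaussian is a declared stand-in), 5S rRNA contamination, or any direct
chemical (non-enzymatic) modification of the RNA. Passing tests therefore
demonstrate correctness of the computations under a clean, known data model
— not robustness to every pathology of real chromatography.

Determinism: every simulation is a pure function of (parameters, registry,
seed); per-sample substreams derive from `(seed, sample index)` through a
fixed integer map, so adding samples never reshuffles existing ones.

## Problem sizes and numerical choices

The test suite and acceptance script use: single-sample fixtures of 25
traces (~12k points); 6-sample paired designs; the 39-sample (12 conditions
+ shared controls) panel; 20 simulation seeds for fold-change recovery;
100 seeds for calibration-slope coverage; clustering oracles on ≤ 5 items
(where exhaustive recomputation is cheap and unambiguous). These sizes make
the whole suite run in well under a minute while leaving every statistical
check adequately powered.

Numerical conventions worth knowing: trapezoidal integration (exact for
the piecewise-linear signal model, < 1% error for sampled Gaussians at the
dwell cadences used); ties in intensity ranking broken by registry order;
correlation-PCA sign fixed as above; eigenvalues clipped at zero before
computing variance shares; the sentinel 0.00001 is compared with `<=` when
deciding undetectability in the simulator and with the 0.02 threshold in
classification.

## Known limitations

* No retention-time alignment across runs: the registry RT is trusted
  within ± tolerance per sample.
* Co-eluting isobars are separated only by RT window; a true co-elution
  within one window would be attributed to whichever transition claims the
  window.
* The mzML writer/reader covers the chromatogram-list subset this package
  needs (64-bit uncompressed arrays, precursor/product isolation windows);
  it is not a general mzML implementation.
* Absolute quantification assumes the calibration matrix behaves like the
  sample matrix; no recovery correction is modelled.
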