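---
title: "Two-dimensional melting-curve genotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional melting-curve genotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melt2d)
```

## The assay model

Closed-tube multiplex genotyping by "2D-PCR" encodes each allele of each
assayed locus as a point in a two-dimensional space whose axes are the
fluorophore channel and the melting temperature (Tm).  Allele-specific
ARMS primers carry a 5' *tag* homologous — up to a small number of
deliberate mismatches — to one of three base-quenching probes (FAM, HEX,
Alexa568).  After amplification, the tag–probe duplex of every allele
present in the template melts at its own calibrated temperature, so the
negative derivative −dF/dT of the fluorescence acquired over a 30–70 °C
ramp shows one peak per present allele at a known (channel, Tm)
coordinate.  Genotypes are read off by inverting this map.

The bundled nine-locus hereditary hearing-loss panel covers the hotspot
mutations of *GJB2* (c.235delC, c.176-191del16, c.299_300delAT),
*SLC26A4* (c.919-2A>G, c.2168A>G, c.1229C>T), *GJB3* (c.538C>T) and the
mitochondrial *MT-RNR1* (m.1494C>T, m.1555A>G).  Its geometry obeys
three decoding conventions, checked by `validate_channel_rules()`:
every FAM coordinate is a wild allele, every Alexa568 coordinate a
mutant allele, and HEX coordinates split at 48 °C (wild below, mutant
above).  The tightest within-channel spacing is 2.4 °C (FAM), which
motivates the default peak-to-coordinate matching tolerance of
±1.0 °C — less than half the smallest gap, so Tm windows are pairwise
disjoint.

More homologous tags form more stable duplexes: within FAM and HEX the
hottest coordinate belongs to the tag with the fewest probe mismatches
(a property asserted in the test suite via `tag_probe_mismatches()`).
`check_arms_design()` verifies the two ARMS rules: the 3'-terminal base
discriminates the alleles, and any engineered destabilising mismatch
sits 3–6 bases from the 3' end.  Because the printed oligo table marks
the artificial sites typographically rather than by position, the check
takes declared positions (or a template context) as input instead of
inferring them.

## The synthetic-data generator

`render_channel()` renders each duplex as a two-state melting
transition: fluorescence $a \cdot \sigma((T_m - T)/w)$ with logistic
$\sigma$, amplitude $a$ and width $w$.  The negative derivative of this
sigmoid peaks exactly at $T_m$, which makes the generator's truth
directly comparable with the peak caller's output.  A sample's trace is
the sum of one component per present allele plus a linear baseline and
additive Gaussian noise.

Defaults, chosen once as the package's study conditions:

* temperature grid 30–70 °C at 0.1 °C steps — the instrument acquires
  continuously over this ramp; a fixed uniform grid is the software
  contract;
* transition width 0.5 °C, giving a derivative full width at half
  maximum of ≈1.76 °C that resolves the minimal 2.4 °C spacing;
* dosage rule: homozygous/homoplasmic alleles contribute amplitude 1.0,
  heterozygous/heteroplasmic alleles 0.5 each (peak heights are not
  tabulated for the reference assay, so a linear dose–amplitude rule is
  the neutral choice); optional per-channel scale factors emulate
  unequal probe amounts;
* noise sd 0.005 (relative to unit amplitude) and baseline slope
  −0.002 units/°C.

`fixture_cohort()` replays the 116-patient study cohort genotype by
genotype, including the one sample carrying the SLC26A4 compound
heterozygote together with homoplasmic m.1555A>G — so 50 distinct
carriers arise from 34 + 15 + 2 gene-positive samples.
`sample_cohort()` draws random cohorts under Hardy–Weinberg equilibrium
with independent loci; mitochondrial loci are a single Bernoulli draw
between the homoplasmic states.  Heteroplasmy is representable and
decodable but never sampled, mirroring the assay validation data in
which only homoplasmic states occurred.

What the generator does *not* emulate: amplification kinetics and
plateau effects, probe photochemistry, inter-run temperature
calibration drift, and non-linear baselines.  Passing round-trip tests
therefore demonstrate the correctness of the decoding logic under the
stated signal model, not instrument-level robustness.

## Peak calling

`negative_derivative()` applies order-2 Savitzky–Golay smoothing
(window 0.5 °C by default, forced odd and ≥5 points) followed by a
central-difference negative derivative.  `detect_peaks()` keeps interior
local maxima that clear

1. a relative gate: `min_height_frac` (default 0.25) of the curve's
   global maximum;
2. an absolute floor: `floor_mult` (default 5) times the curve's noise
   scale; and
3. a prominence guard of 10⁻⁶.

The noise scale is estimated robustly from the *raw* fluorescence — the
median absolute deviation of its second differences, which is blind to
the smooth melt signal — and propagated to derivative units through the
l2 gain of the smoothing-plus-differencing operator, computed from its
impulse response.  Estimating noise on the derivative curve itself (for
example from the MAD of its quiet tail) proved unreliable: on traces
with many peaks the signal inflates the estimate enough to swallow a
heterozygote peak riding the shoulder of a stronger neighbour.  The
prominence guard exists for the opposite regime: an analytically flat
channel over a linear baseline has a constant positive derivative whose
floating-point ripple passes any purely relative height gate, but with
essentially zero topographic prominence; 10⁻⁶ is orders of magnitude
below any real peak and orders above double-precision ripple.

Retained maxima closer than `min_separation` (default 1.5 °C, below the
2.4 °C minimal spacing) are pruned greedily keeping the higher peak.
Each surviving peak is refined by parabolic interpolation through the
maximum and its two neighbours, with the vertex offset clamped to half
a grid step; this gives sub-grid Tm accuracy (≤0.2 °C for isolated
sigmoids of width ≤1 °C, tested).  Grid edges are excluded so boundary
half-peaks are never called.

## Decoding and QC

`assign_peaks()` matches each peak to the unique same-channel
coordinate within tolerance; a validated panel guarantees uniqueness,
and pathological ties are broken by the smaller Tm deviation and
flagged.  When two peaks compete for one coordinate the closer wins and
the loser is flagged `competing_peaks`.  `call_genotypes()` maps
allele evidence to classes: for diploid loci wild-only → `WW`, both →
`WM`, mutant-only → `MM`; for mitochondrial loci the homoplasmic states
and `heteroplasmic` when both alleles appear (QC-flagged, because the
assay could physically show it but the validation cohorts did not).  A
locus with no evidence is `no_call` — a QC failure by contract, since a
working multiplex emits at least one allele peak per locus; the
software deliberately does not attempt to distinguish a truly absent
locus from a low-amplitude dropout.  `hex_threshold_check()` guards the
48 °C HEX convention on decoder output, where a violation can only
arise from a mis-specified panel.

## Cohort statistics

`summarize_cohort()` reproduces the study's counting rules: gene
positivity counts samples with ≥1 mutant allele in the gene; compound
heterozygotes carry two different heterozygous sites in one gene;
overall carriers are deduplicated across genes (the overlap is computed
from the data); per-site mutant alleles are het + 2·hom over 2n for
nuclear loci and carrier counts over n for mitochondrial loci, with
heterozygotes for different genes counted separately.  Percentages are
rounded to one decimal, matching the reference tables.

`chi_square_2x2()` is Pearson's statistic without continuity
correction (df = 1) — the variant that reproduces the published
allele-frequency comparison of 3.26 exactly.  `compare_with_region()`
rebuilds an external 2×2 cell from a published rate and cohort size,
doubling patient counts to allele denominators where appropriate and
rounding the reconstructed count to the nearest integer.  Because the
published rates are themselves rounded to one decimal, a reconstructed
count can differ from the unpublished original by ±1, which moves a
chi-square of order 10 by up to ≈0.3; comparisons against printed
statistics therefore carry a tolerance, and one published value (11.75)
is consistent only with an external count one below the nearest-integer
reconstruction.  `cohens_kappa()` pools all (sample, locus) labels;
kappa is defined as 1 whenever observed agreement is total, including
the degenerate single-category case, and its p-value uses the
large-sample normal approximation under kappa = 0.

## Problem sizes and determinism

The test suite exercises: the exhaustive noiseless round-trip over all
27 single-locus genotype classes; 500 simulated samples at default
noise (4,500 locus calls) decoded against truth; 1,000 random 2×2
tables against an independent chi-square reference; and the 116-sample
fixture cohort through simulation, decoding, summary and concordance.
All stochastic steps take explicit seeds, and identical seed plus
configuration yields byte-identical outputs end to end, including
through the command-line interface.

## Known limitations

* Tm values are calibrated inputs; the package does not predict Tm from
  sequence thermodynamics.
* Merged peaks are separated only by local-maximum logic, not by
  multi-component deconvolution; baselines are handled as linear.
* The heterozygote dosage rule (0.5/0.5) is an idealisation; real peak
  height ratios vary with amplification efficiency.
* Alleles outside the panel are invisible by construction (e.g. an
  insertion at a position adjacent to an assayed deletion will not be
  detected), which is a property of the assay, not of the software.
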