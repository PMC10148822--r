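---
title: "Quantifying stimulus-evoked DRG responses, marker co-expression and behavioral endpoints"
author: "drgquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stimulus-evoked DRG responses, marker co-expression and behavioral endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgquant)
set.seed(1)
```

# Overview

`drgquant` implements the quantitative core of a sensory-neuron study of
mechanical pain: in vivo two-photon calcium imaging of dorsal root ganglion
(DRG) neurons under graded knee/paw stimulation, multiplexed in-situ
(RNAscope-style) marker co-expression in DRG sections, single-cell
RNA-sequencing count-matrix quality control and threshold co-expression, and
the behavioral/molecular endpoint derivations that precede inferential
statistics. Every stage is driven by a seeded synthetic-data generator with
full ground truth, so the statistical behaviour of each rule is testable
without any external data.

# The imaging model

## Acquisition protocol

A recording is framed as an `ImagingProtocol`: frames at 0.7 Hz, an initial
30-frame force-free block (the global baseline), then one epoch per stimulus
of 10 pre-stimulus, 10 stimulus-application and 10 post-stimulus frames. The
default field is 981.36 × 981.36 µm² at 1.92 µm/pixel. All of these are
parameters; the defaults describe the acquisition this package was designed
around.

## ΔF/F₀ and the responder criterion

For each neuron, `computeDff()` forms

$$\Delta F/F_0(t) = \frac{F(t) - F_0}{F_0},$$

where \(F_0\) is the mean fluorescence over the baseline period. A neuron is
a *responder* to a stimulus when its **peak** ΔF/F₀ during the 10-frame
application window strictly exceeds \(k \times \mathrm{SD}\) of the baseline
ΔF/F₀, with \(k = 4\) by default. Two conventions are deliberately exposed:

* **Baseline period** (`baselineMode`): the default `"global"` uses the
  30-frame force-free block for both \(F_0\) and the SD, reading "the
  baseline period" as the force-free block that defines \(F_0\). The
  alternative `"prestim"` renormalizes each epoch against its own 10
  pre-stimulus frames; both are supported because either reading is
  defensible when stimuli are separated by minutes of recovery.
* **SD convention** (`sdType`): sample SD (n−1) by default; population SD
  available. Whether the SD is taken on raw fluorescence or on ΔF/F₀ changes
  nothing: the two differ by the factor \(F_0\) only, so the 4× comparison
  is identical — we compute it on ΔF/F₀.

The inequality at the boundary is strict (`>`), so a peak exactly at 4 SD is
*not* a responder. On pure Gaussian noise with known SD, the false-positive
probability of the rule over an m-frame window is \(1 - \Phi(k)^m\), about
3.17 × 10⁻⁴ for \(k = 4, m = 10\); `responderFalsePositiveRate()` verifies
this empirically and the acceptance suite checks it at 10⁶ windows.

## Peak AUC

`peakAuc()` locates the peak frame within the application window, expands to
the maximal contiguous run of strictly positive ΔF/F₀ containing that frame
(the run may extend into post-stimulus frames, never constrained to the
window), and integrates by the trapezoidal rule with frame spacing
\(1/0.7\) s. This is the closest parameter-free reading of "peak area under
the curve" computed by generic curve-analysis software: no baseline offset,
zero as the reference level. Degenerate cases return 0: a non-positive peak,
or a single-frame run (which has no trapezoid support). AUC is linear in
ΔF/F₀ and non-negative by construction.

## Totals, percentages, size distributions

The total number of neurons imaged is estimated by counting neurons in a
sub-region of average density and extrapolating by area ratio
(`estimateTotalNeurons()`, rounded half-away-from-zero to an integer);
percent responders is `100 × responders / total` (`percentResponders()`).
Responder soma areas are summarized as relative frequency histograms
(`areaHistogram()`) over left-closed right-open bins; the default edges are
100 µm² wide from 0 to 2000 µm², chosen to cover small (~80 µm²) through
large (~1600 µm²) DRG somata, and fully configurable. Values outside the
edges go to open end-bins by default. `summarizeSession()` assembles the
per-stimulus table and histograms; the mean peak AUC over responders is
reported as missing — never 0 — when there are no responders.

# The synthetic imaging generator

`simulateImagingSession()` draws, per neuron: a lognormal soma area
(defaults `meanlog = log(360)`, `sdlog = 0.75`, spanning roughly 80–1600 µm²,
i.e. diameters ~10–45 µm); a lognormal baseline fluorescence around 100
arbitrary units; and per stimulus, a Bernoulli responder flag. Responders
receive one transient with a difference-of-exponentials kernel
(`rise_tau = 0.2` s, `decay_tau = 1.5` s, GCaMP6s-like), starting at a
uniform onset within the application window (leaving at least one stimulus
frame after onset so the sampled peak falls inside the window). Two
normalization choices matter:

* the kernel is normalized over the **sampled frame grid**, so the realized
  noiseless peak ΔF/F₀ equals the drawn amplitude exactly — amplitudes are
  in ΔF/F₀ units by construction, which makes ground truth sharp;
* transients are confined to their own epoch, mirroring the recovery pause
  between stimuli that lets fluorescence return to baseline; without this,
  decay tails would leak into later windows and noiseless ground-truth
  recovery would not be exact.

Noise is additive Gaussian with SD proportional to the neuron's baseline
fluorescence (`noiseSD` as a fraction); this is the simplest model under
which the 4σ criterion has the closed-form false-positive rate above.
Amplitude defaults (`meanlog = log(0.8)`, `sdlog = 0.5`) are realistic for a
slow genetically encoded indicator but are placeholders, not calibrated
values — the study this emulates does not report real amplitudes or noise
levels, so both are exposed in the configuration.

In `"stack"` mode neurons are rendered as 2-D Gaussian blobs (σ = half the
soma radius) on the protocol's pixel grid, with a disk ROI label per neuron;
the blob profile is normalized to mean 1 over its ROI so that mean-ROI
extraction (`extractTraces()`) recovers the generating trace. Overlap
between ROIs is permitted unless `forbidOverlap = TRUE` (rejection
sampling). There is no optics/PSF model, no photobleaching and no motion —
the real acquisition used spinal clamps precisely to avoid motion, and
motion correction is out of scope.

What the generator does *not* emulate — slow baseline drift, correlated
(shared) noise across neurons, neuropil contamination, non-Gaussian photon
statistics — limits what passing tests show about real recordings: they
validate the *rules* (normalization, thresholding, integration, bookkeeping),
not robustness to real-world artifacts.

# Marker co-expression

`CellMarkerTable` holds RNAscope-style per-cell records (animal → section →
cell, diameter in µm, a logical per probe). `classifyCombinations()` assigns
every cell to exactly one node of the 2ᵏ positivity lattice (all-negative
included), so counts partition the cells and percents sum to 100.
`aggregateNested()` follows the section-sampling design: percentages per
section, averaged within animal, then mean ± SEM across animals; SEM is the
sample SD over √n and is missing (never 0) for a single unit.
`diameterDistributions()` produces per-subset relative frequency histograms
(default 2.5-µm bins over 0–60 µm) and pairwise two-sample two-tailed
Kolmogorov–Smirnov comparisons (asymptotic p-values via `stats::ks.test`);
the D statistic is checked in the test suite against a brute-force ECDF scan.

The generator `simulateMarkerTable()` draws each cell's combination from
configured lattice probabilities (which must sum to 1) and a lognormal
diameter, optionally combination-specific; 2–4 sections per animal by
default, matching the usual sectioning design.

# Count-matrix QC and threshold co-expression

`simulateCountMatrix()` constructs a sparse gene × cell matrix in which each
cell is built either to pass or to fail the standard filter; failure is by
too few detected genes or by a high mitochondrial fraction (genes prefixed
`mt-`). Because construction controls the outcome, the filter can be checked
cell for cell. `qcFilter()` retains cells with `n_features > 200` (strict)
AND `percent_mito < 15` (strict), recomputing both covariates from the
matrix so stored values can never drift; it is idempotent and preserves gene
set and cell order. `logNormalizeCounts()` applies
\( \ln(1 + 10^4 \cdot c / \text{total}) \) — the scale (10,000) and natural
log follow the defaults of the standard single-cell toolchain, since only
"log normalized" is specified; both are arguments.
`thresholdCoexpression()` calls a gene expressed when its normalized value
strictly exceeds 0.1 and reports the fraction of cells expressing all listed
genes, optionally conditioned on a further gene (e.g. the fraction of
Scn10a⁺ cells co-expressing Piezo2 and Ntrk1). Thresholding raw counts
instead is available via `assayName = "counts"` for sensitivity analysis.
Clustering, UMAP and cluster annotation are deliberately not implemented —
they are routine toolchain steps; the co-expression rule operates on the
filtered matrix directly.

# Behavioral and molecular endpoints

* `swellingDifference()` — post-injection minus baseline caliper reading
  (mm; may be negative).
* `timecourseAuc()` — trapezoidal integral of each subject's series over
  the time axis, baseline timepoint included, raw values by default.
  Whether published time-course AUCs anchor at baseline is not recoverable,
  so `subtractBaseline = TRUE` exposes the alternative; the x-axis unit is
  whatever the input uses (days or weeks), and the AUC scales accordingly.
* `logThresholds()` — log-transform of withdrawal thresholds before
  analysis; base 10 by default ("log-transformed" alone does not fix the
  base, and base 10 is the common choice for von Frey data), configurable.
* `relativeExpression()` — comparative ΔΔCT: per-sample
  ΔCT = CT_target − CT_reference, ΔΔCT against the control-group mean ΔCT,
  fold = 2^(−ΔΔCT). The control group has geometric-mean fold 1 by
  construction.
* `groupSummary()` — mean ± SEM tables ready for standard inferential
  routines (repeated-measures ANOVA, post-tests, rank tests), which are
  delegated to existing statistical software and not re-implemented here.

The Dixon up-down 50% withdrawal estimator is cited to prior literature by
the protocols this package mirrors and is out of scope.

# Numerical choices and degenerate inputs

* Strict inequalities at every stated boundary: responder (> 4 SD), QC
  (> 200 features, < 15% mito), expression (> 0.1).
* Extrapolated totals round half-away-from-zero (not banker's rounding).
* Histograms are left-closed right-open; an empty input yields an empty
  (flagged) distribution rather than an error.
* A trace whose baseline mean is non-positive signals corrupt input and
  errors; a cell with zero total counts cannot be log-normalized.
* SEM and mean-AUC-over-responders are reported missing, never 0, when
  undefined.
* All generators take one integer seed and are pure functions of their
  arguments: identical calls give bit-identical output, and draws happen in
  a fixed documented order.

# Scales used by the test suite

The packaged tests run the statistical checks at sizes a laptop handles in
seconds: 10⁶ noise windows for the false-positive rate; 300-neuron sessions
(two stimuli) for ground-truth recovery and ≥ 99% sensitivity at amplitudes
≥ 6 noise SDs; 5 animals × 3 sections × 500 cells (triple-positive
probability 0.38) for nested marker recovery; 1,000-cell count matrices with
a 20% constructed failure rate for QC and co-expression recovery. Sampling
checks use 3 analytic binomial SDs of the configured probability as the
agreement band. `scripts/acceptance.R` reruns all of these from scratch at a
user-chosen seed.

# Limitations

The synthetic data validate rule implementations, not biological inference:
no claim is made that the default amplitude, noise or size parameters match
any particular real dataset. The imaging module assumes ROIs are given
(drawn or rendered); it does not segment. The KS p-values are asymptotic and
approximate for small samples with ties, exactly as in the standard test.
Inferential group comparisons are intentionally left to standard statistical
packages.
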