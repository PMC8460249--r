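---
title: "Methods: glomerular tuning-curve correlation analysis and its synthetic test bed"
author: "glomtune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glomerular tuning-curve correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomtune)
```

## Scope

glomtune quantifies how similarly the glomerular compartments of a single
antennal-lobe local interneuron (LN) respond to an odor panel.  The
pipeline is: ROI mean traces → blank-trial biexponential bleach correction
→ ΔF/F₀ → 3-s response AUC → per-glomerulus tuning curves normalised to
the glomerulus maximum → pairwise Spearman correlation within the neuron →
per-neuron mean *r* → nonparametric group comparison across cell types and
manipulations.  A generative model of such recordings, with ground truth
attached, backs the test suite.

## Signal model of the generator

A fluorescence trace of glomerulus $g$ under stimulus $o$ is

$$F(t) = B\, b(t)\, \bigl(1 + A_{go}\, k(t)\bigr) + \varepsilon(t),$$

* $B$ — resting fluorescence.  Drawn once per neuron from
  LogNormal($\log 1000$, $0.3$) AU: indicator loading through the patch
  pipette and imaging depth vary between preparations, and this is the
  dominant source of between-neuron signal-to-noise differences.
* $b(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}$ — multiplicative
  photobleaching (defaults $a_1 = 0.15$, $\tau_1 = 8$ s, $a_2 = 0.85$,
  $\tau_2 = 200$ s: a small fast component on top of slow bulk bleaching).
* $k(t)$ — difference-of-exponentials calcium transient
  ($\tau_\text{rise} = 0.1$ s, $\tau_\text{decay} = 1.5$ s, peak
  normalised to 1) starting at stimulus onset (2 s into a 10-s trial,
  500 ms pulse).
* $\varepsilon$ — i.i.d. Gaussian camera noise, SD `noise_sigma` (AU),
  clipped so counts stay positive (cameras do not report negative AU).
* Frames sit at bin centres $t_i = (i + 0.5)/f$ with $f = 18$ Hz;
  windows are half-open $[\text{start}, \text{end})$.

The drive amplitudes $A_{go}$ (the peak ΔF/F₀ a perfect correction would
recover) come from

$$A_{g\cdot} = s_g\, A \,
  \frac{\rho\, d + (1 - \rho)\, p_g}{\max_o\bigl(\rho\, d + (1-\rho)\,p_g\bigr)},$$

with $d, p_g \sim$ Uniform(0,1) per odor, gains
$s_g \sim$ LogNormal(0, 0.4) (neurite density varies between glomeruli),
amplitude scale $A$, and shared weight $\rho \in [0,1]$.  Uniform tuning
draws (rather than, say, Dirichlet) are deliberate: only the rank
structure matters for a Spearman-based analysis, and uniforms give
full-support ranks with minimal assumptions.  For the spikelet subtype
(TYPE_IIA1) the private vectors are shared within `n_groups = 3`
round-robin groups — spikelet-coordinated blocks of similarly tuned
glomeruli — and independent across groups.  Spikelet waveforms, membrane
potentials and indicator saturation are *not* modelled; the group-shared
component stands in for the coordination they produce.

Per neuron, the glomerulus count is drawn uniformly from 9–25 (the
per-neuron range this class of recordings shows) unless fixed.  One trial
per odor is the default, matching single-sweep analysis; the blank gets
one trial with zero drive and full bleaching/noise.  All randomness stems
from one master seed per neuron, split into named substreams (`tuning`,
`gains`, `private`, `baseline`, `noise`, `placement`), so extending the
odor panel never perturbs the gain draws.  Roster helpers combine the
neuron index with the regime label when deriving master seeds, keeping
the random streams of different experimental groups independent.

## Regimes and calibration

| regime | mechanism emulated | $\rho$ | $A$ | target mean *r* |
|---|---|---|---|---|
| TYPE_I | propagated action potentials | 1 (forced) | 1.0 | 0.95 |
| TYPE_I_HYPERPOL | local input, spikes suppressed | 0.828 | 0.3 | 0.75 |
| TYPE_I_QX314 | local input, Na⁺ channels blocked | 0.797 | 0.3 | 0.74 |
| TYPE_IIA1 | graded + spikelet-coordinated groups | 0.688 | 0.3 | 0.67 |
| TYPE_IIA2 / TYPE_IIB | graded, independent tuning | 0.609 | 0.3 | 0.51 |

The published statistics are group means, not generative parameters, so a
calibration bridges the two — once, then frozen:

1. `calibrate_noise_sigma()`: with $\rho = 1$ the only departure of
   TYPE_I pairwise *r* from 1 is acquisition noise, so the camera-noise SD
   is bisected until the Monte-Carlo grand mean of per-neuron mean *r*
   equals 0.95.  Result: `noise_sigma = 57.5` AU (on a 1000 AU baseline),
   shared by all regimes — reduced response amplitude ($A = 0.3$ after
   spike suppression) lowers the signal-to-noise of the other regimes
   automatically.
2. `calibrate_shared_weight()`: with noise fixed, $\rho$ is bisected per
   regime (grand mean over 80–240 pipeline-analysed neurons, disjoint
   seed range) against each group target, and the frozen values were
   verified on an independent 320-neuron sample to sit within 0.02 of
   their targets (the calibration's stated tolerance).

Monte-Carlo grand means are monotonically nondecreasing in $\rho$ under
fixed seeds (verified property), which bisection relies on.  A target
outside the achievable range at the given noise level raises an error
naming that range.

With 5–6 neurons per blocked group and across-neuron SDs of ~0.11 (close
to the published group SDs of 0.12–0.26), a roster's grand mean carries a
sampling SE of ~0.05.  Small-roster grand means therefore scatter around
the calibrated expectation by that much — re-running the original
experiment at the same N would scatter equally.  The A-level validation
checks should be read with this in mind.

## Analysis pipeline choices

* **Bleach fit** (`fit_bleach`): Levenberg–Marquardt least squares of
  $a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + c$ on the blank trial, one fit
  per glomerulus, applied to all of that glomerulus's trials.  The offset
  $c$ absorbs stray light and is retained in the correction.  Biexponential
  least squares is multimodal when the two time constants are poorly
  separated, and the slow component is nearly linear over a 10-s window,
  so the fit runs a short ladder of $(\tau_1, \tau_2)$ starts, keeps the
  best residual, stops early at the estimated noise floor (robust
  second-difference estimator), and judges convergence by the achieved
  residual rather than the LM status code alone.  On non-convergence a
  monoexponential fallback is used and flagged.  Oracle tests require the
  fitted *curve* (not the parameters, which trade off) to match noise-free
  generating curves to $10^{-3}$ of the trace range.
* **Correction mode**: divisive,
  $F_\text{corr} = F / (\hat F(t)/\hat F(0))$, because bleaching is
  multiplicative photophysics.  A subtractive mode is provided
  (`bleach_mode = "subtract"`) since the choice is not dictated by the
  data; with the blank's own fit both modes flatten the blank exactly.
* **F₀**: mean of the corrected trace over $[\text{onset} - 1\,\text{s},
  \text{onset})$.  A pre-stimulus *window* mean (not the first frame) is
  used for noise robustness; the window is configurable.
* **AUC** (`response_auc`): trapezoid over $[\text{onset}, \text{onset} +
  3\,\text{s})$ with linearly interpolated values at the window edges, so
  the integral always spans exactly the analysis window (a constant
  ΔF/F₀ of 0.1 integrates to 0.3 exactly, independent of frame phase).
  Negative AUCs (inhibition-dominated responses) are retained.
* **Tuning curves**: per-glomerulus AUC vector divided by its maximum;
  the blank AUC is reported but never subtracted (no such step exists in
  the protocol being modelled) and excluded from the maximum.  Ties for
  the maximum are flagged and resolved to the first odor in panel order.
  Glomeruli with no positive AUC are marked non-responsive and excluded
  from correlation with a record — clipping negatives instead would
  inflate rank ties.
* **Spearman** (`spearman_r`): Pearson correlation of average-tie ranks
  (ties are common in 9-point curves).  Constant vectors give an
  undefined coefficient (`NA`), excluded from summaries with a count —
  not coerced to 0.  On tie-free vectors the implementation equals
  $1 - 6\sum d_i^2 / (n(n^2-1))$ exactly (verified exhaustively to
  $n = 6$).
* **Summaries**: mean/median/min/max over the upper-triangle
  off-diagonal coefficients, always on the *raw* scale.  Setting negative
  *r* to zero (`heatmap_matrix`) is a display convention only and never
  feeds back into statistics.
* **Group tests**: tie-corrected Kruskal–Wallis (via
  `stats::kruskal.test`) with the chi-square approximation — group sizes
  here are 5–18, where the approximation holds its nominal size (verified
  empirically: type-I error 0.045 at $\alpha = 0.05$ over 2000 null
  replicates).  Dunn post hoc $z$ uses pooled mean ranks with the tie
  term, two-sided normal p-values multiplied by the number of requested
  comparisons (classic Bonferroni-style Dunn; Holm ordering available).
  Box statistics use type-7 quartiles and Tukey whiskers (most extreme
  points within 1.5 IQR).

## Degenerate inputs and tie-breaks

Flat blank traces short-circuit to an exact constant fit (identity
correction).  A missing blank trial downgrades to no bleach correction
with a warning.  Fewer than two responsive glomeruli is an error the
experiment runner records per neuron while continuing the run.  All-equal
group values give $H = 0$, $p = 1$; empty groups are errors.

## Validation problem sizes

The shipped suite exercises: the exhaustive Spearman oracle to length 6;
a 3×3 $(\tau_1, \tau_2)$ bleach-recovery grid plus noisy-blank noise
floors; 1000-seed independence checks at $\rho = 0$; a 6-point $\rho$
monotonicity grid at 50 neurons per point with common random numbers; 100
replicate group-comparison experiments (16/6/5 rosters) for detection and
false-positive rates; and 2000 null replicates for the omnibus test's
size.  These sizes give Monte-Carlo error well below the asserted margins
while keeping the default run lightweight.

## What passing tests do and do not show

The generator reproduces the *correlation structure* of the five regimes
under realistic noise, bleaching and gain heterogeneity.  It does not
contain membrane biophysics, odorant chemistry, optics (PSF, scattering,
motion) or indicator nonlinearity, and real recordings may hold
structured noise (breathing, drift) that i.i.d. Gaussian noise does not
emulate.  Passing the regime-reproduction checks therefore shows the
pipeline recovers the statistics a recording with this signal/noise
structure implies — not that the generator is a complete model of the
preparation.
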