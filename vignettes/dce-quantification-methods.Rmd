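---
title: "Quantifying DCE-MRI: from signal to Ktrans-MVD correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DCE-MRI: from signal to Ktrans-MVD correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcequant)
```

## The problem

Dynamic contrast-enhanced (DCE) MRI watches a gadolinium bolus wash
through tissue and, through a tracer-kinetic model, turns the signal
dynamics into physiological parameters: the volume transfer constant
Ktrans, the extravascular extracellular volume fraction ve and the
plasma volume fraction vp. In preclinical liver-tumor work these
parameters are candidate imaging biomarkers of vascularity, and the
natural histological anchor is microvessel density (MVD) counted on
CD31-stained sections. `dcequant` implements the full quantification
chain for a protocol of this kind — an ablated hepatic tumor imaged
coronally at 3 T, with necrotic (CNA), partially necrotic (PNA) and
viable (VTA) subregions delineated on histology — and the statistics
that relate the imaging parameters to MVD per subregion.

Because no raw scans are distributed with studies of this kind, the
package carries two data sources of its own: a bundled 15-tumor
subregion table (`loadTable1Fixture()`) on which all cohort statistics
can be recomputed exactly, and a digital phantom that emulates the
acquisition end to end so every processing stage is testable against
known ground truth.

## Signal model and T1 mapping

All images are spoiled gradient-echo (SPGR):

$$S = S_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-TR/T_1}.$$

Precontrast T1 (T10) and the equilibrium signal S0 are estimated per
voxel from four flip angles (2, 5, 10, 12 degrees; TR = 2.3 ms) by the
standard linearization of this equation — `fitVFA()` regresses
$S/\sin\alpha$ on $S/\tan\alpha$, whose slope is $E_1$. The linearized
fit is deterministic and, on noise-free input, inverts the forward
model to machine precision; voxels yielding a slope outside (0, 1) are
flagged rather than propagated. We assume the commanded flip angle is
the true one (no B1 correction), and the two baseline frames of the
dynamic series are not merged into the VFA fit.

During the dynamic series only the 12-degree images are available, so
postcontrast T1(t) comes from inverting the SPGR equation at the known
S0 (`t1FromSignal()`). The inversion has a bounded domain: signal at or
above $S_0\sin\alpha$ (the $T_1 \to 0$ limit) is clamped to a floor of
1 ms and flagged, nonpositive signal is clamped to a 20 s ceiling and
flagged. Clamping rather than erroring keeps one pathological voxel
from aborting a whole map.

Concentration then follows from the relaxation-rate difference,

$$C(t) = \frac{1/T_1(t) - 1/T_{10}}{r_1},$$

with a single relaxivity $r_1 = 4.39\ \mathrm{s^{-1} mM^{-1}}$ applied
to blood and tissue alike — a deliberate simplification that mirrors
the protocol the package models. Slightly negative concentrations under
noise are passed through unclipped: the fit that consumes them is least
squares, which stays unbiased under symmetric noise, and clipping would
bias the baseline.

## Arterial input function

The model input Cp(t) is measured per subject from blood-pool voxels.
The field practice is visual selection of curves with a high, early,
narrow first pass; `scoreAIFCandidates()` makes that operational as the
score $\mathrm{peak}/(\mathrm{TTP}\times\mathrm{FWHM})$, with the FWHM
found by linear interpolation between frames (the 2.4 s frame spacing
is coarse relative to the bolus width). Ranking is deterministic, with
exact ties broken by voxel index. The top-k voxels (k = 5 by default;
the number averaged per subject is a package choice, configurable) are
averaged and converted from whole blood to plasma,

$$C_p = \frac{C_b}{1 - \mathrm{Hct}}, \qquad \mathrm{Hct} = 0.45,$$

the physically standard direction of the hematocrit correction. A
`convention = "multiply"` switch preserves the alternative rescaled
form seen in some reports; since the conversion is a global scale on
Cp, the choice rescales Ktrans, vp (and ve, via ve = Ktrans/kep) by
$(1-\mathrm{Hct})^{-2}$ uniformly and leaves every correlation result
untouched — a property the test suite asserts rather than assumes. An
explicit voxel list is accepted everywhere as the operator-driven mode.

## The extended Kety model and its fitting

Tissue concentration follows the extended Kety (extended Tofts) model

$$C_t(t) = v_p C_p(t - t_0) + K^{trans}\!\int_0^t C_p(\tau - t_0)\,
  e^{-\frac{K^{trans}}{v_e}(t-\tau)}\,d\tau ,$$

with a per-voxel bolus-arrival delay $t_0$. Conventions that matter:

* **Units.** Rate constants are /min (the scale on which reported
  tumor values of 0.04–4 live); time grids are in seconds. The
  conversion happens once, inside `ketyForward()`.
* **Delay.** Applied by linear interpolation of Cp, so sub-frame
  delays are representable; the curve is zero before the input starts.
* **Convolution.** Trapezoidal quadrature on the uniform grid,
  evaluated by the exact $O(n)$ recursion for an exponential kernel.
  Against the analytic impulse response, the discrete operator is
  accurate to well under 0.5% on the 120-frame, 2.4 s grid, and
  halving the grid spacing moves noise-free fitted Ktrans by < 1%.
* **Degenerate voxels.** Ktrans > 0 with ve = 0 is rejected (the
  efflux rate is undefined); an all-zero curve converges trivially to
  Ktrans = vp = 0; when the fitted Ktrans lands on the zero bound, ve
  is unidentifiable and is reported as `NA` with a flag instead of a
  made-up number. Necrotic cores routinely produce such voxels, which
  is why the flag exists rather than a hard error.

Fitting is bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) on $(K^{trans}, v_e, v_p, t_0)$ with bounds
[0, 10] /min, [1e-6, 1], [0, 1] and [0, 30] s — generous brackets
around the physiological range — and the single documented start
(0.1, 0.2, 0.02, 0). The returned optimum never exceeds the objective
at the start (a property the tests check). Pure single-start fitting
is reliable in the low-Ktrans regime but can stall in a local minimum
at high Ktrans (~1 /min), where the optimizer trades the vp spike for
an earlier delay; `multistart = TRUE` therefore adds restarts at
Ktrans = 0.05, 0.5 and 2 /min seeded with a data-driven arrival-time
estimate (the lag between the tissue curve and the input function
first exceeding 10% of their maxima). With multistart on, every tumor
voxel of the full-size noise-free phantom recovers Ktrans to better
than 1e-9 relative; map fitting defaults to it in the pipeline.

## Subregion summarization

Histology-derived labels (1 = CNA, 2 = PNA, 3 = VTA) are taken as
given on, or resampled to, the DCE grid; `resampleROI()` does
majority-vote nearest-neighbor resampling with ties toward the lower
code. No deformable registration is attempted — the package models a
workflow in which sectioning was aligned to the imaging plane.

Each region contributes one representative value per parameter: the
mean over a 3 x 3 in-plane window ("2nd neighborhood", 9 voxels) on
the Ktrans map. The window is in-plane because 2 mm slices over
0.75 mm in-plane voxels make through-plane averaging anatomically
incoherent. Where the window goes is not prescribed by the protocol
the package models, so `pickRegionCenter()` fixes it
deterministically: among all windows lying fully inside the region,
the one whose mean Ktrans is the median of the eligible window means
(ties to the lower voxel index). The median-window rule is robust —
contaminating a minority of region voxels moves it far less than it
moves the plain regional mean — and an explicit center override
remains for operator-driven use. If a region is too thin to contain
any 3 x 3 window, the fallback is the region voxel nearest the
centroid (the centroid itself can lie outside an annular region), and
the result is flagged.

## Statistics

`runFullAnalysis()` reproduces the cohort analysis: Pearson
correlations (two-sided t-distribution p, n - 2 df) of each parameter
against MVD within CNA, PNA, VTA and the combined set, and Wilcoxon
signed-rank contrasts between the three region pairs for each
parameter and for MVD.

Two conventions deserve a note. First, "measuring from both the PNA
and the VTA" is implemented as the per-tumor unweighted mean of the
two regions (n stays 15), not as pooling 30 rows; a `pooled` mode is
kept for sensitivity analysis. Second, the signed-rank test drops
zero differences and midranks ties, and for up to 25 informative
pairs computes the p-value from the exact permutation distribution
(by convolution over doubled midranks, so ties are exact too). The
exactness matters: with 2-decimal data, rounding-induced ties push
normal-approximation implementations just past the p = 0.001
threshold on contrasts that the exact distribution places at 1.2e-4.
Above n = 25 the normal approximation with tie and continuity
correction takes over. Two-sided p-values throughout; no
multiple-testing correction is applied, matching the analysis the
package reproduces (each test reported at its nominal level).

On the bundled table these choices reproduce the reference pattern:
Ktrans–MVD r of 0.0075 (CNA), 0.8124 (PNA), 0.5743 (VTA) and 0.8470
(combined means), the combined r exceeding either region alone, and
the significance grid of the subregion contrasts.

## What the phantom emulates — and what it does not

`makeGroundTruth()` builds a coronal 160 x 160 x 8 grid (0.75 mm
in-plane, 2 mm slices) containing one ablated tumor as concentric
discs on four central slices — CNA core, PNA ring, VTA rim, radii
3.75/6.75/9.75 mm so each ring is about 4 voxels wide and admits
interior 3 x 3 windows — inside a liver ellipse, plus a small
blood-pool cylinder for AIF extraction. Voxel-wise parameters are
lognormal around region means taken from the bundled table's column
means (Ktrans 0.044/0.293/1.00 /min), with a 10% within-region CV;
`intraCV = 0` gives exactly uniform regions. T10 is 1.1 s in tumor,
0.8 s in liver, 1.6 s in blood.

The synthetic input function is a gamma-variate first pass (arrival
12 s, mode 5 s later) plus a small biexponential recirculation
shoulder, normalized so its grid maximum equals the configured peak
(5 mM whole blood). Any smooth bolus with a tall, narrow, early first
pass would serve; this one satisfies the AIF selection criteria the
scoring module operationalizes. The acquisition defaults mirror the
modeled protocol: TR/TE 2.3/4.5 ms, 2.4 s sampling, 120 dynamics with
2 baseline frames, dynamic flip 12 degrees.

Noise is additive Gaussian on the magnitude signal, not Rician: at
the signal levels of interest the two are practically identical,
and the Gaussian model keeps the least-squares likelihood exact.
`sampleMVD()` emulates the five-field counting protocol: field counts
drawn around slope x (region mean Ktrans) + intercept (slope 13.9,
intercept 2.96, field SD 3 — a line through the bundled table's
PNA/VTA column means), truncated at zero, with the necrotic core at a
near-zero rate (1.11); the reported value is the five-field mean.
`simulateCohort()` reproduces the between-tumor variability structure
(lognormal, CVs from the table columns) directly at summary level,
which is what the Monte-Carlo calibration and power checks run on.

What passing phantom tests does **not** show: robustness to motion
and breathing artifacts, B1 inhomogeneity, inflow effects, water
exchange, T2* effects, dual-input (arterial + portal) liver supply,
or histology-to-image misregistration. None of these are modeled, by
design; on real liver data they are the dominant error sources.

## Problem sizes and numerical choices

The test suite exercises most stages on a 48 x 48 x 3 phantom (one
tumor slice, ~450 tumor voxels) and reserves the full 160 x 160 x 8
grid (2116 tumor voxels) for the end-to-end recovery check; the
Monte-Carlo calibration uses 500 null cohorts and 200 default-link
cohorts of 15 tumors. These sizes were chosen so the whole suite runs
in a few minutes while still covering the full-resolution geometry
once. Optimizer tolerances are ftol = ptol = 1e-12 with at most 200
iterations; the SPGR inversion clamps at 1 ms and 20 s; the
signed-rank test switches from exact to approximate at n = 26.

## Known limitations

* ve in necrotic tissue is weakly identified whenever Ktrans ≈ 0;
  the package flags it rather than suppressing the value, because the
  reference table it reproduces does report ve in the CNA.
* The exact hematocrit convention, relaxivity and AIF voxel count are
  global scale factors on the parameter maps; absolute Ktrans values
  should be compared across studies only under matched conventions.
  Correlation-based conclusions are invariant to all three.
* The phantom's lognormal parameter fields are spatially uncorrelated
  within regions; real tumors have smooth spatial structure, so
  neighborhood averaging on real maps removes more noise than it does
  here.
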