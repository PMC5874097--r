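# dcequant

Voxel-wise pharmacokinetic quantification of dynamic contrast-enhanced
(DCE) MRI, built for preclinical liver-tumor studies that validate
imaging parameters against histology. The package takes a spoiled
gradient-echo acquisition — multi-flip-angle precontrast volumes plus a
4D dynamic series — through variable flip angle T1 mapping, conversion
of signal to contrast-agent concentration, arterial input function
(AIF) extraction, extended Kety model fitting, tumor-subregion
summarization, and finally the correlation of Ktrans/ve/vp with
microvessel density (MVD) from CD31 immunohistochemistry.

It is aimed at imaging scientists who need a reproducible, fully tested
reference implementation of this chain: every stage is exercised
against a built-in digital phantom with known ground truth, and the
cohort statistics are reproducible exactly from a bundled 15-tumor
subregion table.

## The model

Signal is spoiled gradient-echo,
S = S0 · sinα · (1 − E1)/(1 − E1·cosα) with E1 = exp(−TR/T1).
Precontrast (S0, T10) come from the linearized variable flip angle fit;
postcontrast T1(t) from inverting the SPGR equation at known S0.
Concentration follows C(t) = (1/T1(t) − 1/T10)/r1 with
r1 = 4.39 s⁻¹mM⁻¹, and the measured whole-blood input is converted to
plasma by Cp = Cb/(1 − Hct), Hct = 0.45.

Tissue kinetics follow the extended Kety (extended Tofts) model

    Ct(t) = vp·Cp(t − t0) + Ktrans · ∫ Cp(τ − t0) · exp(−(Ktrans/ve)(t − τ)) dτ

fitted per voxel by bounded Levenberg–Marquardt least squares, with
Ktrans in 1/min, ve and vp as fractions and the bolus delay t0 in
seconds. Subregions (complete necrosis CNA, partial necrosis PNA,
viable tumor VTA) are each summarized by the mean of a 3×3 in-plane
window placed deterministically on the Ktrans map, and related to MVD
by Pearson correlation and Wilcoxon signed-rank contrasts (exact
distribution with midranks up to n = 25).

## Worked example

Simulate one noise-free study with the digital phantom and recover its
parameters end to end:

```r
library(dcequant)

acq <- acquisitionParams()              # TR 2.3 ms, 120 x 2.4 s dynamics
st  <- simulatePhantomStudy(phantomConfig(), acq, noiseSd = 0, seed = 1)

lab <- labelMap(st$truth)
roi <- lab %in% 1:3;          dim(roi) <- dim(lab)
fit <- roi | lab == 5L;       dim(fit) <- dim(lab)

t1set <- fitVFAMap(st$vfa, acq@flipAngles, acq@tr, mask = fit)
conc  <- concentrationSeries(st$dyn, t1set, mask = fit)

blood <- lab == 5L;           dim(blood) <- dim(lab)
cand  <- scoreAIFCandidates(conc, blood)
aif   <- extractAIF(conc, cand$voxel[1:5], acq@hct)
aif
#> AIF: 120 frames; peak 9.09 mM at 16.8 s, FWHM 9.1 s (5 source voxels)

maps <- fitKetyMap(conc, aif, roi, multistart = TRUE)
maps
#> ParameterMaps: 160 x 160 x 8; 2116 ROI voxels, 2116 converged
#>   Ktrans [/min]: median 0.841 (range 0.0328-1.35)

rel <- abs(ktransMap(maps)[roi] - ktransMap(st$truth)[roi]) /
       ktransMap(st$truth)[roi]
max(rel)
#> [1] 2.249248e-12
```

The recovered Ktrans map matches the ground truth at every tumor voxel
to machine precision; the AIF peak (9.09 mM plasma) is the 5 mM
whole-blood bolus divided by 1 − Hct.

The cohort statistics run on any summary table in the bundled layout:

```r
res <- runFullAnalysis(loadTable1Fixture())
subset(res$correlations, parameter == "ktrans")
#>   region_set parameter           r            p  n
#> 1        CNA    ktrans 0.007518782 9.787837e-01 15
#> 4        PNA    ktrans 0.812388370 2.332079e-04 15
#> 7        VTA    ktrans 0.574255094 2.516817e-02 15
#> 10   PNA+VTA    ktrans 0.846970925 6.775735e-05 15
```

Ktrans is uncorrelated with MVD in necrosis, strongly correlated in
the partially necrotic and viable regions, and strongest for the
per-tumor PNA+VTA means — the pattern the subregion analysis is built
to expose. `runPipeline(pipelineConfig())` ties all stages together
over a simulated cohort and writes maps, summaries, correlation tables
and a report; `inst/scripts/dcequant-cli.R` wraps it for the shell.

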