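# coreshell

Quantitative shell-thickness analysis for core-shell hydrogel capsules
imaged by transmitted-light microscopy.

Capsules with a liquid core and an alginate shell are fabricated by
ionotropic gelation: an agarose bead template is soaked in CaCl₂, then
immersed in alginate, and the calcium stored in the core crosslinks a shell
around it. The shell is stained with iron-oxide nanoparticles, so thicker
shells are darker and redder. Two questions drive the analysis:

1. **How does shell thickness depend on the soaking concentration?**
   The volumetric model `V_s = α · n_Ca²⁺` gives the thickness law

   ```
   h = R_c · ( (α·[Ca²⁺] + 1)^(1/3) − 1 )
   ```

   which linearizes to `(h/R_c + 1)³ − 1 = α·[Ca²⁺]`, fitted through the
   origin to estimate the gelation constant `α` (in mM⁻¹).

2. **Do thin shells form at all at low concentration?** Shells too thin to
   measure directly are assessed by colour: the mean red-minus-blue
   intensity (R−B) at the capsule centre grows with thickness and, unlike
   the raw red channel, does not saturate at high concentration. A linear
   calibration of measured thickness on R−B, extrapolated to the
   background-level colour of faint capsules, predicts *negative*
   thickness — physically impossible, hence the inference that below a
   threshold concentration no continuous shell forms.

The package implements the geometric model (`predictThickness`,
`fitAlpha`), the image pipeline (`segmentCapsule`, `centreRegion`,
`extractColourStats`, `measureRadius`), the calibration and threshold
inference (`fitColourCalibration`, `predictThicknessFromColour`,
`detectFormationThreshold`), a synthetic capsule-image generator
(`renderCapsule`, `generateDataset`) and end-to-end orchestration
(`runPipeline`, `writeReport`). See the methods vignette
(`vignettes/capsule-shell-analysis.Rmd`) for the model assumptions, the
optical design of the generator and the numerical choices.

## Worked example

Generate a synthetic study (10 concentrations from 0.1 to 100 mM, four
replicates, true α = 0.033 mM⁻¹, no shell at ≤ 2 mM) and analyse it:

```r
library(coreshell)

d <- file.path(tempdir(), "demo")
generateDataset(scenarioSpec(seed = 2026L), opticsParams(), d)

cfg <- pipelineConfig(columnMap = list(sample_id = "sample_id",
  conc_mM = "conc_mM", R_c_um = "R_c_um", h_um = "h_true_um"))
report <- runPipeline(file.path(d, "manifest.csv"),
                      file.path(d, "ground_truth.csv"), cfg)
report
#> AnalysisReport
#>   alpha-hat: 0.033 mM^-1 (n = 28 measured)
#>   calibration: slope 11.133 um/unit, intercept -79.67 um, r2 0.999
#>   samples: 40 analysed, 0 skipped
#>   formation threshold: 2 mM (all replicates shell-absent)

head(perSampleTable(report)[, c("sample_id", "conc_mM", "R_minus_B",
                                "h_pred_um", "status")])
#>   sample_id conc_mM R_minus_B h_pred_um status
#> 1  c0p1_r01     0.1  4.937759 -24.69344 absent
#> 2  c0p1_r02     0.1  4.954751 -24.50427 absent
#> 3  c0p1_r03     0.1  4.862069 -25.53613 absent
#> 4  c0p1_r04     0.1  5.045198 -23.49730 absent
#> 5  c1p0_r01     1.0  5.085973 -23.04334 absent
#> 6  c1p0_r02     1.0  5.093023 -22.96485 absent
```

Reading the output: the through-origin fit on the 28 directly measurable
capsules recovers α = 0.033 mM⁻¹; the colour calibration maps one R−B
intensity unit to ~11 µm of shell; capsules soaked at ≤ 2 mM sit at the
background colour (R−B ≈ 5) and extrapolate to ≈ −24 µm, so every
replicate there is classified shell-absent and the detected formation
threshold is 2 mM. Forward prediction works directly from a model object:

```r
predictThickness(shellModel(0.033), 30, 650)
#> [1] 167.5815
```

`writeReport(report, "results/")` writes the per-sample and per-
concentration CSVs, the calibration JSON (slope, intercept, r², n), a text
summary, and the two diagnostic figures (linearized thickness vs
concentration with the through-origin fit; thickness vs R−B with the
calibration line).

A thin command-line wrapper is installed with the package
(`inst/scripts/coreshell-pipeline.R`) with `simulate` and `run-all` verbs.

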