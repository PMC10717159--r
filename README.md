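# wormtwitch

Quantification of *C. elegans* body-wall-muscle phenotypes from microscopy
data: muscle **contraction strength and frequency** from single-worm movies,
**movement-trace area** from plate photographs, **muscle nuclei counts** and
**whole-body fluorescence intensity** from micrographs, and the matching
**group statistics** (mean ± SEM, one-way ANOVA, Tukey HSD). It is aimed at
worm labs measuring muscle degeneration phenotypes — e.g. dystrophin
(*dys-1*) mutants, the nematode model of Duchenne muscular dystrophy,
sensitised with a twitchin (*unc-22*) background — and at anyone who needs
these assays as reproducible, tested code rather than manual ImageJ steps.

Because no raw movies or per-animal tables are publicly deposited for these
assays, the package ships a **synthetic-data module**: generators for
movies, area signals, trace images, nuclei images and cohort tables with
exact ground truth, so every stage of the pipeline is validated end to end
without laboratory data.

## The contraction assay

A worm is filmed for ten seconds at Δt = 0.07 s/frame. Frames are segmented
(per-frame Otsu by default, largest 8-connected component), giving the body
area aₜ (px²). Movies qualify only if the entire body is captured
continuously for **more than 3 s** (mask nonempty, touching no border);
statistics are computed on the longest such run of T frames. On the
mean-centred signal dₜ = aₜ − ā:

* **contractions** n = number of downward peaks of dₜ (local minima with
  topographic prominence ≥ 10% of the IQR, after a 3-frame moving average);
* **rate of change in body area** = (1/n) Σᵢ (d{upper(i)} − d{lower(i)}),
  the mean peak-to-trough excursion, in px²;
* **frequency** = n / (T · Δt), in s⁻¹.

The methods vignette (`vignettes/contraction-assay.Rmd`) documents every
convention (plateau handling, prominence, tie rules, the strict 3-s
boundary, the resolution of the ambiguous printed strength formula) and
what the synthetic generators do and do not emulate.

## Worked example

Simulate a ten-second movie of a worm contracting at 1 Hz with a 100 px²
amplitude (contrast-to-noise 10), then run the full assay:

```r
library(wormtwitch)

sp <- worm_scene_spec(contraction_amplitude = 100, contraction_freq_hz = 1,
                      baseline_area = 350, pixel_noise_sd = 0.1, seed = 42)
mv <- gen_worm_movie(sp)
res <- run_contraction_assay(mv$stack)
res
#> Body-wall muscle contraction assay
#>   analysis window : 143 frames at 0.07 s/frame (10.01 s)
#>   contractions    : 10
#>   rate of change  : 99.4 px^2
#>   frequency       : 0.999 /s
mv$truth$true_n_contractions
#> [1] 10
```

All ten ground-truth contractions are found; the measured strength
(99.4 px² vs the true 100 px² peak-to-trough) is ~0.6% low because the
cosine extrema fall between 0.07 s samples. The frequency is 10 contractions
over the 10.01 s analysis window.

Group comparison on a simulated two-genotype cohort (the built-in preset
encodes a strong amplitude deficit in the double mutant at equal
frequency):

```r
tab <- gen_cohort(cohort_preset("contractility", seed = 42))$table
fit <- one_way_anova(value ~ condition, subset(tab, endpoint == "amplitude_px2"))
fit
#> One-way ANOVA
#>   F(1, 58) = 326.15, p = < 2.2e-16
#>   SS between = 14.2759, SS within = 2.53873
#>   Group means +/- SEM:
#>     dys-1;unc-22             1.038 +/- 0.0286 (n = 30)
#>     unc-22                   2.014 +/- 0.0458 (n = 30)
tukey_hsd(fit)
#> Tukey HSD (k = 2, df = 58, alpha = 0.05)
#>   condition_a condition_b mean_diff     q    p_adj significant
#>  dys-1;unc-22      unc-22    0.9756 25.54 1.49e-11        TRUE
```

The double mutant's weaker contraction amplitude is flagged
(p_adj ≪ 0.05); running the same comparison on the `frequency_hz` endpoint
is expected not to flag anything, since the preset's frequencies are equal.

Other entry points: `quantify_track_area()` (trace area, px²/mm²),
`count_nuclei()` and `total_intensity()` (fluorescence),
`analyze_area_series()` (contraction metrics on a precomputed CSV signal),
`run_pipeline()` (simulate → measure → compare with optional blinding and a
hashed provenance manifest), and the CLI
`Rscript inst/cli/wormtwitch.R {simulate|segment|contract|track|nuclei|intensity|stats|run} …`.

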