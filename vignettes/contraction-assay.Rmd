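---
title: "Quantifying C. elegans muscle contraction, locomotion and muscle fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying C. elegans muscle contraction, locomotion and muscle fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assays

`wormtwitch` quantifies four read-outs used to characterise body-wall-muscle
phenotypes in *Caenorhabditis elegans*, in particular in dystrophin (*dys-1*)
mutants sensitised with a twitchin (*unc-22*) background:

1. **Contraction assay.** A single worm is filmed for ten seconds at 0.07 s
   per frame. Each frame is segmented, the worm's projected body area
   $a_t$ (px²) is extracted, and the mean-centred signal
   $d_t = a_t - \bar a$ is analysed. Each muscle contraction transiently
   reduces the projected area, so the *downward peaks* (local minima) of
   $d_t$ are counted as contractions. Three statistics are reported:
   the contraction count $n$, the *rate of change in body area*
   $\frac{1}{n}\sum_{i=1}^{n} (d_{u(i)} - d_{\ell(i)})$ — the mean
   excursion from each trough $\ell(i)$ to its nearest preceding upper peak
   $u(i)$ — and the contraction frequency
   $f = n / (T \cdot \Delta t)$ with $T$ the number of analysis frames and
   $\Delta t$ the frame interval.
2. **Movement-trace assay.** A worm explores a plate for 30 minutes; its
   track, carved into the bacterial lawn, is photographed and the covered
   area is measured by thresholding.
3. **Nuclei counting.** GFP-labelled body-wall-muscle nuclei in one bundle
   are counted from a fluorescence micrograph.
4. **Whole-body intensity.** Background-subtracted integrated GFP intensity
   over the segmented body.

Group comparisons throughout use mean ± SEM summaries, one-way ANOVA and
Tukey's HSD at the 0.05 level — the analysis conventionally applied to these
assays.

# Movie eligibility (QC)

Only movies in which the entire body is captured continuously for **more
than three seconds** enter the analysis. "Entire body captured" is
operationalised as: the frame's segmented mask is nonempty and touches no
image border (a clipped worm is the only observable failure mode in a
single-worm movie). The filter finds the longest run of consecutive
full-body frames and requires `run_length · Δt > 3 s`, *strictly* —
following the wording "more than". At 0.07 s/frame, 43 frames (3.01 s)
pass and 42 frames (2.94 s) do not. All downstream statistics are computed
on that longest run only, not on the whole movie: "captured continuously"
implies one contiguous analysis window, and the frequency denominator `T`
is the length of that window.

# Segmentation

The measurement tool used originally for these assays (ImageJ) is cited
without a thresholding method, so the default here is per-frame Otsu
thresholding — parameter-free and reproducible — with a fixed-threshold
override for calibrated settings. After thresholding, only the largest
8-connected component of at least `min_object_px = 20` pixels is kept;
this suppresses debris while never splitting a worm. Otsu is computed on a
256-bin histogram of the frame's intensity range; when the between-class
variance is flat over an empty histogram gap the lowest maximiser is
taken (any choice in the gap induces the same segmentation).

# Peak detection

No peak-detection procedure is stated for the original assay, so the
package uses the simplest transparent one, with every default overridable
and an exhaustive brute-force enumeration kept as a reference
implementation:

* optional centred moving-average smoothing, default window 3 frames
  (0.21 s at the default frame rate — below half the period of the fastest
  contractions considered, ~2 Hz, so troughs are never merged);
* lower peaks are local minima of the smoothed signal with **topographic
  prominence** at least `min_prominence_px2`, default 10% of the
  deviation-series interquartile range (a scale-free floor: it rises with
  contraction amplitude and sits far above segmentation noise at realistic
  contrast);
* upper peaks are the maxima between adjacent troughs plus flanking local
  maxima where present;
* series endpoints are never peaks (truncation artifacts);
* a leading trough with no preceding upper peak uses the window's first
  sample as its upper reference, so a real contraction at window start is
  not discarded;
* peak *positions* come from the smoothed signal, peak *values* are read
  from the unsmoothed signal at those positions, so amplitudes are not
  attenuated by smoothing.

Numerical conventions: plateaus (runs of exactly equal values) count as a
single extremum at the run centre; among tied flanking maxima the one
nearest the trough is used; the moving average is computed as direct
window means rather than cumulative-sum differences, because plateau
detection compares smoothed values for exact equality and must not be
perturbed by cancellation artifacts. These conventions are shared by the
brute-force reference (`inst/validation/peak-oracle.R`), against which the
detector is tested for exact agreement on thousands of random series,
plateaus included.

## Two readings of the strength formula

The printed definition of contraction strength — "the average of the
subtracted values between the upper and lower peaks/number of
contractions" — is ambiguous about precedence. The package resolves it as
the **mean peak-to-trough excursion** (sum of per-contraction excursions ÷
contraction count): the alternative reading, dividing that average by the
count a second time, shrinks with movie length and cannot represent a
per-contraction strength. The alternative remains selectable
(`amplitude_mode = "excursion_over_n"`) for sensitivity analysis.
Similarly, "number of contractions / number of analysis frames × 0.07" is
read as $n/(T \times 0.07)$, which has units of s⁻¹; the literal
left-to-right reading does not.

# The synthetic-data generators

No raw movies or per-animal tables are publicly deposited for these
assays, so every stage is validated against generators with exact ground
truth.

**Area signal.** The contraction signal is modelled as
$a(t) = A_0 - \tfrac{A}{2}\,(1 - \cos 2\pi f t)$ plus optional Gaussian
noise: a cosine is the simplest waveform with unambiguous analytic troughs
(at $t = (2k+1)/2f$), giving an exact oracle for counts, trough positions
and amplitude. A trough belongs to the ground truth iff its analytic
minimum lies inside the recorded window.

**Movies.** Frames show one bright worm (contrast 1) on a dark background:
pixels are ranked by distance to a fixed sinusoidal centreline and the
closest $\lfloor a(t)\rceil$ pixels form the body, so the foreground count
equals the rounded analytic area *exactly* before noise — the noiseless
round trip through segmentation is exact by construction, and any
discrepancy is a segmentation bug. The worm does not undulate; this
isolates the contraction signal from posture changes, which the area
statistic is meant to be robust to anyway. Pixel noise is i.i.d. Gaussian;
its default SD of 0.1 (contrast-to-noise 10) reflects the high contrast of
stereomicroscope recordings of a dark worm on bright agar. Frames can be
deliberately clipped at the image border to exercise the QC filter.

**Tracks** are persistent random walks rasterized (Bresenham, configurable
stroke) as dark-on-light, with the union pixel count as ground truth — so
self-crossing paths are counted once, as a thresholding measurement would.
**Nuclei images** are sums of isotropic Gaussian spots at integer centres
with a minimum pairwise separation. **Cohorts** draw per-animal endpoint
values from per-condition normal models (truncated at zero for areas and
counts, rounded for counts), 30 animals per condition by default — the
stated per-condition minimum for these assays.

**What the presets encode.** Published figures for these assays give group
means ± SEM, not per-animal tables, and no amplitude units, so presets are
calibrated to *standardized* effect sizes rather than raw values: the
`contractility` preset sets a Cohen's d = 5 amplitude deficit in the
double mutant at exactly equal contraction frequency (the qualitative
structure the assay was designed to resolve: weaker contraction, preserved
rhythm); the `rescue` preset orders trace-area means by febuxostat dose
with a further uric-acid co-administration benefit and no prednisone
effect; the `nuclei` preset reduces counts in the mutant with partial
dose-dependent restoration. Passing tests therefore demonstrate that the
pipeline *resolves this ordering and significance structure*, not that it
reproduces any published number.

**What the generators do not emulate**: undulation and posture dynamics,
uneven illumination, out-of-focus frames, worm–track interaction on
plates, anisotropic or overlapping nuclei, autofluorescence gradients.
Exact round trips on noiseless synthetic data bound algorithmic
correctness, not robustness to these real-data complications.

# Fluorescence quantification

Nuclei are detected by a difference-of-Gaussians band-pass (default σ
1.5–3 px, matching ~2 px nuclear spots) followed by local-maximum picking
with a minimum separation and a threshold relative to the strongest
response. On noiseless images detection is exact for up to ~40 spots
separated by at least 3σ; the automated threshold stands in for the human
"detectable nucleus" criterion, which is not otherwise quantified. The
bundle region is taken to be the supplied (pre-cropped) image.

Whole-body intensity subtracts a background level estimated from non-body
pixels — by default their intensity mode (exact tabulation when the image
has few distinct values, a 256-bin histogram mode otherwise), optionally a
low percentile — and integrates `max(pixel − background, 0)` over the
body mask. The identity `integrated = mean × area` holds by construction.
Note that both the mode and percentile estimators are shift- and
scale-equivariant, so adding an offset to a clean image leaves the
integrated intensity unchanged and rescaling the image rescales it
exactly.

# Statistics

ANOVA uses the standard fixed-effects decomposition; degenerate inputs are
defined rather than errors (zero between-group variance → F = 0, p = 1;
zero within-group variance with distinct means → F = ∞, p = 0). Tukey HSD
uses the Tukey–Kramer standard error for unequal group sizes, with
adjusted p values from the studentized range distribution
(`stats::ptukey`), independently verified to 10⁻⁶ against a direct
quadrature of the distribution (`inst/validation/srange-oracle.R`). No
normality or homogeneity pre-tests gate the analysis — the assay's
convention is unconditional ANOVA — but a Brown–Forsythe heterogeneity
advisory is attached and a warning emitted when its p < 0.01. Day-course
data are compared per day; no pooled or repeated-measures model is fitted.

# Blinding in the pipeline

Drug-effect assays of this kind are scored double-blind. `run_pipeline()`
models this as label masking: with `blinded = TRUE` the measurement and
summary stages see opaque condition codes and the code→label key is
applied only at the statistics stage. This is a software correctness check
— measurements cannot depend on labels, and blinded and unblinded runs of
the same seed agree byte for byte on every number — not a claim about
experimental practice.

# Validation study sizes

The shipped validation studies (test suite and `scripts/acceptance.R`)
use: ten-second, 143-frame movies of 60×80 px at contrast-to-noise 10,
100 movies per cell of a 3×3 grid (amplitude 50/100/200 px² × frequency
0.5/1/2 Hz); 1,000 random series (≤200 frames) for detector-vs-enumeration
agreement; 50 seeds per noiseless round-trip family; 2,000 simulated null
cohorts for the type-I error of the simulate→measure→Tukey chain; and 100
seeded cohorts for the preset structure. At these sizes the complete
validation runs in a few minutes on one CPU. Expected behaviour at the
defaults: contraction counts are recovered exactly, and the measured
amplitude is biased low by up to ~3.5% at 2 Hz — the cost of sampling a
cosine extremum on a 0.07 s grid (expected loss
$\tfrac{A}{2}\,\mathbb{E}[1-\cos 2\pi f u]$ per extremum for a half-frame
offset $u$), not a detector artifact.

One validation bound deserves a note: requiring the preset's
amplitude-deficit/equal-frequency structure in at least 95 of 100 seeds
places the bound exactly at the binomial expectation, since the frequency
endpoint is a true null tested at the 0.05 level. The observed count
therefore fluctuates around 95 from seed set to seed set; the type-I-error
study (which bounds the same quantity in [0.03, 0.07] over 2,000 tables)
is the stable version of the same check.

# Known limitations

* Area is used as "body size"; body length is not measured and no
  area→distance calibration is attempted for trace areas (none is defined
  for these assays).
* Single-worm scenes only: no tracking, no skeletonisation, no posture
  analysis, no multi-animal disambiguation.
* Qualitative read-outs of the original study — mitochondrial
  fragmentation scoring and sarcomere-line clarity — have no computational
  definition and are deliberately out of scope rather than invented.
* The nuclei counter assumes approximately isotropic spots within a factor
  ~2 of the configured σ; elongated or merged nuclei will undercount.
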