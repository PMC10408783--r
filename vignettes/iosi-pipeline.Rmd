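---
title: "Mapping evoked cortical activity with iosimap: model, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping evoked cortical activity with iosimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iosimap)
```

## The measurement

Intrinsic optical signal imaging (IOSI) maps cortical activity through the
activity-dependent change in how much light the cortex reflects: increased
local blood volume and deoxygenation absorb more red light, so an activated
region *darkens* by roughly 0.01–0.1% of the reflected intensity. A session
consists of repeated, stimulus-triggered camera trials (by default 10 Hz
frames starting 1 s before stimulus onset and running 3 s after it, 30
trials), plus a green-light reference image of the surface vasculature used
for anatomical localization and session-to-session alignment.

The quantity of interest at each pixel is the fractional reflectance change

$$\frac{\Delta R}{R} = \frac{P_k - B}{B},$$

where $B$ is the mean of the 0.9 s (nine frames) immediately preceding
stimulus onset and $P_k$ are post-stimulus images averaged in 0.3 s bins
covering 0.5–2.0 s after onset (five bins). Per-trial $\Delta R/R$ bins are
averaged across trials and summed across bins to produce a single *evoked
map*; activated pixels are negative.

## Pipeline order and numerical conventions

The pipeline applies, in this fixed order:

1. **Spatial Gaussian filter** per frame, $\sigma = 0.5$ raw pixels with
   kernel size $2\lceil 2\sigma\rceil + 1$ (so 3×3 at the default). Borders
   use edge replication, which preserves constant frames exactly. There is
   no temporal smoothing.
2. **×4 spatial downsample** by non-overlapping block means (trailing
   partial blocks are dropped). Block averaging is constant-preserving and
   noise-reducing; plain decimation is available as an option
   (`downsample(..., method = "decimate")`).
3. **Temporal averaging** into the baseline image and post-stimulus bins.
   Every averaging window must convert to a whole number of frames at the
   configured frame rate; a fractional window is a hard error, never a
   silent rounding, because the published frame counts (nine baseline
   frames, five 3-frame bins) define the analysis.
4. **$\Delta R/R$** per trial against that trial's own baseline (never a
   session-pooled baseline), then mean over trials and sum over bins.

Filtering, downsampling and temporal averaging are all linear, but the
ratio in step 4 is not, so the order matters numerically; it is frozen as
above and the fused filter+downsample kernel used internally is tested to
agree with the sequential operations to rounding error. Two useful exact
invariants follow from the conventions: a temporally constant movie yields
an identically zero evoked map regardless of spatial content, and scaling
all frames of a trial by any positive gain leaves $\Delta R/R$ unchanged.

Indexing is 0-based `(row, col)` with row 0 at the top, and `onset_frame`
is the index of the first frame at or after stimulus onset; with the
defaults the baseline frames are indices 1–9 and binning starts at index
`onset + 5`.

## From evoked map to activation map

A circular mask marking the cranial window (center, radius in analysis
pixels; user-supplied in the session config, with a best-effort automatic
fit offered by `fit_window_circle()`) zeroes all outside pixels. Binary
maps are then produced one of two ways:

* **z-score mode** (small maps, e.g. single-whisker): pixels with
  $z < -3$, where $z$ uses the sample mean and SD of the masked map.
* **percent-of-peak mode** (large maps): pixels whose signal magnitude
  $-\Delta R/R$ reaches a fraction of the peak in-window magnitude. The
  fraction has no canonical value; the package default is 0.5, which has
  the convenient property that on a noiseless Gaussian response it marks
  exactly the half-peak contour used as the phantom's ground-truth area.

**The z-scoring population.** After masking, out-of-window pixels are
exactly 0. The package's default (`in_mask_only = FALSE`) computes the
z-score mean and SD over the *whole* masked image, zeros included — this
is what the reference MATLAB implementation of the pipeline does when it
z-scores the masked image. The alternative (`in_mask_only = TRUE`)
restricts the statistics to in-window pixels. The difference is a
deliberate bias–calibration tradeoff: including the zeroed surround
deflates the SD (by roughly the square root of the in-window fraction) and
so admits more pixels at a given cut, while the in-window variant is
exactly tail-calibrated — under a pure-noise map the expected fraction of
$z < -3$ pixels is $\Phi(-3) \approx 0.00135$, a property the test suite
verifies by simulation. Both conventions are exposed; results in this
package's documentation state which one they use.

Binary maps are cleaned with a 3×3 **binary median filter** (majority vote
of the 9-neighborhood, border padded `FALSE`; ties are impossible), which
removes isolated noise pixels and is idempotent on large solid regions.

## Quantification

* **Area**: true-pixel count × (analysis pixel size)².
* **Ellipse**: the moment-matched ("fit ellipse") convention — center at
  the pixel centroid, axes and orientation from the central second-moment
  matrix (including the 1/12 per-pixel term, so a filled rectangle gives
  an exact axis ratio), scaled so the ellipse area equals the pixel area.
  When a map has several connected components the largest is fitted by
  default. Alternative boundary-fit conventions would move centers by
  sub-pixel amounts, so the convention is pinned and tested against closed
  forms (squares, rectangles, discs) and a brute-force double-sum oracle.
* **Displacement**: difference of ellipse centers in µm, +x rightward
  (columns), +y downward (rows).
* **Displacement comparison**: one-way MANOVA on the 2-D displacement
  vectors via Wilks' Λ with Rao's F approximation (`stats::manova`); for
  two groups this equals Hotelling's T², which the tests verify against a
  closed form to 1e-10. Its type-I error at α = 0.05 is checked by null
  simulation (1000 draws).
* **Plasticity**: paired two-tailed t test on per-animal pre/post areas.
  Because the percent change of the group means and the mean of per-pair
  percent changes differ in general (0.16 → 0.30 mm² is +87.5% of means,
  while per-animal ratios can average differently, e.g. ~82%), both are
  reported.
* **Trial accumulation**: for each $k$, the evoked map over trials
  $1..k$ is masked, thresholded, cleaned and measured, reported as percent
  of the all-trial area — the standard way to ask how many trials a stable
  map needs. The value at $k = n$ is 100 by construction.
* **Longitudinal comparison**: sessions are aligned by integer-pixel
  translation maximizing the cross-correlation of their vasculature
  images; no rotation or scaling, matching how chronic-window sessions are
  aligned in practice.

## The phantom: what it emulates, and what it does not

`phantom_config()` synthesizes sessions with closed-form ground truth:

$$R(x, t) = V(x)\,\bigl(1 + A\, G(x)\, s(t)\bigr)\,\bigl(1 + \varepsilon_{x,t}\bigr)$$

* $V$: a baseline-level field (default 10,000 counts) with seeded dark
  curvilinear vessels (random walks, width 2–6 raw px, 35% contrast) —
  enough structure for alignment and ratiometric cancellation tests.
* $G$: a spatial Gaussian normalized to peak 1, default $\sigma$ = 192 µm
  so the half-peak contour encloses 0.160 mm², the scale of a
  single-whisker cortical map. The ground-truth "area" of a phantom is
  *defined* as this half-peak contour area — an explicit, testable
  convention (a thresholded area necessarily depends on SNR).
* $A$: peak fractional change, default −10⁻³ (within the 0.01–0.1%
  intrinsic-signal range).
* $s(t)$: a gamma-shaped time course, zero until 0.3 s after onset,
  peaking 1.2 s later, FWHM 3 s (shape parameter solved numerically from
  the FWHM). These defaults describe a sustained hemodynamic response that
  stays elevated through the 0.5–2 s binning window — the binning grid is
  designed to capture the bulk of the response, and with these defaults
  the five bin means sum to ≈ 4.3 of a possible 5. A faster-decaying
  course (e.g. FWHM 1.5 s) would leave the bins seeing barely half the
  attainable signal and would make the pinned amplitude/noise conditions
  unrecoverable by a z = −3 cut; the sustained shape is both the more
  realistic choice and the one consistent with the binning design.
* $\varepsilon$: iid Gaussian, SD 0.007 per raw pixel per frame —
  multiplicative noise approximating shot noise at a 20,000 e⁻ well
  (valid above ~10⁴ photoelectrons). A Poisson option
  (`noise_model = "poisson"`) draws photon counts directly.

Geometry defaults are chosen once for realism and tractability: a 512×512
raw grid of 8.25 µm on-sample pixels (equivalent to a binned sensor;
4.22 mm field of view), 33 µm analysis pixels after the ×4 downsample, and
a 2 mm-radius window mask (a 4 mm cranial window). Everything is seeded
with per-trial sub-streams, so output is bit-reproducible and any single
trial can be regenerated independently; simulation helpers synthesize and
reduce one trial at a time so full sessions never hold the raw movie in
memory.

The phantom deliberately omits optical blur, vessel pulsation, motion,
slow hemodynamic drifts and spatially structured noise. Passing recovery
tests therefore demonstrates that the *pipeline arithmetic and
thresholding machinery* behave as specified at realistic SNR — not that
the pipeline is robust to every artifact of in vivo data.

With the default conditions, simulation shows the z = −3 route recovers
the blob center to well under one analysis pixel and the half-peak area to
within ±20% (the in-window z variant is centered on ratio ≈ 0.97; the
whole-image variant sits near ≈ 1.17 because of its deflated SD), and the
trial-accumulation curve crosses 50% of the final area by ~10 of 30 trials
under the whole-image convention — the behavior expected of
single-whisker maps. These statements are computed by the test suite and
the acceptance script, not assumed.

## Problem sizes and numerical edge cases

Simulation-based tests use the default 512×512/30-trial phantom for
recovery and accumulation claims (20 and 10 seeds respectively) and small
64–192 px phantoms for property tests; statistical calibrations use 1000
null MANOVA draws and 200 paired-t replicates. Edge cases are hard errors
with informative messages rather than silent coercions: fractional
averaging windows, a zero baseline pixel (reported with its location),
zero-variance maps in z-scoring, percent-of-peak on a map with no negative
in-window pixels, an empty all-trial map in the accumulation curve, and a
window circle entirely outside the image. Ties cannot occur in the 3×3
median; a pixel at exactly the mask radius is inside (`<=`); the realized
threshold is always recorded in $\Delta R/R$ units alongside the rule that
produced it.

## A small worked example

```{r example, eval = FALSE}
# synthesize a session at a reduced size, process it end to end
pc <- phantom_config(image_size = c(192, 192), noise_sd_frac = 0,
                     window_radius_mm = 0.75, n_trials = 2, seed = 1)
ph <- make_phantom_session(pc)
res <- process_session(ph$session,
                       spec = threshold_spec("percent_max", percent = 0.5),
                       overlay = FALSE)
res$area_mm2          # ~0.16 mm^2, the half-peak truth
ph$truth$true_area_mm2
res$ellipse           # center ~ (23.5, 23.5) analysis px
```

## Known limitations

* Single-wavelength reflectance only: no multispectral unmixing or
  oximetry, no hemodynamic deconvolution, no motion correction.
* Session alignment is integer-pixel translation; rotation between
  chronic sessions is not modeled.
* The automatic window fit is a convenience for well-lit, roughly
  centered windows; the user-supplied circle is authoritative.
* The 30 Hz acquisition variant is supported through the config (any
  frame rate whose windows are integral frame counts), but no claim is
  made about equivalence of results across frame rates.
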