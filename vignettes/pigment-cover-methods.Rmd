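---
title: "Measuring pigment cover: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pigment cover: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picover)
```

## The measurement problem

Chromatophores (and, in crustaceans, the multicellular chromatosomes
they form) change an animal's colour by translocating pigment granules:
concentrated pigment looks punctate, dispersed pigment spreads into
branched arbors. The classical quantification is the Hogben–Slome
chromatophore index (CI): each cell is assigned an ordinal class 1–5
and the region's CI is the class average. The CI has two structural
weaknesses. First, heavily dispersed cells overlap, so they can no
longer be counted or scored individually; by convention such regions
are scored CI = 5. Second, once *every* cell is in class 5 the index is
saturated, although the tissue can continue to darken as cover rises.

Pigment cover (PiC) sidesteps both problems by measuring the *area
fraction* of a region of interest occupied by pigment:

$$\mathrm{PiC} \;=\; \frac{\sum_i A_i}{A_{\mathrm{ROI}}} \in [0, 1],$$

where $A_i$ are the areas of the segmented pigment particles. It
requires no cell-by-cell decisions and does not saturate until the
region is literally full.

## Pipeline

`measure_pic()` runs, in order:

1. **ROI crop** (`crop_roi()`; `roi_physical()` converts a physical
   area such as 1 mm² into pixels via the µm/px pixel size, rounding
   the side to whole pixels).
2. **Optional contrast stretch** of the brightness plane
   (`enhance_contrast()`): the low/high clip values are the
   percentiles that leave at most `saturated_fraction/2` of pixels in
   each tail (the total is split equally between tails), then
   $[low, high]$ is mapped linearly to $[0, 255]$. A 1 % total
   saturation is the conventional light normalization. The stretch is
   monotone, so it never reorders pixel values.
3. **HSB conversion** (`srgb_to_hsb()`): standard hexcone model; hue is
   stored in a byte over the full circle. Achromatic pixels ($S = 0$)
   get hue 0 by convention; this never affects a band decision because
   chromatic selections always combine a hue band with a saturation
   floor.
4. **Thresholding**: an automatic algorithm picks a brightness cut
   from the histogram, expressed as an HSB band
   (`color_threshold_spec`), or the user supplies explicit `manual`
   bands. Either way the bands end up verbatim in the result object
   and the batch CSV, which is what makes a hand-adapted measurement
   reproducible after the fact.
5. **Particle analysis** (`label_components()`,
   `analyze_particles()`): connected components of the mask, default
   8-connectivity, default minimum size 1 px (no size filter), border
   particles kept.
6. **Cover** (`compute_pic()`): integer particle-area sum over integer
   ROI area.

### Foreground convention and the two pigment targets

All three automatic algorithms return a threshold $t$ with the fixed
convention *foreground = values strictly above $t$*. Dark pigment on a
white background is therefore expressed as a **pass band $[0, t]$** on
brightness — not by redefining the threshold — and light pigment on a
black background as the band $[t+1, 255]$. One convention, stated once,
rather than per-target sign flips.

### Threshold algorithms

* `threshold_isodata()` — iterative intermeans: iterate
  $t \leftarrow \mathrm{round}\big((\mu_{\le t} + \mu_{> t})/2\big)$
  from the midpoint of the occupied range until the value repeats. The
  update rounds half-*down*, which removes the 127/128 oscillation on
  symmetric two-spike histograms; iteration is capped at 256 steps
  (then an error, never a silent result). The returned value always
  satisfies the fixed-point condition checked by exhaustive scan in
  the test suite.
* `threshold_ij_default()` — the same fixed point initialised at the
  mean of the occupied extremes; exposed separately so a protocol can
  name the exact variant it used.
* `threshold_max_entropy()` — Kapur–Sahoo–Wong: maximise
  $H_{\le t} + H_{> t}$, the Shannon entropies of the two
  class-conditional normalized histograms (natural log; empty bins
  skipped, $0\log 0 := 0$; ties go to the smallest $t$). Computed for
  all 256 cuts, so it is exhaustive by construction.

**A known maximum-entropy caveat.** On *sharply* bimodal histograms —
two narrow peaks separated by an empty gap, which is exactly what a
noiseless synthetic scene produces — the entropy criterion can place
its cut at the edge of a mode rather than mid-gap, because splitting a
high-mass peak can yield more combined entropy than splitting the gap.
Real tissue photographs have broad histograms where this rarely
matters, but it is why the package's *default* method is the
intermeans `"default"` variant, with MaxEntropy available when a
threshold-quality check on the actual images favours it.

### Transparency

Transparency is measured on a chromatic background that does not occur
on the animal (green or blue): the fraction of pixels whose hue falls
in a band centred on the background colour *and* whose saturation is at
least 30 (default). The saturation floor is this package's addition:
without it, white or grey glare would count as background. The hue
bands default to ±18 bytes (~±25°) around the rendered background hues.

## Colour spaces

`srgb_to_lab()` performs the standard chain — IEC 61966-2-1 piecewise
gamma decode, linear RGB→XYZ (D65), XYZ→L\*a\*b\* against the D65 white
point, 2° observer, no ICC handling — so image linearization happens
inside the conversion. Byte packing is an internal convention: L\* maps
$[0,100] \to [0,255]$ and a\*/b\* are offset by 128. Conversions keep
full float precision internally and round half-away-from-zero once at
the end.

Because hue is stored in a single byte, inverting HSB back to sRGB can
move a fully saturated channel by up to 3 counts (the circle is
quantized to 256 steps of ~1.4°); the round-trip test asserts exactly
that quantization bound.

## The statistics layer

### Beta regression

PiC is a proportion, so the PiC~CI relation is modelled with a beta
likelihood parameterized by mean $\mu$ and precision $\phi$:
$y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with
$g(\mu) = \beta_0 + \beta_1 \cdot \mathrm{CI}$ and $g$ one of logit,
log, or log–log. "Log–log" is taken as $g(\mu) = -\ln(-\ln \mu)$, the
convention of the regression software this model family is associated
with; the AIC is $-2\,\mathrm{loglik} + 2 \cdot 3$ (three estimated
parameters), and the pseudo-$R^2$ is the squared Pearson correlation
between the link-transformed response and the linear predictor — both
stated explicitly because several conventions circulate.

Implementation choices:

* Maximum likelihood via BFGS with the analytic score, started from an
  OLS fit of the link-transformed response **on the fit's own link
  scale** plus a method-of-moments precision. (A logit-scale start for
  the log link routinely lands outside the log link's feasible region,
  where fitted means exceed 1 and the likelihood is undefined; an
  own-link start is feasible by construction.) A second BFGS pass from
  the optimum polishes convergence; fits are deterministic, so
  refitting the same data reproduces the log-likelihood to better than
  $10^{-8}$.
* Responses at exactly 0 or 1 are shrunk by
  $y^* = (y(n-1) + 0.5)/n$ — the standard boundary adjustment, since
  the beta likelihood is undefined at the boundaries — with a message.
* $\phi$ is a single scalar; no precision covariates.

The published dark-pigment calibration
$\ln(\mathrm{PiC}) = -3.362 + 0.659\,\mathrm{CI}$ is exposed as
`predict_pic_from_ci()`, valid on $1 \le \mathrm{CI} \le 5$ only —
outside that domain the function refuses rather than extrapolates.
Parameter-recovery simulations (`simulate_beta_recovery()`; 200
replicates of $n = 50$, $\phi = 200$, CI uniform on the half-integer
grid) recover the slope to within 0.03 and the intercept to within
0.15 on average, which is the package's evidence that the fitting
layer would reproduce a calibration of this form from data of the
published study's size.

### Rank statistics

`friedman_test()` applies mid-ranks within blocks and divides the
chi-square statistic by the tie correction
$1 - \sum (t^3 - t) / (nk(k^2-1))$ (base R's version omits this, which
is why the statistic is implemented here). A table whose blocks are
all fully tied but which is not constant returns $\chi^2 = 0$;
a constant table is an error. `wilcoxon_signed_rank()` drops zero
differences, mid-ranks the rest, and reports
$Z = (W - \mu_W)/\sigma_W$ with tie-corrected variance and **no
continuity correction** — the form under which a five-pair,
all-positive-differences sample gives $Z = 7.5/\sqrt{13.75} = +2.023$.
An exact sign-flip permutation p-value is available via `exact = TRUE`
for $n \le 20$.

## The synthetic scene generator

`render_scene()` is the package's ground-truth instrument. It emulates
the kind of image the measurement protocol expects — pigmented
chromatosomes on a uniform coloured backdrop, photographed with camera
noise — not any particular species' anatomy:

* A chromatosome is a **core disk** (radius $0.25 r$) plus, for
  classes 2–5, $n$ tapered radial rays of length
  $\{0.45, 0.65, 0.85, 1.0\} \times r$. Ray width tapers linearly from
  the core radius to 1 px at the tip. With centre and rotation fixed,
  the class-$k$ footprint is a strict subset of the class-$(k{+}1)$
  footprint, so cover is strictly monotone in dispersion class — the
  property that makes class sweeps meaningful. (Rays alone would not
  nest against the class-1 disk; the shared core is what guarantees
  it.)
* Backgrounds are white (255,255,255), black (0,0,0), green (0,170,0)
  and blue (0,90,200); the chromatic two are strongly saturated so hue
  bands can select them. Pigment defaults to black.
* The pigment mask — and hence `cover` — is frozen **before** noise;
  i.i.d. Gaussian noise (default σ = 8 grey levels, a realistic
  consumer-camera value) is added per channel afterwards, rounded and
  clamped. Identical `scene_spec`s give byte-identical images; batch
  generators derive one seed per scene from (master seed, index).

`simulate_ci_pic_dataset()` runs the full pipeline (HSB → MaxEntropy
brightness threshold → particles → PiC) over scenes spanning classes
and densities, at 128×128 px and ~4–28 chromatosomes of base radius
12 px per scene — sizes chosen so a 50-scene batch renders and measures
in seconds while leaving dozens of particles per scene.

### What passing on synthetic scenes does and does not show

The generator reproduces: bimodal pigment/background contrast, overlap
between neighbouring chromatosomes, dispersion-dependent footprints,
additive sensor noise, and border-straddling cells. It does **not**
reproduce: uneven illumination (available as an option, off by
default), shadows and glare, translucent tissue tinting, pigments of
intermediate colour, or optical blur — so a clean pass here validates
the *algorithmic* chain (segmentation arithmetic, labelling, cover
accounting), not robustness to difficult photography. Note also that
the simulator's geometric class→cover relation is not the exponential
CI→PiC law seen in real tissue, so simulator tables are not expected
to prefer the log link; the link-selection check instead simulates
from the fitted statistical model itself.

Two qualitative phenomena of the CI are reproduced by construction and
asserted in tests: cover keeps varying (0.5 → >0.9) across dense
scenes whose every chromatosome is class 5 (CI saturation), and
measured PiC rises strictly with class at fixed centres.

## Degenerate inputs and numerical conventions

* Histograms with fewer than two occupied bins cannot be thresholded
  (error, not a guess); empty masks histogram to an error.
* A constant channel cannot be contrast-stretched: returned unchanged
  with a warning.
* Intermeans updates round half-down; channel byte packing rounds
  half-away-from-zero; both stated so results are bit-reproducible.
* A hue band covering the full circle "selects everything" and is
  rejected in transparency measurement.
* ROIs are 0-based, row-major, half-open; bounds violations name the
  offending edge.
* Alpha channels in input files are rejected (a pixel must be tissue
  or background, not partially either).

## Known limitations

* 8-bit channels throughout, by design parity with 24-bit RGB
  processing; 16-bit sources must be downscaled before import.
* No ICC colour management; the Lab conversion assumes well-behaved
  sRGB input.
* The maximum-entropy threshold's mode-edge behaviour on near-delta
  histograms, discussed above.
* `measure_transparency()` treats tinted-but-translucent pixels as
  not-background as soon as their hue leaves the band; a per-pixel
  partial-transparency model is out of scope.
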