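---
title: "Quantifying colony-level phenotypic heterogeneity with colonyhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colony-level phenotypic heterogeneity with colonyhet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyhet)
```

## The biological setting

Methionine-auxotrophic lactic acid bacteria acquire methionine through
transporters of different affinity. When a high-affinity methionine
transporter operon is reported by a promoter-GFP fusion, colonies grown on
defined agar at low methionine split into two stable classes: GFP+ colonies
that strongly express the transporter and GFP− colonies that rely on a
low-affinity uptake route. The fraction of GFP+ colonies is roughly 45% at
the lowest methionine concentrations and falls steeply to zero at high
concentrations. Because expression states are inherited for tens of
generations, switching between states is rare and shows up as angular
*sectors* within otherwise homogeneous colonies — under 3% of colonies at the
lowest concentration, declining with dose.

`colonyhet` packages the quantitative half of such an experiment: a seeded
synthetic plate generator with exact ground truth, an automatic
colony-detection pipeline, GFP+/GFP− classification, dose–response and
switching-rate curve fits, rank tests, flow-cytometry gating, and
generation-number estimation — all reproducible from one master seed.

## The synthetic-data model

No public image set accompanies the colony experiments, so the generator is
a first-class module: every downstream stage is validated against its
sidecar ground truth.

**Dose–response truth.** The probability that a colony is GFP+ is a logistic
decline

$$p_+(x) = \frac{a}{1 + e^{k\,(x - x_0)}},$$

with plateau $a = 0.45$, midpoint $x_0 = 0.75$ mM and steepness
$k = 10\,\mathrm{mM^{-1}}$. The plateau equals the observed low-dose GFP+
fraction; the published steep-step parameterization is ambiguous on an mM
axis (see *Axis transforms* below), so the generator uses this analytically
well-behaved form whose low- and high-dose limits match the observations.
The sector (switching) probability is an exponential decline

$$p_s(x) = \min\!\left(e^{-\alpha (x - \beta)},\; p_{\max}\right),$$

with $\alpha = 1.34\,\mathrm{mM^{-1}}$ (the published fitted decay rate),
$\beta = -2.7279$ mM chosen so that $p_s(0.025\,\mathrm{mM}) = 2.5\%$ —
strictly below the reported sub-3% rarity — and a safety clamp
$p_{\max} = 0.03$.

**Colonies.** Phenotypes are i.i.d. Bernoulli$(p_+(x))$. Colony mean
fluorescence is log-normal per phenotype (defaults: medians 10,000 and
20,000 a.u. on the 16-bit scale, log-sd 0.12 — about a 5.8-sigma separation
of the log-modes, giving a visibly bimodal colony intensity histogram with
~0.2% intrinsic class overlap). Diameters are normal, truncated positive:
GFP+ colonies default to 2.0 mm while GFP− colonies grow from 1.8 mm toward
2.2 mm as methionine increases, reproducing the slight GFP+ size advantage
at low dose and large GFP− colonies at high dose. Sectored colonies carry a
wedge of 40–180° drawn at an intensity sampled from the *opposite*
phenotype's component.

**Rendering.** Colonies are disks with a flat interior and a cosine edge
taper whose width is 15% of the radius, *centered on the nominal radius*:
the half-intensity contour of a rendered colony therefore sits exactly at
the ground-truth radius, which makes threshold-based detection unbiased by
construction rather than by calibration. Centers are placed by rejection
sampling with a hard minimum center distance (60 px) exceeding twice the
largest expected radius, so colonies never merge; this mirrors the analyzed
experiments, where merged colonies were discarded during curation rather
than split. A linear background gradient (20% across the field), Gaussian
pixel noise (sd 200 a.u. on a 500 a.u. background) and a Poisson number of
artifact blobs complete the image. Artifacts are persistent-direction
random-walk strands confined to a small box — elongated debris with
circularity far below 0.6, there to exercise the shape filter.

**What the generator does not emulate** — and hence what passing tests do
not establish about real plates: uneven illumination beyond a linear
gradient, out-of-focus or touching colonies, agar texture, autofluorescence
halos, camera vignetting, and sectors with non-radial geometry. The
detection pipeline's recall/false-discovery figures quantify performance
under the generator's assumptions, not under arbitrary microscopy
conditions; the manual-curation path exists precisely because real images
violate them.

**Seeding.** One master seed lives in the configuration; each plate's
population and rendering noise use streams derived by fixed integer
splitting, so any plate can be regenerated independently and
bit-identically.

## Colony detection

Detection follows the classical five-step scheme: binarize; remove wrongly
segmented regions by size and shape; fit circles; annotate switching;
summarize.

1. **Binarization.** A pixel is foreground iff its normalized intensity is
   ≥ the threshold. The automatic threshold is Otsu's two-class
   variance-maximizing criterion applied to the *log*-intensity histogram
   and mapped back to the intensity scale. Fluorescence spans a
   multiplicative range; on the raw histogram the dominant background class
   can push the two-class optimum up into the dim-colony mode (on fixture
   plates this swallowed the dimmest GFP− colonies entirely), while in the
   log domain the background/colony split is the stable optimum.
2. **Regions.** Foreground is labeled with 8-connectivity. Area, centroid,
   bounding box and perimeter are measured per region; the perimeter comes
   from a Moore boundary trace with edge-weighted steps (1 orthogonal,
   $\sqrt2$ diagonal). Circularity $4\pi A / P^2$ is clamped at 1.05
   because the digital estimator slightly exceeds 1 on small round shapes.
   Defaults keep regions with area in $[\pi 5^2, \pi 150^2]$ px²,
   circularity ≥ 0.8, and a 5 px border margin; each removal is logged with
   its reason.
3. **Circle fit.** An algebraic least-squares (Kåsa) fit to the traced
   boundary — one linear solve, exact on true circles. Half a pixel is
   added to the radius because boundary pixel *centers* sit on average half
   a pixel inside the true contour. Fits with radial RMS residual above
   15% of the radius are flagged `poor-fit`.
4. **Radius refinement and sector score.** The reported radius is refined
   to the half-maximum crossing of the radial intensity profile: the
   thresholded footprint depends on where the threshold happened to fall on
   the edge taper (up to ~1 px bias for bright colonies), whereas the
   half-intensity radius is threshold-independent and matches the
   generator's radius convention. The sector score divides the disk into 36
   angular bins and computes the contrast
   $(\max - \min)/(\max + \min)$ of the bin means; a colony is flagged
   sectored when the score reaches 0.3 *and* the above-midline bins form
   one contiguous arc covering 10–90% of the circle. A 2× intensity wedge
   scores $(2-1)/(2+1) = 1/3$; scattered speckle fails the contiguity
   rule. With the default intensity model the wedge/base contrast is itself
   log-normal, so roughly a third of true sectors fall below the 0.3
   threshold — automatic sector calling is deliberately conservative, which
   matters when comparing its output to a rarity *bound*.
5. **Curation and summary.** A curation table (keep / remove /
   sector_true / sector_false per colony id) reproduces the manual
   inspection step, with every override recorded in the QC flags. Each
   retained colony is summarized by center, radius, diameter in mm
   (2 × radius × pixel size), and mean fluorescence over the fitted disk.

On 20 default fixture plates the pipeline attains recall ≥ 0.95 (measured:
1.00) and false discovery ≤ 0.02 (measured: 0.00), with matched radii
within ±0.15 px of truth.

## Classification and dose–response statistics

**Mixture threshold.** Colony mean fluorescences at the lowest
concentration are pooled and log-transformed; a two-component Gaussian EM
(best of 10 seeded restarts) yields the classification threshold at the
posterior-0.5 crossing between the component means. A fit is *degenerate* —
one mode only — when a weight falls below 0.02 or the means are closer
than 3 joint standard deviations. The 3-sigma overlap rule was calibrated on simulated
data: EM fits to genuinely unimodal samples separate their split means by
up to ~2.6 joint sds (occasionally collapsing a narrow spurious component
onto a few points), while resolvably bimodal colony data sits above 5. For
degenerate fits a configurable fixed threshold is used instead, mirroring
the fixed demarcation line drawn in the original analysis.

**Step fit.** The GFP+ fraction versus concentration is fitted by
$y = a - a/(1 + e^{-k(t(x) + b)})$ with $k$ fixed at 100. For fixed $b$
the model is linear in $a$, so the fit profiles $a$ out and searches $b$
on a fine grid with local refinement — a generic gradient optimizer stalls
on this objective, which is flat except within ~1/k of the step. Standard
errors come from the Jacobian at the optimum,
$\mathrm{se} = \sqrt{\mathrm{diag}\left(\frac{RSS}{n-p}(J^\top J)^{-1}\right)}$,
with two-sided *t* tests of each parameter against zero. When no data point
lies on the transition the derivative in $b$ is numerically zero everywhere
and `se_b` is reported as `Inf` rather than a fabricated finite value.

**Axis transforms.** The published parameter values for both the step fit
and the switching-rate fit are inconsistent with a linear mM axis under the
printed formulas (the printed step offset puts the transition at negative
concentration; the printed exponential exceeds 1 below 6.4 mM). Rather than
guessing the intended axis, both fits expose a configurable transform
(identity, log10, negation) with identity as the default, and always report
which transform was used.

**Switching fit.** The sectored fraction versus concentration is fitted by
$y = e^{-a(t(x) - b)}$ via Levenberg–Marquardt least squares, started from
a log-linear regression on the positive fractions with a small multi-start
fallback. A constant input returns the flat limit $a = 0$ (with $b$
undefined, since only $a\,b$ is identified as $a \to 0$).

**Rank tests.** Group comparisons (e.g. GFP+ vs GFP− colony diameters) use
the two-tailed Mann–Whitney U test with midranks; the p-value is exact when
the pooled sample size is at most 20 and tie-free, otherwise a normal
approximation with tie and continuity corrections. Exhaustive comparison
against enumeration shows the corrected approximation within 0.02 of exact
wherever both groups have ≥ 5 observations; below that it deviates by up to
0.088 (at $n_1 = n_2 = 2$), which is why the exact path is the default for
small samples.

**Generations.** A colony founded by one cell that grew to $X$ cells has
$n = \log X / \log 2$ generations; $X$ scales the counted flow-cytometry
events by the analyzed fraction of the resuspension volume (conventionally
120 of 400 µL). The estimate is exactly log2-linear: doubling $X$ adds one
generation.

**Plate-reader normalization.** Reporter signal is background-corrected and
divided by background-corrected OD600; points whose corrected OD does not
exceed a floor (default 0.01) are masked rather than producing unstable
ratios.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based `(row, col)`; circle centers are
  fractional.
* A constant image cannot be auto-thresholded (error); an explicit level is
  always honored, with ≥ as the inclusion convention everywhere.
* Circle fits need ≥ 3 non-collinear boundary points; collinear input is a
  degenerate-fit error, not a huge circle.
* The EM floors component sds at 10⁻⁶ log-units and declares rather than
  hides degeneracy; classification requires a positive finite threshold.
* All-zero GFP+ fractions step-fit to $a = 0$; all-zero sector fractions
  are an explicit "no decline to fit" error.
* The 16-bit image writers never rescale: TIFF via the `tiff` package and
  PNG via a built-in minimal 16-bit grayscale encoder (the `png` package
  writes at most 8 bits per sample); both round-trip bit-identically.

## Problem sizes used by the test-suite reproductions

The packaged checks rerun the science at reduced scale, chosen as the
smallest sizes at which the binomial sampling error is comfortably inside
each tolerance: plateau recovery refits 25 binomially sampled dose–response
replicates (300 colonies per concentration); the end-to-end GFP+ fraction
pools 12 simulated plates of ~80 colonies; the sector bound pools 20
plates; decay-rate recovery refits 25 noisy replicates of the switching
curve. Switching fractions for the decay refit carry Gaussian measurement
noise (sd 0.002) rather than binomial counts: at realistic colony numbers
(~400 per concentration) most grid fractions are below 1/400 and the count
data leave the decay rate essentially unidentified — a caveat that applies
equally to fitting real sector counts.

## Known limitations

* Merged or touching colonies are rejected by the circularity filter, not
  split; the generator's hard-core placement means this path is untested on
  merged inputs beyond rejection.
* Automatic sector calling undercounts switches whose intensity contrast is
  small; it is a lower bound, with curation as the corrective.
* The mixture threshold assumes log-normal intensity components; heavily
  skewed or multi-modal populations should use a fixed threshold.
* The steep-step fit treats $k$ as known and fixed; it quantifies the
  plateau and transition location, not the transition width.
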