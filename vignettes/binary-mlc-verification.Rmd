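---
title: "Verifying binary-MLC motion from scintillator video: models and methods"
author: "scintQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying binary-MLC motion from scintillator video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
measurement model, the calibrations, the reconstruction, the simulator that
stands in for the real hardware, and the numerical decisions taken where
the method description leaves the design open.

## 1. The measurement and its data model

A helical tomotherapy delivery is controlled by a sinogram: `P x 64` leaf
open fractions in `[0, 1]`, one row per 294.12 ms projection (51
projections per 15 s gantry rotation).  The QA measurement films a 20 cm
diameter plastic scintillator at the isocenter with a camcorder: 8-bit
640 x 480 grayscale frames at 29.97 fps, 0.468 mm/pixel.  Each leaf maps
to a ~13.35 px wide strip; a 5 x 5 px ROI sits at the centre of each strip
on the horizontal diameter.  Only leaves 18-47 fall on the scintillator.

Photometry follows three elementary relations: the per-frame ROI light is
the ROI mean minus the dark level `BG` (default 0.36 pv, the beam-off ROI
mean; it is *not* clipped at zero, so noise propagates symmetrically); the
accumulated light `Q` is the plain sum over frames; the centre reference is
the mean of leaves 32 and 33, which flank the isocenter.  For a rotating
delivery every frame is rotated back to the 0-degree reference by its
recorded gantry angle before the (fixed) ROIs are read.  The back-rotation
is implemented as bilinear sampling of each ROI pixel at its
forward-rotated position - mathematically the same operation as rotating
the image, restricted to the pixels actually read - with out-of-image
samples reading as `BG`.

## 2. Calibrations

Four calibrations turn ROI light into leaf open times:

* **Open-time line.**  Static exposures of the 10 cm centre field
  (leaves 25-40) over open times 29.41-294.12 ms give an ordinary
  least-squares line `Q = slope * t + b`.  The line keeps an intercept:
  nothing in the measurement forces it through the origin, and the
  intercept absorbs small systematic offsets (dark frames in the exposure
  window, quantization bias).  The inverse map clips negative predictions
  to zero.
* **Lateral correction `k1`.**  One exposure per observed leaf, opened
  alone for 294.12 ms.  `k1[j]` is the inverse of the per-leaf light
  normalized at leaf 32; it flattens the response of the cylindrical
  detector (no flattening filter, depth differences).  `k1[32] = 1` by
  construction.
* **Drift correction `k2`.**  A long constant exposure; the per-frame
  centre light is averaged in 10 s windows and normalized at the 100 s
  bin, and `k2` is the inverse, piecewise constant over bins (the method
  description gives no interpolation rule; constant bins are the least
  committal choice).  Exposures must reach the normalization point.
* **Field-size factors.**  Centred apertures of n = 1..28 leaves give the
  centre and field-edge per-frame light (edge = mean of the two closed
  ROIs flanking the aperture).  These are diagnostics: the open/closed
  threshold is deliberately a single global value.

The corrected light is `qc = q * k1 * k2`, applied per leaf and per frame.

## 3. Reconstruction and scoring

Corrected light is accumulated per projection, classified open when
strictly greater than the threshold `Th` (a value equal to `Th` is
closed), and converted to open time through the inverse calibration line,
expressed as a fraction of the projection duration and clipped to `[0, 1]`
(scatter can push a wide open field above the full-open calibration).
`Th` is swept over integer pixel values 0-100 - the relevant printed
operating points are integers in this range - and chosen by the maximum
Youden index `J = sens + spec - 1`; ties break toward the smallest
threshold, which preserves the ability to detect single-leaf openings
whose light (29.1 pv/frame) is far below a wide field's.

Classification compares the *per-projection mean per-frame* corrected
light against `Th`, which makes the threshold directly comparable to the
printed per-frame anchor values; a per-frame classification mode is also
provided.

Scoring restricts to the observed leaves: sensitivity (open bins detected
open), specificity (closed detected closed), the relative-error map
`(recon - truth) / max(truth in projection) * 100`, its mean +/- population
SD (the *leaf open error*), the fraction of bins within +/-3 %, and a
signed histogram in 1 % bins (bin width unstated in the source material;
1 % matches the printed integer thresholds' resolution).  Degenerate
truths - no open or no closed bins - give `NaN` rates with a warning
rather than an arbitrary number; the all-open simple pattern therefore has
no specificity, and the threshold for it must come from elsewhere (the
ROC of a modulated plan, or the documented 44 pv operating point).

### Frame-to-projection attribution

A projection lasts 8.81 frame periods, so roughly every ninth frame
straddles a projection boundary.  Three accumulation schemes are provided:

* `"midpoint"`: whole frames go to the projection containing their
  midpoint.  Simple, but a full-open projection then accumulates 8 or 9
  whole frames instead of 8.81 - a ~9 % sawtooth that dwarfs the 2 %
  fidelity the rest of the pipeline supports.  Kept as an option because
  of its transparency.
* `"overlap"`: boundary frames are split in proportion to the time
  overlap, normalized by the frame's overlap with the delivery window (so
  a frame extending past the delivery end still gives all its light to the
  last projection).  Exact when emission is uniform across the frame, but
  biased when an opening abuts a boundary on one side only.
* `"gated"` (default): exploits the gating structure.  Leaf openings are
  centred within their projection (the simulator's convention, stated
  below), so a straddling frame can hold only the *tail* of the earlier
  opening and the *head* of the later one.  Frames fully inside a
  projection fix the interior open time; a forward sweep then resolves
  each boundary frame in order - the tail is determined by the
  already-resolved earlier projection, and the head is the measured frame
  light minus that tail.  Noise-free this recovers open times exactly (up
  to 8-bit quantization), and light is conserved frame by frame.

The choice matters: the package's round-trip property (scatter-free,
noise-free simulations reconstruct any plan within 0.02 open-fraction
units with a perfect confusion matrix) holds under `"gated"`, and is what
the test suite asserts.

## 4. The forward simulator

No video of the original measurements is available, so the simulator *is*
the measurement for every test.  It renders, per frame, a separable light
pattern in the gantry frame - a column profile over leaf strips times an
exponential attenuation along the beam path, masked to the scintillator
disc - rotated to the frame's gantry angle by evaluating the pattern at
back-rotated coordinates (no forward resampling error).  Per frame, each
leaf contributes in proportion to the fraction of the frame window it was
open.  Gaussian pixel noise and the dark level are added everywhere, the
image is quantized to 8 bits (round half away from zero, clipped at 255),
and transient artifacts - saturated discs of radius 2-5 px at uniform
positions - are injected with probability 0.002 per frame.

Model parameters, defaults, and their provenance:

| parameter | default | why |
|---|---|---|
| gain | 29.1 pv/frame | single-open-leaf own-ROI light, printed anchor |
| scatter kernel | `0.073 * exp(-d / 22.2)` | least squares on the four light anchors plus the 0.48 single-leaf output factor |
| lateral profile | quadratic, 0.90 at leaves 18/47 | the published profile figure shows a slight symmetric slope but prints no numbers; 10 % end-of-range drop is a representative choice |
| drift | 1.01 at 0 s, linear to 0.99 at 300 s | the published stability curve starts slightly above 1 and decays; ~2 % over 300 s matches its visual scale |
| BG | 0.36 pv | printed dark level |
| pixel noise | sd 0.5 pv | not quantified in the source; chosen so dark frames dither the 8-bit quantizer without masking single-leaf light |
| transient rate | 0.002/frame | 18 artifacts in 9000 frames |
| attenuation | 0.05 /cm | ~6 MV effective attenuation in plastic; breaks the half-turn symmetry the angle tracker needs |

The five light anchors over-determine the two kernel parameters and are
not mutually consistent with any monotone single-scale kernel (the edge
light at 24 open leaves implies a heavier tail than the centre saturation
allows), so the fit keeps residuals of a few pixel values; they are stored
in the calibrated model and checked only against a loose guard (8 pv)
whose purpose is to catch degenerate fits, not to claim the anchors are
reproduced exactly.  The gain anchor *is* exact by construction.

**Gating convention.**  The controller's intra-projection timing is not
specified in the source material; the simulator opens each leaf centred
within its projection window, the natural choice for a system synchronized
to the gantry.  The gated accumulation above is the measurement-side dual
of this convention.

**What the simulator does not emulate.**  Radiation transport, Cherenkov
physics, couch motion (excluded by design), camera vignetting or gamma,
interlacing, rolling shutter, gantry-angle jitter (angles are exact unless
a wobble is injected), and the true - unpublished - per-ROI field-size
curves.  Passing round trips therefore demonstrate the *pipeline's*
internal consistency and noise robustness, not hardware-level accuracy;
conversely the scatter model reproduces the method's characteristic
failure mode (closed leaves glowing above threshold beside wide fields,
small openings hiding below it), which is what makes the simulated
clinical verification informative.

## 5. The synthetic plans

`simplePattern()` opens every observed leaf fully for 133 projections.
`clinicalPattern()` is a statistical stand-in for a modulated prostate
plan: a contiguous aperture whose centre drifts sinusoidally across the
observed range, a smooth cross-leaf shape, log-normal per-leaf jitter,
clipping to `[0.07, 1]` (0.07 of a projection is about the 20 ms clinical
minimum open time), and an affine rescale of the open fractions - iterated
against the clipping - until the modulation factor (max over mean open
time, nonzero bins) is within 1 % of the 1.649 target.  Averaging over
nonzero bins only keeps the factor independent of how many leaves never
open; the alternative is available as an option.  The generator is
seed-deterministic.

## 6. Gantry rotational stability

A single central leaf is held open while the gantry rotates (15-60 s per
revolution).  The stripe through the isocenter is sampled on a ring
(default three-quarters of the largest ring that fits the image) in
0.2-degree steps; the edge that passes through the isocenter is the 50 %-
of-maximum crossing on the leading side of the brightest lobe.  Beam
attenuation across the scintillator makes the entry side brighter,
resolving the half-turn ambiguity of a diameter-shaped stripe.  Angles are
unwrapped assuming less than a half turn between frames (true for all
supported speeds at 29.97 fps) and fitted with a least-squares line;
residuals are taken against the theoretical `360/period` line with a free
phase.  Whether the published tracking used the leading or trailing edge
is not stated; the leading edge is used, and any constant offset is
absorbed by the free phase, leaving the speed and residuals unaffected.

## 7. Numerical choices and degenerate inputs

* 8-bit quantization rounds half away from zero and clips at 255; the
  0.36 pv dark level quantizes to 0 in noise-free renders, which the
  calibration intercept absorbs.
* ROC tie-breaks go to the smallest threshold; Youden values are rounded
  at 1e-12 before the argmax so floating-point noise cannot break ties.
* `predictOpenTime` clips negative open times to 0; reconstructed
  fractions clip at 1.
* Empty stacks (recordings shorter than one frame period) warn rather
  than error; tracking skips beam-off frames with a warning; apertures
  whose flanking ROI falls outside the observed range lose that edge with
  a warning.
* All leaf indices are 1-based (leaf 18-47 as in the field's usage);
  projection indices are 1-based in every R interface.
* Sinogram CSVs are written at full precision so write-read round trips
  are bit-identical.

## 8. Problem sizes

The test suite runs most pipeline checks on a reduced canvas (200 x 200 px
images, observed leaves 26-39) - the machine-side timing is untouched -
and the acceptance-style checks at the full 640 x 480 geometry with the
133-projection simple pattern, a 40-projection modulated plan, four
rotation periods, and 20 x 9000 frames of artifact counting on a small
canvas.  The acceptance script shortens the drift-calibration exposure to
120 s: the correction only needs to span the 100 s normalization point
plus the 39 s delivery.  These are the package's chosen problem sizes for
routine runs; all full-scale settings remain available as arguments.

## 9. Known limitations

* The scatter kernel is phenomenological and anchor-fitted; per-ROI
  field-size curves were never published, so absolute specificity and
  leaf-open-error figures from the simulator characterize the model, not
  the hardware.
* The simple all-open pattern has no closed observed bins, so its
  specificity is undefined here; the published nonunit specificity for
  that pattern cannot be reproduced under this data model and is not
  targeted.
* The gated accumulation assumes centred openings; a controller with
  different intra-projection timing would need the dual rule.
* A single global threshold is used by design; per-field-size adaptive
  thresholds are out of scope.
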