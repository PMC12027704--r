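---
title: "Color fidelity assessment for dermatological imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color fidelity assessment for dermatological imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromacal)
```

## The problem

Dermoscopic diagnosis leans heavily on color: melanin browns, blue-gray
veils, and erythema reds separate benign nevi from melanoma, and subtle hue
shifts matter clinically. Consumer cameras, smartphones, and even
professional dermoscopy systems each impose their own color rendering, and
dermoscope LED illumination is often spectrally poor, so the same lesion can
photograph very differently across devices. `chromacal` implements the
quantitative side of a color quality-control workflow for this setting:

1. measure a 24-patch ColorChecker photograph and summarize per-patch color
   deviations (CIELAB and CIEDE2000 metrics);
2. score a light source's quality from its spectral power distribution
   (correlated color temperature, color rendering index, and a
   television-style camera/display consistency score);
3. calibrate captures against a neutral gray card (white-balance gains and
   exposure), and recommend manual camera settings for a given source;
4. generate all of the above inputs synthetically, with known ground truth,
   so the entire pipeline is testable end to end.

## Color spaces and difference metrics

Measured sRGB values are decoded with the standard piecewise transfer
function, mapped to XYZ by the fixed sRGB matrix, and converted to CIELAB
under D65 (2-degree observer). The D65 white point is taken as the image of
RGB = (1,1,1) under the sRGB matrix, so pure white maps to exactly
(100, 0, 0). Per patch the package reports:

- `dE76`: the Euclidean distance in CIELAB,
  $\Delta E^* = \sqrt{\Delta L^{*2} + \Delta a^{*2} + \Delta b^{*2}}$;
- `dC76`: the chroma difference $\Delta C^* = C_1^* - C_2^*$ with
  $C^* = \sqrt{a^{*2} + b^{*2}}$, returned signed and summarized as a
  magnitude;
- `dL`: the signed lightness difference;
- `dE00`: the full CIEDE2000 difference with the `SL/SC/SH` weighting
  functions and the blue-region rotation term, verified against the
  standard 34-pair verification set to better than $10^{-4}$;
- `dC00`: a CIEDE2000 chroma difference. The literature rarely defines this
  term explicitly; this package defines it as the chroma component
  $|\Delta C'|/(k_C S_C)$ of the CIEDE2000 formula, computed from the same
  primed-chroma intermediates as `dE00`, so it is always bounded by `dE00`.

Parametric weights default to $k_L = k_C = k_H = 1$, the graphic-arts
setting. (Some descriptions of the normalized CIELAB space give b* a range
of -100..10; the package treats the upper bound as the conventional 100,
reading the 10 as a misprint.)

## Chart measurement

The packaged reference values are the *classic* (pre-2015) 24-patch set,
stored under their native D50 illuminant and adapted to D65 with the
Bradford transform, since camera sRGB output is interpreted under D65. The
vintage matters: post-2014 charts have slightly different values, and a
user CSV can replace the packaged set. One quirk of the classic set worth
knowing: the cyan patch (18) lies slightly outside the sRGB gamut, so any
sRGB rendering of it clips; the package flags this rather than hiding it.

Patch regions come from either path:

- **corner hint (reference behavior):** four chart corners define a
  homography from the canonical 4 x 6 grid; deterministic and exact.
- **automatic detection:** the bright patches are segmented from the dark
  chart grid by a luminance-threshold search; a threshold is accepted only
  if it produces exactly 24 compact, similarly sized components that
  organize into 4 rows of 6 *and* account for at least 98% of the
  foreground pixels (this last condition rejects thresholds inside the
  background noise band, which otherwise attach single-pixel halos to the
  patches). Anything else raises "chart not found"; a partial silent result
  is never returned.

Each patch is sampled on its central area -- the region shrunk by a margin
fraction of 0.25 per side, i.e. the central half of each dimension -- with
a 10% two-sided trimmed mean per channel. The margin avoids edge bleed and
the trim absorbs specular outliers and dust; both are configurable. Because
dermoscope optics restrict the field to a single patch, the same
measurement can be assembled from 24 individual captures
(`assemble_single_patch_table()`), and the two acquisition paths agree to
within one 8-bit count on identical synthetic content.

Summaries report average, minimum and maximum per metric along with the
patch index attaining each extreme, over an optionally reduced patch set
(saturated primaries are uncommon in clinical imagery, so excluding, say,
patches 1, 10, 13 is supported and only ever shrinks the min-max interval).

## Light-source scoring

All spectral computation runs on a canonical 5 nm grid over 380-780 nm.
Measured SPDs are linearly interpolated onto it; synthesized Planckian and
daylight curves are evaluated analytically. Normalizing a curve to 1.0 at
555 nm is presentation only -- every index is scale invariant.

**CCT and Duv.** Tristimulus values come from the packaged CIE 1931
2-degree color-matching functions; the correlated color temperature is the
Planckian radiator nearest in the 1960 uv diagram, found by Robertson's
isotemperature-line construction on a dense locus table (1-mired steps,
computed at load from Planck's law through the same observer, so the
method is fully self-consistent with the packaged data). `duv` is signed
positive above the locus; note that with these conventions the equal-energy
spectrum sits *below* the locus (duv about -0.0044) while daylight sits
above (+0.0032 at D65). Sources beyond |duv| > 0.05 are flagged as having
no physically meaningful CCT.

**CRI.** The test-sample method: each of 14 reflectance samples is rendered
under the source and under the reference illuminant at the source's CCT
(Planckian below 5000 K, the daylight series at or above), the test
renderings are chromatically adapted with the von Kries correction in the
1960 uv diagram, differences are taken in U\*V\*W\*, and
$R_i = 100 - 4.6\,\Delta E_{UVW,i}$ with $R_a$ the mean of the first
eight. Two caveats are deliberate and documented:

- The official test-color reflectance tabulation is not shipped. The
  packaged samples are *synthetic stand-ins*: CIELAB anchors spanning the
  official set's character (eight moderate-chroma hues around the circle,
  four saturated colors, a skin tone, a leaf green), converted to maximally
  smooth reflectance curves (see below). Every analytic limit -- a source
  identical to its reference scores exactly 100, narrowing emission bands
  monotonically lowers Ra -- holds for any reflectance set, and those are
  the properties the tests pin down. Absolute Ra values for narrowband
  sources, however, depend on the sample set and should be read as
  package-internal, not as official CRI values.
- The reference rule is discontinuous at 5000 K by construction: a daylight
  curve synthesized at nominally 5000 K has a computed CCT a hair below
  5000 K and is therefore compared against a Planckian reference, scoring
  about 98 rather than 100. This is the standard's own crossover behavior,
  not an artifact.

**Television-chain score.** Where the CRI asks how colors look to an
observer, this score asks how faithfully a camera-plus-display chain
reproduces them. The package implements its own documented model chain:
Gaussian R/G/B camera sensitivities (peaks 600/535/460 nm), per-channel
white balance against the illuminant, a fixed 3 x 3 matrix to display
primaries (least-squares fitted once over the 24 patches under D65, rows
normalized to preserve white), clipping to the display gamut, and CIELAB on
a Rec. 709-primaries display. The 24 chart patches are imaged under the
test source and under the reference illuminant at the test CCT through the
*same* chain; the mean CIEDE2000 between the two renderings maps to
$Q_a = 100 / (1 + (\overline{\Delta E_{00}}/3.5)^2)$. The reference is
Planckian below 4000 K, daylight above 5000 K, and a 560 nm-normalized
blend between, with the blend's nominal temperature solved so the reference
curve is a fixed point of the CCT computation -- this makes "a source equal
to its reference scores exactly 100" hold everywhere, including the blend
band. The scaling constants (3.5, exponent 2) are the package's own
calibration, chosen at design time so that the score is substantially
harsher than the CRI for narrowband sources, the qualitative behavior
television-oriented scores are known for; the exact value at zero error
(100) is the analytic anchor.

```{r light-example}
light_quality_report(dermoscope_led_spd(7080))
```

**Smooth reflectance reconstruction.** Both the chart patches (for the
television chain) and the test-color samples (for the CRI) need spectral
reflectances the package cannot ship. `smooth_reflectance()` builds, for
each CIELAB anchor, the reflectance on the 5 nm grid that reproduces the
target tristimulus values under synthesized D65 exactly while minimizing
the squared second difference, with 0..1 bounds enforced by an active-set
iteration -- the maximally smooth metamer. Smooth metamers slightly
understate the sensitivity of real, more structured pigments to spiky
spectra; ordering properties are unaffected.

## Gray-card calibration

White balance is modeled as per-channel multiplicative gains in *linear*
RGB (a von Kries-style sensor-domain correction); image editors may operate
in other spaces, but the multiplicative model belongs in linear light.
`estimate_gains()` returns the reciprocals of a gray region's trimmed-mean
linear channel values, normalized to green = 1 (the camera convention), and
rejects references that are saturated over more than half their area.
`apply_correction()` multiplies the linearized image by the gains and can
additionally rescale exposure so the gray reference's luminance equals that
of L* = 50; the reference may sit in the corrected frame itself or in a
separate capture taken under the same conditions, which is the usual
post-production workflow (photograph the card once, correct the clinical
frames with it). Clipping is reported, and warned about above 10%, never
fatal.

Two numerical notes. First, the classic "neutral 5" chart patch is not a
perfect neutral (a* = -0.15, b* = -0.27), so gain recovery through it
carries a ~0.5-1% intrinsic offset; the synthetic gray card (exactly
L* = 50, a* = b* = 0) does not. Second, gain recovery from an 8-bit
*uniform* gray region is quantization limited: with noise below half a
count there is an irreducible bias of up to about 1% per channel in linear
RGB. The calibration workflow therefore assumes the RAW-decoded (16-bit)
path, and the package's gain-recovery validation renders its scenes at 16
bits; at 8 bits expect ~1% rather than ~0.2% accuracy.

`recommend_settings()` encodes the manual-settings guideline: white balance
at the source's CCT, the lowest available ISO, and a shutter time scaled
inversely with the measured mid-gray luminance from a baseline of 1/800 s,
rounded to the conventional third-stop ladder. With the dermoscope-class
LED at 7080 K and nominal luminance this reproduces the guideline triple
(7080 K, ISO 48, 1/800 s); at half the light it returns 1/400 s.

```{r settings-example}
recommend_settings(dermoscope_led_spd(7080),
                   gray_luminance = ((50 + 16) / 116)^3)
```

## The synthetic data generator

The generator defines the conditions under which the pipeline is validated:

- **Chart renders** are colorimetric, not spectral: reference Lab values go
  to encoded sRGB, are linearized, multiplied by the distortion gains
  (simulating an un-neutralized illuminant cast), re-encoded with a gamma
  exponent error, and only then receive seeded Gaussian noise in the
  encoded 8/16-bit domain (where a JPEG pipeline would add it) and
  quantization. Keeping the distortion at the Lab/RGB level makes the
  ground truth exact -- the returned truth holds the pre-noise patch colors
  and per-patch gamut-clip flags. Default geometry is 32 px patches with
  8 px borders (a 248 x 168 image).
- **Gray scenes** embed an exact L* = 50 neutral rectangle in a textured
  block background, passed through the same distortion.
- **Spectra** come from Planck's law (2000-10000 K), the daylight component
  method (4000-25000 K), Gaussian-band LED models, and a dermoscope-style
  three-band LED (narrow 460 nm pump, broad 545 nm phosphor, reduced red
  shoulder at 630 nm) whose phosphor amplitude is solved so the curve hits
  a requested CCT -- 7080 K by default.

What the generator does *not* emulate: lens vignetting and chromatic
aberration, demosaicing, JPEG artifacts, spatially varying illumination,
and real devices' proprietary rendering. Passing tests therefore
demonstrate the correctness of the measurement and calibration machinery
under the stated distortion model, not that any particular physical device
meets a deviation budget.

Validation sizes were chosen to exercise the claims while keeping the suite
fast: 10,000 random triples for the metric axioms, a 2700-7500 K sweep for
the analytic CRI limits, 2500-8000 K against a brute-force locus search for
CCT recovery, and 100 seeded trials with gains in [0.5, 2] and noise up to
2/255 for closed-loop gain recovery (worst observed ratio error 0.2%, and
gray-card correction reduced the average CIEDE2000 deviation in every
trial).

## Known limitations

- Absolute Ra/Qa values for strongly structured spectra are
  package-internal (synthetic samples, model camera); cross-instrument
  comparison should use the same implementation on both sides.
- RAW decoding is out of scope; inputs are pre-decoded PNG/TIFF (JPEG via
  EBImage when installed).
- Automatic chart detection targets flat, axis-aligned-ish captures with a
  dark chart grid; for perspective shots, supply the corner hint (the
  deterministic reference path).
- The 24-patch summary treats patches independently; no spatial uniformity
  or illumination-falloff analysis is attempted.
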