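---
title: "Quantifying lesion color variegation as histogram entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lesion color variegation as histogram entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromentropy)
```

## The model

A pigmented skin lesion's color variegation is summarized as the Shannon
entropy of its gray-level histogram. Given a polygonal region of interest
(ROI) on an 8-bit photograph, the pixels inside the ROI are binned into the
256 intensity levels, counts are normalized to probabilities $p_i$, and

$$H = -\sum_{i=0}^{255} p_i \log_2 p_i \quad \text{bits}, \qquad 0 \le H \le 8.$$

$H$ is a property of the histogram alone: it is blind to *where* colors sit
within the lesion, and measures only how evenly the ROI's mass is spread
over intensity levels. A homogeneous patch of skin scores 0; a region
exercising all 256 levels equally scores 8.

Because baseline skin heterogeneity varies between patients (age,
phototype, photodamage such as xerosis can raise the entropy of perfectly
healthy skin), absolute $H$ is paired with an internal control: a second
ROI on clinically normal perilesional skin from the same photograph. The
relative entropy

$$\Delta H = H_{\text{lesion}} - H_{\text{control}}$$

expresses the lesion's excess heterogeneity over its own background. Note
this is a plain difference of entropies, not a Kullback–Leibler divergence.
$\Delta H$ can be negative (a lesion more uniform than its surroundings),
and `relative_entropy()` refuses to form it across results computed under
different grayscale conventions, since the difference is only meaningful
within one processing pipeline. The package deliberately computes metrics
only — no diagnostic threshold or classification is offered.

## Parameters that matter

* **Grayscale conversion** (`method`): `"unweighted_mean"` (default) maps
  each pixel to $\mathrm{round}((r+g+b)/3)$; `"luma_bt601"` to
  $\mathrm{round}(0.299r + 0.587g + 0.114b)$. The unweighted mean is the
  default because it matches ImageJ's default RGB-to-gray conversion, the
  toolchain this workflow interoperates with; the luma option is the
  perceptual standard. Rounding is half away from zero
  ($\lfloor x + 0.5\rfloor$ on non-negative values), again matching
  ImageJ's `int(x + 0.5)`. The method used is recorded in every result's
  provenance. Which convention the original Fiji analyses used is not
  determinable from published descriptions, which is exactly why both are
  offered and stamped on results.
* **Bins**: fixed at 256. The protocol is explicitly 0–255; 16-bit or
  float images are rejected rather than rescaled, so a histogram bin is
  always one native intensity level.
* **Pixel-inclusion rule**: a pixel belongs to a polygon ROI iff its
  center $(c + 0.5, r + 0.5)$ (0-based indices, origin top-left, y
  downward) is inside under the even-odd fill rule. This is deterministic,
  oracle-checkable, and follows common raster conventions; whether any
  particular ImageJ session includes boundary pixels identically cannot be
  verified without the original `.roi` files, so masks here are defined by
  this rule alone and the rasterizer is validated against an independent
  per-pixel ray-casting oracle rather than against Fiji.
* **Normalization tolerance**: a probability vector must satisfy
  $|\sum_i p_i - 1| \le 10^{-9}$; anything further off is an error, never a
  silent renormalization.

## Reported precision

Entropies are computed in double precision and stored unrounded; JSON
output carries full precision (17 significant digits, so a read-back is
bit-exact), while CSV displays 2 decimals to match conventional report
tables. Published tables in this area print 2 decimals without stating
whether values were rounded or truncated; the package sidesteps the
question by always storing full precision and rounding only at display.

## What the phantom generator emulates — and what it does not

Clinical photographs behind published entropy values are generally not
deposited, so validation rests on synthetic phantoms with analytically
known answers:

* `exact_histogram_phantom()` builds an image whose full-frame histogram
  equals a prescribed 256-count vector *exactly* (the multiset of pixel
  values is laid out and then spatially permuted), so its entropy is known
  in closed form. This tests the histogram/entropy path with hard
  equality, not tolerance.
* `lesion_phantom()` builds the two-region configuration: i.i.d. draws
  from a lesion distribution inside a polygon, background draws outside,
  plus a disjoint control polygon placed in the widest margin between the
  lesion's bounding box and the frame. The defaults realize a calibration
  setting with known ground truth — a centred 100×100-pixel lesion
  (10,000 pixels) uniform over 16 levels ($H = 4$) on a constant
  background ($H = 0$) — so the expected $\Delta H$ is 4 bits up to
  multinomial sampling error, which at $10^4$ pixels is well inside 0.05
  bits.

Pixels are spatially independent by design: since $H$ is spatially blind,
i.i.d. sampling exercises everything the metric can see. The phantoms
therefore do **not** emulate camera optics, JPEG compression artifacts,
illumination gradients, skin texture, or lesion morphology. Passing tests
demonstrate that the pipeline computes the defined quantity correctly; they
say nothing about how acquisition conditions perturb $H$ on real
photographs (JPEG compression in particular measurably does, which is why
inputs are accepted as decoded and the caveat is documented).

All generation is driven by one explicit integer seed through a named
generator (Mersenne-Twister, recorded in the phantom's provenance sidecar),
so a spec maps to exactly one image, byte for byte, on any platform; the
global RNG state of the session is left untouched.

## The plug-in estimator

Entropy of an empirical histogram (the "plug-in" estimator) is negatively
biased at finite pixel counts: with $k$ occupied levels the bias is about
$(k-1)/(2n\ln 2)$ bits at $n$ pixels. `empirical_vs_analytic_entropy()`
quantifies this for any distribution and sample size. At the ROI sizes
typical of photographs (tens of thousands of pixels) the bias is far below
the 2-decimal display precision; the validation suite checks convergence
at $10^6$ draws to within 0.01 bits and strict sub-maximality of the
uniform-256 measurement at finite $n$.

## Numerical choices and degenerate inputs

* $0 \cdot \log_2 0$ is taken as 0, the standard convention for entropy
  sums; a bin with no pixels contributes nothing.
* The degenerate single-level ROI returns exactly `0` (an explicit `+ 0`
  normalizes IEEE negative zero away so displays never read `-0.00`).
* Log base is 2 throughout; there is no nat/dit option.
* An empty ROI (polygon covering no pixel centers, or a zero-total
  histogram) is an error, as are dimension mismatches between image and
  mask, channel counts other than 1 or 3 after alpha stripping, and
  non-8-bit inputs.
* Alpha channels are stripped; fully transparent pixels still count —
  transparency is not part of the protocol.
* Polygon validity requires at least 3 vertices and nonzero shoelace
  area; vertices may lie outside the frame, with the mask clipped to it.

## Design choices on open ground

* **ImageJ `.roi` scope**: only polygon and freehand selections (which
  share the vertex layout) are decoded; ovals, lines, points and composite
  selections are rejected by name, since the delineation workflow this
  supports is specifically polygonal. Sub-pixel float coordinates are
  honored when the file's header flags them. `.roi` files are read, never
  written, and `.zip` ROI sets are out of scope.
* **Control-ROI placement** in phantoms is automatic (widest-margin
  rectangle) rather than user-balanced in size; disjointness from the
  lesion is guaranteed by construction, and a lesion filling the frame is
  an error.
* **CSV dialect** is fixed: `.` decimal separator, `,` delimiter, no
  locale variation, for bit-identical outputs across systems.
* **Exit codes** in the CLI separate usage (1), validation (2) and I/O (3)
  failures; logs go to standard error and results only to the requested
  sink, so the tool composes in shell pipelines.

## Validation problem sizes

The shipped test suite validates the rasterizer and entropy path against
independent oracles on 200 random scenes up to 64×64 pixels with random
(possibly self-intersecting) polygons; exact-histogram recovery on 50
random specs up to 48×48; $\Delta H$ recovery on 20 seeded 256×256
two-region phantoms; and property suites (permutation invariance,
count-scale invariance, coarsening monotonicity, antisymmetry of
$\Delta H$, translation covariance, seeded byte-identity) on dozens of
random cases each. These sizes give the oracles full coverage of boundary
behavior while keeping the whole suite in the tens of seconds.

## Known limitations

* Grayscale entropy discards hue: two lesions with identical gray
  histograms but different color composition score identically. Per-channel
  or color-space (Lab/HSV) entropy is out of scope in this version.
* $H$ is acquisition-sensitive — lighting, white balance and compression
  all move it — and absolute values are only comparable within one imaging
  convention; $\Delta H$ mitigates but does not remove this.
* No automatic lesion segmentation: ROIs are delineated by the user, and
  ROI placement subjectivity propagates into the metric.
* The plug-in estimator's small-sample bias is uncorrected (no
  Miller–Madow adjustment); at typical ROI sizes it is negligible, but
  entropies of very small ROIs (hundreds of pixels) are biased low.
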