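---
title: "Phase-gradient morphometry: model, detector and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-gradient morphometry: model, detector and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasemorph)
```

## The physical model

Quantitative phase microscopy measures the optical path delay of a
transparent specimen: for a plane wave along $z$,

$$\varphi(x,y) = \frac{2\pi}{\lambda}\int_0^{h(x,y)}
  \left(n_c(x,y,z) - n_m\right)\,dz
  \;\approx\; \frac{2\pi}{\lambda}\,\bigl(n_c(x,y) - n_m\bigr)\,h(x,y),$$

with the axially averaged index $n_c$. Thickness and index are coupled in
$\varphi$, which is why a phase image alone cannot delineate substructure.

`phasemorph` models a nucleated cell as nested homogeneous spheres. A ray at
in-plane offset $d$ from a sphere of radius $R$ traverses a chord of length
$2\sqrt{R^2 - d^2}$, so the phantom's phase is a sum of chord terms, each
weighted by the index contrast against its *enclosing* medium:

$$\varphi(x,y) = \frac{2\pi}{\lambda}\Bigl[(n_1-n_m)\,2\sqrt{R_1^2-x^2-y^2}
 + (n_2-n_1)\,2\sqrt{R_2^2-(x-x_2)^2-y^2}\Bigr],$$

each square root taken as zero where its argument is negative. The additive
decomposition requires every inclusion's projected disc to lie inside the
body's disc; `cell_model()` enforces this and names the offending component
otherwise. The closed-form lateral derivative (per component,
$-C\,(x-x_c)/\sqrt{R^2-(x-x_c)^2-(y-y_c)^2}$ with $C = (4\pi/\lambda)\,
\Delta n$) diverges on each rim; `analytic_gradient_profile()` treats rim
points as an explicit error rather than returning a sentinel, because the
one-sided derivative genuinely has no finite value there.

### Default phantom

The reference phantom uses physiologically plausible values for a nucleated
mammalian cell: body $R_1 = 6$ µm, $n_1 = 1.37$; nucleus $R_2 = 2.5$ µm at
$(3, 0, 0)$, $n_2 = 1.45$; medium $n_m = 1.33$; $\lambda = 632.8$ nm (the
HeNe line; instrument presets use 633 nm and the configuration carries the
wavelength explicitly). The raster is $255 \times 255$ px over
$15 \times 15$ µm², pixel pitch $15/255 \approx 0.0588$ µm.

### Coordinate convention

Pixels are addressed by their centres: column $i$ (1-based) sits at
$x_i = -\mathrm{width}/2 + (i - \tfrac12)\Delta x$. With 255 pixels this
places row/column 128 exactly on $y = 0$ / $x = 0$, and makes the grid
mirror-symmetric, which the rendered phantom inherits exactly. Rendering
samples the chord model at pixel centres with no supersampling or
anti-aliasing, so a boundary pixel takes its centre's value; sizes inherited
from the raster are therefore accurate to about one pixel pitch by
construction.

## Gradient operators

`forward_diff_gradient()` computes
$g[r,c] = (\varphi[r,c+1]-\varphi[r,c])/\Delta x$; the final column (or row)
has no forward neighbour and is padded with zero so the map stays aligned
with its source — the padded index is excluded from jump candidacy.
Gradients are expressed per micrometre, not per pixel, so detector behaviour
is calibration-independent. For smooth interior points the forward
difference obeys the first-order truncation bound
$|g - \varphi'| \le \max |\varphi''|\,\Delta x$, and the tests verify both
the bound (at points at least three pitches from any boundary) and the
expected error contraction under grid refinement.

Squaring the gradient removes the "shadow artifact" — the sign reversal of a
first derivative across an edge — yielding an all-positive edge-strength map
(`modulus_squared()`). Squaring is a monotone transform of the magnitude,
so extremum locations are unchanged; the detector preserves this exactly
(below).

Profiles (`extract_profile()`) follow a full row, a full column, or an
oblique segment sampled at the nearest pixel per unit step along its
dominant axis. Nearest-pixel sampling (rather than interpolation) keeps
spikes localised to single pixels, at the cost of sub-pixel path accuracy —
acceptable because jump *positions* are the quantity of interest. For
column (and steep oblique) profiles the pipeline differentiates the phase
along the traversal axis: crossing a boundary along the profile is what
produces the nested $(+,-)$ spike pairs that the pairing stage requires. The
cross-derivative sampled along a column instead produces rim spikes of a
single sign, which carry no pairing structure.

## The jump detector

The detector is deliberately parameter-light:

1. threshold: samples with $|g| \ge f \cdot \max |g|$ over the profile,
   default $f = 0.3$;
2. group suprathreshold samples into contiguous runs of one sign;
3. one jump per run, at the maximum-magnitude index (ties to the lowest
   index).

A relative threshold makes detection invariant to index contrast and
calibration. The default 0.3 sits between the boundary-spike magnitudes
(which the singular chord slope pushes far above interior values) and the
smooth interior gradient; on the reference phantom it recovers the
four-jump structure on every section crossing both discs. Two degenerate
cases are defined away: a run spanning the entire profile (a constant
profile) contains no localised spike and yields nothing, and the padded
terminal index never becomes a jump. On squared profiles the threshold is
applied in equivalent magnitude terms ($g^2 \ge (f \max|g|)^2$), which makes
the squared and signed routes provably identical in their extremum indices;
signs are then read from the companion signed profile.

`pair_jumps()` requires the nested-hill pattern ($m$ positive then $m$
negative signs) and pairs outside-in. A violation signals overlapping,
non-nested media — outside the model class — and is reported with the
offending sign sequence rather than silently repaired.

Distances are exact rational pixel arithmetic times the pitch
(`pixel_pair_distance()`); rounding to the conventional three decimals
happens only at display. Error statistics follow the field's reporting
habit: the maximum absolute error is taken over *diameter* rows only, while
the mean relative error averages over all rows with known set values,
including the boundary-gap rows.

## Noise model and robustness

`add_gaussian_noise()` injects i.i.d. zero-mean Gaussian noise with variance
$P_\mathrm{signal} / 10^{\mathrm{SNR}/10}$, where $P_\mathrm{signal}$ is the
mean squared phase over the full image including the zero background — the
standard white-Gaussian-SNR convention; defining the power over the cell's
support alone would change $\sigma$ by only $\sqrt{2}$ at this geometry.
Each realisation is a pure function of its integer seed and the caller's
RNG stream is left untouched.

Differencing amplifies pixel noise by $\sqrt{2}/\Delta x$: at 35 dB the
phase noise ($\sigma \approx 0.051$ rad) becomes gradient noise of
$\approx 1.2$ rad µm⁻¹ against boundary spikes of 10–12 rad µm⁻¹. Jump
*positions* are therefore stable to within one pixel at 35 dB, and the
measured separations are unaffected at their one-pixel resolution. The
stricter property that the argmax *index* of every run is bit-identical to
the noiseless run is, however, fragile: runs contain near-boundary samples
within $\approx 3$ rad µm⁻¹ of the spike maximum, so noise occasionally
flips which pixel wins, and the identity rate across seeds stays well below
certainty at any threshold. The test suite states the strict identity
property at its nominal rate and the acceptance script reports both the
identity fraction and the maximum observed index shift, so the distinction
is visible in computed output rather than prose.

## What the simulator does and does not emulate

The generator produces ideal chord-model phase maps plus white Gaussian
noise. It emulates the geometry, contrasts and sampling of a QPM
measurement of a nucleated cell, which is what the jump detector consumes.
It does **not** emulate diffraction and the instrument transfer function,
coherent speckle or halo artifacts, phase-wrapping, reflection-induced
centre depressions seen on high-index beads, or refractive-index
inhomogeneity within a compartment. Passing tests therefore demonstrate the
correctness of the measurement chain on its model class, not robustness to
every instrument artifact; external maps are accepted as already-retrieved
phase rasters with an explicit pixel calibration for exactly this reason.

## Problem sizes and numerical choices

The suite and the acceptance script run the phantom at $255^2$ (reference),
$510^2$ (scale-invariance) and $1023^2$ (refinement) pixels, and ten noise
seeds at 35 dB — sizes chosen so every property is exercised at the
reference geometry while the whole chain stays interactive. Grid-doubling
moves every reported distance by less than one coarse pixel; refinement
$255 \to 1023$ contracts the worst interior forward-difference error about
threefold at fixed evaluation points (the first-order rate, limited by the
boundary-adjacent points where $\varphi''$ is largest).

Known limitations: sizes are quantised to the pixel pitch (no subpixel edge
interpolation, by design); media must be strictly nested for pairing;
near-tangent sections whose inner chord falls below a few pixels produce
spikes too weak for the relative threshold and report the outer pair only.
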