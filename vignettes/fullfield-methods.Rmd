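---
title: "Ultra-wide-angle visual fMRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultra-wide-angle visual fMRI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fullfield)
```

Human vision spans roughly 220 degrees, yet conventional scanner projection
setups stimulate only the central 15--20. One way around this is to project
onto a large curved screen inside the scanner bore itself, a section of a
cylinder viewed from about 15 cm away, which yields an unobstructed view of
about 175 degrees. Doing science with such a display requires solving a
chain of geometry, image-processing and analysis problems, and this package
implements that chain end to end: the optics of the tilted cylindrical
screen, the computational warp that pre-distorts images for it, the
stimulus families used in wide-field retinotopy and scene-perception
protocols, the block-design sequencing, and the first-level GLM analysis
with winner-take-all eccentricity preference maps. A synthetic-data module
stands in for the scanner, the projector and the participants, so every
stage is testable on one machine.

## The screen and viewing model

The screen is modelled as a section of a cylinder of radius 11 in
(27.94 cm) spanning a 120 degree chord about the cylinder axis, tilted by
10 degrees relative to the bore axis, with a display surface of 58.5 cm
(arc) by 44 cm (linear). The observer's eye sits on the mid-sagittal plane
at `eye_to_screen_cm` from the screen centre along the radius; 13.5--16.5 cm
covers the realistic range of head sizes and cushions, with 15 cm the
nominal value used for reported stimulus sizes. All visual angles are
computed monocularly from this single cyclopean point.

Two closed forms carry most of the weight. The horizontal extent of the
screen at the eye is

$$ W(d) = 2\,\mathrm{atan2}\!\left(r\sin\tfrac{\theta}{2},\;
   r\cos\tfrac{\theta}{2} - (r-d)\right), $$

with cylinder radius $r$, chord angle $\theta$ and viewing distance $d$:
175 degrees at 15 cm, ranging 168--182 over the realistic distances. For
the vertical extent we treat the screen's vertical section as a chord of
height $H = 44$ cm centred on the line of sight, giving
$2\,\mathrm{atan}(H/2d)$. Because the chord is centred, its tilt drops out
of the subtended angle (both endpoints are equidistant from the eye), and
the same formula reproduces the measured 106--117 degree range across
viewing distances. It remains an approximation in that a given observer's
eye may sit below the screen's vertical midline; the function documents
this.

The rendering camera for full-field views follows the standard perspective
relation `hfov = 2 atan(aspect * tan(vfov / 2))`: a 105 degree vertical
field of view at 4:3 gives 120.2 degrees horizontally, matching the
screen's 120 degree chord.

## Projector model and pose reconstruction

A pinhole projector aims up the bore, its rays striking the wall at 18.5
degrees ("just over 18"); tilting the screen by 10 degrees raises the
effective incidence on the display surface to 28.5 degrees. The grazing
geometry means only part of the raster reaches the screen: about 828 of
1024 columns and 284 of 768 rows, i.e. roughly 30% of the pixels (the
product of the two marginal extents, which is how that figure is derived
from the bounding rows and columns). The two pose parameters no optical
report states -- throw distance and lens field of view -- are recovered
numerically by `projector_pose()`, which solves the two-parameter pinhole
model so the ray-traced screen outline spans exactly 828 x 284 raster
pixels. Everything downstream (synthetic calibrations, the warp oracle,
the active-region check) is computed from this reconstructed pose at run
time; nothing is hard-coded.

`trace_projector_ray()` intersects per-pixel rays with the tilted cylinder
and returns surface coordinates `(s, h)` -- arc length along the
circumference and height along the rulings -- or an off-screen flag; such
pixels are set to black at presentation.

## The calibration-driven warp

Projecting a rectangular image onto a curved, obliquely lit screen
requires pre-warping. The physical calibration procedure marks projector
raster coordinates of known positions along the screen outline (the ends
and midpoint of the top and bottom edges at minimum; the package's
synthetic calibrations default to nine labelled points per edge plus a
half-height middle outline). `fit_calibration()` fits a circle through
each edge -- cylinder cross-sections project to near-circular arcs, and
three points determine a circle; extra points are fit by least squares
with reported residuals -- and builds interpolating curves through the
labelled points.

The mapping itself "wallpapers" the source canvas onto the surface:
horizontal source position is proportional to arc length (so the 4:3
aspect of the 1024 x 768 canvas is preserved on the 58.5 x 44 cm
surface), and the vertical map between the edges is *projective* rather
than linear. That choice is forced by geometry: the screen's vertical
rulings are straight lines in space, so their images under a pinhole are
parameterised projectively, and at the reconstructed pose a linear
interpolation would err by tens of pixels mid-screen. With a middle
calibration arc the per-column Möbius map is exact for the rulings; with
only two edges the code falls back to linear interpolation and says so.
Edge curves are interpolated with Forsythe--Malcolm--Moler spline end
conditions, which keep the endpoint error of strongly curved projected
edges below 0.2 px at nine points per edge.

`build_warp_map()` inverts the forward map over the raster (dense forward
seeding plus Newton polishing, sub-0.01 px inversion error) to give
per-pixel source coordinates and an on-screen mask; `warp_image()`
resamples bilinearly (nearest-neighbour for masks and checkerboards, to
avoid gray halos), and `unwarp_image()` provides the verification
inverse. Against the ray-traced ground truth the calibrated map agrees to
well under a pixel, and a warp/unwarp round trip of a structured scene
exceeds 30 dB PSNR over the canvas interior. The vertical direction is
downsampled roughly 2.7-fold on the raster, so the round trip is not
information-preserving at the highest vertical frequencies; smooth
natural-scene content survives essentially intact. A 4k projector raster
is a pure rescale of the map (3.125x vertically, from 2400/768).

## Stimulus generation

All stimuli are drawn on the canonical pre-warp canvas (1024 x 768,
values in [0, 1]) and pass through the warp unresized. Degrees convert to
canvas pixels through the wallpaper mapping: eccentricity is converted to
surface arc length through the viewing geometry (closed form on the
horizontal meridian) and then scaled by the canvas pitch. The canvas is
isotropic to within 0.3% (1024 px / 58.5 cm vs 768 px / 44 cm), so rings
are circles in canvas space.

* **Eccentricity rings** (`make_ring_checkerboard`): polar checkerboards
  confined to the five standard bands (centre <= 1.8, 2.0--5.6, 6.3--16.5,
  18.5--50.3, >= 55.3 degrees), flickering through black-white,
  white-black and random-colour states at 4 Hz. Check counts are not
  specified by any protocol we know of; the package uses 24 angular
  wedges and log-spaced radial rings (ratio 1.35), which scales check
  size with eccentricity in the same spirit as cortical magnification.
* **Phase scrambles** (`phase_scramble`): random phases are added per FFT
  coefficient, with conjugate symmetry guaranteed by drawing the phase
  field from the FFT of white noise; the amplitude spectrum is preserved
  exactly and the DC term (mean luminance) is untouched. One phase field
  is shared across colour channels by default (preserving inter-channel
  structure); the output is intentionally not clipped, since clipping
  would perturb the spectrum -- quantisation happens at PNG write time.
* **Postcards** (`make_postcard`): the whole image (never a crop) is
  rescaled to 205 x 154 px (44 degrees wide at the nominal distance) and
  centre-padded back to the canvas; faces and objects use a 171 x 129 px
  bounding box on white.
* **Scotomas** (`apply_scotoma`): a central disc of 0, 29, 58, 88 or 140
  degrees diameter (the methods-table values; the 30/138 variant used in
  some summaries is available by argument) is replaced by the background
  with a hard edge.
* **Item arrays** (`layout_item_array`): 13 items -- 3 of 113 px diameter
  on an inner circle, 6 of 178 px on a middle circle, 4 of 295 px at the
  image corners -- with uniform positional jitter and a rejection loop
  enforcing non-overlap. The circle radii (80 and 225 px), corner inset
  (153 px) and jitter (+-5 px) are package choices: the published layout
  gives counts and diameters but not radii, and these values leave >= 13
  px of clearance between the tightest item pairs so the rejection loop
  converges quickly while keeping visibly jittered positions.
* **Luminance matching** (`match_luminance`): exact rank-preserving
  histogram specification to the average sorted-pixel profile of the set
  (for equal-sized images this is exact; unequal sizes fall back to an
  interpolated average quantile function). This equates luminance
  histograms in the same sense as SHINE-style matching without
  reimplementing that toolbox.

`build_exp3_stimuli()` assembles the full factorial set -- 4 content types
x 20 base images x 5 scotoma levels = 400 unique stimuli -- from
procedural content, with a manifest TSV.

## Block designs

Three protocols are generated with exact published timing at TR 2 s:

* retinotopy: 7 conditions x 7 six-second blocks, seven interleaved
  fixation blocks plus one at each end -- 348 s, 174 TRs;
* scenes (full-field/postcard x intact/scrambled, plus faces and two
  object classes): 21 twelve-second blocks each followed by 6 s fixation --
  with 6 s lead-in/lead-out, 390 s, 195 TRs;
* content x scotoma: 2 epochs of 20 condition blocks and 5 rest blocks of
  8 s -- with 8 s lead-in/lead-out, 416 s, 208 TRs.

The published totals for the latter two protocols exceed the bare block
arithmetic by 12 and 16 s; the package models the difference as symmetric
lead-in/lead-out fixation, which is an assumption (the placement of the
residual fixation is not documented) and is flagged as such here rather
than asserted anywhere else. Block orders are permuted independently
within each epoch; because a permutation has no repeated labels, the
no-adjacent-repeat constraint can only fail at epoch boundaries, where the
next epoch's permutation is simply redrawn (rest blocks are exempt). Each
block's trial sequence repeats one randomly chosen image consecutively --
the one-back target -- and image pools are split across a condition's
blocks within a run without reuse. Runs serialise to BIDS-style
`events.tsv` tables.

## GLM analysis

The first-level model regresses each voxel's time course on HRF-convolved
condition boxcars (double-gamma kernel: response gamma shape 6, undershoot
shape 16 at ratio 1/6, rate 1 -- peaking at 5 s), six motion nuisance
columns when available, low-order Legendre drift terms (order 2 by
default, mirroring the linear-trend-removal step of standard
preprocessing) and an intercept. The kernel is normalised to unit
integral so a sustained block regressor plateaus at 1 and betas read in
the units of the data. Serial correlations are handled by AR(1)
prewhitening (Cochrane--Orcutt, one iteration, per-voxel coefficient from
the OLS residuals) -- a standard stand-in where the original software's
exact correction is undocumented, so numerical equality with any
particular implementation's betas is not claimed. Betas are converted to
percent signal change by referencing each voxel's fitted baseline
(`100 * beta / intercept`), which recovers planted amplitudes exactly in
the noiseless case -- unlike scaling by the raw mean, which is biased by
the activation itself.

ROI logic follows the published procedure: uncorrected voxel-wise
thresholds on contrast t-maps (e.g. scenes minus faces at p < 0.0001,
one-sided), minimum-statistic conjunctions over pairwise contrasts (far
periphery beating every other eccentricity band), and removal of overlap
between independently defined ROIs with the overlap fraction reported.
The eccentricity preference map takes, per voxel, the condition with the
highest (optionally subject-averaged) response and the margin between the
best and second-best conditions as its strength; ties resolve to the
lowest condition index with zero strength. Temporal SNR is the voxel mean
over the temporal standard deviation. The ROI ANOVA is a balanced two-way
fixed-effects `aov` with eta squared reported as SS_effect / SS_total.

## The synthetic module, and what passing tests do and do not show

`synth_bold()` simulates `y = baseline (1 + sum_c beta_c x_c / 100) +
drift + AR(1) noise` at baseline 100 (so PSC is natural), with Legendre
drift and noise innovations scaled to a marginal SD of `sigma`.
`synth_retinotopic_population()` plants one preferred eccentricity band
per voxel with a configurable amplitude margin, emulating the
centre-to-periphery progression of preferences; `synth_calibration()`
projects labelled screen-outline points through the ray tracer with
optional pixel noise; `synth_images()` draws procedural scenes (gradient
rooms with furniture blocks and falling amplitude spectra), schematic
faces and geometric objects, so no copyrighted photographs enter the
pipeline. Everything is a pure function of its seed.

The simulations deliberately omit hemodynamic nonlinearities,
physiological noise spectra, motion, spatial autocorrelation and
between-subject variability. Green tests therefore certify the
*computational* pipeline -- geometry, warping, sequencing, estimation and
map logic -- under the package's own noise model; they do not certify
effect sizes or statistical conclusions on real scanner data, and the
published group results (ROI betas, behavioural accuracies, tSNR tables)
are human-data quantities the package does not attempt to reproduce.

Default problem sizes were chosen so the full suite runs in a couple of
minutes on a single core: populations of a few hundred voxels on the
174-TR retinotopy design, eight simulated subjects for the group
preference map (recovery > 99% at a 1 PSC margin over sigma = 2 noise),
and 10^4-seed sweeps for the randomisation constraint.

## Numerical choices and known limitations

* Angles are degrees at API boundaries and radians internally; surface
  coordinates are cm with the origin at the screen centre; unit
  conversion is fixed at 2.54 cm/in.
* The warp-map inversion seeds from a 1400 x 500 forward grid and applies
  three Newton steps; pixels whose residual exceeds 0.05 px are treated
  as off-screen, which trims at most a hair's width at the region
  boundary.
* Circle fits use the Kasa least-squares form (exact through three
  points); collinear edges and crossing arcs are rejected.
* `preference_map` breaks exact ties toward the lowest condition index,
  deterministically.
* The vertical-extent formula and the reconstructed projector pose are
  approximations documented above; both reproduce the published
  quantities they model but neither claims to be the as-built optical
  path (in particular the mirror periscope is collapsed into an
  equivalent virtual projector).
* Photometric (luminance falloff) correction, projector lens distortion
  and real-time rendering are out of scope.
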