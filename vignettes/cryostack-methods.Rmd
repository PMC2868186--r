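---
title: "Methods: colour cryo-imaging reconstruction and morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colour cryo-imaging reconstruction and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cryostack` reconstructs and quantifies whole-animal block-face
cryo-imaging data: serial true-colour photographs of the face of a frozen
specimen block, taken after each microtome cut, acquired as overlapping
camera tiles. This vignette records the models the package implements, the
conventions and defaults it commits to, and the places where a design was
genuinely open and a choice had to be made.

## Conventions

Voxel arrays are ordered (z, y, x) with z the section index increasing with
cutting depth; colour volumes carry a trailing RGB channel dimension with
8-bit values 0..255. Indices are 1-based (native R); the physical position
of voxel *i* along an axis with spacing *s* is (i − 1)·s, i.e. voxel centres
with voxel 1 at the origin. Region reads take ordinary R index vectors; an
empty index vector is a legal zero-size read. All 8-bit quantization and all
reported percentages use round-half-away-from-zero, because printed tables
are rounded that way; unrounded values are always retained (attribute
`unrounded`, or full-precision columns). Default geometry follows the target
instrument: 15.6 µm in-plane pixels, 40 µm sections, 1036 × 1360 px tiles in
grids with ≥ 15% overlap.

## Colour feature detectors

Tissue classes separate on simple functions of the RGB triple
(S = R + G + B, I~max~ = 255):

* channel ratio `f_C = C / S` — red selects liver, lung and vasculature;
* brown `f_Br = 0.33 f_R + 0.67 f_G` — brown tissue mixes one part red with
  two parts green and no blue; the printed two-decimal weights are used
  as printed, not 1/3 and 2/3;
* balanced `f = (|R−G| + |G−B| + |R−B|) / (3·255)` — an achromaticity
  score, identically `2(max − min)/765`, at most 2/3; near zero for the
  white embedding compound (OCT).

Voxels with S = 0 get `f = 0` by convention: black voxels carry no chromatic
evidence and should stay transparent under any positive threshold. Ratio and
brown features are invariant to uniform intensity scaling; the balanced
feature scales linearly with intensity, which is why background
classification adds a brightness conjunct: a voxel is OCT iff the balanced
feature is at most `T_chroma` **and** mean(R, G, B) is at least `T_bright`.
Without the brightness term, dark gray tissue — equally achromatic — would
be removed with the embedding. Defaults `T_chroma = 0.06`, `T_bright = 200`
separate the phantom's organ colours from its 245-level white embedding;
they are engineering defaults, configurable everywhere, not measured
constants.

The step opacity transfer function maps a feature map to binary opacity,
`alpha = 255` strictly above the threshold T and `0` at or below it. The
boundary is deliberately exclusive; `step_otf` is monotone in T.

## Flat-field correction and the vignetting model

Each tile is corrected per channel by
`out = clip(round(tile · mean(white_c) / white))`, with the white-card
reference clamped below at a configurable floor (default 1). Normalizing by
the channel mean makes a spatially uniform reference a no-op and preserves
overall brightness.

The phantom's vignetting is a radially symmetric multiplicative gain
`1 − s·(r/r_max)²` per tile, **normalized to unit mean**. The normalization
is what makes mean-referenced white-card correction unbiased: dividing a
raw attenuating gain out of a tile while multiplying by the reference mean
would return the ideal image scaled by the gain's mean, not the ideal image.
The unit-mean field exceeds 1 at the tile centre, so exposure headroom
matters: with the default white embedding at level 245, a vignette strength
above ≈ 0.12 drives highlights past 255 and makes the correction lossy
(the generator warns). The default strength is 0.1, under which a generated
tile is recovered to within ±1 intensity level — the residual being pure
8-bit quantization of the tile and of the white card. The paper-trail for
the instrument gives no quantitative noise or vignetting figures; these
defaults are plausible test conditions, not instrument claims.

## Mosaicking and tile-position refinement

Nominal tile origins come from acquisition metadata when present (the
instrument records global tile coordinates) and otherwise from the grid
geometry and overlap fraction. With refinement enabled, tiles are visited in
raster order; each is registered to its already-placed left (or top)
neighbour by maximizing normalized cross-correlation of the luminance
(0.299R + 0.587G + 0.114B) over integer shifts within a small search
radius. Candidates are visited in order of increasing shift magnitude and
only a strictly better score displaces the incumbent, so structureless
(flat-on-flat) comparisons resolve to the nominal position. A best shift as
large as the overlap width is treated as a failure and falls back to the
nominal position with a warning. Overlaps are blended by linear feathering
(weights ramp linearly across the overlap width and are renormalized by
their sum), which is exact wherever the overlapping content agrees — in
particular, stitching a noiseless, jitter-free acquisition reproduces the
ideal section bit-exactly. Output dimensions depend only on the grid
geometry, never on the recovered jitters; border pixels a refined tile
vacates are filled with the embedding colour.

Identifiability caveat: a tile position is only recoverable where the
overlap zone contains specimen content. On sections of pure embedding
compound the problem has no signal at all — and after flat-field correction
a ±1-level quantization residual remains that is *fixed in the tile frame*,
so correlation locks onto that fixed pattern rather than the (featureless)
scene. Jitter-recovery validation therefore measures specimen-bearing
sections.

## Section alignment

Each section is registered to its predecessor (chained, since the stage
error accumulates per return) by the peak of the FFT cross-correlation of
mean-subtracted luminance — a matched filter. A *whitened* spectrum (pure
phase correlation) was evaluated and rejected: adjacent anatomy differs
non-translationally, and whitening amplifies those differences into
spurious peaks (on two concentric discs of different radius it returns an
essentially random shift). The matched filter instead produces a
correlation plateau — a smaller structure nested anywhere inside a larger
one scores identically — which is resolved by taking the smallest shift
among near-maximal entries, i.e. "do not move unless the data demand it".
Injected pure translations are still recovered exactly. Estimated shifts
beyond a cap (default 50 px) are flagged and not applied; sections with
uniform luminance carry no signal and keep a zero shift. Cumulative shifts
are applied on a padded canvas (fill: embedding white, so the balanced
detector still classifies padding as background); registration is
integer-pixel only, as subpixel shifts would resample 8-bit colour for no
benefit at 15.6 µm pixels.

## Semiautomatic segmentation

Automatic initialization thresholds a detector with the step OTF, removes
background voxels, and discards connected components below a size floor
(26-connectivity in 3D by default; 6 and 18 available). Manual correction
is represented as per-section PNG mask import/export rather than a GUI.

Sparse manual labels are completed by shape interpolation: between two
labelled sections the exact signed Euclidean distance fields (positive
inside; computed by a Felzenszwalb distance transform in compiled code) are
blended linearly in z and the intermediate mask is the positive superlevel
set. Labelled sections are reproduced bit-exactly; sections outside the
labelled bracket copy the nearest labelled mask; a nearest-section copying
mode is available as a fallback. Interpolating between an empty and a full
mask is undefined (±∞ blend) and yields empty, which is the conservative
choice. Blood-pool exclusion removes from an organ mask all voxels whose
red ratio exceeds `T_blood`, leaving the tissue-only mask used for cardiac
tissue mass. Mask merging into a labelled volume is first-wins in list
order with overlap accounting.

## Multiscale volume access

The pyramid stores every level as independently addressable bricks
(default 64 × 256 × 256 voxels), so any region of any level is readable
without touching the rest — subsampled whole-animal views and
full-resolution crops alike. Level L+1 is the 2×2×2 **box-filter mean** of
level L, computed separably with edge blocks averaged over the voxels
available, quantized once per level with round-half-up. A box filter is
used instead of decimation because decimation aliases structures near the
voxel scale (20 µm vessels at 15.6 µm pixels). Box averaging conserves the
per-channel global mean exactly when the level dimensions are even; odd
dimensions overweight the partial edge blocks in proportion to edge
content, so mean-conservation checks are meaningful only under
even-divisible geometry (the validation phantom uses a canvas divisible
by 4). The on-disk layout is one directory per level of raw 8-bit bricks
plus JSON metadata.

## Volumetry, normalization and derived comparisons

Region volume is whole-voxel count × (dy·dx·dz), reported in mm³ —
consistent with labelling a voxel by its centre. Organ volumes are
normalized by gross body weight (mm³/g, reducing animal-size variability)
and by brain volume (dimensionless, reducing lean-mass variability;
brain/brain = 1 by construction). Percent comparisons come in two
complementary conventions, `higher` = (a/b − 1)·100 and
`thinner` = (b − a)/b·100, rounded half-up to the requested precision with
the unrounded value attached. One published skin comparison (epidermis
"16% thinner", 407 vs 348) is consistent with neither denominator (14.5%
or 17.0%); the operation therefore reports both rather than guessing.
Skin-layer thicknesses are run lengths along a user-chosen ray times the
pixel size, corrected by the ray direction norm (a 45° ray crosses √2 more
tissue per pixel step); they are reported in µm — the anatomically sensible
unit — even where source tables print "mm" at values that can only be µm.
Fractional vascularization is the vessel share of the enclosing adipose
region (vessels included in the denominator). Cardiac-phase uncertainty at
freezing is a reporting caveat, not a model.

## Multiplanar reformatting and bone morphometry

Planes are defined in physical mm coordinates by an origin, unit normal,
unit in-plane axis u (v = normal × u), extent and sample spacing; samples
outside the volume are background-filled and counted in a warning, because
planes along a bone axis routinely exit the block. Nearest and trilinear
interpolation are available; an axis-aligned plane at native spacing with
nearest interpolation reproduces the stored section bit-exactly, and
trilinear sampling reproduces any trilinear field up to 8-bit rounding.
Bone endpoints are user-supplied landmarks (measured interactively on
reformats); lengths are Euclidean distances in mm, cortical areas are pixel
counts × pixel area on transverse planes (the mask's inclusion or exclusion
of the medullary cavity is the user's, and is recorded as such), and the
derived ratios are tibia/femur, length over body length (nose to tail
base), and cortical area over length.

## Rendering

Orthographic, axis-aligned front-to-back compositing with associated
(premultiplied) colour: with a = alpha/255,
`C ← C + (1 − A)·a·C_voxel`, `A ← A + (1 − A)·a`, early termination at
A ≥ 0.999, remaining transparency filled with the background. With binary
opacity from the step OTF this reduces to a first-hit projection of the
thresholded structure. No lighting, perspective or GPU path — interactive
rendering belongs to external visualization software.

## The phantom: what it emulates and what it does not

The generator produces what the instrument would record of ellipsoidal
"organs" (known analytic volume 4/3·π·abc) frozen in a bright achromatic
embedding block: per-section tile grids with the configured overlap,
unit-mean radial vignetting identical in every tile and in the white-card
reference, i.i.d. Gaussian colour noise per organ (clipped, quantized),
optional per-tile sensor noise, and integer stage jitter per tile with the
first tile anchoring each section's frame (absolute positions are
unidentifiable from content alone). Identical seeds give bit-identical
output. Ground truth carries the label volume, analytic volumes, true
jitters, the gain field and the ideal volume.

Test conditions (chosen once as plausible, the sources giving no figures):
organ colour noise σ = 6, vignette strength 0.1, jitter ≤ 2–3 px, 2 × 2
tile grids at 20% overlap, native 40/15.6/15.6 µm spacing. Validation
problem sizes: a 1 mm-radius sphere (≈ 69 × 175 × 175 voxels, ≈ 430 000
organ voxels) for end-to-end volumetry, recovered within 2% (observed:
0.035%, the pure rasterization error — colour noise at these settings never
crosses the red-ratio threshold); an 8 × 144 × 144 flat phantom for
registration, interpolation and pyramid checks; a 221³ unit-µm grid for
rasterization convergence.

What passing these tests shows: the arithmetic, geometry and registration
chain are correct, self-consistent and exactly invertible under their own
model. What they do not show: robustness to real tissue texture, freezing
artifacts, knife chatter, ice crystals, specimen deformation, colour drift
across sections, or fluorescence — none of which the phantom emulates.

## Known limitations

* Integer-pixel registration only; no nonrigid correction.
* Chained section alignment accumulates any rare per-pair error into all
  later sections (it preserves shapes, not absolute position).
* Tile refinement needs specimen content in the overlap zones; empty zones
  fall back to nominal placement.
* Detector thresholds are data-dependent and must be chosen per acquisition;
  defaults suit the phantom's palette.
* The pyramid's level means are biased by partial edge blocks on
  odd-dimension levels.
* No statistical machinery across animals: the morphometry compares
  individual specimens.
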