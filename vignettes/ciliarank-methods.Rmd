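---
title: "Quantifying ciliary antibody staining: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ciliary antibody staining: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliarank)
```

## The problem

Immunofluorescence (IF) staining of nasal-brushing slides is used as a
pre-genetic screen for primary ciliary dyskinesia (PCD): an antibody
against an axonemal protein (red channel) is co-stained with an
acetylated-α-tubulin axoneme marker (green channel), and a protein absent
from — or mislocalized out of — the ciliary axoneme is diagnostic. The
same *degraded staining pattern*, however, can be produced artifactually:
when a slide is stored badly between collection and staining, the red
signal weakens in cilia and reappears as diffuse cytoplasmic background.
Distinguishing storage artifact from genuine protein mislocalization
therefore requires quantifying how specific the red staining is, per slide,
across many storage conditions and antibodies.

`ciliarank` implements an automated pipeline for exactly this: per-channel
object segmentation, a small set of interpretable shape / intensity /
colocalization parameters, red↔green object pairing, a significance screen
across storage conditions, and a mean-rank metric that integrates all
parameters into a single ordering of storage conditions (which storage
protocol is safest) or antibodies (which epitope tolerates storage).

## The measured parameters

All object parameters are computed on 8-connected segmented objects from
pixel-center moments (no subpixel interpolation; every value is exactly
reproducible by a brute-force sum over mask pixels, which is how the test
suite checks them).

* **Area** (`AreaShape_Area`): pixel count; physical area is
  `area_px * pixel_size_um^2` — the linear pixel size (default 0.1136
  µm/px) enters squared for areal measures and once for distances.
* **Eccentricity**: with `λ1 ≥ λ2` the eigenvalues of the 2×2 central
  second-moment matrix of the mask, `sqrt(1 − λ2/λ1)`; 0 for a disc, → 1
  for a line. Cilia are elongated: *higher is more marker-like*.
* **Compactness**: radial-variance form `2π · MSD / area`, where MSD is
  the mean squared distance of mask pixels from their centroid; a filled
  disc scores 1, irregular/holed/elongated shapes score more. This form is
  perimeter-free and robust to boundary noise; a classical
  `perimeter²/(4π·area)` variant (with the π/4 pixel-edge correction that
  makes a rasterized disc score 1) is available via `method = "perimeter"`.
* **Intensity mass displacement**: Euclidean distance between the
  geometric and the intensity-weighted centroid of an object, in px.
  Uniform or symmetric staining gives 0; signal pulled to one side (e.g.
  into the cytoplasm) gives large values. Invariant to uniform intensity
  rescaling but *not* to additive offsets.
* **Rank-weighted colocalization (RWC)**, directional: within an analysis
  mask, both channels are midranked; with `D_i` the absolute rank
  difference at pixel i and `Rmax = max D`, pixel weights are
  `(Rmax − D_i)/Rmax`, and the coefficient is the weight-discounted share
  of primary-channel intensity on pixels above both thresholds. It lies in
  [0, 1] by construction and is asymmetric: red→green asks "is the red
  signal where the green is", which degrades with storage, while
  green→red stays flat when the marker is stable. Pearson correlation
  (range [−1, 1], symmetric) is reported alongside; published descriptions
  of two-channel correlation sometimes quote the [−1, 1] range, which
  matches Pearson, so both are always computed and kept distinct.
* **Centroid distance** (`Distance_Centroid_mCilia`): Euclidean distance
  between the *geometric* (unweighted) centroids of a paired red and green
  object, reported in µm.

## Pairing and the unique-pair filter

Each red object is assigned to the green object with which it shares the
most pixels (ties to the lower green id; zero overlap = unpaired). Before
any per-object statistics are aggregated, pairs are restricted to green
objects with exactly one red child. This removes ambiguous many-to-one
matches so that object parameters always describe an unambiguous
red/marker pair from the same cell. Max-overlap parent assignment was
chosen over centroid-containment because it is well-defined for elongated
concave objects (a tuft's centroid can lie outside the tuft).

## Screening and the mean-rank metric

Per-slide parameter values (slide = donor × condition × antibody; the mean
over that slide's surviving objects or images) are screened for
association with storage condition with a Kruskal–Wallis test at
`alpha = 0.001`. The rank-based test was chosen because object features
are heavily right-skewed; a one-way ANOVA alternative is available, and
Benjamini–Hochberg adjusted p-values are reported alongside the fixed
stringent threshold (off by default, mirroring the original fixed-alpha
practice).

For ranking, values are first averaged to design-cell means (across
donors), then across the other axis: conditions are scored on values
averaged across antibodies, antibodies on values averaged across all
storage conditions. Each parameter then ranks the entities 1..n in its
better-direction (see `default_direction_map()`); ties get average ranks.
The **overall performance rank** of an entity is the arithmetic mean of
its per-parameter ranks, reported at one decimal. The alternative of
ranking conditions within each antibody first and averaging ranks is
available (`rank_within_antibody = TRUE`); averaging values first was made
the default because it matches how the reference rank tables describe
their construction. A condition-subset re-ranking (e.g. dropping the
prolonged room-temperature conditions) supports asking whether an
antibody's poor rank is driven only by the worst storage.

## The synthetic slide generator

The generator exists so that every stage is testable against known ground
truth without any microscope data. One cell is: an elliptical body, an
apical anchor on its boundary, 3–6 ridge primitives (anti-aliased segments
with Gaussian cross-profile, length 12–20 px, σ 1.0–1.6 px) fanning
outward from the anchor — the ciliary tuft — and a nucleus ellipse placed
inward. The green channel carries the tuft; the blue channel a soft
nucleus blob; background (200 intensity units) and Gaussian read-out noise
(σ = 60) are added everywhere and images are quantized to 16-bit on write.

Degradation is a single fraction `delta ∈ [0, 1]`:

```
red = (1 − delta) · tuft + delta · diffuse + background + noise
```

where `diffuse` has *exactly* the tuft's integrated mass, so the red
channel's total signal is invariant to `delta` — degradation moves signal,
it does not remove it, isolating localization as the only degraded
property. The diffuse density decays exponentially from the ciliary base
into the cytoplasm (length scale 15 px) and is modulated by a smooth
random blotch field: displaced/unassembled protein accumulates in the
apical cytoplasm and nonspecific staining is patchy, so the degraded
object remains an asymmetric, ragged extension of the tuft rather than
becoming a clean ellipse (a clean ellipse would paradoxically score as
*more* regular than cilia).

A simulated study is donors × conditions × antibodies (default 5 × 7 × 8 =
280 slides, 22 images per slide, 1–5 cells per 192×192 px image at 0.1136
µm/px). The per-slide `delta` is `base(condition) × multiplier(antibody)`,
clipped to [0, 1]: the base deltas (0.05 … 0.70) follow the storage-quality
gradient from continuous −80 °C storage (best) to 28 days at room
temperature (worst), and the per-antibody multipliers (0.70 … 1.40) follow
the observed sensitivity ordering from RSPH4A (most storage-tolerant) to
CCDC39 (most sensitive). These numbers are free design parameters of the
simulator chosen once to span intact-to-degraded; they are not measured
values. Every slide draws from its own RNG stream derived from
(master seed, donor, condition, antibody) by a 32-bit FNV-1a hash, so
regeneration is bit-identical and independent of generation order.

What the generator does *not* emulate: point-spread-function blur,
channel bleed-through, z-stacks, autofluorescent mucus, inter-donor
biology, or segmentation-hostile cell clumping. Passing tests on synthetic
studies therefore demonstrate that the measurement and scoring machinery
recovers a known localization gradient under noise — not that the pipeline
is validated on clinical material.

## Numerical and design choices

* **Segmentation** (per channel): Gaussian smoothing σ = 1 px, global
  threshold, hole filling, 8-connected labeling, area window
  [40, 10⁶] px (40 px ≈ 0.5 µm² suppresses speckle). Border-touching
  objects are kept (partially imaged cells still carry signal). No
  declumping/watershed: a tuft is analyzed as one stained region. The
  shared default threshold is two-class Otsu; the *test channel* defaults
  to a background-referenced threshold (median + 3·MAD), because Otsu
  places its cut between the background mode and the bright ciliary mode
  and would leave intermediate diffuse cytoplasmic intensities — the very
  signature of degradation — outside the objects. Every setting is
  exposed in the config, per channel.
* **Colocalization analysis mask**: pixels above threshold in at least one
  channel (union of foregrounds). Whole-image masks inflate rank agreement
  through the empty background; the union mask restricts the comparison
  to stained pixels while still counting displaced red mass in the
  denominator. Thresholds default to the same background-referenced rule;
  note that with exactly zero noise the MAD collapses and this estimator
  degenerates to the median, so noise-free synthetic checks use Otsu.
* **Degenerate inputs**: constant images segment to zero objects with a
  warning (no defined threshold); single-pixel objects get eccentricity 0;
  all-zero intensity in a mask gives mass displacement 0; zero channel
  variance gives Pearson `NA`; zero red objects give an undefined pairing
  percentage. All are reported, never silently dropped.
* **Monotonicity of mass displacement**: the property "mass displacement
  grows with delta" is checked within the *intact* (delta = 0) object
  mask. Re-segmenting at every delta changes object identity — at high
  delta the object becomes the cytoplasmic region itself, which is again
  fairly symmetric — so the raw re-segmented sequence is not monotone for
  any mass-preserving mixture model.
* **Problem sizes in the test suite**: the gradient-recovery study runs
  5 donors × 7 conditions × 2 antibodies (the sensitivity extremes,
  RSPH4A and CCDC39) × 10 images per slide at 192×192 px; the
  fluorochrome-swap study uses 2 donors × 7 conditions × 2 antibodies × 2
  images at 128×128 px. These sizes recover the injected ordering reliably
  while keeping a full test run in a couple of minutes.

## Known limitations

* Equivalence with the original interactive pipeline's absolute object
  counts cannot be asserted: its exact threshold method and size limits
  are not published, so only order-of-magnitude and ordering behavior are
  testable.
* The significance screen treats the slide as the unit of replication
  (objects within a slide are not independent); pooling antibodies into
  one Kruskal–Wallis per parameter is a pragmatic, conservative choice,
  not an inference of the original analysis design.
* RWC values depend on the threshold rule; comparisons are only meaningful
  within a run with a fixed configuration.
* Absolute intensities are never compared across slides (acquisition
  settings are assumed unstandardized); all intensity-derived parameters
  are internal to an image.
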