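---
title: "Methods: hot-spot detection and classification in SPECT/CT SLN imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hot-spot detection and classification in SPECT/CT SLN imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slndetect)
```

## The detection model

`slndetect` assists the reading of sentinel-lymph-node (SLN) SPECT/CT: it
turns the emission volume into a set of disjoint "hot spots", judges each
spot against anatomical plausibility rules derived from the co-registered
CT, and presents two probability-ordered candidate lists (true / false)
for expert review. The package assumes the two volumes are co-registered
(hybrid scanner) and performs no registration, reconstruction, or
attenuation/scatter correction.

### Common grid and background suppression

Native SPECT (~4 mm isotropic) and CT (~1×1×5 mm) are resampled to a 1 mm
isotropic lattice so tissue context can be read voxel-by-voxel under each
hot spot. The order-3 resampler uses the cubic B-spline kernel applied
directly, without the interpolation prefilter. This is a deliberate
numerical choice: the direct B-spline weights are non-negative and sum to
one, so constants are reproduced exactly, emission values never undershoot
zero, and the count integral is conserved; an interpolating cubic kernel
(negative side lobes) would inflate total counts after the physical
non-negativity clamp — for an isolated hot voxel by over 20 %. The price is
extra smoothing of about half a native voxel, which is accepted: the
emission data are already smoothed by the reconstruction filter, and
resolution-limited merging of nearby maxima is handled explicitly by the
segmentation (two maxima that blur into one plateau become one hot spot).
Nearest-neighbour (order 0) is used for label grids; the background
threshold is applied after resampling by default, with the opposite order
available in the configuration.

Reconstructed counts are not calibrated to injected megabecquerels, so the
"1 % of injected activity" background rule is realised semi-quantitatively:
voxels below `fraction` (default 0.01) of a reference value are zeroed.
The default reference is the global maximum voxel value — the injection
depot dominates every image, so this tracks the injected activity while
never erasing the depot itself; a total-counts reference is selectable.
Suppression is idempotent and never zeroes the global maximum.

### Hot-spot segmentation

Seeds are local maxima under a moving 3×3×3 mask: every positive voxel
whose value is ≥ all in-bounds 26-neighbours. On a flat plateau of equal
connected values exactly one seed is kept, at the lexicographically
smallest (x, y, z) index — the rule is arbitrary but a deterministic
tie-break is required. From each seed a region grows breadth-first over
26-connectivity; a neighbour *n* of an accepted voxel *c* is accepted iff
`0 < v(n) ≤ v(c)`. A voxel rejected from one parent may be accepted later
from another, so each claim set equals monotone-path reachability from its
seed — the property the test-suite oracle checks by naive fixpoint
iteration. Claim sets are grown independently per seed; voxels claimed by
two or more seeds are then deleted from every claim set. This guarantees
pairwise disjointness (no spot is absorbed by a neighbour); remaining
voxels of different spots may still be adjacent, which the segmentation
reports as a residual-adjacency count rather than eroding further. Hot
spots that lose their seed (or all voxels) to the shared set are discarded
with a log entry. Border voxels use truncated neighbourhoods; no padding
value is invented. Recursion is realised with an explicit queue, so region
size is not limited by stack depth.

### CT tissue context

CT voxels are partitioned by Hounsfield thresholds into air (< −200), fat
([−200, −20)), muscle ([−20, 150)) and bone (≥ 150). The printed bounds
are touching, so half-open lower-inclusive intervals make the partition
total and deterministic; the classification is monotone in HU. Bone is not
homogeneous at low-dose CT (trabecular gaps, marrow), so the binary bone
mask is replaced by its morphological closing with a ball element,
default radius 3 mm — enough to close trabecular gaps without bridging
distinct bones. Out-of-grid voxels count as foreground during the erosion
half of the closing, so the operation is extensive (no bone voxel is ever
lost) and idempotent. The body mask is the largest 26-connected non-air
component with holes filled per axial slice: interior gas (bowel) counts
as inside the body, surrounding air does not.

### Classification

A lymph node cannot lie outside the body, in bone, or in air, and SLNs are
embedded in fatty and connective tissue. CT values *inside* a hot spot are
deliberately not used — at low-dose resolution the nodal tissue itself is
not resolvable — so the CT evidence is the tissue composition of a thin
shell (default 2 mm) around the spot. The hard criteria for a true finding
(all must hold, each threshold configurable, none hard-coded):

| criterion | default | unit |
|---|---|---|
| not flagged as injection site | — | — |
| inside-body fraction | ≥ 0.5 | — |
| shell fat+muscle fraction | ≥ 0.5 | — |
| shell bone fraction | ≤ 0.3 | — |
| shell air fraction | ≤ 0.3 | — |
| volume | ≥ 8 | mm³ |

The probability score is `p = w_spect · (peak / global max) + w_ct ·
(shell soft-tissue fraction)` with default weights 0.5/0.5, clipped to
[0, 1]. It is treated as an ordinal ranking score, not a calibrated
probability; it is monotone in both inputs by construction. Every hot spot
receives a verdict — none is dropped — and the two output lists order true
findings by descending and false findings by ascending probability (most
confidently false first), ties broken by descending peak then label.

The injection depot dominates uptake and must never appear among the
candidates. Auto mode flags the hot spot with maximal total counts; when
the injection location is known (as it is for the operators, and for
phantoms), coordinate mode flags every spot whose centroid lies within the
exclusion radius (default 30 mm) of the given point.

Side is assigned by the centroid x against the midline (auto midline =
body-mask centroid; an exact tie goes right and is logged). The
inguinal/secondary split uses a single axial landmark plane supplied in
the configuration — no computable anatomical rule exists for it without an
atlas, which is out of scope; phantoms emit the plane in their ground
truth.

### Evaluation statistics

Confusion counts a (TP), b (FP), c (FN), d (TN) with sensitivity
`a/(a+c)`, specificity `d/(b+d)`, FP rate `b/(b+d)`, FN rate `c/(a+c)`.
`d` may be unknown (only positive calls adjudicated); any rate whose
denominator is unavailable is returned as `NA` ("undefined"), never 0.
Report formatting follows the field's presentation — percentages to one
decimal, proportions to three — while full precision is kept in the
objects. Per-unit rollups (patient, groin) return both the crosstab rates
(conditioned on truly positive units) and event proportions over all units
(e.g. complications); these are distinct quantities and are never
conflated. Phantom runs are scored by greedy matching of true findings, in
descending probability, to planted nodes within 10 mm — greedy rather than
optimal assignment because phantom nodes are well separated by
construction, and the simpler rule is deterministic.

## The phantom

The generator emulates the statistical structure the detector assumes. On
CT: an ellipsoid body (semi-axes 42×34×60 mm) with a 10 mm subcutaneous
fat shell and muscle interior; a spine-like posterior cylinder and two
femur-like cylinders (HU 700); one bowel-gas sphere; Gaussian HU noise
(sd 20). Class centres (−1000/−100/40/700) sit well inside the
segmentation intervals so the noise rarely flips labels. On SPECT: an
extended injection depot (10 mm-radius sphere, 10⁶ counts — an intradermal
depot is a blob, not a point, which keeps its blurred peak low enough that
the 1 %-of-maximum threshold stays below the faintest node) and
4 mm-radius nodes carrying 0.1–2 % of the depot activity each (defaults
1 %, 0.6 %, 0.3 %). Decoys with node-like activity are planted where a
lymph node cannot be: inside bone, outside the body, and centred at the
gas-pocket boundary.

Counting noise is drawn as Poisson counts from the painted activity and
the Gaussian PSF (default FWHM 8 mm) is applied afterwards. The order
matters: noise arises in the acquired counts, while the PSF here stands
for the system resolution *including* the reconstruction's Gaussian
post-filter, so the emitted volume is smooth — like reconstructed emission
data, which is what the local-maxima segmentation is designed for.
Applying Poisson noise after the blur would produce a voxel-wise-rough
field no reconstructed SPECT resembles, on which any plateau-based seed
detector degenerates.

A single master seed drives everything through fixed-order derived
sub-seeds (node placement, CT noise, Poisson noise), so switching one
component off does not perturb the others and equal seeds give
byte-identical volumes. Random node placement rejects positions outside
the soft-tissue interior, within 12 mm of bone or gas, or closer than
32 mm to the depot, the decoys or each other, and restarts the whole
configuration when a partial layout dead-ends. `degrade_to_native()`
block-averages the 1 mm pair down to the native scanner grids (4 mm SPECT,
1×1×5 mm CT) so the resampling step can be exercised end to end.

What the phantom does *not* model: attenuation, scatter, reconstruction
artefacts, anatomical variability, organ parenchyma, and partial-volume
effects beyond Gaussian blur. Passing phantom tests therefore demonstrates
the correctness and robustness of the algorithmic chain under controlled
noise, not clinical performance; patient-level sensitivity/specificity
cannot be reproduced without patient data.

## Problem sizes and runtimes

The test suite validates the segmentation against a brute-force
monotone-path oracle on 1000 random grids up to 6×6×6 with values in 0–4
(every plateau and tie configuration arises at this size), the tissue
partition on 10⁶ random HU values, and the full pipeline on 20 noisy
96×96×128 phantoms with randomised node placement (~1 minute). The
acceptance script repeats the phantom study with seeds derived from its
`--seed` and recomputes the published crosstab quantities through the
statistics functions.

## Known limitations

- Strict voxel-level *non-adjacency* of hot spots is not guaranteed, only
  disjointness; residual adjacency is reported, not eroded.
- The probability score is ordinal; its weights are not fitted.
- The inguinal/secondary boundary is a single plane, not an anatomical
  atlas; oblique drainage territories are out of scope.
- DICOM series ingestion is not implemented; convert to NIfTI first.
- No learning from expert corrections: the rule set is fixed by
  configuration.
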