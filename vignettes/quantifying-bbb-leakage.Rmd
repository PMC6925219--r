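---
title: "Quantifying BBB leakage and microglia-vessel interaction in two-photon stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying BBB leakage and microglia-vessel interaction in two-photon stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselquant)
```

## The measurement problem

In vivo two-photon imaging of the cerebral cortex yields multi-channel
z-stacks: a genetic reporter marks microglia, and intravenously injected
dextran-conjugated fluorophores of graded molecular size (10, 40, 70 kDa)
fill the vasculature. An intact blood-brain barrier confines all three
tracers to the lumen; inflammation can open the barrier size-selectively,
letting small dextrans into the parenchyma while larger ones stay
intravascular. The same stacks show microglia migrating to and contacting
vessels. This package turns those images into numbers: a relative leakage
index per dextran size, a per-cell vessel-contact verdict, colocalization,
and morphological and motility measurements of individual microglia.

Because no public image data accompany this kind of experiment, the
package ships a synthetic scene generator with complete ground truth.
Every quantification stage is validated against scenes whose vessel
geometry, cell placements, leak fractions, puncta counts, frame shifts
and tip movements are known exactly.

## Pipeline stages and their models

### Registration, projection, depth selection

Time-lapses are corrected for lateral drift by translation-only
registration: each frame is aligned to the first at the integer shift
maximizing the FFT cross-correlation of mean-subtracted frames. Subpixel
refinement is deliberately off — integer shifts make the correction
exactly invertible and the downstream measurements deterministic.
Rotation and axial drift are not modeled. Borders exposed by the
correction are filled with the modal image value, i.e. the background
plateau, which leaves extravascular intensity means unbiased.

Analysis images are maximum-intensity projections over a slice range
(default 10 slices at a 2 um step). Depth selection keeps the 100-200 um
band below the pia (cortical layer II/III): the field is divided into
50 um sections and the two most superficial ones are excluded to avoid
surgical artefacts. The window is half-open `[100, 200)` and a slice
belongs to it by its center depth, so a 2 um-step stack starting at the
pia contributes slices 51-100 (1-based).

### Vessel delineation

Vessels are segmented on the projected image of the *impermeant* 70 kDa
channel — the mask must not be eroded by the leak it is used to measure.
The threshold is the maximum-entropy (Kapur) criterion: over a 256-bin
histogram spanning `[min, max]` (the 8-bit ImageJ convention), the
threshold maximizes the sum of Shannon entropies of the normalized
below- and above-threshold partitions. Ties are broken toward the
smallest threshold so results are reproducible. The binarized image is
hole-filled (a lumen darker than the wall still belongs to the vessel),
8-connected components are labeled, and components below 40 um^2 are
discarded; the bound is inclusive. The test suite checks the threshold
against an independent exhaustive-search implementation of the same
criterion on every image class it generates.

Thresholding is applied to the projection rather than per z-plane;
per-plane masking would only matter for vessels running steeply through
the volume, which the straight-tube phantoms do not exercise.

### Leakage indexing

Permeability is the arithmetic mean of dextran-channel intensity over
parenchymal pixels — everything outside the vessel mask after dilating
it by 1 px to absorb partial-volume bleed at the wall (the margin is
configurable; no particular value is canonical). Indices are reported
relative to the mean of the control group, so the control group averages
exactly 1.00 by construction. When a longitudinal series is analyzed the
reference can instead be a baseline session (`reference_mode =
"baseline_day"`). Whether parenchymal means should exclude microglial
somata is left as measured — no exclusion — since the soma area fraction
is small and the choice applies equally to all groups.

### Vessel-associated microglia

A microglia is vessel-associated when the gap between its reporter
signal and the vessel signal, read along a line profile, is below 1 um
(4 px at 0.254 um/px). The implemented rule follows the four manual
steps: draw a line from the presumed cell center to the vessel, sample
both channels at unit-pixel steps (nearest-pixel lookup, so the gap is
an integer pixel count), subtract each profile's own standard deviation
from its samples and clamp at zero, then take the distance between the
index where the adjusted reporter first reaches zero (and stays zero)
and the index where the adjusted vessel signal first rises. Overlapping
signals (gap <= 0) are contacts. The criterion is applied in micrometers
so calibrations other than 0.254 um/px behave sensibly; at that
calibration the verdict flips exactly between 3 and 4 px.

Two ambiguities had to be resolved. The standard deviation could be
taken over the profile or the whole image; the profile's own SD is used,
because the rule's "decreases to zero" reading is then self-normalizing
per profile. And the "presumed center" is operationalized as the soma
centroid, with the profile aimed at the nearest vessel-mask pixel and
extended a few pixels into the vessel — a deterministic surrogate for
the manual line. A soma centroid already inside the vessel mask is a
contact with gap 0.

Colocalization is the plain Pearson correlation of paired pixel
intensities within an ROI. The thresholded (Costes) variant is not
implemented; nothing in the workflow depends on it.

### Morphometry, puncta, coverage, motility

Somata are segmented automatically (maximum-entropy threshold, then a
1.5 um morphological opening that removes the thin processes, then
8-connected labeling) — a reproducible stand-in for manual tracing.
Processes are measured by skeletonizing the cell mask minus the soma
with Zhang-Suen thinning. Each skeleton component approaching the soma
within 2.5 um is one process; its length is the geodesic skeleton path
from the soma-exit pixel to the farthest tip plus the small gap thinning
leaves at the junction. Path length is measured on the skeleton polyline
resampled every 5 px: the naive sqrt(2)-weighted chain length
overestimates digital straight lines by up to ~8% at shallow angles,
and resampling removes that staircase bias. Fragments shorter than
1.5 um are slivers of imperfect soma subtraction and are ignored.

CD68 puncta are counted inside the cell mask after maximum-entropy
thresholding of the puncta channel, keeping components within an area
band (0.1-10 um^2 by default); a cell is CD68-positive with strictly
more than two puncta. The analogous AQP4-inclusion flag uses the same
machinery with a threshold of one punctum — no count rule exists for
AQP4 inclusions, so the weakest sensible rule (any detectable
inclusion) is the package's choice. Pericyte coverage is the percentage
of the vessel-surface mask overlapped by the marker mask.

Motility is measured on registered time-lapses: process tips are
skeleton endpoints outside a soma-exclusion radius, linked greedily to
the nearest endpoint in the next frame within a 2 um/frame gate (above
microglial process speeds, below the inter-tip spacing of the
fixtures), and a cell's motility is the mean per-interval tip
displacement in um. This operationalizes a quantity that is usually
reported only as a plotted trend; absolute cross-study motility values
should not be compared against it.

## The synthetic generator

The generator renders what the quantification needs and no more:

* **Vessels** are straight cylinders along x (default radius 3 um,
  capillary scale), bright in every dextran channel. No flow, no
  branching, no pulsation.
* **Leak** is an extravascular halo decaying exponentially from the
  vessel wall (length constant 10 um) whose *integrated* extravascular
  intensity equals `leak_fraction` times the integrated intravascular
  intensity — exactly, by normalizing the rendered halo. Real
  extravasation has kinetics and spatial structure the generator does
  not claim to model; the halo exists so that a configured fraction can
  be recovered by the measurement chain.
* **Microglia** are spheres (soma, default radius 3 um) with straight
  tapering-free processes fanning away from the vessel, rendered as
  1 px-radius tubes so skeletonization is well-posed. The soma edge
  therefore defines the cell-to-vessel gap, which is the placement
  parameter. Processes pointing toward the vessel, overlapping cells and
  3D-tortuous arbors are not modeled.
* **Puncta** are small bright blobs placed inside the soma with a
  minimum separation so each survives thresholding as its own component.
* **Noise** is Poisson shot noise (gain = photons per intensity unit)
  plus Gaussian read noise, both off by default and enabled as
  `default_noise()` (gain 1, sd 20) in integration tests — the
  shot-noise-limited regime of GaAsP detection. No PSF beyond the
  rendering's inherent blur, no photobleaching, no motion within a
  frame.

Scenes default to 0.254 um/px and 2 um z-steps — the acquisition
calibration — on fields of 192-480 px, which keeps the whole validation
suite in the minute range while leaving every geometric quantity several
pixels wide. All randomness flows from one root seed through named
substreams (noise, jitter, puncta), so a configuration renders
bit-identically and adding one stochastic element never perturbs
another. Arrays are indexed `(z, y, x)` 1-based, the natural R
convention.

Passing on this material demonstrates that the measurement chain is
correct and unbiased under its own assumptions; it does not certify
performance on real tissue, where vessel tortuosity, depth-dependent
scattering, motion within frames and overlapping arbors add failure
modes the phantoms exclude.

## Numerical choices worth knowing

* Threshold ties take the smallest candidate; histogram bins span
  `[min, max]` of the data, so adding a constant shifts the threshold by
  that constant.
* Constant images, empty masks, empty manifests, missing channels,
  unreachable vessels and unregistrable (constant) frames raise classed
  errors (`vq_*`) rather than producing silent numbers.
* The contact rule is strict: gap exactly 4 px at 0.254 um/px
  (1.016 um) is *not* a contact.
* The 40 um^2 particle bound is inclusive; areas are pixel counts times
  the squared pixel size, with no subpixel correction.
* Registration assumes the true shift is below half the field;
  cross-correlation peaks are wrapped accordingly.
* `run_experiment()` stamps every CSV row with an FNV-1a hash of the
  full configuration; identical configs and seeds give byte-identical
  reports.

## Limitations

The package quantifies projected 2D geometry; process lengths of
strongly z-oriented arbors are underestimated by projection, and the
fixtures place processes in-plane. The leakage index is relative, not a
permeability coefficient — no tracer kinetics are modeled. Statistical
comparison across groups (t-tests, ANOVA) is out of scope; the reports
carry means and SDs only.
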