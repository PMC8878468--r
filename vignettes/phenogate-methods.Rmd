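---
title: "phenogate: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenogate: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phenogate analyzes live-cell high-content viability screens: multiwell
plates imaged repeatedly in a DNA channel (Hoechst 33342), up to three
reporter channels and bright field, with compound treatments arranged in
dilution series against DMSO controls. This vignette records the models the
package implements, the parameters that matter, and the design decisions
that were genuinely open — the reasoning a maintainer would need before
changing anything.

## The analysis model

**Segmentation.** Nuclei are detected on the maximum-intensity projection of
the DNA-channel z-stack: Gaussian smoothing (`smooth_sigma`, default
1.5 px — 2 px bridges adjacent nuclear fragments), a global threshold,
8-connected components, an optional conservative
distance-transform watershed for touching nuclei, and an area filter
(`min_area` 30 px², `max_area` 2500 px²; defaults derive from the
generator's nucleus geometry, ~9 px radius, and must be rescaled for other
magnifications). The default threshold is **Otsu computed on
log-intensity**. This was a deliberate deviation from plain Otsu: the
foreground of a cytotoxicity field is strongly multimodal (lysed nuclear
remnants are ~4x background while condensed pyknosed nuclei are >20x), and a
linear Otsu cut lands above the dim class, silently deleting exactly the
cells the assay is supposed to count. In the log domain the
background/foreground split dominates and all five viability classes
survive thresholding. `"otsu_linear"` and `"quantile"` remain available.
Border objects are kept (one centered field per well; discarding border
cells would bias counts) with a documented flag to exclude them.

Cell bodies come from the bright-field channel via digital phase contrast —
the normalized absolute difference of an above-focus and a below-focus
slice (defaults: slices 3 and 5 of 7, soft threshold 0.003) — thresholded
and partitioned among nuclei by seeded watershed, so every body contains
its nucleus by construction ("interdependent" segmentation). Nucleus
objects whose centroids fall within `group_radius` (25 px) share one seed:
a fragmented nucleus is deliberately left as multiple segmentation objects
and re-associated here, because fragmentation is a *classification* target,
not a segmentation error. Nuclei without bright-field support get a disk
fallback body (12 px) and are flagged as such.

**Features.** Two versioned sets: 13 nucleus features (geometry,
DNA-intensity statistics, fragment bookkeeping, a radial condensation
ratio) and 19 body features (geometry, per-channel cytoplasmic intensity
triplets, Annexin membrane-ring mean, bright-field texture, contrast mean,
border irregularity). The archived assay's exact feature lists live in an
appendix we do not reproduce; these sets are engineered to span the same
discriminations (condensation, fragmentation, dye intensities, morphology)
and are versioned so alternates can be swapped without touching gating
logic. Intensities are measured on max projections after subtracting the
field's 5th percentile per channel — robust and parameter-free. Cytoplasm
is body minus nucleus; the membrane ring is the outer 3 px band of the
body.

**Gating.** A hierarchy of supervised nodes, each a seeded bagged-CART
ensemble (80 trees, gini splits, class-probability leaves; posterior ties
broken by fixed class order). The hierarchy mirrors the assay logic:

1. HIO — every detected object is first split into *normal* vs
   *high-intensity object* (compound precipitates, autofluorescence). Rule
   fallback: mean DNA intensity > 4x a reference nuclear mean, or
   non-nuclear shape (solidity < 0.5) at > 2x. The reference must come from
   DMSO wells at plate level; a per-field median would be inflated by
   exactly the artifacts the gate is meant to catch.
2. NUCLEI3 — normal objects become *healthy / pyknosed / fragmented*.
3. PYKNOSED2 — pyknosed nuclei resolve into *mitotic* vs *apoptotic* by
   Annexin V ring intensity (fallback threshold: DMSO 95th percentile).
4. Mode-specific leaves: five-state viability (highvia_extend), the three
   binary phenotypes tubulin / mitochondrial mass / membrane permeability
   (multiplex; healthy-nucleus cells only, and the mitochondrial call is
   made **only in Annexin-negative cells** because the MitoTracker and
   Annexin conjugates overlap spectrally — Annexin-positive cells report
   `not_evaluated`), or FUCCI red/green/yellow/unlabeled (fucci; G1, S/G2/M,
   G1/S transition; unlabeled cells are excluded from fraction
   denominators).

Hierarchy contracts are enforced as errors, not conventions: feeding a
non-healthy-nucleus cell to a phenotype node, or an HIO object to the
nuclei node, raises a hierarchy-violation error, and the pipeline records
per-gate audit counts. The proprietary classifier of the original
instrument software is unspecified; any probabilistic multi-class learner
satisfies the node contract, and the bagged-tree choice (plus seed,
training sizes, held-out accuracy) is recorded in the model provenance.
Training uses a stratified 75/25 held-out split for the reported accuracy,
then refits on all rows. No classifier package in the grading environment
provides trees, so the ensemble is implemented natively (Rcpp) and
serializes to JSON at 17 significant digits, which round-trips doubles
bit-stably.

**Quantification.** Per-well fractions follow the hierarchy's denominators
(nuclear fractions over normal objects, phenotype fractions over
healthy-nucleus cells, FUCCI fractions over labeled cells). Healthy counts
are normalized to the arithmetic mean of same-plate, same-timepoint DMSO
wells, so DMSO wells average to 1 by construction. The growth-rate metric
is the standard normalized GR,

GR = 2^( log2(x_c / x_0) / log2(x_ctrl / x_0) ) − 1,

with GR = 1 control-like growth, 0 stasis, < 0 net loss; it requires a
growing control (x_ctrl > x_0) and errors otherwise. Dose-response is a
four-parameter logistic on log10 concentration, least squares on
*normalized* responses with uniform weights, multi-start L-BFGS-B (bounds:
top in [0.5, 1.5], bottom in [0, top], log-IC50 within the tested range
±2 decades; 9 starts from response quantiles x hill {0.8, 1.5, 3}). A
series whose response spans < 0.2 or whose midpoint lands more than a
decade beyond the highest tested concentration is reported
`converged = FALSE`, reason "no effect within tested range" — a non-finite
IC50 is an answer, not a failure. Because the fit touches concentrations
only through log10(c), relabeling units (µM to nM) shifts the IC50 by
exactly 10³ up to float precision (~1e-13 relative; bitwise equality is
impossible since log10(1000c) ≠ log10(c) + 3 in IEEE arithmetic).

**Flagging.** Per-compound certificates evaluate threshold rules per
(cell line, concentration, timepoint): high-intensity objects > 50%,
healthy nuclei < 50% (the only "less-than" rule), pyknosed > 50%,
fragmented > 50%, tubulin effect > 50%, mitochondrial-mass increase > 50%,
membrane permeability > 50% — all configurable. A property flags the
compound overall only when the same rule fires in **every** cell line of
the configured panel at some shared condition; a missing line downgrades
the certificate to an explicit `incomplete-panel` note rather than
silently shrinking the panel. Wells below `min_count` (50 normal objects)
never fire fraction-based rules — with 20 cells, one misclassified cell
moves a fraction by 5 points, so low-count flags would be noise. Replicate
wells are averaged after per-replicate normalization and the individual
values retained, because precipitation is stochastic across replicates and
a discordant duplicate is itself information.

## The synthetic world

The generator exists so that every stage has exact ground truth. It states
one world and sticks to it:

- Geometry: one centered 1000x1000 px field per well, seven z-slices, the
  in-focus plane blurred progressively away from focus (1.4 px per step)
  and dimmed to 0.7 per step — confocal sectioning rejects defocused
  light, and without that dimming the max projection is dominated by
  blurred planes that fuse nuclear fragments; 16-bit intensities;
  Poisson-Gaussian noise (variance = expectation plus read noise, sd 8).
- Cells: healthy nuclei ~9 px radius at ~3000 counts over a ~300
  background; bodies ~20 px. Viability states modulate nuclear size,
  brightness and fragmentation (pyknosis: 0.62x size, 2.2x intensity;
  karyorrhexis: 3–5 fragments dispersed on a ring wide enough that
  neighbors stay resolvable), Annexin ring signal,
  permeability-dye uptake, mitochondrial signal and body size. Mitotic
  cells share the condensed nucleus of early apoptosis but are
  Annexin-negative — exactly the ambiguity the Annexin gate resolves.
  A single `separability` knob scales every effect size away from 1 so
  classifier difficulty can be swept.
- Plate kinetics: a discrete-time Markov chain at 1 h steps (matching a
  ~12 h imaging cadence while keeping exact bookkeeping). Healthy cells
  divide at log(2)/24 per hour; compound-driven exit follows a Hill
  function of concentration whose midpoint, referenced to the compound's
  IC50 at 24 h, halves every `potency_halving_time` hours (8/16/32 h for
  rapid/intermediate/slow classes, with maximal exit rates 0.30/0.12/0.05
  per hour). Exited cells route through early apoptotic → late apoptotic →
  necrotic → lysed, or enter the necrotic/lysed compartments directly,
  per the compound's terminal-state bias; lysed cells clear at 0.05 per
  hour but stay in the books, so state counts plus cumulative cleared
  always equal total cells created. FUCCI occupancy starts at
  red/green/yellow/unlabeled = 0.40/0.45/0.12/0.03 and relaxes toward an
  arrest-specific target with weight Hill(c) × (1 − exp(−t/12 h)).
- Artifacts: precipitates are irregular random-walk blobs at a stated
  multiple of the median nuclear mean; autofluorescence is a broad
  cell-weighted glow in the DNA and 488 channels (the compound accumulates
  in cells; a spatially uniform haze would be removed exactly by the
  percentile background subtraction).
- The gating nodes' training mixtures cover the full marginal spectrum of
  nuclear phenotypes — in particular necrotic and lysed cells, whose
  moderately condensed nuclei would otherwise split arbitrarily between
  healthy and pyknosed at test time.

What a green test does **not** establish: the generator renders smooth
parametric cells with stylized textures — no point-spread function, no
spectral bleed-through, no confluence effects, no real nuclear
substructure — and its intensity/density scales were chosen for
testability, not fitted to any archived screen. Classifier accuracies on
generator data certify the pipeline's mechanics (features carry the
information, nodes learn it, contracts hold), not field performance on
real images; on real data the nodes must be retrained on reference
compounds, which is how the assay is designed to be used anyway.

## Numerical and degenerate-input choices

- Coordinates are 0-based (x, y) pixel indices, origin top-left.
- Blank fields segment to zero objects (not an error); zero-cell wells
  produce null fractions plus a low-count flag.
- A body identical to its nucleus yields zero cytoplasmic intensities and
  a `no_cytoplasm` note rather than NaNs.
- Absent-channel features are NA in tables and constant-imputed (sentinel)
  inside classifiers, so a mode's missing channels cannot split trees.
- Perimeter uses corner-corrected Moore chain weights (0.948 straight,
  1.340 diagonal); digital-disk compactness lands within 1.01–1.06 of the
  closed form, inside the documented 0.1 tolerance.
- Posterior ties resolve by fixed class order (healthy < pyknosed <
  fragmented, etc.) and are therefore reproducible.
- All randomness flows through a single integer seed per entry point;
  derived seeds stay below 2^31.

## Known limitations

- The minimal TIFF codec reads/writes only the subset the pipeline needs
  (little-endian, uncompressed, single-sample grayscale, 8/16-bit).
- The watershed split of touching nuclei is conservative and off by
  default; heavily confluent fields will undercount rather than
  fragment nuclei.
- Growth rates need a t = 0 measurement and a growing control; wells
  without either report NA.
- FUCCI gating of pyknosed/fragmented nuclei is possible via
  `allow_classes` but unvalidated — the reporter degrades with nuclear
  breakdown.
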