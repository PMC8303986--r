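---
title: "Dose-rate metrics for proton PBS FLASH fields: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-rate metrics for proton PBS FLASH fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsflash)
```

## The problem

Ultra-high dose rates (> 40 Gy/s) appear to spare normal tissue relative to
conventional radiotherapy at equal dose — the FLASH effect. Cyclotron-based
proton systems can reach such rates in transmission (shoot-through) mode,
where a single high-energy layer passes its plateau through the patient.
But pencil-beam scanning (PBS) delivers dose as hundreds of sequential
Gaussian spots, so "the dose rate" of a voxel is genuinely ambiguous: it
depends on whether one counts the instantaneous rate of each spot, the time
between spots, or only the spots that matter dosimetrically. Three metrics
are in use, and they disagree by an order of magnitude on the same field.
This package computes all three, voxel by voxel, together with the machine
and delivery model they require, so that planning studies can report them
side by side.

## Machine model

A layer's cyclotron beam current is set by the plan's **minimum MU per
spot**: the machine must be able to deliver its smallest spot in the fixed
minimum-MU dwell time (2 ms by default), so the layer runs at
`minMuPerSpot / dwellTimeMinMu` MU/s. Monitor units convert to protons
(5.17e6 protons/MU for a high-energy transmission beam) and hence to nozzle
current. The dose side of the calibration is a single anchor: at the
machine's highest transmission (~640 nA) the spot peak dose rate (SPDR, the
on-axis maximum of a single spot near 4 cm depth in water) is 2600 Gy/s.
From the anchor we derive one dose-per-MU constant

k = SPDR_cal / (I_cal / e / protonsPerMU) ≈ 3.365e-3 Gy/MU,

and SPDR = k × MU-rate for any minimum-MU setting: ~168 Gy/s at 100
MU/spot, ~673 Gy/s at 400 MU/spot. We derive k from the anchor rather than
from a physical spot-dose integral: the integral route needs an absolute
spot model (sigma, integral depth dose) that a planning study typically
does not have, while the anchor is a published machine characteristic. The
chain is linear, so `spdrFromMinMu`, `currentFromMinMu` and
`minMuFromCurrent` are exact inverses of one another.

Spots heavier than the minimum MU dwell proportionally longer at the same
instantaneous rate (the layer current is fixed); the energy-layer switching
time plays no role because transmission plans are single-energy.

## Delivery timeline

`buildTimeline` lays the spots of a field on a time axis: the first spot
starts at t = 0, each spot occupies its dwell, and consecutive spots are
separated by the lateral Euclidean distance divided by the scan speed
(10 mm/ms by default, also used for inter-row repositioning — the machine
literature does not distinguish the two, and on a serpentine path the
distinction is immaterial since all hops are one lattice spacing). No dose
is delivered during transits, and dose within a dwell accrues at a constant
rate: each spot is a rectangular pulse. The cyclotron's MHz pulse
microstructure is far below this model's resolution and is deliberately
ignored.

The default scan pattern is row-serpentine (`serpentineOrder`): rows sorted
by y, alternate rows reversed, ties broken by x then input index. On a
lattice it minimizes travel, and it is the pattern implied by the
edge-strip structure that the ADR map develops at the outermost scan lines.
Any explicit order can be supplied instead, which matters because ADR is
scanning-direction dependent. Fields carry their own time origin and are
treated as temporally disjoint; inter-field dead time is not modeled
because every metric here is computed per field.

## Dose engine

The per-spot kernel is a lateral Gaussian around the spot axis,
`exp(-r² / 2σ(z)²)`, scaled by the layer SPDR and by a depth factor
normalized to 1 at the SPDR reference depth (40 mm). Defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `sigma0` | 4.0 | mm | clinical spot sigma range for ~240–250 MeV beams is 3–6 mm; results quoted below are checked across that range |
| `sigmaGrowth` | 0.02 | mm/mm | mild multiple-Coulomb-scattering growth in the plateau |
| `depthAttenuation` | 5e-4 | /mm | slow linear on-axis loss (protons scattered out of the core) |
| `peakDepthRef` | 40 | mm | depth where the SPDR of a transmission spot is defined in water |
| `cutoffRadius` | 3.5 | σ | keeps > 99.8% of the lateral integral |

This flat-plateau-with-linear-trends model is a deliberate simplification
of a full pencil-beam convolution-superposition engine. It preserves every
property the dose-rate metrics probe — the lateral Gaussian (1% of peak at
3σ), monotone depth attenuation, and field-edge effects — while remaining
exact enough that the minimum-MU spot's center dose is SPDR × 2 ms (2.6 Gy
at the 1300 Gy/s benchmark setting) by construction. It has no nuclear
halo, no second Gaussian, no heterogeneity corrections.

`buildInfluence` superposes the kernel over all spots into a sparse
voxel-by-spot dose matrix (a `Matrix::dgCMatrix`). Because each spot is a
rectangular pulse, the instantaneous rate of an entry is exactly
`dose / dwell`; the matrix therefore stores only doses and the per-spot
dwells, and the invariant D = Ḋ × τ holds to machine precision. Voxels are
sampled at their centers (2 mm default grid, no sub-voxel integration).

## The three metrics

**DADR** is the dose-weighted mean rate; it is computed in closed form from
the sparse matrix. Voxels with zero dose are undefined.

**ADR** builds each voxel's piecewise-linear cumulative dose d_j(t) from
its entries and the timeline, finds t₀ and t₁ with d_j(t₀) = d\* and
d_j(t₁) = D_j − d\* by linear interpolation inside the crossing dwell
segment, and returns (D_j − 2d\*)/(t₁ − t₀). When a threshold is hit
exactly at a segment boundary the *earliest* crossing time is used; the
choice is deterministic and measure-zero for continuous inputs. Voxels with
D_j ≤ 2d\* are undefined. The interpolation is validated in the test suite
against a naive 1 µs fixed-step time integration (agreement within 0.1% on
random fields); for a single uninterrupted linear ramp ADR equals the ramp
slope exactly.

**DTDR** is the minimum rate among spots whose individual contribution
exceeds d\*; with no qualifying spot the voxel is undefined. Ties between
equal minimum rates do not affect the value (the first spot index would be
the reported argmin). On a uniform minimum-MU field every qualifying spot
has Ḋ = D/τ with D > d\*, so DTDR > d\*/τ = 50 Gy/s everywhere it is
defined — which is why DTDR coverage at 40 Gy/s is always 100% on such
fields, independent of sigma.

The ADR window-trimming threshold and the DTDR qualification threshold both
default to 0.1 Gy but are independent configuration keys
(`adrDoseThreshold`, `dtdrDoseThreshold`): they play different roles and
there is no physical requirement that they be equal. DTDR is computed per
field; no cross-field DTDR is defined.

**Undefined voxels** are excluded (`NA`) rather than assigned 0, because
DRVHs are built over irradiated voxels only and a 0 Gy/s entry would
corrupt coverage statistics; the `undefinedPolicy = "zero"` option exists
for sensitivity checks.

## Histograms and statistics

DVHs and DRVHs are cumulative ("volume at or above"), built over a voxel
mask and the metric's defined voxels. Statistics (V_40Gy/s, D2%, Dmax,
mean) are computed from the raw voxel values retained in the object, never
from the rebinned curve. Plan-level DRVHs pool per-field histograms with
multiplicity — a voxel irradiated by k fields contributes k samples. This
convention matches per-field dose-rate reporting and differs from
per-voxel combination rules (max or min across fields), which would give
systematically different plan curves; the choice is therefore explicit in
`poolFields` documentation. Because pooling needs only per-field samples,
multi-field plans never require resampling fields onto a shared grid: each
field is computed in its own beam's-eye-view frame.

For benchmark coverage the evaluation mask is the **field footprint**: the
convex hull of the spot centers, at the reference-depth voxel slab. The
Gaussian tails extend laterally without bound, so "percent of the volume"
is ill-posed without such a convention; the hull is grown by a relative
sliver (1e-9) so lattice points lying exactly on the boundary are included.
Degenerate footprints (a single spot, a collinear row) fall back to a
bounding-box test.

## Synthetic fixtures

The generators produce every input the engine needs:

- `makeUniformField` — the water-phantom benchmark: 5 × 5 cm², 5 mm
  spacing, 121 uniform minimum-MU spots, serpentine order. Uniform
  minimum-MU weights are the only self-consistent reading of a benchmark
  that fixes just an SPDR. The `spdrOverride` argument pins the layer SPDR
  (1300 Gy/s for the benchmark) so the calibration chain can be bypassed
  where a published comparison fixed the rate directly.
- `makeSingleSpot` — the SPDR-defining configuration.
- `makeMultifieldCylinder` — a synthetic stand-in for patient anatomy:
  five fields at 72° intervals covering a 40 mm × 60 mm cylinder
  (median-lung-target scale). It is illustrative only: it has the geometry
  and timing structure of a multi-field plan but makes no claim of
  reproducing any patient result. Optional MU jitter (seeded,
  deterministic) produces non-uniform-weight variants.

What the fixtures do **not** emulate: optimized (non-uniform) clinical spot
weights, CT heterogeneity, range straggling, setup/motion uncertainty.
Passing tests on these fixtures validate the metric definitions and the
delivery model, not patient-plan dose accuracy.

## What the benchmark shows — and a scale caveat

On the benchmark field (SPDR 1300 Gy/s, d\* = 0.1 Gy, 2 mm grid) all three
metrics cover 100% of the footprint at 40 Gy/s, and the qualitative
structure of the three maps is reproduced: DADR is uniform to within a
fraction of a percent; ADR develops elevated strips at the outermost scan
lines (edge voxels collect their dose in a short burst of adjacent rows);
DTDR peaks *between* spots, because a voxel at a spot center keeps that
spot's weak far neighbors above threshold.

Mean values over the footprint order as ADR (≈127 Gy/s) < DADR (≈681 Gy/s)
and DTDR (≈60 Gy/s) < DADR, but on this *small, fast* field the mean ADR
sits **above** the mean DTDR: the field delivers in 302 ms, so the
time-averaged rate cannot drop below ~85 Gy/s, while DTDR is pinned just
above d\*/τ = 50 Gy/s by barely-qualifying lattice neighbors. The
often-quoted ordering ADR ≤ DTDR ≤ DADR is a property of patient-scale
deliveries, not of voxel algebra — the package reproduces it at a 12 × 12
cm field (1.56 s delivery: means 55.5 ≤ 58.7 ≤ 666 Gy/s), and the test
suite asserts it at that scale. No per-voxel ordering holds in either
regime; counterexamples are easy to construct.

## Numerical choices and problem sizes

- Influence cutoff 3.5σ; doubling it changes footprint-mean ADR by < 0.3%.
- The benchmark grid spans the field plus an 8 mm lateral margin and a
  32–48 mm depth window with a voxel plane exactly at the 40 mm reference
  depth (34 × 34 × 9 voxels at 2 mm) — small enough that the full pipeline
  runs in about a second, large enough that the footprint slab is fully
  interior. Property tests use 20-spot random fields on 3 × 3 voxel probe
  grids, and the patient-scale ordering check uses a 4 mm grid on a single
  depth slab.
- Thresholds compare with strict inequalities as defined
  (D_{j,i} > d\*; D_j > 2d\*); dwell validation allows a 1e-9 relative
  slack so text round-trips of minimum-MU weights stay deliverable.
- All internal units are SI plus mm and MU: seconds, Gy, Gy/s, mm, MU;
  nanoamperes appear only in display output.

## Known limitations

- The depth model is a normalized linear plateau; it is not a measured
  integral depth dose, and absolute doses away from the reference depth are
  only qualitatively right.
- Single-energy transmission fields only; no energy-layer switching, no
  synchrotron delivery structure.
- Per-field metrics with per-field time origins; no inter-field or
  inter-fraction time structure.
- No radiobiological modeling: d\* is a dosimetric cutoff, not a
  tissue-specific FLASH parameter.
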