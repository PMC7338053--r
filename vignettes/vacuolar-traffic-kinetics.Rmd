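---
title: "Modeling and quantifying cargo traffic to the yeast vacuole"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying cargo traffic to the yeast vacuole}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vactraffic)
library(dplyr)
```

## The biological system

In budding yeast, a biosynthetic cargo destined for the vacuole leaves the ER,
transits the Golgi, accumulates in prevacuolar endosome (PVE) compartments that
sit on the vacuole surface, and finally reaches the vacuole lumen. Two kinetic
questions organize this package:

1. **When does vacuolar cargo leave a maturing Golgi cisterna?** Yeast Golgi
   cisternae are optically resolvable and mature individually: an early marker
   (e.g. Vrg4) is replaced by a late marker (e.g. Sec7). Cargo sorted by the
   Vps10 receptor is packaged by the GGA clathrin adaptors, which arrive with
   the late marker, so cargo exit is expected to begin near the early-to-late
   transition — not at the end of maturation.
2. **How does cargo move from PVE compartments to the vacuole?** PVE
   compartments are long-lived organelles: they are never seen to disappear by
   full fusion. Transfer instead proceeds gradually, punctuated by discrete
   kiss-and-run events in which a transient fusion pore passes a sizable
   fraction of the remaining cargo at once.

Both questions were answered with 4D (time-lapse 3D) confocal microscopy. The
raw live-cell movies behind those observations are not publicly deposited, so
this package pairs every analysis with a ground-truthed synthetic movie
generator that encodes the reported experimental conditions. Passing tests
therefore demonstrate that the *procedures* recover what the *model* puts in —
they do not re-measure real cells.

## The compartment kinetic model

`simulate_timeline()` simulates one cell as a small set of compartments with
analytic true-fluorescence series:

* **Cisternae.** The early marker falls and the late marker rises as logistic
  transitions with time constant `marker_tau` (default 8 s), crossing at the
  transition midpoint; the late marker departs one lifetime later. Cargo is
  constant until the midpoint, then
  - decays exponentially at `cargo_exit_rate` (default 0.02 /s) in `wildtype`
    and `apl4_null` modes (AP-1 is dispensable for vacuolar sorting),
  - persists in `gga_null` mode (no GGAs, exit abolished; marker transitions
    are also shallower, as observed in that background), and
  - transiently rises by `cargo_overshoot` then persists in `vps10_null`
    mode (no receptor; the cargo behaves like a secretory cargo and is
    eventually secreted).
* **PVE compartments.** Cargo leaves continuously at `pve_leak_rate` plus
  instantaneous kiss-and-run bursts scheduled as a Poisson process of
  intensity `burst_rate`; each burst removes a truncated-normal fraction of
  the remaining cargo. A compartment is delivery-quiescent for the whole
  movie with probability `quiescent_prob`. The PVE marker fluctuates as a
  multiplicative log-AR(1) and never reaches zero.
* **Vacuole.** One per cell. Everything a PVE loses is credited to the
  vacuole in the same frame, so in the vacuole-directed modes the summed
  cargo over all compartments is constant frame by frame (the conservation
  property the test-suite checks to 1e-6 relative). `vps10_null` is not a
  closed system — its cisternal overshoot is recycling inflow and its cargo
  leaves by secretion — so conservation applies to the other modes.

Burst execution is instantaneous between frames, matching transfers that
complete within a single stack interval. `apply_photobleach()` reproduces the
pre-acquisition bleach used before transfer movies: cargo in every non-PVE
compartment is scaled by `1 - efficiency` at the bleach frame, while cargo
arriving in the vacuole afterwards is unbleached.

### Default parameters and where they come from

| parameter | default | unit | basis |
|---|---|---|---|
| `burst_rate` | 1/300 | 1/s | reported burst frequency, about one per 5 min |
| `burst_fraction_mean`, `burst_fraction_sd` | 0.375, 0.15 | — | reported ~35–40% of remaining cargo per burst |
| `burst_fraction_range` | (0.16, 0.95) | — | events below the 15% scoring threshold are invisible to the statistic; very large events occur |
| `pve_leak_rate` | 5e-4 | 1/s | set once so bursts carry roughly three quarters of net transfer at the default burst parameters |
| `quiescent_prob` | 0.3 | — | a substantial minority of loaded PVE compartments delivers nothing at first |
| `cargo_exit_rate` | 0.02 | 1/s | post-midpoint decline reaching ~0.4 of the plateau 45 s past the transition |
| `adaptor_offset_arrival`, `adaptor_offset_departure` | 30, 12 | s | AP-1 arrives ~20–40 s and departs ~10–15 s after Sec7/Gga2 |
| `load_time_meanlog`, `load_time_sdlog` | log(720), 0.55 | log-s | lognormal PVE-loading time: median 12 min, ~34% of cells past 15 min, matching the onset spread of whole-cell delivery |
| acquisition geometry | 60–80 nm XY, 0.25–0.30 µm Z, 20–30 sections | | the live-cell confocal settings being emulated |

Absolute brightness, photon gain and background are free parameters: the
source experiments report arbitrary units, and every analysis in the package
is scale-invariant by construction (normalizations divide by trace-derived
references, burst fractions are ratios, the background rule is
scale-equivariant).

## The measurement procedures

`render_movie()` is a linear forward imaging model: punctate compartments
become anisotropic 3-D Gaussians at the PSF width whose integrated intensity
is `photon_gain x true_signal`; the vacuole is a spherical membrane shell
plus a filled lumen; optional noise is Poisson counting noise plus Gaussian
read noise, clipped at zero.

`segment_structures()` thresholds a Gaussian-smoothed marker channel (Otsu by
default, with a k-sigma alternative for dim channels) and labels 3-D
26-connected components above `min_voxels` (default 10, suppressing
single-voxel noise). This replaces the manual per-structure ROI editing used
on the real movies — automation is the point: the same rule runs on every
movie. For the vacuole membrane channel each shell is closed and filled
slice-wise so the mask includes the lumen, because the measured cargo is
luminal. Masks link into tracks by greedy nearest-centroid matching with a
maximum per-frame displacement; ties break by distance, then overlap, then
label, so linking is deterministic and order-invariant.

`measure_in_mask()` implements the published rule of measuring one channel
inside a volume defined by another: sum inside the mask minus voxel count
times the frame's median-outside-all-masks background, floored at zero. Two
optional mask policies handle the unavoidable crosstalk between a PVE and the
vacuole it touches (both lie within one PSF width of the mask boundary):

* PVE traces keep their full (dilated) mask and subtract the vacuole's
  estimated luminal density over the overlap volume;
* vacuole traces exclude the dilated PVE support and rescale by the excluded
  volume fraction, treating luminal cargo as a uniform density.

On noise-free synthetic movies these policies keep trace errors at a few
percent RMS of the trace maximum; without them, bleed-through reaches ~10%.

### Maturation analysis

Marker traces are normalized to the mean of their three highest values
(`normalize_top3()`, more stable than the single maximum on noisy data) or to
the mean of their first/last six values (`normalize_endpoint6()`, used for
the aligned averages: cargo and the early marker start at plateau, the late
marker ends at plateau). The transition midpoint is defined operationally as
the first crossing of the normalized late trace above the normalized early
trace, linearly interpolated; with several crossings the one nearest the late
trace's half-maximum time wins. This definition is parameter-free, symmetric
in the two markers, and robust to amplitude differences. Events are used only
when their window covers [-40, +45] s around the midpoint, approximating a
90 s window centred on the transition; aligned traces snap to the 2 s grid
(ties toward earlier time) and grid points carried by fewer than half the
events are dropped — the averaging conventions are declared choices.

Adaptor timing (`adaptor_timing()`) defines arrival as the first sustained
(two-frame) crossing above half-maximum of the top3-normalized trace and
departure as the last sustained fall below it, interpolated at the crossing.
The two-frame persistence rule suppresses single-frame spikes.

### Delivery and burst statistics

Per-cell delivery records use the mean of the last three frames as the final
value (robust to single-frame noise; "final value" is otherwise undefined
under noise), score first appearance at 5% of that value, and report the
fraction of cells appearing later than 15 min. Cells whose final value does
not clear three times the noise floor are excluded from appearance scoring
rather than scored at spurious times.

Burst scoring resamples each active PVE cargo trace at 10 s boundaries
(nearest frame, ties earlier) and calls an interval a burst when more than
15% of the remaining cargo is lost in it. Consecutive qualifying intervals
are separate bursts, because the rule scores intervals, not merged episodes.
Increases (noise, homotypic fusion) score zero. A floor guard
(`floor_frac = 0.02` of initial cargo) suppresses calls once the compartment
is nearly empty — the statistic's detection floor: on a nearly-empty
compartment any measurement noise is a large *fraction* of the remaining
cargo, so sub-threshold noise inevitably over-calls there, and recovery tests
against generator truth are run noise-off for that reason. The burst share of
transfer is reported relative to total net transfer (an
alternative denominator, initial cargo, is available), and per-burst and
per-movie weighted summaries are both produced because the published pooling
is ambiguous on that point. Active compartments are those whose net transfer
exceeds 10% of initial cargo.

## What the generator does and does not emulate

The generator reproduces: the acquisition geometry and frame schedules of the
three experiment families (2 s maturation windows, 60 s delivery stacks over
an hour, 5 s burst movies over 10 min), the pre-acquisition photobleach,
maturation-coupled cargo exit in four genetic backgrounds, quiescent PVE
compartments, Poisson-scheduled partial-fusion bursts, marker fluctuation,
PSF blur, Poisson/read noise, and per-event amplitude spread (moderate
expression selection is emulated by lognormal amplitudes, since no intensity
criterion is published — an optional intensity filter is available instead of
a guessed threshold).

It does not emulate: cell-to-cell optical background variation beyond a flat
offset, compartment motility beyond static positions (linking is exercised on
constructed moving fixtures), PVE fission/homotypic fusion, deconvolution
(the pipeline runs on undeconvolved synthetic data), ER aggregate dissolution
kinetics, or the possibility that real bursts are partly imaging artifacts —
the simulator treats them as true transfers. Conclusions about real movies
therefore rest on the procedures, validated here for correctness and
calibration, not on the synthetic data resembling any particular cell.

## Numerical choices and degenerate inputs

* Conservation bookkeeping is exact by construction (each frame's vacuole
  increment equals the compartment losses), so the 1e-6 tolerance absorbs
  only floating-point accumulation.
* Burst fractions are drawn by rejection from the truncated normal, honoring
  the open support exactly.
* All-zero traces cannot be normalized and raise errors; a late marker that
  never crosses the early marker is not a maturation event and is skipped
  with a diagnosable error; empty masks are errors, but a frame with no
  structures is a valid empty result.
* Otsu runs on the flattened 3-D volume (one histogram per stack, not per
  slice). Structures whose PSF support leaves the field raise a geometry
  error rather than truncating silently.
* Every simulation takes an integer seed and restores the caller's RNG state;
  identical configuration and seed give bit-identical movies and truth.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
problems chosen as the package's own validation sizes: 48x48x12-voxel fields
for rendered movies, 20–50 movies or cells per statistical check, 200 events
for timing recovery, and 1000 random series for the burst-scan equivalence
check. These sizes put Monte-Carlo error comfortably inside each check's
tolerance while keeping the whole suite fast on one CPU.

## Known limitations

* The k-sigma "detectable cargo" rule stands in for manual scoring; its
  threshold (3 background SDs) is a declared default, flagged in outputs, not
  a published criterion.
* Crosstalk compensation assumes luminal cargo is spatially uniform within
  the vacuole; strongly polarized luminal distributions would bias the
  rescaled estimate.
* The burst statistic cannot see events below the 15% threshold and
  saturates when several events fall in one 10 s interval; both effects are
  quantified by the recovery tests.
* Whole-cell movies are assumed single-cell (or pre-cropped); there is no
  cell-boundary segmentation.
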