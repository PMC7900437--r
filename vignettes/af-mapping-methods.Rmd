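---
title: "Methods: high-density AF mapping analysis and its synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-density AF mapping analysis and its synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibwave)
```

`fibwave` analyzes unipolar multichannel electrograms recorded by
high-density epicardial contact mapping during atrial fibrillation (AF), and
ships a synthetic propagation/electrogram generator that provides exact
ground truth for every stage of the analysis. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
generator does and does not emulate.

## The measurement model

A rectangular electrode array (default: 16 × 16 lattice at 2.5 mm spacing
with 7 masked corner sites, i.e. 249 active electrodes) records unipolar
electrograms at 1039 Hz. Each passage of a depolarization wavefront under an
electrode produces a biphasic deflection whose steepest negative slope marks
the local activation time (AT). The ventricular far-field (the QRST complex)
contaminates all atrial channels; a ventricular reference channel tracks the
beats.

The analysis chain is:

1. **Beat detection and QRST cancellation** — fiducials at the steepest
   negative slope of the reference channel's dominant deflection (300 ms
   refractory); per channel, the beat-aligned average over all beats in a
   (−100, +500) ms window forms the QRST template, which is subtracted at
   every fiducial, optionally with a per-beat least-squares amplitude scale.
   Samples outside beat windows are untouched.
2. **AT detection** — candidates at local minima of the first difference
   below −k·MAD of the channel derivative (k = 4), with a floor of 20% of
   the channel's steepest descent so noise-free channels (zero MAD) remain
   detectable; non-maximum suppression keeps the steeper candidate within a
   40 ms refractory. An optional iterative refinement re-scores candidates
   by slope magnitude × periodicity likelihood against the channel's running
   cycle-length estimate.
3. **Conduction and block** — neighboring electrodes whose AT difference
   implies an apparent velocity below 20 cm/s are classified as conduction
   block. The limit is the largest whole millisecond still compatible with
   conduction: `floor(distance / v_block)`, which gives 12 ms for orthogonal
   (2.5 mm) and 17 ms for oblique (2.5·√2 mm) neighbor pairs. These integer
   limits are deliberate: they are the printed operating points of the
   method, not rounded conveniences.
4. **Local conduction velocity** — a least-squares plane
   `T(x, y) = a·x + b·y + c` through an event and the conducted-paired
   activations of its direct neighbors. Speed is `100/√(a² + b²)` cm/s,
   propagation direction `atan2(b, a)` (the direction along which
   activation gets later — the direction the front is heading). Estimates
   are invalid with fewer than 3 conducted neighbors (rank requirement of
   the 3-parameter fit), collinear geometry, or a gradient below
   10⁻⁶ ms/mm (simultaneous activation).
5. **Anisotropy** — per electrode, the mean resultant length
   `R = |mean(exp(iθ))|` of its conduction directions (circular variance
   `1 − R`); at least 3 valid estimates are required. Pooling is over the
   whole file by default; windowed use is possible by subsetting the series.
6. **Electrical dissociation** — the percentage of paired neighbor links
   classified as blocked.
7. **AF cycle length (AFCL)** — per electrode the median inter-activation
   interval (≥ 3 activations), regionally the median over electrodes.
8. **Waves** — vertices are activation events; an undirected edge joins
   events at neighboring electrodes whose AT difference is within the
   12/17 ms limit; waves are the connected components. Boundaries thus
   arise implicitly at the array edge and along block lines. Waves whose
   earliest event lies on the array periphery are *peripheral*; waves first
   appearing strictly inside the mapped area are *breakthroughs*. Waves
   spanning fewer than 3 distinct electrodes are removed as noise-prone.
   Counts are normalized to the cycle length
   (`waves_per_cycle = n_waves × AFCL / window`).
9. **Conduction paths and re-entry** — within a wave, a directed edge runs
   from the earlier to the later event of a neighboring pair when
   `0 ≤ Δt ≤ limit` (per-step apparent CV ≥ 20 cm/s; simultaneous events
   oriented by electrode id). The conduction path is the minimum
   total-spatial-length trajectory from the wave's earliest to its latest
   event. A revisit of an electrode after at least 75% of the mean AFCL
   marks a self-intersection; qualifying waves are re-entries, with the
   revolution count taken at the most-revisited electrode ("maximal
   rotation"). The share of the window covered by the union of qualifying
   trajectories' time spans is the re-entry presence percentage; the union
   convention is our choice where simultaneous re-entries overlap.

Interpreting "starting and end point of a wave" as its earliest and latest
*events* (rather than spatial extremes) keeps the trajectory definition
consistent with path continuity; cross-cycle event linking is impossible by
construction because the Δt limits (≤ 17 ms) are far below any plausible
AFCL, so cycles separate without explicit segmentation.

## The synthetic generator

The generator is a measurement-model emulator, not a PDE or ionic model:
activation is earliest-arrival on the 8-neighbor electrode graph, with edge
traversal time `edge length / speed` and blocked edges impassable. This
produces exactly the observable the analysis consumes — per-electrode ATs —
with exact ground truth, which is the point; continuum eikonal or ionic
dynamics would add realism the analysis never sees. Anisotropic propagation
uses an elliptical metric with an `(x, y)` speed pair.

* **Planar/focal sources** (`simulate_arrival_times`) fire once or
  periodically; with several sources each electrode takes the minimum
  arrival per cycle, so colliding wavefronts fuse at equal-time boundaries,
  as in the mapped data. Unreachable electrodes (fully enclosed by block)
  are reported, never silently dropped.
* **Rotors** (`simulate_rotor`) place activation at
  `onset + n·period + period·φ/2π` with φ the polar angle about the core;
  every electrode's cycle length is exactly the period, and the core
  electrode (phase singularity) emits no events.
* **Compound AF episodes** (`simulate_af_episode`) launch one peripheral
  planar wavefront per cycle from a random edge, with Gaussian jitter on
  cycle onsets, per-cycle random block-line segments, and Poisson focal
  breakthroughs. Breakthroughs are generated as small late-coupled waves
  (onset 0.35–0.55 cycle after the local planar activation, geodesic radius
  1–2 electrodes): a min-arrival focal source colliding with the same
  cycle's planar wave would fuse with it at an equal-time boundary and
  never appear as a distinct wave, whereas real breakthroughs surface into
  tissue that was activated earlier in the cycle and are separated from it
  by refractoriness. The late-coupling construction reproduces exactly that
  temporal isolation. All randomness derives from the scenario seed (the
  Poisson focal count is the first draw), making every episode
  bit-reproducible.
* **Electrogram synthesis** (`synthesize_egms`) renders each AT as a
  derivative-of-Gaussian deflection (1 mV peak-to-peak, σ = 2 ms; steepest
  negative slope exactly at the AT), adds a channel-identical QRST waveform
  at regular ventricular beats (default RR 1200 ms, in the anesthetized
  equine range; QRST support 600 ms), emits a clean reference channel,
  optionally applies the first-order 0.56 Hz high-pass / 408 Hz low-pass
  acquisition filters, and adds seeded Gaussian noise. The channel-identical
  far-field makes averaged-template cancellation exact in the noise-free
  case, giving a clean oracle for the cancellation stage. The far-field
  morphology itself is a modeling choice; no quantitative template is
  available for the mapping hardware.

Ground-truth wave labels are computed inside the generator by its own
union-find pass over the same wave definition the analysis uses (neighbor
events within the 12/17 ms limits) — that definition *is* the wave concept,
so truth and reconstruction share it by necessity; independence lies in the
implementations (hand-rolled union-find vs. igraph components). True blocked
edges are not consulted by the labeling: block manifests as detour delay,
exactly as a mapping catheter sees it.

### What the generator does not emulate

Electrode-to-tissue contact variability, baseline wander and mains
interference, fractionated multi-component electrograms, endo–epicardial
dissociation beyond the breakthrough abstraction, beat-to-beat far-field
morphology changes, and rate adaptation of conduction. Passing tests
therefore demonstrate correctness of the *analysis operators* against their
definitions and robustness to additive noise — not detector performance on
fractionated clinical signals.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| spacing | 2.5 | mm | array geometry of the mapping plaque |
| sampling rate | 1039 | Hz | acquisition hardware rate |
| block threshold | 20 | cm/s | conduction-block velocity criterion |
| AT limits | 12 / 17 | ms | `floor(distance / v_block)`, orth./oblique |
| refractory floor | 40 | ms | below any plausible atrial refractory period |
| template window | (−100, +500) | ms | covers the equine QRST (QT ≈ 500 ms) |
| detector k | 4 | MADs | slope threshold; amplitude-invariant |
| min wave size | 3 | electrodes | noise-prone below this |
| re-entry bound | 0.75 | ×AFCL | self-intersection recovery criterion |
| episode AFCL | 185 | ms | baseline right-atrial cycle length in persistent AF |
| episode speed | 80 | cm/s | baseline AF conduction velocity scale |
| far-field RR | 1200 | ms | anesthetized equine ventricular rate |

## Numerical choices and degenerate inputs

* AT resolution is 1000/1039 ≈ 0.962 ms/sample; detected ATs sit at
  mid-sample positions of the first difference. Quantization matters for
  conduction velocity: at 120 cm/s the per-link orthogonal delay is
  2.08 ms, only ~2 samples, so individual plane-fit estimates alias when
  the wavefront is aligned with a lattice symmetry axis (whole columns
  quantize identically). The CV recovery benchmark therefore uses oblique
  incidence angles and judges the quantized case by the median error over
  the speed sweep; with exact (unquantized) arrival times every interior
  estimate recovers speed within 5% and direction within 0.02 rad.
* Ties: the earliest event of a wave is unique after tie-breaking toward
  peripheral electrodes (classification) and by electrode id (trajectory
  start); simultaneous activations in the directed path graph are oriented
  from lower to higher electrode id.
* Degenerate inputs: empty series give empty wave lists; flat channels give
  zero activations without error; simultaneous activation of a neighborhood
  yields an invalid (zero-gradient) CV estimate; zero paired links make the
  dissociation index an error rather than a silent 0/0.
* Quantiles in summaries are linear-interpolation (type 7); groups with
  fewer than 4 observations are flagged and excluded, matching the
  reporting convention of the field.
* QTc correction is a continuous piecewise-linear map of heart rate whose
  coefficients must be supplied via configuration; the shipped default is a
  labeled zero-correction placeholder because no species-specific
  coefficients are bundled.

## Problem sizes used by the test suite

The suite exercises 10 × 10 to 16 × 16 lattices; compound episodes of
2–20 s; oracle equivalence on 100 random lattices up to 10 × 10 with random
block sets; rotors of 3–8 cycles at 150–250 ms periods; and
signal-chain checks at SNR 10 (noise SD = half the deflection amplitude
divided by 10) on 20 s recordings, where the QRST template averages over
16 beats. Template contamination by atrial activity decays as 1/N beats, so
very short segments (few beats) degrade detection sensitivity inside beat
windows — a real limitation of averaged-template cancellation, visible in
the generator too.

## Known limitations

* The AT detector is a transparent slope/periodicity scheme with every
  constant exposed; the probabilistic detector used with the original
  mapping system is external to this package and not re-implemented.
* Wave reconstruction trusts the 12/17 ms limits; very slow but genuine
  conduction (< 20 cm/s) is indistinguishable from block by definition.
* The re-entry trajectory definition requires the conduction path to pass
  through revisited electrodes; phase-singularity methods are out of scope.
* Two atria are handled as two independent grids with region labels; no
  3-D geometry or inter-atrial conduction is modeled.
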