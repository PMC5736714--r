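---
title: "Collective phototaxis: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective phototaxis: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phototaxr)
```

## The model and its assumptions

`phototaxr` simulates a colony of gliding cyanobacteria as overdamped,
finite-size agents on a continuous plane above a square slime lattice. The
model deliberately contains only three ingredients, each tied to a known
piece of *Synechocystis* biology:

* **A weak, probabilistic light bias.** Gliding cells respond to the
  *direction* of a light source, not to an intensity gradient. Each step, a
  sighted cell aims exactly at the light with probability `p_photo` and
  otherwise moves in a uniformly random direction. There is no persistence
  term: headings are redrawn every step, so all persistence in trajectories
  is emergent (slime trails and tugs).
* **Stigmergic slime.** Cells deposit `S_rate` of slime per step at the
  lattice site under their centre. Friction is inversely proportional to the
  local slime: `gamma = gamma0 * S0 / S`. Slime neither decays nor diffuses
  — appropriate for a dense gel on the simulated timescales — so trails are
  permanent one-cell-wide tracks, and a site saturates at `S_max`.
* **Transient pilus tugs.** Each cell can attach to at most `a` neighbours
  within `2R + A` of its centre per step (pili of length `A` reaching from
  the cell edge). The signed tug magnitude
  `K(D) = (1 + k1 (tanh(k2 (D - 2R)) - 1))/a` is repulsive below contact
  (soft-core volume exclusion) and saturates to `1/a` at long range.
  Attachments are re-drawn every step; there is no bond persistence.

Motion is fully overdamped: the displacement is `(G + F)/gamma`, clamped to
`R/10` per step. With the default parameters an unhindered cell on
slime-saturated ground moves exactly `R/10` — the clamp and the friction
scale coincide by construction (`gamma0 = 1/(0.1 R)`), so the cap only binds
when tug forces would push a crowded cell faster.

The collective behaviour is emergent: cells drift to the bright edge of the
colony, stall on the slime-poor substrate beyond it, accumulate, and — once
enough cells deposit in the same place — break out as dense fingers whose
tips advance at the rate at which they can lay fresh slime.

## Parameters

| name | meaning | default | units |
|------|---------|---------|-------|
| `R` | cell radius | 1 | length (sets the length unit) |
| `A` | pilus reach beyond the cell edge | 4R | length |
| `a` | pili per cell (donor tug budget) | 4 | count |
| `gamma0` | friction at slime level `S0` | 1/(0.1R) | inverse speed |
| `k1`, `k2` | tug force amplitude, steepness | 1, 2 | — , 1/length |
| `S0` | initial slime inside the colony | 1000 | slime |
| `S_max` | per-site slime cap | 1000 | slime |
| `S_rate` | deposition per cell per step | 0.1 | slime/step |
| `p_photo` | probability of a light-directed heading | 0.1 | — |
| `phi_ch` | freeloader fraction | 0 | — |
| `rho` | mean colony density | 0.05 | cells/area |
| `S_floor` | minimum effective slime in the friction law | 1 | slime |
| `dt`, `f_bias` | time step, bias-force magnitude | fixed at 1 | — |

One length unit corresponds to a cell radius (~1 µm); the time unit is set by
the maximal gliding speed, so `R/10` per step matches observed speeds of
0.3–1 µm/s at step lengths of ~0.1 µm.

## Design choices where the model description is open

Several details are not pinned down by the model's published description;
the package fixes them as follows (all exposed in `sim_config()`):

* **Lattice spacing = R.** "The grid point closest to the cell centre" is
  resolved on a lattice with one site per cell radius, keeping slime trails
  one cell wide. Nearest site by coordinate rounding.
* **`S_floor` clamp.** The friction law diverges on virgin substrate
  (S = 0). Cells at the colony edge are described as moving *slower*, not
  freezing, so the effective slime is clamped below at `S_floor = 1`,
  i.e. at most a 1000-fold slow-down. Without the clamp no cell could ever
  leave the colony and fingers could not nucleate.
* **Deposition timing.** Slime is deposited at the *post-move* position at
  the end of each iteration; friction at step *t* reads the field as left by
  step *t − 1*. The per-step order is: headings, tug selection, forces,
  move, deposit.
* **Tug direction and bookkeeping.** The force a donor applies to a
  recipient acts along the unit vector from recipient to donor (attraction
  for K > 0, separation for overlap). The budget `a` caps a cell as a
  *donor*; a crowded cell may receive more than `a` tugs. Donor choices are
  independent, so reciprocity is possible but never enforced — the test
  suite deliberately does not assert action–reaction symmetry.
* **Coincident centres.** If two centres coincide exactly (possible under
  clamped crowding), the separation direction for that pair is drawn
  uniformly at random that step; there is no division by zero.
* **Step cap semantics.** `R/10` is a hard clamp on the displacement
  magnitude, not on forces, preserving the displacement direction.
* **Unbounded plane.** There are no walls; the slime lattice is a lazily
  grown window and untouched sites read 0.
* **Randomness.** One seeded generator per run with a fixed draw order
  (headings for cells 1..n, tug selections for donors 1..n, then any
  coincident-pair directions). Runs are bit-reproducible, and
  `resume()` after `run_sim()` is bit-identical to one longer run. The
  donor's eligible-neighbour list is sorted before sampling so the result is
  independent of the spatial-hash layout; the accelerated neighbour search
  is tested for exact equality against an O(n²) oracle.

## Scenario presets

`phototax_preset()` bundles the standard experiments: `"circle"` (finger
formation from a circular colony), `"flat"` (a tall thin rectangle whose
front faces the light; basis of the rose-plot and `p_photo`-sweep analyses),
`"slime_band"`, `"freeloaders"`, and `"light_switch"` (source rotated 90°
clockwise at `t_switch`). The flat colony's aspect ratio (height:width
10:1) and the slime-band geometry are package choices: the band is a
saturated strip 10 units wide starting 18 units beyond the colony front, far
enough that fingers are established before they reach it, near enough that
they cross it well within a 30,000-step run.

## What the analyses measure

* `direction_histogram()` — the direction of each cell's net displacement
  over a 5-step moving window, histogrammed in 36 bins (10°). Windows with
  exactly zero displacement carry no direction and are excluded (their count
  is reported). Raw angles are retained so `anisotropy()` computes the mean
  resultant length from angles, not bin centres. These analyses need a
  unit-stride span; the cheap pattern is a coarse run followed by
  `resume(rec, n, record_every = 1)` over the analysis window.
* `detect_fingers()` — single-linkage clusters (linkage `2R + A`) of cells
  at least `2R` beyond the initial colony boundary, keeping clusters of 10
  or more cells. `finger_onset()` reports the first recorded step from which
  detection persists for 500 steps; the persistence window must be covered
  by the record. These thresholds are an *operational* definition of a
  finger — small enough to catch the few-cell aggregates that seed fingers,
  strict enough to ignore stragglers. It fires at the first persistent
  protrusion, which precedes the stage at which fingers are visually obvious
  in snapshots (by t ≈ 8,000 in the circular scenario a typical run already
  has ~9 fingers of 16–51 cells, while the first 10-cell protrusion appears
  around t ≈ 2,000–3,500).
* `band_speed_profile()` — per-step speeds stratified by position relative
  to the band (`before`/`inside`/`after`), restricted by default to cells
  that actually reach the band, with `before_from` available to exclude the
  colony interior (where cells sit on `S0` ground and move at full speed).
* `freeloader_drift()` — mean signed displacement per step along the light
  axis, split by the freeloader flag.

## Problem sizes used by the tests and the acceptance script

Stochastic checks run at reduced but fully sufficient scales, chosen so each
property is resolved with wide margins: the anisotropy sweep uses flat
colonies of 300 cells for 20,000 steps (the ordering 0.004 < 0.03 < 0.19 <
0.73 across `p_photo` ∈ {0, 0.01, 0.1, 0.5} is separated by orders of
magnitude); the band scenario uses 300 cells for 30,000 steps; freeloader
entrainment uses 500 cells for 50,000 steps (the entrainment signal is
~70 standard errors above zero); the light-switch scenario switches at
16,000 steps and compares 1,000-step windows before and well after the
switch. The circular finger-formation scenario runs at full scale
(500 cells, 16,000 steps).

## What the synthetic colonies do and do not show

All inputs are generated by the package itself; no experimental data enters.
Passing tests therefore demonstrate that *this model* reproduces the
qualitative phenomenology — edge accumulation before finger formation,
robust phototaxis at `p_photo` as small as 0.01, speed-up inside pre-laid
slime with reversion afterwards, entrainment of blind cells, and finger
reorientation after a light switch — under its stated assumptions. They do
not validate the model against micrographs or measured speeds, and several
known features of the real system are outside the model by construction: no
cell growth or division, no slime decay or diffusion, no photoreceptor
signalling dynamics, no hydrodynamics, and no persistence in individual cell
headings.

## Numerical notes and limitations

* Angles are wrapped into [0, 2π); a sighted cell matches the light
  direction *exactly* with probability `p_photo`, which is what makes the
  heading-match fraction an unbiased estimator of `p_photo` (a uniform draw
  hits any fixed angle with probability zero).
* The onset detector returns `NA` when fingers never persist within the
  record, and cannot call an onset whose persistence window extends past the
  end of the record.
* Friction reads the single nearest site — there is no interpolation — so a
  cell straddling a slime edge feels either side, not a blend. This is the
  source of the sharp speed changes at the slime-band boundary.
* Very dense colonies (`rho` well above ~0.5) spend most of their time at
  the displacement clamp; the dynamics remain well-defined but the friction
  law no longer differentiates speeds.
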