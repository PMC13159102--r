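---
title: "Models and methods behind centroclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind centroclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific question

Cancer cells with supernumerary centrosomes survive mitosis by gathering
their centrosomes into two spindle poles.  A minimal physical picture of
this process has three ingredients: microtubules, a minus-end-directed
kinesin-14 motor (HSET/KIFC1) that can crosslink and slide pairs of
microtubules, and pericentriolar-material (PCM) condensates built around
the scaffold protein CDK5RAP2 that act as motor cargo and as microtubule
nucleation sites.  `centroclust` implements this picture as a 2-D
agent-based simulation with a clustering statistic, together with the
quantification methods used around it in practice: FRAP recovery
fitting, kymograph-style track analysis, and condensate image
quantification.  All inputs are synthetic, generated by seeded
generators with known ground truth.

## The simulation model

### Entities and mechanics

The simulator is an overdamped (Brownian-dynamics) model in a circular
arena with a soft harmonic wall.  Three kinds of agents exist:

* **Filaments** (microtubules): inextensible, semiflexible polylines of
  ~1 um segments.  Bending follows a discrete worm-like-chain energy
  with flexural rigidity 20 pN um^2 (the microtubule value); segment
  lengths are restored exactly after every step by a follow-the-leader
  projection from the minus end (vertex 0), so contour length is
  conserved to machine precision.
* **Motor couplers** (HSET): point beads with two independent heads.  A
  free head within the 0.05 um capture range binds at rate 5/s; a bound
  head walks toward the minus end at `v(F) = v0 max(0, 1 - F/F_stall)`
  with `v0 = 0.087 um/s` (the measured condensate transport velocity)
  and a 5 pN stall force, dwells at the minus end, and unbinds at the
  configured rate.  The unbinding rate is the processivity dial: 0.05/s
  means a ~20 s engagement (processive), 5/s a ~0.2 s touch.
* **Condensate complexes** (CDK5RAP2 units): point particles carrying
  (i) one HSET-like motor hand with the coupler's parameters, (ii) a
  weak "wanderer" lattice hand (on/off 1/s) that tethers without
  walking, (iii) two adhesive hands that form Hookean bonds with other
  complexes within 0.25 um (on 10/s, off 0.1/s) — at most two partners,
  mimicking nonspecific condensate stickiness — and (iv) one nucleation
  site that seeds a filament at addition time, minus end anchored to the
  complex, growing to full length over 20 s.

A complex's own hands are barred from binding its own nucleated
filament.  This is not cosmetic: that filament's minus end is anchored
at the complex itself, so self-binding instantly satisfies the motor
hand at abscissa ~0 and freezes the complex in place.  Early versions
without the exclusion showed no transport at all.

### Numerical scheme

Positions follow explicit Euler-Maruyama steps with a diagonal
(Jacobi-implicit) treatment of the stiff spring terms,

    dx = dt * F(x) / (gamma + dt * S),

where `S` sums the spring constants acting on the point.  This is
unconditionally stable in the on-diagonal stiffness, which matters
because motor beads have protein-scale drag (gamma = 0.05 pN s/um) but
are connected by 100 pN/um links; a fully explicit step would need
dt < 5e-4 s instead of the protocol's 0.005 s.  Thermal noise uses
`sqrt(2 kT dt / gamma)` per coordinate with kT = 0.0042 pN um; free
particles therefore diffuse at exactly `D = kT/gamma`, which the test
suite verifies against the 2-D Einstein relation.  All randomness flows
through one PCG32 stream serialized inside the state object, so a run
is a pure function of (config, seed), bit for bit.

### Protocol and statistic

A run has two phases: motors bundle the initial filament network for
`t_bundle` = 100 s; complexes are then added uniformly at random and the
system evolves to `t_total` = 500 s with dt = 0.005 s.  Complex
positions are recorded at addition, on a configurable cadence, and at
the end.

Clustering is quantified from pairwise distances with a 3 um threshold.
Two readings of "percentage of short-distance complexes" are computed:

* **per complex** — the fraction of complexes with at least one
  neighbour closer than 3 um (`fold_change` in the summary);
* **per pair** — the fraction of unordered pairs closer than 3 um
  (`fold_change_pairs`).

The fold change divides the end-of-run percentage by the post-addition
percentage.  The heatmap and trend machinery default to the per-pair
reading.  The reason is dynamic range, not taste: with `n` complexes
uniform in a disk of radius `R`, the expected number of 3 um neighbours
per complex is `(n-1) * 9 / R^2`, so the per-complex baseline is already
50–80% at any density worth simulating (24 complexes in a 15 um arena
give ~55%), leaving the ratio pinned between 1 and ~1.8 and dominated by
baseline shot noise.  The per-pair baseline stays at a few percent and
the same simulations separate cleanly.  Both statistics are reported
everywhere so either convention can be read off.

### Parameter defaults and the desk-scale world

The source protocol adopts its parameter table from earlier published
simulator configurations that are not reproduced in the available text,
so the defaults here are documented stand-ins chosen from the measured
quantities (motor speed) and standard motor/cytoskeleton values (stall
force 5 pN, link stiffness 100 pN/um, binding 5/s at 0.05 um).  Every
value is a `sim_config` field, echoed into each record.

The acceptance trend tests run a reduced world that one CPU finishes in
minutes: 15 um arena, 30 filaments of 7 um, 24 complexes, 10–200
motors, full 500 s protocol at dt = 0.005 s, six paired seeds per sweep
point.  With it, the per-pair clustering fold change is monotonically
decreasing in the HSET unbinding rate (Spearman, p < 0.01) and
increasing in motor count (p < 0.01).  One caveat the heatmaps make
visible: at the most processive corner (0.05/s) the fold change dips
below the 0.1/s column, because complexes become pinned at the first
minus end they reach before the network itself has coalesced — a
jamming effect, not noise.  The Spearman trend over the whole sweep
remains strongly negative.

## FRAP analysis

Traces carry raw ROI, background, and reference (unbleached condensate)
intensities.  Normalization is the standard double ratio
`N(t) = [(ROI - bg)/(ref - bg)] / prebleach mean`, which cancels both
the camera offset and acquisition photobleaching; whether to rescale
before or after reference correction is immaterial because the two
operations commute up to the prebleach constant — the double form is
used because it is the common convention.  Frames whose reference drops
below 50% of its prebleach mean are trimmed with a warning.

Recovery is fitted to `N(t) = F0 + (plateau - F0)(1 - e^{-kt})` by
bounded least squares (`nls`, port algorithm), with deterministic
initialization: `F0` from the first post-bleach frame, plateau from the
final 10% of frames, `k` from a log-linear regression of
`plateau - N(t)`.  A zero-noise trace makes the residual surface
degenerate for `nls`, so a bounded BFGS fallback handles that case.
Derived quantities satisfy `t_half = ln 2 / k` and
`mobile = (plateau - F0)/(1 - F0)`, `immobile = 1 - mobile` identically.
Flat post-bleach traces (fully immobile) are flagged rather than fitted,
since `k` is unidentifiable there.

## Track and kymograph analysis

Tracks are uniform-cadence tables of abscissae along a filament
(5 s/frame in the TIRF regime).  Steps are labelled by sign once they
exceed a noise floor of 0.1 um — twice the 0.05 um localization sigma,
so single-frame jitter rarely crosses it.  Maximal runs of at least
three same-sign above-floor steps are processive events; their velocity
is the least-squares slope (sign-flipped so minus-end-directed motion is
positive) and their run distance the net displacement.  The remaining
stretches are diffusive when they persist longer than three frame
intervals (15 s) and most of their steps exceed the floor, static
otherwise.  The majority clause is the package's reading of an
ambiguously worded classification rule; requiring only one above-floor
step would misclassify pure localization noise (~16% of whose steps
cross the floor by chance) as diffusive.  Events partition each track,
adjacent events share their boundary frame, and ties at changepoints go
to the earlier event.  Event rates divide pooled counts by microtubule
length times acquisition minutes.

## Condensate image quantification

Images are numeric matrices (plain-text CSV on disk; the analysis is
agnostic to the container).  Droplet detection is the classic
particle-analysis pipeline: a global Otsu threshold over a 256-bin
histogram, 8-connected components (union-find, compiled), and a 4 px
minimum area.  If automatic thresholding marks more than 30% of the
frame as foreground the image is declared droplet-free: Otsu always
returns *some* split, and on a unimodal noise image that split bisects
the noise rather than finding droplets.  Droplets touching the image
border are excluded from size statistics; density uses an unbiased
counting frame (droplets touching the right/bottom border are not
counted) so that densities add over tiled sub-images.

The partition coefficient is the mean intensity inside the droplet mask
over the mean in the dilute phase, computed outside a 2 px dilation ring
around the droplets to avoid edge bleed.  The default subtracts no
background: synthetic and in vitro droplet fields contain no true dark
pixels, so a percentile-based "background" sits inside the dilute-phase
noise and arbitrarily inflates the ratio (a 1st-percentile rule was
tried and rejected for exactly this failure on images with known
enrichment).  A numeric dark level or the percentile rule remain
available as options for data that do include dark regions.

Phase diagrams classify a (protein, salt) grid as droplet-positive at a
minimum droplet count (default 5) and mark boundary cells as positive
cells 4-adjacent to negative ones.

## Synthetic data: what it does and does not establish

Each generator is a pure function of its argument list including the
seed, restores the caller's RNG state, and attaches its spec (also
written as `spec.json` beside serialized fixtures).  Default noise
levels — localization sigma 0.05 um, FRAP sigma 0.02, Poisson shot noise
plus Gaussian readout for images — are chosen to resemble the data
regime of single-particle TIRF and confocal FRAP, not fitted to any
dataset.

The FRAP generator embeds a known normalized curve into raw channels
with mild reference photobleaching so that normalization must actively
undo the corruption.  The track generator composes static/drift/static
phases with per-track speeds (and optionally run distances) drawn from
the printed normal distributions; run distances are truncated only at
the physical bound (a run cannot exceed its filament).  The droplet
generator places non-overlapping disks at a known enrichment ratio.

Green tests on these fixtures establish that each analysis stage
recovers the parameters of its own generative model at realistic noise
— they do not establish anything about microscope PSFs, photophysics,
tracking errors on crossing trajectories, or condensates that deviate
from the single-exponential / disk / constant-velocity idealizations.
The simulation trend tests establish the qualitative physics
(processivity and motor abundance promote clustering) in a reduced
arena; absolute fold-change values are not comparable to any published
heatmap because the original parameter table is unavailable.

## Known limitations

* 2-D only; no microtubule dynamic instability, no steric exclusion
  between filaments, no hydrodynamic coupling.
* The diagonal-implicit integrator damps stiff modes but is first-order;
  energies are not exactly Boltzmann-distributed for bound clusters.
* Event classification is threshold-based, not probabilistic; tracks
  with speeds near `noise_floor / frame_interval` (0.02 um/s at
  defaults) blur between static and processive.
* Otsu thresholding assumes bimodal intensity; dim droplets near the
  noise floor need an explicit threshold.
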