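---
title: "A Brownian-ratchet model of bacterial chromosome segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Brownian-ratchet model of bacterial chromosome segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minratchet)
```

## The model

`minratchet` simulates the segregation of two bacterial sister chromosomes
as a problem in confined polymer physics.  Each chromosome is a
self-avoiding **ring polymer** of `N` monomers on a cubic lattice, confined
in a hard-walled rod of 80 × 10 × 10 lattice units (aspect ratio 1:8, the
shape of an *E. coli* cell).  Chains are represented with the
**bond-fluctuation method** (BFM): a monomer occupies the 8 corner sites of
a unit cube, and consecutive monomers are joined by bonds from the
108-vector set with squared lengths {4, 5, 6, 9, 10}.  Together with
excluded volume, this bond set makes it geometrically impossible for chain
segments to cross during single-site displacements, so ring topology is
conserved — the property that makes BFM the standard lattice model for
entangled polymer dynamics.

Dynamics are plain Metropolis-free local moves: one Monte-Carlo step (MCS)
attempts `M` single-monomer displacements (one lattice unit along a random
axis; `M` = total monomers), each accepted only if the monomer is untethered,
the cube stays in the box, the advancing face is unoccupied, and both ring
bonds remain in the allowed set.  All moves are symmetric, so detailed
balance holds with respect to the uniform measure over valid
configurations; the package verifies this against exhaustive enumeration
for a small ring (see *Correctness checks*).

With `N = 80` each chain fills ~8% of the box and the free-chain radius of
gyration (≈ 11 lattice units, measured by simulation in a large box)
exceeds the lateral box size, so the two rings are strongly confined and
overlap is entropically costly.  Purely entropic repulsion therefore
already drives de-mixing — the baseline (`no_tether`) condition.

### Membrane tethering and the ratchet

The model's subject is what transient **tethering of DNA to the membrane**
adds to this entropic baseline.  A tethering field assigns every
membrane-proximal monomer (cube within `border_distance` = 1 lattice unit
of a *lateral* wall; the poles carry no sites) a per-MCS binding
probability `p(x, t)`; a monomer that binds is frozen in place for a
geometrically distributed dwell time (mean `dwell_mean` MCS, memoryless
release) and then released.  Spatial bias in `p(x, t)` rectifies the
chain's random motion — a Brownian ratchet: excursions toward regions of
high binding probability are held, excursions away are not.

Four field geometries are provided (`tether_field()`):

* **uniform** — `p = p_max` everywhere (control: drag without bias);
* **static_gradient** — `p = p_max · (2|x/Lx − ½|)^s`, zero at mid-cell,
  maximal at the poles; the exponent `s` (`steepness`) sets how tightly
  binding concentrates near the poles;
* **oscillating_gradient** — the static profile restricted to one axial
  half of the cell, the active half alternating every `period` MCS
  (idealized Min oscillation: MinD occupies one polar half at a time);
* **mind_profile** — `p_max` times a time-resolved axial intensity profile
  series (measured, or synthetic via `synthesize_min_oscillation()`),
  max-normalized per frame, interpolated in `x`, nearest-frame in time with
  cyclic wrap.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `Lx, Ly, Lz` | 80, 10, 10 | box, lattice units (1:8 rod) |
| `N` | 80 | monomers per ring |
| `p_max` | 0.03 | binding probability per MCS per eligible monomer |
| `dwell_mean` | 100 MCS | mean immobilization time (×10 in `dwell_x10`) |
| `steepness` | 1 | gradient exponent |
| `period` | 2500 MCS | oscillation half-cycle |
| `border_distance` | 1 | lateral-wall proximity for eligibility |
| `n_mix` | 5×10⁴ MCS | constrained mixing to build the initial state |
| `n_mcs` | 5×10⁵ MCS | default run budget (8×10⁵ for steady-state ensembles) |

Two ratios govern the physics, and the defaults were chosen by reasoning
about them rather than by fitting:

* **Duty cycle** `p·τ/(1 + p·τ)` — the fraction of time a membrane monomer
  spends frozen.  With `p_max = 0.03` and `τ = 100` a pole-proximal monomer
  is held ~75% of the time but released dozens of times per oscillation:
  tethering is *weak and transient*.  This matters: with, say, `p_max·τ ≈ 10`
  the entangled mid-cell mixture is pinned where it sits before the chains
  have sorted to opposite poles — segregation becomes *slower and less
  precise* than with no tethering at all, which is exactly the behaviour the
  `dwell_x10` condition (τ = 1000) is designed to show.  Efficient ratcheting
  needs grip, but not a death grip.
* **Cycle/relaxation separation** — in vivo the Min oscillation (tens of
  seconds) is ~100× faster than chromosome segregation (tens of minutes), so
  a chromosome barely diffuses during the half-cycle in which "its" pole is
  inactive.  The half-cycle of 2500 MCS against a chain relaxation time of
  order 10⁵ MCS preserves that separation of timescales.

The initial condition is the mixed state a cell faces after replication:
two rings sharing the same axial window at mid-cell.  It is built from a
deterministic interleaved template followed by `n_mix` MCS of ordinary
moves during which any move taking either axial centre of mass (CM) more
than 1 lattice unit from mid-cell is rejected — long enough (5×10⁴ MCS)
for the two rings to interdigitate genuinely.  Short mixing would leave the
template rings laterally stacked and make the entropic baseline look
artificially fast.

## Observables

Per run: the relative axial CM of each polymer (`center_of_mass_rel`, in
[−0.5, 0.5], 0 = mid-cell), axial density profiles, radius of gyration.
Per ensemble (`run_experiment`, replicate *i* seeded `seed_base + i`): the
final-CM distribution and the separation statistic **Δ = mean |cm_rel|**.
Because the two rings can occasionally slide past one another, "right
polymer" statistics (the analogue of plotting the right-hand chromosome's
position distribution) use the polymer observed on the right at measurement
time; the t = 0 labels are also recorded.  Condition orderings are tested
with one-sided Mann-Whitney rank tests on per-replicate Δ
(`compare_conditions`): final positions are bounded and non-Gaussian, so
rank tests, not t tests.

The **force–distance probe** (`force_distance_curve`) measures the
effective inter-polymer repulsion the way a tug-of-war would: add an
attractive energy `U = f·d` (d = axial CM separation, energies in kT;
axial moves get a Metropolis factor `min(1, exp(−f·Δd))`), equilibrate, and
record the separation at which the attraction balances the repulsion.
Entropic repulsion dies off at large separations, while a polar gradient
keeps pulling the chains apart — so at matched distances the gradient
condition balances a larger force.

## The synthetic MinD profile generator

`synthesize_min_oscillation()` emulates a time-lapse series of axial
EYFP-MinD intensity profiles: a polar cap, maximal at one pole and
decaying toward mid-cell, switching poles every half-period, sampled every
7 s (a typical Min imaging interval) with optional multiplicative noise.
The default cap is a **linear wedge** reaching zero at mid-cell
(`shape = "linear"`, `sharpness = 2`), the shape of the time-averaged
membrane-bound MinD zone in gradient schematics; an exponential cap
(`shape = "exponential"`, intensity `exp(−sharpness·u)`) is available for
smoother, reaction-diffusion-like profiles.  What the synthetic series
does *not* emulate: photobleaching, cell-to-cell variability of period and
amplitude, the finite width of the MinD polar zone boundary, or
segmentation artifacts in profile extraction.  Consequently the
`mind_profile` condition tests that the measured-profile *machinery*
(per-frame normalization, axial interpolation, nearest-frame time lookup
with cyclic wrap, noise) reproduces the idealized oscillating gradient —
it cannot certify behaviour on real micrographs.

Per-frame max-normalization (rather than global) keeps the polar cap
saturating at `p_max` every half-cycle even when total fluorescence
drifts; nearest-frame time lookup is used instead of temporal
interpolation because the 7-s frame spacing is much faster than chain
motion (interpolating would also blur the pole switch).  The default MCS
per second maps one full profile oscillation onto `2 × period` MCS so the
idealized and profile-driven oscillations run at the same speed.

## Analysis metrics for 1D data

`nucleoid_separation()` quantifies two-lobe separation in an axial
intensity profile: after moving-average smoothing (window 3 samples) and
prominence-based peak detection (threshold 5% of the maximum — both exposed,
needed only for noisy profiles), the profile is split at the interior
valley and it reports the distance **D** between the intensity-weighted
lobe centres and the depth **R = 1 − I_valley / mean(I_peaks)**.  R is a
convention of this package: the figure-style definition of "depth of
separation" is illustrated graphically in the source material rather than
written as a formula, so a bounded, unitless, rescaling-invariant form was
chosen.  R = 0 for a single-peaked profile and → 1 for fully resolved
lobes; a single-peak profile reports one nucleoid with R = D = 0.

`msd_curve()` / `apparent_diffusion()` implement standard single-particle
tracking estimation: time- and ensemble-averaged mean squared displacement
per lag, and the least-squares slope over the first 4 lags divided by 4
(2D).  Four lags is the common short-time compromise between bias
(confinement bends the curve down at long lags) and variance; it is a
parameter.  `simulate_focus_tracks()` generates the matching synthetic
ground truth (2D Gaussian walks, optional reflective disc confinement).
Only ratio-level comparisons between conditions (e.g. a planted 1.5×
mobility difference) are meaningful for real foci, since localization
noise adds an intercept the slope fit tolerates but does not remove.

## Correctness checks

The test suite leans on independent oracles rather than reference outputs:

* the bond set is compared against its squared-length characterisation,
  and the compiled kernel is replayed move-by-move against a pure-R
  implementation of the acceptance rules;
* equilibrium: a 4-monomer ring in a 6×6×6 box is sampled for 10⁶ MCS and
  its visit statistics are compared (chi-square) with marginals computed
  by exhaustive enumeration of all 4,579,392 valid configurations — the
  uniform measure implied by detailed balance.  Enumeration lives in a
  separate routine that shares no code with the kernel.  (The single-move
  graph has tiny non-ergodic pockets — in the 4³ box ~1% of states are
  unreachable — so marginal statistics, not per-state frequencies, are
  compared.);
* binding: logged binding events are tested against the analytic field
  shape conditional on recorded exposure; realized dwell times against the
  geometric law; `p_max = 0` against the no-tether code path bit for bit;
* estimators: MSD/diffusion recovery on planted Brownian tracks;
  separation metrics on analytic Gaussian mixtures.

Degenerate inputs are defined, not avoided: `steepness = 0` is the uniform
field; `dwell_mean = Inf` freezes permanently (the all-bound limit stops
the dynamics entirely); an all-zero profile frame yields a zero field;
ties in the left/right labelling are broken by the RNG.

## Problem sizes and what passing shows

Model-level acceptance tests run 14 replicates × 8×10⁵ MCS per condition.
The budget matters: ensemble averages plateau by ~3×10⁵ MCS, but a few
percent of gradient replicates sort to opposite poles only slowly (a chain
transiently held on the wrong side), and 8×10⁵ MCS is enough for every
replicate to reach its steady-state position — the regime the model's
claims are about.  Final positions are time-averaged over the trailing
5×10⁴ MCS of each trace, which damps the breathing that the oscillating
field imprints on the CM without changing its mean.  The replicate count
keeps the complete suite inside tens of minutes on a desk machine; a power
check at these sizes: the smallest real effect tested (oscillating
gradient vs no tether, about 1.3 standard deviations of per-replicate Δ)
is detected by the one-sided rank test at α = 0.01 with power > 0.95.
The headline orderings these ensembles reproduce:

* static and oscillating polar gradients increase Δ over entropy alone,
  and position the chains more precisely (smaller final-CM spread);
* uniform tethering does not improve segregation and slows it
  (longer time to half-separation);
* 10× dwell time drops segregation *below* the entropic baseline;
* the gradient segregates even with inter-chain excluded volume disabled
  (`entropy_off_gradient`) — the ratchet needs no entropic push;
* a synthetic MinD profile series drives segregation statistically
  indistinguishably from the idealized oscillating gradient;
* shallower gradients are less efficient but still beat entropy alone
  (steepness 2 ≥ 1 ≥ 0.5 > none).

## Known limitations

* Lattice kinetics are not mapped to physical time; MCS are the only
  clock, so all rate comparisons are internal to the model.
* The tether field is a mean-field probability: tethering sites are not
  discrete, saturable proteins, and release is force-independent (no slip
  or catch bonds).
* Rings have fixed length — no replication, no supercoiling, no
  hydrodynamics.
* The "entropy off" mode removes only inter-chain excluded volume;
  intra-chain self-avoidance is retained (an interpretation: without it
  the chains would not be polymers at all).
* Absolute binding kinetics in vivo are unknown; only orderings between
  tethering regimes, not absolute segregation speeds, are meaningful.
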