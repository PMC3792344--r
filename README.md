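# minratchet

Most bacteria segregate their replicated chromosomes without a mitotic
spindle, and in *E. coli* the responsible machinery has long been unclear.
One candidate mechanism is a **Brownian ratchet**: transient tethering of
chromosomal DNA to membrane sites whose density forms a polar gradient —
such as the one laid down by the oscillating Min system — rectifies the
random motion of each chromosome toward a pole, on top of the entropic
repulsion that two confined polymers already exert on each other.

`minratchet` is a simulation and analysis toolkit for that hypothesis:

* a lattice Monte-Carlo simulator of two self-avoiding **ring polymers**
  (bond-fluctuation method, 108-bond non-crossing move set) in a
  hard-walled 80 × 10 × 10 rod (aspect ratio 1:8, N = 80 monomers per
  chain);
* **membrane tethering fields**: uniform, static polar gradient
  `p(x) = p_max (2|x/Lx − ½|)^s`, pole-to-pole oscillating gradient, or a
  field driven by a time-resolved axial MinD intensity profile series
  (measured TSV or synthetic generator);
* **observables**: centre-of-mass trajectories and ensemble distributions,
  axial density profiles, radius of gyration, a force–distance probe of
  the inter-polymer repulsion (Metropolis coupling `U = f·d`);
* **analysis metrics for 1D data**: nucleoid separation depth *R* and
  distance *D* from axial intensity profiles, and MSD / apparent diffusion
  coefficients from 2D focus tracks.

Monomers within one lattice unit of a *lateral* wall bind with
probability `p(x, t)` per Monte-Carlo step and are immobilized for a
geometrically distributed dwell time (mean 100 MCS); the spatial bias of
repeated catch-and-release is the ratchet.  The methods vignette
(`vignettes/segregation-model.Rmd`) derives and motivates every default.

## A worked example

```r
library(minratchet)

## two entangled rings at mid-cell, then 5e5 MCS under an oscillating
## polar gradient of tethering sites
st  <- init_overlapping_rings(seed = 1)
run <- run_mcs(st, tether_field("oscillating_gradient"), n_mcs = 5e5,
               record_every = 5000)
run$state
#> <seg_state: 2 rings of N=80 in 80x10x10 box, mcs=500000>
#>   cm_rel: +0.194 -0.256   tethered: 42/160   interchain exclusion: TRUE
```

The two chromosomes started mixed at mid-cell (`cm_rel` ≈ 0) and ended
near the quarter positions (±0.25 = centres of the two cell halves) — the
positions replicated chromosomes occupy before division.  At any moment a
small fraction of monomers is tethered; the grip is transient, which is
what makes the ratchet work.

Condition-level comparisons use replicate ensembles:

```r
none <- run_experiment(experiment_spec("no_tether",       n_replicates = 8,
                                       seed_base = 1))
stat <- run_experiment(experiment_spec("static_gradient", n_replicates = 8,
                                       seed_base = 100))
compare_conditions(stat, none)
#>                 a               b delta_a delta_b  effect p_greater significant
#> 1 static_gradient       no_tether   0.326   0.244  0.0817   0.00047        TRUE
#> 2       no_tether static_gradient   0.244   0.326 -0.0817   0.99968       FALSE
```

`delta` is the separation statistic (mean final |CM| relative to cell
length): the polar gradient parks the chains significantly further
out than entropic repulsion alone.  The same interface exposes the other
study conditions (`uniform`, `dwell_x10`, `entropy_off_gradient`,
`mind_profile`, `steepness_sweep`) — see `condition_config()`.

Analysis metrics work on plain tables:

```r
x <- seq(-2.5, 2.5, by = 0.02)                       # positions, um
y <- exp(-(x + 1)^2/(2*0.2^2)) + exp(-(x - 1)^2/(2*0.2^2))
nucleoid_separation(x, y)
#> <separation: 2 nucleoids, R = 1.000, D = 2>

tracks <- simulate_focus_tracks(1e4, 30, dt = 0.05, D0 = 0.01, seed = 1)
apparent_diffusion(msd_curve(tracks, max_lag = 8), fit_lags = 4)$D
#> [1] 0.01002491
```

A thin command-line wrapper with the same functionality (subcommands
`simulate`, `ensemble`, `force-curve`, `min-profile-synth`,
`metrics-separation`, `metrics-msd`, `fixtures`) is installed as
`exec/minratchet`.

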