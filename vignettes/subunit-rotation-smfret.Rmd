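---
title: "Modelling and analysing subunit-rotation smFRET trajectories"
author: "rotafret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing subunit-rotation smFRET trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotafret)
```

## The system and the model

Serine recombinases cut both strands of two synapsed DNA sites and are
thought to exchange them by rotating one half of the cleaved
protein--DNA complex 180 degrees about a flat hydrophobic interface
before re-ligation.  On a linked two-site substrate carrying a
donor/acceptor pair, each stage of the cycle sits at a distinct
inter-dye distance, so a surface-immobilized complex under TIRF
illumination reports the cycle as FRET-efficiency jumps between four
levels.

`rotafret` treats the cycle as a continuous-time Markov chain on the
linear chain

```
lnr  <->  cnr  <->  cr  <->  lr
```

(ligated/cleaved, non-recombinant/recombinant).  The six rate constants
are cleavage and ligation on each side (`k_cle`, `k_lig_nr`, `k_lig_r`,
`k_cle_r`) and the forward/reverse rotation rates (`k_rec`,
`k_non_rec`).  Only nearest neighbours on the chain communicate; a
direct lnr -> cr jump has zero rate and can only *appear* in data as a
camera artifact (see *Frame blur* below).

Presets carry the published operating points: rotation rates 0.86 and
0.48 s^-1 for Sin at 37 °C and 1.14 and 0.41 s^-1 for Tn3, and state
FRET levels 0.16/0.29/0.50/0.77 (Sin) and 0.12/0.31/0.54/0.73 (Tn3).
Cleavage/ligation rates are not published at single-transition
resolution, so every preset carries a declared placeholder of
1.0 s^-1, exposed as ordinary configuration.  The Sin room-temperature
and +Mg presets take their state levels from the corresponding reported
conditions and reuse the 37 °C rotation rates as stand-ins.

## What the simulator emulates, and what it does not

`simulate_state_path()` is an exact (Gillespie) realization of the rate
matrix.  `render_trace()` integrates the path into 50 ms camera frames
(~25 s per trace), splits a mean total intensity of 1000 counts/frame
between acceptor and donor according to the frame's time-weighted mean
efficiency, and adds per-channel Gaussian noise (SD 50 counts,
EMCCD-like read-out after gain; Poisson shot noise is available as an
option).  Two independent exponential clocks (default 0.01 s^-1 each)
bleach the acceptor (intensity reverts to the donor channel) or the
donor (both channels fall to background).  A configurable fraction
(default 0.15) of traces is donor-only, the zero-FRET nuisance
population always present in a TIRF field.  Mid-frame transitions are
rendered by exact time-weighted averaging, which is what produces
"skipped states" downstream when a dwell approaches the frame time.

Real data differ in ways the generator does not attempt: diffusive
intensity fluctuations, dye blinking, spectral crosstalk and gamma
heterogeneity between molecules, baseline drift, and any non-Markovian
kinetics.  Passing the recovery tests therefore shows that the analysis
chain is a consistent estimator under its own assumptions at realistic
signal-to-noise -- not that those assumptions hold for any particular
microscope.

## Idealization

Each filtered trace is idealized individually (no stitching) with a
Gaussian-emission hidden Markov model fit by Baum--Welch EM from 10
randomized starts (alternating occupancy-weighted quantile seeding and
range-spread seeding, so sparsely visited extreme states are not
missed), Viterbi-decoded, and canonicalized by ascending mean.  Two
modelling choices deserve comment:

* **Shared emission width.**  By default one emission SD is estimated
  for all states (`shared_sd = TRUE`).  The width is set by camera
  noise, which is the same for every state; the practical benefit is
  that a surplus model state cannot inflate its variance into a
  catch-all for non-Gaussian stray frames.  Per-state widths remain
  available, and the BIC in `select_k()` counts parameters accordingly
  ((K-1) + K(K-1) + K + 1 tied, (K-1) + K(K-1) + 2K untied).
* **Model order.**  The pipeline default fits K = 4 states per trace,
  mirroring the original per-trace idealization; per-trace BIC
  selection over 1..K is available (`hmm_mode = "select"`).  The number
  of *physical* states is decided later, at the TDP stage, so the
  per-trace order is an implementation device, not a scientific claim.

Numerical guards: variance floor 1e-4 E^2 (noiseless test signals
otherwise collapse EM), convergence when the log-likelihood gain drops
below 1e-6, at most 1000 iterations, Viterbi ties broken toward the
lowest state index.

## Frame blur and its containment

A transition in the middle of a 50 ms frame leaves one frame whose
efficiency is a mixture of the two flanking levels.  At the rates
simulated here several percent of frames are such blur frames, and they
are the single largest threat to state counting: EM gladly parks a
spare state on them, and those phantom levels then demand extra
clusters in the transition-density plot.  Three post-processing steps,
each grounded in the physics, contain this:

1. `viterbi_path()` re-estimates each state level from dwell-interior
   frames only (a dwell's first and last frame can straddle a
   transition), removing the blur bias from the level estimate.
2. `merge_idealized_states()` merges decoded states closer than 0.06 in
   E -- above the level-estimation noise, below half the smallest
   physical state separation (0.13) -- which removes duplicate states
   that EM creates when a trace visits fewer states than the model
   order.
3. `extract_transitions()` discards, per trace, states whose mean dwell
   is shorter than 2 frames.  A physical state at the rates considered
   here dwells for about 10 frames on average; a state visited almost
   exclusively for single frames is a blur container.  Its orphan
   frames join the preceding dwell, yielding exactly the composite
   ("skipped") transitions expected when an intermediate dwell is
   unresolved.

`prune_broad_states()` additionally removes states whose emission width
exceeds 1.5x the median of their peers; with shared widths it is a
no-op and it exists for the per-state-width mode.

## Transition-density-plot clustering

Only interior transitions enter the TDP: the first and last run of a
trace have censored dwells and are excluded outright.  Records carry
the fitted level before and after the change and the dwell preceding
it.  The Gaussian-convolved TDP grid (`build_tdp()`) is display-only;
the mixture is fit on the raw (E_before, E_after) points, where the
likelihood is well defined.

For each candidate K (1..10), the model is a mixture of K(K-1)
isotropic 2D Gaussians whose centres are constrained to the ordered
pairs of K shared state levels; free parameters are the levels, the
cluster weights and one variance per cluster (floored at 1e-4 E^2).
Thirty seeded initializations are screened with 25 EM iterations each
and the best is polished to convergence (relative tolerance 1e-6, max
300 iterations); with well-separated levels the winner coincides with
running every start to convergence.  K_opt minimizes
BIC = -2 logL + p log(n) with p = K + (K(K-1) - 1) + K(K-1); ties go to
the smallest K; K = 1 is scored as a single broad component (p = 2).

## Dwell-time kinetics

The dwell before an i -> j transition is exponential in the *total*
exit rate of state i, regardless of destination.  Cumulative dwell-time
distributions are therefore fit per transition cluster (unbinned
empirical CDF at midpoint plotting positions, Levenberg--Marquardt, A2
= 0 for mono fits, mono/bi chosen by BIC with both reported), and the
weighted-average rate

k_av = 1 / (A1/k1 + A2/k2)

estimates that total exit rate.  Multiplying by the branching fraction
of i -> j among all exits from i (derived from the TDP cluster weights)
converts it to the transition's own rate coefficient; scaled this way,
competing exits sum back to the state's total exit rate.  The literal
"lifetime x weight" reading is available as `mode = "lifetime"` in
`scale_by_cluster_weight()` for comparison.

Uncertainties come from 100 bootstrap resamples of the dwells (seeded;
refit per resample; per-parameter SD and 3xSD reported).  The
propagation formulas are implemented in two modes: `"paper"` evaluates
DM = (A1/k1) sqrt((dA1/A1)^2 + (dk1/k1)^2), DN likewise, and
Dk_av = sqrt(DM^2 + DN^2) exactly as printed -- note this quantity has
units of time; `"propagated"` multiplies by k_av^2, the first-order
delta-method result for k_av = 1/(M+N), and is labelled as the
package's own correction, not a published formula.

One-frame dwells are retained: they drive the fast biexponential
component whose time constant approaches the frame time.

## Distances and accessible volumes

The Förster relations `efficiency_to_distance()` /
`distance_to_efficiency()` and `predict_table()` reproduce the
published efficiency-to-distance table; rows whose printed E and
printed distance disagree (after rounding) by more than 0.1 Å are
flagged with both the forward-computed distance and the back-computed
efficiency rather than silently matched.  Förster radii are inputs;
computing them from spectra is out of scope.

`compute_av()` implements the three-radii accessible-volume model: a
dye position is allowed when the dye sphere (one of three radii, clouds
superposed with equal weight) clears all atoms, and when a linker of
length L and width w can reach it through free space.  Geodesics are
computed by Dijkstra on the 26-neighbour grid graph seeded with exact
line-of-sight distances, so in open space the metric is exact (the
unobstructed AV is a true ball) and the graph approximation only enters
behind obstacles.  Grid spacing defaults to 1 Å (0.5 Å for
high-accuracy work; eight-fold cost).  Dye geometries (linker length
~20 Å, width 4.5 Å, three radii per fluorophore) are plausible
literature-style values shipped as documented defaults -- the exact
parameters of the original dye-cloud calculations are not published, so
absolute predicted distances are indicative.  `rotation_scan()` rotates
one half of a structure rigidly about a user-specified axis and records
the FRET-averaged distance per angle; on an asymmetric synapse the
0-180° and 180-360° halves of the profile differ, which is the
geometric signature distinguishing the two senses of rotation.

## Problem sizes and reproducibility

The recovery analyses run 200 traces x 25 s at 50 ms frames per
replicate, with TDP clustering over K = 1..10 and 30 initializations --
the same shape as the study they mirror; ten seeded replicates back the
state-count claim.  A master seed drawn through `run_config()`
determines every stage seed (`sample.int` from the master; each trace
and bootstrap gets its own derived seed), so any report is regenerable
from its config alone, and `run_pipeline()` logs record counts per
stage so filtering decisions are auditable.

## Known limitations

* Dwell times are integer multiples of the frame time and events briefer
  than a frame are missed, so apparent dwells are slightly long and the
  state-lifetimes rate estimates carry a downward bias of order 10% at
  the simulated operating points — inherent to the method at 50 ms
  frames, and well inside the recovery tolerances used here.
* The blur-containment rules assume state dwells well above one frame;
  systems with genuine sub-frame states need a blur-aware observation
  model rather than post-hoc filtering.
* Bleach detection is a windowed median jump test; gradual
  photophysics (slow quenching, drift) is not modelled or detected.
* The AV implementation targets toy-to-moderate structures (the grid is
  cubic in the linker length); it has no dye--dye photophysics and
  fixes kappa^2 = 2/3 implicitly through the Förster radius input.
* Real-data corrections (gamma, crosstalk, background) are implemented
  but default to the uncorrected proximity ratio, matching how the
  TIRF state levels are reported.
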