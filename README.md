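# rotafret

Simulation and analysis of single-molecule FRET (smFRET) trajectories of
serine-recombinase synaptic complexes undergoing **subunit rotation** —
the mechanism by which one half of a cleaved recombinase–DNA complex
rotates 180° about a flat protein interface to exchange DNA strands.

The strand-exchange cycle is modelled as a continuous-time Markov chain
on four intermediates,

```
lnr  <->  cnr  <->  cr  <->  lr          (ligated/cleaved, non-/recombinant)
     k_cle   k_rec    k_lig
     k_lig   k_non-rec k_cle
```

each with its own FRET efficiency.  The package contains the full
analysis chain used to measure the rotation rates from camera traces:

* **Simulator** — Gillespie realization of the kinetic scheme, rendered
  into 50 ms camera frames with shot-like noise, donor/acceptor
  photobleaching, a donor-only nuisance population, and exact
  time-weighted frame averaging (the origin of "skipped states").
* **Trace I/O and QC** — delimited trace tables, FRET conversion with
  gamma/crosstalk/background corrections, declared quality filters and
  single-step bleach truncation.
* **Idealization** — Gaussian-emission hidden Markov model (Baum–Welch
  EM, multi-start, Viterbi), with compiled kernels.
* **Transition analysis** — transition density plot (TDP) of
  (E_before, E_after) pairs, clustered with a constrained mixture of
  K(K−1) isotropic 2D Gaussians; the number of FRET states K_opt is
  selected by BIC over K = 1…10 with 30 initializations.
* **Dwell-time kinetics** — unbinned cumulative dwell-time
  distributions fit with mono/biexponentials, cluster-weight scaling,
  the weighted-average rate k_av = 1/(A₁/k₁ + A₂/k₂), bootstrap errors
  (100 resamples, 3×SD) and the printed error-propagation formulas.
* **Photophysics & structure** — Förster efficiency/distance
  conversion, FRET-vs-lifetime and Perrin reference lines,
  accessible-volume (three-radii AV) dye-cloud simulation on PDB
  structures, and a rigid-body 360° subunit-rotation scan of the
  FRET-averaged inter-dye distance.

## Worked example

```r
library(rotafret)

cfg <- run_config("sin37", n_traces = 200, duration = 25, seed = 11)
rep <- run_pipeline(cfg, quiet = TRUE)
rep
#> Pipeline run (sin37 preset): K_opt = 4
#>   levels: lnr=0.159(0.071) cnr=0.288(0.010) cr=0.500(0.010) lr=0.771(0.071)
#>   rates (k_trans, 1/s):
#>     lnr->cnr  0.810 (n=421)
#>     lnr->cr  0.027 (n=17)
#>     cnr->lnr  0.789 (n=428)
#>     cnr->cr  0.843 (n=410)
#>     cr->cnr  0.432 (n=390)
#>     cr->lr  0.876 (n=751)
#>     lr->cr  0.909 (n=736)
#>     ...
```

Reading this: 200 simulated 25 s traces at the Sin-37 °C operating
point were filtered, idealized and pooled into a TDP; BIC selected
**four** FRET states at levels 0.16/0.29/0.50/0.77 (the generating
values), and the dwell-time analysis recovered the forward rotation
rate cnr→cr as 0.843 s⁻¹ against the generating 0.86 s⁻¹ (reverse:
0.432 vs 0.48 s⁻¹).  Low-weight entries such as lnr→cr are "skipped"
transitions — intermediate dwells shorter than one 50 ms frame.

Distance conversion of the measured state efficiencies:

```r
subset(predict_table(), system == "Sin" & condition == "37C",
       select = c(state, E, R0, R_DA_computed, R_DA_printed))
#>   state    E   R0  R_DA_computed  R_DA_printed
#>     lnr 0.16 67.4           88.9          88.9
#>     cnr 0.29 67.4           78.2          78.2
#>     cr  0.50 67.4           67.4          67.4
#>     lr  0.77 67.4           55.1          55.1
```

The numbered scripts under `analysis/` run the same chain as a
narrative workflow (simulate → idealize → cluster → kinetics → distance
table → rotation scan) and write their tables under `results/`.

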