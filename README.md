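# navgate

Voltage-gated sodium (Nav) channels open for less than a millisecond
before fast inactivation shuts them. The classical "hinged-lid" picture
holds that the IFM motif itself plugs the pore; recent structures put
the bound motif far from the permeation pathway, and functional work on
rNav1.4 instead locates the final gate in **two rings of bulky
hydrophobic residues at the intracellular end of the S6 helices**, one
α-helical turn apart, which close *downstream* of IFM binding. Shrinking
the side chains in both rings (e.g. the DIII double mutant I1284A/I1288A,
"DIIIAA") leaves a **"leaky" inactivated state** that still conducts at
~20 % of the peak current with strongly reduced Na⁺/K⁺ selectivity.

`navgate` packages the complete computational toolkit for this picture:

* **Markov voltage-clamp simulator** — an 8-state gating scheme
  (activation × {DIV-VSD, IFM binding, gate closure}) with the
  single-barrier rate law *k(V) = k₀·exp(z·FV/RT)*, exact per-epoch
  propagation of the master equation, GHK multi-ion currents
  (outward positive) and gating currents *I₉ = N·e₀·Σ q·k·P*.
* **Synthetic cut-open-oocyte recordings** — ten reference fixtures
  (WT, single/double/quadruple S6 alanine mutants, IFM mutants) with
  capacitive transients (clamp τ = 75 µs), 20 kHz band-limited noise and
  online P/N leak subtraction, written as diffable TSV + JSON sidecars.
* **The electrophysiology analysis pipeline** — 1–2-exponential kinetics
  with amplitude-weighted time constants, off-gating decomposition and
  charge-immobilization curves, two-state Boltzmann fits for h∞
  (`Base + (1−Base)/(1+e^{z(V−V_{1/2})F/RT})`), G-V and Q-V
  (`1/(1+e^{−z(V−V_{1/2})F/RT})`), and the time-resolved selectivity
  procedure: instantaneous I-V → V_rev(t) → GHK inversion
  `P_Na/P_K = ([K]_i/[Na]_o)·e^{V_rev F/RT}`.
* **A HOLE-style pore profiler** — maximal-inscribed-sphere tracing of
  PDB/mmCIF structures, two-tier constriction detection, lining-residue
  reports, and cross-isoform residue mapping by global alignment.

## Worked example

```r
library(navgate)

## leaky steady-state current of the DIII double mutant at +60 mV
sol <- solution_pair(na_out = 57.5, na_in = 12)   # mM, 11.5 degC
rec <- generate_recording("DIIIAA",
                          protocol_builtin("step", test_mV = 60,
                                           test_dur_ms = 30),
                          sol, noise_model(0.14, 20, seed = 1),
                          pn = pn_spec(4, -130, -1))
ps <- peak_and_steady(rec$sweeps[[1]])
#> peak 7.76 uA, steady 1.39 uA, Iss/Ipeak = 0.179

## selectivity of the leaky state from its reversal potential
permeability_ratio(18, solution_pair(na_out = 57.5, k_in = 120))
#> [1] 4.35
```

The first number is the mutant's hallmark: ~18 % of the peak current
persists at the end of a 30 ms depolarization (wild type: < 3 %, run
`"WT"` to see it). The second inverts the GHK reversal relation at the
steady-state component's measured reversal (18 mV in bionic
57.5 Na⁺ out / 120 K⁺ in): the leaky inactivated state conducts with
P_Na/P_K ≈ 4, about three-fold less Na⁺-selective than the open state
(≈ 11). `fixture_catalog()` lists all ten constructs with the
observables each is tuned to reproduce.

## Layout

`R/` implementation · `inst/extdata/fixtures` versioned fixture configs ·
`inst/extdata/structures` synthetic stand-in pore geometries (labelled:
they mimic the published two-tier architecture, they are **not**
deposited coordinates) · `vignettes/navgate-methods.Rmd` the methods
notes · `exec/navgate` a small CLI (`simulate`, `pore`, `catalog`).
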