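# cardiomd

Heart failure progressively dismantles the transverse-tubule (T-tubule)
system of ventricular myocytes. L-type calcium channels (LTCCs) that
normally sit in dyads opposite ryanodine receptors (RyRs) are redistributed
to the surface sarcolemma, where they no longer sense the large dyadic Ca²⁺
transients; β₂-adrenergic receptors (β₂AR) and phosphodiesterases (PDE)
lose their T-tubular confinement, so cAMP/PKA signaling that is normally
local becomes cell-wide. `cardiomd` is a single-cell simulation package for
studying how these microdomain changes alter the LTCC current (I_CaL) and
create cellular arrhythmia triggers — early afterdepolarizations (EADs) and
non-repolarizing membrane-potential oscillations — in a human ventricular
myocyte. It is aimed at cardiac electrophysiology modellers.

## Model

The core is the O'Hara–Rudy human endocardial action-potential model
(compiled C right-hand side, 44 states) extended with:

- **Six LTCC subpopulations.** Each channel is T-tubular or surface
  (probability `f_TT`), β₂AR-associated or not (`f_B2AR`), and
  PDE-regulated or not (`f_PDE`). The subgroup weights are the products,
  e.g. w_A = f_TT·f_B2AR·f_PDE for T-tubular channels with both partners;
  channels without β₂AR collapse into one subgroup per membrane (C, F).
  Total I_CaL is the weight-sum of the subpopulation currents; channel
  number and unitary conductance are held fixed across remodeling.
- **Binary PKA phosphorylation.** A phosphorylated LTCC carries 2.5× the
  current. PDE-regulated channels are 25% phosphorylated at rest and 75%
  under sympathetic stimulation; PDE-free, β₂AR-associated channels are
  fully phosphorylated under stimulation (PDE itself is PKA-activated, so
  its absence changes nothing at rest); β₂AR-free channels are never
  phosphorylated. Seven further targets (RyR, phospholamban, I_Ks, I_Na,
  I_NaK, I_Kur→I_Kb, troponin I) switch 25%→75% with stimulation, with
  per-target effect magnitudes in an editable constants file
  (`inst/extdata/phospho_effects.yaml`).
- **A sub-sarcolemmal Ca²⁺ compartment** (`casl`, 2% of cell volume,
  Shannon-type sarcolemmal buffers) that surface LTCCs, redistributed NCX,
  and surface Ca-dependent inactivation sense.
- **NCX redistribution and RyR orphaning.** The T-tubular NCX fraction
  0.8·f_TT moves to the surface (sensing `casl`) as tubules are lost;
  RyRs decouple in the same proportion, the orphaned pool being triggered
  by bulk cytosolic Ca²⁺ only.

Protocols: the voltage-clamp step (−96.7 → −6.7 mV) with per-component
mono-exponential decay fits (τ₁ T-tubular, τ₂ surface), steady-state pacing
at 1000 ms cycle length with APD90 (time from maximal upstroke velocity to
90% repolarization), EAD counting, beat classification
(normal / EAD / oscillatory), and APD90/classification heatmaps over the
(f_TT, f_PDE, f_B2AR) grid.

## Worked example

```r
library(cardiomd)

# intact control myocyte (case 1: 80% of LTCCs in dyads with B2AR + PDE)
cfg <- model_config(case_id = 1)

vc <- run_voltage_clamp(cfg)
sprintf("tau1 = %.1f ms (T-tubular), tau2 = %.1f ms (surface)",
        vc$tau1$tau, vc$tau2$tau)
#> "tau1 = 17.9 ms (T-tubular), tau2 = 81.9 ms (surface)"

pe <- run_pacing_experiment(cfg, recorded_beats = 3,
                            max_conditioning_beats = 200)
pe$metrics
#>   beat    apd90 t_upstroke n_ead  class
#> 1    1 290.6040        1.2     0 normal
#> 2    2 290.5871        1.2     0 normal
#> 3    3 290.5704        1.2     0 normal
```

The T-tubular current inactivates fast (τ₁ ≈ 18 ms) because dyadic Ca²⁺
accumulates steeply; the surface component decays several-fold more slowly.
The paced control cell repolarizes normally with APD90 ≈ 291 ms. A
de-tubulated cell lacking PDE control, under sympathetic stimulation,
fails to repolarize:

```r
cfg5 <- model_config(case_id = 5,
                     remodeling = remodeling_params(stimulated = TRUE))
pe5 <- run_pacing_experiment(cfg5, recorded_beats = 3,
                             max_conditioning_beats = 200)
table(pe5$metrics$class)
#>      normal oscillatory
#>           2           1
```

A command-line front end is provided as `exec/cardiomd`
(`cardiomd clamp|pace|sweep|case ...`), writing traces and metrics as
provenance-stamped CSV.

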