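---
title: "Microdomain remodeling and arrhythmogenic triggers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microdomain remodeling and arrhythmogenic triggers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiomd)
```

`cardiomd` simulates a family of human ventricular heart-failure myocyte
models: a baseline endocardial action-potential model extended with graded
T-tubule loss, six L-type calcium-channel (LTCC) subpopulations, binary
PKA/CaMKII phosphorylation populations, a sub-sarcolemmal Ca compartment,
and redistribution of Na/Ca exchangers (NCX) and ryanodine receptors
(RyRs). This vignette is the package's account of the science: the model
and its assumptions, the parameters that matter, the numerical and design
choices, and what the tests do and do not establish.

## The baseline cell

The starting point is the O'Hara–Rudy human endocardial ventricular
myocyte: Hodgkin–Huxley currents (I_Na, I_NaL, I_to, I_CaL with its Na/K
components, I_Kr, I_Ks, I_K1, NCX, Na/K-ATPase, background and pump
currents), four Ca compartments (bulk myoplasm, dyadic subspace, network
and junctional SR) with instantaneous-buffer approximations, and dynamic
CaMKII activation driven by dyadic Ca. The right-hand side is transcribed
into C (`src/ord_model.c`); the stiff solver is `deSolve::lsoda` at
relative tolerance 1e-6 and absolute tolerance 1e-8, with analysis traces
sampled at 0.1 ms. Protocols integrate segment-wise (stimulus on, stimulus
off) so the solver never steps across a current discontinuity. The
stimulus is −80 µA/µF for 0.5 ms, carried on the K⁺ balance; cell type is
fixed endocardial throughout.

With phosphorylation fractions set to zero, all subgroup weight on the
dyadic population, and the dynamic CaMKII mix applied to LTCCs
(`ttub_camk = "dynamic"`), the extended model *is* the baseline cell: the
test suite verifies a stable resting state near −88 mV, an APD90 at
1000 ms cycle length in the published endocardial range, and that
perturbing any of the new machinery (surface-CDI scale, orphaned-release
constants, surface CaMKII fraction) leaves the intact cell's AP unchanged
to below 1 µV.

## Subgroups and phosphorylation populations

Each LTCC is characterized by three independent Bernoulli properties:
located in a T-tubule (probability `f_tt`), associated with a β₂
adrenergic receptor (`f_b2ar`), and subject to phosphodiesterase (PDE)
activity (`f_pde`). The subgroup weights are the products; channels
without β₂AR association can never be phosphorylated, so both their PDE
states collapse into one subgroup per membrane. `subgroup_fractions()`
normalizes exactly (the largest weight absorbs the rounding residue), and
the test suite checks the partition over the full sweep grid.

Phosphorylation is binary per channel, so each subgroup splits into a
phosphorylated and an unphosphorylated population; a PKA-phosphorylated
LTCC carries `ltcc_amp_factor` (default 2.5) times the unit current. The
phosphorylated fractions encode the signaling logic:

| class                    | basal | stimulated |
|--------------------------|-------|------------|
| β₂AR + PDE (A, D)        | 0.25  | 0.75       |
| β₂AR, no PDE (B, E)      | 0.25  | 1.00       |
| no β₂AR (C, F)           | 0     | 0          |

PDE is itself activated by PKA, so at rest (no PKA drive) the presence or
absence of PDE is irrelevant — PDE-free channels take the basal fraction.
Under sympathetic stimulation PDE is the only brake on PKA, so channels
lacking it become fully phosphorylated. Seven further PKA targets (RyR,
phospholamban, I_Ks, I_Na, I_NaK, I_Kur and troponin I) switch from 25% to
75% phosphorylated with stimulation, independent of the LTCC-specific
`f_pde`/`f_b2ar` (those fractions describe LTCC-co-localized signaling
only). Per-target effect magnitudes live in
`inst/extdata/phospho_effects.yaml`, as data with a citation string per
entry. The LTCC ×2.5 amplitude is the literature value; the non-LTCC
magnitudes were calibrated once so that the healthy (intact) myocyte shows
the expected modest APD90 prolongation under sympathetic stimulation
rather than paradoxical shortening, and were not revisited afterwards.
The baseline human model has no explicit I_Kur; that target is mapped to
the background K⁺ current I_Kb, its conventional surrogate in this
formulation.

CaMKII phosphorylation of I_Na, I_NaL, SR release and uptake keeps the
baseline model's dynamic CaMKII-activity fractions. For LTCCs the package
follows the experimental picture that CaMKII phosphorylation is a feature
of surface-membrane channels: T-tubular LTCCs carry none (outside the
baseline-reduction mode), while surface channels carry a constant
CaMKII-phosphorylated fraction (`camk_fraction`, default 0.25, matching
the basal PKA fraction), using the baseline model's phosphorylated-gate
kinetics (slower voltage inactivation, 1.1× permeability).

## The sub-sarcolemmal compartment and surface CDI

Surface LTCCs sense and feed a sub-sarcolemmal Ca pool `casl`:
`vsl_frac = 0.02` of cell volume and a sub-sarcolemma↔myoplasm exchange
time constant `tau_sl = 0.18` ms, both the Shannon rabbit values, with
Shannon's sarcolemmal buffers (low-affinity 1.65 mM/Kd 13 µM plus
high-affinity 0.3 mM/Kd 0.3 µM; the high-affinity sites dominate
differential buffering at sub-micromolar Ca). Surface NCX exchanges Ca
with this pool, and the surface channels' Ca-dependent inactivation (CDI)
mode fraction (`ncasl`, the analogue of the dyadic `nca`) is driven by it.

One structural parameter has no counterpart in the baseline model:
`sl_cdi_scale` (default 0.65) attenuates the CDI-mode entry rate of
surface channels. The motivation is twofold. Physiologically,
super-resolution patch-clamp work on failing myocytes reports weaker CDI
for surface-membrane LTCCs outside the restricted dyadic geometry.
Structurally, the baseline CDI-mode kinetics make the CDI branch
quasi-absorbing under maintained depolarization (the recovery gate `jca`
relaxes to ~0.03 at plateau potentials), so any local Ca above roughly
0.15 µM drives surface channels into CDI within ~200 ms; without
attenuation the de-tubulated cell cannot exhibit the sustained surface
current that underlies its arrhythmogenic phenotype. The default was
calibrated against qualitative beat classifications only — a basal
de-tubulated myocyte must repolarize normally, while a fully
phosphorylated surface current under sympathetic stimulation must fail to
repolarize (the oscillatory phenotype) — and not against any numeric
decay-constant or APD target.

## NCX redistribution and RyR orphaning

In the intact cell a fifth of the NCX operates at the surface membrane and
the rest in the T-tubular region. `ncx_distribution(f_tt)` returns
`(0.8·f_tt, 0.2 + 0.8·(1 − f_tt))`. Internally the native fifth keeps its
baseline subspace formulation, the T-tubular fraction (0.8·f_tt) keeps the
baseline bulk-Ca formulation, and only the redistributed fraction
(0.8·(1 − f_tt)) senses the sub-sarcolemmal pool — so at `f_tt = 1` the
model is exactly the baseline cell.

RyRs decouple from LTCCs in proportion to tubule loss
(`ryr_coupling(f_tt)`). Coupled release keeps the baseline gain
formulation with the *T-tubular* LTCC current as trigger: redistribution
weakens the trigger through the current itself, reproducing the weaker
dyadic release of de-tubulated cells. Orphaned RyRs (fraction `1 − f_tt`)
are gated by bulk cytosolic Ca through a Hill activation (K = 2 µM,
n = 2, trigger amplitude 2 µA/µF-equivalent — the scale of the intact
trigger current), share the SR-load dependence and relaxation kinetics of
coupled release, and release into the myoplasm. Because diastolic and
transient bulk Ca sit far below K, orphaned release is weak — the intended
phenotype. The orphaned pool is a single population (no CaMKII sub-split).

## Protocols and trace metrics

**Voltage clamp.** The myocyte is held at −96.7 mV until the gating and
Ca-handling states stop changing (relative drift per 10 s chunk below
1e-3; monovalent ion concentrations drift quasi-statically under a
sustained clamp, as in a dialyzed cell, and are excluded from the
criterion), then stepped to −6.7 mV for 500 ms with components sampled at
0.1 ms. Each I_CaL component (T-tubular τ₁, surface τ₂) is fitted with a
single exponential plus offset by multi-start Levenberg–Marquardt. The
fit window opens where the current has relaxed to 95% of its post-peak
magnitude and closes where the decay phase ends — the point at which the
magnitude rebounds by more than 2% of the peak above its running minimum
(late SR-release-driven bumps are not inactivation) — or at the step end
for monotone decays, from which slow constants are extrapolated. Fits on
traces whose decay phase is cut before half the decay has happened, or
with residuals above 10% of the peak, are flagged (`ok = FALSE`) but still
reported.

**APD90 and beat classification.** APD90 is the time from maximal
upstroke velocity to 90% repolarization (diastolic reference taken just
before the stimulus; crossing located by linear interpolation). An EAD is
a local minimum followed by a local maximum during repolarization, with
prominence ≥ 1 mV on a 1 ms-smoothed trace, takeoff at or below +20 mV
(the spike-notch-dome complex is not an EAD) and peak above −50 mV. A
beat that never reaches 90% repolarization before the next stimulus is
`oscillatory` and carries no finite APD90; oscillatory beats are excluded
from mean APD90 (they can optionally be assigned the cycle length by
post-processing the returned metrics).

**Pacing.** Cells are paced at 1000 ms cycle length until the maximum
relative state change between successive beat starts falls below 1e-4
(capped at 1000 beats by default), then 3 beats (APD analysis) or 15
beats (EAD evaluation) are recorded. `sweep_heatmap()` repeats this over
the (f_tt, f_pde) grid per β₂AR level; it is deterministic and
order-independent, and records per-cell failures without aborting the
sweep.

## Problem sizes used by the test suite

The shipped tests condition with caps of 60–200 beats (the intact cell
converges in ~80 beats at the 1e-4 criterion) and exercise a reduced
3×3×2 sweep (f_tt, f_pde ∈ {0, 0.5, 1}; f_b2ar ∈ {0.25, 1}; 15 recorded
beats) rather than the full 11×11×5 grid; the full grid runs with the
same code path via `sweep_heatmap()` defaults. Sweep beats are sampled at
0.5 ms (APD90 is stable under sampling-interval halving well below this).

## Design choices where the design was open

- Cell type endocardial; the baseline model's default.
- Steady state defined by the 1e-4 beat-to-beat criterion; doubling the
  conditioning leaves APD90 within 1 ms (tested).
- Case presets (1–6) put 80% of channels in one subgroup; at each case's
  nominal corner the product weights of the other subgroups vanish, so
  the remaining 20% is spread uniformly (0.04 each) over the other five
  subgroups. Cases pin the LTCC weights; NCX/RyR remodeling uses the
  corner `f_tt`.
- The orphaned-RyR trigger, the surface-CDI attenuation, and the non-LTCC
  effect magnitudes are the three places where constants were set by
  calibration rather than taken from a source; each is documented above
  with its calibration criterion, and all are config-exposed.

## Limitations

The model family represents microdomain remodeling only: no β₁AR
signaling, no dynamic cAMP/PKA/PDE network (phosphorylated fractions are
quasi-static populations), no heart-failure remodeling of I_NaL, I_Ks or
I_Kr, no cell-to-cell coupling, no contraction mechanics, and well-mixed
compartments throughout. Conclusions about tissue-level arrhythmia cannot
be drawn from single-cell triggers. The phosphorylation effect table
approximates a detailed signaling model; with it, the package reproduces
the qualitative trigger phenotypes (stimulation-dependence of EADs, the
protective effect of PDE and of β₂AR scarcity, oscillations in heavily
de-tubulated cells) and the fast dyadic decay constant, while the slow
surface-component decay constants come out faster than the reported
values — with the baseline gate structure, a surface current's fitted
decay is bounded by the voltage-inactivation gate mixture once CDI is
attenuated, so the package's τ₂ values sit well below the published slow
constants. Tests passing on this model therefore demonstrate internal
consistency and the mechanistic phenotypes, not quantitative agreement of
every reported constant, and say nothing about behavior in real,
spatially heterogeneous myocytes.
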