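---
title: "Reciprocal regulation in bifunctional two-component systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal regulation in bifunctional two-component systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcskinetics)
```

## The models

Many bacterial sensor histidine kinases (HK) are bifunctional: the same
enzyme autophosphorylates, passes the phosphoryl group to its response
regulator (RR), and dephosphorylates the phosphorylated regulator (RR-P).
In the PhoQ/PhoP and NRII/NRI systems an allosteric effector regulates the
two opposing activities *reciprocally* — binding inhibits autophosphorylation
and activates the phosphatase. The package implements three mass-action
variants of this motif, all in micromolar and minutes (the natural units of
the in vitro experiments these models describe):

* **Covalent modification cycle** (`cycle_params()`): a single bifunctional
  converter enzyme `E` phosphorylates a substrate through
  `E + S <-> ES -> E + Sp`; the effector-bound form carries the opposing
  activity, `EL + Sp <-> ELSp -> EL + S`, with `E + L <-> EL`. This is the
  minimal system in which reciprocal regulation can generate zero-order
  ultrasensitivity.
* **Two-component system** (`tcs_params()`): `H <-> Hp` (autophosphorylation
  with forward rate `k_ap` and reverse rate `k_ad`; ATP and ADP are constant
  cofactors lumped into the rate constants), phosphotransfer
  `Hp + R <-> HpR -> H + Rp`, effector binding `H + L <-> HL`, phosphatase
  `HL + Rp <-> HLRp -> HL + R`, and optional regulator autodephosphorylation
  `Rp -> R` at rate `k_auto` (the intrinsic phosphatase activity of
  regulators such as NRI; `k_auto = ln 2 / 5` per minute corresponds to the
  5-minute half-life measured for NRI-P).
* **Basal-activity extension** (`basal_tcs_params()`): the effector-bound
  kinase may retain autokinase/transfer activity (`HL <-> HpL`,
  `HpL + R <-> HpLR -> HL + Rp`) and the free kinase may retain phosphatase
  activity (`H + Rp <-> HRp -> H + R`), each scaled by factors in `[0, 1]`
  for catalysis and binding. Effector binding to the phosphorylated kinase
  (`Hp + L <-> HpL`) closes a binding–phosphorylation square; to prevent a
  futile cycle at steady state the products of rate constants around the
  square must balance. `balance_effector_loop()` derives the HpL
  dissociation rate that nulls the loop, and `loop_flux_check()` warns when
  a user-supplied rate violates it. Because the published constraint for
  this square is not recoverable in closed form from the available text,
  enforcing the zero-cycle-flux condition directly is this package's own
  design choice.

A note on the reverse autophosphorylation rate `k_ad` (default 0): with a
strictly irreversible autokinase the exact steady state of the full model
pins `Rp * L` to a constant whenever free HK is present, producing an
absolutely robust but *kinked* response in the total regulator. The smooth
quadratic below, and a transfer-side lumped constant, exist only when the
phosphorylated kinase can relax back (`k_ad > 0`). All presets therefore use
a nonzero `k_ad`.

States carry every species explicitly; the three conservation laws (total
regulator/substrate, total enzyme, total effector) are *test invariants*,
not eliminations, at the model-core level.

## Steady-state reductions

**Regulator excess.** With `H_T/R_T -> 0` (the measured situation in
EnvZ/OmpR, PhoQ/PhoP and NRII/NRI) the complexes are negligible in the
regulator balance, and eliminating `Hp`, `HpR`, `HL`, `HLRp` at steady state
gives the quadratic

$$Rp^2 - Rp\,(R_T + K_1 + K_2) + K_1 R_T = 0, \qquad
K_1 = \frac{k_{ap} K_d K_m^p}{k_{cat}^p\,L}, \quad
K_2 = \frac{k_{ad} K_m^t}{k_{cat}^t},$$

whose physical root is the smaller one (`solve_bg_quadratic()`, computed
with the cancellation-free formula; the root is the *free* RR-P, consistent
with the limit in which the quadratic holds). Two limits
(`approx_bg_limits()`): for `K1 >> K2` the response rises linearly with
`R_T` and plateaus at `K1`, which sets both the robustness threshold and the
plateau (PhoR/PhoB-like); for `K1 << K2` it is hyperbolic,
`Rp ~ K1 R_T/(K2 + R_T)`, with a threshold `~K2` far above the plateau
(NRII/NRI-like). Because only `K1` carries the effector dependence — and
inversely, `K1` proportional to `1/L` (`effective_k1()`) — lowering the
stimulus raises both the robust plateau and (in the first regime) its
threshold: *stimulus-dependent* concentration robustness
(`stimulus_dependent_robustness()`).

**Low-affinity effector** (`lambda = K_d/H_T >= 100` by default): free
effector equals total effector and the quadratic applies directly
(`solve_tcs_low_affinity()`); the cycle analogue is exactly hyperbolic in
the effector (`solve_cycle_low_affinity()`), so the response is graded
(effective Hill coefficient 1).

**High-affinity effector** (`lambda <= 0.01` by default, i.e. a
stoichiometric binding parameter `H_T/K_d >= 100`): virtually every effector
molecule is enzyme-bound, partitioning the enzyme into a phosphatase pool of
size `L_T` and a kinase pool `H_T - L_T` (`enzyme_partition()`). The system
then behaves like a Goldbeter–Koshland cycle with two independent converter
pools. Eliminating the autophosphorylation step compresses the kinase branch
into a single Michaelis–Menten activity with apparent parameters

$$k_{cat}^{app} = \frac{k_{ap}\,k_{cat}^t}{k_{ap} + k_{cat}^t}, \qquad
K_m^{app} = K_m^t\,\frac{k_{ap} + k_{ad}}{k_{ap} + k_{cat}^t},$$

(`apparent_transfer_params()`). The regulatory factor
`(k_ap + k_ad)/(k_ap + pt_cat)` matters: when autophosphorylation is slow
relative to transfer, `Km_app` is much smaller than the intrinsic `Km_t`, so
the intrinsic transfer step may be first-order (`Km_t > R_T`) while the
apparent activity still operates in the zero-order regime — ultrasensitivity
then only *requires* saturation of the phosphatase (`Km_p << R_T`). The
price is a transition point

$$L^* = H_T\,\frac{k_{cat}^{app}}{k_{cat}^{app} + k_{cat}^p}$$

(`transition_point()`) shifted to lower effector concentrations, since
`kcat_app ~ k_ap` in that limit. `L*` is always below the total enzyme: the
ultrasensitive mode works only while the enzyme can still absorb the
effector, i.e. for low-abundance input signals.

Near the transition the zero-order balance amplifies the (small) free
effector concentration, which the steady-state flux balance pins to a closed
form in the modified fraction. `solve_cycle_high_affinity()` and
`solve_tcs_high_affinity()` therefore iterate the Goldbeter–Koshland root
with effector-corrected pools to self-consistency (a damped fixed point,
relative tolerance 1e-12); without this lowest-order correction the
reduction would err by more than 10% of the total close to `L*`.
`approx_switch_solution()` keeps the cruder sharp-switch expansion (on/off
branches to leading order in the normalized Michaelis constants), valid
outside a window of about 10% around `L*`.

Outside its declared regime every reduction warns (or errors with
`strict = TRUE`) rather than silently extrapolating; the thresholds
(`lambda >= 100`, `lambda <= 0.01`, 10x ordering margins for the quadratic
limits) are defaults with arguments to override.

## Numerical choices

* **Steady states** (`integrate_to_steady_state()`) use the stiff BDF
  integrator of deSolve (`rtol = 1e-10`, `atol = 1e-12`). Effector binding
  at `K_d` of 1e-4 uM makes these systems stiff by construction, and the
  automatic stiff/non-stiff switching of `lsoda` thrashes near zero-order
  transitions, so plain BDF is the default. Integration proceeds over
  chunks with the total horizon doubling from chunk to chunk — transition
  regions can take four orders of magnitude longer to converge than the
  binding timescale — and convergence is declared when the right-hand-side
  infinity norm falls below `1e-10 * max(1, max(state))` *and* the state
  moves by less than 1e-8 (relative) over a horizon doubling. Default
  initial conditions put all protein in the free, unmodified pools and all
  effector free.
* **Quadratic and Goldbeter–Koshland roots** use the stable `q`-formula and
  select the unique root in the physical interval, asserting uniqueness;
  degenerate cases (equal maximal rates; one activity absent) reduce to the
  exact linear solutions.
* **Hill coefficients** are operationalized as `n_H = ln(81)/|ln(x90/x10)|`
  with the 10%/90% points of the observed dynamic range interpolated on the
  logarithmic sweep axis; decreasing curves use the reciprocal ratio.
  Non-monotone curves are an error, never silently truncated. On exact Hill
  curves sampled over twelve decades the estimator recovers exponents
  0.5–8 within 2%; sweeps should bracket both crossing levels comfortably,
  since truncated ranges bias `n_H` upward for shallow curves.
* **Robustness reports** define the plateau as the mean over the top decade
  of the sweep and the threshold as the first crossing of 95% of it; the
  flatness check (maximum log-log slope over the top decade, tolerance
  0.05) requires sweeps extending well past the expected threshold.

## Synthetic data and study conditions

No deposited datasets exist for the titrations this theory was fitted to,
so `generate_titration()` emulates their *shapes*: RR-P vs total-RR
robustness titrations (plateau and hyperbolic regimes) and RR-P vs effector
titrations (graded, ultrasensitive, and autodephosphorylation-damped).
Noise is multiplicative Gaussian with a fixed coefficient of variation
(default 5%), truncated at zero — gel and Phos-tag quantifications have
roughly proportional error; the model is a deliberate simplification (no
baseline offset, no heteroscedastic floor) and is swappable. Every dataset
derives from one explicit seed and carries its ground-truth parameters, so
recovery studies are reproducible end to end. Passing tests on these data
demonstrate correctness of the estimation machinery under the assumed error
structure, not robustness to the systematic errors of real gels
(saturation, background subtraction, loading effects).

The preset catalog fixes the study conditions once:

* `plateau_robust` (`K1 = 1, K2 = 0.005` uM) and `hyperbolic_robust`
  (`K1 = 0.2, K2 = 5` uM) — the two robustness regimes, with `K1/K2` ratios
  deep enough (200x and 25x) that the limiting behaviors are clean.
* `graded_low_affinity` — `lambda = 1e3` with a non-saturated transfer side
  (`K2 = 100 R_T`), which makes the effector response exactly hyperbolic;
  with a saturated transfer side the low-affinity response would steepen
  toward `n_H ~ 2` (a kinked `min(R_T, K1(L))` profile) even though it can
  never be a zero-order switch.
* `ultrasensitive_high_affinity` — `lambda = 1e-3` with both apparent
  Michaelis constants at 1% of `R_T` and `H_T/R_T = 0.01`.
* `nri_like_autodephos` — a high-affinity, saturated set with
  `k_auto = ln 2/5` per minute and a maximal phosphorylation level well
  below the total regulator, emulating the weakly sensitive NRII/NRI
  response; lowering `k_auto` over three decades restores the switch.

Two study designs need justification beyond the presets. For the
basal-activity analysis the basal H·Rp association is scaled to 0.02 of the
regulated one (basal complex dissociation constant comparable to the
regulator pool): with the *full* association rate the basal complex binds so
tightly that free HK is sequestered by RR-P and the switch is destroyed at
any catalytic factor — the model's own statement that ultrasensitivity
requires the phosphatase activity to bind preferentially through the
effector-bound form. With the moderated binding, sweeping the basal
catalytic factor over 0, 0.01, 0.1, 1 erodes the Hill coefficient
progressively, while turning the basal autokinase and transfer on at full
strength changes it only mildly provided autophosphorylation is slow
relative to transfer (the Fig-7-style base here uses `k_ap = k_ad = 10`,
`pt_cat = 500` per minute; the erosion from basal kinase activity scales
with `k_ap/pt_cat`).

Problem sizes throughout the test and acceptance suites — about 100
regime-interior points per reduction for the oracle-equivalence grids,
20-40 point sweeps for Hill estimates, 20 replicates of 12-point designs at
5% noise for the recovery study — are chosen as the smallest designs that
exercise each property cleanly.

## Two-compartment systems

For transmembrane kinases the effector binds in the periplasm or the
extracellular space while catalysis is cytosolic. Since effector binding
moves no mass between compartments, the mass balances keep the
single-compartment structure when written in molecule numbers; expressed in
cytosolic concentration units only the effector association rate acquires
the volume ratio `alpha = V_cyt/V_ext` (`two_compartment_rescale()`,
`compartment_context()`). The high-affinity condition becomes
`K_d < alpha * H_T`: a periplasmic effector (`alpha` between 1.5 and 4 for
periplasmic volume fractions of 40% down to 20%,
`volume_ratio_from_periplasmic_fraction()`) *favors* ultrasensitivity,
a dilute extracellular effector (`alpha << 1`) suppresses it.

## Fitting workflows

`fit_bg()` estimates `(K1, K2)` from a total-regulator titration with the
quadratic root as prediction; `fit_tcs_autodephos()` fits chosen parameters
of the full model (each prediction a stiff-ODE steady state) to an effector
titration, the workflow used for NRI-P data with `k_auto` fixed at its
measured value. Both optimize in log-parameter space (positivity by
construction) with multi-start (default 5 seeded starts), weight by inverse
variance when standard deviations are supplied, and keep the log of
accepted objective values. Identifiability is reported, not hidden:
near-flat directions show up as relative standard errors above 100% from
the local quadratic approximation of the objective. Derived constants
(`Km_t`, `Km_p`, `K_d`) may be fitted directly; they are realized through
the corresponding association rate after all direct rates are set.

## Known limitations

* The reductions are asymptotic, not uniform: accuracy degrades within a
  few percent of the transition point and outside the declared affinity
  regimes; the ODE solver is the arbiter everywhere.
* Monostability is assumed (these models have a unique interior steady
  state); there is no bifurcation or continuation analysis.
* No stochastic simulation, no spatial effects (the external compartment is
  taken as well mixed), no transcriptional autoregulation layer above the
  signaling module, and at most two compartments.
* The noise model is a single multiplicative Gaussian term; fits to real
  quantifications may need measurement-specific error models.
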