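---
title: "Coupled electromechanics of a cardiomyocyte-fibroblast ensemble: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled electromechanics of a cardiomyocyte-fibroblast ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardiofib` simulates one human ventricular cardiomyocyte electrically and
mechanically coupled to `n` cardiac fibroblasts, and asks when that coupling
turns a calcium-overloaded but regularly beating myocyte into one that
produces early afterdepolarizations (EADs) or full extra beats
(extrasystoles). This vignette is the package's own account of the model, of
the calibration choices behind the packaged parameter sets, and of what the
simulations do and do not show.

## The model

### Myocyte electrophysiology

The sarcolemmal currents follow the ten Tusscher–Panfilov 2006 (TP06)
epicardial formulation, in the standard units (mV, ms, mM, pA/pF), with the
L-type Ca²⁺ conductance anchored at 5·10⁻⁵ (F·s)⁻¹ and a dimensionless
multiplier used by the overload protocols. The membrane equation is

$$\frac{dV_{myo}}{dt} = -\frac{1}{C_{myo}}\Big(i_{myo}(V_{myo},t)
 + \sum_{i=1}^{n} g_{gap}\,(V_{myo}-V_{cf_i})\Big),$$

with $C_{myo}$ = 185 pF and one ohmic gap-junction term per fibroblast
($g_{gap}$ in nS, 0.5–4.0 in the study protocols).

Two departures from plain TP06:

* **RyR gating.** SR release uses a four-state (R/O/I/RI) ryanodine-receptor
  scheme: Ca²⁺-dependent opening (∝ Ca²⁺$_{ss}$²), Ca²⁺-dependent
  inactivation, and slow recovery from the inactivated states (τ = 200 ms),
  which gives post-release refractoriness. Opening is additionally gated by
  SR content through a steep luminal factor (half point 3.22 mM, Hill
  exponent 30): near the normal diastolic SR load (≈3.15 mM) the effective
  opening rate matches the TP06 scale, while an overloaded store releases
  spontaneously once the cytosolic trigger is sufficient. The steepness is a
  calibration choice — it is what lets a cell that paces normally at its
  steady state ignite store-overload-induced release under an i_CaL
  increase, without a hair trigger at norm.
* **Buffering split.** The TP06 generalized cytosolic buffer (0.2 mM) is
  split into an explicit 70 µM troponin-C pool with its own kinetics (below)
  and a residual instantaneous buffer of 0.13 mM, preserving total capacity.

### Mechanics

The preparation is a Hill-type rheological network: a contractile element
(CE, the sarcomeres) in series with an elastic element SE, that chain in
parallel with the passive elasticity PE, `n` fibroblast elastic elements
PEfb and a viscous element VS1, and the whole branch in series with the end
compliance XSE. The force balance of the preparation is

$$F_{myo} = F_{XSE} = F_{PE} + n\,F_{PEfb} + F_{CE} + F_{VS1},
\qquad F_{PEfb} = \beta_{2fb}\,(e^{\alpha_{2fb} l_2} - 1),$$

where $l_2$ is the strain of the parallel branch and the $(\alpha, \beta)$
pair of PEfb is shared with PE. A second viscous element, VS2, acts across
the sarcomere coordinate inside the contractile branch (cross-bridge lattice
damping); placing it there rather than on the outer node keeps the printed
force balance exact and regularizes the otherwise index-2 constraint. Per
time step the inner node is solved for the CE velocity by bracketed Illinois
root-finding (|imbalance| < 10⁻¹³ in normalized force units), after which
the outer balance gives the branch rate in closed form — the recorded
balance residual is below 10⁻⁸ at every accepted step by construction.

Activation couples Ca²⁺ to force through two cooperative laws:

* **Ca–TnC kinetics.**
  $d[\mathrm{CaTnC}]/dt = a_{on}[\mathrm{Ca}]_i(A_{tot}-[\mathrm{CaTnC}])
  - k_{off}\,[\mathrm{CaTnC}]$ with
  $k_{off} = k_{off,0}\,e^{-k_A [\mathrm{CaTnC}]}\,\pi(N_{xb})$ and
  $\pi(N) = \pi_{min} + (1-\pi_{min})e^{-qN}$ strictly decreasing in the
  attached cross-bridge fraction. As a beat relaxes and cross-bridges
  detach, the off-rate rises, so the complex keeps releasing Ca²⁺ at a
  nearly constant flux late into relaxation — the "Xb-induced spontaneous
  Ca²⁺ release" pathway that primes the RyR reopening.
* **Cross-bridge kinetics.** Attachment grows with CaTnC (Hill form) and
  with sarcomere length through an ascending-limb overlap ramp
  (length-dependent activation, the myocyte's mechano-electric feedback);
  detachment grows with shortening/lengthening speed. The force–velocity
  factor is a Hill hyperbola (curvature 0.25) with a capped lengthening
  branch, which keeps the balance root unique.

Whole-preparation isometry still allows internal sarcomere shortening
through SE/XSE: at 90 % L_max the sarcomeres cycle between ≈89 % and ≈85 %
and never fall below 80 % (L_max corresponds to a sarcomere length of
2.23 µm). Peak twitch force of the uncoupled myocyte at 90 % L_max, 1 Hz
steady state, is 1.0 by the packaged normalization constant.

### Fibroblasts

Each fibroblast is a MacCannell active membrane (6.3 pF; delayed-rectifier
i_Kv, inward-rectifier i_K1, Na⁺/K⁺ pump, Na⁺ background; fixed internal
ion concentrations; uncoupled rest ≈ −49 mV) plus, in *model 2*, the
non-selective mechanosensitive current

$$i_{MS}(\Delta l, V_{cf}) = g_{max}\, a(\Delta l)\,(V_{cf} - V_{rev}(L)),$$

a linear I–V whose slope factor $a(\Delta l) = 1 + s\,\Delta l$ is 1 at zero
deformation ($\Delta l$ is measured relative to the run's initial length)
and whose reversal potential is affine in the instantaneous fibroblast
length over the 80–90 % L_max working range with endpoint values −38 mV and
−30 mV. The current carries positive charge only: it changes the fibroblast
potential, never its ion pools. Below −38 mV it is always depolarizing and
above −30 mV always repolarizing, for every working length.

Three constants of i_MS are not constrained by published values and are
package calibrations:

* `g_max` = 1.0 nS. Larger values depolarize the coupled resting potentials
  more strongly; 1.0 nS reproduces the qualitative resting-potential
  separation between the electrotonic-only and electromechanical modes
  while keeping the normally paced ensemble free of triggered activity.
* `a_slope` = 5 per unit strain, so compression to the short end of the
  working range halves the conductance rather than extinguishing it (both
  I–V lines in the diagnostic diagram keep meaningful slopes).
* **Orientation of V_rev**: −38 mV is assigned to the 90 % endpoint and
  −30 mV to the 80 % endpoint. The experimental direction is not fixed by
  the published summary values, and this orientation is the one for which a
  shorter initial length further depolarizes both resting potentials — the
  behavior the coupled measurements require. The orientation is exposed as
  a configuration switch (`vrev_neg_at_long`), and the sign-band invariant
  holds either way.

### Modes

* `single` — the isolated myocyte (n = 0).
* `model1` — electrotonic coupling only: gap currents, no i_MS, no
  fibroblast elastic elements.
* `model2` — electrotonic plus mechanical coupling: gap currents, i_MS, and
  `n` PEfb elements in the force balance.

With `g_max = 0` and `beta_fb = 0`, `model2` trajectories coincide with
`model1`; with `g_gap = 0`, `model1` decouples into the single myocyte plus
isolated fibroblasts. These reductions are tested to 10⁻⁶ mV.

## Numerics

The system is integrated with a fixed-step hybrid: Rush–Larsen exponential
updates for all Hodgkin–Huxley gates (myocyte and fibroblast), a per-state
exponential update with renormalization for the RyR occupancies (the
occupancy sum is conserved exactly), and forward Euler for potentials,
concentrations and mechanical coordinates, at dt = 20 µs — the de-facto
standard discretization for this model family, and the regime in which the
original formulation was published. We chose this over an adaptive stiff
solver because the per-step mechanics root-solve and the event-driven
protocols make step-size control awkward, while at 20 µs the solution is
already well inside the convergence regime: halving dt changes the membrane
potential by < 0.2 mV away from the AP upstroke (the upstroke itself shifts
by a fraction of a step, which dominates any sup-norm comparison) and APD90
by < 1 ms. Traces are sampled at 1 ms by default.

Initial conditions are packaged 1-Hz steady-state snapshots of the single
myocyte (20 min of pacing) at 80, 85 and 90 % L_max; coupled runs start
from the snapshot plus the uncoupled fibroblast rest state, with an optional
`pre_pace_s` settling phase at baseline multipliers. Onset times of
triggered activity proved insensitive to pre-pacing length (0–100 s probed),
so the default is 0.

Everything is deterministic: identical configurations produce bit-identical
traces on a fixed platform, and no part of the package consumes random
numbers.

## Event definitions

An AP onset is an upward crossing of −40 mV with dV/dt > 10 mV/ms. An EAD is
an upward deflection of ≥ 5 mV that starts after the AP peak, before the
potential first falls below −70 mV, from a take-off potential below −10 mV
(the take-off ceiling excludes the physiological spike-notch-dome of the
epicardial AP), and whose peak does not qualify as an AP onset. An
extrasystole is an AP onset more than 10 ms away from any stimulus,
confirmed by an extra force peak when a force channel is present.
Contractile failure is a settled peak active force below 5 % of the
uncoupled norm. The 5 mV, −40 mV, 10 mV/ms, ±10 ms and −10 mV constants are
package choices (robust on the synthetic classifier fixtures) and are
exposed in the threshold configuration.

## Calibration of the overload corridor

The constants of the RyR scheme, the cooperative Ca–TnC law and i_MS are not
fixed by published summary values; they were calibrated, once, against the
qualitative behaviors the study protocols demand:

1. the isolated myocyte paces period-1 at 1 Hz with a normal Ca²⁺ transient
   (peak ≈ 0.9 µM, diastolic SR load ≈ 3.15 mM);
2. a second Ca²⁺ pulse 300 ms after a release finds the RyR refractory;
3. doubling the L-type conductance produces beat-to-beat alternation of the
   SR-load signal and, via gradual Na⁺ and Ca²⁺ accumulation, spontaneous
   diastolic SR release;
4. triggered activity is absent at baseline in every mode, absent in the
   single myocyte at 1.4× i_CaL, and escalates with fibroblast number and
   junctional conductance in `model2`;
5. freezing the Ca–TnC off-rate just before a spontaneous release removes
   the extra beat and steepens the post-freeze dissociation-flux decay.

Under this calibration the coupled overload runs reproduce the mechanism
end to end: the overloaded SR crosses its release gate during late
relaxation, exactly when the cooperative Ca–TnC dump keeps cytosolic Ca²⁺
elevated and the RyR has just recovered; the Na⁺/Ca²⁺ exchanger converts
the spontaneous release into a depolarizing bump; and the fibroblast-raised
resting potential decides whether that bump stays subthreshold or becomes a
full ectopic beat.

Because the overload corridor rests on calibrated rather than measured
constants, several of its absolute numbers are calibration-dependent and
should be read as properties of *this* parameter set:

* In the two-fibroblast, 3 nS, 2× i_CaL protocol the first extrasystole
  appears at ≈ 103 s. The onset is set by the Na⁺ accumulation timescale of
  the base electrophysiology; every calibration lever we probed either
  leaves the onset on a ≈ 100–110 s plateau or collapses it into the
  initial loading transient, so intermediate onset times are not reachable
  by tuning the release constants alone.
* The four-fibroblast, 3 nS triggered-activity threshold is 1.7× i_CaL on
  the 0.1 grid.
* With SERCA halved, no i_CaL multiplier up to 3.5× produces triggered
  activity. In this architecture the halved-SERCA store ceiling (≈ 2.9 mM
  at 3.4×) lies *below* the normal steady-state load, so no
  store-overload criterion can fire for the SERCA-halved cell without also
  firing at norm, and the cytosolic route would require diastolic Ca²⁺
  levels the exchanger prevents. A release criterion sensitive to the
  ratio of load to uptake capacity, rather than to absolute load, would be
  needed to make uptake depression arrhythmogenic at higher multipliers.
* In the isolated myocyte at 2× i_CaL the spontaneous releases arise after
  full repolarization (diastolic, DAD-like, subthreshold), so the strict
  EAD definition classifies that run as event-free; escalation to
  classified events (EADs/extrasystoles) requires the fibroblast-raised
  resting potential of the coupled modes.
* At 3 nS the electromechanical mode develops slightly *more* force than
  the electrotonic-only mode (0.58 vs 0.50 normalized): the elevated
  fibroblast plateau potential reduces the gap-junction drain during the
  AP, and in this calibration that outweighs the resting-potential-mediated
  Ca²⁺ unloading. Within each mode, force still falls monotonically with
  fibroblast number and junctional conductance, and at 0.5 nS the two
  modes are practically indistinguishable.
* The documented cooperativity-clamp switch point is 350 ms after the
  beat's stimulus (robust over ±20 ms and more); clamping later than
  ≈ 400 ms only delays the spontaneous release within the beat.

## Problem sizes

The packaged protocols use: 200-s paced runs for overload and vulnerability
experiments (the published protocol length); 12-beat runs for
resting-potential grids (resting potentials settle within a few beats);
5-beat runs for twitch morphology; threshold scans on a 0.1-multiplier grid
accelerated by monotone bisection (≤ 6 full runs per scan). A 200-s run
takes roughly 15–20 s on one CPU core at the default step.

## Limitations

Beyond the explicit scope cuts (no tissue-level propagation, no paracrine
signalling, no Ca²⁺-dependence of gap junctions or of i_K1/i_Ks, no
isotonic/afterloaded protocols, fixed fibroblast ion pools), the main
caveat is that all overload phenomenology depends on calibrated constants,
not measured ones: the package demonstrates and dissects the mechanism —
store overload plus cooperative Ca–TnC release plus fibroblast-raised
resting potential — but absolute onset times and thresholds carry the
uncertainty documented above.
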