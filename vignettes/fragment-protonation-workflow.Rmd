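---
title: "Deciding whether a fragment binds in its protonated form: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether a fragment binds in its protonated form: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonbind)
```

## The scientific question

A crystallographic fragment screen can place a small carboxylic acid — here,
a benzoic-acid-like fragment — in a kinase ATP site with an interaction
pattern that only makes sense if the acid is *protonated* (neutral). In
water at physiological pH a group with pKa ≈ 4.1–4.2 is >99% deprotonated,
so the observation demands an explanation. `protonbind` implements the
quantitative chain used to interrogate such a case:

1. **Can ITC see the binding at all?** Binding-equilibrium and
   experiment-design math (saturation, Wiseman c value, displacement
   design), plus simulation and fitting of integrated-heat thermograms.
2. **How much of the neutral form is present?** Henderson–Hasselbalch
   arithmetic under the measured buffer pH values, pKa fitting from
   titration curves, and the linkage free energy of a binding-induced pKa
   shift.
3. **Does the neutral form behave differently in MD?** Hydrogen-bond
   occupancy and persistence statistics of donor–acceptor distance series
   under a distance criterion.

## Binding equilibria and ITC design

### Single-site mass balance

For one protein site, `solve_single_site(P, L, Kd)` takes the smaller root
of \(x^2 - (P + L + K_d)x + PL = 0\), computed via the stable branch
(product of roots over the larger root) to avoid cancellation when
\(PL \ll (P+L+K_d)^2\). Fractional saturation is \(x/P\).

```{r}
solve_single_site(20e-6, 4.2e-3, 1e-3)$saturation   # ~0.81
solve_single_site(20e-6, 4.2e-3, 10e-3)$saturation  # ~0.30
```

These are the two design scenarios for a 20 µM cell loaded with 4.2 mM
fragment: adequate saturation if the fragment's Kd is 1 mM, inadequate if
it is 10 mM. The inverse design formula
\[
[\mathrm{frag}]_{cell} = \frac{D_{sat} K_d}{1 - D_{sat}} + D_{sat}[P]
\]
(`required_fragment_conc`) gives 4.016 mM for an 80% target at Kd = 1 mM
and round-trips through the solver to the requested saturation at relative
tolerance 1e−9. The target saturation must be strictly below 1 — full
saturation needs unbounded ligand — and the formula's second term shows why
the protein concentration matters only weakly for weak binders.

### The c value

`c_value(P, Kd, n)` returns \(c = n[P]/K_d\) with a flag for the empirical
1–1000 window within which an ITC isotherm determines Kd reliably. The
classic definition is the `n = 1` case; stoichiometry is included because
the site concentration, not the protein concentration, sets the isotherm
shape. A direct titration of a 1 mM binder at 140 µM protein sits at
c = 0.14 — below the window, which is the quantitative reason a direct
fragment titration fails here.

### Competitive equilibrium

`solve_competitive` handles two mutually exclusive ligands. Given free
protein \(P_f\), each complex is \(X_{tot}P_f/(K_X + P_f)\), making the
protein balance a strictly increasing function of \(P_f\); we bisect it to
machine resolution (~200 halvings, exact interval collapse) rather than
using the closed-form cubic, trading a few microseconds for immunity to
root-selection mistakes. Mass conservation is enforced to relative 1e−9
and checked in the returned object. `kd_b = Inf` is admitted as the
inert-competitor limit, and the solver then reproduces the single-site
answer for ligand A.

### Displacement inversion

A displacement titration measures the strong ligand's *apparent*
dissociation constant in the presence of the fragment. The inversion
\[
K_a^{frag} = \left(\frac{K_{ref}}{K_{obs}} - 1\right)\frac{1}{[\mathrm{frag}]_{cell}}
\]
is implemented in association-constant space (`kd_from_displacement`
converts at the boundary, because only that reading of the relation yields
positive affinities), returning `Inf` — "no detectable affinity" — when the
apparent and reference constants coincide, and rejecting
\(K_{obs} > K_{ref}\), which competition cannot produce.

**Which fragment concentration to use.** Injections dilute the preloaded
fragment (here by ~17% over a full 36.4 µL protocol into a 200 µL cell), so
inverting with the preload concentration biases the recovered fragment Kd
upward by roughly the mean dilution (~10% here, with a further bias because
the apparent Kd is informed mostly by pre-equivalence injections).
`mean_fragment_conc` therefore returns the dilution-corrected in-cell
concentration averaged over the fitted injections, optionally weighted by
each injection's absolute normalized heat. The weighting concentrates the
average where the isotherm actually constrains the apparent Kd; in
simulation it reduces the recovery error from ~4–5% to under 2% across
fragment Kd values from 0.3 to 10 mM.

## Thermogram simulation and fitting

### The forward model

`injection_schedule` captures the protocol: cell volume (default 200 µL — a
typical active volume for automated microcalorimeters of this class; the
instrument's value is not public, and normalized heats are insensitive to
it), injection volumes (default one 0.4 µL pre-injection plus 18 × 2 µL),
syringe and cell concentrations, temperature (default 298.15 K).

Dilution follows the standard overfill model: injecting \(dV\) scales every
pre-existing cell concentration by \(1 - dV/V_0\) and the injected material
mixes instantly. The heat of injection \(i\) is
\[
q_i = \Delta H \, V_0 \,(c_i - c_{i-1} f_i),
\]
with \(c_i\) the equilibrium complex concentration after injection \(i\)
and \(f_i\) the dilution factor — heat is credited for newly formed
complex, not for complex expelled from the active volume. This bookkeeping
is exact and deterministic, so bit-exact regression tests are possible.
Stoichiometry enters as a site concentration \(n[P]\). Displacement
simulation uses the competitive solver at each composition and credits both
complexes' enthalpy changes; an inert preload (ΔH = 0, Kd = ∞) reproduces
the direct simulation pointwise.

Two consequences worth knowing:

- In the low-c regime the per-injection normalized heat is capped by the
  bound fraction of the injectant, \([P]/([P]+K_d)\) — about 12% of |ΔH|
  at 140 µM protein and Kd = 1 mM — and the curve is a featureless
  monotone decay. With a fragment-sized |ΔH| of a few kJ/mol the signal
  sits at the instrument noise floor, which is the model's version of "no
  binding detected".
- Displacing a weak ligand whose ΔH has the *same* sign as the strong
  ligand's attenuates the net heats (the weak complex breaks
  endothermically); opposite signs amplify them. A displacement experiment
  distinguishes thermodynamic profiles only insofar as the enthalpies
  differ.

### Fitting

`fit_one_site` fits (N, Kd, ΔH) to normalized heats by Levenberg–Marquardt
(`minpack.lm::nls.lm`), with Kd and N on the log scale to enforce
positivity. Five deterministic starts span four orders of magnitude of Kd
around the cell protein concentration; the best converged fit wins, so no
randomness enters the optimizer. The first (0.4 µL) injection is excluded
by default, as universal ITC practice discards the pre-injection; a
constant heat-of-dilution offset can optionally be co-fitted
(`fit_offset = TRUE`) since blank-subtraction details vary between
protocols. Standard errors come from the residual-scaled curvature, mapped
to the natural scale by the delta method. A converged fit whose c value
falls outside 1–1000 carries a reliability warning; noiseless round trips
recover parameters to relative 1e−6, and an all-zero thermogram never
yields a silently confident fit.

```{r}
sch <- injection_schedule(syringe_conc = 300e-6, cell_protein_conc = 20e-6)
truth <- binding_parameters(kd = kd_from_dg(-37.3), dh = -50, n = 0.9)
fit_one_site(simulate_direct(truth, sch))
```

## Protonation arithmetic

`protonated_fraction` is the Henderson–Hasselbalch form
\(1/(1 + 10^{pH - pK_a})\). The buffer-composition-driven pH drop (6.9 →
5.3 when the soaking solution's organic solvents are added) is treated
strictly as *measured input* — no cosolvent pH model is attempted, because
mixed-solvent pH shifts are not reliably predictable. At pH 5.3 and
pKa 4.1 the neutral fraction is 5.9%; at the ITC buffer's pH 6.9 it is
0.2%. That two-order-of-magnitude contrast between crystallization and
calorimetry conditions is the crux of the analysis.

`fit_pka` fits the one-proton sigmoid (Hill coefficient fixed at 1 — the
analyte has a single carboxylic acid, and freeing the slope only inflates
the variance on small titrations). Replicate curves are fitted separately
and averaged, mirroring how instrument triplicates are reported; a curve
whose fractions never enter (0.1, 0.9) triggers a `fit-unreliable` warning
rather than an error, since the point estimate may still be wanted.

`ddg_from_dpka` converts a binding-induced pKa shift into the linkage free
energy \(RT\ln(10)\,\Delta pK_a\) — 6.85 kJ/mol for a +1.2 shift at 25 °C —
the free-energy preference for binding the protonated form implied by
thermodynamic linkage. Whether to fold in the pH-dependent availability of
the neutral species is left to the caller (combine with
`protonated_fraction` as needed): the linkage term is a property of the
complex, the availability term a property of the solution, and conflating
them hides the buffer dependence that the analysis turns on.

## Hydrogen-bond persistence

`distance_series` computes per-frame Euclidean donor–acceptor distances
from a trajectory; multi-atom selections (e.g. both carboxylate oxygens)
use the per-frame *minimum* distance, matching how a rotatable group's
contact is perceived in distance plots. `summarize_hbond` applies a
distance-only criterion, default 3.5 Å with ties counted as bonded — no
donor–H–acceptor angle term, because the analysis this mirrors used none;
the default applies the cutoff to whatever pair you select, so choosing
H···acceptor atoms gives the hydrogen-distance reading and choosing heavy
atoms the heavy-atom reading. Occupancy is the bonded-frame fraction
*before* gap bridging; segments are maximal bonded runs after bridging
unbonded gaps of at most `gap_tolerance` frames (default 0; contacts
"broken only for very short periods" motivate exposing it). A break is a
segment ending before the last frame, a reform a segment starting after
the first, so a single unbroken contact has zero events. The segment
length in ns is frames × interval (a 1-frame segment has nonzero
duration). These definitions agree with a brute-force run-length oracle on
random series in the test suite.

Trajectories are read from multi-model PDB via `bio3d`; the frame interval
is metadata the format does not carry and must be supplied, never guessed.

## The synthetic-data generators

Every generator is a pure function of (parameters, seed) via
`withr::with_seed`, leaving the caller's RNG untouched, and returns ground
truth alongside the fixture so tests never re-derive truth from the data.

- `gen_thermogram`: ideal simulation plus i.i.d. Gaussian heat noise, in
  µJ. The default noise scale used in tests, 0.5 µJ, is a realistic
  integrated-heat noise floor for modern microcalorimeters.
- `gen_ph_titration`: sigmoid points plus truncated Gaussian noise clipped
  to [0, 1]; σ = 0.02 in the recovery studies, a typical spread for
  UV-metric triplicates. Warns when the grid misses pKa ± 1.
- `gen_distance_series`: a first-order Markov (telegraph) chain over
  bound/unbound states, Gaussian jitter (0.2 Å) around state means of
  2.9 Å and 6.0 Å. The initial state is drawn from the stationary
  distribution, so occupancy is unbiased at any length. The two built-in
  scenarios (`hbond_scenario`) caricature the protonated ligand
  (persistent Glu121/Val123 hinge contacts ~0.95 occupancy, no
  Lys72/Thr183 contact) and the deprotonated ligand (stable Lys72 ~0.9,
  intermittent Thr183 ~0.5 with break/reform events, no hinge contacts);
  they live in one YAML file so tests and documentation cannot drift
  apart. Analyses use 4000 frames × 0.25 ns = 1 µs, matching the
  production-simulation scale the scenarios emulate.
- `gen_trajectory_file` realises distance series as a minimal multi-model
  PDB (one collinear placeholder atom pair per series); re-reading
  reproduces distances to the 3-decimal PDB precision (<1e−3 Å).

**What the synthetic data do not emulate:** force-field physics, water,
correlated multi-contact kinetics, drift, or real kinase geometry. Passing
the end-to-end tests shows the *statistics pipeline* is correct — occupancy,
segmentation, event counting, file round-trips — not that any force field
or simulation protocol is validated.

## Numerical choices and degenerate inputs

- Concentrations are SI molar throughout; enthalpies kJ/mol; heats µJ;
  distances Å; times ns. Temperature defaults to 298.15 K wherever
  optional.
- Mass balances are validated to relative 1e−9 inside the equilibrium
  containers themselves, so a solver regression fails loudly at
  construction.
- `solve_single_site` with zero ligand returns exactly zero complex;
  `kd_from_displacement` with equal constants returns `Inf` rather than a
  huge number; degenerate (flat) titration curves fit without crashing but
  warn where the estimate is meaningless.
- The c-window predicate tolerates 1e−9 relative slack so exact boundary
  ratios (e.g. 1 mM / 1 µM) land inside the window.

## Problem sizes

The validation studies use: 1000 random triples against the single-site
bisection oracle; a 100-point noiseless fit sweep inside the c window plus
50 noisy replicates; three displacement inversions across fragment Kd
0.3–3 mM; 1000 random binary series against the run-length oracle; and
10⁴–10⁵-frame telegraph chains for the stationary-occupancy checks. These
sizes give comfortable statistical resolution for every asserted tolerance
while keeping the full suite in the low minutes on one core.

## Known limitations

- No activity-coefficient or ionic-strength corrections; no cooperative or
  multi-site binding models.
- The ITC model works at integrated-heat level; raw power traces and peak
  integration are out of scope, as is any instrument response function.
- No structure-based pKa prediction: a computed pKa shift is an *input* to
  the linkage math here, not an output.
- The trajectory reader handles multi-model PDB only; binary MD formats
  need prior conversion.
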