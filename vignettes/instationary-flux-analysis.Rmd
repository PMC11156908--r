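---
title: "Isotopically nonstationary 13C flux analysis with picoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopically nonstationary 13C flux analysis with picoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picoflux)
```

## The problem

Fast-growing photoautotrophs fix CO2 through the Calvin–Benson–Bassham
(CBB) cycle and partition the fixed carbon between storage carbohydrate,
protein, lipid and nucleotides. Which branch points control that
partitioning cannot be read off transcript or metabolite levels alone;
it requires the intracellular fluxes. Because photoautotrophic central
metabolism never reaches an informative isotopic steady state on a
practical time scale (every carbon eventually comes from CO2, so at
isotopic steady state everything is uniformly labeled), fluxes must be
inferred from the *transient* incorporation of a 13C tracer —
isotopically nonstationary metabolic flux analysis (INST-MFA).

`picoflux` implements the full INST-MFA chain for compartmentalized
photoautotroph networks: an atom-transition network model, elementary
metabolite unit (EMU) decomposition, stiff-capable integration of the
transient EMU balances, multi-start least-squares estimation of fluxes,
pool sizes and dilution parameters, chi-square goodness of fit,
parameter-continuation (profile-likelihood) confidence intervals,
CO2-normalized flux maps, biomass-composition mass balance, and
ATP/NADPH energetics ledgers. A synthetic-experiment generator with
known ground truth stands in for LC-MS data, so every stage of the
pipeline is testable end to end.

## The model

### Network, steady state, and parameterization

A network is a table of reactions with 1-based carbon atom transitions
written in lowercase letters, e.g.

```
r_ppc   PEP.c (abc) + CO2.c (d) -> OAA.c (abcd)
```

Compartments are species suffixes (`.h` chloroplast, `.c` cytosol, `.m`
mitochondria); the same chemical in two compartments is two species, and
transporters connect them. The external inorganic-carbon pool (`.ext`)
is excluded from mass balance and carries the prescribed tracer MID;
intracellular CO2 is a balanced species, so carbon released by
decarboxylation can be re-fixed by RuBisCO or PEP carboxylase. The
glyoxylate shunt is absent from the bundled networks, matching its
apparent loss in the modeled organism.

Metabolic steady state is `S v = 0` over the balanced species. Rather
than penalizing violations, all fitting is parameterized in the null
space: `v = N theta` with `N` an orthonormal basis, so every candidate
during optimization satisfies the balance exactly. Reversible reactions
carry a net flux plus a nonnegative exchange flux; the exchange is
optimized on the bounded ratio scale `r in [0, 1)` with
`exch = r / (1 - r)`, the standard device that keeps unidentifiably
large exchanges finite in the parameter vector. Sink (biomass) fluxes
are not fixed inputs: they enter the objective as measured extracellular
fluxes with SDs, and the net CO2 uptake is read off the fitted solution,
never supplied.

### EMU decomposition

Simulating full positional isotopomer distributions costs `2^C` states
per species. The EMU decomposition tracks only the carbon subsets that
can influence a measured fragment: starting from the measured
(full-molecule) fragments it walks backwards through the atom maps,
emitting a transfer when one reactant supplies all tracked carbons and a
convolution when a condensation splits them across reactants. The
resulting system is block-triangular in EMU size, and its state count
is bounded by — and usually well below — the per-species `sum(2^C)` of
exhaustive positional enumeration (291 vs 328 state variables on the
bundled scenario network, 36 vs 58 on the reduced one); the gap widens
when measurements cover fragments rather than full molecules or when
species carry more carbons.

Rotationally symmetric metabolites (succinate, fumarate) are handled by
50/50 scrambling on production: every unidirectional reaction producing
a symmetric species is split into two half-weight variants with mirrored
atom maps. This is required to reproduce the rapid fumarate labeling
through the fumarase exchange flux while succinate itself stays dark.

### Transient balances and integration

For EMU *i* of a species with pool size `P` (umol/gDW) the balance is

```
P dx_i/dt = sum_j v_j conv(sources_j) - (sum_j v_j) x_i
```

with fluxes converted from mmol/gDW/h at the boundary (factor
1000/3600). The label input is an ideal step at t = 0: after the
bicarbonate bolus a residual fraction of the inorganic-carbon pool
(default 0.05) stays unlabeled and the rest is tracer of purity 0.99;
both are configurable, since the study protocol tuned the bolus to
approximate a step without publishing the achieved fractions. The
quench delay of up to ~10 s between sampling and freezing is *not*
modeled and is a known bias source at the earliest time point.

The cascade is integrated with an adaptive Dormand–Prince RK5(4) scheme
implemented in C++ (relative tolerance 1e-8, absolute 1e-10 by
default, 1e-9/1e-11 during fitting where smoothness of the output in
the parameters matters more than raw speed). A step budget caps the
work a single integration may spend, so infeasible parameter corners
fail fast instead of stalling the optimizer.

Two independent checks guard the simulator. A brute-force positional
isotopomer integrator (plain R, `deSolve::lsoda`, every `2^C` state)
must agree with the EMU path to 1e-6 on all bundled toy networks and on
both scenario networks; and an algebraic steady-state solver must match
the long-time transient limit. Natural isotope abundance is available
as a forward binomial convolution (applied to simulations) or as the
inverse correction (applied to data); the default workflow simulates
forward so that both raw and corrected data can be fitted.

## Estimation

The objective is the SD-weighted sum of squared residuals (SSR) over all
MID values and measured extracellular fluxes. Measurement SDs are
floored at 0.005 mole fraction, since triplicate SDs are unstable.
Optimization is bounded Levenberg–Marquardt (`minpack.lm`) over the
null-space coordinates, exchange ratios, log10 pool sizes and optional
dilution fractions. The multistart is two-phase: every start gets a
short exploratory run and only the best basin receives the full
iteration budget (the study protocol uses at least 100 starts on the
full network; the bundled recovery studies use 3–20 on reduced
networks, which the noise-free recovery test shows is sufficient at
that scale). Irreversibility is enforced by hinge penalty residuals
that vanish at any feasible point; the reported SSR contains only
measurement terms. Ties between equal-SSR starts resolve to the lowest
start index.

Two numerical choices deserve emphasis, because the obvious
alternatives fail quietly:

* **Machine-precision finite differences.** The numerical Jacobian uses
  exact-epsilon steps (`epsfcn = 0`) over a tightly toleranced
  integration (relative tolerance 1e-9 during fitting). At those
  tolerances the adaptive step-acceptance sequence of the integrator is
  locally frozen, so the simulated residuals are smooth at machine
  scale and the optimizer converges in tens of iterations; coarse FD
  steps instead sample the integrator's tolerance-level noise and stall
  the line search.
* **Bounded exchange, bounded turnover.** Exchange ratios are capped at
  0.8 (exchange fluxes up to 4x the flux scale) and any parameter point
  whose pool turnover exceeds 50/s is treated as infeasible during
  fitting. Both limits sit far above anything observable: a pool
  turning over faster than once per 20 ms is at isotopic equilibrium
  throughout a 30–600 s sampling grid, so larger exchanges are
  observationally equivalent, and letting the optimizer chase them
  merely burns explicit-integrator steps on physically
  indistinguishable corners.

A fit is statistically acceptable when its SSR lies in the central 95%
chi-square range for `df = n_measurements - n_parameters`; `df` counts
every fitted quantity (free net fluxes, exchange ratios, pools,
dilutions). Dilution parameters — the fraction of a measured pool that
never labels, from inactive pools or channeling — mix the observed MID
as `(1-d) active + d unlabeled`; they are available on every measured
metabolite but default to off in the bundled scenarios, which contain no
inactive pools.

Confidence intervals use parameter continuation. The profiled quantity
is pinned exactly by reparameterization — for a net flux, the
null-space coordinates are rotated so one axis is that flux and the
optimizer works in the orthogonal complement, so every profile point
still satisfies the steady-state balance exactly. The walk steps
outward from the optimum (initial step 2% of the parameter scale by
default, doubling while the profile stays flat), re-optimizing all
other parameters warm-started at each step, until the SSR crosses
`SSR_min + qchisq(0.95, 1)`; the crossing is then localized by a few
regula-falsi refits, which removes the convexity bias that plain chord
interpolation has over wide steps. The reference SSR tracks the lowest
value seen anywhere along the profile, so an incompletely converged
base fit widens rather than narrows the interval. A walk that reaches
a parameter bound reports that side as bound-limited: at the
irreversibility bound 0 this means "the CI includes zero", at the box
bound of an exchange ratio it means structural unidentifiability. On a
linear-Gaussian problem the profile interval reproduces the analytic
Wald interval to 2%.

Flux maps are reported normalized to 100 units of net CO2 uptake, which
preserves all flux ratios and makes strains of different absolute
growth comparable.

## Biomass and energetics

Measured macromolecular compositions (% of ash-free dry weight) rarely
close to 100%. The correction applies component-specific factors (FAME
and carbohydrate under-recovery; default 1.0 since the study's factors
are not published) *before* the global closure scaling — this order
keeps the closure a pure normalization. Assumed fractions for DNA, RNA
and chlorophyll default to the per-strain table values and are
configurable. Precursor demands are linear in the composition: each
class contributes `fraction/100 x mmol precursor per gram of class` from
an editable monomer table with literature-typical stoichiometries
(anhydroglucose 162 g/mol for carbohydrate, ~9.3 mmol amino acids per g
protein split over pyruvate/OAA/AKG/PEP families, ~32 mmol acetyl-CoA
per g C18 FAME; the DNA/RNA/chlorophyll proxies in the scenario-network
table are synthetic stand-ins and labeled as such). Growth rates come
from the log-linear slope of total organic carbon over time.

The energetics ledger is linear in the fluxes: ATP demand is the
flux-weighted sum of per-reaction costs plus a maintenance term (default
2.85 mmol/gDW/h, the published value for a related green alga), NADPH
likewise without maintenance. Consumption is positive and production
negative, so the NADP-dependent malic enzyme — active in the
protein-rich scenario's OAA -> malate -> pyruvate cycle — reduces net
NADPH demand. NADH is tracked as a separate currency and never enters
the headline ATP/NADPH ratio (no transhydrogenase assumed). Reference
stoichiometries: linear electron flow produces ATP/NADPH at
`(12 x 3/14)/2 = 1.29`, the CBB cycle consumes at `3/2 = 1.5`.

## The synthetic experiment generator

The generator defines the study conditions rather than emulating any
particular dataset: a 13C step at t = 0, sampling at 0/30/60/180/300/600
s, three biological replicates, and independent Gaussian MID noise of SD
0.01 mole fraction (the scale at which triplicate LC-MS MIDs typically
scatter). Noisy replicate MIDs are truncated to [0,1] and renormalized
so they stay on the simplex; a pure-Gaussian mode exists for SSR
calibration studies, where exact chi-square behavior is the point.
Sink fluxes are measured with 5% relative SD. A single master seed makes
a dataset byte-reproducible.

Three presets on a 20-reaction compartmentalized scenario network
(lumped CBB, triose-phosphate export, storage-carbohydrate branch,
anaplerosis, incomplete TCA) encode the contrasting regimes:

* `tg1` — carbohydrate-rich: strong hexose-phosphate -> G1P -> storage
  branch, no malic-enzyme flux; net CO2 uptake 6.17 mmol/gDW/h.
* `tg2` — protein-rich: roughly half the normalized storage flux,
  higher triose-phosphate export and amino-acid sink demand, higher PEP
  carboxylase anaplerosis, and an active OAA -> malate -> pyruvate
  malic-enzyme cycle producing NADPH; net uptake 9.57 mmol/gDW/h.
* `myb99` — extreme carbohydrate partitioning (56% AFDW carbohydrate).

All presets carry a zero AKG -> succinate flux (the incomplete-TCA
configuration), a high fumarase exchange, and pool sizes chosen so CBB
intermediates label on a seconds scale while TCA-derived amino-acid
precursors lag — the qualitative signatures the study's measurements
show. True pool sizes for this organism are unpublished; the presets
use order-of-magnitude contrasts (small CBB pools, larger amino-acid
and organic-acid pools), which is sufficient for the package's purpose
of validating the estimator. A condensed single-compartment variant
(`tg2_micro`, 10 reactions) supports the statistical studies below at
low cost.

What passing tests on these scenarios do *not* show: correctness of any
particular published flux value, robustness to real LC-MS artifacts
(correlated noise, fragment contamination, retention-time drift), or
identifiability on genome-scale networks.

## Numerical and statistical validation

The test suite ships these studies (sizes chosen to keep a full run in
the tens of minutes on one CPU):

* **Oracle equivalence** — EMU vs brute-force isotopomer integration to
  1e-6 on four toy networks and both scenario networks at all six study
  time points.
* **Noise-free recovery** — 20-start fits on the reduced TG2-like
  scenario recover every net flux to better than 0.1%.
* **CI coverage** — across 50 noisy repetitions (SD 0.01, triplicates),
  95% profile CIs on the four free fluxes cover the truth in at least
  90% of cases. The study is conditional: pool sizes are held at their
  true values (they are the flat, weakly identified directions, and
  conditioning on them makes each repetition's global fit affordable)
  and the Gaussian noise mode is used, under which the least-squares
  model is exactly specified.
* **SSR calibration** — with Gaussian noise, the SSR evaluated at the
  true parameters falls inside the central 95% chi-square range in
  93–97 of 100 repetitions.
* **Scenario contrast** — fitted TG1-like and TG2-like experiments
  reproduce the higher normalized storage-branch flux (TG1-like), the
  higher triose-phosphate export (TG2-like), and an AKG -> succinate CI
  that includes zero in both.

### A note on truncated noise at the simplex boundary

The generator's default noise model truncates noisy MIDs to [0,1] and
renormalizes, keeping replicates on the simplex. For entries at the
boundary — a fully unlabeled M+0 of 1, higher masses of 0 — truncation
is one-sided and biases the mean by roughly `0.4 x SD` per entry. A
weighted least-squares fit takes those biased values at face value, and
the effect is not hypothetical: in the bundled scenarios it shifts a
strictly-zero branch flux (AKG -> succinate, pinned to within about
5e-4 mmol/gDW/h because the 3 umol/gDW succinate pool stays dark over
600 s) far enough that its confidence interval can exclude zero. This
is exactly why mass-spectrometry practice retains negative
natural-abundance-corrected intensities instead of clipping them. The
statistical studies therefore use the Gaussian mode, and the truncated
mode stands as a realism caveat for fitting boundary-heavy real data.

## Design choices made where the design was open

* Backward (demand-driven) minimal EMU construction; the originating
  study delegates this to closed-source software, so the algorithm is
  this package's own.
* Pool sizes may be held fixed during scenario fits (the bundled
  drivers and statistical studies condition on the preset pools);
  profile CIs then quantify flux uncertainty conditional on those
  pools. The full pipeline fits pools by default.
* The measurement SD of a replicate mean is taken as
  `noise SD / sqrt(n)` from the known generator noise, rather than the
  unstable empirical triplicate SD.
* Criterion-style comparisons against published per-strain SSR brackets
  and CO2 uptakes are out of scope at desk scale: they require the
  study's deposited measurement tables, which the package deliberately
  does not bundle. The synthetic scenarios reproduce the qualitative
  structure instead.

## Known limitations

* Finite-difference sensitivities (no forward/adjoint ODE gradients);
  adequate at bundled network sizes, the dominant cost at larger ones.
* The explicit integrator trades stiffness robustness for speed; the
  200/s turnover guard documents that trade.
* No gas–liquid CO2 mass-transfer model (the bicarbonate bolus design
  avoids it) and no quench-delay correction.
* One tracer element (13C); no 15N, no cumomer/isotopomer fitting
  formulations, no Bayesian posterior sampling.
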