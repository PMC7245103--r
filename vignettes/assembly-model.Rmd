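---
title: "A stochastic model of molybdenum-blue cluster self-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic model of molybdenum-blue cluster self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobluesim)
```

## The scientific problem

Acidified, mildly reduced molybdate solutions self-assemble into a handful
of giant, well-defined polyoxometalate clusters — the {Mo36} cluster, the
{Mo132} Keplerate ball and the {Mo154} molybdenum-blue wheel — even though
the underlying building-block chemistry could in principle produce
thousands of structures of comparable stability. `mobluesim` implements a
coarse-grained kinetic Monte Carlo model of this assembly process in which
the selectivity emerges from an *embedded autocatalytic set*: the {Mo36}
cluster catalyzes the production of the {Mo6} hexad building block and the
assembly of its own structure, thereby replicating itself, and
cross-catalyzes the formation of the {Mo154} wheel.

The package has four working layers:

* a **reaction-network generator** (`enumerate_species()`,
  `enumerate_reactions()`, `assign_base_constants()`,
  `annotate_templates()`, `extend_with_inhibitor()`),
* an **exact stochastic simulation engine** (Gillespie direct method,
  compiled; `run_simulation()`, `run_ensemble()`),
* an **analysis layer** for critical transitions, scaling exponents,
  coexistence, lag times and seeding experiments,
* a **stopped-flow-style kinetics module** (finite-difference rate curves,
  Beer–Lambert conversion, and a two-step autocatalytic sigmoid model with
  generator and fitter),

plus a registry of the known cluster structures with formula-level
oxidation-state arithmetic.

## The coarse-grained species space

Species are identified by nuclearity (number of Mo atoms) only; two
intermediates with the same Mo count are the same species. Two deliberate
exceptions structure the model:

1. **Two dimers.** Nuclearity 2 splits into the corner-bonded dimer `M2c`
   and the reduced edge-bonded dimer `M2e`. They play different structural
   roles: the corner dimer feeds the oxidized (wheel) family, the reduced
   edge dimer the {Mo132} ball. The dimerization ratio `D` — the ratio of
   the corner to edge channel rate constants — is the model's control
   parameter; experimentally it maps to pH and reduction potential.
2. **Lineages.** Intermediates above the hexad (`lineage_threshold = 6`)
   carry a lineage tag, `corner_dimer_path` (terminating in {Mo36} and
   {Mo154}) or `edge_dimer_path` (terminating in {Mo132}); corner/edge
   mixing is disallowed there. The intermediate space between {Mo36} and
   the giants is not characterized experimentally, so this lineage scheme
   is an explicit modelling surrogate.

Three further coarse-graining choices were genuinely open and we document
the reasoning:

* **Even-nuclearity lineages** (`lineage_step = 2`, the default when all
  targets are even). Lineage intermediates exist at even nuclearities
  only, so lineage growth proceeds by whole building blocks — the
  lineage's own dimer and the {Mo6} hexad — and free monomers enter the
  assembly cascade only through dimerization. With monomer additions
  allowed everywhere (`lineage_step = 1`, also available), the giant
  structures grow on the monomer pool alone, the dimer supply stops
  mattering, and the dimerization ratio loses its experimentally observed
  control over the product distribution.
* **An oxidized small-cluster ladder.** The {Mo3}–{Mo6} condensation
  ladder is built from corner dimers only (`{Mo6} = 3 x {Mo2c}`): the
  hexad and everything downstream of it ({Mo36}, the wheel) are fully
  oxidized structures, while the reduced edge dimer's productive fate is
  the ball lineage (`reduced_dimer_in_ladder = FALSE`,
  `monomer_in_ladder = FALSE`). This roots the hexad supply in the
  corner-dimer flux and hence in `D`.
* **Terminal templates.** A completed {Mo36} is a closed structure: it
  accelerates other reactions but does not itself react; the wheel path
  above nuclearity 36 is reached by hexad additions that bypass the closed
  cluster. Treating the template as an ordinary consumable intermediate
  made templation *deplete* the autocatalyst, inverting the ablation
  phenomenology.

## The rate model

All unimolecular degradations have rate constant 1.0; they set the time
unit. The exceptions are the completed giants {Mo132} and {Mo154}, which
are known to be stable and degrade at `k_d = 1e-6` (configurably also
{Mo36}). Bimolecular syntheses start from `k_bi_base = 1` and acquire:

* a collision prefactor `sqrt(temperature / mu) / volume` with reduced
  mass `mu = m_A m_B / (m_A + m_B)` and `m = nuclearity` in model units
  (`k_B = 1`, `mass_per_mo = 1`, `volume = 10`);
* the completion bias `1 + k_nano / (1 + free_sites(product))`, a monotone
  decreasing function of the product's free bonding sites (`N - n` on a
  path to target `N`); with `k_nano = 0` the bias is off. The functional
  form is our choice; only its monotonicity matters for the mechanism.
  Default `k_nano = 1`;
* the dimerization split: the two monomer pairing channels share
  `k_bi_base` in ratio `D` (corner : edge), normalized so their sum is
  `2 k_bi_base` independent of `D`;
* a factor `corner_link_factor = 0.15` on lineage-growth steps that
  incorporate a corner dimer: the fully oxidized corner dimer is a far
  less reactive linker than the reduced edge dimer, so oxidized-family
  growth leans on the hexad supply;
* the template factor: a synthesis annotated with a template runs
  `1 + (template_factor - 1) * N_template` times faster (count-
  proportional, default `template_factor = 10`, so the acceleration is
  exactly 10.0 with a single template present). A step-function mode
  (`template_mode = "presence"`) is available; we default to the
  proportional form because the autocatalytic ignition it produces — each
  added template molecule contributes recognition surface — is what
  sustains the template population against its own unit-rate degradation.

The default templation rules encode the embedded autocatalytic set: {Mo36}
accelerates (i) the syntheses of the {Mo154} wheel path, (ii) the
condensation of the small oxidized clusters up to {Mo6}, and (iii) the
syntheses along its own corner-lineage path — the molecular-recognition
route by which a completed cluster coordinates incoming fragments and
replicates. Rules are data (`annotate_templates()`), so ablation
(`list()`) and cross-catalysis variants (e.g. a Keggin templating a ring
path) are one-line configurations.

## The engine

`run_simulation()` is an exact direct-method Gillespie simulation: waiting
times are exponential in the total propensity and reactions fire with
probability proportional to their mass-action propensity
(`k_eff N_A`, `k_eff N_A N_B`, or `k_eff N_A (N_A - 1) / 2` for identical
reactants). The compiled core maintains a Fenwick tree over propensities
with per-species dependency lists, so a step costs O(log R) plus the
propensities actually touched. Tau-leaping is deliberately absent: the
networks here have at most a few hundred species and exactness is cheap.
Total Mo mass is asserted at every sampled time; trajectories are
bit-reproducible given a seed, and replicate `r` of an ensemble uses seed
`seed_base + r`. A pure-R `ssa_step()` implements the identical update for
inspection and testing.

## Reference study conditions

The package-wide defaults — used by the tests, the command-line tools and
the acceptance script — are an all-monomer pool of 3000 Mo in a volume of
10 model units, simulated to a horizon of 40 time units with time-averages
taken over the second half of each trajectory (the first half discards the
assembly transient). At these conditions a single trajectory fires on the
order of 10^4–10^5 reactions and takes well under a second, so the
21-point dimerization-ratio sweep at 100 replicates per point completes in
minutes on one core. These sizes are the package's reference conditions
for a finite, stochastic regime: a handful to a couple of dozen completed
giants per trajectory, where nucleation noise and resource competition are
visible rather than averaged away.

## What the model reproduces

At the reference conditions the model exhibits, and the test suite
asserts:

* **A critical transition in `D`.** Below a critical dimerization ratio
  the {Mo154} wheel essentially never forms; above it the wheel forms
  robustly. The transition is driven by the ignition of the {Mo36}
  autocatalytic loop, which requires a sufficient corner-dimer (and hence
  hexad) supply. `detect_critical_point()` locates the steepest change of
  the abundance curve (optionally smoothed; midpoint convention), and
  `fit_scaling_exponents()` fits two-sided log–log scaling around it,
  reporting exponents with their windows — exponents are window-sensitive
  and meaningless without them.
* **Ball/wheel competition and coexistence.** The {Mo132} ball dominates
  below the transition (abundant reduced dimers, with hexads still
  supplied by the smouldering template loop), collapses above it, and
  coexists with the wheel in a narrow window. `coexistence_curve()`
  quantifies this with a normalized-minimum metric.
* **Template ablation.** Deleting the template rules at otherwise
  identical, matched-seed conditions collapses the time-averaged {Mo36}
  abundance by more than an order of magnitude and abolishes wheel
  formation entirely: the autocatalytic cycle, not the raw thermodynamics,
  sustains the template.
* **Sigmoidal growth, seeding and saturation.** Unseeded trajectories show
  a lag, a burst of near-exponential growth and saturation of the wheel
  count. Seeding the initial pool with preformed {Mo36} removes the lag
  monotonically and the initial rate saturates at large seed amounts — and
  overdosing the seed eventually depresses the early rate, as the seed
  stock decays faster than it can be replicated.
* **The forward-rate paradox.** Raising `k_bi_base` beyond a knee does not
  increase — and eventually suppresses — the wheel yield: faster
  indiscriminate chemistry traps material in low-nuclearity clusters and
  competing stubs instead of completing giants.

The {Mo132} maximum lies close below the detected transition but, at the
reference conditions, not always within a single grid step of it; the
sweep summaries report both locations so the gap is visible rather than
hidden.

## The kinetics module

The stopped-flow analysis layer is deliberately independent of the
simulator. Sigmoidal product-formation traces are modelled with the
minimal two-step autocatalytic scheme — slow continuous nucleation
`A -> B` (`k1`, 1/s) plus autocatalytic growth `A + B -> 2B`
(`k2`, 1/(M s)) — which has the closed-form solution implemented in
`autocatalytic_solution()`. This rate law is a surrogate for the real
(unknown) mechanism: it is the smallest model with the observed
uncatalyzed-then-autocatalytic structure. Concentrations are counted in
product units (e.g. total Mo / 36 for {Mo36}), so `A0 + B0` is conserved;
the divisor is the caller's choice. `fit_sigmoid()` performs
Levenberg–Marquardt least squares on log-transformed parameters (enforcing
positivity), supports fixing any parameter (e.g. `B0` to a known seed
concentration), and returns an explicit failure object — never a crash —
for flat or non-converging traces. `lag_time()` uses the classical
tangent construction: the time-axis intercept, relative to the initial
baseline, of the tangent at maximum slope, with slopes from the same
central-difference operator as `finite_difference_rate()`. Beer–Lambert
conversion requires a user-supplied molar absorptivity; none is assumed.

`simulate_sigmoid()` is the synthetic-trace generator used for
parameter-recovery studies: exact closed-form kinetics plus i.i.d.
Gaussian noise. It emulates the shape, sampling density and noise scale of
a stopped-flow concentration trace, but none of an instrument's
systematic artefacts — baseline drift, mixing dead time, correlated
detector noise, photo-degradation. Recovery tests passing on it therefore
demonstrate the fitter's correctness and statistical efficiency, not
robustness to instrumental systematics.

## Degenerate inputs and numerical choices

Empty compositions have nuclearity 0; a registry validation reports
violations as data rather than errors. A flat abundance curve yields an
explicit no-transition result, and scaling fits report a side as
undetermined when fewer than three usable points fall in the window. The
sigmoid solution switches to its exact `k2 = 0` first-order limit to avoid
cancellation, and caps the logistic ratio at overflow. The SSA engine
guards against floating-point drift in the propensity tree by periodic
rebuilds and rejects (unreachable) negative counts. All exported
randomness flows through explicit seeds.

## Known limitations

The model is phenomenological: rate constants are in model units and only
ratios are meaningful; no pH speciation, ionic strength, counter-ion or
temperature dependence is modelled beyond the knobs described above. The
intermediate space is a lineage-tagged nuclearity ladder, not a structural
ensemble; conclusions about *which* intermediates carry the flux are
outside its resolution. Scaling exponents from finite, stochastic sweeps
are window- and grid-sensitive and should be read as descriptive, not
universal. The inhibitor extension models only reversible unproductive
sequestration. The crystallographic registry stores formula-level
arithmetic only — no geometry, no bond-valence sums.
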