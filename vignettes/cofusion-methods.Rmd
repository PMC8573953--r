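---
title: "Modeling a fusing clostridial coculture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a fusing clostridial coculture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofusion)
```

`cofusion` models a syntrophic *Clostridium acetobutylicum* (*Cac*,
a solventogenic glucose fermenter) / *Clostridium ljungdahlii* (*Clj*,
an acetogen that cannot take up glucose) coculture in which cells fuse
membranes and exchange proteomes. This vignette is the package's own
account of the models it implements, the parameters that matter, and
the design decisions taken where the design was genuinely open.

## The hybrid-state growth model

Each organism is partitioned into a nonhybrid pool (state 0) and five
hybrid states. A hybrid state indexes doubling times since a fusion
event: a freshly fused cell (state 1) carries roughly half nonnative
protein, and each division halves that share, so after five doublings
the cell is treated as having reverted to its nonhybrid pool. Five
states is a modeling choice that lets hybrid-cell "recycling" feed the
nonhybrid pools late in the culture while keeping the state space
small; the equations generalize to any number of states (the last state
always recycles into state 0).

The abundance balance couples the twelve pools through one fusion rate
constant `f`:

* state 0 gains by Monod growth and by recycling from the last hybrid
  state, and loses by fusion at rate `f · X0_Cac · X0_Clj` (fusion is
  first order in each nonhybrid abundance; only nonhybrid cells fuse);
* state 1 gains the fusion flux and passes cells onward at its growth
  rate;
* states 2..5 are a pure aging chain, `mu[l-1]·X[l-1] − mu[l]·X[l]`.

Two structural properties follow and are enforced by tests: summing all
equations telescopes every fusion and transition term away, so the
community total grows only through the nonhybrid growth terms; and the
system is homogeneous, so the zero state is a fixed point. Note the
aging-chain form means hybrid-state "growth" moves cells between states
rather than adding net cells; the equations are implemented exactly as
written rather than reinterpreted with doubling semantics, since the
structural reading is itself a statement about what fusion does and
does not contribute to net growth.

**Growth rates.** All hybrid states of an organism share the organism's
*monoculture* time-dependent specific growth rate (hybrid-state rates
are not separately identifiable from coculture data). Monoculture
OD600 curves are interpolated with a monotone piecewise-cubic Hermite
interpolant (Fritsch–Carlson, the PCHIP family; `stats::splinefun`
method `"monoH.FC"`), which is exact at the measurements and cannot
overshoot between them — important because the rate is a log-ratio and
an overshooting interpolant would manufacture spurious growth. Rates
are computed on a regular 0.1-h grid as
`mu_n = log(OD_n/OD_{n-1}) / (t_n - t_{n-1})`; a 48-h curve yields 481
grid points and 480 interval rates. Between grid points the rate lookup
is piecewise constant and left-continuous, matching the interval
definition of the rates.

**Fitting `f`.** The fit minimizes the weighted squared Euclidean
distance between predicted and observed species fractional abundances,
with inverse-variance weights from the observation standard deviations;
standard deviations below 1e-3 (fractional units) are clamped to that
floor so a single ultra-precise point cannot dominate. The optimizer is
deterministic and derivative-free: a 41-point log-spaced scan over
`[1e-16, 1e-8]` liter cells⁻¹ h⁻¹ followed by golden-section refinement
in the bracketing decade. Because `f` multiplies absolute abundances
while only fractions are observed, `f` and the absolute inoculum scale
trade off exactly; the package convention is a total inoculum of 1e11
cells/liter split 10%/90% (*Cac*/*Clj*, the experimental inoculation
convention), and every fit reports the scale it used.

**Integration.** Fixed-step forward Euler (default 0.01 h for the
growth model) with abundances clamped at zero after each step. Euler is
deliberate: the convergence test asserts the first-order error
signature (halving the step roughly halves the endpoint error), and the
clamping rule is part of the contract. Genome copy number is converted
to relative abundance one-genome-per-cell.

## The constraint-based layer

`metabolic_network` is a dense stoichiometric container (metabolites ×
reactions, bounds in mmol gDW⁻¹ h⁻¹, per-reaction source-organism tag).
FBA maximizes the objective subject to `S v = 0` and bounds; FVA
computes per-reaction flux ranges with the objective constrained to a
fraction of its optimum; blocked reactions are those whose FVA range at
fraction 0, with all exchanges opened to ±1000, is {0} within 1e-6.
Only objective values and FVA envelopes are treated as contract-stable;
individual flux vectors at degenerate optima are not asserted anywhere.

The LP solver is an internal two-phase tableau simplex with Bland's
anti-cycling rule (Dantzig pivoting for speed until a high iteration
count). It is written in R and cross-checked in the test suite against
brute-force vertex enumeration on every small fixture. The tradeoff is
scale: dense tableau simplex is comfortable for the lumped toy networks
the package ships and for models up to a few hundred reactions, but
genome-scale work would want a sparse industrial LP backend. Tolerances:
pivoting/feasibility 1e-9, flux-is-zero 1e-6.

**Biomass rescaling.** Biomass equations are standardized so one unit
of biomass flux drains 1.0 g dry weight per mmol: coefficients are
multiplied by `1000 / sum_j |coef_j| * MW_j` over biomass reactants,
with molecular weights computed from metabolite formulas. The FBA
optimum scales by the inverse factor, and the operation is idempotent.
Components without a parseable formula are an error that names the
offenders.

**Formats.** The native on-disk format is the widely used
constraint-based JSON schema; SBML Level 3 + FBC is imported through a
minimal reader (species, formulas, flux-bound parameters, active
objective). Spreadsheet supplements are expected as per-sheet CSV
exports (`time_h,value[,sd]`); no spreadsheet reader is bundled.

## Hybrid model construction

A hybrid model is the union of host and donor reaction content with the
*host* biomass and objective retained (no genomic DNA is exchanged, so
a hybrid keeps its own biomass composition). Donor metabolites map into
the host namespace through a caller-supplied id map, defaulting to
exact id match, with unmatched donor species imported as new
metabolites. Donor reactions whose mapped stoichiometry equals a host
reaction up to a scalar are kept once, tagged `shared`, with union
bounds — without this, duplicated pathways would double apparent flux
capacity and inflate FVA-based counts.

The acetogen model is first augmented with the six reactions expressed
only in coculture: exchanges for acetoin, acetone, 2,3-butanediol and
isopropanol plus the NADPH-dependent secondary-alcohol and
2,3-butanediol dehydrogenases. The operation is idempotent and only
adds what is missing.

**Energy-generating cycles.** Merging two reconstructions can create
thermodynamically impossible loops that generate ATP from nothing. The
certificate used here: with every exchange closed, the maximum flux
through each energy-dissipation reaction (ATP maintenance, or a
constructed ATP hydrolysis sink) must be zero. While it is positive,
the package finds a minimal-total-flux solution still carrying the
dissipation (an L1 LP), and closes the cycle-carrying direction of the
largest-flux reversible loop member, then re-certifies. This is a
minimal-intervention heuristic: it provably terminates and preserves
the certificate, but the specific direction closed depends on the L1
solution, so the post-strip model is reported together with the list of
constrained reactions rather than claimed canonical.

**Gain of function.** For a hybrid built from a host: native reactions
unblocked by the merge (`blocked(host) \ blocked(hybrid)`), donor
reactions able to carry flux, donor reactions whose FVA range at
objective fraction 1 excludes zero (these necessarily shape the optimal
growth phenotype), and the percent change in maximum growth.

## The DMMM community simulation

The dynamic multispecies simulation advances extracellular pools with
forward Euler steps (default 0.1 h, the rate-grid spacing) over a 33-h
span. At each step:

1. Culture-level glucose and fructose drawdown rates come from finite
   differences of the monotone interpolants of measured (or synthetic)
   concentration curves, floored at zero.
2. Drawdown is allocated across subpopulations proportionally to
   abundance × hybrid-state glucose uptake efficiency (glucose), or to
   abundance among fructose-capable members (fructose; hybrid-state
   scaling is applied to glucose only, since transporter dilution is
   quantified for the glucose system). Efficiencies are `1 - 2^-l` for
   the glucose-native fermenter and `2^-l` for the acetogen, direct
   consequences of halving nonnative proteome per doubling.
3. Each subpopulation solves its own LP, posed per liter of culture:
   substrate bounds are culture-level rates (mmol L⁻¹ h⁻¹), which
   removes any need for an absolute gDW conversion because the
   experimental curves constrain total utilization and abundances only
   set the split. Growth is fixed at the scheduled fraction of the
   subpopulation's own maximum (the growth-efficiency schedule), and a
   secondary objective spends the remaining freedom on product export
   plus, for fermenters in cross-feeding scenarios, H₂/CO₂ evolution —
   a lexicographic convention chosen because growth maximization alone
   leaves exchange fluxes degenerate.
4. Fermenters are solved first; the H₂/CO₂ they evolve within the step
   is the acetogen's uptake budget (instantaneous transfer, no gas
   holdup pool), split across acetogen subpopulations by abundance.
5. Pools update as `pool += dt * sum(net community exchange)`; a step
   that would drive any pool negative is rejected and re-taken as two
   half steps, recursively, at most 20 halvings deep.
6. Per-product maximum theoretical export is computed by FVA-style
   maximization of total community export under the same allocations
   and growth floors; integrating these rates gives cumulative maximum
   theoretical titers (g/L via formula molecular weights). Soluble
   carbon is the summed atomic carbon of the product pools,
   `conc × C × 12.011 / 1000` g/L.

**Scenarios.** `nonfusing` runs only the two nonhybrid models with no
soluble-product cross-feeding (the acetogen's external inputs are
community-evolved CO₂/H₂ and fructose); `fusing` runs all twelve
subpopulations with soluble cross-feeding wherever the schedule permits
consumption; `no_h2_crossfeed` is the fusing setup with acetogen H₂
uptake pinned at zero. With zero fusion the hybrid pools are empty and
the fusing scenario reproduces the nonfusing trajectory exactly — a
degeneracy the acceptance tests assert at 1e-8.

**Growth-efficiency schedule.** The staged schedule encodes three
fermentation phases: 0–10.4 h (fermenter exponential at 56% of maximum
growth, acetogen lag at 5%), 10.4–21 h (fermenter
solventogenesis/sporulation at 35% with butyrate and lactate
consumption, acetogen exponential at 100%), and 21–33 h (additionally,
acetogen acetone consumption). When experimental product profiles are
configured, observed consumption rates become uptake lower bounds.

## The toy community and synthetic data

The fixture pair emulates the coculture biology at lumped-pathway
resolution with integer stoichiometry, so every oracle is
hand-checkable:

* the fermenter takes glucose or fructose through a glycolysis lump to
  pyruvate, acetyl-CoA and the full solvent panel (acetate, butyrate,
  butanol, acetone, ethanol, acetoin, lactate), evolving CO₂ and H₂;
  its recorded optimum on 10 mmol gDW⁻¹ h⁻¹ glucose is biomass flux 10;
* the acetogen has no glucose route, grows on fructose (recorded
  optimum 12.5, with CO₂ refixation through a Wood-Ljungdahl lump) or
  on CO₂+H₂ alone (recorded optimum 1.25), and carries an H₂-driven
  NADPH regeneration reaction that is deliberately blocked until
  augmentation adds its consumers — a planted dead end for the
  blocked-reaction tests.

Every internal reaction is carbon- and electron-balanced by
construction (cofactors carry carbon-free placeholder formulas so the
lumps stay exactly balanced), which is what makes the community-level
carbon-closure test meaningful at 1e-6. Recorded optima live in the
fixture object (`toy_community_models()$optima`), not in test code.

The synthetic generators sample a logistic monoculture OD curve
(defaults: inoculum 0.05, rates 0.6 vs 0.25 h⁻¹ and capacities 6 vs 3
for the fermenter-like and acetogen-like organism, mirroring the
growth asymmetry of the real pair over 48 h) and integrate the fusion
ODEs at a known `f_true` to produce abundance observations; noise is
Gaussian, seeded, and isolated from the global RNG stream. What the
toys do *not* emulate: quantitative fermentation titers, pH and gas
transfer physics, product inhibition, or the regulatory shifts behind
solventogenesis (represented only through the growth-efficiency
schedule). Passing tests therefore demonstrate the machinery —
conservation laws, LP correctness, scenario logic, parameter
recovery — not quantitative agreement with any real fermentation.

## Problem sizes and determinism

Default test and acceptance runs use the toy networks (14–32
reactions), growth-model integrations at 0.01–0.05 h steps over 24–48 h,
and DMMM runs over 33 h at a 1-h step — sizes chosen so the whole suite
runs in well under a minute of LP time while still exercising every
code path. All stochastic steps take explicit seeds; LP solves,
fitting, and scenario runs are deterministic given their inputs.

## Known limitations

* The dense simplex backend is not suited to genome-scale models
  (hundreds to thousands of reactions); the published-model analyses
  in the acceptance suite require the authors' model files and a
  session where loading them is feasible.
* Exchange-flux vectors at degenerate optima depend on the pivoting
  order; only objective values, FVA envelopes and pool trajectories
  under the documented lexicographic convention are stable outputs.
* The fusion model deliberately omits the experimentally observed lag
  in hybrid-cell formation: one mechanistic rate constant, no
  empirical lag correction, which is known to misplace the nonhybrid
  *Cac* abundance peak relative to flow-cytometry data.
* Fructose uptake is not hybrid-state scaled (only glucose transporter
  dilution is quantified); gas transfer is instantaneous within a step
  unless a holdup pool is configured.
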