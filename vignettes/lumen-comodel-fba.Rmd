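---
title: "Modelling prebiotic-driven provitamin D3 biosynthesis with LumenFBA"
author: "LumenFBA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling prebiotic-driven provitamin D3 biosynthesis with LumenFBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LumenFBA)
```

## The problem and the model

Vitamin D3 is produced in skin from 7-dehydrocholesterol (7-DHC,
provitamin D3), and reduced 7-DHC is one intrinsic cause of vitamin D
deficiency. Gut bacteria fermenting dietary fructans (inulin,
short-chain fructooligosaccharides) secrete short-chain acids — acetate,
lactate, pyruvate — that the intestinal host can absorb and channel into
acetyl-CoA and, through the HMG-CoA/cholesterol branch, into 7-DHC.
LumenFBA asks a quantitative version of this question with flux balance
analysis (FBA): given a host metabolic network and a gut microbe joined
through a shared lumen, how much can a prebiotic dose raise the host's
capacity to make 7-DHC and secrete 25-hydroxyvitamin D3?

FBA treats a metabolic network as a stoichiometric matrix $S$ (metabolites
$\times$ reactions) and solves the linear program

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \qquad
lb \le v \le ub,$$

where $v$ are reaction fluxes (mmol·gDW$^{-1}$·h$^{-1}$ by convention) and
$c$ selects the objective. Deficiency-driven demand is modelled by
maximizing the secretion of 25-hydroxyvitamin D3, the circulating
vitamin-D status biomarker and an endpoint of the modelled pathway. For
exchange reactions (boundary reactions on a single metabolite) the
package-wide sign convention is negative flux = uptake, positive =
secretion.

### Assumptions inherited from FBA

* Steady state: no metabolite accumulates; only rates, not
  concentrations, are predicted.
* No regulation: every enzyme is available; results are *capacities*,
  upper bounds on what the network can do.
* A linear objective stands in for the physiological drive (here:
  deficiency-driven demand for 25-OH-D3).

## The co-metabolism construction

`mergeComodel(host, microbe)` namespaces both networks (`H_`, `M_`) and
joins them through a new lumen compartment (`lu`):

* every boundary metabolite of an organism's extracellular compartment
  (join policy; default compartment `"e"`) gets one shared lumen species;
* the organism's former exchange reaction is rewritten as *directed*
  organism–lumen transports — an uptake transport (`H_UP_lac`:
  lumen → organism) when the exchange allowed uptake, a secretion
  transport (`M_SEC_lac`) when it allowed secretion — preserving the
  original bound magnitudes. Splitting a reversible exchange into two
  irreversible transports keeps the four transport classes (host/microbe
  × uptake/secretion) disjoint, which makes secretion capping and
  profiling unambiguous;
* each lumen metabolite receives a single boundary exchange
  (`EX_<met>_lu`) through which diet enters (lower bound < 0) and surplus
  leaves (upper bound > 0).

Organism exchange bounds are therefore read as *capacities* (what the
tissue or cell membrane can transport), while *availability* is set on
the lumen boundary by the diet and the prebiotic dose. This is why the
bundled toy host solved on its own is limited only by its downstream
pathway capacity, whereas the co-model baseline is glucose-limited: the
lumen exchanges open only what the diet provides.

If the host objective sits on an exchange that is rewritten (as with
25-OH-D3 secretion), its coefficient moves to the corresponding lumen
boundary exchange, so "secretion maximization" remains a flux out of the
whole system.

## Doses, diets and the control condition

`doseToFlux()` converts a dose of $d$ grams into per-component uptake
bounds

$$b_i = \frac{d \cdot w_i}{M_i \cdot T} \cdot s,$$

with mass fraction $w_i$, molar mass $M_i$ (g/mmol), amortization horizon
$T$ (default 24 h) and a per-gDW scaling constant $s$ (default 1).
`applyPrebiotic()` then sets the component's lumen exchange to
$(-b_i, 0)$: uptake *allowed up to* the dose, never forced. Forced uptake
(a positive lower bound on consumption) can make models infeasible and
would destroy the monotone, saturating dose response; with allow-up-to
semantics the optimum is provably non-decreasing in the dose, and it
saturates when a downstream capacity (in the toys, the lumped
HMG-CoA→7-DHC step) becomes binding.

Built-in compositions: scFOS is an equal-mass GF2/GF3/GF4 split with
average formula weights 0.50444, 0.66658, 0.82872 g/mmol; inulin is a
single polymer of configurable degree of polymerization (default 10,
1.80157 g/mmol). Absolute fluxes therefore scale with $M_i$, $T$ and $s$,
which are deliberately configuration-level constants: fold changes are
the robust output of this kind of simulation, absolute fluxes are
calibration-dependent.

The control condition caps every microbe→lumen secretion transport
(`capMicrobeSecretion()`, default cap 0 with a feasibility check, or the
smallest viable cap on a grid when growth coupling is requested). Under
the cap the dose response flattens to the baseline, which isolates the
microbial contribution. Minimum microbial growth is *not* enforced by
default (`minGrowth = 0`): a fructan-only microbe cannot grow at dose 0,
so any positive growth floor would make the zero-dose baseline
infeasible; growth coupling remains available as an explicit option.

## Parsimonious FBA and determinism

FBA optima are frequently degenerate: many flux vectors achieve the same
objective. Reported flux tables (secretion profiles, flux modes,
subsystem statistics) therefore use parsimonious FBA (`solvePFBA()`): a
second LP minimizes total absolute flux $\sum_j |v_j|$ (linearized by
splitting each flux into non-negative forward/reverse parts) subject to
the original constraints and $c^\top v \ge z^* - \varepsilon$ with
$\varepsilon = \max(10^{-9}, 10^{-9} |z^*|)$. Plain `solveFBA()` is kept
for objective-only queries.

The LP backend is a dense bounded-variable two-phase primal simplex with
Bland's rule, written for this package: entering and leaving variables
are chosen by smallest index, so there is no randomness anywhere in the
solver and identical inputs give identical vertices (screen outputs are
byte-identical across reruns). Feasibility and optimality tolerances
default to $10^{-9}$. The backend is dimensioned for the desk-scale
models this package tests itself on (up to a few hundred reactions);
genome-scale co-models will solve but slowly.

Numerical conventions used throughout: activity of a reaction in a flux
mode means $|v| \ge 10^{-6}$; a reaction counts as "changed" between two
conditions when $|\Delta v| > 10^{-6}$; the division guard for percent
changes on a zero baseline is $\varepsilon = 10^{-9}$, which
automatically ranks 0→nonzero activations above every finite percent
change.

## The four analyses

* **Dose response** (`runDoseResponse()`): objective and tracked fluxes
  along a dose grid, optionally under the secretion cap. Infeasible dose
  points are recorded with their status and skipped.
* **Mechanism profiling** (`profileSecretionAbsorption()`,
  `runKnockoffScan()`): per-metabolite microbe→lumen secretion and
  lumen→host absorption from one parsimonious solution; knock-off
  (`knockOff()`) zeroes both bounds of one reaction at a time and records
  the objective drop and the readjustment of the other exchanges.
* **Collection screening** (`screenCollection()`): per organism model and
  prebiotic, a utilization call (component exchange present *and* maximal
  growth improves beyond a relative tolerance of $10^{-6}$) and the
  maximum secretion flux of acetate, lactate and pyruvate over the dose
  grid (default 21 points over 0–10 g, the accepted safe dose range).
  Two secretion objectives are offered because the choice is genuinely
  underdetermined: `"potential"` maximizes each metabolite's exchange
  directly (an upper bound on what the organism could secrete) and
  `"growth"` maximizes biomass and reads secretions from the parsimonious
  solution (what growth-optimal metabolism would secrete). They answer
  different questions and can disagree strongly — in the toys, a
  growth-optimal fructan fermenter secretes nothing.
* **Flux modes and subsystems** (`extractFluxModes()`,
  `subsystemFluxChange()`): per-dose activity flags along the
  absorbed-acid → acetyl-CoA → 7-DHC pathway, and the subsystem statistic
  $\text{fraction} = n_\text{changed} / n_\text{total}$ computed over
  internal host reactions after retaining the top 90 % of changed
  reactions ranked by percent change. "Top 90 %" is read as count-based
  truncation (keep $\lceil 0.9\,n_\text{changed}\rceil$, ties broken by
  percent change then id) rather than a percentile threshold; the
  percentile is configurable.

## What the toy generators emulate — and what they do not

`makeToyHost()` (12 reactions) carries the host route: glucose →
2 acetyl-CoA; absorbed lactate → pyruvate → acetyl-CoA; acetate →
acetyl-CoA; 3 acetyl-CoA → 7-DHC (one lumped step with capacity 5,
the saturation bottleneck); 7-DHC → 25-OH-D3 → secretion (objective).
`makeToyMicrobe()` ferments a fructan with organism-specific
stoichiometry: FP-like (*F. prausnitzii*-like) 1 fructan → 4 lactate +
2 acetate; BT-like (*B. thetaiotaomicron*-like) → 3 pyruvate +
2 acetate; a null archetype lacks fructan machinery entirely. Microbes
also carry cytosolic overflow drains for the acids so that fermentation
does not deadlock when a single secretion route is blocked — the
toy analogue of the internal recycling genome-scale models have. With
the one-to-one toy dose mapping (1 g ⇒ uptake bound 1) the pipeline's
reference numbers are hand-checkable:

```{r reference-numbers}
cm <- makeToyComodel()                       # FP-like microbe, toy diet
objectiveValue(solvePFBA(cm))                                    # 2
supp <- applyPrebiotic(cm, toyFructan(), 1)
objectiveValue(solvePFBA(supp))                                  # 4
objectiveValue(solvePFBA(knockOff(supp, "M_SEC_lac")))           # 8/3
```

The baseline 2 is glucose-limited (3 glucose → 6 acetyl-CoA → 2); at a
fructan bound of 1 the 4 lactate + 2 acetate add 6 acetyl-CoA (4 in
total, a 2-fold gain); knocking off the microbe's lactate secretion
leaves only the 2 acetate usable (8/3, a 33 % drop).

A cofactor-aware host variant (`cofactors = TRUE`, 15 reactions) tracks
ATP and NADH: glycolysis yields ATP, the pyruvate decarboxylase route
yields NADH (re-oxidized to ATP), and both acetate activation and the
acyl-transfer route consume ATP. Energy bookkeeping makes the
parsimonious route choice dose-dependent: below the glycolytic ATP
surplus the ATP-consuming acyl route carries the absorbed pyruvate, and
once ATP demand exceeds the surplus the decarboxylase/oxidative-
phosphorylation mode switches on. This exercises dose-dependent
flux-mode switching as a phenomenon; the *direction* of the switch in a
genome-scale model depends on network-wide energetics that a
hand-solvable toy does not try to reproduce.

What the toys deliberately omit: realistic network size and redundancy,
cofactor balancing in the default family, biomass compositions,
thermodynamic (loop-law) constraints, and any calibration of absolute
fluxes to measured uptake rates. Green tests on the toys therefore
demonstrate the machinery (merging, dosing, optimization, statistics)
and the qualitative phenomena (monotone saturation, organism-specific
secretion, knock-off direction), not quantitative predictions for real
host–microbe pairs. For those, supply downloaded SBML/JSON
reconstructions through `readModel()` and calibrate the gram→flux
constants from their documentation.

## Seeds, sizes and reproducibility

The only stochastic component is `makeToyCollection(n, seed)`, which
draws archetypes (weights 0.4/0.4/0.2) and biomass yields; the caller's
RNG state is saved and restored, and a fixed seed reproduces the written
model files byte for byte. The shipped test-suite and acceptance
problem sizes — 12–35 reaction models, a 50-model screen over a 21-point
dose grid — were chosen so every expected value is independently
checkable (brute-force vertex enumeration up to 15 reactions, an
external LP implementation above that) while the full suite stays
comfortably fast on one CPU.

## Known limitations

* The simplex backend is dense and single-threaded; genome-scale
  co-models (10⁴ reactions) need an external LP solver and are out of
  scope for the bundled analyses.
* Gene–protein–reaction rules are parsed and ignored; no gene knockouts,
  only reaction knock-offs.
* SBML output stores subsystems in reaction notes (the legacy COBRA
  convention) and does not carry the co-model structure annotation; use
  COBRA-JSON (`asCoMetabolismModel(readModel(...))`) when a merged model
  must be reloaded as a co-model.
* One microbe per co-model; communities and dynamic/transit extensions
  (rFBA, dFBA) are not modelled.
* Flux variability analysis is not implemented; degeneracy is handled by
  the parsimonious tie-break only.
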