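---
title: "A Nash-equilibrium model of liver machine perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Nash-equilibrium model of liver machine perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusionNE)
```

## The model

`perfusionNE` treats a metabolic network as a game between enzyme groups.
The network is partitioned into nodes; node $j$ repeatedly solves

$$\min_{\nu_j}\; \frac{G_j}{RT}
  = \sum_{i=1}^{C_j} x_{ij}\left(\frac{\Delta G^0_{ij}}{RT} + \ln x_{ij}\right)
  \quad\text{s.t. element/charge balance},\ \nu^*_{-j},$$

where $\nu_j$ are its reaction extents, $x_{ij}$ the mole fractions of its
component set and $\nu^*_{-j}$ the other nodes' current optimal fluxes.
Activities are ideal (equal to mole fractions within the node pool), and
$x\ln x$ is continued by $0$ at $x=0$ so species may be fully consumed.
Standard reaction energies are assembled from per-species formation values,
and temperature enters only through the Gibbs–Helmholtz correction
$\Delta G^0(T)/RT = \Delta G^0(T_0)/RT_0 + (\Delta H^0/R)(1/T - 1/T_0)$
with $T_0 = 298$ K. A Nash equilibrium — every node optimal given the
others — is computed per time step by successive substitution: the nodes
are swept in a fixed (file) order, each re-optimising from the current
running state so the state stays feasible throughout; the sweep stops when
the 2-norm of the flux change falls below $\varepsilon = 10^{-3}$ (the
norm covers both the transport tear-streams and the chemical extents,
because nodes are also coupled through shared cofactor pools). Because
every node minimises the same ideal-mixture free energy, the sweep is
block-coordinate descent on a convex potential, and on small test networks
the fixed point coincides with whole-network Gibbs minimisation — a
property the test suite checks against brute-force grids and closed-form
equilibrium constants.

The inner node problem is solved exactly by cyclic coordinate descent
(compiled C++): along one extent the derivative
$\sum_i S_{ir}(g_i + \ln x_i)$ is monotone, so each coordinate step is a
safeguarded bisection over the feasible interval given by non-negative
amounts, irreversibility, and any capacity bounds. The solve is
deterministic and monotonically non-increasing in the objective from the
always-feasible zero extent. If the undamped sweep oscillates, the
increments are damped (factor 0.5, then 0.25, late in the budget); a
small-but-growing increment (an exchange cycle bootstrapping from a trace
pool, e.g. adenylate recovery after deep depletion) is deliberately not
treated as convergence.

## The reduced liver network

The full-scale network this analysis is modelled after is not publicly
available, so the package ships a reduced fixture built by
`buildReducedLiverNetwork()`: 53 species in three compartments
(extracellular, cytosol, mitochondrion) and 19 lumped chemical reactions —
glycolysis to pyruvate plus lactate dehydrogenase, pyruvate dehydrogenase
and a lumped Krebs cycle, oxidative phosphorylation (P/O = 2.5) with an
explicit electron-leak channel, the purine degradation chain
(adenosine → hypoxanthine → xanthine → urate) releasing superoxide, the
superoxide dismutase / catalase / glutathione peroxidase chemistry,
glutaminase and glutathione synthesis, the committed (irreversible)
malonyl-CoA step with lumped fatty-acid synthesis, mevalonate synthesis as
the bile proxy, adenylate kinase, a capacity-bounded maintenance ATPase,
and carbonic-anhydrase CO₂/bicarbonate buffering — plus 14 transports and
a per-node protonation equilibrium. Every reaction is element- and
charge-balanced (charge is carried as a pseudo-element, so one matrix
covers both constraints), and the test suite verifies every balance.

Two modelling conventions matter:

* **Buffered protons.** The free proton pool at pH 7.4 is ~10⁻⁵ nmol/cell,
  six orders below metabolic turnover, so macro-scale reactions exchange
  protons with an explicit buffer pair (an imidazole-like conjugate
  acid/base with ~8 nmol/cell on each side) — the standard biochemical
  convention that reactions see buffered protons. The free H⁺ species
  remains the pH readout and the substrate of the dismutation and
  carbonic-anhydrase steps, tied to the buffer ratio by per-node
  protonation equilibria.
* **Pooled cofactors.** Mitochondrial reactions draw on pooled cytosolic
  ATP/ADP/NAD(H)/phosphate, a deliberate lumping that avoids doubling the
  cofactor species without changing any balance.

### Fixture thermodynamics

Formation values are solved once (the generator is kept under `data-raw/`)
and frozen in the package. In a mole-fraction equilibrium model the
operative quantity is the *effective* driving force
$\Delta G/RT + \ln Q$ at the operating composition — trace species
contribute tens of units through $\ln Q$ — so the calibration specifies
effective driving forces at 310 K at a reference liver composition, plus
apparent (van 't Hoff) reaction enthalpies, and back-solves exact
per-species values. Anchors held exactly:

* the glutathione peroxidase reaction enthalpy is −196 kJ/mol, and its
  stoichiometry removes one peroxide per two glutathione, producing two
  waters;
* ATP hydrolysis is −30.5 kJ/mol (so the energy to make ~1 nmol/cell of
  ATP, ~3×10⁻⁸ kJ, exceeds the ~2×10⁻¹² kJ released by scavenging the
  ~10⁻⁵ nmol/cell peroxide load by about four orders of magnitude — the
  reason glutathione supplementation cannot perturb the optimal warming
  policy);
* one exact thermodynamic cycle (clean O₂ reduction equals the
  leak + dismutation + catalase route plus five ATP syntheses plus four
  buffer releases) constrains the leak channel's values.

The large positive apparent enthalpies of the catabolic lumps (e.g.
+142 kJ/mol for oxidative phosphorylation, +195 kJ/mol for mevalonate
synthesis) are not literal formation enthalpies: they are the only route
by which temperature enters an equilibrium-seeking model, and they encode
the kinetic cold-suppression (Q10-like activation) of lumped pathways, so
that cold storage stalls metabolism and warming re-activates it. The
exothermic ROS reactions keep their physical sign, which makes the
glutathione channel the dominant scavenger in the cold. Catalase
additionally carries a strongly cold-suppressed throughput capacity
(2×10⁻³ nmol/cell/step at 37 °C, Q10 = 20, i.e. effectively off below
~20 °C): with catalase saturated at cold steps, marginal peroxide loads —
including an injected perturbation — fall on glutathione peroxidase, as
they do in the mitochondrial matrix, which is what makes GSSG production
increase and [GSH]/[GSSG] decrease monotonically with the perturbation.

## The protocol engine

`simulatePhase()` advances hourly steps (configurable). Each step:

1. sets the temperature from the schedule (constant or a monotone
   `TemperaturePolicy`);
2. during perfusion, replenishes extracellular oxygen to the perfusate
   supply level (4 nmol/cell by default) and tops up the aqueous solvent
   (media tables list solutes only);
3. injects the phase's superoxide source — during hypoxic cold storage a
   fixed forced extent (2×10⁻⁴ nmol/cell/h, clamped by substrate and
   residual-oxygen availability) through the purine-degradation chain;
   during perfusion, electron leakage at exactly 2 % of the oxygen
   consumed that step, applied after the equilibrium pass and followed by
   a generous re-equilibration of the ROS node;
4. applies cytochrome-oxidase dysfunction as a multiplicative attenuation
   $\varphi = \exp(-k\,(c - c^\*)/c^\*)$ of the oxidative-phosphorylation
   capacity above the stress threshold $c^\* = 3\times10^{-8}$ M
   (default steepness $k = 0.002$ — deliberately gentle, see Limitations);
5. caps the maintenance ATPase at its temperature-scaled rate
   (0.45 nmol/cell/h at 37 °C, Q10 = 2.2);
6. runs the Nash-equilibrium iteration and records the biomarker panel
   (energy charge by the adenylate convention, pH from the proton pool,
   lactate, [H₂O₂], [O₂⁻], GSH pools and ratio, cumulative oxygen,
   glutathione and ATP bookkeeping).

Amount/concentration conversions use the per-cell volume implied by the
perfusate table's internally consistent glutamine row
(0.1111 nmol/(cell·mM)). The media tables are reproduced verbatim,
including rows whose printed molarity disagrees with g/L ÷ MW; those are
flagged `asPrinted` and never silently corrected, and the recomputed value
is always available through `molarityFromMassConc()`.

## The optimisers

`optimizeTemperature()` proposes monotone warming schedules by adding a
half-normal increment (scale 4 °C) to a random suffix of the incumbent,
clamped to [16, 37] °C — monotone by construction. Acceptance requires a
strict increase of the return
$R = w_1\,\mathrm{Glu} + w_2\,\mathrm{ATP} + w_3\,\mathrm{Mev} + w_4\,\mathrm{EC}$,
viability (lactate ≤ 2.3 mM and pH > 7.3, inclusive and strict exactly as
written) and all six physiology criteria. The weights are not prescribed
anywhere, so the default normalises each metric by its magnitude in the
baseline run and then weights them equally; they are exposed in the
configuration. Ties in $R$ reject. The model's optimal schedules warm
gradually: early cold steps guard the lactate constraint while late warm
steps pay off in glucose turnover, ATP and bile-proxy synthesis.

`minimizeGsh()` searches the supplement range
$[2.22\times10^{-5}, 25.2\times10^{-5}]$ nmol/cell with a shrinking Monte
Carlo envelope: proposals are uniform between the lower bound and the
incumbent best feasible point, feasibility meaning end-of-perfusion
mitochondrial [H₂O₂] inside $[10^{-9}, 10^{-8}]$ M, each evaluated by a
full simulation. The search stops at a 10⁻⁶ nmol/cell resolution and snaps
to the lower bound when the bound itself is feasible; if even the upper
bound fails, the infeasibility is flagged rather than hidden. Both
optimisers draw from private seeded RNG streams, so identical seeds give
bit-identical traces.

The two optimisations are decoupled, and the energy-scale argument above
explains why this costs nothing: the heat of the glutathione–peroxide
chemistry is four orders of magnitude below the ATP economy that drives
the return function.

## Design choices and numerical conventions

* Initial transport/feedback flux estimates default to zero; the node
  sweep order is the file order, fixed for determinism.
* Irreversibility is an extent lower bound of zero, not a penalty. The
  catabolic lumps, the ROS-removal steps and the biosynthetic (fatty-acid,
  mevalonate) lumps are irreversible — committed directions, which also
  keeps the physiology criteria meaningful.
* The electron-leak reaction is bookkeeping for the prescribed 2 %
  diversion: its spontaneous extent is capped at zero and it runs only as
  the forced injection, so "superoxide-forming O₂ = 2 % of O₂ consumed"
  is an exact per-step identity.
* Capacity bounds are per step; under the incremental sweep they are
  debited against the extents already accumulated.
* The inflammation sweep pins the oxidative-phosphorylation capacity to
  the unperturbed run's per-step extents, so the sweep isolates the
  dysfunction response from thermodynamic side effects of the scrubbed
  peroxide (catalase releases oxygen).
* Problem sizes: hourly steps (6 SCS + 8 MP), 200 Monte Carlo iterations
  by default, ~80 outer sweeps per equilibrium step; a full protocol run
  takes on the order of a second, a full 200-iteration policy
  optimisation a few minutes.
* Units: kJ/mol for formation data, nmol/cell for amounts, Kelvin
  internally with Celsius at the interfaces; conversions happen only at
  interfaces.

## What the synthetic network does and does not show

The fixture emulates the pathway structure, the ROS chemistry with its
published concentration bands, the exact stoichiometric identities of the
glutathione channel, the 2 % leak bookkeeping, the viability and
physiology gates, and the qualitative responses: ATP and glutathione fall
in cold storage; perfusion restores the energy charge; accepted policies
warm gradually; [GSH]/[GSSG] falls and oxygen consumption, ETC ATP and
energy charge fall as the peroxide perturbation grows. It does not
reproduce the absolute fluxes of the full-scale network (our oxygen and
GSSG turnover are one to two orders smaller), and three behaviours are
deliberately scale-limited:

* the minimal glutathione supplement stays at its lower bound across the
  sub-stress perturbation range — in this reduced network the equilibrium
  scavenging chemistry always restores the band when any glutathione is
  present, so the minimum is only weakly (not strictly) increasing in the
  perturbation;
* the dysfunction steepness is calibrated gentle so that the oxygen
  response stays monotone without overwhelming the glutathione
  stoichiometry; severe-inflammation behaviour is directionally right but
  quantitatively muted;
* pH and lactate derive from the tracked proton pool and the lactate
  branch of the reduced glycolysis — reasonable conventions, but not
  validated against perfusate chemistry.

Passing the test suite therefore certifies the method — the equilibrium
solver, the protocol bookkeeping, the optimiser contracts and the
directional physiology — not a quantitative reproduction of any particular
liver.
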