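---
title: "Rule-based modeling and network-free simulation with rbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based modeling and network-free simulation with rbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbnet)
```

## The modeling problem

Signaling proteins carry multiple binding domains and multiple sites of
post-translational modification. Because sites combine independently, the
number of distinct chemical species that a handful of proteins can form is
astronomically larger than the number of proteins: a receptor with one
ligand site and six phosphotyrosines, each of which can be empty,
phosphorylated, or occupied by one of a few nested adapter complexes,
already has hundreds of thousands of possible states, and a dimer has
billions. Writing one differential equation per species is hopeless; this
combinatorial complexity is the reason rule-based modeling exists.

A rule-based model replaces the species list by a set of *molecule types*
(typed graphs of components with internal states) and *rules*. A rule is a
pattern-rewriting statement: any collection of molecules matching the
reactant patterns can undergo the rule's transformation (bond formation or
removal, a state flip, synthesis, degradation, transport), and every
reaction in that class shares one mass-action rate constant. The reaction
network is defined implicitly, and the simulators never need to enumerate
it.

rbnet implements this formalism end to end: a plain-text dialect for model
files, site-graph pattern matching, two stochastic simulation engines with
complementary cost profiles, exact state-space counting, physically
constrained parameter-ensemble sampling, and the post-processing used for
site-specific phosphorylation time courses (max-normalization,
average-linkage Pearson clustering, contact-map extraction).

## Site graphs, patterns, and matching

A species is a connected graph of molecule instances; each component
carries a concrete internal state and at most one bond. A pattern may leave
states unspecified, mention only some components, and use three bond
wildcards: unbound (no marker), bound-to-anything (`!+`), and unspecified
(`!?`). A component mentioned without a bond marker means *unbound* — this
convention is load-bearing: `A(b)` matches only free `A`, which is exactly
what a binding rule's reactant means.

`find_embeddings()` enumerates injective structure-preserving maps of a
pattern into a concrete mixture. Symmetric duplicates are counted
(a pattern `A(b!1).A(b!1)` embeds twice into one dimer); rate laws divide
by the automorphism count of the full reactant side instead, which is the
standard convention that keeps an `A + A` rule from double-counting
unordered pairs. The matcher anchors on one pattern molecule and forces the
rest through bonds, so its cost is local; a vectorized fast path covers the
ubiquitous single-molecule patterns.

Species identity uses a canonical label: iterative neighborhood (color)
refinement followed by exhaustive tie-breaking among refined color classes,
taking the lexicographically minimal serialization. Signaling complexes are
small chains and trees (tens of molecules), where refinement almost always
separates molecules after one round because bonds record which *component*
they attach to; residual classes (e.g. the two protomers of a symmetric
dimer) are tiny, so the factorial tie-break is cheap. A cap of 20,000
candidate orderings guards against pathological symmetric inputs; hitting
it is an error, not a silent approximation.

## The two simulators

### Network-free (particle-based)

`simulate_network_free()` tracks every molecule instance. Per rule and
reactant pattern it maintains the current embedding list; the total rate is

    sum over rules of  k * n1 [* n2 or * (n1 - 1)] / symmetry factor

with embedding counts `n`. Each event draws an exponential waiting time at
the total rate, picks a rule proportionally, and picks embeddings
uniformly. Two deliberate conventions:

* **Null events.** For 2-reactant rules the embeddings are drawn
  independently; if they land in the same complex the clock still advances
  but nothing changes. This rejection step is what makes the algorithm
  exact while enforcing that bimolecular rules describe inter-complex
  events (ring closure is out of scope).
* **Local index updates.** After an event, only embeddings touching the
  affected complexes are discarded and re-matched. Because reactant
  patterns are connected, an embedding can never straddle complexes, so
  this locality is exact — the test suite re-verifies the incremental index
  against a from-scratch recomputation after hundreds of events.

The per-event cost therefore depends on the number of particles, rules and
components, never on the size of the implied network.

### On-the-fly (population-based)

`simulate_onthefly()` is a Gillespie direct-method simulator over a lazily
generated network: species are canonical labels with populations, and a
species is rule-expanded only when it first becomes populated. Reaction
channels carry embedding multiplicities and the same symmetry factors as
the network-free engine, so both simulators sample the same Markov process
— the package's central cross-check, asserted on toys where means must
agree within Monte-Carlo error, and against an exact master-equation
solution on a small binding system.

On combinatorially complex models lazy expansion is exactly what fails, by
design: the generated network grows superlinearly with simulated time
until the species cap stops growth gracefully (`capped` flag, partial
results). The census output (populated species, generated species,
generated reactions per sample time) quantifies this. Both "currently
populated" (population >= 1 at the sample instant) and "ever generated"
counts are exported, since either reading of a populated-species census is
defensible.

### Protocols, equilibration, and compartment scaling

A protocol is an equilibration phase (simulated before time zero, no
sampling, no automatic steady-state detection — the burn-in length is the
caller's choice, since no convergence criterion is universally valid)
followed by species additions at time zero, given as copies or as a molar
concentration converted through a 3-D compartment's effective volume
(`round(conc * N_A * volume)`). The `scale` argument implements
compartment scaling: seed and added copy numbers are multiplied by `scale`
(rounded half to even — deterministic and unbiased) and 2-reactant rate
constants divided by it, which is the correct transformation for per-cell
bimolecular units.

## Exact state-space counting

The counting module formalizes the "how many states can this receptor
have" calculation. A docking site is described by its unbound states (one,
or two when phosphorylatable) plus the set of distinct adapter complexes
that can occupy it, enumerated recursively: a binder has its own
modification states and child sites, each child site independently empty
or occupied, possibly gated on the parent's modification state (GRB2 binds
SHC1 only when SHC1 is phosphorylated). The canonical specifications ship
with the package:

```{r counts}
length(enumerate_site_states(shc1_site_spec()))   # 8
length(enumerate_site_states(grb2_site_spec()))   # 6
length(enumerate_site_states(pi3k_site_spec()))   # 3
count_dual_site(list(grb2_site_spec("Y1114"), shc1_site_spec("Y1114")))  # 12
count_monomer_states(egfr_state_spec())           # 2*8*6*8*12*6*6
count_monomer_states(erbb3_state_spec())          # 2*3^6*8
count_dimer_states(egfr_state_spec(), erbb3_state_spec())
count_dimer_states(egfr_state_spec(), egfr_state_spec())
```

A heterodimer multiplies the monomer counts; a homodimer's protomers are
indistinguishable, so its states are unordered pairs with repetition,
`n(n+1)/2` — the only convention under which the two protomers are not
double-counted. All arithmetic is exact: counts live in the exactly-representable
double-integer range (below 2^53, comfortably containing every quantity
the package asserts) and the code aborts rather than round beyond it.

## Parameter ensembles and detailed balance

Model parameters fall into six feasibility classes (bimolecular
association 1e-7–1e-5 per molecule per second on a per-cell basis,
unimolecular dissociation 1e-2–1, phosphatase-catalyzed, receptor
trafficking and endocytic degradation 1e-3–1e-1 per second, copy numbers
1e4–1e6 per cell). `sample_parameters()` draws each class-assigned
parameter log-uniformly within its range — the ranges span orders of
magnitude, so uniform-in-log is the scale-free choice — rounds copy
numbers to integers, and never lets association constants exceed the
diffusion cap (configurable; default the class upper bound, since the
physical cap in per-cell units depends on unstated volumes).

Thermodynamic consistency: around any cycle of reversible binding
reactions the product of equilibrium constants must be one. The
implementation finds cycles rigorously as the dependent columns of the
stoichiometric matrix built from one representative generated reaction per
reversible binding pair (a bounded eager expansion of the network from the
model's seeds); QR column selection plays the role of the spanning tree.
Tree pairs keep their sampled constants; each cycle-closing pair's
dissociation constant is reset to close its cycle exactly. Catalytic,
trafficking and degradation rules are exempt — they are irreversible,
energy-consuming steps, the standard scope for this constraint. If a
closing constant cannot be kept inside its class range the set is rejected
and redrawn whole, so the delivered ensemble is log-uniform *restricted to
the thermodynamically feasible region*; an independent audit recomputes
every fundamental-cycle product from scratch (tolerance 1e-9) for every
emitted set.

## Clustering and contact maps

Phosphorylation time courses are compared after dividing each by its own
maximum (all-zero rows stay zero and are flagged). Rows are then ordered
by agglomerative average-linkage clustering under the distance
1 − Pearson correlation. Ties are broken deterministically — among equally
close pairs, the one containing the lowest original row index merges first
— because reproducible output matters more than matching any particular
renderer's internal order; constant rows, for which correlation is
undefined, are segregated and appended. The implementation is checked
against `stats::hclust` (merge heights and cophenetic matrices) on
tie-free random matrices.

`extract_contact_map()` reduces a rule set to the structure a contact-map
drawing shows: one undirected binding edge per distinct component pair
that any bond-forming rule touches (contextual refinements collapse into a
multiplicity count), and one directed enzyme–substrate edge per catalyzed
state change. The enzyme is the other reactant-pattern molecule when
exactly one exists; rules whose catalyst is implicit in a bound-any
context carry an explicit `@enzyme=Name` suffix in their name. Transport,
degradation and uncatalyzed state changes are listed as unmapped, so every
rule is accounted for. Writers emit deterministic GraphML, DOT and JSON.

## Synthetic data: what the fixtures do and do not emulate

The toy models (`build_toy()`) exist because their behavior is known in
closed form or by exhaustive enumeration: the 3-species binding
equilibrium, the symmetric isomerization, `A + A` dimerization for the
symmetry factor, the 2^3 phosphoforms of a 3-site receptor, a linear
assembly chain, and a two-site receptor whose context-dependent binding
rules form exactly one thermodynamic cycle. Their default conditions
(copies of order 100, association 5e-4, dissociation 0.1) put them in the
regime where the mean-field equilibrium is within a small fraction of a
standard error of the stochastic mean, so closed-form checks are
meaningful.

`build_erbb_mini()` is an original reduced ERBB signaling model authored
for this package: EGF and HRG ligands, EGFR and ERBB3, ligand-gated
dimerization, transphosphorylation of the 13 receptor tyrosines in dimer
context, phospho-gated recruitment of SHC1 (with its own phosphosite and
GRB2 relay), GRB2 with independent SOS1/GAB1 arms, PI3K on the six ERBB3
sites; tier 2 adds per-site dephosphorylation, a Ras→RAF→MEK→ERK backbone,
a PI3K→Akt arm, and ERK-dependent negative feedback on SOS1. The receptor
site layout projects exactly onto the counting specifications above, which
pins the fixture to the canonical state-space arithmetic. It is *not* a
transcription of any full-scale model file: rate constants are mid-class
defaults (kinase steps 1 s^-1; the feasibility-class table has no
kinase-catalysis row, so that constant is marked unclassed), copy numbers
default to 1e4 per protein (the low end of the feasible class, keeping
desk-scale particle simulation tractable), and no biological conclusions
should be drawn from its dynamics. What passing tests on these fixtures
demonstrates is the correctness of the machinery — matching, rates,
symmetry, thermodynamic constraints, cost scaling — not the biology of any
real cell line.

## Numerical and design choices

* Determinism: every stochastic entry point takes a seed and draws all
  choices from R's generator in a fixed order; identical inputs give
  byte-identical outputs.
* Detailed-balance tolerance 1e-9 (relative, on cycle products); QR rank
  decisions at LAPACK defaults.
* Canonical labeling cap: 20,000 tie-break orderings.
* Exact-count guard at 2^53.
* Event clock: an event drawn beyond a sampling boundary is discarded and
  the clock clamped, which is exact by memorylessness.
* Null events advance time (rejection sampling); they are counted
  separately in trajectory metadata.
* Problem sizes in the shipped tests: toys at 40–100 copies with 100–200
  replicate runs for distributional checks; the exact master-equation
  check at 12+12 molecules; matcher properties on ~500 random instances of
  at most 6 molecules; the ERBB cost-scaling runs at compartment scale
  0.01 with 5 nM ligand doses (network-free to 60 s; on-the-fly to 12 s
  with a 2,000-species cap). These sizes were chosen so the full suite
  documents the claimed properties at desk scale.

## Known limitations

* Mass-action rate laws only; no functional/Hill rates, no energy-based
  rule refinement.
* Bimolecular rules are inter-complex by definition; intramolecular ring
  closure is not modeled.
* Compartments are molecule attributes with transport as a state change;
  no membrane-adjacency topology is enforced.
* The on-the-fly engine is a linear-scan direct method — deliberately
  simple, since its scientific role here is oracle and contrast, not
  production performance.
* The dialect is a documented BNGL subset (no functions, no fixed species,
  no explicit DeleteMolecules keyword; deletion is inferred from the rule
  diff).
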