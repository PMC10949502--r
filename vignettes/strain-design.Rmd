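---
title: "Constraint-based strain design on a C. glutamicum core network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based strain design on a C. glutamicum core network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgflux)
```

# The modelling problem

Pyruvate sits at the junction of glycolysis and the TCA cycle, and every
pyruvate-derived product (L-alanine, L-valine, L-leucine) competes with
pyruvate oxidation for carbon. `cgflux` implements the computational side
of model-guided producer design for *Corynebacterium glutamicum*:
steady-state flux simulation, a reaction-essentiality taxonomy that tells
the engineer which reactions to delete, attenuate or leave alone, product
yield ceilings, attenuation sweeps, and the sequence design of antisense
sRNAs used to downregulate essential targets.

All flux computations share one mathematical object, the stoichiometric
steady state

$$S\,v = 0,\qquad l \le v \le u,$$

where $S$ is the metabolites-by-reactions stoichiometric matrix, $v$ the
flux vector (mmol/gCDW/h) and $l, u$ the flux bounds. Exchange reactions
carry the sign convention that is standard across constraint-based
tools: uptake is negative flux, so a glucose uptake cap of 4.67
mmol/gCDW/h is imposed as a lower bound of $-4.67$ on the glucose
exchange. Oxygen uptake is unrestricted (a wide finite bound of 1000 is
used as practical infinity throughout).

## The three solvers

**FBA** maximises one flux (the objective reaction) over the steady-state
polytope — a single linear programme.

**FVA** holds the objective at a fraction of its optimum and minimises
and maximises each flux in turn ($2N$ LPs). The fraction applies
multiplicatively to a positive optimum and as-is to a zero optimum,
because a fraction of zero is zero.

**Geometric FBA** resolves the degeneracy of alternate optima. The FBA
optimum is pinned, then iteratively: (i) compute FVA intervals, (ii)
find the flux vector of minimal L1 distance to the interval midpoints,
(iii) restrict each flux to the segment between that vector and the
midpoint, and repeat until the widest interval falls below
$\sqrt{\texttt{lp\_tolerance}}$ (default $\sqrt{10^{-9}} \approx
3\times10^{-5}$), with an iteration cap of 30. The fixed point is a
unique central distribution: it is invariant under reaction reordering
(no step depends on order) and commutes with a common positive rescaling
of stoichiometry and bounds. On a symmetric two-branch diamond it returns
the 5/5 split.

The L1 step is itself an LP (deviation variables $v_j - p_j + q_j =
m_j$, $p,q\ge0$); deviation variables are only created for reactions
whose interval is still wide, and FVA skips reactions already pinned, so
later iterations are cheap.

## The LP engine

No linear-programming package is assumed; the package carries a dense
bounded-variable two-phase revised simplex. Design points that matter
for reproducibility:

* deterministic pricing (largest reduced-cost violation, ties by column
  order) with Bland's rule engaged after a run of degenerate pivots, so
  cycling cannot occur and a fixed problem always returns the same
  vertex;
* explicit basis inverse with periodic refactorisation and a final
  re-solve of the basic system, keeping residuals near machine
  precision;
* feasibility/optimality tolerance `lp_tolerance` ($10^{-9}$ by
  default), also used row-wise on $|S v|$;
* infeasible and unbounded problems are reported as statuses, not
  errors, because genotype screens legitimately produce zero-growth
  (infeasible-floor) scenarios.

The test suite validates the engine against an independent brute-force
oracle: exhaustive enumeration of basic solutions of the flux polytope
on small random networks (over 100 seeds), for both the FBA optimum and
the FVA interval endpoints.

# The essentiality taxonomy and regulation modes

At the production optimum (see below), each reaction's FVA interval
$(v_{\min}, v_{\max})$ is classified, after rounding values within
$\varepsilon$ (default $10^{-6}$) to zero:

* **blocked** — both endpoints zero;
* **essential** — the interval excludes zero ($v_{\min} v_{\max} > 0$);
* **substitutable** — otherwise (the interval spans or touches zero
  with nonzero width).

The textbook form of the essential rule ("nonzero flux with identical
minimum and maximum") misses required-but-variable reactions such as an
interval $(1, 5)$; the interval-excludes-zero rule subsumes it and makes
the three classes a true partition, which the tests assert on every
model.

Regulation modes compare the growth state (biomass objective,
geometric FBA) with the production state (product objective under the
biomass floor, geometric FBA): **U** when production flux magnitude
exceeds growth flux magnitude, **D** when an essential reaction carries
less flux in production than in growth, **KO** when a substitutable or
blocked reaction carries no production flux, **none** otherwise. KO
extends the U/D vocabulary to the deletions an engineer actually
performs on dispensable drains. Note that a reaction with zero flux in
both states is classified KO when dispensable — dispensability, not the
growth/production flux difference, is what licenses a deletion.

**Which states feed the comparison** is a genuinely open design
choice; this implementation uses geometric-FBA central states for
both, because vertex solutions of degenerate optima would
make the U/D assignment an artefact of the solver's tie-breaking.

**The production state** is: biomass $\ge f \times$ (max biomass) with
$f = 0.2$ by default, product export maximised, FVA at objective
fraction 1.0. The alternative reading "biomass fixed at exactly 20%" is
noted but not implemented; at the product optimum the floor is active
anyway, so the two coincide there.

# Theoretical yields

`max_theoretical_yield()` computes the stoichiometric ceiling: substrate
uptake fixed at 1, biomass floor and ATP-maintenance demand released,
product export maximised. Maintenance is ON for production simulation
and OFF for theoretical yields — a "theoretical maximum" is a
stoichiometric, not a physiological, quantity. On the bundled core
model the ceilings are exactly

* L-alanine 2.00 mol/mol (glucose → 2 pyruvate → 2 alanine,
  redox-closed through alanine dehydrogenase),
* L-valine 1.00 mol/mol (2 pyruvate per valine, one CO₂ released at
  acetolactate synthase),
* L-leucine 2/3 mol/mol (2 pyruvate + 1 acetyl-CoA per leucine; the
  acetyl-CoA costs a third pyruvate through PDH, and 3 CO₂ are released
  per leucine overall),

each verified in the acceptance suite together with the carbon-
conservation bound (yield × product carbon ≤ 6).

# The attenuation sweep

The sweep emulates promoter attenuation of one reaction (aconitase in
the worked example). The control is the production state; the target's
control flux defines caps $r \times v_{\mathrm{ctrl}}$ for $r$ from 1.0
down to 0.1. Each row is solved lexicographically: maximise biomass
under the cap, then maximise the product at that biomass, then centre
the remaining degeneracy with geometric FBA.

This design was chosen over the naive alternative (re-solving the
biomass-floored production problem with the cap) deliberately: at the
production optimum the aconitase flux is pinned to exactly the
biomass floor's glutamate demand, so any cap below the control makes
the floored problem infeasible and the sweep would be vacuous. With
biomass re-maximised under the cap, the $r = 1$ row provably reproduces
the unswept production state (the cap is exactly the control flux, so
maximal biomass equals the floor and maximal product equals the
control product), and as $r$ falls the biomass ceiling falls linearly
with the cap while the product rises — the growth-versus-product
trade-off the attenuation experiment probes. The cap is an upper bound,
not an equality (`cap_mode = "equality"` exists behind a flag), because
attenuating an enzyme lowers capacity rather than prescribing flux.

Relative fluxes divide each row by the control; $0/0$ is defined as 1
("no change"), matching the no-change encoding of attenuation heat
maps.

# The core model

No genome-scale reconstruction ships with this package; the generator
instead builds a curated central-carbon core network (61 reactions, 50
metabolites) that emulates genome-scale behaviour at reduced scale. Subsystems: PTS and permease/glucokinase
glucose uptake, glycolysis/gluconeogenesis (with fructose
bisphosphatase and PEP carboxykinase), oxidative and non-oxidative PPP,
PDH, full TCA cycle, glyoxylate shunt, pyc/ppc anaplerosis, malic
enzyme, lactate (ldhA/lldD) and alanine (alaT/alaD) drains, the
ilvBN→ilvC→ilvD→ilvE valine branch and leuA→leuCD→leuB→ilvE leucine
branch, pta/ackA acetate metabolism, lumped respiration, a biomass
pseudo-reaction and an ATP-maintenance pseudo-reaction. The full
inventory with formulas, bounds, gene tags and subsystems can be
exported with `write_model(model, "core.tsv", "tsv")`.

Design choices a reader should know:

* **Elemental bookkeeping covers C and N only** — the elements that
  govern every yield claim. Carrier moieties netted out of all
  reactions (CoA, NAD(P)H, adenine nucleotides, menaquinone) carry
  zero counts; `check_mass_balance()` verifies every internal reaction
  and returns an empty table on the generator output.
* **NADPH supply.** Besides the oxidative PPP and isocitrate
  dehydrogenase, the model carries malic enzyme. The
  pyc→malate-dehydrogenase→malic-enzyme cycle converts NADH + ATP into
  NADPH without carbon loss — the canonical NADPH route in
  *C. glutamicum* flux models. Without it the valine ceiling would sit
  at 6/7 mol/mol (oxidative-PPP CO₂ loss), not at the correct 1.00.
* **Glyoxylate shunt present but closed** (bounds 0) on glucose, open
  on acetate medium and in the evolved genotype preset — reproducing
  its transcriptional repression on glucose without a regulatory model.
* **Lactate and alanine drains.** Both directions of lactate turnover
  exist (NADH-dependent ldhA and quinone-dependent lldD), and alanine
  can be made by transaminase (alaT) or dehydrogenase (alaD). These
  pairs are genuine *C. glutamicum* enzymes, and they are what makes
  ldh/alaT substitutable rather than blocked at the production
  optimum: redox slack can flow through the lactate pair, and the two
  alanine routes substitute for each other (the alaT FVA interval
  spans zero).
* **Biomass composition is invented** (no composition is published at
  core scale): round-number demands of G6P (0.3), R5P (0.2), E4P
  (0.1), PEP (0.6), pyruvate (1.5), acetyl-CoA (1.2), OAA (0.9),
  glutamate (1.2), alanine (0.3), NADPH (6) and ATP (40) per biomass
  unit. The ATP coefficient was set so that the growth optimum carries
  a respiratory TCA burden exceeding the production-state TCA flux,
  which reproduces the qualitative downregulation (D) calls for
  aceE/gltA/acn/icd. Because the composition is invented, **absolute
  growth-rate numbers are not reproduction targets** — only
  zero/nonzero growth and orderings are asserted anywhere in the
  package.
* **Maintenance ATP defaults to 0** (yield mode); 2.0 mmol/gCDW/h is a
  reasonable growth-mode convention, settable via
  `build_core_model(maintenance_atp =)`. The maintenance reaction's
  upper bound stays open so surplus ATP can always be dissipated.
* **icd attenuation** (the evolved R543S allele, ~80% activity loss) is
  modelled purely as scaling the reaction bounds by 0.2. With the open
  default capacity (1000) this scaling does not bind — the growth
  rescue in the LEU-29 preset is carried by glyoxylate-shunt
  activation, which is the experimentally identified mechanism. Under
  finite capacity bounds the scaling becomes active.
* **Bifido shunt.** `augment_with_bifido_shunt()` adds the two
  phosphoketolase reactions (F6P + Pi → E4P + AcP; X5P + Pi → G3P +
  AcP). Together with the non-oxidative PPP, triose recombination
  (aldolase + bisphosphatase) and pta, the acetyl-CoA ceiling rises
  from 2 per glucose (PDH route, one CO₂ per acetyl-CoA) to exactly 3
  (no carbon loss); re-augmentation is an error by design.

## What the generator does and does not emulate

Passing tests on the core model demonstrate the *method* — solvers,
taxonomy, sweep and yield machinery — under a network whose central
carbon stoichiometry matches the organism's. They do not demonstrate
genome-scale behaviour: the core model has no transcriptional
regulation, no kinetics or thermodynamics, no gene–protein–reaction
logic (the gene tag is an annotation), a single compartment, and an
invented biomass equation. Yield ceilings that depend only on pathway
stoichiometry transfer to the genome-scale setting (they are upper
bounds of it); flux magnitudes, growth rates and the genome-scale
model's constrained yields (which reflect its additional demands) do
not.

## Toy fixtures

`build_toy_network()` provides a chain (unique optimum 10), a symmetric
diamond (the geometric-FBA midpoint fixture) and seeded random networks
built on a linear backbone (guaranteeing a connected, feasible network
with a positive optimum) with random extra edges — the substrate of the
brute-force solver oracles. Generation localises the RNG so the
caller's seed state is untouched. Test problem sizes: oracle networks
use 4–10 reactions (vertex enumeration is exponential and exact there);
the property suites run the full 61-reaction core model.

# Antisense sRNA design

Coordinates use biological numbering with no position zero: the A of
the start codon is +1 and −1 abuts it, so a window −4..+48 spans 52 nt.
The default binding window is +1..+24, producing a 24-nt antisense
sequence. The two common ways of stating such a window — a 24-bp
binding residue versus a window ending at +21 (21 nt) — disagree by
three nucleotides; this implementation treats the binding-sequence
length of 24 as authoritative. The binding
sequence is the reverse complement of the sense window
(double-reverse-complement identity and GC preservation are property
tests). Non-ATG start codons (GTG/TTG starts occur in
*C. glutamicum*) produce a warning, not an error.

Cassettes assemble binding–scaffold–terminator. The bundled MicC-,
DsrA- and MicF-type scaffold and terminator sequences are
**constructed synthetic stand-ins** (hairpin-plus-U-tract
architecture, labelled synthetic in file names and headers), because
the natural sequences are not part of this package's sources; supply
your own FASTA to use them. Mutating marginal residues to lower the
folding energy requires a folding engine and is out of scope — the
assembly API accepts a user-edited binding sequence instead.

# Degenerate and edge inputs

* Zero-optimum objectives: FVA thresholds switch from multiplicative to
  additive, avoiding the degenerate "fraction of zero".
* Infeasible genotypes (e.g. both anaplerotic routes deleted) return
  status `infeasible` from `fba()` and an explicit error from workflows
  that require feasibility, naming the offending fraction or stage.
* Sweep rows that lose feasibility are recorded as infeasible rows; the
  sweep continues.
* `knock_out()` is idempotent and commutes over disjoint sets; bound
  updates re-validate `lower ≤ upper` immediately.
* Relative fluxes define 0/0 = 1; a nonzero flux over a zero control is
  reported as signed infinity rather than silently clamped.

# Reproducibility

The pipeline (`run_pipeline()`) writes TSV/JSON artifacts with fixed
12-significant-digit formatting and a manifest without timestamps, so
repeated runs on the same host and configuration are byte-identical (a
test asserts this). `scripts/acceptance.R` recomputes the yield
ceilings from scratch against the installed package.
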