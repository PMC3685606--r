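---
title: "Eliciting anatomical communication routes: model, assumptions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eliciting anatomical communication routes: model, assumptions, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physroute)
```

## The problem

Endocrine communication is realised by translocation: a hormone secreted by
cells in one tissue must physically reach a receptor attached to cell
membranes in another. `physroute` makes the route of that translocation
explicit — as an ordered sequence of discrete body compartments, each
crossed under a definite transport modality — by combining two kinds of
knowledge: ground facts about anatomical connectivity (which vessel segment
feeds which, which capillary bed serves which organ, which fluid bathes
which structure) and a small axiomatic theory of physiological
communication between fluid compartments.

## The representation

A knowledge base holds named individuals (compartments, tissues, proteins,
processes) and ground facts over a closed relation vocabulary. Compartment
kinds are tissue structures, tissue fluids, cardiovascular (CVS) portions
(with subkinds: capillary, venule, arteriole, vessel segment, heart chamber,
macro-region), plasma membranes and boundary spaces. Facts are validated at
assertion time: unknown relations, wrong arities and kind clashes (a tissue
fluid in a tissue-argument position, a modality token outside
advection/diffusion/convection) are classed errors. Individuals are
auto-declared on first use with a kind inferred from the relation's argument
signature; explicit declaration can refine it. Exposure (`exp-to`) and
connection (`CONN`) are stored once and matched in both argument orders;
the ternary communication relation `COMM3` is commutative in its first two
positions. Queries return matches in deterministic lexicographic order, so
every downstream artefact is reproducible.

## The rules

Saturation derives, to fixpoint:

* **Post-production location.** A secreted (`Ltec`) product of a tissue
  structure is found, post-production, in that tissue's fluid; a
  plasma-membrane (`Ltpm`) product is found in, and attached to, its
  producer's membrane. A post-production site is a site the protein is
  found in.
* **Exposure.** A tissue's fluid and structure portions are exposed to each
  other; an entity is exposed to the fluid it is found in, to whatever that
  fluid is exposed to, and to every cohabitant of its fluid; a membrane
  product inherits its producer's exposures. Two auxiliary consequences are
  stated explicitly because the endpoint rule needs them and they follow
  from the intended semantics rather than from the numbered axioms alone:
  the membrane of a structure is exposed to any fluid its structure is
  exposed to, and post-production placement counts as being found
  somewhere. Exposure is symmetric and deliberately **not** transitive: a
  membrane is exposed to the cytoplasm on one side and the tissue fluid on
  the other without those two being exposed to each other. The suite
  checks that no transitivity-only consequence ever appears.
* **Communication.** An organ's tissue fluid communicates with the organ's
  capillaries by convection; connected CVS portions communicate by
  advection; every non-capillary, non-chamber vessel communicates by
  convection with its own wall tissue fluid; connected tissue fluids
  communicate by diffusion.
* **Accessibility.** A protein found somewhere can access any compartment
  reachable over communication edges whose modality it is capable of
  (`CMTP_t`); computed as a worklist reachability closure, with the start
  site included only when a cycle re-enters it. Accessibility facts are
  materialised on demand and are not fed back into the post-production
  rules: potential location is not production.

Two design points deserve note. First, the well-mixed reading of advective
communication ("any two CVS portions communicate") is retained only as a
feasibility assumption; the advection facts actually used for traversal are
those along asserted blood-flow connections, which is what makes "shortest
route in the direction of blood flow" well defined. Second, the convective
vessel-wall rule exempts heart chambers as well as capillaries: the tissue
fluid of the atrial wall is the secretion site of the demonstration
hormone, and routes that short-cut from the wall fluid directly into the
chamber lumen are deliberately ruled out, so the elicited route leaves the
wall through its capillaries and veins.

Saturation is implemented as fixpoint iteration over vectorised relational
joins — each pass adds only facts not yet present, and the recursion-heavy
part (accessibility) is a delta-driven worklist — rather than a fully
semi-naive evaluator; at the knowledge-base sizes this package targets
(hundreds to a few thousand facts) the joins converge in two or three
passes. Termination is guaranteed: the rules are function-free over a
finite domain, and a generous iteration guard assert-checks it. The suite
verifies that the result equals a literal repeat-until-fixpoint oracle on
randomly generated knowledge bases, and that re-saturating changes nothing.

## Triage and the subtending translocation

The scenario of a protein pair is a total function of the two
post-production types: any cytoplasmic partner is typed unsupported (such
interactions run through intracellular pathways out of scope here); two
membrane products are typed unsupported (they would require cell
translocation); two secreted products either share a post-production fluid
(`colocated_direct` — co-location requirements are trivially met there) or
can each move (`both_movers`); a secreted product facing a membrane product
is the endocrine case, and only then is a route elicited. The mover is
always the secreted protein: capability facts alone never make an attached
protein a mover. When the explicit location-type fact is absent, the type
is inferred from the kind of the recorded post-production site (tissue
fluid implies secreted; a structure or membrane implies membrane-bound).

The endocrine case guarantees a subtending translocation, skolemised
deterministically (`transloc::int::<mover>::<fixed>`): its object is the
mover, its origin the mover's post-production fluid, its destination the
tissue fluid exposed to the membrane housing the fixed partner. If several
candidate fluids bathe that membrane the situation is reported as an
ambiguity rather than silently resolved.

## Graphs and route construction

Two graphs are built from the saturated knowledge base. The CVS graph is a
directed multigraph whose **edges** are CVS portions and whose nodes are
boundaries between them, obtained by identifying the downstream end of each
portion with the upstream end of every portion it feeds; parallel vessels
persist as parallel edges, and a valid synthetic body forms a single
strongly connected closed circuit. The exchange graph connects tissue
fluids to the vessels they exchange with; each convective communication
fact is one edge, carrying a boundary-space compartment with a
deterministic identifier (`BND::<a>::<b>`, lexicographic order).

Route construction is three legs: the entry point is the CVS portion
nearest the start fluid in the exchange graph (hop count; lexicographic
tie-break), the exit point mirrors it at the destination, and the middle
leg is a shortest directed path in the CVS graph. Edge weights default to 1
per portion — the theory asks only for "shortest", and per-edge overrides
are retained for future anatomical-length weighting. The search is a
Dijkstra variant that, among equal-weight shortest paths, returns the
lexicographically smallest edge-id sequence; with strictly positive weights
this secondary criterion is compatible with the greedy settlement order, so
results are fully deterministic and the suite checks them against
exhaustive path enumeration on small random multigraphs. Entry/exit
selection minimises exchange-graph hops only, not total route length,
keeping the legs independent. Macro-region portions (the pulmonary
circulation, the left heart) are traversed as single edges; an expand
option substitutes each by the shortest path through its member subgraph.

The mover must be capable of every modality its route uses: diffusion
within the terminal fluids, convection across the two boundary spaces,
advection along the bloodstream. Each missing capability fails the
elicitation with a typed error naming the failing stage, as does a
disconnected graph. When origin and destination coincide the route is the
single shared fluid.

## Condensation and footprint

A raw route is summarised by grouping maximal runs of consecutive
compartments belonging to the same vessel (from the compartments' vessel
metadata for generated bodies; from the packaged membership map for the
reference fixture); chambers and macro-regions group on their own.
Flattening the groups reproduces the raw path exactly. The footprint maps
each compartment kind to its modality — tissue fluid to diffusion,
boundary space to convection, any CVS portion to advection — and
run-length encodes the group modalities; it is invariant under refinement
of the grouping, which the suite checks by computing it at compartment,
sub-vessel and vessel granularity.

## The synthetic body generator

No public accession provides the original full-scale connectivity knowledge
base (hundreds of thousands of facts harvested from a reference anatomy
ontology), so the package ships a deterministic generator that emulates its
described shape at desk scale, plus a verbatim transcription of the
published 60-compartment route as a plain-text fixture. The generator's
defaults are the demonstration's study conditions: a 44-segment aorta run
terminating at the left-kidney branch (the printed route's aorta stretch),
a right kidney and a gut branch upstream, a three-segment right-atrium
chamber, a pulmonary macro-region with a small unfoldable member chain, and
the heart wall as a vascularised organ drained by a two-segment
cardiac-vein chain directly into the right atrium — mirroring the printed
route's venous return. Every tissue and non-capillary vessel carries a
tissue fluid, every portion an endothelium structure, every non-capillary
non-chamber portion a smooth-muscle structure, every structure the plasma
membrane of its cells. Generation is a pure function of its parameters
(byte-identical fact files across runs); identifiers follow a documented
scheme (`AO-17`, `CAP-kidney_L`, `TF-ARTL-kidney_L-1`) and tests assert
structure and patterns, never the original publication's segment numbers —
except against the packaged fixture itself.

What the generator does **not** emulate: real cardiac venous anatomy beyond
a generic organ-vein chain, lymphatic return paths, barrier
physicochemistry and patency, anatomical segment lengths (all portions have
unit cost), and the sheer scale of the curated knowledge base. Passing
tests therefore demonstrate the correctness of the reasoning and
construction machinery under realistic topology, not fidelity to any
individual's vasculature.

## Problem sizes and numerical choices

The default body has ~75 CVS portions, ~450 individuals and ~500 asserted
facts, saturating to ~950 facts in well under a second; property suites run
dozens of random bodies (aortas of 2–8 segments, 1–3 organs) and a hundred
random communication graphs. All tie-breaks are lexicographic on
identifiers; boundary identifiers order their two endpoints; the skolem for
a subtending translocation is a pure function of the mover/fixed pair.
There is no randomness anywhere in the pipeline — the generator's `seed`
parameter is recorded for interface stability but topology is entirely
parameter-determined — so identical inputs yield byte-identical JSON.

## Known limitations

Only cardiovascular routes are elicited (no lymphatics, no transcellular or
intracellular legs); no temporal or quantitative transport modelling (no
rates, no barrier permeability); one route per query (alternate or k-best
routes would repeat the same construction); triage treats post-production
types as single-valued per protein. The ambiguity error on multiple
candidate destination fluids is a deliberate refusal to guess.
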