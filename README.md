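# physroute

Eliciting candidate anatomical routes for protein interactions.

A considerable share of endocrine physiology is carried by proteins that
interact far from where they are made: a hormone secreted into the tissue
fluid of one organ must reach a membrane-bound receptor in another. Which
concrete anatomical path — which tissue fluids, capillary walls, veins,
heart chambers, arteries — does that communication follow, and by which
transport modality at each step? `physroute` answers this with knowledge
representation and reasoning: a typed fact store over a closed vocabulary of
anatomical-connectivity and protein-localisation relations, a
forward-chaining rule engine for location, exposure and communication
axioms, and a route-elicitation algorithm over the derived graphs. It is
written for systems physiologists and knowledge engineers who want symbolic,
auditable routes rather than black-box correlations between model variables.

## The theory in brief

Ground facts use relations such as `prod-by` (protein produced by a tissue
structure), `postp_t` (subcellular type of its post-production site: `Ltcyt`
cytoplasm, `Ltpm` plasma membrane, `Ltec` extracellular), `tf-of` / `ts-of`
/ `pm-of` / `cap-of` (a tissue's fluid, structure, membranes, capillaries),
`CONN` (anatomical connection) and `CMTP_t` (the modalities a protein can
move by). Forward rules derive:

* **location** — a secreted product is found post-production in its producer
  tissue's fluid; a membrane product is found in, and attached to, its
  producer's plasma membrane;
* **exposure** (`exp-to`, symmetric, deliberately not transitive) — a
  tissue's fluid and structure portions are mutually exposed; an entity is
  exposed to the fluid it is found in and to whatever that fluid is exposed
  to;
* **communication** (`COMM3(x, y, m)`) — an organ's tissue fluid exchanges
  with its capillaries by *convection*; connected cardiovascular portions
  communicate by *advection* in the direction of blood flow; non-capillary
  vessels exchange with their own wall fluid by convection; connected
  tissue fluids by *diffusion*;
* **accessibility** (`acc`) — the transitive closure of communication edges
  restricted to the modalities the protein is capable of.

Triage classifies a protein pair by its post-production types: `(Ltec,
Ltpm)` is the endocrine case — the secreted ligand is the mover, the
receptor is fixed — and the interaction requires a subtending translocation
from the ligand's secretion fluid to the tissue fluid bathing the receptor's
membrane. Route construction then finds the vascular entry point nearest the
start fluid, the exit point nearest the end fluid, the shortest directed
path through the cardiovascular multigraph (unit weight per portion,
deterministic lexicographic tie-breaks), and concatenates three legs into a
raw compartment sequence with explicit inter-endothelial boundary spaces at
each convective crossing. The sequence is summarised by grouping consecutive
portions of the same vessel, and abstracted into the physiological
communication footprint: maximal runs of one transport modality.

## Worked example

The demonstration scenario is an atrial natriuretic peptide (ANP) analogue:
`anp` is secreted by the atrial heart-wall myocardium and can advect,
diffuse and convect; `anpr` is a plasma-membrane product of the smooth
muscle of the first left-kidney arteriole.

```r
library(physroute)

kb <- attach_case_study_proteins(generate_body_kb())
classify_interaction(kb, "anp", "anpr")
#> <interaction int::anp::anpr: endocrine_one_mover>
#>   mover = anp, fixed = anpr

route <- elicit_route(kb, "anp", "anpr")
route
#> <route for int::anp::anpr: TF-heart_wall -> TF-ARTL-kidney_L-1>
#>   raw path: 60 compartments; condensed: 14 groups
#>   footprint: Diffusion - Convection - Advection - Convection - Diffusion

route$footprint
#> 1. Diffusion: C1
#> 2. Convection: C2
#> 3. Advection: C3-12
#> 4. Convection: C13
#> 5. Diffusion: C14
```

The 60-compartment raw path starts in the heart-wall tissue fluid, crosses
an inter-endothelial boundary space into the atrial capillaries, advects
through the cardiac veins, right heart, pulmonary circulation, left heart
and the 44 aorta segments to the left renal artery and arterioles, and
crosses a second boundary space into the kidney arteriolar tissue fluid —
hence the five-step footprint. The same summary is obtained from the
packaged reference-route fixture via `load_reference_fixture()`,
`condense_path()` and `footprint()`.

A command-line front end is installed under
`inst/scripts/physroute.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/physroute.R", package="physroute"))')" \
  gen-kb --out body.tsv --case-study
Rscript .../physroute.R elicit --kb body.tsv --mover anp --target anpr --out route.json
```

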