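---
title: "Methods: reconstructing phytohormone crosstalk networks from pathway data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing phytohormone crosstalk networks from pathway data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hormonet)
```

## The problem

Phytohormones — abscisic acid, auxin, brassinosteroid, cytokinin, ethylene,
gibberellin, jasmonic acid and salicylic acid — are not synthesized in
isolation: their biosynthesis, inactivation, conjugation and degradation
pathways share substrates, intermediates and enzymes, so perturbing one
hormone's pathway propagates to others. `hormonet` reconstructs this
crosstalk structure from pathway-database flat-files and asks three
questions:

1. Which enzymes sit at structural hubs of the crosstalk network, and do
   they chain into a *consecutive metabolic route* (each step's product a
   neighbouring step's substrate)?
2. Do the transcription factors regulating those enzymes' genes form
   *circular control units* — simple cycles in the network of TFs that share
   target genes?
3. Does presence/absence evidence (a transcriptome and a proteome of a
   tissue of interest) support the route?

## Network models

**GECN (genome-scale enzyme correlation network).** Nodes are enzymes,
collapsed by EC string — distinct gene products with the same EC are one
node, because pathway databases annotate reactions at the EC level. An
undirected edge joins two enzymes when some *non-currency* compound
participates, on either side, in at least one reaction of each. The edge
stores the full shared-compound set as provenance.

**Currency policy.** Ubiquitous cofactors (water, H+, ATP, ADP, AMP,
phosphate, diphosphate, NAD(H), NADP(H), CO2, O2, CoA, UDP) are excluded
from edge formation; otherwise ATP alone would connect most of metabolism.
S-adenosyl-L-methionine and UDP-D-glucose are deliberately *not* currency by
default: both act as route-relevant co-substrates in hormone methylation and
conjugation steps, and removing them would erase real crosstalk edges. The
set is a plain compound-id vector and fully configurable
(`currency_policy()`).

**EAPCN (enzyme-based phytohormone crosstalk network).** The GECN restricted
to hormone-annotated pathways, plus one node per hormone. An enzyme joins
when it catalyses a reaction in an annotated pathway; `acts_in` edges record
the pathway ids and roles. Hormone-pair queries
(`shared_crosstalk_enzymes()`) intersect the two hormones' enzyme
neighbourhoods.

**Coupling graph and routes.** A stricter producer/consumer relation drives
route extraction: an edge requires a non-currency compound that is a
*product* of one enzyme's reaction and a *substrate* of the other's
(reversible reactions contribute both sides). Coupling is kept undirected
because a biosynthetic route can traverse pathways in either direction
(e.g. an inactivation step feeding a biosynthesis step). A consecutive
metabolic route is a maximum-cardinality simple path in this graph. Longest
simple path is NP-hard; the exact depth-first search is used up to
`max_exact_nodes = 50` nodes (hub sets are small — the packaged route has
13 enzymes) and a greedy beam search takes over beyond that, with a warning.

Routes are canonicalized with the smaller endpoint first, where EC
identifiers are ordered by their numeric fields (dashes last), not by plain
string comparison: EC numbers are hierarchical codes, and field order is the
ordering practitioners expect (1.3.1.- before 1.14.17.4). This also makes
the packaged route come out in its conventional step orientation, ending at
the ACC oxidase. The printed link between consecutive steps is the
lexicographically smallest compound of the edge's provenance.

## The twelve centrality indices

The hub analysis scores every node on twelve indices, following the
cytoHubba conventions: degree; clustering coefficient; betweenness; stress;
closeness; eccentricity; radiality; maximum neighborhood component (MNC);
density of MNC (DMNC, exponent `dmnc_epsilon = 1.7`); maximal clique
centrality (MCC, the sum of `(|C|-1)!` over maximal cliques containing the
node, enumerated Bron–Kerbosch style with a 5000-node guard); BottleNeck
(fraction 0.25); and the edge percolated component (EPC).

Two normalizations are chosen so that *larger is always more central* and
disconnected networks are handled gracefully: closeness is harmonic
(`sum(1/d)` over reachable nodes) and eccentricity is reported as the
reciprocal of the largest within-component distance. Radiality uses the
component diameter: `mean(diameter + 1 - d(v, u))` over the component, with
isolated nodes scoring 0 on all three path summaries.

EPC is a Monte-Carlo estimate: each edge survives a realization with
probability `epc_keep_probability` (default 0.5), and a node's score is the
mean over `epc_realizations` (default 1000) of its surviving component's
size divided by the node count. With keep probability 1 it equals the
component fraction exactly — a useful degenerate check. The seed is a
parameter, so results are reproducible.

BottleNeck builds, for each source, a deterministic BFS shortest-path tree —
each node's parent is the *smallest-id* neighbour one level closer — and
counts the sources for which a node's descendant count exceeds a quarter of
the tree. One caveat follows directly from that determinism: when a node has
several equidistant parent candidates, the smallest-id rule breaks the tie
by label, so BottleNeck is the one index that is not label-invariant on
graphs with shortest-path ties (on trees and complete graphs, where no ties
arise, it is). The alternative — averaging over all shortest-path trees — is
exponential; reproducibility was preferred.

Ranks in the centrality table are dense (ties share a rank, `1, 2, 2, 3`),
so hub sets are reproducible. Hub selection (`rank_and_select_hubs()`) uses
ordinal positions with (score descending, id ascending) tie-break: a hub is
a node in the top `k` for at least `m` of the twelve indices.

## Overlapping clusters by cohesiveness growth

Community structure uses greedy cohesiveness maximization. The cohesiveness
of a set is `w_in / (w_in + w_bound + p·|V|)`, with `w_in` internal edges,
`w_bound` boundary edges, unit weights (these networks are unweighted) and a
size penalty `p = 2` by default. Growth from a seed applies the single best
addition (from the boundary) or removal (never the seed) until no move
improves the score; ties go to the smallest node id, so growth is
deterministic. Seeds are processed in degree-descending order, skipping
nodes already covered by an earlier grown cluster (members of every grown
cluster count as covered, whether or not that cluster survives filtering —
this bounds runtime and is decided before any filtering is applied). Grown
clusters merge to a fixed point whenever the overlap score
`|A∩B|² / (|A|·|B|)` reaches `merge_overlap = 0.8`; merging to a fixed point
makes the final set independent of merge order. Finally clusters smaller
than `min_size = 3` or with internal density below `min_density = 0.5` are
discarded.

A structural note: with the default penalty, a degree-1 node attached to a
dense clique is absorbed during growth (the internal edge it adds outweighs
the penalty), so "clique plus pendant" yields the clique *with* its pendant.
That is the intended behaviour of best-improvement growth, not a defect.

## TF circular control units

Two TFs are joined when they regulate at least one common target gene; the
shared targets are the edge provenance. All simple cycles of length 3 to
`max_len = 15` are enumerated by an anchored depth-first search (each cycle
is found exactly once at its smallest node, oriented toward the smaller
second element); the cap bounds the Johnson-style enumeration on dense
graphs and logs a message when it truncates. Cycles are grouped into
*control units* by the transitive closure of "share at least one edge" —
units that merely share a TF stay distinct, which matches how separate
regulatory rings can pass through one pleiotropic factor. Each unit reports
the target genes on its internal edges intersected with the genes encoding
crosstalk-network enzymes. Within a unit, the longest simple path of the
protein-protein interaction graph induced on its members is reported as the
unit's PPI route (exhaustive search; units are small).

## Expression overlay

Evidence is presence/absence, as transcriptome and proteome surveys of a
tissue report it. A route step's genes are collected by EC matching — a
family-level EC such as `2.4.1.-` aggregates the genes of every matching
enzyme record, because pathway databases list many loci under family ECs —
then intersected with the expressed-gene and detected-protein lists; a step
is protein-supported if any of its genes is detected. Regulating TFs are
those whose targets hit the step's genes, restricted to the expressed set.
Beyond the descriptive overlay, `permutation_support()` adds a simple null
model: random enzyme sets of the route's size, scored by the same
transcript-coverage fraction, give
`p = (1 + #{coverage >= observed}) / (n_perm + 1)`.

## Synthetic data: what it emulates and what it does not

`generate_pathway_db()` emits flat-files with a planted producer/consumer
chain (unique linker compounds, so recovery is unambiguous), hormone
annotations, and the requested number of hormone-bridging enzymes per pair —
each bridge is one reaction assigned to a pathway of each hormone, with
dedicated compounds so bridges cannot perturb the coupling graph. Background
reactions draw from a compound pool disjoint from the linkers, so they
cannot extend the planted chain; the generator nevertheless re-runs the
exact route extractor before returning and fails loudly if the planted route
is not uniquely recovered. Defaults mirror the packaged study conditions: a
13-step route, an 11-enzyme auxin–cytokinin bridge set, all eight hormones,
a planted 6-TF cycle, evidence sensitivity 0.9 with a 5% false-positive
rate. `generate_regulation()` plants co-target cycles (consecutive TFs share
a dedicated target) plus background co-targeting at a configurable density,
and a PPI chain over each planted cycle.

What passing on synthetic data does *not* show: real pathway databases have
heavy-tailed compound usage, promiscuous enzyme families and annotation
errors, none of which the generator mimics; recovery rates on planted
structures are upper bounds on what genome-scale data would give. The
packaged fixture is likewise a desk-scale curated dataset, not a
reconstruction of a full genome-scale database, so
genome-scale hub orderings are out of scope and the index implementations
are validated against exhaustive oracles on small random graphs instead
(200 graphs of up to 8 nodes in the test suite, plus 100-seed
planted-recovery sweeps; these sizes keep the whole suite under a few
minutes on one core while still exercising every code path).

## Numerical choices and degenerate inputs

- Ties are always broken by node id (ascending) after the primary score;
  every traversal iterates nodes in sorted order, so all outputs are
  deterministic and two runs with one seed are byte-identical.
- Isolated nodes: degree 0 on local indices, 0 on path indices (harmonic
  closeness over an empty set), `1/n` on EPC, 0 on MNC/DMNC/MCC.
- Empty inputs: an empty annotation table gives an empty EAPCN; an empty
  graph gives an empty cluster set; empty evidence lists parse with a
  warning, not an error.
- Validation (`validate_db()`) reports rather than throws; the parsers
  abort on error-level entries (dangling references, duplicate ids) and
  tolerate warning-level ones (an EC shared by two enzyme records).

## Known limitations

- Edge formation treats any shared compound as interaction; it does not
  distinguish synergistic from antagonistic crosstalk, which would need
  directionality or sign information the input formats do not carry.
- No flux, kinetics or thermodynamic direction inference; reversibility is
  taken from the database annotation only.
- The cycle cap and the exact-route node guard trade completeness for
  bounded runtime on dense or large graphs; both log when they bind.
- Hub selection thresholds (`k`, `m`) are parameters, not estimates; the
  method ranks, it does not test significance, and clusters carry no
  p-values.
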