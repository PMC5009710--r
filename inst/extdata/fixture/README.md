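# Packaged crosstalk fixture

A small curated dataset of Arabidopsis phytohormone biosynthesis crosstalk,
used by the test suite and the worked examples. It contains:

- `compounds.dat`, `reactions.dat`, `enzymes.dat`, `pathways.dat` — a
  BioCyc-style flat-file pathway database covering the 13-enzyme consecutive
  metabolic route (steps 1-13, ending at aminocyclopropanecarboxylate
  oxidase, EC 1.14.17.4) and the auxin-cytokinin bridge enzymes.
- `hormone_annotations.tsv` — hormone-to-pathway annotations for all eight
  hormones.
- `route_enzymes.txt` — the route's 13 EC identifiers in step order.
- `regulation.tsv`, `ppi.tsv` — TF-to-target rows forming the circular
  control units (rings of TFs whose consecutive pairs share one dedicated
  target) and the protein-interaction chain of unit C
  (HYH-HY5-MYB75-GL3-EGL3-TT2).
- `expressed_genes.txt`, `detected_proteins.txt` — root-stele
  presence/absence evidence; every route step except EC 2.4.1.203 has at
  least one expressed enzyme-encoding gene.

## Curation notes

- **Synthetic placeholders.** Four route links have no named metabolite in
  the source material; they are encoded as `SYNTHETIC-LINK-*` compounds with
  dedicated `RXN-SYNLINK-*` reactions so steps 1-13 form a single coupling
  path. The steps 9-10 link is synthetic because both enzymes only *consume*
  indole-3-acetate (a shared substrate, which creates a shared-compound edge
  but not a producer-to-consumer coupling). All synthetic entities carry the
  `SYNTHETIC-` prefix.
- **Auxin-cytokinin bridge set (11 enzymes).** The bridge memberships are
  encoded as `RXN-SYNBRIDGE-*` reactions assigned to one auxin- and one
  cytokinin-annotated pathway each, with unique synthetic compounds so they
  cannot perturb the coupling graph. The source material is internally
  inconsistent here (twelve ECs listed, eleven counted); this fixture keeps
  eleven and drops EC 2.4.1.12 (cellulose synthase), the listed EC with no
  other auxin/cytokinin tie. EC 2.4.1.12 is still present in the database,
  outside any hormone-annotated pathway.
- **TF units.** Each circular control unit is a ring: consecutive TF pairs
  share exactly one dedicated target, so each unit contributes exactly one
  simple cycle and units sharing a TF (but no edge) stay distinct. Named
  enzyme-encoding targets are used where the unit is known to regulate them;
  remaining ring positions use synthetic filler loci with the non-existent
  chromosome prefix `AT9G9...`. Two source locus typos are corrected
  (AGL15 = AT5G13790, PIF3 = AT1G09530).
- **ACC provenance.** ACC production is assigned to EC 4.4.1.14 only, so the
  step 10-11 link is L-phenylalanine and the step 12-13 link is ACC.
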