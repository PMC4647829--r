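---
title: "Comparing metabolic pathways as enzymatic step sequences"
author: "essalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing metabolic pathways as enzymatic step sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essalign)
```

## The model

Metabolism can be compared across organisms without touching gene or
protein sequence: encode each reaction by the first three levels of its
Enzyme Commission number (the general reaction chemistry), turn each
pathway map into linear chains of consecutive reactions, and align the
chains the way one aligns biological sequences. Two pathways that perform
similar chemistry in a similar order then align with a low cost even when
the proteins involved are unrelated — which is exactly the signature of
functional conservation and of enzyme recruitment (the reuse of a catalytic
activity in a new pathway context, the "patchwork" view of metabolic
evolution).

`essalign` implements that programme end to end. The three underlying
assumptions are worth stating explicitly:

* **3-level EC numbers are the right alphabet.** Truncating to
  class.subclass.sub-subclass groups enzymes by chemistry rather than
  substrate specificity. Promiscuous enzymes (several ECs on one reaction)
  become parallel graph nodes; reactions with no EC assignment get the
  `9.9.9` sentinel, which is similar only to itself so unannotated steps
  never create spurious similarity.
* **Pathways can be linearised.** A map is a branched graph; breadth-first
  trees from its metabolic inputs, read leaf-to-root, give a systematic
  (if redundant) set of linear fragments. Branched sub-pathways are
  deliberately represented per branch, never as a unit.
* **A shuffled null is the right yardstick.** What counts as a
  "significant" alignment score is calibrated against databases with the
  same sequence lengths and the same global EC composition but no
  conserved order.

## From KGML to sequences

`parseKGML` reads only what the pipeline needs from the KGML dialect:
`reaction` elements with `substrate`/`product` children and the
`type="reversible"` attribute; enzyme-like entries whose `name` tokens
carry EC labels for a reaction; and compound entries marked as entering
from another map. Compound identity is the raw KGML id string — KGML
already canonicalises compounds, and no chemical normalisation is applied.
Currency metabolites are **not** filtered by default (an exclusion list can
be supplied to `buildEnzymeGraph`, default empty).

The enzyme graph has one node per (reaction, distinct EC) pair. A
reversible reaction behaves as two opposite directed reactions sharing one
node, so its substrate and product sets are pooled on both sides.
Self-loops are excluded, and so are edges between two nodes of the *same*
reaction: a reversible reaction would otherwise connect its own parallel
EC nodes through its own substrate pool, which describes no enzymatic
step. For the same reason, root criterion A ("some substrate is produced
by no other enzyme in the map") only considers producers from other
reactions.

Roots are metabolic inputs by either of two criteria: (A) a substrate
produced nowhere else in the map, or (B) a substrate annotated as imported
from another map on a node with at most two distinct neighbours. BFS
expansion and root processing are in ascending node-id order, which makes
every downstream artifact deterministic; the ordering is a tie-break of
this implementation, not biology. Candidate paths shorter than two steps
are dropped. Duplicate sequences are kept within the redundant database and
collapse only at the global non-redundant (`deduplicateESS`) stage, where
the representative is the first by (organism, map, index) and the union of
provenances is retained.

## The alignment score

`alignESS` minimises the total column cost of a global alignment:
substitution costs come from an `ECWeightMatrix`, each gap column costs
`gap` (default 1.0, the maximal mismatch cost — a gap should never be
cheaper than the worst substitution, and with `gap <= 1` the normalized
score is guaranteed to stay in [0, 1]). The reported score is
`total cost / alignment columns`: 0 for identical sequences, 1 for
maximally dissimilar ones.

Two numerical choices deserve attention:

* **The DP objective is minimal total cost; normalization is post hoc.**
  The alignment that minimises `cost/length` is not guaranteed to be
  found; this is a deliberate simplification that keeps the recurrence
  linear.
* **Ties are resolved symmetrically.** Minimum-cost alignments of a pair
  can have different lengths (three 2/3-mismatches cost the same as two
  identities plus two gaps, but over 3 vs 4 columns). The scorer therefore
  uses a secondary objective — among minimum-cost alignments, maximise the
  number of substitution columns (the shortest alignment) — which is a
  symmetric function of the pair, so `score(a, b) == score(b, a)` exactly.
  Residual traceback ties prefer substitution, then a gap in the second
  sequence, then a gap in the first.

The weight matrix has two modes. `uniform` is purely structural: 0, 1/3,
2/3, 1 by the deepest shared hierarchy level, with any first-level
difference forced to 1 and `9.9.9` at distance 1 from everything else. In
`entropy` mode the distance between two ECs sharing a prefix is the
Shannon entropy of the catalogue occurrence distribution under their
deepest common ancestor class divided by the whole-catalogue entropy,
clamped to (0, 1]: a pair inside a small, homogeneous class counts as
closer than a pair inside a large, diverse one. The entropy functional is
this package's own reconstruction of an "entropy-based" weighting —
uniform mode is the reproducible default for testing, entropy mode the
default for analysis runs, and results at the usual threshold should be
compared across both.

## Significance

`shuffleDatabase` pools every EC token in the database, permutes the pool
with a seeded generator, and refills the original sequence lengths, so the
global EC multiset and every per-sequence length are preserved exactly —
the two conservation laws the tests assert. Shuffling is global across the
database rather than within organisms, following the reading that the
null should destroy ordered structure everywhere while keeping overall
composition. Ten replicates (seeds `base + 1 .. base + R`) are the
default; each is aligned all-against-all with the same matrix and gap as
the real run, and ensembles refuse comparisons against mismatched
settings.

The real-vs-null comparison is reported, never decided automatically: the
per-bin dispersion curve `(real - null mean) / null sd` (with a 0
convention when both agree at zero spread, and an infinity sentinel
otherwise), the crossing point where the null catches up with the real
histogram, the fraction of null alignments at or below a threshold, and
the coverage (fraction of sequences participating in at least one
sub-threshold alignment). The operating threshold defaults to 0.3, a
parameter the user owns. Score histograms use half-open bins `[x, x + w)`
of width 0.05 with the final bin closed at 1; thresholding is always
applied to raw scores, not to bins, and binning is float-safe so a score
sitting exactly on an edge lands in the right-hand bin.

## Conservation, clustering, scanning

A pair of sequences is *functionally conserved* when its score is at or
below the operating threshold and the pair is present in more than 75 % of
the organism panel. "Present" is judged on the **union** of the two
provenance organism sets — the panel-coverage reading — because the
coverage requirement expresses that the pair jointly spans the clade; the
stricter each-sequence-individually reading is available via
`coverageMode = "each"`. The same-map subset of conserved pairs (the
MMFCD) drives per-map conservation: the ECs occurring in identical,
non-gap aligned columns (exact 3-level equality; `9.9.9` never counts)
against all ECs the map's sequences carry. Because the database records
sequences rather than full map annotations, the clade EC set is defined
from the map's sequences. Category boundaries are half-open and
deterministic: proportion ≥ 0.70 conserved, [0.30, 0.70) moderately,
(0, 0.30) barely, exactly 0 non-conserved — resolving the ambiguity of
prose boundaries like "between 30 and 69 %" at the boundary values. A pair
whose two sequences share several maps contributes to every shared map.

Map clustering counts, for every sub-threshold alignment, each combination
of the two sequences' provenance maps (within-map combinations land on the
diagonal, which is included in row totals by default;
`excludeDiagonal = TRUE` is available since the choice is genuinely open).
Rows are normalized after counting and symmetrisation. The distance is
1 − Spearman rank correlation of row profiles (average ranks under ties);
zero-variance rows, where rank correlation is undefined, get distance 1 to
everything and are reported. Average-linkage trees are cut at a fraction
(default 0.46) of the maximum merge height; a fraction of 0 is
special-cased to singletons since zero-height duplicates would otherwise
still merge.

`scanQuery` aligns one query against the whole database and groups hits by
provenance map; a hit with multi-map provenance counts once per map, so
both the raw hit count and the per-map sum are reported. `scanNull`
replays the scan against the ensemble's shuffled replicates. The
EC-occurrence report contextualises hit counts — a query made of globally
abundant chemistry will match broadly for compositional reasons — and no
multiple-testing correction is applied.

## What the synthetic data does and does not emulate

`generateToyPathway` emits genuine KGML (entry/reaction/substrate/product
elements), exercising every parser branch — reversible, EC-less, multi-EC,
cross-map-linked and cyclic reactions — with the planted truth computed by
`traceEssPaths`, an independent adjacency-matrix tracer kept deliberately
separate from the production BFS code. `generatePlantedDatabase` plants
families of mutated seed copies among random background sequences. Its
defaults are chosen once so the labels are an exact oracle at the 0.3
threshold: seeds are rejection-sampled to pairwise scores above 0.7;
members mutate at most `floor(0.375 * length)` positions within the same
EC class (score to seed at most 0.25); background sequences are uniform
draws at lengths 10–14, disjoint from the family range 4–6, so with gap
cost 1 the unavoidable gap columns alone keep any family-background score
far above threshold. Family provenance covers 80 % of a 40-organism panel
(the panel size and the >75 % coverage rule of the conservation stage).

What this emulates: planted low-score structure against a compositional
background, provenance at controlled panel coverage, and block-structured
map similarity. What it does not: realistic pathway topology statistics,
realistic EC frequency distributions, correlated gene loss across
organisms, or any phylogenetic structure in the panel. Passing tests
therefore demonstrate that the algorithms recover planted structure under
the stated conditions — not that real metabolism contains such structure.

## Problem sizes and numerical conventions

The validation suite runs at sizes chosen for exactness and repeatability:
the planted database at 20 families × 10 members + 300 background
sequences (500 sequences, 124,750 pairs per replicate, 10 shuffled
replicates); the DP-vs-enumeration check on 200 pairs of length ≤ 6 over a
10-EC alphabet (exhaustive path enumeration without memoisation); score
properties on 1,000 random pairs; tracer equivalence on 50 toy pathways of
≤ 8 reactions; map-cluster recovery on 3 planted blocks of 5 maps.
Degenerate inputs follow explicit contracts: an empty KGML yields a valid
empty model; an empty graph yields no roots; fewer than two sequences
yield an empty alignment table with a warning; an empty database is an
error for operations that need one.

## Known limitations

* Local alignment, affine gaps and 4-level EC comparison are out of scope.
* The normalized score is not a metric; downstream monotone uses
  (thresholding, ranking) are safe, but triangle-inequality reasoning is
  not.
* The entropy weight matrix and the normalized scorer are reconstructions
  flagged in configuration; conclusions that depend on fine score
  differences between the two matrix modes should be checked under both.
* Map conservation judges the clade EC set from the sequences in the
  database, not from full map annotation; maps whose enzymes rarely enter
  any ESS will look artificially small.
* Promiscuous-enzyme effects are represented only as parallel nodes;
  no attempt is made to model multifunctionality beyond that.
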