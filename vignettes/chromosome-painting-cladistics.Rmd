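---
title: "Chromosomal cladistics from cross-species chromosome painting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosomal cladistics from cross-species chromosome painting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoclad)
```

## The problem and the data

Cross-species chromosome painting (ZOO-FISH) hybridizes whole-chromosome
probes of one species onto the metaphases of another, revealing which
segments of the two genomes are homologous. Because chromosomal
rearrangements are rare genomic events, the pattern of conserved syntenies,
segmental associations (two reference chromosomes joined on one target
chromosome) and syntenic disruptions (one reference chromosome split across
several targets) carries phylogenetic signal that is independent of sequence
data. `chromoclad` implements the full analysis chain for such data in
phyllostomid bats: from painting homology maps to a binary cladistic matrix,
an exhaustive maximum-parsimony phylogeny with bootstrap and Bremer support,
and an a-posteriori classification of every chromosomal change.

The package ships the painting maps for the tribe Phyllostomini transcribed
from the per-probe results: PHA (*Phyllostomus hastatus*, the reference
complement) and CBR (*Carollia brevicauda*) probe panels on TSA (*Tonatia
saurophila*), LSI (*Lophostoma silvicola*) and PDI (*P. discolor*), plus the
karyotype configurations of all five species.

```{r fixtures}
maps <- phyllostomini_maps()
segment_count_table(maps)[, c("target", "probe", "n_signals", "n_segments")]
```

One transcription caveat is carried openly: the per-probe enumeration for
CBR probes on LSI sums to 25 segments while the reported total is 26. The
map's `note` field states this; nothing in the pipeline hides it.

## Data model

A `karyotype` records 2n, FN and per-chromosome morphologies. Two
arithmetic identities are validated (as report entries, never exceptions):
2n = 2 × (autosome pairs) + (sex chromosomes), and FN = autosomal arms
summed over both homologs, counting 2 per bi-armed and 1 per one-armed
chromosome and excluding the sex pair. This is the only convention that
reproduces all the printed (2n, FN) pairs of the study taxa. `sex_system`
accepts two or three chromosomes because CBR carries an XY1Y2 multiple
sex-chromosome system; its config lists the male complement (2n = 21) so
that the Y2 probe label validates.

A `homology_map` stores one row per (probe, target) pair with `n_blocks`,
the number of discontiguous hybridization blocks of that probe on that
chromosome. A probe painting one chromosome in two blocks separated by
non-homologous material (PHA-5 on TSA-6) is a single signal with
`n_blocks = 2`: this preserves both the per-chromosome synteny fact and the
segment total, since `count_segments()` sums blocks, not rows. Region
qualifiers ("short arm", "distal") are free text and never parsed; painting
has no base-pair resolution, so no coordinate conventions arise.

## Character coding

The reference complement (PHA) provides the minimal conserved units.
`synteny_partition()` groups the units detected on each taxon by target
chromosome; from these partitions:

* **association characters** (`A.<u>+<v>`) — one per unordered pair of
  units joined on a single chromosome in at least one taxon. Pairwise only:
  a three-unit syntenic group yields three pairwise characters, the
  simplest coding consistent with binary states (and the reason a coded
  matrix here need not have the same column count as a manually coded one).
* **disruption characters** (`D.<u>`) — one per unit that is split across
  chromosomes, or present in more than one block on a single chromosome, in
  at least one taxon.
* **structural characters** (`S.*`) — pericentric inversions, NOR
  position, heterochromatin states, supplied as a per-taxon annotation
  table. Heterochromatin-only differences are never coded as synteny
  characters: whole-chromosome probes carry no information about
  constitutive heterochromatin.

States are 1 (derived condition present), 0 (both units detected, condition
absent) or `?` (undetected). A taxon lacking painting data for a unit
scores `?`, not 0 — absence of painting evidence is not evidence of
conservation. This matters in practice: PDI was hybridized with only two
probes, so almost all its synteny states are unknown. Polarity is *not*
assumed during coding; direction is established a posteriori by outgroup
rooting. All characters carry equal weight, on the premise that
rearrangements are equally likely to occur anywhere.

Column order is deterministic (associations, disruptions, structural, each
lexicographic by id), so re-deriving a matrix from the same maps is
reproducible and independent of input taxon order. Matrices are written as
plain TSV or as a NEXUS `DATA` block (`DATATYPE=STANDARD SYMBOLS="01"
MISSING=?`); the NEXUS writer is deterministic, so read → write → read
round trips are byte-stable, and character ids survive in a bracketed
comment.

## Exhaustive maximum parsimony

Unrooted binary topologies are enumerated through the bijection with rooted
trees on n−1 leaves (stepwise addition), giving every topology exactly once
— (2n−5)!!, i.e. 945 for the seven study taxa. Each topology is stored as a
postorder merge schedule, and Fitch lengths are computed as bitmask
set operations vectorised over characters; `?` is the full state set
{0,1} (union semantics), so missing data never adds steps. Root choice does
not affect the count, which the tests verify by rerooting.

`exhaustive_search()` scores every topology and returns *all*
most-parsimonious trees in canonical newick order (children sorted by
smallest descendant, used for deduplication and deterministic output),
together with the tree length and the ensemble consistency index
CI = Σ min-steps / length, reported to 4 decimals. The per-character
minimum is (distinct observed non-`?` states) − 1, so CI = 1 exactly on
homoplasy-free data.

Exhaustive enumeration is refused above 9 taxa: at n = 10 the space has
over two million topologies and the precomputed schedules and
topology-by-character steps matrix stop being a sensible representation. A
branch-and-bound search would be the right extension; the study scale here
is n = 7, where a full search over 945 topologies with ~50 characters takes
well under a second.

## Support values

Both support measures reuse the topology-by-character steps matrix, so each
bootstrap replicate is a single weighted re-scoring of the whole tree space
rather than a fresh search:

* **Bootstrap** (`bootstrap_support()`, default 2,000 replicates):
  characters resampled with replacement to the original count; the
  bipartitions of *all* MP trees of a replicate are tallied, fractionally
  (1/count) when a replicate ties over several trees, avoiding bias toward
  arbitrary tie order. A single seed drives the replicate stream, and two
  runs with the same seed are bit-identical.
* **Bremer decay** (`bremer_support()`): for every clade in the strict
  consensus of the MP trees, the minimum length among enumerated topologies
  *not* containing the clade, minus the MP length. Computed by full
  enumeration, hence exact and seed-independent at this scale.

`majority_rule_consensus()` summarises tree sets by bipartition frequency
(retain strictly above the threshold, default 0.5, which guarantees a
compatible set) and annotates nodes with frequencies.

## Rooting and a-posteriori character mapping

`root_on_outgroup()` places the root on the branch separating the outgroup
(here the Desmodontinae, DEC + DRO + DYO) from the ingroup, refusing
outgroups not separable by a single edge. `ancestral_states()` computes
most-parsimonious-reconstruction state sets per node (two-pass dynamic
programming with unit costs); ambiguity is resolved under DELTRAN by
default (changes pushed toward the tips; ties at the root resolve to the
ancestral state 0) with ACCTRAN selectable, and every character whose
category differs between the two optimizations is flagged rather than
silently resolved.

Each character then receives exactly one category, with precedence
homoplasy > plesiomorphy > autapomorphy > synapomorphy:

* **constant** — minimum conceivable steps is 0;
* **homoplasy** — realised steps exceed the minimum;
* **plesiomorphy** — the derived state is present at the ingroup's most
  recent common ancestor *and* at the root: the change happened below the
  ingroup and is shared with the outgroup. A state fixed on the ingroup
  stem itself is deliberately *not* a plesiomorphy but a synapomorphy of
  the ingroup — shared derived chromosomes of the whole tribe count as
  evidence for its monophyly;
* **autapomorphy / synapomorphy** — the single change sits on a terminal /
  internal branch.

The exact plesiomorphy rule is not fixed by the original description; the
rule above is this package's choice, and the precedence is applied per
character so the four counts always partition the matrix.
`root_state_report()` complements the classification with the character
set inferred at the ingroup root and the reference units conserved in toto
there — the character-level counterpart of an ancestral-karyotype
reconstruction (drawing ideograms or assigning 2n to internal nodes is out
of scope).

## The synthetic-data generator

Because the published 7 × 55 matrix is distributed only as a formatted
document, end-to-end validation runs on simulated data.
`simulate_karyotypes()` evolves an ancestral complement of single-unit
chromosomes (default 16 units, a PHA-like complement of 15 autosome pairs
plus X) along a known rooted tree:

* **fusion** joins two chromosomes (creating associations between all unit
  pairs across the junction) and marks the product bi-armed;
* **fission** splits a chromosome at a block boundary (creating a
  disruption); breakpoints inside a unit's block — the pattern behind a
  probe painting two blocks on one chromosome — are possible behind an
  off-by-default flag;
* **reciprocal translocation** exchanges terminal block runs;
* **inversion** toggles the morphology flag only: it is invisible to
  painting and surfaces solely as a structural character (one per event).

Event counts per branch are Poisson with mean rate × branch length
(defaults: fusion 0.3, fission 0.3, translocation 0.2, inversion 0.2 per
unit branch length — roughly one event per branch, a moderate regime for a
group spanning strong karyotypic conservatism and a megaevolved lineage);
fixed per-branch counts can be supplied instead for designed experiments.
Breakpoints and operands are uniform among valid choices, with invalid
draws resampled; there are no gain or loss events, so genomic content is
constant — which is also the regime the coding assumes. Everything is
deterministic per seed, and the event log replays from the ancestral
complement to bit-identical tip complements (`replay_events()`), the
round-trip oracle used in the tests.

The emitted truth matrix is computed directly from the tip complements and
the event log — *not* by running the character coder — so the generator
and the coder cross-validate each other: the tests assert that coding the
emitted maps reproduces the emitted matrix exactly.

What the generator does not emulate: breakpoint hotspots or reuse,
heterochromatin dynamics, centromere repositioning, partial detection
(simulated maps have no `?`; real PDI-style sparse panels do), and
hemiplasy (no population process). Passing the simulation studies therefore
shows the pipeline is correct on clean rearrangement histories, not that
real painting data meet those assumptions.

## The recovery study and its design

The validation experiment simulates the published rooted topology
((DEC,(DRO,DYO)),(TSA,(LSI,(PHA,PDI)))) with two events per branch and 16
units, rejecting seeds whose matrix is not homoplasy-free (tree length on
the true tree above the sum of per-character minima), until 100 clean runs
are collected. Two event mixes are run (`analysis/03_parsimony_simulation.R`,
`scripts/acceptance.R`):

* **fusion + inversion (durable markers)**: a created character can never
  be erased, so every branch carries at least one clean marker, and a
  homoplasy-free matrix identifies the generating topology — the unique MP
  tree must equal it in 100/100 clean runs. This is the regime under which
  the 100% recovery guarantee is a theorem, and the suite asserts it.
* **full mix (erasable markers)**: a fission or translocation below a
  marked branch can destroy an association — or convert it into a marker
  of a nested clade (a stem association lost in one descendant re-reads as
  a synapomorphy of the remaining pair) — without raising any character
  above its minimum steps. Such runs are clean yet genuinely
  non-identifying, so no search can recover them; the achieved fraction is
  reported as a number and not gated.

## Numerical and degenerate-input choices

* `?` in Fitch is {0,1}; characters scored in no taxon are rejected at
  matrix construction.
* CI at length 0 errors when the minima sum is positive and returns 1 for
  an empty/constant matrix.
* Equally parsimonious trees are all retained and ordered by canonical
  newick; downstream consumers (Bremer, consensus, rooting) receive the
  full set.
* DELTRAN/ACCTRAN ties: DELTRAN keeps the parental state, ACCTRAN switches;
  root ties resolve to 0 (DELTRAN) or 1 (ACCTRAN). Both reconstructions are
  exact minimum-length assignments (backtraces of the dynamic program).
* Fission on a single-block, single-unit chromosome has no valid
  breakpoint: the event is resampled (bounded, then the branch simply
  carries fewer events).
* Species codes are closed to the eight study taxa plus codes registered
  via `options(chromoclad.species = ...)`; synthetic datasets use their
  own tip labels with validation relaxed.

## Problem sizes

The shipped studies use: 7 taxa (945 topologies) for every search, 2,000
bootstrap replicates, 100 clean simulations per recovery arm, 1,000 random
instances for the Fitch-versus-brute-force oracle check (≤ 6 taxa × ≤ 10
characters, where the oracle enumerates every internal labeling). The whole
test suite and the acceptance script each run in about a minute on one CPU.

## Known limitations

* No branch-and-bound or heuristic search: hard 9-taxon cap.
* Binary characters only; no ordered multistate coding, no weighting.
* The coded matrix from the shipped maps covers the four painted taxa;
  outgroup painting data come from other studies and are not transcribed
  here, so the seven-taxon analysis is exercised on simulated data unless a
  transcription of the published matrix is provided.
* Bootstrap percentages on tiny matrices are diluted by replicate ties
  (fractional tallying); this is by design, not sampling error.
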