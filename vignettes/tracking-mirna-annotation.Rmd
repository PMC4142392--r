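---
title: "Tracking miRNA annotation changes: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking miRNA annotation changes: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtracker)
```

## The change model

miRBase publishes each release as three files: `miRNA.dat` (EMBL-style flat
file of precursor stem-loop records, whose `FT miRNA` features delimit the
mature products), `mature.fa` (the mature sequences the community actually
consumes) and `miRNA.dead` (cumulative removals, with an optional `FW`
forward pointer when a record was merged into a surviving one). `mirtracker`
models the database's evolution as an event stream over these snapshots.

Identity follows **accession numbers, never names**. Precursors have carried
`MI` accessions from the first release; mature records only gained `MIMAT`
accessions in release 6.0, so earlier mature records are identified by
(species, name, sequence) and must be reconciled before diffing (see
retro-assignment below). Names are not a usable key because the same name has
been re-issued for different molecules in real nomenclature history; the diff
engine therefore reports such a situation as one record removed plus one
added, never as a rename.

For each pair of consecutive snapshots every accession receives at most one
**change event** carrying a set of types:

| type | trigger |
|---|---|
| `ADDED` | accession appears, never seen before |
| `RESURRECTED` | accession appears after a spell in `miRNA.dead` |
| `NAME_CHANGE` | name differs (case-sensitively — "mir" vs "miR" is meaningful) |
| `SEQUENCE_CHANGE` | normalized sequence differs |
| `RELATION_CHANGE` | parent/product accession set differs |
| `DELETED` | accession disappears, no forward pointer |
| `MERGED` | accession disappears with a `FW` pointer (the merge target) |

The seven-type taxonomy is the package's own granularity choice: it is the
minimum needed to render per-record histories and the added / removed /
changed / unchanged comparison buckets, while keeping `MERGED` and
`RESURRECTED` — both observed in real data — distinguishable from plain
deletion and addition. A record renamed *and* sequence-changed in one
transition gets one event with both types; the comparison query's single
"changed" bucket is the union of the three changed sets.

Events persist in a two-table store — `CHANGES` (one row per change type,
keyed by an event id grouping all changes of one accession at one transition)
and `STATES` (the record's tracked annotation *after* the change; absent for
removals) — plus a release registry and the retro-assignment provenance
table. Release ordering is numeric on the parsed (major, minor) pair, so
"9.2" < "10.0" < "21"; lexicographic ordering is wrong for real labels and is
deliberately not used. The store's central invariant is **event-sourcing
soundness**: replaying events in ordinal order from an empty state
reconstructs the tracked annotation of every ingested release exactly, which
is asserted wholesale in the test suite. Comparisons between arbitrary
releases are computed from reconstructed snapshots, not by summing events, so
gaps in the ingested series cannot corrupt counts.

Equality of a reconstruction is asserted on the tracked-annotation projection
(accession, molecule type, name, sequence, species code, relation set) — the
store tracks exactly what its schema holds. Opaque annotation (literature
references, cross-references) is retained verbatim by the parser and carried
through the writer's round trip, but is not versioned as events.

## Parsing and normalization

Parsing is tolerant of dialect drift across two decades of releases: the
required fields are `ID`/`AC`/`SQ` for precursors and the header name for
matures; everything else is optional, and unknown line types are kept as
opaque annotation rather than rejected. Sequences are uppercased and DNA is
converted to RNA (T to U); the stored alphabet is `{A,C,G,U,N}` and anything
else is an error. Feature coordinates are 1-based inclusive, as in the file
dialect, and are kept that way internally.

Mature records are joined to precursor features by accession when present,
else by product name plus sequence identity. Every mature sequence is
cross-validated against the precursor substring at its feature coordinates;
a mismatch is surfaced as a warning and **mature.fa wins**, because it is the
file downstream consumers read. A mature.fa entry with no matching feature at
all is an error naming the orphan — silent dropping would falsify histories.

## Retro-assignment of mature accessions

Releases up to 5.1 carry no mature accessions. The reconciler walks backwards
from the anchor (the earliest release whose matures are all accessioned),
matching each unaccessioned record against the already-canonicalized
next-later release by a rule cascade:

1. exact species + name match (`rule:name`);
2. exact sequence match within the species (`rule:sequence`);
3. maximal contiguous sequence overlap — containment or ≥ 16 shared nt —
   with ties broken by name edit distance, then lexicographic name
   (`rule:overlap`).

The anchor remains a fallback reference at every step so records spanning a
gap still match. Explicit overrides (a TSV of release, species, name,
sequence, accession) take absolute precedence, providing the escape hatch
that manual curation needs. Assignment is injective per release: a rule whose
candidate accession is already taken falls through to the next rule. Records
that nothing matches receive `PROV` identifiers derived from a hash of
(species, name, sequence), so they are total, reported, and stable across
rebuilds — adding an unrelated record cannot change existing assignments.
The 16-nt overlap floor is chosen as comfortably more than half of the
shortest real mature (~19 nt), which makes a chance overlap between two
unrelated ~22-nt sequences vanishingly unlikely while tolerating 1–3 nt
end-shifts, the dominant real revision mode.

## The synthetic release series

The simulator exists so that every module is testable without downloading
archives. It emits real-dialect files plus a ground-truth log of every
injected change, written with the same taxonomy and canonical type ordering
the diff engine produces; on non-adversarial parameters (no record swapping
both name and sequence in one transition — operations are mutually exclusive
per precursor within a transition by construction) the diff output must equal
the log exactly, giving precision = recall = 1 as a property, not a
statistic.

Default conditions: 3 species, 30 initial precursors, two arm products
(-5p/-3p) per precursor, 6 releases, and per-record per-transition rates
p_add = 0.05, p_delete = 0.02, p_merge = 0.02, p_rename = 0.06,
p_seqchange = 0.06, p_relink = 0.02, p_resurrect = 0.05, with half of all
sequence changes hitting the seed (p_seed_region_hit = 0.5). These are
round numbers of the magnitude seen across real release transitions — a few
percent of records change per release, renames and sequence revisions being
the commonest — chosen once as plausible study conditions rather than fitted
to any particular pair of releases. Sequence changes are the isomiR-style
edits that dominate real revisions: 1–2 nt end-shifts (5' shifts reframe the
seed; 3' shifts do not) or a single point substitution, which also edits the
precursor since the mature is a genuine substring of it.

What the simulator does *not* emulate: hairpin thermodynamics (precursor
sequences are i.i.d. uniform — folding is not under test), expression-aware
isomiR distributions, cross-species homology, and real nomenclature history.
Passing tests therefore demonstrate that the tracking machinery is correct on
well-formed inputs spanning the full change vocabulary, not that any
particular real release pair will be free of curation surprises; on real
data, retro-assignment discrepancies surface per-record via the provenance
table rather than being absorbed.

Two deliberate simulator design choices keep the ground truth exact. A
relink (re-parenting of a mature) stays within its species and embeds the
mature's sequence into the new parent, since a mature's name prefix *is* its
species; and a parent rename only renames the matures whose names derive
from that parent, so relinked-in matures keep their names and name collisions
cannot arise. Resurrections draw only from records dead in an earlier
release — deleting and restoring within one transition would be a no-op in
the files but a phantom pair of events in the log.

## Seed-match prediction and the overlap ratio

The functional-impact module quantifies what a sequence revision does to a
miRNA's predicted targetome. It uses transparent canonical seed matching:
seed = positions 2–8, site strings are exact Watson–Crick reverse
complements in the 3'UTR (6mer = rc(2–7); 7mer-m8 = rc(2–8); 7mer-A1 =
rc(2–7) + A; 8mer = rc(2–8) + A), G:U wobble excluded — the simplest
defensible convention, with no trained scoring model. Consequently the
published nonoverlap percentages obtained with proprietary predictors are not
comparison points for this module; what is reproduced is the statistic's
definition and properties: the ratio of common to total unique
(miRNA, transcript) interactions, restricted to records present in both
releases whose sequence changed. Interactions deduplicate multiple sites per
transcript — the ratio counts interactions, not sites — while per-pair site
counts (including overlapping occurrences) are still reported.

Degenerate inputs are explicit: an empty UTR set predicts nothing (not an
error), while an overlap over an empty union is undefined and raises an
error rather than returning a conventional 0, since 0 would falsely signal
complete turnover. A seed change makes the 7mer-m8 site strings of the two
versions distinct, so on UTRs containing exactly one site string the old and
new interaction sets are provably disjoint — one of the module's property
tests; a change outside positions 1–8 preserves all 7mer-m8 sites and yields
a ratio of exactly 1 in 7mer-m8-only runs.

## Numerical and interface choices

* **Determinism.** All iteration orders are C-locale lexicographic
  (radix-sorted), so event lists and emitted files are byte-identical across
  runs and platforms; the simulator is a pure function of its parameters and
  seed.
* **Name lookup** is case-insensitive by default (users paste
  "HSA-MIR-21") but exact-case matches win when they exist, because case is
  what distinguishes a precursor ("mir") from a mature ("miR") name; storage
  is always case-sensitive.
* **Ambiguity is reported, never resolved heuristically**: an update query
  matching several accessions returns status `ambiguous` and expects a
  release context for disambiguation; merged records chase forward pointers
  transitively and cycles are an error naming the cycle.
* **Self-comparison** of a release puts every record in `unchanged` — used
  as a sanity check throughout.
* The events of the *first* ingested release are `ADDED` against an empty
  database; a dead entry predating the ingested window generates no event.

## Problem sizes in the test suite

The suite runs entirely offline in about 75 seconds: round-trip and diff
properties on simulated series of 12–25 precursors over 2–6 releases;
event-sourcing soundness on an 8-release, 200-precursor series;
ground-truth recovery across 20 seeded runs; and ~10⁴ random name mutations
against the nomenclature grammar validator. `scripts/acceptance.R` repeats
the pipeline at 60 precursors × 8 releases plus a 6-release retro-assignment
series and a 60-transcript synthetic UTR set.

## Known limitations

* Genomic coordinates (GFF/BED), `aliases.txt` and literature-reference
  parsing beyond verbatim retention are out of scope.
* Retro-assignment is automated; where real early-release curation deviates
  from the rule cascade, correctness depends on the overrides table, and
  unresolved records are visible as `PROV` identifiers rather than guessed.
* The seed matcher is deliberately simple: no conservation, context scoring,
  or wobble pairing. Its overlap ratios characterize sequence-change impact
  under canonical site rules, not any specific published predictor.
* The store is single-writer and in-memory with TSV persistence; it targets
  analysis reproducibility, not concurrent service backends.
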