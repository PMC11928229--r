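---
title: "Ontology-enhanced authoring of taxon-by-character matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-enhanced authoring of taxon-by-character matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charrec)
```

## The problem

Descriptive taxonomy records phenotypes as taxon-by-character matrices, but
the vocabulary used in published treatments is notoriously inconsistent:
the same state appears as "maroon" or "red brown", measurements are given
without the landmarks that make them comparable, and colors are recorded
as unstandardized names. Data produced this way are hard to compare across
treatments, for humans and harder still for machines. The most effective
place to fix this is at authoring time, in the hands of the author, not in
post-publication curation.

`charrec` is a headless engine for that workflow: a controlled phenotype
vocabulary with a full term lifecycle, a resolver that maps free-text
input onto preferred terms, characters with explicit measurement landmarks
and units, palette-based color capture, a curation queue for the conflicts
that inevitably arise when many authors extend a shared vocabulary, and
machine-readable exports (CSV, TriG knowledge graphs, generated narrative
text). A sedge genus (*Carex*) is the running example; nothing in the
engine is specific to it.

## The ontology model and term lifecycle

The vocabulary is an in-memory ontology with six top-level branches:
anatomical entities, qualities, units, scopes, a `to_review` holding area
for user-contributed terms, and collections. Terms carry a persistent
CURIE identifier (`carex:` plus a zero-padded 7-digit integer, minted
monotonically and never reused), a canonical lowercase underscore label
(display forms are derived, never stored), an optional definition, and
three synonym tiers beyond the label:

* **exact synonyms** — alternative spellings of the same concept
  ("cespitose" for *caespitose*);
* **broad synonyms** — strings of which only one sense matches ("light"
  for *bright*), which resolve with a warning;
* **not-recommended synonyms** — discouraged forms ("acutish" for
  *acute*), which resolve with a suggestion to use the preferred term.

Deprecation never deletes: a deprecated term keeps its identifier and
points to its replacement via `replaced_by`, so previously recorded
matrices stay resolvable. Replacement links are followed transitively to
the first live term; chains longer than one step are legal (the fixture
contains one of length two) and both the subclass graph and the
replacement graph are kept acyclic by every mutating operation. Whether
one-step chains suffice in practice is an open question; transitive
resolution is the safe superset.

Ontologies serialize to Turtle with a fixed prefix block and fully
deterministic ordering (roots first, then terms by label, fixed predicate
order), so saves are byte-identical and diffs are meaningful. Triples
whose predicates fall outside the schema are preserved verbatim in an
extras store and re-emitted, which keeps richer source ontologies intact
through an edit cycle. The reader is deliberately limited to this profile
(no blank nodes, collections, or multi-line literals); it is a format for
this package's files, not a general RDF toolkit, and OWL reasoning is out
of scope. In the test suite an independent RDF parser re-parses every
export as an oracle.

```{r}
o <- make_demo_ontology()
o
match_term(o, "cespitose")$match_kind
match_term(o, "awl shaped")$suggestion |> (\(id) o$terms[[id]]$label)()
```

## Term resolution and form linting

`match_term()` is exact-after-normalization, with strict tier priority:
live label, exact synonym, broad synonym, not-recommended synonym, then
labels/synonyms of deprecated terms (resolving through the replacement
chain). Ties inside a tier break by ascending identifier, so resolution
is a pure function of ontology state and query. There is deliberately no
edit-distance fuzziness: misspellings observed in practice motivate a
spell-checker, but an auto-applying fuzzy match would silently change
meaning, so anything unmatched is kept raw and routed to a new-term
proposal instead. If a user insists on a broad synonym such as "light",
the preferred term is recorded and the raw input kept in provenance; this
choice of semantics is unvalidated against observed author intent.

`validate_term_form()` lints candidate labels for the three error
patterns observed in user contributions — leading prepositions ("in
terminal spike"), embedded conjunctions ("papillose or smooth"), and
plural head nouns ("primarily pistillate inflorescence units"). The
stop-lists and the plural-suffix exception lexicon are JSON configuration
(`inst/extdata/config/term_form.json`), not code constants, because these
lists grow with observation. Flags are warnings for the curation queue,
never hard rejections. The plural heuristic is suffix-based
(`-s`/`-es`/`-ies`, with exceptions for `-ous`, `-us`, `-is`, `-ss` and a
word list), so genuinely irregular plurals can slip through; this is a
known limitation.

## Characters, landmarks and constraints

A character pairs an anatomical entity with a quality ("growth form of
plant", "length of stem"). Numerical characters must state a measurement
landmark — at least one of `measured_from` / `measured_to` /
`measured_at`, plus optional include/exclude refinements — and a unit from
the unit branch; each landmark slot is verified against the ontology
(exists and live), with unverified slots surfaced as warnings so new
landmark terms can be proposed first. Characters get their own `chr:`
identifier namespace: they are ontology-linked interface objects, not
ontology classes.

Complex characters take constraint clauses: structural (`+S`, associated
organ), positional (`+P`, e.g. "at mid-length") and distance (`+D`,
anchored to a reference organ with a magnitude). Percent magnitudes are
stored as ratios in [0, 1] ("at 10% below the flowering stem" is anchor +
0.10 + direction) so they are arithmetic-ready; display text is derived.

Recommendation starts from the recommended core set — the characters
every treatment of the group should record, keeping descriptions
parallel — and a hand-crafted decision tree adds characters along the
answered path: if the inflorescence is unbranched, inflorescence-unit
characters are never offered. Where the core set and tree activations
overlap, duplicates are dropped keeping first occurrence; ordering rules
for this overlap are not externally validated and are our choice.

## The matrix, shared values and update flags

Recording a state routes text through the resolver (with preferred-term
substitution on acceptance and the raw input always kept in provenance),
checks numeric ranges (`low <= high`, the character's unit), and accepts
palette colors for categorical characters. Certainty and degree modifiers
come from the modifier subgroup of the vocabulary; free-text pre- and
post-constraints are allowed. Provenance is append-only: no operation,
including replacement swaps, erases input history. Timestamps come from
an injectable clock, so sessions and their exports are reproducible;
multi-user behavior is simulated by explicit user ids (there is no
authentication layer in a headless core).

Every recorded value feeds a shared-value pool keyed by (taxon,
character), offered for reuse sorted by use count then recency. The pool
applies no auto-filtering — a reused misspelling stays on offer, with its
resolution warning attached — because silent filtering would hide exactly
the peer-visible signal that lets experts police each other's entries.

When terms are deprecated after recording, `scan_deprecated()` raises one
idempotent flag per affected state; authors either accept the suggested
replacement (value swapped, provenance appended) or contest it, which
files a deprecation dispute for expert review. Accepting every open flag
provably reaches a fixed point with no deprecated values.

## Color capture

Palettes are JSON data files (8 colors per hue family here: brown,
yellow-brown, yellow-green, green, red) pairing a label with an sRGB
triple; picking from a palette records both, so colors are comparable
numerically later. These packaged palettes are plausible stand-ins: the
mined palettes derived from calibrated specimen images belong to a
companion dataset and are deliberately not reproduced — palettes are
replaceable data, not code. Free-text colors ("white", "blue-green") are
accepted but carry no triple and are marked non-computable.

Color distance defaults to Euclidean distance in sRGB space, with a
redmean perceptual approximation selectable; which ΔE metric (if any) an
interactive tool should use is a configuration decision, and the default
is chosen for transparency, not perceptual fidelity. Nearest-color lookup
is an argmin over all palette entries with first-wins tie-breaking, and
is tested against exhaustive brute force.

## The conflict queue

Issues are typed: category assignment, definition approval, new-term
approval, exact-synonym identification, equivalent-term determination,
and deprecation disputes, plus a configurable extension type. Only six
types have externally grounded semantics; the seventh is left as a
documented extension slot rather than an invented meaning. Duplicate
(type, payload) submissions coalesce to one issue. Resolutions are
explicit records — notably, a synonym merge always names the survivor;
direction is never inferred — and are applied atomically: the mutated
ontology is validated before the issue closes, and a rejected mutation
leaves ontology and queue untouched. Whether a merged-away label should
remain matchable as an exact synonym of the survivor or only through the
replacement chain is configurable (`merge_keep_synonym`), with the
synonym behavior as default. Resolving emits update notices (new /
deprecated / modified terms) and re-scans affected matrices; the queue
persists as an append-only JSON-lines log.

## Exports

* **CSV** — RFC 4180, one header of character display names in organ-tab
  order, one row per (taxon, sample); multi-states joined by `"; "`;
  modifiers and constraints rendered in the micro-syntax
  `pre degree value post (certainty)`.
* **TriG** — one named graph per (taxon, sample); each state is a node
  under the package's documented `crm:` namespace with predicates for
  character, entity, quality, value (term IRI, decimal range plus unit
  IRI, or an `"rgb(r,g,b)"` literal plus label), modifiers, constraints
  and provenance. Pending raw-text states export with the `to_review`
  class as value plus the raw literal.
* **Narrative text** — deterministic template rendering grouped by organ
  tab (templates are configuration:
  `inst/extdata/config/templates.json`); ranges render `low–high unit`
  with point values collapsed. The narrative export is plain text /
  Markdown; a word-processor binary format is out of scope. No external
  example of generated prose exists to validate the template structure
  against, so it is marked as this package's own design.

The filled-state count is conserved across session file, CSV, TriG and
description, and repeated exports are byte-identical.

## The vocabulary-variation metric

`vocabulary_variation()` counts distinct word tokens across all state
values and constraints, tokenizing on non-alphanumerics, lowercasing and
keeping numbers — documented precisely so the worked reduction example is
reproducible: freehand matrices pooling 116 distinct words against
controlled matrices pooling 30 give `round((1 - 30/116) * 100) = 74`
percent reduction. Whether such counts should pool across participants or
average per matrix is ambiguous in general, so pooling is an explicit
argument (the metric takes a list of matrices and a baseline count).

```{r}
vf <- make_vocab_study_fixture()
v_free <- vocabulary_variation(vf$freehand, vf$ontology)
vocabulary_variation(vf$controlled, vf$ontology,
                     baseline = v_free$distinct_words)$reduction_pct
```

## What the fixtures emulate — and what they do not

The fixture generator is first-class, tested code. `make_demo_ontology()`
builds a ~76-term miniature with every synonym tier populated, a one-step
and a two-step replacement chain, measurement-landmark assertions, a
recommended-character collection and one user-contributed term under
review. `make_student_task_fixture()` replays the classroom recording
task: one taxon, 2 samples, the 6 recommended characters, 11 states
entered by two users (growth form is recorded once per taxon; every other
character once per sample — the layout chosen to match the task's stated
totals), on a counter clock starting 2022-04-01. The freehand-vocabulary
word list is calibrated to pool exactly 116 distinct tokens, the
controlled list to 30, because those are the study conditions the metric
is demonstrated under.

These fixtures are miniatures. They do not emulate: an ontology at
production scale (thousands of classes), concurrent editing, real
misspelling distributions, image-calibrated palette derivation, or
natural-language character parsing. Passing tests therefore demonstrate
the correctness of the mechanics — resolution tiers, lifecycle
invariants, export conservation — not robustness against the full
messiness of real authoring sessions.

## Numerical and testing choices

* Randomized property suites use 100 generated sessions for the
  round-trip checks and 1000 random sRGB triples for the nearest-color
  oracle, sizes at which the suites complete in well under a minute while
  exercising every value kind.
* Range values compare by their canonical display key (`%g` formatting)
  across the JSON store boundary, since JSON does not distinguish `40`
  from `40.0`.
* Degenerate inputs are defined errors, not silent repairs: empty labels,
  `low > high` ranges, kind-mismatched inputs, zero vocabulary baselines,
  out-of-range sRGB components, cyclic replacements and double-processed
  flags all raise typed conditions (`charrec_*_error`).
* Determinism everywhere: sorted emission orders, injected clocks, seeded
  generators; two runs of any export on the same session are
  byte-identical.

## Known limitations

Beyond those noted above: the Turtle profile is intentionally narrow; the
plural heuristic is English-only; decision trees are hand-crafted and
taxon-group-specific; and the engine is single-process — the
collaboration it models (shared pools, update flags) assumes sessions are
merged through the session files, not edited concurrently.
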