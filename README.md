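# charrec

Ontology-enhanced authoring of taxon-by-character matrices, as a headless
R library plus a thin command-line interface.

## The problem

Published phenotype data — taxon-by-character matrices and morphological
descriptions — suffer from inconsistent vocabulary: the same state is
written "maroon" or "red brown", measurements lack the landmarks that
make them comparable, colors are free-text names. `charrec` implements
the authoring-time fix: characters and states are recorded against a
controlled vocabulary with persistent identifiers, synonym tiers,
deprecation-with-replacement, explicit measurement landmarks and units,
and palette-based sRGB color capture, so the resulting matrix is FAIR
(findable, accessible, interoperable, reusable) at the moment of
creation. The matrix exports as CSV for spreadsheets, as a TriG knowledge
graph for computer agents, and as generated narrative text for readers.

At its core:

* **Term lifecycle** — terms are `carex:NNNNNNN` CURIEs, minted
  monotonically and never reused. Deprecation sets
  `owl:deprecated` + `replaced_by` and keeps the identifier, so old data
  stay resolvable; `resolve_replacement_chain()` follows links to the
  first live term.
* **Tiered resolution** — free text resolves by strict priority: exact
  label > exact synonym > broad synonym > not-recommended synonym >
  deprecated term (with its live replacement suggested). Exact-after-
  normalization only; unmatched input becomes a raw state plus a
  new-term proposal in the curation queue.
* **Vocabulary-variation metric** — distinct word tokens across state
  values and constraints; the percent reduction against a baseline
  vocabulary is `round((1 - observed/baseline) * 100)`.
* **Conflict queue** — typed issues (category assignment, definition
  approval, new-term approval, exact-synonym identification,
  equivalent-term determination, deprecation disputes, plus an extension
  type) with atomic, validated resolutions and update notices back to
  affected matrices.

## A worked example

```r
library(charrec)

fx <- make_student_task_fixture()   # ontology, characters, palettes, session
fx$matrix
#> <cr_matrix> 11 filled cell(s), 11 state(s), 0 flag(s)

# free text resolves to the preferred term
m <- match_term(fx$ontology, "cespitose")
fx$ontology$terms[[m$matched_term]]$label
#> [1] "caespitose"

# the recorded task is complete: 6 characters, 2 samples, 11 states
completeness_check(fx$matrix, fx$expected)[c("characters", "samples", "states")]
#> $characters
#> [1] 6
#> $samples
#> [1] 2
#> $states
#> [1] 11

# controlled vocabulary shrinks the word pool by 74%
vf <- make_vocab_study_fixture()
base <- vocabulary_variation(vf$freehand, vf$ontology)$distinct_words   # 116
vocabulary_variation(vf$controlled, vf$ontology, baseline = base)$reduction_pct
#> [1] 74

generate_description(fx$matrix, fx$ontology, fx$taxon)
#> Carex demonstrativa, sample A. habit: plant caespitose. stem: stem 40 cm.
#> leaf: leaf blade 3–5 mm; leaf sheath light yellow-brown; leaf smooth
#> throughout. perigynium: perigynium apex slightly acute. ...
```

The sample-A line above is exactly what the narrative exporter prints for
the generated session; the deprecation workflow, decision-tree character
recommendation and TriG export are shown in the vignette
(`vignettes/authoring-fair-matrices.Rmd`).

## Command line

A thin CLI over the same functions ships at `inst/cli/charrec`:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "charrec", package = "charrec"))')
Rscript "$cli" fixtures make-all --out demo/
Rscript "$cli" resolve "cespitose" --ontology demo/demo_ontology.ttl
Rscript "$cli" export --format trig --session demo/student_session.json \
    --characters demo/characters.json --ontology demo/demo_ontology.ttl \
    --out demo/matrix.trig
```

Commands print JSON and exit nonzero on error.

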