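---
title: "Mining adverse drug reactions from drug labels: models and design choices"
author: "adrminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining adverse drug reactions from drug labels: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrminer)
```

## The problem

Drug labels carry the authoritative record of a drug's adverse reactions
(ADRs), but as prose. To analyze ADRs at corpus scale — which reactions
co-occur across drugs, which chemical classes share a reaction — mentions
must first be found in text and normalized to a controlled vocabulary of
preferred terms. `adrminer` implements a dictionary- and rule-based
pipeline for this: no machine learning, no context modelling, just an
expandable term dictionary, deterministic matching, and set arithmetic on
the normalized results. That makes every downstream number exactly
reproducible and every error attributable to a specific rule.

The pipeline deliberately assumes that *any* mention of an ADR in a
drug's label associates that ADR with the drug. Negated or speculative
statements ("depression was not observed") are tagged like any other
mention, and discontinuous mentions ("corneal exposure and ulceration"
containing the concept *corneal ulceration*) are not detected. Both are
out of scope by design; they require contextual models that a dictionary
matcher cannot express, and they bound what the results can claim.

## The term dictionary and its expansion rules

A vocabulary entry has a preferred term, optional synonyms, and an
abbreviation lexicon of (long form → short form) pairs. Compilation
(`compileDictionary()`) generates the matchable surface forms:

* **Number expansion** (`expandNumber()`): the head noun (final token) is
  inflected both ways with a conservative rule-based English inflector,
  so a vocabulary listing only *peripheral neuropathy* still matches
  *peripheral neuropathies* and vice versa. Latin clinical endings
  (-us, -is, -osis, -itis, -oma), acronyms and words already ending in
  *s* are left alone: a wrong plural in the index would create false
  positives, which is worse than a missed variant. The expansion is
  closed — expanding any generated form yields only forms already in the
  set — which keeps the compiled index a fixpoint of its own rules.
* **Laboratory-finding variants** (`generateLabVariants()`): preferred
  names shaped "⟨analyte⟩ ⟨direction⟩" are expanded over direction-word
  synonym groups (default *increased/elevated/high/raised* and
  *decreased/reduced/low/lowered*, configurable) in both orders, with the
  analyte optionally replaced by its abbreviation short form:
  *Aspartate aminotransferase increased* → *increased AST*, *AST
  elevated*, *high AST*, … The two default groups generalize the handful
  of printed examples this rule family is known from; the full original
  rule set is not published, so the grammar here is a declared
  generalization, kept configurable.
* **The acronym guard**: short surfaces are where dictionary taggers fail
  in practice (the word *all* mapping to *acute lymphocytic leukaemia*).
  Surfaces shorter than `minAcronymLen` characters (default 5) are
  indexed only when they are declared abbreviation short forms, matched
  case-sensitively, and not on the stoplist (default `all`, `aids`). A
  consequence worth knowing: a short plain term like *rash* is not
  matchable at the default setting; lower `minAcronymLen` (or declare the
  term as its own abbreviation) if your vocabulary has legitimate short
  preferred terms. We chose the strict default because the false-positive
  mode is documented and the false-negative mode is visible and
  configurable.

Matching is case-insensitive at or above the guard length,
case-sensitive below it. All strings are NFC-normalized with whitespace
collapsed and punctuation stripped at token boundaries before key
construction, so matching does not depend on typographic accidents of
the source document.

## Labels, offsets and header exclusion

Labels are read from an XML dialect with `Text`/`Section` elements,
optional curated `Mentions` (span annotations) and `Reactions`
(normalized preferred-term ids), mirroring public structured-label
corpora. Offsets are 0-based, half-open, in characters (not bytes), and
every mention's `str` attribute is checked against its text slice on
read — a corrupted offset fails loudly at parse time, not silently at
scoring time. Unknown attributes are preserved on round trip, since the
synthetic fixtures rather than any particular corpus release are the
test surface.

Section titles and table headers mention ADR terms without asserting
them, so `detectHeaders()` marks (i) lines equal to the section title,
(ii) fully upper-case lines (the conventional rendering of headings in
label text; the regex is configurable), and (iii) rows explicitly
flagged as table headers in the markup. How the original corpora marked
table headers is not recoverable, so the cue-based rule is a declared
approximation. `filterHeaders()` removes any mention whose span
intersects a header span — any overlap, including straddling a boundary.

## Tagging

`tagDocument()` scans each section left to right over token boundaries.
At each token it tries the longest indexed surface first; a match
suppresses shorter matches inside it and scanning resumes after it, so
no two mentions overlap and *severe dermatitis* wins over *dermatitis*.
Token-boundary anchoring means *rash* can never match inside *brashare*.
A surface shared by several entries yields one mention carrying every
matched id — ambiguity is preserved, not resolved arbitrarily — and
ambiguous mentions contribute to every matched term when profiles are
counted. Output order (section, start) and sorted id sets make the
tagger deterministic.

Per-drug profiles union mentions over all of a drug's labels, because a
drug (a generic/active ingredient) can have several branded labels; the
analysis level is the drug, not the label.

## Evaluation

Scoring is at the level of normalized preferred terms per drug:
TP = |predicted ∩ gold|, R = TP/|gold|, P = TP/|predicted|,
F = 2PR/(P+R), with 0 substituted where a denominator vanishes. Both
micro aggregation (pool TP/gold/predicted counts, then compute metrics)
and macro aggregation (average per-drug metrics) are provided, and
reports always state the mode: the two are genuinely different
statistics, pooled counts published for a corpus need not be jointly
consistent with any single mode, and conflating them is a classic source
of unreproducible evaluation numbers.

## The co-occurrence network

Two ADR terms are joined when at least ⌈f·n⌉ of the n drugs list both;
the threshold uses an exact-ceiling computation guarded against binary
floating-point fuzz (so f = 0.3, n = 10 gives 3, never 4). Edge weight
is the co-occurring drug count; terms with no qualifying edge are
excluded from the node set, so the network contains no isolated
vertices. Raising f can only remove edges (threshold monotonicity), and
every edge weight is bounded by the support of its endpoints — both are
asserted by the class validity method on every construction.

Degree centrality is the neighbor count. Eigenvector centrality is the
principal eigenvector of the **unweighted** adjacency matrix — the
definition speaks of neighbors contributing proportionally to their own
centrality, not of weighted contributions — computed by shifted power
iteration (A + I, which has the same eigenvectors but avoids the ±λ
oscillation of plain power iteration on bipartite graphs) to a relative
tolerance of 1e-10. The vector is reported nonnegative with unit
Euclidean norm over the largest connected component; nodes in other
components get 0 and a warning, because the principal eigenvector of a
disconnected graph is supported on one component only and any value
assigned elsewhere would be an artifact of the normalization. Rankings
order by (eigenvector desc, degree desc, term id), and
`rankAndCompare()` additionally reports whether degree and eigenvector
rank a network identically — a diagnostic that holds for some real
networks but is not an invariant.

## Class effects

Drugs are mapped to chemical ontology terms and inherit every is-a
ancestor, so membership is ancestor-closed by construction. For class C
and ADR e, PCR = (drugs of C whose profile contains e)/|C|; PCR = 1
declares a class effect. Both the count and the ratio are reported so
any rescaling stays recoverable. The PCR table applies a minimum class
size (default 2) because a singleton "class" trivially has PCR = 1 for
its member's whole profile. `sharedAdrs()` computes the same set by
profile intersection; the two code paths are cross-checked in the tests.
A drug counts as associated with an ADR on any mention — no frequency
floor — consistent with the any-mention assumption stated above.

`extractSubtree()` renders a selected term set as a hierarchical view:
in computed-intermediate mode the output contains the selected terms,
every term on an upward is-a chain between two selected terms, and one
deterministic path to a top node per selected term (preferring parents
already included, then the smallest parent id). The included set is
iterated to a fixpoint on its own induced, transitively reduced graph,
which makes extraction idempotent: re-extracting an extracted view
returns it unchanged. Output edges are the ontology's reachability
restricted to included terms and transitively reduced, which keeps the
exported OBO readable without losing any ancestry.

## The synthetic universe

Real ADR vocabularies are license-restricted and curated label corpora
are access-restricted, so the test universe is synthesized end to end
from a closed vocabulary (adjective–noun reaction names, invented
analytes), with every artifact written to disk in standard formats and
every planted fact recorded in a ground-truth JSON. One integer seed
drives a single RNG stream; two runs with the same configuration are
byte-identical.

The generator emulates the features the pipeline is sensitive to:
surface variants rendered through the dictionary's own expansion rules
(a configurable fraction of mentions), ADR names planted inside
markup-flagged table-header rows (which a correct tagger must exclude —
these are deliberately terms *outside* the drug's profile, so a filter
failure shows up as a precision loss), acronym-trap distractor sentences
containing bare *all*/*aids*, multi-parent ontology terms, and planted
drug classes whose members share an exact ADR set. Non-planted classes
are post-processed so that no class other than the planted ones fully
shares any ADR; the zero-false-positive expectation is thus a property
of the construction, not of chance. It does **not** emulate clinical
narrative: sections are templated sentences, there is no negation or
speculation, no discontinuous mentions, no OCR noise, and no
distribution shift between dictionary and corpus. Passing on this
universe therefore demonstrates the mechanics (expansion, matching,
filtering, counting, thresholding, class arithmetic) — it says nothing
about recall on real prose, which is bounded by dictionary coverage.

Default study conditions (used by the acceptance script and the deeper
tests): 20 drugs, 60 ADR terms, one label per drug, profiles of about 12
ADRs, 30% variant rendering, and one planted 3-drug class sharing 43
ADRs with 5 private ADRs per member — a scaled-down mirror of a
benzimidazole-like class-effect scenario. Property-style suites run on
smaller instances (≤ 10 drugs, ≤ 8 ADRs for network oracles; ≤ 14-term
DAGs for extraction oracles) so the exhaustive reference computations
stay cheap.

## Numerical and degenerate-input choices

* Thresholds: exact ceiling with a 1e-9 fuzz guard.
* Power iteration: shifted (A + I), relative tolerance 1e-10, iteration
  cap 1e5; tests cross-check against dense eigendecomposition to 1e-8.
* Ties in tagging fall to the longest match, then the sorted id set;
  ties in ranking fall to degree, then term id; parent choice in subtree
  root paths falls to included-first, then smallest id.
* Empty inputs: an empty drug table, an empty aggregation list and an
  empty ontology class are errors (they have no meaningful value); an
  empty document, an empty mention list and an empty profile are valid
  and flow through as empty results.
* Unannotated labels read with `NULL` (absent) gold fields, distinct
  from annotated-but-empty.

## Known limitations

Dictionary coverage bounds recall; context is ignored (negation,
speculation, hypotheticals are tagged); discontinuous mentions are
missed; the header heuristics are cue-based approximations; eigenvector
centrality on near-disconnected networks reflects the largest component
only; and PCR treats all class sizes above the floor equally, although
PCR = 1 over 2 drugs is far weaker evidence than over 10 — the reported
`n_class_drugs` lets readers weigh that.
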