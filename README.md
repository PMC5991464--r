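# adrminer

Ontology-based mining and class-effect analysis of adverse drug reactions
(ADRs) from structured drug labels.

Regulatory drug labels list the adverse reactions observed for a drug, but
as free text. `adrminer` is for pharmacovigilance researchers who want to
turn a corpus of structured label documents into analyzable data: it tags
ADR mentions with an expandable term dictionary, normalizes them to
preferred terms, scores the tagging against gold annotations, builds
thresholded ADR–ADR co-occurrence networks with centrality analysis, and
computes ontology-based drug class effects.

## Methods at a glance

* **Dictionary compilation** — each vocabulary entry (preferred term,
  synonyms, abbreviation lexicon) is expanded by rule: singular/plural
  inflection of the head noun (*peripheral neuropathy* ⇄ *peripheral
  neuropathies*) and laboratory-finding reordering for names of the shape
  “⟨analyte⟩ ⟨direction⟩” (*Aspartate aminotransferase increased* →
  *increased AST*, *AST elevated*, *high AST*, …). Surfaces shorter than
  `minAcronymLen` (default 5) characters are treated as acronyms: matched
  case-sensitively, only if declared as abbreviation short forms, and
  suppressed by a stoplist (`all`, `aids`) — so the ordinary word *all*
  never maps to *acute lymphocytic leukaemia*.
* **Tagging** — leftmost-longest matching at token boundaries; mentions
  intersecting section titles or table-header rows are discarded; mentions
  from all of a drug's labels are unioned into a per-drug profile of
  normalized preferred terms.
* **Evaluation** — per-drug recall *R* = TP/|gold|, precision
  *P* = TP/|predicted|, *F* = 2PR/(P+R) over preferred-term sets, with
  micro (pooled counts) and macro (averaged metrics) aggregation.
* **Co-occurrence network** — ADR terms *a*, *b* are joined when at least
  ⌈f·n⌉ of the *n* drugs list both (e.g. 27 of 53 drugs at *f* = 0.5);
  edge weight is that drug count. Degree centrality counts neighbors;
  eigenvector centrality is the principal eigenvector of the unweighted
  adjacency matrix, unit-normalized on the largest connected component.
* **Class effects** — drugs inherit every is-a ancestor of their chemical
  ontology term; for a class *C* and ADR *e* the proportional class-level
  ratio is PCR = |{d ∈ C : e ∈ profile(d)}| / |C|, and PCR = 1 declares a
  drug class effect. Shared ADRs are exported as a hierarchical
  sub-ontology (computed-intermediate extraction).
* **Synthetic universe** — real ADR vocabularies are license-restricted
  and curated label corpora access-restricted, so `generateUniverse()`
  builds a fully synthetic, seeded test universe (dictionary, is-a
  ontology, labels with planted gold mentions, drug classes with planted
  shared-ADR effects) with machine-readable ground truth.

## Worked example

```r
library(adrminer)

dict <- compileDictionary(loadTermTable("dictionary.tsv"))
dict
#> TermDictionary: 2 entries, compiled (34 case-insensitive + 1 case-sensitive surfaces)

doc <- labelDocument("examplinib", "examplinib_L1",
  sections = data.frame(section_id = "S1", title = "adverse reactions",
    text = paste0("ADVERSE REACTIONS\nSome subjects developed peripheral ",
                  "neuropathies and high AST during the study.")))
mentions <- filterHeaders(tagDocument(doc, dict), detectHeaders(doc))
mentions[, 1:5]
#>   section_id start length                 surface term_ids
#> 1         S1    42     23 peripheral neuropathies 10034620
#> 2         S1    70      8                high AST 10003481

normalizeToProfile("examplinib", mentions)
#> DrugAdrProfile 'examplinib': 2 ADR term(s), 2 mention(s)
```

The plural *peripheral neuropathies* is recognized through the number
expansion of the dictionary entry *peripheral neuropathy* (id 10034620),
and *high AST* is normalized back to *Aspartate aminotransferase
increased* (id 10003481) through the laboratory-variant rule. The
`ADVERSE REACTIONS` header line is excluded from tagging.

A complete synthetic study — generation, tagging, evaluation, network and
class-effect analysis — runs with:

```r
runPipeline(list(seed = 42, synth = list(distractor_rate = 0)), "out/")
```

which writes `mentions.json`, `profiles.json`, `evaluation.json`,
network TSV/GraphML exports, `pcr.tsv`, one sub-ontology OBO per detected
class effect, and a run manifest.

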