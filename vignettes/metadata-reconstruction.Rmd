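---
title: "Reconstructing SRA sample metadata: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing SRA sample metadata: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sramend)
```

## The problem

Public RNA-seq archives hold millions of runs whose sample descriptions are
fragmented across several records: the SRA run XML (study, sample,
experiment and run blocks), the linked BioSample attribute list, and the
tabular fields returned by the NCBI API. A large share of those fields are
empty or filled with placeholders ("unknown", "missing"), keys are
submitter-defined and unnormalized, and values are frequently stored in the
wrong field or only implied by free text. Assembling a usable cohort — say,
all bulk RNA-seq runs of primary melanoma biopsies from untreated donors —
therefore requires heavy manual curation.

`sramend` reconstructs a fixed schema of **19 metadata classes** per run
(organ, disease, cell line, biopsy site and type, library selection,
sequencing source, donor age/sex/ethnicity, treatment and its timing,
clinical response, a cancer flag, plus four submission-mandatory fields) by
combining three mechanisms, in a fixed order of trust:

1. **API-direct copy** for the four fields every submission must carry
   (study accession, instrument platform, base count, library strategy).
2. **Deterministic rules**: alias-tagged field extraction, gazetteer
   matching against a cell-line registry, keyword heuristics for library
   selection / sequencing source / biopsy type, validation
   (type-and-range, ontology, cross-source consistency), attribute
   propagation from recognized cell lines, and normalization of disease and
   anatomy terms to ontology identifiers.
3. **Model completion** for whatever rules could not establish: one prompt
   per run and class against a pluggable backend, with per-prediction
   confidence. The packaged backend is a deterministic mock driven by a
   truth table; real model runners plug in behind the same two-function
   contract (`generate`, identity metadata) without changing anything else.

Rule-extracted, validated values are treated as ground truth: under the
default `locked` resolution policy the model only fills gaps and flagged
conflicts. The alternative `per_class_preference` policy lets the
statistically stronger source win per class — the rule value for library
selection and treatment, the model value elsewhere — while the losing value
is always retained in an `_alt` provenance column.

## The class schema

Classes carry a *kind* that decides both routing and validation:
`api_direct` (never prompted), `discrete`/`boolean` (closed label sets;
validation is case-insensitive membership with canonical casing restored),
`open_vocab` (free text; scored context-tolerantly), and
`numeric_or_qualitative` (`age`). The registry ships as a TSV
(`inst/extdata/classes.tsv`) so users can edit definitions or preferences
without touching code. Schema invariants (19 classes, 4 API-direct, 15
model-routed, the printed label sets) are enforced at load time.

Age bounds are \[0, 120\] years with qualitative fallbacks
child/teen/adult/senior — plausibility bounds for human donors. Sex folds
m/f abbreviations and accepts male/female/unknown. "unknown" is an
out-of-band abstention token for every class except `response` and `sex`,
whose closed sets legitimately include it.

## Contexts and the token budget

Each merged record is rendered into labeled sentences in a stable order
(study → sample → experiment → run → BioSample → API → user notes), with
placeholder values dropped. Overlong contexts degrade model extraction, so
bundles above a **2000-token budget** (default; `--token-budget`) are
summarized extractively: accession-shaped identifiers and boilerplate are
stripped, exact duplicate sentences removed, and remaining sentences kept
greedily in document order by *rare-term content* — the sum of inverse
within-bundle term frequencies — until the budget is met. The scoring rule
and boilerplate list are package decisions (the underlying idea is only
"keep rare informative phrasing"); both are configurable. The tokenizer is
a deterministic whitespace word counter by default, pluggable so a
backend's own tokenizer can be injected. Summarization is idempotent, and a
single sentence longer than the entire budget is truncated at a token
boundary with a warning.

## Rules and their limits

The library-selection heuristic is a table of keyword groups (polyA,
inverse rRNA, hybrid selection, small RNA) matched case-insensitively and
separator-elastically ("oligo.dT" also hits "oligo-dT", "oligo dT",
"oligodT") with precedence in that order. When no keyword fires the rule
stage **abstains** instead of answering "other": the "other" fallback
belongs to the model prompt, and abstention keeps genuinely undecided cases
on the model's desk. Biopsy type follows a strict three-way rule —
metastasis only with an established cancer context and an explicit
metastasis mention; blood on blood-related keywords without metastasis;
primary otherwise within a cancer context; abstain without one. Cancer
context comes from a keyword list plus the disease lexicon's cancer flags.

Cross-source consistency compares candidates from SRA XML, BioSample and
API after normalization: agreement is accepted as validated, disagreement
keeps all values `flagged` and emits an ambiguity note that is injected
into the model prompt. Duplicate BioSample attribute keys keep the first
occurrence and log the collision (the upstream formats do not define a
winner; first-wins is deterministic and auditable).

## Lexicons

Three flat TSVs drive normalization: a cell-line registry (canonical name,
synonyms, and the attributes a recognized line implies), a disease map with
Disease-Ontology-style identifiers and a cancer flag, and an anatomy map
with Uberon-style identifiers. The packaged fixture set (20 lines, ~34
diseases, ~32 anatomy terms) exists so the package installs and tests fully
offline; full Cellosaurus / DO / Uberon exports in the same schema are
drop-in replacements via `load_lexicons(dir)`. The gazetteer lowercases
names and synonyms, purges a configurable stoplist of generic terms and
phrases under 3 characters, and adds a regex fallback that equates
separator variants between letter and digit runs ("MCF7" ↔ "MCF-7").
Overlapping hits keep the longest match, then the earliest — a package
decision where the underlying behavior was unspecified.

Cell-line propagation fills biopsy site, cell type, organ, disease, age,
sex and ethnicity **only where missing**, never overwriting a validated
value, and tags fills as `lexicon_propagation`.

## Confidence

The backend returns per-token log-probabilities for the generated answer;
confidence is the mean negative log-likelihood (nats/token) and its
exponential, the perplexity, computed over answer tokens only (scope is a
package decision). `ppl == exp(mean_nll)` is enforced to 1e-9 throughout.

## The synthetic benchmark

Well-annotated real runs are scarce, so the generator builds labeled
paragraph contexts — and full SRA-like XML fixtures — that emulate the
pipeline's input space:

* **Balanced labels including "unknown"** per class (counts within ±1,
  per tier). A class whose label is "unknown" is *absent* from the text;
  known labels are stated *explicitly* (with the class keyword, and as a
  BioSample attribute in the XML rendering) or *paraphrased* through a
  lexicon synonym or an indirect cue, drawn 60/40 by default. Because
  absence is synonymous with an unknown label, the absent rate is fixed by
  balance and the explicit/paraphrase proportions apply to the remainder.
* **Per-class independence.** Labels are drawn independently per class,
  mirroring the per-class datasets of a one-adapter-per-class design. A
  consequence: a sample can carry a cell line whose registry organ differs
  from the sample's organ label, so cell-line propagation introduces a
  small, known error floor in end-to-end accuracy (~0.87 mean with a
  noise-free mock at n = 60); per-class evaluation of the model stage
  itself is unaffected. This is a deliberate trade-off, not a bug.
* **Split structure by construction.** Open-vocabulary value pools are
  partitioned across the reference (train-like) pool and the ID/MID/OOD
  tiers, so no open-vocabulary value recurs across splits. Each tier
  carries protocol boilerplate whose token overlap with the reference
  decreases from ID (identical) through MID (partial) to OOD (none).
* **Proximity splitting.** Samples are scored by maximum similarity to the
  reference set — token-set Jaccard by default; an embedding similarity
  with the same signature can be plugged in — sorted descending (ties by
  sample id) and cut into ID/MID/OOD partitions, 400/1200/400 by default
  from a 2000-sample pool. Mean similarity is monotone ID ≥ MID ≥ OOD by
  construction. Leakage diagnostics count cross-split near-duplicate pairs
  at a similarity threshold and verify pool disjointness.

What passing these tests shows — and does not. The generator's contexts are
template-assembled; they exercise every pipeline mechanism (parsing,
merging, rules, prompts, resolution, scoring) under controlled truth, but
they do not reproduce the linguistic messiness of real submitter text.
Accuracy on the synthetic benchmark is an upper bound on real-data
behavior, and the mock backend measures the harness, not a model.

The mock backend answers from the generator's machine-readable truth
markers (keyed by run accession, delivered out-of-band so they can never
leak into rule extraction or scoring) and perturbs answers with seeded
abstention/substitution noise. With rates $a$ and $s$, the abstention share
of errors on known references converges to $a/(a+s)$; the test suite checks
recovery within three standard errors at n = 1000.

## Evaluation

Matching is hybrid: exact (case-insensitive, full-set) for closed classes;
for open vocabulary a prediction is correct when any predicted value
matches any reference value by normalized string equality, a shared
lexicon/ontology identifier, or a listed synonym pair ("mouth" vs "oral
cavity"). Any-overlap is the default multi-value rule; a strict full-set
mode is available. Accuracy excludes reference-unknown pairs on request
(the convention for annotated-data reporting; "not applicable" counts as
unknown), signaling an undefined result distinctly when nothing remains.
Two trivial baselines (always-majority, always-unknown) expose majority
bias and over-abstention; errors are partitioned into abstentions and
substitutions with `class=value` pattern tallies.

## Numerical and operational choices

* Problem sizes in the shipped tests and acceptance script: pools of
  60–2000 samples, a 200-sample reference, taxonomy checks at n = 1000 —
  sizes chosen to make every property measurable in seconds on one CPU.
* All randomness is seeded; rule extraction and the mock pipeline are
  bit-reproducible (two runs export byte-identical tables).
* Exports: CSV/TSV/JSON always; Parquet/Feather behind the optional
  `arrow` capability; XLSX has no writer capability in this build and
  requesting it raises an error listing what is available.
* Live NCBI fetching is out of the tested path by design: every command and
  test runs from fixture directories; a live fetcher is a thin adapter
  behind the same three-function contract.

## Known limitations

Alias tables and heuristic synonym lists are curated defaults, not
exhaustive; ontology normalization is flat lookup (no graph reasoning over
ancestors); the hybrid matcher's tolerance rules are package-defined
stand-ins; treatment-like classes — where information is diluted in study
text — remain intrinsically hard for any extraction strategy, and nothing
in this package claims otherwise.
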