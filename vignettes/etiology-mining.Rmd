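---
title: "Mining symptom etiologies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining symptom etiologies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etiominer)
```

## The problem

Clinicians building a differential diagnosis need to know the possible
causes (*etiologies*) of a symptom. Curated resources cover the common
causes well but lag behind the literature on rare ones. This package
implements two complementary ways of mining symptom--etiology pairs from
sentence-level biomedical text, plus the evaluation machinery to compare
them:

1. **Syntactic patterns with human-guided bootstrapping** -- derive
   dependency-path extraction patterns from a handful of seed pairs, have a
   reviewer accept or reject each proposed pattern, and iterate.
2. **Generative verification** -- ask a large language model for an
   exhaustive etiology list, then ground every proposed item in corpus
   sentences through retrieval, model-based ranking, and a final yes/no
   vetting step, discarding anything without surviving evidence.

Everything operates on dependency-parsed sentences (CoNLL-U, basic
Universal Dependencies); the package never runs a parser itself.

## Dependency-path patterns

For a sentence with matched symptom span $A$ and etiology span $B$, the
span heads (the unique token in each span governed from outside it) become
endpoints of the unique undirected path through the dependency tree. The
path is linearized into a pattern: endpoints become capture placeholders,
interior tokens become lemma anchors, and each edge keeps its relation
label plus the direction it was walked (`<label` dependent-to-head,
`>label` head-to-dependent). For

> sciatica in low back pain is usually caused by disc herniation

with endpoints *sciatica* and *herniation* this yields

```
[symptom placeholder] : <nsubjpass : lemm=cause : >nmod_by : [disease placeholder]
```

Everything off the path (`in low back pain`, `is usually`) is dropped, so
the pattern generalizes far better than a surface template. Three design
points deserve note:

* **Direction notation.** The orientation of `<`/`>` is fixed by the
  passive construction above, where the symptom is the `nsubjpass`
  dependent of *caused*: walking out of the symptom is a
  dependent-to-head step, hence `<nsubjpass`.
* **Case-fused labels.** `nmod_by` is produced when a nominal-modifier
  edge's dependent carries a case-marking child (`by`). The tree itself is
  never mutated: matching resolves `nmod_by` structurally as `nmod` plus a
  case child with that lemma, so plain basic-UD trees are matched as-is.
  Fusion applies to `nmod` and `obl` dependents.
* **Directly connected endpoints.** When the two endpoints are linked by a
  single edge the path has no interior token, and the "lowest mutual
  ancestor" of a head--dependent pair is one of the pair itself, so no
  lexical anchor exists. We emit the single-edge pattern but flag it
  `anchor_free`; such patterns (e.g. `[symptom] : >nmod_with : [disease]`,
  the "sciatica with ____" shape) are precisely the ones a reviewer should
  reject, because nominal attachment alone does not assert causation. An
  alternative reading -- re-rooting the path through a shared governor --
  would add an anchor but changes the path semantics; we prefer the
  conservative emission plus review.

Matched placeholders are expanded to phrase boundaries by recursively
attaching dependents whose relation is `compound`, `amod`, `nummod`,
`flat`, or `nmod` without a case child, excluding determiners and
punctuation, and requiring contiguity (expansion stops at the first gap).
This set reproduces expansions like *herniation* → *disc herniation* /
*lumbar disc herniation* while keeping prepositional attachments out; it
is an argument of `expand_phrase()` for corpora with different annotation
habits. Placeholder tokens must be nominal when part-of-speech tags are
present; sentences without POS are matched unrestricted.

## Iterative bootstrapping

`run_bootstrap()` loops four steps: propose patterns from all sentences
containing a seed pair (`propose_patterns`, ranked by yield, threshold
`min_yield = 2` -- the conventional review threshold under which patterns
are too specific to be worth a reviewer's time), review each proposal
(accept/reject), apply the accepted pool corpus-wide (`apply_patterns`),
and harvest new seeds from the most frequent extractions (`select_seeds`,
defaults top 10 symptoms × top 50 etiologies, frequencies pooled by
fingerprint so spelling variants count together). The loop stops when no
new pattern reaches the yield threshold, with a safety cap of 10
iterations. A pattern decided once is never re-proposed, and the decision
log makes any session replayable to an identical state.

The reviewer is a contract, not a UI: `reviewer_interactive()` prompts on
the console, `reviewer_scripted()` replays a decision table, and
`reviewer_oracle()` -- used throughout the tests -- accepts a pattern when
its captures on the sample sentences agree with a gold standard at
precision ≥ 0.8, imitating a careful human inspecting sample matches.

Yield is counted over seed-matching sentences (what a reviewer actually
inspects), not over the whole corpus at proposal time.

## Mention unification

Extracted mentions are grouped into concepts keyed by a string
fingerprint: lowercase; strip punctuation; drop a leading article;
collapse whitespace; deduplicate and sort the tokens; and, when the joined
name is longer than 6 characters, replace each token by its American
Soundex code. Two choices are deliberate:

* The 6-character test applies to the whole joined name, but Soundex is
  then applied **per token**, since Soundex is defined for single words;
  codes are lowercased so the fingerprint is idempotent.
* Abbreviations are expanded **before** fingerprinting, using
  parenthetical definitions harvested from the corpus with the
  Schwartz--Hearst character-matching procedure (right-to-left scan, first
  short-form character anchored to a word-initial character, long-form
  candidate bounded by min(|SF|+5, 2·|SF|) words; conflicting definitions
  resolved by frequency then first occurrence).

Several Soundex variants exist; plain American Soundex is used here and
isolated behind `soundex()` so it can be swapped. Entity linking against a disease ontology is exposed only
as the `linker` argument of `unify()`; the default keeps the fingerprint
as the concept id, which leaves unlinkable names as faithful singletons.

## The verification pipeline

`verify_all()` composes four stages behind a pluggable backend
(`llm_backend()`): generation, retrieval, ranking, vetting. The three
prompts are stored verbatim as templates; tests assert their
characteristic clauses, because downstream behaviour (the "done" sentinel,
the ≤3-sentence array format, the yes/no reply) depends on the exact
wording. Default decoding parameters are temperature 1, max_tokens 4096,
top_p 1.

Retrieval scores each sentence against the query *"an etiology for
\<symptom\>"*. The default embedder is tf-idf cosine similarity -- a
transparent lexical baseline; a dense sentence embedder can be injected
through `retrieval_config(embedder=)`. Hard constraints (on by default)
additionally require the exact symptom and etiology phrases in the
sentence; this trades recall (paraphrased mentions are lost) for a large
precision gain at the vetting stage.

The ranking response is parsed tolerantly (code fences stripped, single
quotes accepted) because a generative model is not guaranteed to emit
valid JSON; any returned sentence that is not an exact member of the
candidate list is discarded. Vetting answers are normalized to `yes`/`no`;
anything else counts as `no` with a warning. Generation can be run
`n_runs` times with best-of-by-count selection; merging runs is not
attempted because near-duplicate names across runs have no reliable
automatic resolution.

The per-etiology funnel (generated → with candidate evidence → with
vetted evidence) is reported with every run and is monotonically
non-increasing by construction.

## The synthetic corpus

`generate_corpus()` emits parsed sentences from hand-built dependency
skeletons -- no parser, no downloads, byte-identical output for a fixed
seed. Six causal templates cover the common constructions (passive
*caused by*, transitive *induced*, *attributed to*, *associated with*,
participial *resulting from*, copular *is a common cause of*), one
distractor plants the symptom and etiology in a non-causal `nmod_with`
attachment ("Symptoms included X with Y and numbness"), and filler
sentences carry no relation at all. Slots are filled from small realistic
vocabularies; multi-word names are wired as compound chains. Surface
variants (title case, leading article), parenthetical abbreviation
definitions and subsequent short-form mentions are planted at configurable
rates, and the gold set records every relation span and every
variant-to-canonical mapping.

Defaults: equal weight on all seven templates, `noise_rate` 0.1,
`abbrev_rate` 0.15, `variant_rate` 0.3 -- enough distractor and variant
mass that the bootstrap trap and the unification machinery are genuinely
exercised.

What the generator does *not* emulate: parse errors, coordination and
apposition ambiguity, long sentences with multiple relations,
cross-sentence coreference, and the topical skew of real abstracts.
Passing tests on this corpus therefore demonstrate algorithmic
correctness -- path derivation, matching, bookkeeping, normalization --
not robustness to noisy parses, for which the quarantine path of
`read_conllu()` and the reviewer loop are the intended defences.

Problem sizes in the tests and the acceptance script (500-sentence
bootstrap benchmark, 1,000 round-trip relations, 50-sentence verification
corpus, 100 names × 5 variants for unification) were chosen to exercise
every code path at comfortable desk scale.

## Evaluation conventions

`pool_etiologies()` merges per-source name lists under an injectable
normalizer (default: the fingerprint; supply a lookup for a manually
curated mapping). Reference items are labelled supported by assumption;
everything else needs an annotation. `prf()` takes all supported pooled
items as the recall denominator and the source's own items as the
precision denominator; unsupported items never enter the gold set.
Aggregated sources ("patterns + gpt") are scored as a union with each
name counted once. `macro_average()` averages each component across
symptoms directly -- F is the mean of per-symptom F values, not
recomputed from averaged recall and precision. `overlap_counts()`
partitions supported items into the regions of the (at most three-set)
membership diagram, and `cohen_kappa()` gives chance-corrected
inter-annotator agreement; the degenerate case of two identical constant
annotators returns 1.

## Known limitations

* Only linearized path patterns are matched; richer query operators
  (sequential context, exact-word tokens at arbitrary positions) and
  enhanced-UD graphs are out of scope.
* The default retrieval embedder is lexical; semantic paraphrases of a
  symptom are only found through a plugged-in dense embedder.
* Abbreviation handling covers parenthetical definitions only.
* Pattern coverage is inherently open-ended: there is a long tail of ways
  to express causation, and a bootstrapped pool will never close it
  completely.
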