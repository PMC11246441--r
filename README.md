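# etiominer

Mining symptom etiologies (the diseases, conditions and exposures that
cause a clinical symptom) from dependency-parsed biomedical text.
Clinicians assembling a differential diagnosis rely on curated resources
that lag behind the literature, especially on rare causes; `etiominer`
implements two complementary literature-mining routes and the evaluation
machinery to compare them:

* **Syntactic patterns + human-guided bootstrapping.** From a seed pair
  like ⟨sciatica, herniation⟩, every co-occurrence sentence is turned into
  a linearized dependency-path pattern: the span heads become capture
  slots, interior tokens become lemma anchors, and each tree edge keeps
  its relation label and walk direction, e.g.

  ```
  [symptom placeholder] : <nsubjpass : lemm=cause : >nmod_by : [disease placeholder]
  ```

  Patterns are ranked by yield, accepted or rejected by a reviewer, the
  accepted pool is applied corpus-wide, and the most frequent extracted
  pairs seed the next round — iterating until new patterns become too
  specific (low yield) to matter.

* **LLM generation + fact verification.** A generative model is prompted
  for an exhaustive etiology list; each proposed item is grounded by
  retrieving candidate evidence sentences (tf-idf similarity to
  *"an etiology for \<symptom\>"*, optionally hard-constrained to contain
  both exact phrases), asking the model to rank ≤ 3 sentences as best
  evidence, and vetting each kept sentence with a yes/no prompt. Items
  without vetted evidence are discarded, removing hallucinations and
  attaching provenance. The model sits behind a pluggable backend, so the
  whole pipeline runs offline against scripted responses.

Extracted mentions are unified into ranked concepts via a canonical
fingerprint (lowercase → strip punctuation/articles → deduplicate and
sort tokens → per-token American Soundex for names over 6 characters)
with Schwartz–Hearst parenthetical abbreviation expansion. Evaluation
follows the pooled-judgment convention: sources are pooled under a name
normalizer, supported items form the recall denominator, and
precision/recall/F are reported per symptom with direct macro averaging,
plus source-overlap counts and Cohen's kappa for annotator agreement.

A deterministic synthetic-corpus generator (hand-built dependency
skeletons for six causal constructions, a non-causal distractor, filler,
surface variants and abbreviation definitions, with a full gold standard)
makes every stage testable without downloads.

## Worked example

```r
library(etiominer)

fix  <- system.file("extdata", "sciatica_example.conllu", package = "etiominer")
corp <- read_conllu(fix)
s    <- corp$sentences[["sciatica_example"]]

hit <- search_cooccurrence(corp, "sciatica", "herniation")
pat <- generate_pattern(s, c(hit$a_start, hit$a_end), c(hit$b_start, hit$b_end))
pat
#> <etio_pattern> [symptom placeholder] : <nsubjpass : lemm=cause : >nmod_by : [disease placeholder]

match_pattern(pat, s)[, c("sent_id", "symptom_text", "etiology_text")]
#>            sent_id symptom_text   etiology_text
#> 1 sciatica_example     sciatica disc herniation
```

The pattern keeps only the dependency path between the captures —
off-path words ("in low back pain", "is usually") never constrain it —
and the captured head *herniation* is expanded to its phrase boundary
*disc herniation*.

Bootstrapping against the synthetic benchmark, with the gold-set oracle
standing in for the human reviewer:

```r
gen <- generate_corpus(generator_config(n_sentences = 500, rng_seed = 42))
st  <- run_bootstrap(gen$corpus,
                     seed_tuples("hiccups", "multiple sclerosis"),
                     reviewer_oracle(gen$gold))
st
#> <etio_bootstrap_state> 3 iteration(s), 6 accepted / 3 rejected patterns, 122 seeds, 389 extractions
```

All six planted causal templates are accepted and the non-causal
distractor pattern (`[symptom placeholder] : >nmod_with : [disease
placeholder]`) is rejected. Unifying the extracted mentions:

```r
u <- unify(mentions(st$extractions$etiology_text),
           abbrevs = detect_abbreviations(gen$corpus))
head(u$concepts, 4)
#>       concept_id                    display count
#> 1 l364 m346 s536 lateral medullary syndrome    39
#> 2      d200 h653            disc herniation    38
#> 3      m431 s462         multiple sclerosis    38
#> 4           s623                sarcoidosis    37
```

Counts pool case variants, word-order variants and abbreviated mentions
("LMS") of the same etiology into one concept.

A thin command-line front end over the same functions ships in
`inst/cli/etiominer.R` (`simulate`, `corpus validate/search`,
`pattern derive/match`, `bootstrap`, `unify`, `verify`, `evaluate`).

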