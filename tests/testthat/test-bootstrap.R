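test_that("proposals are deduplicated, ranked by yield and thresholded", {
  cfg <- generator_config(n_sentences = 30, symptom_vocab = "sciatica",
                          etiology_vocab = "herniation",
                          template_mix = c(caused_by = 3, induced = 1),
                          abbrev_rate = 0, noise_rate = 0, variant_rate = 0,
                          rng_seed = 2)
  gen <- generate_corpus(cfg)
  seeds <- seed_tuples("sciatica", "herniation")
  props <- propose_patterns(gen$corpus, seeds, min_yield = 1)
  expect_identical(length(props), 2L)  # one pattern per template
  yields <- vapply(props, `[[`, integer(1), "yield")
  expect_true(all(diff(yields) <= 0))
  expect_identical(sum(yields), 30L)
  # threshold: min_yield above both yields leaves nothing
  expect_length(propose_patterns(gen$corpus, seeds, min_yield = 31), 0L)
  # previously decided patterns are not re-proposed
  decided <- props[[1]]$pattern$text_form
  rest <- propose_patterns(gen$corpus, seeds, min_yield = 1, decided = decided)
  expect_identical(length(rest), 1L)
  # no co-occurrence: empty proposal list
  expect_length(propose_patterns(gen$corpus,
                                 seed_tuples("anosmia", "lymphoma"), 1), 0L)
})

test_that("apply_patterns removes exact duplicates but keeps per-pattern keys", {
  s <- sciatica_sentence()
  corp <- corpus(list(s))
  p <- parse_pattern(sciatica_pattern_text)
  ext <- apply_patterns(corp, list(p, p))
  expect_identical(nrow(ext), 1L)   # same pattern twice: one extraction
  expect_identical(nrow(apply_patterns(corp, list())), 0L)
  # a second pattern reaching the same pair through another path is kept
  q <- parse_pattern(
    "[symptom placeholder] : <nsubjpass : lemm=cause : >nmod : [disease placeholder]")
  ext2 <- apply_patterns(corp, list(p, q))
  expect_identical(nrow(ext2), 2L)
  expect_identical(length(unique(ext2$pattern)), 2L)
})

test_that("seed harvesting matches a frequency-sort oracle", {
  ext <- empty_ext <- data.frame()
  mk <- function(sym, eti) data.frame(
    sent_id = "x", symptom_start = 1L, symptom_end = 1L,
    etiology_start = 3L, etiology_end = 3L,
    symptom_text = sym, etiology_text = eti, pattern = "p",
    stringsAsFactors = FALSE)
  ext <- rbind(mk("sciatica", "herniation"), mk("Sciatica", "herniation"),
               mk("sciatica", "lymphoma"), mk("hiccups", "lymphoma"),
               mk("hiccups", "stroke"), mk("anosmia", "stroke"))
  # fingerprint pools the case variants of sciatica (count 3)
  top1 <- select_seeds(ext, k_symptoms = 1, k_etiologies = 50)
  expect_true(all(tolower(top1$symptom) == "sciatica"))
  # counting oracle: five distinct fingerprint-collapsed pairs
  all_seeds <- select_seeds(ext, 10, 50)
  expect_identical(nrow(all_seeds), 5L)
  expect_identical(nrow(select_seeds(ext[0, ], 10, 50)), 0L)
  expect_identical(nrow(select_seeds(ext, 0, 50)), 0L)
})

test_that("bootstrap recovers planted templates and rejects the distractor", {
  cfg <- generator_config(n_sentences = 500, rng_seed = 42)
  gen <- generate_corpus(cfg)
  rel <- gen$gold$relations
  pair <- paste(rel$symptom_canonical, rel$etiology_canonical, sep = "|")
  seed <- strsplit(names(sort(table(pair), decreasing = TRUE))[1],
                   "|", fixed = TRUE)[[1]]
  st <- run_bootstrap(gen$corpus, seed_tuples(seed[1], seed[2]),
                      reviewer_oracle(gen$gold))
  accepted <- vapply(st$accepted, `[[`, character(1), "text_form")
  # all six causal templates accepted, distractor rejected
  expect_length(intersect(accepted, c(
    "[symptom placeholder] : <nsubjpass : lemm=cause : >nmod_by : [disease placeholder]",
    "[symptom placeholder] : <dobj : lemm=induce : >nsubj : [disease placeholder]",
    "[symptom placeholder] : <nsubjpass : lemm=attribute : >nmod_to : [disease placeholder]",
    "[symptom placeholder] : <nsubjpass : lemm=associate : >nmod_with : [disease placeholder]",
    "[symptom placeholder] : >acl : lemm=result : >nmod_from : [disease placeholder]",
    "[symptom placeholder] : <nmod_of : lemm=cause : >nsubj : [disease placeholder]")),
    6L)
  expect_true(
    "[symptom placeholder] : >nmod_with : [disease placeholder]" %in%
      st$rejected)
  expect_lte(st$iteration, 3L)
})

test_that("replaying a recorded decision log reproduces the state exactly", {
  cfg <- generator_config(n_sentences = 150, rng_seed = 8)
  gen <- generate_corpus(cfg)
  rel <- gen$gold$relations
  seeds <- seed_tuples(rel$symptom_canonical[1], rel$etiology_canonical[1])
  st <- run_bootstrap(gen$corpus, seeds, reviewer_oracle(gen$gold))
  replay <- run_bootstrap(gen$corpus, seeds, reviewer_scripted(st$decisions))
  expect_identical(replay$decisions, st$decisions)
  expect_identical(replay$extractions, st$extractions)
  expect_identical(replay$seed_pool, st$seed_pool)
})

test_that("pools grow monotonically and yields never shrink with more data", {
  cfg <- generator_config(n_sentences = 120, rng_seed = 15)
  gen <- generate_corpus(cfg)
  rel <- gen$gold$relations
  seeds <- seed_tuples(rel$symptom_canonical[1], rel$etiology_canonical[1])
  # yield monotonicity under corpus growth
  half <- corpus(gen$corpus$sentences[1:60])
  p_half <- propose_patterns(half, seeds, min_yield = 1)
  p_full <- propose_patterns(gen$corpus, seeds, min_yield = 1)
  for (pr in p_half) {
    full_match <- Filter(function(x)
      x$pattern$text_form == pr$pattern$text_form, p_full)
    expect_gte(full_match[[1]]$yield, pr$yield)
  }
  # accepted/rejected pools are disjoint after a run
  st <- run_bootstrap(gen$corpus, seeds, reviewer_oracle(gen$gold))
  accepted <- vapply(st$accepted, `[[`, character(1), "text_form")
  expect_length(intersect(accepted, st$rejected), 0L)
  # seed pool contains the initial seeds
  expect_true(nrow(merge(seeds, st$seed_pool)) == nrow(seeds))
})

test_that("corpus without co-occurrences terminates with empty pools", {
  gen <- generate_corpus(generator_config(n_sentences = 20, rng_seed = 4))
  st <- run_bootstrap(gen$corpus, seed_tuples("nosuch", "thing"),
                      reviewer_oracle(gen$gold))
  expect_identical(st$iteration, 0L)
  expect_length(st$accepted, 0L)
  expect_identical(nrow(st$extractions), 0L)
})
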