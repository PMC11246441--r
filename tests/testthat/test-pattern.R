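test_that("dependency path through the passive causal sentence is correct", {
  s <- sciatica_sentence()
  p <- shortest_dependency_path(s, 1L, 11L)
  expect_identical(p$nodes, c(1L, 8L, 11L))
  expect_identical(p$edges$label, c("nsubjpass", "nmod"))
  expect_identical(p$edges$direction, c("up", "down"))
  # directly governed pair: 2-node path
  d <- shortest_dependency_path(s, 10L, 11L)
  expect_identical(d$nodes, c(10L, 11L))
})

test_that("paths agree with a breadth-first-search oracle on random trees", {
  set.seed(31)
  for (rep in 1:20) {
    s <- random_tree_sentence(12)
    ab <- sample.int(12, 2)
    p <- shortest_dependency_path(s, ab[1], ab[2])
    expect_identical(p$nodes, bfs_path(s, ab[1], ab[2]))
  }
})

test_that("pattern generation drops off-path tokens and fuses case lemmas", {
  s <- sciatica_sentence()
  p <- generate_pattern(s, c(1, 1), c(10, 11))
  expect_identical(p$text_form, sciatica_pattern_text)
  expect_false(attr(p, "anchor_free"))
  # none of the off-path words leak into the pattern
  for (w in c("low", "back", "pain", "usually", "disc", "in"))
    expect_false(grepl(w, p$text_form))
})

test_that("directly connected endpoints yield a flagged single-edge pattern", {
  s <- parsed_sentence("direct", tokify(
    c("sciatica", "with", "herniation"), c(0, 3, 1),
    c("root", "case", "nmod")))
  p <- generate_pattern(s, c(1, 1), c(3, 3))
  expect_true(attr(p, "anchor_free"))
  expect_identical(
    p$text_form,
    "[symptom placeholder] : >nmod_with : [disease placeholder]")
})

test_that("a subject-object template derives its two-edge verb pattern", {
  cfg <- generator_config(n_sentences = 40, template_mix = c(induced = 1),
                          noise_rate = 0, variant_rate = 0, abbrev_rate = 0,
                          rng_seed = 5)
  gen <- generate_corpus(cfg)
  rel <- gen$gold$relations[1, ]
  s <- gen$corpus$sentences[[rel$sent_id]]
  p <- generate_pattern(s, c(rel$symptom_start, rel$symptom_end),
                        c(rel$etiology_start, rel$etiology_end))
  expect_identical(
    p$text_form,
    "[symptom placeholder] : <dobj : lemm=induce : >nsubj : [disease placeholder]")
})

test_that("parse/linearize round-trip is identity, errors are located", {
  p <- parse_pattern(sciatica_pattern_text)
  expect_identical(linearize(p), sciatica_pattern_text)
  expect_error(parse_pattern(""), "empty")
  expect_error(parse_pattern("[symptom placeholder] : ???"), "element 2")
  expect_error(parse_pattern(
    "[symptom placeholder] : <nsubj : [symptom placeholder]"), "distinct")

  # 100 random structurally valid patterns
  set.seed(77)
  labels <- c("nsubj", "nsubjpass", "dobj", "nmod", "nmod_by", "acl", "conj")
  for (rep in 1:100) {
    k <- sample(0:3, 1)  # interior anchors
    els <- list(list(kind = "placeholder",
                     role = sample(c("symptom", "etiology"), 1)))
    for (i in seq_len(k + 1)) {
      els[[length(els) + 1]] <- list(kind = "edge",
                                     label = sample(labels, 1),
                                     direction = sample(c("up", "down"), 1))
      if (i <= k)
        els[[length(els) + 1]] <- list(
          kind = "anchor",
          lemma = paste(sample(letters, 5, replace = TRUE), collapse = ""))
    }
    first <- els[[1]]$role
    els[[length(els) + 1]] <- list(
      kind = "placeholder",
      role = if (first == "symptom") "etiology" else "symptom")
    p <- etiominer:::new_pattern(els)
    q <- parse_pattern(p$text_form)
    expect_identical(q$elements, p$elements)
    expect_identical(q$text_form, p$text_form)
  }
})

test_that("pattern files round-trip and skip comments", {
  pats <- list(parse_pattern(sciatica_pattern_text),
               parse_pattern("[symptom placeholder] : <dobj : lemm=induce : >nsubj : [disease placeholder]"))
  f <- tempfile(fileext = ".txt")
  writeLines(c("# published pattern list", "",
               vapply(pats, `[[`, character(1), "text_form")), f)
  loaded <- read_patterns(f)
  expect_identical(vapply(loaded, `[[`, character(1), "text_form"),
                   vapply(pats, `[[`, character(1), "text_form"))
})

test_that("matching captures and phrase-expands the causal pair", {
  s <- sciatica_sentence()
  p <- parse_pattern(sciatica_pattern_text)
  caps <- match_pattern(p, s)
  expect_identical(nrow(caps), 1L)
  expect_identical(caps$symptom_text, "sciatica")
  expect_identical(caps$etiology_text, "disc herniation")

  # anchor lemma missing from the sentence: no match
  q <- parse_pattern(
    "[symptom placeholder] : <nsubjpass : lemm=induce : >nmod_by : [disease placeholder]")
  expect_identical(nrow(match_pattern(q, s)), 0L)

  # case-fused label requires the case child: plain nmod does not satisfy it
  r <- parse_pattern(
    "[symptom placeholder] : <nsubjpass : lemm=cause : >nmod_with : [disease placeholder]")
  expect_identical(nrow(match_pattern(r, s)), 0L)
})

test_that("a pattern matches exactly the sentences instantiating its template", {
  cfg <- generator_config(n_sentences = 50,
                          template_mix = c(caused_by = 1, induced = 1),
                          noise_rate = 0, variant_rate = 0, abbrev_rate = 0,
                          rng_seed = 23)
  gen <- generate_corpus(cfg)
  rel <- gen$gold$relations
  p <- parse_pattern(sciatica_pattern_text)
  matched <- unlist(lapply(gen$corpus$sentences, function(s)
    if (nrow(match_pattern(p, s)) > 0) s$sent_id))
  expect_setequal(matched, rel$sent_id[rel$template == "caused_by"])
})

test_that("phrase expansion follows modifier relations and contiguity", {
  s <- sciatica_sentence()
  expect_identical(expand_phrase(s, 11L), c(10L, 11L))  # disc herniation
  expect_identical(expand_phrase(s, 8L), c(8L, 8L))     # verb: singleton
  # "low back pain": amod + compound children of pain
  expect_identical(expand_phrase(s, 5L), c(3L, 5L))
  # non-contiguous dependent: expansion stops at the break
  br <- parsed_sentence("brk", tokify(
    c("renal", "but", "cyst"), c(3, 3, 0), c("amod", "cc", "root")))
  expect_identical(expand_phrase(br, 3L), c(3L, 3L))
})

test_that("generate/match round-trip recovers span heads on synthetic matches", {
  cfg <- generator_config(n_sentences = 60, noise_rate = 0, rng_seed = 19)
  gen <- generate_corpus(cfg)
  rel <- gen$gold$relations
  for (i in seq_len(nrow(rel))) {
    s <- gen$corpus$sentences[[rel$sent_id[i]]]
    p <- generate_pattern(s, c(rel$symptom_start[i], rel$symptom_end[i]),
                          c(rel$etiology_start[i], rel$etiology_end[i]))
    caps <- match_pattern(p, s)
    expect_gt(nrow(caps), 0L)
    hit <- any(caps$symptom_end >= rel$symptom_start[i] &
                 caps$symptom_start <= rel$symptom_end[i] &
                 caps$etiology_end >= rel$etiology_start[i] &
                 caps$etiology_start <= rel$etiology_end[i])
    expect_true(hit)
  }
})
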