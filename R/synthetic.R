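# Deterministic generator of parsed sentences with planted symptom-etiology
# relations. Every sentence is emitted from a hand-built dependency skeleton
# (no parser is invoked), so the trees are valid by construction and every
# planted relation is known exactly. The templates mirror the causal
# constructions common in PubMed abstracts ("X is caused by Y", "Y induced
# X", "X resulting from Y", "Y is a common cause of X") plus one distractor
# construction ("symptoms included X with Y and numbness") in which the
# symptom and etiology co-occur without a causal assertion -- a known trap
# for pattern bootstrapping.

# skeleton row: form lemma upos head deprel; {SYM}/{ETI} mark slots
.skel <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(form = r[[1]], lemma = r[[2]], upos = r[[3]],
               head = as.integer(r[[4]]), deprel = r[[5]],
               stringsAsFactors = FALSE)))
}

etio_templates <- function() {
  list(
    caused_by = list(type = "causal", skeleton = .skel(
      list("{SYM}", "", "NOUN", 3, "nsubjpass"),
      list("is", "be", "AUX", 3, "auxpass"),
      list("caused", "cause", "VERB", 0, "root"),
      list("by", "by", "ADP", 5, "case"),
      list("{ETI}", "", "NOUN", 3, "nmod"),
      list(".", ".", "PUNCT", 3, "punct"))),
    induced = list(type = "causal", skeleton = .skel(
      list("{ETI}", "", "NOUN", 2, "nsubj"),
      list("induced", "induce", "VERB", 0, "root"),
      list("{SYM}", "", "NOUN", 2, "dobj"),
      list(".", ".", "PUNCT", 2, "punct"))),
    attributed_to = list(type = "causal", skeleton = .skel(
      list("{SYM}", "", "NOUN", 3, "nsubjpass"),
      list("was", "be", "AUX", 3, "auxpass"),
      list("attributed", "attribute", "VERB", 0, "root"),
      list("to", "to", "ADP", 5, "case"),
      list("{ETI}", "", "NOUN", 3, "nmod"),
      list(".", ".", "PUNCT", 3, "punct"))),
    associated_with = list(type = "causal", skeleton = .skel(
      list("{SYM}", "", "NOUN", 3, "nsubjpass"),
      list("is", "be", "AUX", 3, "auxpass"),
      list("associated", "associate", "VERB", 0, "root"),
      list("with", "with", "ADP", 5, "case"),
      list("{ETI}", "", "NOUN", 3, "nmod"),
      list(".", ".", "PUNCT", 3, "punct"))),
    resulting_from = list(type = "causal", skeleton = .skel(
      list("{SYM}", "", "NOUN", 0, "root"),
      list("resulting", "result", "VERB", 1, "acl"),
      list("from", "from", "ADP", 4, "case"),
      list("{ETI}", "", "NOUN", 2, "nmod"),
      list(".", ".", "PUNCT", 1, "punct"))),
    cause_of = list(type = "causal", skeleton = .skel(
      list("{ETI}", "", "NOUN", 5, "nsubj"),
      list("is", "be", "AUX", 5, "cop"),
      list("a", "a", "DET", 5, "det"),
      list("common", "common", "ADJ", 5, "amod"),
      list("cause", "cause", "NOUN", 0, "root"),
      list("of", "of", "ADP", 7, "case"),
      list("{SYM}", "", "NOUN", 5, "nmod"),
      list(".", ".", "PUNCT", 5, "punct"))),
    included_with = list(type = "distractor", skeleton = .skel(
      list("Symptoms", "symptom", "NOUN", 2, "nsubj"),
      list("included", "include", "VERB", 0, "root"),
      list("{SYM}", "", "NOUN", 2, "dobj"),
      list("with", "with", "ADP", 5, "case"),
      list("{ETI}", "", "NOUN", 3, "nmod"),
      list("and", "and", "CCONJ", 7, "cc"),
      list("numbness", "numbness", "NOUN", 5, "conj"),
      list(".", ".", "PUNCT", 2, "punct")))
  )
}

.fillers <- function() {
  list(
    .skel(list("The", "the", "DET", 2, "det"),
          list("study", "study", "NOUN", 3, "nsubj"),
          list("enrolled", "enroll", "VERB", 0, "root"),
          list("forty", "forty", "NUM", 6, "nummod"),
          list("consecutive", "consecutive", "ADJ", 6, "amod"),
          list("patients", "patient", "NOUN", 3, "dobj"),
          list(".", ".", "PUNCT", 3, "punct")),
    .skel(list("Data", "data", "NOUN", 3, "nsubjpass"),
          list("were", "be", "AUX", 3, "auxpass"),
          list("collected", "collect", "VERB", 0, "root"),
          list("retrospectively", "retrospectively", "ADV", 3, "advmod"),
          list(".", ".", "PUNCT", 3, "punct")),
    .skel(list("Mean", "mean", "ADJ", 2, "amod"),
          list("follow-up", "follow-up", "NOUN", 5, "nsubj"),
          list("was", "be", "AUX", 5, "cop"),
          list("twelve", "twelve", "NUM", 5, "nummod"),
          list("months", "month", "NOUN", 0, "root"),
          list(".", ".", "PUNCT", 5, "punct")))
}

#' Default vocabularies for the synthetic corpus
#'
#' Small sets of real symptom and etiology names (some multi-word) giving
#' the generator a realistic phrase-structure mix.
#' @return Character vector of names.
#' @export
default_symptom_vocab <- function() {
  c("sciatica", "hiccups", "jaundice", "chest pain", "back pain",
    "anosmia", "polyuria", "paresthesia")
}

#' @rdname default_symptom_vocab
#' @export
default_etiology_vocab <- function() {
  c("disc herniation", "endometriosis", "lymphoma", "viral hepatitis",
    "multiple sclerosis", "meningitis", "renal cyst", "pancreatitis",
    "gastric distention", "sarcoidosis", "myocardial infarction",
    "lateral medullary syndrome")
}

#' Configuration for the synthetic corpus generator
#'
#' @param n_sentences Number of sentences to emit.
#' @param symptom_vocab,etiology_vocab Name vocabularies; entries may be
#'   multi-word (the last word is wired as the phrase head, preceding words
#'   as `compound` dependents).
#' @param template_mix Named non-negative weights over template ids
#'   (see [etio_templates()]); default gives equal weight to the six causal
#'   templates and the distractor.
#' @param abbrev_rate Fraction of multi-word etiology slots that carry a
#'   parenthetical abbreviation definition ("viral hepatitis ( VH )").
#' @param noise_rate Fraction of sentences that are irrelevant filler.
#' @param variant_rate Fraction of slot realizations that use a surface
#'   variant (title case, or a leading article) of the canonical name.
#' @param rng_seed Integer seed; identical config implies byte-identical
#'   output.
#' @return A list of class `etio_gen_config`.
#' @export
generator_config <- function(n_sentences = 100L,
                             symptom_vocab = default_symptom_vocab(),
                             etiology_vocab = default_etiology_vocab(),
                             template_mix = NULL,
                             abbrev_rate = 0.15,
                             noise_rate = 0.1,
                             variant_rate = 0.3,
                             rng_seed = 1L) {
  if (length(symptom_vocab) == 0L || length(etiology_vocab) == 0L)
    stop("symptom and etiology vocabularies must be non-empty")
  tmpl <- etio_templates()
  if (is.null(template_mix))
    template_mix <- stats::setNames(rep(1, length(tmpl)), names(tmpl))
  unknown <- setdiff(names(template_mix), names(tmpl))
  if (length(unknown) > 0L)
    stop("unknown template ids in template_mix: ", paste(unknown, collapse = ", "))
  if (any(template_mix < 0) || sum(template_mix) <= 0)
    stop("template_mix weights must be non-negative with positive sum")
  for (r in c(abbrev_rate, noise_rate, variant_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  structure(list(n_sentences = as.integer(n_sentences),
                 symptom_vocab = symptom_vocab,
                 etiology_vocab = etiology_vocab,
                 template_mix = template_mix,
                 abbrev_rate = abbrev_rate, noise_rate = noise_rate,
                 variant_rate = variant_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "etio_gen_config")
}

.titlecase <- function(x) {
  words <- strsplit(x, " ", fixed = TRUE)[[1]]
  paste(toupper(substring(words, 1, 1)), substring(words, 2), sep = "",
        collapse = " ")
}

.initials <- function(x) {
  toupper(paste(substring(strsplit(x, " ", fixed = TRUE)[[1]], 1, 1),
                collapse = ""))
}

#' Generate a synthetic parsed corpus with gold relations
#'
#' Emits `n_sentences` parsed sentences from the template skeletons. Each
#' causal sentence contributes exactly one gold relation; distractor and
#' filler sentences contribute none. The gold set also records a concept
#' map from every surface variant planted (case variants, leading articles,
#' abbreviations) to its canonical vocabulary entry, which downstream
#' mention unification is expected to recover.
#'
#' @param config An [generator_config()] object.
#' @return A list with `corpus` (an `etio_corpus`) and `gold` (class
#'   `etio_gold`: `relations` data.frame with sentence ids, spans, texts and
#'   canonical names; `concept_map` data.frame of variant/canonical/role).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "etio_gen_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$rng_seed)

  tmpl <- etio_templates()
  fillers <- .fillers()
  weights <- config$template_mix[names(config$template_mix)]
  sentences <- vector("list", config$n_sentences)
  relations <- list()
  variants <- list()
  abbrev_defined <- character()   # canonical etiologies with a defined abbrev

  add_variant <- function(variant, canonical, role) {
    variants[[length(variants) + 1L]] <<- data.frame(
      variant = variant, canonical = canonical, role = role,
      stringsAsFactors = FALSE)
  }

  # realize one slot: returns list(words, lemmas, article, abbrev, text)
  realize_slot <- function(canonical, role) {
    style <- if (stats::runif(1) < config$variant_rate)
      sample(c("title", "article"), 1L) else "plain"
    text <- if (style == "title") .titlecase(canonical) else canonical
    list(words = strsplit(text, " ", fixed = TRUE)[[1]],
         article = style == "article", text = text,
         canonical = canonical, role = role)
  }

  for (i in seq_len(config$n_sentences)) {
    sent_id <- sprintf("syn%05d", i)
    if (stats::runif(1) < config$noise_rate) {
      skel <- fillers[[sample.int(length(fillers), 1L)]]
      sentences[[i]] <- parsed_sentence(sent_id, .emit_tokens(skel, list()),
                                        doc_id = "synthetic")
      next
    }
    tid <- sample(names(weights), 1L, prob = weights)
    tm <- tmpl[[tid]]
    sym <- realize_slot(sample(config$symptom_vocab, 1L), "symptom")
    eti_canon <- sample(config$etiology_vocab, 1L)

    use_abbrev <- eti_canon %in% abbrev_defined && stats::runif(1) < 0.25
    if (use_abbrev) {
      eti <- list(words = .initials(eti_canon), article = FALSE,
                  text = .initials(eti_canon), canonical = eti_canon,
                  role = "etiology")
    } else {
      eti <- realize_slot(eti_canon, "etiology")
    }
    define_abbrev <- !use_abbrev && length(eti$words) >= 2L &&
      stats::runif(1) < config$abbrev_rate
    if (define_abbrev) {
      eti$abbrev <- .initials(eti_canon)
      abbrev_defined <- union(abbrev_defined, eti_canon)
      add_variant(eti$abbrev, eti_canon, "etiology")
    }
    add_variant(sym$text, sym$canonical, "symptom")
    add_variant(eti$text, eti$canonical, "etiology")

    emitted <- .emit_tokens(tm$skeleton, list(SYM = sym, ETI = eti))
    sentences[[i]] <- parsed_sentence(sent_id, emitted$tokens,
                                      doc_id = "synthetic")
    if (tm$type == "causal") {
      relations[[length(relations) + 1L]] <- data.frame(
        sent_id = sent_id, template = tid,
        symptom_start = emitted$spans$SYM[1L],
        symptom_end = emitted$spans$SYM[2L],
        etiology_start = emitted$spans$ETI[1L],
        etiology_end = emitted$spans$ETI[2L],
        symptom_text = sym$text, etiology_text = eti$text,
        symptom_canonical = sym$canonical,
        etiology_canonical = eti$canonical,
        stringsAsFactors = FALSE)
    }
  }

  relations <- if (length(relations)) do.call(rbind, relations) else
    data.frame(sent_id = character(), template = character(),
               symptom_start = integer(), symptom_end = integer(),
               etiology_start = integer(), etiology_end = integer(),
               symptom_text = character(), etiology_text = character(),
               symptom_canonical = character(),
               etiology_canonical = character(), stringsAsFactors = FALSE)
  cm <- if (length(variants)) do.call(rbind, variants) else
    data.frame(variant = character(), canonical = character(),
               role = character(), stringsAsFactors = FALSE)
  cm <- cm[!duplicated(paste(cm$variant, cm$role)), , drop = FALSE]
  rownames(cm) <- NULL
  bad <- tapply(cm$canonical, paste(cm$variant, cm$role),
                function(x) length(unique(x)))
  if (any(bad > 1L))
    stop("internal error: a planted variant maps to multiple canonicals")
  list(corpus = corpus(sentences, provenance = "synthetic generator"),
       gold = structure(list(relations = relations, concept_map = cm),
                        class = "etio_gold"))
}

# Expand a skeleton into a token table, splicing multi-word slot phrases.
# Returns the token data.frame when no slots, else list(tokens, spans) with
# spans = content-word range per slot (article excluded).
.emit_tokens <- function(skeleton, slots) {
  n <- nrow(skeleton)
  widths <- integer(n)
  for (i in seq_len(n)) {
    f <- skeleton$form[i]
    if (f %in% c("{SYM}", "{ETI}")) {
      sl <- slots[[sub("[{}]", "", gsub("[{}]", "", f))]]
      widths[i] <- (if (isTRUE(sl$article)) 1L else 0L) + length(sl$words) +
        (if (!is.null(sl$abbrev)) 3L else 0L)
    } else widths[i] <- 1L
  }
  offset <- cumsum(c(0L, widths[-n]))
  # final index of each skeleton row's main token (slot phrase head)
  main <- integer(n)
  for (i in seq_len(n)) {
    f <- skeleton$form[i]
    if (f %in% c("{SYM}", "{ETI}")) {
      sl <- slots[[gsub("[{}]", "", f)]]
      main[i] <- offset[i] + (if (isTRUE(sl$article)) 1L else 0L) +
        length(sl$words)
    } else main[i] <- offset[i] + 1L
  }
  rows <- list()
  spans <- list()
  for (i in seq_len(n)) {
    f <- skeleton$form[i]
    hd <- if (skeleton$head[i] == 0L) 0L else main[skeleton$head[i]]
    if (f %in% c("{SYM}", "{ETI}")) {
      key <- gsub("[{}]", "", f)
      sl <- slots[[key]]
      pos <- offset[i]
      if (isTRUE(sl$article)) {
        pos <- pos + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          id = pos, form = "the", lemma = "the", upos = "DET",
          head = main[i], deprel = "det", stringsAsFactors = FALSE)
      }
      k <- length(sl$words)
      for (w in seq_len(k)) {
        pos <- offset[i] + (if (isTRUE(sl$article)) 1L else 0L) + w
        rows[[length(rows) + 1L]] <- data.frame(
          id = pos, form = sl$words[w], lemma = tolower(sl$words[w]),
          upos = "NOUN",
          head = if (w < k) main[i] else hd,
          deprel = if (w < k) "compound" else skeleton$deprel[i],
          stringsAsFactors = FALSE)
      }
      spans[[key]] <- c(main[i] - k + 1L, main[i])
      if (!is.null(sl$abbrev)) {
        base <- main[i]
        rows[[length(rows) + 1L]] <- data.frame(
          id = base + 1L, form = "(", lemma = "(", upos = "PUNCT",
          head = base + 2L, deprel = "punct", stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          id = base + 2L, form = sl$abbrev, lemma = tolower(sl$abbrev),
          upos = "NOUN", head = base, deprel = "appos",
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          id = base + 3L, form = ")", lemma = ")", upos = "PUNCT",
          head = base + 2L, deprel = "punct", stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        id = main[i], form = f, lemma = skeleton$lemma[i],
        upos = skeleton$upos[i], head = hd, deprel = skeleton$deprel[i],
        stringsAsFactors = FALSE)
    }
  }
  tokens <- do.call(rbind, rows)
  tokens <- tokens[order(tokens$id), , drop = FALSE]
  rownames(tokens) <- NULL
  if (length(slots) == 0L) return(tokens)
  list(tokens = tokens, spans = spans)
}
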