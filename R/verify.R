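# Generate -> retrieve -> rank -> vet verification of model-proposed
# etiologies. A generative model is first prompted for an exhaustive list of
# etiologies for a symptom; each proposed etiology is then grounded against
# a sentence corpus: candidate evidence sentences are retrieved by
# similarity to the query "an etiology for <symptom>" (optionally with hard
# constraints requiring both exact phrases to appear), the model ranks up to
# three sentences as best evidence, and a final yes/no prompt vets each
# kept sentence. An etiology survives only with at least one vetted
# sentence, which removes hallucinations and attaches provenance.
#
# The model sits behind a minimal backend contract so the whole pipeline is
# testable with scripted responses.

#' Prompt templates
#'
#' The four prompt templates of the pipeline, with `<symptom>`,
#' `<candidate_etiology>`, `<sentences>` and `<evidence_sentence>` slots.
#' @name prompts
#' @export
prompt_generation <- paste0(
  "Provide an exhaustive list of all possible <symptom> etiologies. ",
  "Be succinct, list only names, each name in its own line. ",
  "Include all known etiologies, even the most rare ones. ",
  "write done when you finish listing all etiologies.")

#' @rdname prompts
#' @export
prompt_ranking <- paste0(
  "From the list of sentences below (one per line), which 3 sentences ",
  "would be the most convincing ones to be used as evidence that ",
  "<candidate_etiology> is an etiology for <symptom>?\n",
  "When selecting the 3 sentences, prioritize sentences which explicitly ",
  "state that the item belongs to the list over ones where this is only ",
  "implied.\n",
  "Only select sentences from the list below, do not add new sentences. ",
  "If the list does not contain 3 sentences that could be used as ",
  "supportive evidence, return fewer sentences, or 0 sentences (an empty ",
  "list) if needed.\n",
  "Format the results as a Python array, where each item is a dict with ",
  "two items, the first item (\"sent\"), is the sentence itself. The second ",
  "item (\"reason\") is a textual explanation of the reason why the ",
  "sentence was selected.\n",
  "Be succinct, reply with the Python list and nothing else.\n\n",
  "<sentences>")

#' @rdname prompts
#' @export
prompt_vetting <- paste0(
  "Can the following sentence be used as evidence that ",
  "\"<candidate_etiology>\" is an etiology for <symptom>? ",
  "Be succinct, and reply with yes or no only.\n",
  "The sentence is:\n<evidence_sentence>")

fill_prompt <- function(template, ...) {
  slots <- list(...)
  for (nm in names(slots))
    template <- gsub(paste0("<", nm, ">"), slots[[nm]], template,
                     fixed = TRUE)
  template
}

#' Construct an LLM backend
#'
#' A backend is a function `(prompt, temperature, max_tokens, top_p) ->
#' character` wrapped with a name. Default decoding parameters are
#' temperature 1, max_tokens 4096, top_p 1.
#'
#' @param complete Completion function.
#' @param name Backend label.
#' @return An object of class `etio_backend`.
#' @export
llm_backend <- function(complete, name = "custom") {
  stopifnot(is.function(complete))
  structure(list(complete = complete, name = name), class = "etio_backend")
}

.complete <- function(backend, prompt, temperature = 1, max_tokens = 4096,
                      top_p = 1) {
  stopifnot(inherits(backend, "etio_backend"))
  res <- backend$complete(prompt, temperature, max_tokens, top_p)
  paste(as.character(res), collapse = "\n")
}

#' Scripted mock backend
#'
#' Deterministic backend for tests and offline runs: `handlers` is a list
#' of `list(match = <regex on the prompt>, response = <string or
#' function(prompt)>)`; the first matching handler answers. A pure function
#' of the prompt, so pipeline runs are bit-reproducible.
#'
#' @param handlers Handler list.
#' @param default Response when no handler matches.
#' @return An `etio_backend`.
#' @export
scripted_backend <- function(handlers, default = "") {
  llm_backend(function(prompt, temperature, max_tokens, top_p) {
    for (h in handlers) {
      if (grepl(h$match, prompt)) {
        if (is.function(h$response)) return(h$response(prompt))
        return(h$response)
      }
    }
    default
  }, name = "scripted")
}

#' OpenAI-compatible live backend
#'
#' Thin adapter that posts a chat completion via the system `curl` binary.
#' Requires network access and an API key; every call is logged via
#' `message()`. Never used by the test suite.
#'
#' @param model Model identifier.
#' @param api_key API key (default: `OPENAI_API_KEY` environment variable).
#' @param base_url API root.
#' @return An `etio_backend`.
#' @export
openai_backend <- function(model, api_key = Sys.getenv("OPENAI_API_KEY"),
                           base_url = "https://api.openai.com/v1") {
  llm_backend(function(prompt, temperature, max_tokens, top_p) {
    body <- jsonlite::toJSON(list(
      model = model, temperature = temperature, max_tokens = max_tokens,
      top_p = top_p,
      messages = list(list(role = "user", content = prompt))),
      auto_unbox = TRUE)
    tmp <- tempfile(fileext = ".json"); writeLines(body, tmp)
    message("openai_backend: POST /chat/completions (", nchar(prompt),
            " prompt chars)")
    out <- system2("curl",
                   c("-s", paste0(base_url, "/chat/completions"),
                     "-H", shQuote("Content-Type: application/json"),
                     "-H", shQuote(paste0("Authorization: Bearer ", api_key)),
                     "-d", paste0("@", tmp)),
                   stdout = TRUE)
    parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"),
                                 simplifyVector = FALSE)
    parsed$choices[[1]]$message$content
  }, name = paste0("openai:", model))
}

#' Retrieval configuration
#'
#' @param top_n Number of candidate evidence sentences kept (default 50).
#' @param hard_constraints Require candidate sentences to contain both the
#'   symptom and the etiology as exact, case-insensitive phrases.
#' @param embedder Optional function `(query, texts) -> numeric scores`;
#'   the default is term-weighted (tf-idf cosine) lexical similarity.
#' @return List of class `etio_retrieval_config`.
#' @export
retrieval_config <- function(top_n = 50L, hard_constraints = TRUE,
                             embedder = NULL) {
  stopifnot(top_n >= 1L)
  structure(list(top_n = as.integer(top_n),
                 hard_constraints = isTRUE(hard_constraints),
                 embedder = embedder),
            class = "etio_retrieval_config")
}

#' Generate candidate etiologies for a symptom
#'
#' Sends the generation prompt with the symptom substituted and parses one
#' name per line: bullets and enumeration prefixes are stripped, blank
#' lines and the terminal "done" sentinel removed, and names deduplicated
#' case-insensitively preserving first occurrence. With `n_runs > 1` the
#' prompt is issued several times and the run with the most names is kept.
#'
#' @param symptom Symptom name.
#' @param backend An `etio_backend`.
#' @param n_runs Number of generation runs (best-of-by-count selection).
#' @return Character vector of etiology names.
#' @export
generate_etiologies <- function(symptom, backend, n_runs = 1L) {
  parse_run <- function(resp) {
    lines <- trimws(strsplit(resp, "\n", fixed = TRUE)[[1]])
    lines <- sub("^[-*•]+\\s*", "", lines)
    lines <- sub("^[0-9]+[.)]\\s*", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    lines <- lines[tolower(gsub("[[:punct:]]", "", lines)) != "done"]
    lines[!duplicated(tolower(lines))]
  }
  prompt <- fill_prompt(prompt_generation, symptom = symptom)
  runs <- lapply(seq_len(max(1L, n_runs)), function(i)
    parse_run(.complete(backend, prompt)))
  runs[[which.max(vapply(runs, length, integer(1)))]]
}

# tf-idf cosine similarity of each text against the query
lexical_similarity <- function(query, texts) {
  tokenize <- function(x) {
    t <- strsplit(tolower(gsub("[^a-z0-9 ]", " ", tolower(x))), "\\s+")[[1]]
    t[nzchar(t)]
  }
  docs <- lapply(texts, tokenize)
  q <- tokenize(query)
  vocab <- unique(c(unlist(docs), q))
  df <- numeric(length(vocab)); names(df) <- vocab
  for (d in docs) df[unique(d)] <- df[unique(d)] + 1
  idf <- log((length(docs) + 1) / (df + 1)) + 1
  vec <- function(tokens) {
    tf <- table(tokens)
    v <- numeric(length(vocab)); names(v) <- vocab
    v[names(tf)] <- as.numeric(tf) * idf[names(tf)]
    v
  }
  qv <- vec(q); qn <- sqrt(sum(qv^2))
  vapply(docs, function(d) {
    if (length(d) == 0L) return(0)
    dv <- vec(d); dn <- sqrt(sum(dv^2))
    if (dn == 0 || qn == 0) 0 else sum(qv * dv) / (qn * dn)
  }, numeric(1))
}

.contains_phrase <- function(text, phrase) {
  grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                           tolower(trimws(phrase))), "\\b"),
        tolower(text))
}

#' Retrieve candidate evidence sentences
#'
#' Scores every corpus sentence against the query "an etiology for
#' <symptom>" with the configured similarity and keeps the `top_n` best,
#' ties broken by sentence id. With hard constraints on, only sentences
#' containing both the symptom and the etiology as exact case-insensitive
#' phrases survive.
#'
#' @param symptom,etiology Phrase strings.
#' @param corp An `etio_corpus`.
#' @param cfg An [retrieval_config()].
#' @return `data.frame` of candidates: `sent_id`, `text`, `score`.
#' @export
retrieve_evidence <- function(symptom, etiology, corp,
                              cfg = retrieval_config()) {
  texts <- vapply(corp$sentences, sentence_text, character(1))
  ids <- names(corp$sentences)
  if (length(texts) == 0L)
    return(data.frame(sent_id = character(), text = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  query <- paste("an etiology for", symptom)
  scorer <- if (is.null(cfg$embedder)) lexical_similarity else cfg$embedder
  scores <- scorer(query, texts)
  keep <- rep(TRUE, length(texts))
  if (cfg$hard_constraints) {
    keep <- vapply(texts, function(t)
      .contains_phrase(t, symptom) && .contains_phrase(t, etiology),
      logical(1), USE.NAMES = FALSE)
  }
  out <- data.frame(sent_id = ids[keep], text = unname(texts[keep]),
                    score = unname(scores[keep]), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$sent_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, cfg$top_n)
}

# Tolerant parse of the ranking response: a Python/JSON-style array of
# {"sent": ..., "reason": ...} dicts, possibly in code fences or with
# single quotes. Unparseable input yields an empty result with the raw
# payload attached, never an error.
parse_ranking_response <- function(resp) {
  txt <- gsub("```[a-zA-Z]*", "", resp)
  txt <- trimws(gsub("```", "", txt))
  parsed <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                     error = function(e) NULL)
  if (is.null(parsed)) {
    txt2 <- gsub("(?<![a-zA-Z])'|'(?![a-zA-Z])", "\"", txt, perl = TRUE)
    parsed <- tryCatch(jsonlite::fromJSON(txt2, simplifyVector = FALSE),
                       error = function(e) NULL)
  }
  if (is.null(parsed) || !is.list(parsed)) {
    out <- data.frame(sent = character(), reason = character(),
                      stringsAsFactors = FALSE)
    attr(out, "raw_response") <- resp
    return(out)
  }
  rows <- lapply(parsed, function(item) {
    if (!is.list(item) || is.null(item$sent)) return(NULL)
    data.frame(sent = as.character(item$sent),
               reason = as.character(item$reason %||% ""),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- data.frame(sent = character(), reason = character(),
                      stringsAsFactors = FALSE)
    attr(out, "raw_response") <- resp
    return(out)
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank candidate evidence with the model
#'
#' Sends the ranking prompt with the candidate sentences one per line and
#' parses the structured response. Returned items whose sentence is not an
#' exact member of the candidate list are dropped (the prompt instructs
#' "Only select sentences from the list below, do not add new sentences",
#' and the membership check enforces it against fabrication). At most 3
#' items are kept; an unparseable response yields zero items with the raw
#' payload preserved.
#'
#' @param symptom,etiology Phrase strings.
#' @param candidates Candidate `data.frame` from [retrieve_evidence()].
#' @param backend An `etio_backend`.
#' @return `data.frame` with `sent`, `reason` (<= 3 rows).
#' @export
rank_evidence <- function(symptom, etiology, candidates, backend) {
  stopifnot(nrow(candidates) > 0L)
  prompt <- fill_prompt(prompt_ranking,
                        candidate_etiology = etiology, symptom = symptom,
                        sentences = paste(candidates$text, collapse = "\n"))
  parsed <- parse_ranking_response(.complete(backend, prompt))
  parsed <- parsed[parsed$sent %in% candidates$text, , drop = FALSE]
  rownames(parsed) <- NULL
  utils::head(parsed, 3L)
}

#' Vet one evidence sentence
#'
#' Sends the yes/no vetting prompt. The response is normalized (case,
#' punctuation, surrounding whitespace); anything that is not exactly yes
#' or no after normalization is treated as no, with a warning.
#'
#' @param symptom,etiology Phrase strings.
#' @param sentence Evidence sentence text.
#' @param backend An `etio_backend`.
#' @return `"yes"` or `"no"`.
#' @export
vet_evidence <- function(symptom, etiology, sentence, backend) {
  prompt <- fill_prompt(prompt_vetting,
                        candidate_etiology = etiology, symptom = symptom,
                        evidence_sentence = sentence)
  resp <- .complete(backend, prompt)
  norm <- tolower(gsub("[[:punct:][:space:]]", "", resp))
  if (norm == "yes") return("yes")
  if (norm != "no")
    warning("unrecognized vetting response treated as 'no': ",
            substring(resp, 1, 80))
  "no"
}

#' Run the full verification pipeline for one symptom
#'
#' Composes generation, retrieval, ranking and vetting; an etiology
#' survives only if at least one of its ranked sentences is vetted yes.
#' The output is always a subset of the generated names, and the per-stage
#' funnel (generated, with candidate evidence, with vetted evidence) is
#' reported alongside the verified items.
#'
#' @param symptom Symptom name.
#' @param backend An `etio_backend`.
#' @param corp Evidence corpus.
#' @param cfg An [retrieval_config()].
#' @param n_runs Generation runs (see [generate_etiologies()]).
#' @return List of class `etio_verification`: `verified` (list of
#'   etiologies with their vetted evidence), `funnel` (per-etiology
#'   `data.frame`: `etiology`, `n_candidates`, `n_ranked`, `n_vetted`,
#'   `verified`), `counts` (`generated`, `with_candidates`, `verified`),
#'   and `failures` (etiologies whose backend calls errored).
#' @export
verify_all <- function(symptom, backend, corp, cfg = retrieval_config(),
                       n_runs = 1L) {
  names_gen <- generate_etiologies(symptom, backend, n_runs)
  verified <- list()
  failures <- character()
  funnel <- list()
  for (eti in names_gen) {
    row <- data.frame(etiology = eti, n_candidates = 0L, n_ranked = 0L,
                      n_vetted = 0L, verified = FALSE,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      cands <- retrieve_evidence(symptom, eti, corp, cfg)
      row$n_candidates <- nrow(cands)
      evidence <- NULL
      if (nrow(cands) > 0L) {
        ranked <- rank_evidence(symptom, eti, cands, backend)
        row$n_ranked <- nrow(ranked)
        if (nrow(ranked) > 0L) {
          verdicts <- vapply(ranked$sent, function(s)
            vet_evidence(symptom, eti, s, backend), character(1),
            USE.NAMES = FALSE)
          keep <- verdicts == "yes"
          row$n_vetted <- sum(keep)
          if (any(keep)) {
            evidence <- data.frame(sent = ranked$sent[keep],
                                   reason = ranked$reason[keep],
                                   verdict = "yes",
                                   stringsAsFactors = FALSE)
          }
        }
      }
      evidence
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, eti)
    } else if (!is.null(res)) {
      row$verified <- TRUE
      verified[[length(verified) + 1L]] <-
        list(etiology = eti, evidence = res)
    }
    funnel[[length(funnel) + 1L]] <- row
  }
  funnel <- if (length(funnel)) do.call(rbind, funnel) else
    data.frame(etiology = character(), n_candidates = integer(),
               n_ranked = integer(), n_vetted = integer(),
               verified = logical(), stringsAsFactors = FALSE)
  structure(list(
    verified = verified,
    funnel = funnel,
    counts = c(generated = length(names_gen),
               with_candidates = sum(funnel$n_candidates > 0L),
               verified = sum(funnel$verified)),
    failures = failures),
    class = "etio_verification")
}

#' @export
print.etio_verification <- function(x, ...) {
  cat(sprintf("<etio_verification> generated %d -> with candidates %d -> verified %d\n",
              x$counts[["generated"]], x$counts[["with_candidates"]],
              x$counts[["verified"]]))
  invisible(x)
}
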