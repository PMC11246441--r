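# Human-in-the-loop iterative bootstrapping of a pattern pool.
#
# One round: (1) find corpus sentences containing both elements of a seed
# (symptom, etiology) tuple; (2) derive a pattern from each matching
# sentence and rank the deduplicated patterns by yield for review; (3) apply
# the accepted pool to the whole corpus; (4) harvest the most frequent
# co-extracted (symptom, etiology) pairs as new seeds. Rounds repeat until
# no new pattern reaches the yield threshold -- newly discovered patterns
# becoming very specific (low yield) is the stopping signal.

#' Seed tuples
#'
#' @param symptom,etiology Equal-length character vectors of non-empty names.
#' @return A `data.frame` with columns `symptom`, `etiology`.
#' @export
seed_tuples <- function(symptom, etiology) {
  stopifnot(length(symptom) == length(etiology),
            all(nzchar(symptom)), all(nzchar(etiology)))
  unique(data.frame(symptom = symptom, etiology = etiology,
                    stringsAsFactors = FALSE))
}

#' Read seeds from a two-column CSV
#'
#' @param path CSV with columns `symptom,etiology`.
#' @return Seed `data.frame` as from [seed_tuples()].
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  seed_tuples(df$symptom, df$etiology)
}

#' Propose ranked patterns from seed matches
#'
#' Runs the co-occurrence search for every seed, derives a pattern from each
#' span match, deduplicates by text form and ranks by yield (the number of
#' distinct seed-matching sentences that produced the pattern), descending,
#' ties broken by text form. Patterns below `min_yield` and previously
#' decided patterns are omitted. Matches with an ambiguous span head are
#' logged and skipped.
#'
#' @param corp An `etio_corpus`.
#' @param seeds Seed `data.frame` ([seed_tuples()]).
#' @param min_yield Minimum yield to surface a pattern for review.
#' @param decided Character vector of text forms already accepted/rejected.
#' @param n_samples Provenance sentences kept per pattern.
#' @return List of ranked proposals; each has `pattern`, `yield`,
#'   `sample_sent_ids`.
#' @export
propose_patterns <- function(corp, seeds, min_yield = 2L,
                             decided = character(), n_samples = 5L) {
  if (nrow(seeds) == 0L) return(list())
  by_form <- list()   # text_form -> list(pattern, sent_ids)
  for (r in seq_len(nrow(seeds))) {
    matches <- search_cooccurrence(corp, seeds$symptom[r], seeds$etiology[r])
    for (m in seq_len(nrow(matches))) {
      if (nrow(matches) == 0L) break
      sent <- corp$sentences[[matches$sent_id[m]]]
      pat <- tryCatch(
        generate_pattern(sent,
                         c(matches$a_start[m], matches$a_end[m]),
                         c(matches$b_start[m], matches$b_end[m])),
        etio_ambiguous_head = function(e) NULL)
      if (is.null(pat)) next
      tf <- pat$text_form
      if (is.null(by_form[[tf]]))
        by_form[[tf]] <- list(pattern = pat, sent_ids = character())
      by_form[[tf]]$sent_ids <- union(by_form[[tf]]$sent_ids, sent$sent_id)
    }
  }
  if (length(by_form) == 0L) return(list())
  forms <- names(by_form)
  keep <- !(forms %in% decided)
  yields <- vapply(by_form, function(x) length(x$sent_ids), integer(1))
  keep <- keep & yields >= min_yield
  forms <- forms[keep]
  if (length(forms) == 0L) return(list())
  yields <- yields[forms]
  ord <- order(-yields, forms)
  lapply(forms[ord], function(tf) {
    list(pattern = by_form[[tf]]$pattern,
         yield = length(by_form[[tf]]$sent_ids),
         sample_sent_ids = utils::head(sort(by_form[[tf]]$sent_ids),
                                       n_samples))
  })
}

#' Apply a pattern pool over a corpus
#'
#' Union of [match_pattern()] over all sentences and patterns, with exact
#' duplicates (same sentence, spans and pattern) removed, in stable
#' (sent_id, spans) order. Two patterns matching the same pair through
#' different paths both survive: the pattern is part of the extraction key.
#'
#' @param corp An `etio_corpus`.
#' @param patterns List of `etio_pattern`.
#' @return Capture `data.frame` (see [match_pattern()]).
#' @export
apply_patterns <- function(corp, patterns) {
  out <- list()
  for (s in corp$sentences) {
    for (p in patterns) {
      caps <- match_pattern(p, s)
      if (nrow(caps) > 0L) out[[length(out) + 1L]] <- caps
    }
  }
  if (length(out) == 0L) return(empty_captures())
  ext <- do.call(rbind, out)
  key <- paste(ext$sent_id, ext$symptom_start, ext$symptom_end,
               ext$etiology_start, ext$etiology_end, ext$pattern)
  ext <- ext[!duplicated(key), , drop = FALSE]
  ext <- ext[order(ext$sent_id, ext$symptom_start, ext$etiology_start,
                   ext$pattern), , drop = FALSE]
  rownames(ext) <- NULL
  ext
}

# frequency-ranked representative surfaces, fingerprint-collapsed
.rank_mentions <- function(texts, k) {
  if (length(texts) == 0L || k <= 0L) return(data.frame(
    fp = character(), surface = character(), n = integer(),
    stringsAsFactors = FALSE))
  fp <- vapply(texts, function(t)
    tryCatch(fingerprint(t), etio_empty_fingerprint = function(e) NA_character_),
    character(1), USE.NAMES = FALSE)
  ok <- !is.na(fp)
  texts <- texts[ok]; fp <- fp[ok]
  groups <- split(texts, fp)
  surface <- vapply(groups, function(g) {
    tab <- sort(table(g), decreasing = TRUE)
    cands <- names(tab)[tab == tab[1L]]
    cands[order(nchar(cands), cands)][1L]
  }, character(1))
  n <- vapply(groups, length, integer(1))
  df <- data.frame(fp = names(groups), surface = surface, n = n,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n, df$surface), , drop = FALSE]
  utils::head(df, k)
}

#' Harvest new seed tuples from extractions
#'
#' Symptoms and etiologies are ranked by extraction frequency with spelling
#' variants pooled by fingerprint, ties broken lexicographically. The
#' returned seeds are the co-extracted pairs whose symptom is among the top
#' `k_symptoms` and etiology among the top `k_etiologies` (defaults follow
#' the bootstrapping protocol: top 10 symptoms, top 50 etiologies).
#'
#' @param extractions Capture `data.frame` from [apply_patterns()].
#' @param k_symptoms,k_etiologies Pool sizes.
#' @return Seed `data.frame` ([seed_tuples()]).
#' @export
select_seeds <- function(extractions, k_symptoms = 10L, k_etiologies = 50L) {
  empty <- seed_tuples(character(), character())
  if (nrow(extractions) == 0L) return(empty)
  top_s <- .rank_mentions(extractions$symptom_text, k_symptoms)
  top_e <- .rank_mentions(extractions$etiology_text, k_etiologies)
  if (nrow(top_s) == 0L || nrow(top_e) == 0L) return(empty)
  fp_s <- vapply(extractions$symptom_text, function(t)
    tryCatch(fingerprint(t), etio_empty_fingerprint = function(e) NA_character_),
    character(1), USE.NAMES = FALSE)
  fp_e <- vapply(extractions$etiology_text, function(t)
    tryCatch(fingerprint(t), etio_empty_fingerprint = function(e) NA_character_),
    character(1), USE.NAMES = FALSE)
  keep <- fp_s %in% top_s$fp & fp_e %in% top_e$fp & !is.na(fp_s) & !is.na(fp_e)
  if (!any(keep)) return(empty)
  pairs <- unique(data.frame(
    symptom = top_s$surface[match(fp_s[keep], top_s$fp)],
    etiology = top_e$surface[match(fp_e[keep], top_e$fp)],
    stringsAsFactors = FALSE))
  pairs[order(pairs$symptom, pairs$etiology), , drop = FALSE]
}

#' Reviewer contracts
#'
#' A reviewer is a function `(pattern, yield, sample_sentences) -> "accept"
#' | "reject"` standing in for the human pattern developer.
#' `reviewer_oracle` accepts a pattern when its captures on the provided
#' sample sentences agree with the gold relations at precision at least
#' `min_precision` -- it rejects the distractor trap the way a careful human
#' would. `reviewer_scripted` replays a recorded decision table (text form
#' to verdict; unknown patterns are rejected with a warning), making
#' sessions exactly reproducible. `reviewer_interactive` prompts on the
#' console.
#'
#' @param gold An `etio_gold` object from [generate_corpus()].
#' @param min_precision Acceptance threshold on sample precision.
#' @return A reviewer function.
#' @export
reviewer_oracle <- function(gold, min_precision = 0.8) {
  rel_key <- paste(gold$relations$sent_id,
                   gold$relations$symptom_start, gold$relations$symptom_end,
                   gold$relations$etiology_start, gold$relations$etiology_end)
  function(pattern, yield, sample_sentences) {
    caps <- do.call(rbind, lapply(sample_sentences, function(s)
      match_pattern(pattern, s)))
    if (is.null(caps) || nrow(caps) == 0L) return("reject")
    key <- paste(caps$sent_id, caps$symptom_start, caps$symptom_end,
                 caps$etiology_start, caps$etiology_end)
    if (mean(key %in% rel_key) >= min_precision) "accept" else "reject"
  }
}

#' @rdname reviewer_oracle
#' @param decisions `data.frame` with columns `pattern` (text form) and
#'   `verdict` (`"accept"`/`"reject"`).
#' @export
reviewer_scripted <- function(decisions) {
  stopifnot(all(c("pattern", "verdict") %in% names(decisions)))
  function(pattern, yield, sample_sentences) {
    hit <- match(pattern$text_form, decisions$pattern)
    if (is.na(hit)) {
      warning("no scripted decision for pattern: ", pattern$text_form)
      return("reject")
    }
    decisions$verdict[hit]
  }
}

#' @rdname reviewer_oracle
#' @export
reviewer_interactive <- function() {
  function(pattern, yield, sample_sentences) {
    cat(sprintf("(%d) %s\n", yield, pattern$text_form))
    for (s in sample_sentences) cat("   ", sentence_text(s), "\n")
    repeat {
      ans <- tolower(trimws(readline("accept? [y/n] ")))
      if (ans %in% c("y", "yes")) return("accept")
      if (ans %in% c("n", "no")) return("reject")
    }
  }
}

#' Run the iterative bootstrapping loop
#'
#' Alternates pattern proposal, review, extraction and seed harvesting until
#' no new pattern reaches `min_yield` or the iteration cap is hit. The
#' returned state carries the full audit trail: seed pool, accepted and
#' rejected pools, extraction log and an append-only decision log, so a
#' recorded session replays to a bit-identical state with
#' [reviewer_scripted()]. A pattern rejected once is never re-proposed.
#'
#' @param corp An `etio_corpus`.
#' @param seeds Initial seed `data.frame`.
#' @param reviewer Reviewer function (see [reviewer_oracle()]).
#' @param min_yield Proposal threshold (review protocol default: 2).
#' @param max_iterations Safety cap on rounds.
#' @param k_symptoms,k_etiologies Seed-harvest pool sizes.
#' @return A list of class `etio_bootstrap_state`.
#' @export
run_bootstrap <- function(corp, seeds, reviewer, min_yield = 2L,
                          max_iterations = 10L, k_symptoms = 10L,
                          k_etiologies = 50L) {
  state <- structure(list(
    iteration = 0L, seed_pool = seeds,
    accepted = list(), rejected = character(),
    extractions = empty_captures(),
    decisions = data.frame(pattern = character(), verdict = character(),
                           yield = integer(), iteration = integer(),
                           stringsAsFactors = FALSE)),
    class = "etio_bootstrap_state")

  repeat {
    if (state$iteration >= max_iterations) break
    decided <- c(vapply(state$accepted, `[[`, character(1), "text_form"),
                 state$rejected)
    proposals <- propose_patterns(corp, state$seed_pool, min_yield,
                                  decided = decided)
    if (length(proposals) == 0L) break
    state$iteration <- state$iteration + 1L
    for (pr in proposals) {
      samples <- corp$sentences[pr$sample_sent_ids]
      verdict <- tryCatch(reviewer(pr$pattern, pr$yield, samples),
                          error = function(e) {
                            e$bootstrap_state <- state
                            stop(e)
                          })
      state$decisions <- rbind(state$decisions, data.frame(
        pattern = pr$pattern$text_form, verdict = verdict,
        yield = pr$yield, iteration = state$iteration,
        stringsAsFactors = FALSE))
      if (identical(verdict, "accept"))
        state$accepted[[length(state$accepted) + 1L]] <- pr$pattern
      else
        state$rejected <- c(state$rejected, pr$pattern$text_form)
    }
    state$extractions <- apply_patterns(corp, state$accepted)
    new_seeds <- select_seeds(state$extractions, k_symptoms, k_etiologies)
    state$seed_pool <- unique(rbind(state$seed_pool, new_seeds))
  }
  state
}

#' @export
print.etio_bootstrap_state <- function(x, ...) {
  cat(sprintf(
    "<etio_bootstrap_state> %d iteration(s), %d accepted / %d rejected patterns, %d seeds, %d extractions\n",
    x$iteration, length(x$accepted), length(x$rejected),
    nrow(x$seed_pool), nrow(x$extractions)))
  invisible(x)
}
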