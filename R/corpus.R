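# Column layout of the CoNLL-U 10-column format. Only id/form/lemma/upos/
# head/deprel are interpreted; the rest are carried through for round-trips.
.conllu_cols <- c("id", "form", "lemma", "upos", "xpos", "feats",
                  "head", "deprel", "deps", "misc")

#' Construct a parsed sentence
#'
#' A parsed sentence holds one tokenized sentence together with its basic
#' Universal Dependencies tree: for every token a surface form, lemma,
#' part-of-speech tag, the index of its governing token (`0` for the root)
#' and the dependency relation label.
#'
#' @param sent_id Sentence identifier, unique within a corpus.
#' @param tokens A `data.frame` with columns `id`, `form`, `lemma`, `upos`,
#'   `head`, `deprel` (CoNLL-U names). Extra columns `xpos`, `feats`, `deps`,
#'   `misc` are kept if present, else filled with `"_"`.
#' @param doc_id Optional document identifier.
#' @return An object of class `etio_sentence`.
#' @export
parsed_sentence <- function(sent_id, tokens, doc_id = "") {
  stopifnot(is.character(sent_id), length(sent_id) == 1L, nzchar(sent_id))
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  for (col in setdiff(.conllu_cols, names(tokens))) tokens[[col]] <- "_"
  tokens <- tokens[, .conllu_cols]
  tokens$id <- as.integer(tokens$id)
  tokens$head <- as.integer(tokens$head)
  probs <- validate_tokens(tokens)
  if (length(probs) > 0L) {
    stop(errorCondition(
      sprintf("invalid sentence '%s': %s", sent_id,
              paste(probs, collapse = "; ")),
      class = c("etio_invalid_sentence", "error")))
  }
  structure(list(sent_id = sent_id, doc_id = doc_id, tokens = tokens),
            class = "etio_sentence")
}

#' Check dependency-tree invariants of a token table
#'
#' Verifies contiguous 1..n token indices, a single root (`head == 0`),
#' no self-loops, heads within range, non-empty relation labels, and that
#' the head links form one acyclic tree.
#'
#' @param tokens Token `data.frame` as in [parsed_sentence()].
#' @return Character vector of problems; empty when the tree is valid.
#' @export
validate_tokens <- function(tokens) {
  probs <- character()
  n <- nrow(tokens)
  if (n == 0L) return("sentence has no tokens")
  if (!identical(tokens$id, seq_len(n)))
    probs <- c(probs, "token indices are not contiguous 1..n")
  if (any(is.na(tokens$head)) || any(tokens$head < 0L))
    probs <- c(probs, "head indices must be >= 0")
  if (any(tokens$head > n, na.rm = TRUE))
    probs <- c(probs, "head index beyond sentence bounds")
  loops <- which(tokens$head == tokens$id)
  if (length(loops) > 0L)
    probs <- c(probs, sprintf("self-loop at token %s",
                              paste(loops, collapse = ",")))
  if (any(!nzchar(tokens$deprel)))
    probs <- c(probs, "empty deprel label")
  nroot <- sum(tokens$head == 0L, na.rm = TRUE)
  if (nroot != 1L)
    probs <- c(probs, sprintf("expected exactly one root, found %d", nroot))
  if (length(probs) == 0L) {
    # acyclicity: walk each token to the root, bounded by n steps
    for (i in seq_len(n)) {
      cur <- i
      for (step in seq_len(n + 1L)) {
        cur <- tokens$head[cur]
        if (cur == 0L) break
      }
      if (cur != 0L) {
        probs <- c(probs, sprintf("cycle reachable from token %d", i))
        break
      }
    }
  }
  probs
}

#' Construct a corpus of parsed sentences
#'
#' @param sentences List of [parsed_sentence()] objects with unique `sent_id`s.
#' @param provenance Free-text description of where the sentences came from.
#' @param rejected Optional `data.frame` (`sent_id`, `reason`) of sentences
#'   that failed tree validation and were quarantined.
#' @return An object of class `etio_corpus`.
#' @export
corpus <- function(sentences = list(), provenance = "", rejected = NULL) {
  ids <- vapply(sentences, function(s) s$sent_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sent_ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sentences) <- ids
  if (is.null(rejected))
    rejected <- data.frame(sent_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  structure(list(sentences = sentences, provenance = provenance,
                 rejected = rejected),
            class = "etio_corpus")
}

#' @export
print.etio_corpus <- function(x, ...) {
  cat(sprintf("<etio_corpus> %d sentences (%d rejected)\n",
              length(x$sentences), nrow(x$rejected)))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
print.etio_sentence <- function(x, ...) {
  cat(sprintf("<etio_sentence> %s: %s\n", x$sent_id, sentence_text(x)))
  invisible(x)
}

#' Plain-text form of a sentence
#'
#' @param sentence An `etio_sentence`.
#' @return Single string, surface forms joined by spaces.
#' @export
sentence_text <- function(sentence) paste(sentence$tokens$form, collapse = " ")

#' Read a CoNLL-U file into a corpus
#'
#' Sentences are blocks of 10-column tab-separated lines separated by blank
#' lines. `# sent_id = ...` and `# newdoc id = ...` comments are honoured.
#' Multi-word-token ranges (`1-2`) and empty nodes (`1.1`) are skipped with
#' a warning. Sentences violating tree invariants (cycles, multiple roots,
#' self-loops) are quarantined into the corpus' `rejected` report rather
#' than dropped silently; a structurally malformed line is an error naming
#' the line number.
#'
#' @param path Path to a CoNLL-U file.
#' @return An `etio_corpus`.
#' @export
read_conllu <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  rejected <- list()
  cur <- list()        # token line indices of the current block
  sent_id <- NULL
  doc_id <- ""
  n_auto <- 0L
  skipped <- 0L

  flush_block <- function() {
    if (length(cur) == 0L) return()
    tok <- do.call(rbind, cur)
    tokens <- data.frame(tok, stringsAsFactors = FALSE)
    names(tokens) <- .conllu_cols
    tokens$id <- as.integer(tokens$id)
    tokens$head <- as.integer(tokens$head)
    if (is.null(sent_id)) {
      n_auto <<- n_auto + 1L
      sent_id <<- sprintf("s%d", n_auto)
    }
    probs <- validate_tokens(tokens)
    if (length(probs) > 0L) {
      rejected[[length(rejected) + 1L]] <<- data.frame(
        sent_id = sent_id, reason = paste(probs, collapse = "; "),
        stringsAsFactors = FALSE)
    } else {
      sentences[[length(sentences) + 1L]] <<-
        parsed_sentence(sent_id, tokens, doc_id)
    }
    cur <<- list()
    sent_id <<- NULL
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) { flush_block(); next }
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*sent_id\\s*=\\s*(.+)$", line))[[1]]
      if (length(m) == 2L) sent_id <- trimws(m[[2]])
      m <- regmatches(line, regexec("^#\\s*newdoc id\\s*=\\s*(.+)$", line))[[1]]
      if (length(m) == 2L) doc_id <- trimws(m[[2]])
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10L)
      stop(sprintf("malformed CoNLL-U line %d: expected 10 tab-separated fields, got %d",
                   i, length(fields)))
    if (grepl("[-.]", fields[[1]])) {  # multi-word token range or empty node
      skipped <- skipped + 1L
      next
    }
    if (!grepl("^[0-9]+$", fields[[1]]) || !grepl("^[0-9]+$", fields[[7]]))
      stop(sprintf("malformed CoNLL-U line %d: non-integer id or head", i))
    cur[[length(cur) + 1L]] <- fields
  }
  flush_block()
  if (skipped > 0L)
    warning(sprintf("skipped %d multi-word-token/empty-node lines", skipped))
  rejected <- if (length(rejected)) do.call(rbind, rejected) else NULL
  corpus(sentences, provenance = path, rejected = rejected)
}

#' Write a corpus to a CoNLL-U file
#'
#' Inverse of [read_conllu()]: well-formed input round-trips bit-identically
#' at the token-field level.
#'
#' @param corp An `etio_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(corp, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in corp$sentences) {
    writeLines(sprintf("# sent_id = %s", s$sent_id), con)
    if (nzchar(s$doc_id)) writeLines(sprintf("# doc_id = %s", s$doc_id), con)
    tok <- s$tokens
    writeLines(do.call(paste, c(lapply(tok, as.character), sep = "\t")), con)
    writeLines("", con)
  }
  invisible(path)
}

# Occurrences of a (possibly multi-word) term as contiguous token runs.
# Per-token match tries surface first, then lemma, both case-insensitive;
# punctuation tokens never match. Returns a data.frame(start, end, matched_on).
term_occurrences <- function(sentence, term) {
  words <- tolower(strsplit(trimws(term), "\\s+")[[1]])
  k <- length(words)
  tok <- sentence$tokens
  n <- nrow(tok)
  if (k == 0L || n < k)
    return(data.frame(start = integer(), end = integer(),
                      matched_on = character(), stringsAsFactors = FALSE))
  surf <- tolower(tok$form)
  lemm <- tolower(tok$lemma)
  is_punct <- tok$upos == "PUNCT" | tok$deprel == "punct"
  out <- list()
  for (s in seq_len(n - k + 1L)) {
    idx <- s:(s + k - 1L)
    if (any(is_punct[idx])) next
    if (all(surf[idx] == words)) {
      out[[length(out) + 1L]] <- data.frame(start = s, end = s + k - 1L,
                                            matched_on = "surface",
                                            stringsAsFactors = FALSE)
    } else if (all(surf[idx] == words | lemm[idx] == words)) {
      out[[length(out) + 1L]] <- data.frame(start = s, end = s + k - 1L,
                                            matched_on = "lemma",
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(), end = integer(),
                  matched_on = character(), stringsAsFactors = FALSE)
}

#' Basic co-occurrence search over a corpus
#'
#' Finds every sentence containing both terms as contiguous token sequences,
#' matched case-insensitively on surface form or lemma. Every pair of
#' non-overlapping occurrences yields one span match; overlapping pairs are
#' excluded, so searching a term against itself on a single occurrence
#' returns nothing.
#'
#' @param corp An `etio_corpus`.
#' @param term_a,term_b Non-empty (possibly multi-word) search terms.
#' @return A `data.frame` with one row per span match: `sent_id`,
#'   `a_start`, `a_end`, `b_start`, `b_end`, `a_matched_on`, `b_matched_on`.
#' @export
search_cooccurrence <- function(corp, term_a, term_b) {
  stopifnot(nzchar(trimws(term_a)), nzchar(trimws(term_b)))
  out <- list()
  for (s in corp$sentences) {
    occ_a <- term_occurrences(s, term_a)
    if (nrow(occ_a) == 0L) next
    occ_b <- term_occurrences(s, term_b)
    if (nrow(occ_b) == 0L) next
    for (i in seq_len(nrow(occ_a))) {
      for (j in seq_len(nrow(occ_b))) {
        if (occ_a$start[i] <= occ_b$end[j] && occ_b$start[j] <= occ_a$end[i])
          next  # overlap
        out[[length(out) + 1L]] <- data.frame(
          sent_id = s$sent_id,
          a_start = occ_a$start[i], a_end = occ_a$end[i],
          b_start = occ_b$start[j], b_end = occ_b$end[j],
          a_matched_on = occ_a$matched_on[i],
          b_matched_on = occ_b$matched_on[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(sent_id = character(), a_start = integer(),
                  a_end = integer(), b_start = integer(), b_end = integer(),
                  a_matched_on = character(), b_matched_on = character(),
                  stringsAsFactors = FALSE)
}

#' Syntactic head of a token span
#'
#' The head of a span is the unique token inside it whose governor lies
#' outside the span; it serves as the dependency-path endpoint when a
#' multi-word seed term is matched.
#'
#' @param sentence An `etio_sentence`.
#' @param span Inclusive integer range `c(start, end)` of token indices.
#' @return The head token index.
#' @export
head_of_span <- function(sentence, span) {
  tok <- sentence$tokens
  start <- span[[1]]; end <- span[[2]]
  stopifnot(start >= 1L, end <= nrow(tok), start <= end)
  idx <- start:end
  external <- idx[!(tok$head[idx] %in% idx)]
  if (length(external) != 1L) {
    stop(errorCondition(
      sprintf("span %d..%d in '%s' has %d tokens with external heads (expected 1)",
              start, end, sentence$sent_id, length(external)),
      class = c("etio_ambiguous_head", "error")))
  }
  external
}
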