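# Grouping extracted mentions into concepts.
#
# Raw mentions of the same etiology differ in case, word order, leading
# articles and abbreviation use. A canonical string fingerprint absorbs
# those differences; mentions sharing a fingerprint are unified into one
# concept and concepts are ranked by mention count. Longer names are
# additionally encoded with American Soundex per token so that minor
# spelling variation ("Pfizer"/"Pfister") also pools.

#' American Soundex code of a single token
#'
#' Standard four-character American Soundex: the first letter is kept,
#' remaining letters are mapped to digit classes (b/f/p/v=1, c/g/j/k/q/s/x/z=2,
#' d/t=3, l=4, m/n=5, r=6), adjacent letters with the same code are
#' collapsed -- including across the transparent letters h and w -- vowels
#' reset the run, and the result is zero-padded to one letter plus three
#' digits. Non-alphabetic tokens are passed through unchanged with a
#' warning.
#'
#' @param token A single word.
#' @return The Soundex code (e.g. `"R163"` for `"Robert"`).
#' @export
soundex <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  if (!grepl("^[A-Za-z]+$", token)) {
    warning("non-alphabetic token passed through soundex unchanged: ", token)
    return(token)
  }
  chars <- strsplit(toupper(token), "")[[1]]
  code_of <- function(ch) {
    if (ch %in% c("B", "F", "P", "V")) "1"
    else if (ch %in% c("C", "G", "J", "K", "Q", "S", "X", "Z")) "2"
    else if (ch %in% c("D", "T")) "3"
    else if (ch == "L") "4"
    else if (ch %in% c("M", "N")) "5"
    else if (ch == "R") "6"
    else if (ch %in% c("H", "W")) "-"   # transparent: do not reset the run
    else ""                             # vowels a e i o u y: reset
  }
  digits <- character()
  prev <- code_of(chars[1L])
  for (ch in chars[-1L]) {
    code <- code_of(ch)
    if (code == "-") next
    if (nzchar(code) && code != prev) digits <- c(digits, code)
    prev <- code
  }
  paste0(chars[1L],
         substring(paste0(paste(digits, collapse = ""), "000"), 1L, 3L))
}

#' Canonical string fingerprint of a mention
#'
#' Applies, in order: lowercase; strip punctuation; drop leading articles
#' (a/an/the); trim and collapse whitespace; split on whitespace and remove
#' duplicate tokens; sort the tokens to normalize word order. If the joined
#' normalized name is longer than 6 characters each token is replaced by
#' its [soundex()] code before rejoining; shorter names remain as is.
#'
#' @param name Raw mention text.
#' @return Fingerprint string. A name that normalizes to nothing (all
#'   punctuation) raises a condition of class `etio_empty_fingerprint`.
#' @export
fingerprint <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  x <- tolower(name)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  x <- sub("^(a|an|the) ", "", x)
  x <- gsub("\\s+", " ", trimws(x))
  if (!nzchar(x)) {
    stop(errorCondition(
      sprintf("mention '%s' normalizes to an empty fingerprint", name),
      class = c("etio_empty_fingerprint", "error")))
  }
  tokens <- sort(unique(strsplit(x, " ", fixed = TRUE)[[1]]))
  joined <- paste(tokens, collapse = " ")
  if (nchar(joined) > 6L) {
    # codes are lowercased so the fingerprint is idempotent on its output
    codes <- vapply(tokens, function(t) {
      if (grepl("^[a-z]+$", t)) tolower(soundex(t)) else t
    }, character(1), USE.NAMES = FALSE)
    joined <- paste(codes, collapse = " ")
  }
  joined
}

# Is `sf` a plausible short form per the abbreviation-detection heuristics?
.valid_short_form <- function(sf) {
  nchar(sf) >= 2L && nchar(sf) <= 10L &&
    length(strsplit(trimws(sf), "\\s+")[[1]]) <= 2L &&
    grepl("[A-Za-z]", sf) &&
    grepl("^[A-Za-z0-9]", sf)
}

# Right-to-left character matching of short form into long form; the first
# short-form character must match a word-initial long-form character.
# Returns the matched long-form suffix (a word sequence) or NULL.
.best_long_form <- function(sf, lf_words) {
  lf <- paste(lf_words, collapse = " ")
  s <- tolower(sf); l <- tolower(lf)
  si <- nchar(s); li <- nchar(l)
  while (si >= 1L) {
    ch <- substring(s, si, si)
    if (!grepl("[a-z0-9]", ch)) { si <- si - 1L; next }
    while (li >= 1L &&
           (substring(l, li, li) != ch ||
            (si == 1L && li > 1L &&
             grepl("[a-z0-9]", substring(l, li - 1L, li - 1L))))) {
      li <- li - 1L
    }
    if (li < 1L) return(NULL)
    si <- si - 1L
    li <- li - 1L
  }
  # truncate to whole words: long form starts at the word containing li+1
  starts <- c(1L, utils::head(cumsum(nchar(lf_words) + 1L), -1L) + 1L)
  w <- max(which(starts <= li + 1L))
  cand <- lf_words[w:length(lf_words)]
  n_sf_chars <- sum(strsplit(s, "")[[1]] %in% letters)
  if (length(cand) > min(n_sf_chars + 5L, n_sf_chars * 2L)) return(NULL)
  cand_txt <- paste(cand, collapse = " ")
  if (nchar(cand_txt) <= nchar(sf)) return(NULL)
  if (tolower(cand_txt) == tolower(sf)) return(NULL)
  cand_txt
}

#' Detect parenthetical abbreviation definitions in a corpus
#'
#' Scans every sentence for "long form ( SF )" parentheticals and applies
#' the Schwartz-Hearst character-matching procedure: the short form is
#' scanned right to left, each character is matched into the long-form
#' candidate (the words preceding the parenthesis), and the first short-form
#' character must match a word-initial character. The reversed construction
#' "( SF ) ..." with the definition inside the parentheses is handled by the
#' same candidate rules. Conflicting definitions for one short form are
#' resolved by frequency, then first occurrence.
#'
#' @param corp An `etio_corpus`.
#' @return A `data.frame` of class `etio_abbrev_map`: `short`, `long`,
#'   `sent_id`.
#' @export
detect_abbreviations <- function(corp) {
  found <- list()
  for (s in corp$sentences) {
    forms <- s$tokens$form
    opens <- which(forms == "(")
    for (o in opens) {
      close <- which(forms == ")" & seq_along(forms) > o)
      if (length(close) == 0L) next
      close <- close[1L]
      if (close - o < 2L || o < 2L) next
      inside <- forms[(o + 1L):(close - 1L)]
      if (length(inside) <= 2L && .valid_short_form(paste(inside, collapse = " "))) {
        sf <- paste(inside, collapse = " ")
        lf_words <- forms[max(1L, o - (nchar(sf) + 5L)):(o - 1L)]
        lf_words <- lf_words[!lf_words %in% c("(", ")", ",", ".", ";")]
      } else {
        # reversed order: short form precedes the parenthesized long form
        sf <- forms[o - 1L]
        if (!.valid_short_form(sf)) next
        lf_words <- inside
      }
      if (length(lf_words) == 0L) next
      long <- .best_long_form(sf, lf_words)
      if (is.null(long)) next
      found[[length(found) + 1L]] <- data.frame(
        short = sf, long = long, sent_id = s$sent_id,
        stringsAsFactors = FALSE)
    }
  }
  if (length(found) == 0L) {
    return(structure(data.frame(short = character(), long = character(),
                                sent_id = character(),
                                stringsAsFactors = FALSE),
                     class = c("etio_abbrev_map", "data.frame")))
  }
  all_defs <- do.call(rbind, found)
  out <- list()
  for (sf in unique(all_defs$short)) {
    defs <- all_defs[all_defs$short == sf, , drop = FALSE]
    tab <- table(defs$long)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1L)   # tie: first occurrence in corpus order
      best <- defs$long[defs$long %in% best][1L]
    out[[length(out) + 1L]] <- defs[defs$long == best, , drop = FALSE][1L, ]
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("etio_abbrev_map", "data.frame"))
}

#' Expand known abbreviations inside a mention
#'
#' Whole-word, case-sensitive replacement of each defined short form by its
#' long form (short forms are near-always case-significant).
#'
#' @param text Mention text.
#' @param abbrevs An `etio_abbrev_map`.
#' @return Expanded text.
#' @export
expand_abbreviations <- function(text, abbrevs) {
  if (is.null(abbrevs) || nrow(abbrevs) == 0L) return(text)
  for (i in seq_len(nrow(abbrevs))) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                              abbrevs$short[i]), "\\b")
    text <- gsub(pat, abbrevs$long[i], text)
  }
  text
}

#' Build mention records
#'
#' @param raw Character vector of mention surface texts.
#' @param sent_id,role Optional parallel provenance vectors.
#' @return A `data.frame` with columns `raw`, `sent_id`, `role`.
#' @export
mentions <- function(raw, sent_id = NA_character_, role = "etiology") {
  stopifnot(all(nzchar(raw)))
  data.frame(raw = raw, sent_id = sent_id, role = role,
             stringsAsFactors = FALSE)
}

#' Unify mentions into ranked concepts
#'
#' Each mention has its abbreviations expanded, is fingerprinted, and is
#' grouped with all mentions sharing the fingerprint. Concepts are ranked
#' by mention count, descending, ties by display name; the display name is
#' the most frequent raw surface (ties: shortest, then lexicographic).
#' Mentions whose fingerprint is empty are quarantined, not dropped
#' silently.
#'
#' @param mention_df Mention `data.frame` (see [mentions()]); a plain
#'   character vector is also accepted.
#' @param abbrevs Optional `etio_abbrev_map` used to expand short forms
#'   before fingerprinting.
#' @param linker Optional function `text -> concept id` replacing the
#'   fingerprint as grouping key (the hook for an external entity linker);
#'   the default fingerprint leaves unlinkable names as singleton concepts.
#' @return List with `concepts` (a `data.frame`: `concept_id`, `display`,
#'   `count`) with per-concept mention indices in attribute `members`, and
#'   `unnormalizable` (quarantined mention rows).
#' @export
unify <- function(mention_df, abbrevs = NULL, linker = NULL) {
  if (is.character(mention_df)) mention_df <- mentions(mention_df)
  n <- nrow(mention_df)
  key <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    expanded <- expand_abbreviations(mention_df$raw[i], abbrevs)
    key[i] <- tryCatch(
      if (is.null(linker)) fingerprint(expanded) else linker(expanded),
      etio_empty_fingerprint = function(e) NA_character_)
    ok[i] <- !is.na(key[i])
  }
  quarantined <- mention_df[!ok, , drop = FALSE]
  mention_df <- mention_df[ok, , drop = FALSE]
  key <- key[ok]
  if (nrow(mention_df) == 0L) {
    return(list(concepts = data.frame(concept_id = character(),
                                      display = character(),
                                      count = integer(),
                                      stringsAsFactors = FALSE),
                unnormalizable = quarantined))
  }
  groups <- split(seq_len(nrow(mention_df)), key)
  display <- vapply(groups, function(ix) {
    tab <- sort(table(mention_df$raw[ix]), decreasing = TRUE)
    cands <- names(tab)[tab == tab[1L]]
    cands[order(nchar(cands), cands)][1L]
  }, character(1))
  count <- vapply(groups, length, integer(1))
  concepts <- data.frame(concept_id = names(groups), display = display,
                         count = count, stringsAsFactors = FALSE)
  ord <- order(-concepts$count, concepts$display)
  concepts <- concepts[ord, , drop = FALSE]
  rownames(concepts) <- NULL
  attr(concepts, "members") <- groups[ord]
  list(concepts = concepts, unnormalizable = quarantined)
}
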