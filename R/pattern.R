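# Linearized dependency-path patterns.
#
# A pattern is an alternating sequence of nodes and edges along the tree path
# between the two captured entities: the end nodes are capture placeholders
# (symptom / disease), interior nodes are lemma anchors ("lemm=cause"), and
# each edge carries a dependency label plus the direction it was walked:
# "<label" steps from a dependent to its head, ">label" from a head to a
# dependent. A nominal-modifier edge whose dependent has a case-marking child
# is printed with the case lemma fused into the label ("nmod_by"); the
# underlying basic tree is never mutated and matching resolves the fused
# label structurally.

# relations whose dependent may fuse its case child's lemma into the label
.case_fusing <- c("nmod", "obl")
# relations pulled into a capture's phrase boundary (see expand_phrase)
.expansion_rels <- c("compound", "amod", "nummod", "flat")

placeholder_text <- c(symptom = "[symptom placeholder]",
                      etiology = "[disease placeholder]")

#' Shortest undirected dependency path between two tokens
#'
#' In a tree the undirected path between two nodes is unique; it is found by
#' intersecting the two head-chains at the lowest common ancestor. Each step
#' records the dependency label and whether it was walked upwards
#' (dependent to head) or downwards.
#'
#' @param sentence An `etio_sentence`.
#' @param a,b Distinct token indices.
#' @return A list of class `etio_path` with `nodes` (token indices, `a`
#'   first) and `edges` (`data.frame` of `label`, `direction`).
#' @export
shortest_dependency_path <- function(sentence, a, b) {
  tok <- sentence$tokens
  stopifnot(a != b, a >= 1L, b >= 1L, a <= nrow(tok), b <= nrow(tok))
  chain <- function(i) {          # i, parent(i), ..., root
    out <- i
    while (tok$head[i] != 0L) {
      i <- tok$head[i]
      out <- c(out, i)
    }
    out
  }
  ca <- chain(a); cb <- chain(b)
  lca <- intersect(ca, cb)[1L]    # chains ordered leaf..root: first common
  up <- ca[seq_len(match(lca, ca))]          # a .. lca
  down <- rev(cb[seq_len(match(lca, cb))])   # lca .. b
  nodes <- c(up, down[-1L])
  n <- length(nodes)
  labels <- character(n - 1L); dirs <- character(n - 1L)
  for (k in seq_len(n - 1L)) {
    from <- nodes[k]; to <- nodes[k + 1L]
    if (tok$head[from] == to) {          # walked dependent -> head
      labels[k] <- tok$deprel[from]; dirs[k] <- "up"
    } else {                             # head -> dependent
      stopifnot(tok$head[to] == from)
      labels[k] <- tok$deprel[to]; dirs[k] <- "down"
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(label = labels, direction = dirs,
                                    stringsAsFactors = FALSE)),
            class = "etio_path")
}

# Fused label for the path edge k (1-based between nodes k and k+1):
# when the dependent end of a nominal-modifier edge carries a case child,
# append that child's lemma (nmod -> nmod_by).
.edge_display_label <- function(sentence, nodes, k, label, direction) {
  dep <- if (direction == "up") nodes[k] else nodes[k + 1L]
  if (label %in% .case_fusing) {
    tok <- sentence$tokens
    kids <- which(tok$head == dep & tok$deprel == "case")
    if (length(kids) > 0L)
      return(paste0(label, "_", tolower(tok$lemma[kids[1L]])))
  }
  label
}

new_pattern <- function(elements, source_sent_id = "") {
  p <- structure(list(elements = elements, source_sent_id = source_sent_id,
                      text_form = ""),
                 class = "etio_pattern")
  p$text_form <- linearize(p)
  p
}

#' @export
print.etio_pattern <- function(x, ...) {
  cat("<etio_pattern>", x$text_form, "\n")
  invisible(x)
}

#' Derive a linearized pattern from a matched sentence
#'
#' Implements pattern generation from a sentence with matched symptom and
#' etiology spans: the span heads become the path endpoints, the shortest
#' undirected dependency path between them is linearized with the endpoints
#' as capture placeholders, interior tokens as lemma anchors, and edges as
#' directed label constraints. Tokens off the path never enter the pattern.
#' When the endpoints are directly connected the path has no interior token
#' to anchor on (the lowest mutual ancestor of a head-dependent pair is one
#' of the pair); the single-edge pattern is emitted but flagged
#' `anchor_free = TRUE` so reviewers can treat it with suspicion.
#'
#' @param sentence An `etio_sentence`.
#' @param symptom_span,etiology_span Inclusive token ranges `c(start, end)`.
#' @return An `etio_pattern`; attribute `anchor_free` marks degenerate
#'   single-edge patterns.
#' @export
generate_pattern <- function(sentence, symptom_span, etiology_span) {
  a <- head_of_span(sentence, symptom_span)
  b <- head_of_span(sentence, etiology_span)
  path <- shortest_dependency_path(sentence, a, b)
  tok <- sentence$tokens
  n <- length(path$nodes)
  elements <- list(list(kind = "placeholder", role = "symptom"))
  for (k in seq_len(n - 1L)) {
    lab <- .edge_display_label(sentence, path$nodes, k,
                               path$edges$label[k], path$edges$direction[k])
    elements[[length(elements) + 1L]] <-
      list(kind = "edge", label = lab, direction = path$edges$direction[k])
    if (k < n - 1L) {
      elements[[length(elements) + 1L]] <-
        list(kind = "anchor", lemma = tolower(tok$lemma[path$nodes[k + 1L]]))
    }
  }
  elements[[length(elements) + 1L]] <- list(kind = "placeholder",
                                            role = "etiology")
  p <- new_pattern(elements, sentence$sent_id)
  attr(p, "anchor_free") <- n == 2L
  p
}

#' Linearize a pattern to its text form
#'
#' Elements are joined with `" : "`; edges are printed as `<label`
#' (dependent-to-head step) or `>label` (head-to-dependent), anchors as
#' `lemm=<lemma>`, and the capture slots as `[symptom placeholder]` /
#' `[disease placeholder]`.
#'
#' @param pattern An `etio_pattern`.
#' @return Single string.
#' @export
linearize <- function(pattern) {
  parts <- vapply(pattern$elements, function(el) {
    switch(el$kind,
           placeholder = placeholder_text[[el$role]],
           anchor = paste0("lemm=", el$lemma),
           edge = paste0(if (el$direction == "up") "<" else ">", el$label))
  }, character(1))
  paste(parts, collapse = " : ")
}

#' Parse a pattern text form
#'
#' Inverse of [linearize()]: `parse_pattern(linearize(p))` is structurally
#' identical to `p`. Accepts optional whitespace around `=` and around the
#' `":"` separators.
#'
#' @param text Pattern string.
#' @param source_sent_id Optional provenance id.
#' @return An `etio_pattern`.
#' @export
parse_pattern <- function(text, source_sent_id = "") {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty pattern text")
  parts <- trimws(strsplit(text, ":", fixed = TRUE)[[1]])
  elements <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    el <- parts[[i]]
    if (grepl("^\\[.*\\]$", el)) {
      inner <- tolower(trimws(sub("^\\[(.*)\\]$", "\\1", el)))
      role <- if (grepl("symptom", inner)) "symptom"
              else if (grepl("disease|etiolog", inner)) "etiology"
              else stop(sprintf("element %d: unknown placeholder role '%s'", i, el))
      elements[[i]] <- list(kind = "placeholder", role = role)
    } else if (grepl("^lemm\\s*=", el)) {
      lemma <- tolower(trimws(sub("^lemm\\s*=\\s*", "", el)))
      if (!nzchar(lemma)) stop(sprintf("element %d: empty anchor lemma", i))
      elements[[i]] <- list(kind = "anchor", lemma = lemma)
    } else if (grepl("^[<>]", el)) {
      dir <- if (startsWith(el, "<")) "up" else "down"
      lab <- trimws(substring(el, 2L))
      if (!nzchar(lab)) stop(sprintf("element %d: empty edge label", i))
      elements[[i]] <- list(kind = "edge", label = lab, direction = dir)
    } else {
      stop(sprintf("element %d: cannot parse '%s'", i, el))
    }
  }
  kinds <- vapply(elements, `[[`, character(1), "kind")
  n <- length(elements)
  if (n < 3L || kinds[1L] != "placeholder" || kinds[n] != "placeholder")
    stop("pattern must start and end with placeholders")
  if (identical(elements[[1L]]$role, elements[[n]]$role))
    stop("placeholder roles must be distinct")
  node_pos <- kinds %in% c("placeholder", "anchor")
  if (any(node_pos != (seq_len(n) %% 2L == 1L)))
    stop("pattern elements must alternate node / edge")
  new_pattern(elements, source_sent_id)
}

#' Read / write pattern files
#'
#' One linearized pattern per line, UTF-8; blank lines and `#` comments are
#' ignored, so published pattern lists can be loaded directly.
#'
#' @param path File path.
#' @return `read_patterns`: list of `etio_pattern`.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_pattern)
}

#' @rdname read_patterns
#' @param patterns List of `etio_pattern`.
#' @export
write_patterns <- function(patterns, path) {
  writeLines(vapply(patterns, `[[`, character(1), "text_form"), path,
             useBytes = TRUE)
  invisible(path)
}

# Does the structural edge between tokens `dep` (dependent) and its head
# satisfy pattern label `lab` (possibly case-fused)?
.edge_label_ok <- function(tok, dep, lab) {
  if (tok$deprel[dep] == lab) return(TRUE)
  us <- regexpr("_", lab, fixed = TRUE)
  if (us < 0L) return(FALSE)
  base <- substring(lab, 1L, us - 1L)
  case <- substring(lab, us + 1L)
  if (tok$deprel[dep] != base || !(base %in% .case_fusing)) return(FALSE)
  kids <- which(tok$head == dep & tok$deprel == "case")
  any(tolower(tok$lemma[kids]) == case)
}

.nominal_ok <- function(tok, i) {
  up <- tok$upos[i]
  if (is.na(up) || up %in% c("", "_")) return(TRUE)  # no POS available
  up %in% c("NOUN", "PROPN", "X", "SYM", "NUM")
}

#' Match a pattern against a sentence
#'
#' Finds every assignment of sentence tokens to pattern nodes such that all
#' edge constraints (label and direction, with case-fused labels like
#' `nmod_by` resolved against the base relation plus a case child) and all
#' anchor lemmas (case-insensitive) hold. Capture-slot tokens must be
#' nominal when part-of-speech tags are available. Matched placeholder
#' tokens are expanded to their phrase boundaries with [expand_phrase()]
#' and duplicate (symptom span, etiology span) pairs are collapsed.
#'
#' @param pattern An `etio_pattern`.
#' @param sentence An `etio_sentence`.
#' @return A `data.frame` of captures: `sent_id`, the unexpanded head
#'   indices `symptom_head`/`etiology_head`, the expanded spans
#'   `symptom_start`/`symptom_end`/`etiology_start`/`etiology_end`, the
#'   span texts and the pattern text form. Zero rows when nothing matches.
#' @export
match_pattern <- function(pattern, sentence) {
  tok <- sentence$tokens
  n <- nrow(tok)
  els <- pattern$elements
  node_els <- els[vapply(els, `[[`, character(1), "kind") != "edge"]
  edge_els <- els[vapply(els, `[[`, character(1), "kind") == "edge"]
  n_nodes <- length(node_els)

  node_ok <- function(i, el) {
    if (el$kind == "anchor") tolower(tok$lemma[i]) == el$lemma
    else .nominal_ok(tok, i)
  }

  results <- list()
  walk <- function(assign) {
    k <- length(assign)
    if (k == n_nodes) {
      results[[length(results) + 1L]] <<- assign
      return()
    }
    cur <- assign[k]
    e <- edge_els[[k]]
    if (e$direction == "up") {
      nxt <- tok$head[cur]
      if (nxt == 0L || nxt %in% assign) return()
      if (!.edge_label_ok(tok, cur, e$label)) return()
      if (node_ok(nxt, node_els[[k + 1L]])) walk(c(assign, nxt))
    } else {
      for (nxt in which(tok$head == cur)) {
        if (nxt %in% assign) next
        if (!.edge_label_ok(tok, nxt, e$label)) next
        if (node_ok(nxt, node_els[[k + 1L]])) walk(c(assign, nxt))
      }
    }
  }
  for (start in seq_len(n)) {
    if (node_ok(start, node_els[[1L]])) walk(start)
  }

  if (length(results) == 0L) return(empty_captures())
  rows <- lapply(results, function(assign) {
    sym_i <- assign[1L]; eti_i <- assign[n_nodes]
    if (identical(node_els[[1L]]$role, "etiology")) {
      tmp <- sym_i; sym_i <- eti_i; eti_i <- tmp
    }
    sspan <- expand_phrase(sentence, sym_i)
    espan <- expand_phrase(sentence, eti_i)
    if (sspan[1L] <= espan[2L] && espan[1L] <= sspan[2L]) return(NULL)
    data.frame(sent_id = sentence$sent_id,
               symptom_head = sym_i, etiology_head = eti_i,
               symptom_start = sspan[1L], symptom_end = sspan[2L],
               etiology_start = espan[1L], etiology_end = espan[2L],
               symptom_text = paste(tok$form[sspan[1L]:sspan[2L]], collapse = " "),
               etiology_text = paste(tok$form[espan[1L]:espan[2L]], collapse = " "),
               pattern = pattern$text_form,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_captures())
  out <- do.call(rbind, rows)
  key <- paste(out$symptom_start, out$symptom_end,
               out$etiology_start, out$etiology_end)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_captures <- function() {
  data.frame(sent_id = character(), symptom_head = integer(),
             etiology_head = integer(), symptom_start = integer(),
             symptom_end = integer(), etiology_start = integer(),
             etiology_end = integer(), symptom_text = character(),
             etiology_text = character(), pattern = character(),
             stringsAsFactors = FALSE)
}

#' Expand a captured token to its phrase boundaries
#'
#' Grows a captured head token to the noun phrase it heads by recursively
#' attaching dependents whose relation is in the expansion set (`compound`,
#' `amod`, `nummod`, `flat`, plus `nmod` without a case-marking child).
#' Determiners and punctuation are excluded. The result must be contiguous:
#' expansion stops at a contiguity break, returning the maximal contiguous
#' run of collected tokens that contains the head.
#'
#' @param sentence An `etio_sentence`.
#' @param idx Token index.
#' @param rels Expansion relation set (override to tune phrase boundaries).
#' @return Inclusive token range `c(start, end)`.
#' @export
expand_phrase <- function(sentence, idx,
                          rels = .expansion_rels) {
  tok <- sentence$tokens
  collect <- function(i) {
    out <- i
    kids <- which(tok$head == i)
    for (k in kids) {
      rel <- tok$deprel[k]
      ok <- rel %in% rels ||
        (rel == "nmod" && !any(tok$head == k & tok$deprel == "case"))
      if (ok && tok$upos[k] != "PUNCT" && rel != "det")
        out <- c(out, collect(k))
    }
    out
  }
  got <- sort(unique(collect(idx)))
  # maximal contiguous run containing idx
  lo <- idx
  while ((lo - 1L) %in% got) lo <- lo - 1L
  hi <- idx
  while ((hi + 1L) %in% got) hi <- hi + 1L
  c(lo, hi)
}
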