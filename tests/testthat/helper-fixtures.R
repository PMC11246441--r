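# Shared fixtures and independent oracles.

# compact token-table builder
tokify <- function(forms, heads, rels, lemmas = tolower(forms),
                   upos = rep("NOUN", length(forms))) {
  data.frame(id = seq_along(forms), form = forms, lemma = lemmas,
             upos = upos, head = heads, deprel = rels,
             stringsAsFactors = FALSE)
}

# gold parse of "sciatica in low back pain is usually caused by disc
# herniation" (passive causal construction with an off-path modifier chain)
sciatica_sentence <- function() {
  parsed_sentence("sciatica_example", tokify(
    c("sciatica", "in", "low", "back", "pain", "is", "usually", "caused",
      "by", "disc", "herniation"),
    c(8, 5, 5, 5, 1, 8, 8, 0, 11, 11, 8),
    c("nsubjpass", "case", "amod", "compound", "nmod", "auxpass", "advmod",
      "root", "case", "compound", "nmod"),
    lemmas = c("sciatica", "in", "low", "back", "pain", "be", "usually",
               "cause", "by", "disc", "herniation"),
    upos = c("NOUN", "ADP", "ADJ", "NOUN", "NOUN", "AUX", "ADV", "VERB",
             "ADP", "NOUN", "NOUN")))
}

sciatica_pattern_text <- paste(
  "[symptom placeholder] : <nsubjpass : lemm=cause : >nmod_by :",
  "[disease placeholder]")

# random labelled dependency tree with n tokens (token i>1 attaches to a
# random earlier token, so the tree is valid but shapes vary)
random_tree_sentence <- function(n, id = "rnd") {
  heads <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  rels <- c("root", sample(c("nsubj", "dobj", "nmod", "amod", "compound",
                             "advmod", "conj", "acl"),
                           n - 1L, replace = TRUE))
  parsed_sentence(id, tokify(sprintf("w%d", seq_len(n)), heads, rels))
}

# breadth-first-search path oracle over the undirected tree
bfs_path <- function(sentence, a, b) {
  tok <- sentence$tokens
  n <- nrow(tok)
  adj <- lapply(seq_len(n), function(i)
    c(if (tok$head[i] != 0L) tok$head[i], which(tok$head == i)))
  prev <- rep(NA_integer_, n)
  seen <- logical(n); seen[a] <- TRUE
  queue <- a
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    if (cur == b) break
    for (nb in adj[[cur]]) {
      if (!seen[nb]) { seen[nb] <- TRUE; prev[nb] <- cur; queue <- c(queue, nb) }
    }
  }
  path <- b
  while (path[1L] != a) path <- c(prev[path[1L]], path)
  path
}

# independent table-driven American Soundex (distinct formulation: full
# translation, h/w deletion, run-length collapse, then drop the first
# letter's own run and the vowel separators)
soundex_oracle <- function(word) {
  u <- strsplit(toupper(word), "")[[1]]
  map <- c(B = "1", F = "1", P = "1", V = "1",
           C = "2", G = "2", J = "2", K = "2", Q = "2", S = "2", X = "2",
           Z = "2", D = "3", T = "3", L = "4", M = "5", N = "5", R = "6",
           A = "*", E = "*", I = "*", O = "*", U = "*", Y = "*",
           H = ".", W = ".")
  codes <- unname(map[u])
  codes <- codes[codes != "."]                  # h/w transparent
  codes <- rle(codes)$values                    # collapse adjacent runs
  codes <- codes[-1L]                           # first letter's own run
  digits <- codes[codes != "*"]                 # vowels only break runs
  paste0(u[1L], substring(paste0(paste(digits, collapse = ""), "000"), 1L, 3L))
}

# toy verification fixture: a small synthetic corpus about sciatica plus a
# scripted backend proposing three etiologies, ranking the first candidate
# and vetting everything yes
toy_verify_fixture <- function(n_sentences = 50L, seed = 11L) {
  cfg <- generator_config(
    n_sentences = n_sentences,
    symptom_vocab = "sciatica",
    etiology_vocab = c("disc herniation", "endometriosis", "spinal stenosis"),
    abbrev_rate = 0, noise_rate = 0.1, variant_rate = 0,
    rng_seed = seed)
  gen <- generate_corpus(cfg)
  backend <- scripted_backend(list(
    list(match = "exhaustive list",
         response = "disc herniation\nendometriosis\npiriformis syndrome\ndone"),
    list(match = "most convincing", response = function(prompt) {
      sents <- strsplit(sub(".*nothing else\\.\n\n", "", prompt), "\n")[[1]]
      jsonlite::toJSON(list(list(sent = sents[[1]],
                                 reason = "explicit causal statement")),
                       auto_unbox = TRUE)
    }),
    list(match = "yes or no only", response = "Yes.")))
  list(corpus = gen$corpus, gold = gen$gold, backend = backend)
}
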