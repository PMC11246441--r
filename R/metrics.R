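# Pooled evaluation of etiology sources.
#
# Candidate etiologies from several systems plus a reference source are
# pooled under a shared name normalizer; every supported pooled item forms
# the gold set (reference items are supported by assumption), and each
# system is scored by the fraction of the gold set it finds (recall) and
# the fraction of its own items that are supported (precision).

#' Pool etiologies from several sources
#'
#' Names are collapsed with `normalizer` (default: the mention
#' [fingerprint()], standing in for manual cross-source normalization; pass
#' a lookup into a curated mapping to reproduce a manual pooling exactly).
#' Each pooled item records all contributing sources. Items contributed by
#' the source named `"reference"` are labelled supported automatically;
#' other labels come from `labels`, a `data.frame` of (`name`, `label`)
#' with `label` in supported/unsupported. A label naming no pooled item is
#' an error listing the unmatched names.
#'
#' @param per_source Named list of character vectors, one per source
#'   (at most one source may be called `"reference"`).
#' @param labels Optional annotation `data.frame` (`name`, `label`).
#' @param normalizer Function `name -> key`.
#' @return `data.frame` of class `etio_pooled`: `name` (first surface
#'   seen), `key`, `label`, `sources` (list column).
#' @export
pool_etiologies <- function(per_source, labels = NULL,
                            normalizer = fingerprint) {
  stopifnot(is.list(per_source), !is.null(names(per_source)),
            all(nzchar(names(per_source))))
  items <- list()   # key -> list(name, sources)
  for (src in names(per_source)) {
    for (nm in per_source[[src]]) {
      key <- normalizer(nm)
      if (is.null(items[[key]]))
        items[[key]] <- list(name = nm, sources = character())
      items[[key]]$sources <- union(items[[key]]$sources, src)
    }
  }
  keys <- names(items)
  out <- data.frame(
    name = vapply(items, `[[`, character(1), "name"),
    key = keys,
    label = NA_character_,
    stringsAsFactors = FALSE)
  out$sources <- lapply(items, `[[`, "sources")
  rownames(out) <- NULL
  has_ref <- vapply(out$sources, function(s) "reference" %in% s, logical(1))
  out$label[has_ref] <- "supported"
  if (!is.null(labels) && nrow(labels) > 0L) {
    lab_keys <- vapply(labels$name, normalizer, character(1),
                       USE.NAMES = FALSE)
    unmatched <- labels$name[!(lab_keys %in% out$key)]
    if (length(unmatched) > 0L)
      stop("label file references unknown names: ",
           paste(unmatched, collapse = ", "))
    hit <- match(out$key, lab_keys)
    fill <- !is.na(hit) & is.na(out$label)
    out$label[fill] <- labels$label[hit[fill]]
  }
  if (anyNA(out$label))
    warning(sum(is.na(out$label)), " pooled item(s) carry no label")
  class(out) <- c("etio_pooled", "data.frame")
  out
}

.metrics_row <- function(recall, precision) {
  f <- if (recall > 0 && precision > 0)
    2 * recall * precision / (recall + precision) else 0
  c(recall = recall, precision = precision, f_score = f)
}

#' Precision / recall / F for one source
#'
#' The gold set is every supported pooled item. Recall is the percentage of
#' the gold set contributed by `source`; precision is the percentage of the
#' source's own items that are supported; F is their harmonic mean. All on
#' the 0-100 scale. `source` may be a vector of source names, scored as
#' their union (each pooled item counted once) -- the aggregated
#' "patterns + gpt" reading. A source with zero pooled items gets precision
#' 0 with attribute `undefined_precision`.
#'
#' @param source Source name(s).
#' @param pooled An `etio_pooled` table.
#' @return Named numeric vector `recall`, `precision`, `f_score`.
#' @export
prf <- function(source, pooled) {
  stopifnot(nrow(pooled) > 0L)
  supported <- !is.na(pooled$label) & pooled$label == "supported"
  from_src <- vapply(pooled$sources, function(s) any(source %in% s),
                     logical(1))
  gold_n <- sum(supported)
  n_src <- sum(from_src)
  n_good <- sum(from_src & supported)
  recall <- if (gold_n > 0L) 100 * n_good / gold_n else 0
  if (n_src == 0L) {
    row <- .metrics_row(recall, 0)
    attr(row, "undefined_precision") <- TRUE
    return(row)
  }
  .metrics_row(recall, 100 * n_good / n_src)
}

#' Macro average of metric rows
#'
#' Unweighted arithmetic mean per component. The F column is averaged
#' directly rather than recomputed from the averaged recall and precision,
#' matching the usual per-symptom macro-averaging convention.
#'
#' @param rows A list of metric rows (from [prf()]) or a matrix with
#'   columns `recall`, `precision`, `f_score`.
#' @return Named numeric vector `recall`, `precision`, `f_score`.
#' @export
macro_average <- function(rows) {
  if (is.list(rows)) rows <- do.call(rbind, rows)
  stopifnot(nrow(rows) >= 1L)
  c(recall = mean(rows[, "recall"]),
    precision = mean(rows[, "precision"]),
    f_score = mean(rows[, "f_score"]))
}

#' Overlap counts of supported items across sources
#'
#' Partitions the supported pooled items into the regions of the source
#' membership diagram (7 regions for three sources); region counts sum to
#' the number of supported items. More than three sources is unsupported.
#'
#' @param pooled An `etio_pooled` table.
#' @return Named integer vector; region names join source names with
#'   `"&"`.
#' @export
overlap_counts <- function(pooled) {
  supported <- pooled[!is.na(pooled$label) & pooled$label == "supported", ,
                      drop = FALSE]
  srcs <- sort(unique(unlist(pooled$sources)))
  if (length(srcs) > 3L)
    stop("overlap_counts supports at most 3 sources, got ", length(srcs))
  regions <- unlist(lapply(seq_along(srcs), function(k)
    utils::combn(srcs, k, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  counts <- stats::setNames(integer(length(regions)), regions)
  for (i in seq_len(nrow(supported))) {
    key <- paste(sort(supported$sources[[i]]), collapse = "&")
    counts[[key]] <- counts[[key]] + 1L
  }
  counts
}

#' Cohen's kappa for two annotators
#'
#' Chance-corrected agreement from the contingency table of two parallel
#' label vectors: kappa = (p_o - p_e) / (1 - p_e). When the expected
#' agreement p_e is 1 (both annotators constant and identical), kappa is 1
#' if the labels agree.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) == 0L)
    stop("label vectors must have equal, positive length")
  cats <- union(labels_a, labels_b)
  a <- factor(labels_a, levels = cats)
  b <- factor(labels_b, levels = cats)
  n <- length(a)
  po <- mean(a == b)
  pe <- sum((table(a) / n) * (table(b) / n))
  if (pe >= 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Plain-text metrics table
#'
#' Formats per-symptom metric rows plus their macro average in a compact
#' fixed-width layout.
#'
#' @param rows Named list of metric rows (one per symptom).
#' @return Character vector of lines, invisibly printed.
#' @export
format_metrics_table <- function(rows) {
  mat <- do.call(rbind, rows)
  mat <- rbind(mat, macro_average(rows))
  rownames(mat) <- c(names(rows), "Overall (macro averaged)")
  lines <- c(sprintf("%-28s %8s %10s %8s", "", "R", "P", "F"),
             vapply(rownames(mat), function(r)
               sprintf("%-28s %8.2f %10.2f %8.2f", r,
                       mat[r, "recall"], mat[r, "precision"],
                       mat[r, "f_score"]), character(1)))
  lines
}
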