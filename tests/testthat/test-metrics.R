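test_that("pooling unions sources under the normalizer", {
  pooled <- suppressWarnings(
    pool_etiologies(list(patterns = c("a", "b"), gpt = c("b", "c"),
                         reference = "c")))
  expect_identical(nrow(pooled), 3L)
  n_src <- vapply(pooled$sources, length, integer(1))
  expect_identical(unname(n_src[match(c("a", "b", "c"), pooled$name)]),
                   c(1L, 2L, 2L))
  # reference items are auto-labelled supported
  expect_identical(pooled$label[pooled$name == "c"], "supported")

  # an empty source changes nothing
  pooled2 <- suppressWarnings(
    pool_etiologies(list(patterns = c("a", "b"), gpt = c("b", "c"),
                         reference = "c", extra = character())))
  expect_identical(pooled2$key, pooled$key)

  # fingerprint normalizer collapses case variants across sources
  fp <- suppressWarnings(pool_etiologies(list(patterns = "Disc herniation",
                                              gpt = "disc herniation")))
  expect_identical(nrow(fp), 1L)
  expect_setequal(fp$sources[[1]], c("patterns", "gpt"))

  # unknown names in the label file are an error
  expect_error(
    pool_etiologies(list(patterns = "a"),
                    labels = data.frame(name = "zzz", label = "supported")),
    "unknown names.*zzz")
})

test_that("precision/recall/F match hand-computed values", {
  pooled <- suppressWarnings(pool_etiologies(
    list(patterns = c("a", "b", "c"), reference = c("a", "b", "d", "e")),
    labels = data.frame(name = "c", label = "unsupported")))
  r <- prf("patterns", pooled)
  expect_equal(r[["recall"]], 50)
  expect_equal(r[["precision"]], 200 / 3, tolerance = 1e-12)
  expect_equal(r[["f_score"]], 2 * 50 * (200 / 3) / (50 + 200 / 3),
               tolerance = 1e-12)
  # a source covering the gold set exactly scores 100/100/100
  perfect <- prf("reference", pooled)
  expect_equal(unname(perfect), c(100, 100, 100))
  # zero-item source: precision reported 0 with a flag
  zero <- prf("gpt", pooled)
  expect_identical(zero[["precision"]], 0)
  expect_true(attr(zero, "undefined_precision"))
})

test_that("aggregated sources are scored as a union, counted once", {
  pooled <- suppressWarnings(pool_etiologies(
    list(patterns = c("a", "b"), gpt = c("b", "c"), reference = c("a", "c"))))
  both <- prf(c("patterns", "gpt"), pooled)
  # union {a,b,c}: b unlabelled, a and c supported; gold = {a,c}
  expect_equal(both[["recall"]], 100)
  expect_equal(both[["precision"]], 200 / 3, tolerance = 1e-12)
})

test_that("macro averaging averages each component, F included", {
  rows <- list(c(recall = 79.38, precision = 68.44, f_score = 73.51),
               c(recall = 85.33, precision = 70.83, f_score = 77.41),
               c(recall = 39.82, precision = 86.54, f_score = 54.55))
  avg <- macro_average(rows)
  expect_equal(avg[["f_score"]], mean(c(73.51, 77.41, 54.55)))
  expect_equal(round(avg[["f_score"]], 2), 68.49)
  # averaged F differs from F recomputed off averaged R and P
  f_recomputed <- 2 * avg[["recall"]] * avg[["precision"]] /
    (avg[["recall"]] + avg[["precision"]])
  expect_false(isTRUE(all.equal(avg[["f_score"]], f_recomputed)))
  expect_identical(macro_average(rows[c(1, 1)]), rows[[1]])
  # random rows against the arithmetic mean oracle
  set.seed(2)
  rnd <- lapply(1:5, function(i) {
    r <- runif(2, 0, 100)
    c(recall = r[1], precision = r[2],
      f_score = 2 * r[1] * r[2] / (r[1] + r[2]))
  })
  m <- do.call(rbind, rnd)
  expect_equal(unname(macro_average(rnd)), unname(colMeans(m)))
})

test_that("metric invariants hold over random pooled tables", {
  set.seed(6)
  for (rep in 1:20) {
    nm <- paste0("e", 1:12)
    srcs <- c("patterns", "gpt", "reference")
    per_source <- lapply(srcs, function(s) sample(nm, sample(3:10, 1)))
    names(per_source) <- srcs
    labs <- data.frame(name = nm, label = sample(
      c("supported", "unsupported"), 12, replace = TRUE))
    labs <- labs[labs$name %in% unlist(per_source), , drop = FALSE]
    pooled <- pool_etiologies(per_source, labels = labs,
                              normalizer = identity)
    for (s in srcs) {
      r <- prf(s, pooled)
      expect_true(all(r >= 0 & r <= 100))
      expect_lte(r[["f_score"]], max(r[["recall"]], r[["precision"]]) + 1e-9)
      if (r[["recall"]] * r[["precision"]] == 0)
        expect_identical(r[["f_score"]], 0)
    }
    # pooling conserves items
    expect_lte(nrow(pooled), sum(lengths(per_source)))
  }
})

test_that("overlap counts partition the supported set (enumeration oracle)", {
  pooled <- suppressWarnings(pool_etiologies(
    list(patterns = c("a", "b", "d"), gpt = c("a", "c", "d"),
         reference = c("a", "b", "c", "e"))))
  counts <- overlap_counts(pooled)
  # supported = reference members only (d carries no label): a, b, c, e
  expect_identical(sum(counts), 4L)
  expect_identical(counts[["gpt&patterns&reference"]], 1L)  # a
  expect_identical(counts[["patterns&reference"]], 1L)      # b
  expect_identical(counts[["gpt&reference"]], 1L)           # c
  expect_identical(counts[["reference"]], 1L)               # e

  # degenerate shapes
  all3 <- suppressWarnings(pool_etiologies(
    list(patterns = "x", gpt = "x", reference = "x")))
  c3 <- overlap_counts(all3)
  expect_identical(sum(c3), 1L)
  expect_identical(c3[["gpt&patterns&reference"]], 1L)

  # random membership against a brute-force enumeration oracle
  set.seed(12)
  for (rep in 1:10) {
    member <- matrix(runif(30) < 0.5, nrow = 10,
                     dimnames = list(paste0("n", 1:10),
                                     c("patterns", "gpt", "reference")))
    member[rowSums(member) == 0, 1] <- TRUE
    per_source <- lapply(colnames(member), function(s)
      rownames(member)[member[, s]])
    names(per_source) <- colnames(member)
    pooled <- suppressWarnings(pool_etiologies(per_source,
                                               normalizer = identity))
    counts <- overlap_counts(pooled)
    # only reference members are supported without an annotation file
    for (i in rownames(member)) {
      if (!member[i, "reference"]) next
      key <- paste(sort(colnames(member)[member[i, ]]), collapse = "&")
      counts[[key]] <- counts[[key]] - 1L
    }
    expect_true(all(counts == 0L))
  }

  four <- suppressWarnings(pool_etiologies(
    list(a = "x", b = "x", c = "x", d = "x")))
  expect_error(overlap_counts(four), "at most 3")
})

test_that("Cohen's kappa matches the contingency-table oracle", {
  expect_identical(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_identical(cohen_kappa(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  expect_identical(cohen_kappa(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_error(cohen_kappa(c(1, 0), c(1)), "equal")

  # 20 items, 17 agreements, hand-computed 2x2 value
  a <- c(rep(1, 12), rep(0, 8))
  b <- c(rep(1, 10), 0, 0, 1, rep(0, 7))
  # table: n11=10, n10=2, n01=1, n00=7 -> po=.85
  po <- 17 / 20
  pe <- (12 / 20) * (11 / 20) + (8 / 20) * (9 / 20)
  expect_equal(cohen_kappa(a, b), (po - pe) / (1 - pe))
})
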