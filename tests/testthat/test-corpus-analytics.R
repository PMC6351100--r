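# Aggregation and test statistics.

test_that("the pooled z-test reproduces the published statistics", {
  expect_equal(two_proportion_ztest(26418, 305161, 50, 1502)$z, 7.3353,
               tolerance = 1e-4)
  expect_equal(two_proportion_ztest(15615, 305130, 50, 1502)$z, 3.1406,
               tolerance = 1e-4)
  expect_equal(two_proportion_ztest(5830, 110997, 50, 1502)$z, 3.327,
               tolerance = 1e-3)
})

test_that("z-test properties: null at equality, antisymmetry, tails", {
  expect_equal(two_proportion_ztest(10, 100, 1, 10)$z, 0)
  a <- two_proportion_ztest(30, 200, 10, 150)
  b <- two_proportion_ztest(10, 150, 30, 200)
  expect_equal(a$z, -b$z)
  expect_equal(two_proportion_ztest(30, 200, 10, 150, "two.sided")$p_value,
               2 * a$p_value)
  expect_equal(two_proportion_ztest(30, 200, 10, 150, "less")$p_value,
               1 - a$p_value)
  expect_error(two_proportion_ztest(5, 0, 1, 10), "positive")
  expect_error(two_proportion_ztest(11, 10, 1, 10), "0 <= x <= n")
  expect_warning(z0 <- two_proportion_ztest(0, 10, 0, 20), "degenerate")
  expect_equal(z0$z, 0)
  expect_true(is.na(z0$p_value))
})

test_that("the pooled z matches the chi-square test without correction", {
  # independent oracle: z^2 equals the X-squared of stats::prop.test
  set.seed(5)
  for (k in 1:25) {
    n1 <- sample(50:500, 1); n2 <- sample(20:200, 1)
    x1 <- rbinom(1, n1, 0.2); x2 <- rbinom(1, n2, 0.1)
    if (x1 + x2 == 0 || x1 + x2 == n1 + n2) next
    z <- two_proportion_ztest(x1, n1, x2, n2)$z
    chi <- suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE))$statistic
    expect_equal(z^2, unname(chi), tolerance = 1e-10)
  }
})

test_that("linear_trend_r2 matches the squared-correlation identity", {
  exact <- suppressWarnings(linear_trend_r2(1:5, 2 * (1:5) + 3))
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 2)
  expect_warning(flat <- linear_trend_r2(1:5, rep(4, 5)), "zero variance")
  expect_equal(flat$r_squared, 0)
  set.seed(8)
  x <- 1997:2012; y <- 0.05 * x + rnorm(16)
  fit <- linear_trend_r2(x, y)
  expect_equal(fit$r_squared, stats::cor(x, y)^2)
  expect_error(linear_trend_r2(1:2, 1:2), "3 points")
  expect_error(linear_trend_r2(rep(2000, 4), 1:4), "zero variance")
})

test_that("weighted_average_rate follows the weighting arithmetic", {
  expect_equal(weighted_average_rate(c(A = 0.1, B = 0.2), c(A = 1, B = 1)),
               0.15)
  expect_equal(weighted_average_rate(c(A = 0.1, B = 0.2), c(A = 3, B = 1)),
               0.125)
  expect_equal(weighted_average_rate(c(A = 0.42), c(A = 7)), 0.42)
  expect_message(
    w <- weighted_average_rate(c(A = 0.1, B = 0.2, C = 0.9), c(A = 1, B = 1)),
    "skipping")
  expect_equal(w, 0.15)
  expect_error(weighted_average_rate(c(A = 0.1), c(A = 0)), "positive weight")
  expect_error(weighted_average_rate(c(A = 0.1), c(A = -1)), "non-negative")
})

toy_results <- function() {
  # 6 mentions across 4 docs, 2 years, 2 journals; matches nested by design
  docs <- data.frame(doc_id = c("1", "2", "3", "4"),
                     journal = c("Ja", "Ja", "Jb", "Jb"),
                     year = c(1998L, 1998L, 1999L, 1999L),
                     minable = TRUE)
  mk <- function(acc) data.frame(
    doc_id = c("1", "1", "2", "3", "3", "4"),
    mention_text = c("AA-1", "AA-2", "AA-1", "BB-1", "BB-2", "BB-3"),
    criterion = "x", matched_accession = acc, distance = NA_real_,
    stringsAsFactors = FALSE)
  list(docs = docs,
       strict = mk(c("A", NA, NA, NA, NA, NA)),
       edit = mk(c("A", NA, "A", NA, NA, NA)),
       loose = mk(c("A", "B", "A", "C", NA, NA)))
}

test_that("aggregate_yearly reports planted counts and respects min_year", {
  t <- toy_results()
  y <- aggregate_yearly(list(strict = t$strict, loose = t$loose,
                             edit = t$edit), t$docs, min_year = 1997L)
  expect_equal(y$year, 1997:1999)
  expect_equal(y$mentions_total, c(0L, 3L, 3L))
  expect_equal(y$matched_strict, c(0L, 1L, 0L))
  expect_equal(y$matched_edit, c(0L, 2L, 0L))
  expect_equal(y$matched_loose, c(0L, 3L, 1L))
  expect_equal(y$papers_total, c(0L, 2L, 2L))
  expect_equal(y$pct_edit, c(NA, 100 * 2 / 3, 0))
  # nesting holds in every year
  expect_true(all(y$matched_strict <= y$matched_edit &
                  y$matched_edit <= y$matched_loose &
                  y$matched_loose <= y$mentions_total))
  y99 <- aggregate_yearly(list(edit = t$edit), t$docs, min_year = 1999L)
  expect_equal(y99$year, 1999L)
})

test_that("aggregate_by_journal orders by detections with alphabetical ties", {
  t <- toy_results()
  j <- aggregate_by_journal(t$edit, t$docs)
  # Ja has unique names {aa1, aa2}, Jb {bb1, bb2, bb3}: Jb sorts first
  expect_equal(j$journal, c("Jb", "Ja"))
  expect_equal(j$cell_lines_detected[j$journal == "Jb"], 3L)
  expect_equal(j$cell_lines_problematic[j$journal == "Ja"], 1L)
  expect_equal(j$papers_with_problematic[j$journal == "Ja"], 2L)

  # tie on detections resolves alphabetically; zero journals are retained
  docs2 <- data.frame(doc_id = c("1", "2", "3"),
                      journal = c("Zeta", "Alpha", "Mu"),
                      year = 2000L, minable = TRUE)
  res2 <- data.frame(doc_id = c("1", "2"), mention_text = c("AA-1", "BB-1"),
                     criterion = "x", matched_accession = NA_character_,
                     distance = NA_real_)
  j2 <- aggregate_by_journal(res2, docs2)
  expect_equal(j2$journal, c("Alpha", "Zeta", "Mu"))
  expect_equal(j2$cell_lines_detected, c(1L, 1L, 0L))
  expect_equal(nrow(aggregate_by_journal(res2, docs2, top_n = 2)), 2L)
})

test_that("aggregations are invariant to document order", {
  t <- toy_results()
  perm <- sample(nrow(t$edit))
  y1 <- aggregate_yearly(list(edit = t$edit), t$docs)
  y2 <- aggregate_yearly(list(edit = t$edit[perm, ]), t$docs[sample(4), ])
  expect_equal(y1, y2)
  j1 <- aggregate_by_journal(t$loose, t$docs)
  j2 <- aggregate_by_journal(t$loose[perm, ], t$docs[sample(4), ])
  expect_equal(j1, j2)
})

test_that("paper_level_rate counts papers with at least one match", {
  t <- toy_results()
  r <- paper_level_rate(t$edit)
  expect_equal(r$papers_matched, 2L)   # docs 1 and 2
  expect_equal(r$papers_total, 4L)
  expect_equal(r$fraction, 0.5)
  none <- t$edit; none$matched_accession <- NA_character_
  expect_equal(paper_level_rate(none)$fraction, 0)
  expect_true(is.na(paper_level_rate(t$edit[0, ])$fraction))
})

test_that("per-journal problematic fractions recover the planted truth", {
  w <- small_world(seed = 13, n_docs = 1200,
                   corruption = c(spacehyphen = 0, suffix = 0, case = 0,
                                  typo = 0))
  prob_lex <- lexicon_subset(w$lexicon, TRUE)
  one_per_line <- w$truth$mentions[!duplicated(
    paste(w$truth$mentions$doc_id, w$truth$mentions$accession)), ]
  res <- match_corpus(one_per_line, prob_lex, "edit")$results
  pt <- planted_truth(w$truth)
  jmap <- w$truth$docs$journal[match(res$doc_id, w$truth$docs$doc_id)]
  for (j in unique(jmap)) {
    got <- sum(!is.na(res$matched_accession[jmap == j]))
    want <- pt$by_journal$problematic_lines[pt$by_journal$journal == j]
    expect_equal(got, want)
  }
})
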