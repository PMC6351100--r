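# Lexicon loading, normalization and the three matching criteria.

test_that("load_lexicon parses the TSV schema and indexes every name", {
  tsv <- file.path(tempdir(), "lex.tsv")
  writeLines(c(
    "accession\tprimary_name\tsynonyms\tproblematic\tproblem_category",
    "CVCL_A\tCF-1\tCF-one|CF.1\t1\tmisidentified",
    "CVCL_B\tHeLa\t\t1\tother",
    "CVCL_C\tQX-17\t\t0\t"
  ), tsv)
  lex <- load_lexicon(tsv)
  expect_equal(nrow(lex$entries), 3L)
  # CF.1 normalizes like CF-1's own norm? no: synonyms de-duplicate against
  # each other only; CF-one and CF.1 are distinct normals -> 5 indexed names
  expect_equal(nrow(lex$names), 5L)
  expect_true(all(c("CVCL_A", "CVCL_B", "CVCL_C") %in% lex$names$accession))
})

test_that("schema violations are reported with the offending line", {
  tsv <- file.path(tempdir(), "bad1.tsv")
  writeLines(c(
    "accession\tprimary_name\tsynonyms\tproblematic\tproblem_category",
    "CVCL_A\tCF-1\t\t1\tmisidentified",
    "\tHeLa\t\t1\t"
  ), tsv)
  expect_error(load_lexicon(tsv), "line 3.*empty accession")
  tsv2 <- file.path(tempdir(), "bad2.tsv")
  writeLines(c(
    "accession\tprimary_name\tsynonyms\tproblematic\tproblem_category",
    "CVCL_A\tCF-1\t\t1\tmisidentified",
    "CVCL_A\tHeLa\t\t1\t"
  ), tsv2)
  expect_error(load_lexicon(tsv2), "line 3.*duplicate accession")
  expect_error(load_lexicon(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("a generated lexicon round-trips through its TSV form", {
  lex <- generate_lexicon(generator_config(seed = 3, lexicon_size = 25))$lexicon
  p <- file.path(tempdir(), "roundtrip.tsv")
  write_lexicon(lex, p)
  lex2 <- load_lexicon(p)
  expect_identical(lex$entries, lex2$entries)
  expect_identical(lex$names, lex2$names)
})

test_that("normalize_name folds case and strips special characters", {
  expect_identical(normalize_name("EF 1"), normalize_name("EF-1"))
  expect_identical(normalize_name("HeLa"), normalize_name("HELA"))
  expect_identical(normalize_name(""), "")
  # idempotence
  x <- c("CF-1 mouse", "RAW 264.7", "a--b  c")
  expect_identical(normalize_name(normalize_name(x)), normalize_name(x))
  # custom zero-weight set: only hyphens are free
  cfg <- match_config(zero_weight_chars = "-")
  expect_identical(normalize_name("EF-1", cfg), "ef1")
  expect_identical(normalize_name("EF 1", cfg), "ef 1")
})

test_that("weighted_edit_distance reproduces the worked examples", {
  expect_equal(weighted_edit_distance("CF1", "CF-1"), 0)
  expect_equal(weighted_edit_distance("EF 1", "EF-1"), 0)
  expect_equal(weighted_edit_distance("CF-1", "CF-10"), 1)
  expect_equal(weighted_edit_distance("CF-1", "CAF-1"), 1)
  expect_equal(weighted_edit_distance("abc", "abc"), 0)
  expect_equal(weighted_edit_distance("abc", "abd"), 2)
})

test_that("weighted_edit_distance equals the brute-force oracle", {
  cfg <- match_config()
  alphabet <- c("a", "b", "1", "-")   # includes one zero-weight character
  pool3 <- all_strings(alphabet, 3)   # exhaustive on short strings
  for (a in pool3) for (b in pool3) {
    d <- weighted_edit_distance(a, b, cfg)
    expect_identical(d, bf_edit_distance(a, b, cfg))
  }
  # seeded random pairs up to length 6 over the same alphabet
  set.seed(99)
  for (k in 1:400) {
    a <- random_string(alphabet, 6); b <- random_string(alphabet, 6)
    expect_identical(weighted_edit_distance(a, b, cfg),
                     bf_edit_distance(a, b, cfg),
                     label = paste0("d('", a, "','", b, "')"))
  }
  # non-default weights exercise the general DP (sub cheaper than indel sum)
  cfg2 <- match_config(indel_weight = 3, substitution_weight = 2,
                       threshold = 4)
  expect_equal(weighted_edit_distance("ab", "cb", cfg2), 2)
  expect_equal(weighted_edit_distance("ab", "b", cfg2), 3)
})

test_that("the default distance is a metric and vanishes iff normals agree", {
  cfg <- match_config()
  alphabet <- c("a", "b", "c", "1", "2", "-", " ")
  set.seed(7)
  strs <- replicate(60, random_string(alphabet, 5))
  d <- function(x, y) weighted_edit_distance(x, y, cfg)
  for (k in 1:120) {
    abc <- sample(strs, 3, replace = TRUE)
    expect_gte(d(abc[1], abc[2]), 0)
    expect_equal(d(abc[1], abc[2]), d(abc[2], abc[1]))
    expect_lte(d(abc[1], abc[3]), d(abc[1], abc[2]) + d(abc[2], abc[3]) + 1e-12)
    expect_identical(d(abc[1], abc[2]) == 0,
                     normalize_name(abc[1]) == normalize_name(abc[2]))
  }
})

test_that("with integer weights and threshold 1, edit match <=> equal normals", {
  lex <- tiny_lexicon()
  cfg <- match_config()
  set.seed(11)
  alphabet <- c("c", "f", "e", "h", "1", "7", "-", " ")
  for (k in 1:200) {
    m <- random_string(alphabet, 6)
    if (!nchar(m)) next
    res <- match_mention(m, lex, "edit", cfg)
    expected <- normalize_name(m) %in% lex$names$norm
    expect_identical(!is.na(res$matched_accession), expected, label = m)
  }
})

test_that("match_mention honors the three criteria on the worked examples", {
  lex <- tiny_lexicon()
  loose <- match_mention("CF-1 mouse embryonic fibroblasts", lex, "loose")
  expect_identical(loose$matched_accession, "CVCL_T001")
  strict <- match_mention("CF-1 mouse embryonic fibroblasts", lex, "strict")
  expect_true(is.na(strict$matched_accession))
  expect_identical(match_mention("CF1", lex, "edit")$matched_accession,
                   "CVCL_T001")
  expect_true(is.na(match_mention("CAF-1", lex, "edit")$matched_accession))
  expect_true(is.na(match_mention("CF-10", lex, "edit")$matched_accession))
  expect_identical(match_mention("HELA", lex, "strict")$matched_accession,
                   "CVCL_T002")
  expect_error(match_mention("HeLa", lex, "fuzzy"))
})

test_that("tie-breaking picks the lexicographically smallest accession", {
  lex <- new_lexicon_from_entries(data.frame(
    accession = c("CVCL_B9", "CVCL_A1"),
    primary_name = c("KB", "K-B"), synonyms = "",
    problematic = TRUE, problem_category = "misidentified"))
  expect_identical(match_mention("kb", lex, "edit")$matched_accession,
                   "CVCL_A1")
})

test_that("the optional two-way loose semantics matches the wildcard reading", {
  lex <- tiny_lexicon()
  cfg <- match_config(loose_two_way = TRUE)
  # detected name is a prefix of the lexicon name "CF-one"
  expect_false(is.na(match_mention("CF-o", lex, "loose", cfg)$matched_accession))
  expect_true(is.na(match_mention("CF-o", lex, "loose")$matched_accession))
})

test_that("match_corpus counts mentions and unique names consistently", {
  lex <- tiny_lexicon()
  mentions <- data.frame(
    doc_id = c("d1", "d1", "d1", "d2", "d2", "d2", "d2", "d3", "d3", "d3"),
    surface = c("CF1", "hela", "ZZTOP", "EF 1", "unknown-9", "XX", "YY",
                "abc", "def", "ghi"),
    stringsAsFactors = FALSE)
  out <- match_corpus(mentions, lex, "edit")
  expect_equal(out$summary$total_mentions, 10L)
  expect_equal(out$summary$matched_mentions, 3L)
  expect_equal(sum(!is.na(out$results$matched_accession)), 3L)
  expect_equal(out$summary$unique_names, 10L)
  expect_equal(out$summary$matched_unique_names, 3L)

  empty <- match_corpus(data.frame(surface = character(0)), lex, "strict")
  expect_equal(empty$summary$total_mentions, 0L)
  expect_equal(empty$summary$matched_mentions, 0L)
})

test_that("matched fraction recovers the planted problematic rate", {
  # corruption restricted to operators the loose criterion respects
  w <- small_world(seed = 5, n_docs = 2000,
                   corruption = c(spacehyphen = 0.1, suffix = 0.08,
                                  case = 0.05, typo = 0))
  prob_lex <- lexicon_subset(w$lexicon, TRUE)
  lines <- w$truth$lines
  one_per_line <- w$truth$mentions[!duplicated(
    paste(w$truth$mentions$doc_id, w$truth$mentions$accession)), ]
  out <- match_corpus(one_per_line, prob_lex, "loose")
  # without typos the loose criterion recovers the planted flags exactly
  expect_equal(out$summary$matched_mentions, sum(lines$problematic))
  # and per cohort the realized rate sits inside the 99% binomial band of
  # the configured probability
  for (co in c("nonrrid", "rrid")) {
    sub <- one_per_line[one_per_line$cohort == co, ]
    o <- match_corpus(sub, prob_lex, "loose")
    p <- if (co == "rrid") 0.033 else 0.087
    ci <- binom_ci99(p, nrow(sub))
    frac <- o$summary$matched_mentions / o$summary$total_mentions
    expect_gte(frac, ci[1])
    expect_lte(frac, ci[2])
  }
})
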