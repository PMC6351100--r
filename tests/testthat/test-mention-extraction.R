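# Methods scoping, the dictionary+context recognizer, and the evaluation
# harness.

test_that("extract_methods_section finds methods-like labels", {
  s1 <- c(Methods = "methods text", Results = "results text")
  expect_identical(extract_methods_section(s1), "methods text")
  s2 <- c("Materials and Methods" = "mm text")
  expect_identical(extract_methods_section(s2), "mm text")
  s3 <- c(Introduction = "x", Discussion = "y")
  expect_true(is.na(extract_methods_section(s3)))
  # concatenation of several methods-like sections
  s4 <- c(Methods = "a", "Supplementary methods" = "b")
  expect_identical(extract_methods_section(s4), "a\nb")
})

test_that("documents without a methods section contribute zero mentions", {
  lex <- tiny_lexicon()
  docs <- data.frame(doc_id = c("1", "2"), journal = "J", year = 2000L,
                     minable = TRUE)
  sections <- list(
    "1" = c(Methods = "CF-1 cells were grown overnight."),
    "2" = c(Results = "CF-1 cells were grown overnight."))
  corp <- new_corpus(docs, sections)
  m <- detect_corpus_mentions(corp, lex)
  expect_identical(unique(m$doc_id), "1")
})

test_that("detect_mentions reproduces the curated example sentences", {
  lex <- tiny_lexicon()   # HeLa in dictionary; others via context
  m1 <- detect_mentions("HeLa or HCN-A94 cells were grown in 24 well plates",
                        lex)
  expect_setequal(m1$surface, c("HeLa", "HCN-A94"))
  m2 <- detect_mentions("HeLa or RAW264.7 cells were seeded into 96-well plates",
                        lex)
  expect_setequal(m2$surface, c("HeLa", "RAW264.7"))
  expect_identical(nrow(detect_mentions(
    "The buffer was mixed thoroughly before analysis", lex)), 0L)
})

test_that("detected spans are in bounds, non-overlapping, and faithful", {
  w <- small_world(seed = 21, n_docs = 250)
  for (id in utils::head(w$corpus$docs$doc_id, 200)) {
    secs <- w$corpus$sections[[id]]
    if (!"Methods" %in% names(secs)) next
    txt <- secs[["Methods"]]
    m <- detect_mentions(txt, w$lexicon, doc_id = id, section = "Methods")
    if (!nrow(m)) next
    expect_true(all(m$start >= 0 & m$end <= nchar(txt)))
    expect_true(all(m$end > m$start))
    o <- m[order(m$start), ]
    if (nrow(o) > 1)
      expect_true(all(o$start[-1] >= o$end[-nrow(o)]))
    expect_identical(substr(rep(txt, nrow(m)), m$start + 1L, m$end),
                     m$surface)
  }
})

test_that("evaluate_ner applies the precision/recall/F1 formulas", {
  gold <- data.frame(doc_id = "26012578", section = "Methods",
                     start = c(31, 39), end = c(35, 46),
                     surface = c("HeLa", "HCN-A94"))
  pred <- rbind(gold[, c("doc_id", "section", "start", "end")],
                data.frame(doc_id = "26012578", section = "Methods",
                           start = 120, end = 133))  # the plasmid fp
  ev <- evaluate_ner(gold, pred)
  expect_equal(ev$tp, 2L); expect_equal(ev$fp, 1L); expect_equal(ev$fn, 0L)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 2 * (2 / 3) * 1 / (2 / 3 + 1))

  ident <- evaluate_ner(gold, gold)
  expect_equal(c(ident$precision, ident$recall, ident$f1), c(1, 1, 1))

  none <- evaluate_ner(gold, gold[0, ])
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)   # defined, not NaN
  expect_equal(none$f1, 0)
})

test_that("evaluate_ner counts reconcile and exact mode is stricter", {
  set.seed(3)
  gold <- data.frame(doc_id = sample(c("a", "b"), 12, TRUE),
                     section = "Methods",
                     start = seq(0, 110, by = 10), end = seq(4, 114, by = 10))
  pred <- gold
  pred$start <- pred$start + sample(c(0L, 2L), 12, TRUE)  # some shifted
  ev_o <- evaluate_ner(gold, pred, "overlap")
  ev_e <- evaluate_ner(gold, pred, "exact")
  expect_equal(ev_o$tp + ev_o$fp, nrow(pred))
  expect_equal(ev_o$tp + ev_o$fn, nrow(gold))
  expect_lte(ev_e$tp, ev_o$tp)
  expect_equal(ev_o$tp, 12L)  # 2-char shifts still overlap
  # F1 invariant under row permutation
  ev_p <- evaluate_ner(gold[sample(12), ], pred[sample(12), ], "overlap")
  expect_equal(ev_p$f1, ev_o$f1)
})

test_that("repeated_split_eval is deterministic and perfect without noise", {
  w <- small_world(seed = 31, n_docs = 200,
                   corruption = c(spacehyphen = 0, suffix = 0, case = 0,
                                  typo = 0))
  r1 <- repeated_split_eval(w$corpus, w$lexicon, n_repeats = 3, seed = 17)
  r2 <- repeated_split_eval(w$corpus, w$lexicon, n_repeats = 3, seed = 17)
  expect_identical(r1, r2)
  # uncorrupted names drawn from the recognizer's own dictionary: P = R = 1
  expect_true(all(r1$per_repeat$precision == 1))
  expect_true(all(r1$per_repeat$recall == 1))
  expect_true(all(r1$summary$sd == 0))
  tiny <- w$corpus
  tiny$gold <- tiny$gold[tiny$gold$doc_id == tiny$gold$doc_id[1], ]
  expect_error(repeated_split_eval(tiny, w$lexicon), "at least 10")
})

test_that("dictionary-channel recall does not increase with corruption", {
  recall_at <- function(typo) {
    w <- small_world(seed = 61, n_docs = 300,
                     corruption = c(spacehyphen = 0, suffix = 0, case = 0,
                                    typo = typo))
    pred <- detect_corpus_mentions(
      w$corpus, w$lexicon,
      trigger_config(enabled = character(0)))   # dictionary channel only
    evaluate_ner(w$corpus$gold, pred)$recall
  }
  r <- vapply(c(0, 0.3, 0.8), recall_at, numeric(1))
  expect_true(all(diff(r) <= 0))
  expect_equal(r[1], 1)
})

test_that("paper_level_agreement reproduces the curation confusion table", {
  n <- 1003L
  cur <- c(rep(TRUE, 138), rep(FALSE, 815), rep(FALSE, 17), rep(TRUE, 33))
  alg <- c(rep(TRUE, 138), rep(FALSE, 815), rep(TRUE, 17), rep(FALSE, 33))
  names(cur) <- names(alg) <- sprintf("p%04d", seq_len(n))
  ag <- paper_level_agreement(cur, alg)
  expect_equal(ag$both_found, 138L)
  expect_equal(ag$both_absent, 815L)
  expect_equal(ag$only_algorithm, 17L)
  expect_equal(ag$only_curator, 33L)
  expect_equal(ag$agreement_fraction, 953 / 1003)
  expect_equal(rate_percent(953, 1003, 2), 95.01)

  same <- stats::setNames(c(TRUE, FALSE), c("a", "b"))
  expect_equal(paper_level_agreement(same, same)$agreement_fraction, 1)
  expect_equal(paper_level_agreement(same, !same)$agreement_fraction, 0)
  expect_error(paper_level_agreement(same, stats::setNames(TRUE, "a")),
               "mismatch")
})

test_that("systematic_sample takes every nth record deterministically", {
  expect_equal(systematic_sample(seq_len(130), 65), c(65L, 130L))
  expect_equal(systematic_sample(seq_len(20), 1), seq_len(20))
  expect_equal(length(systematic_sample(seq_len(65085), 65)), 1001L)
  expect_equal(nrow(systematic_sample(data.frame(x = 1:10), 4)), 2L)
  expect_error(systematic_sample(1:10, 0), "positive")
})
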