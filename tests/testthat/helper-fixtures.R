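# Shared fixtures, built in code.

tiny_lexicon <- function() {
  new_lexicon_from_entries(data.frame(
    accession = c("CVCL_T001", "CVCL_T002", "CVCL_T003"),
    primary_name = c("CF-1", "HeLa", "EF-1"),
    synonyms = c("CF-one", "", "EF 1|ef1"),
    problematic = c(TRUE, TRUE, TRUE),
    problem_category = c("misidentified", "misidentified",
                         "partially-contaminated"),
    stringsAsFactors = FALSE
  ))
}

# Independent brute-force oracle for the weighted edit distance: plain
# first-character recursion with memoization, no dynamic-programming table
# shared with the implementation.
bf_edit_distance <- function(a, b, config = match_config()) {
  if (!config$case_sensitive) { a <- tolower(a); b <- tolower(b) }
  zw <- function(ch) !grepl("[[:alnum:]]", ch)
  memo <- new.env(parent = emptyenv())
  rec <- function(a, b) {
    key <- paste0(a, "\r", b)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (!nchar(a) && !nchar(b)) {
      0
    } else if (!nchar(a)) {
      h <- substr(b, 1, 1)
      (if (zw(h)) 0 else config$indel_weight) + rec(a, substring(b, 2))
    } else if (!nchar(b)) {
      h <- substr(a, 1, 1)
      (if (zw(h)) 0 else config$indel_weight) + rec(substring(a, 2), b)
    } else {
      ha <- substr(a, 1, 1); hb <- substr(b, 1, 1)
      del <- (if (zw(ha)) 0 else config$indel_weight) + rec(substring(a, 2), b)
      ins <- (if (zw(hb)) 0 else config$indel_weight) + rec(a, substring(b, 2))
      sub <- (if (ha == hb) 0 else config$substitution_weight) +
        rec(substring(a, 2), substring(b, 2))
      min(del, ins, sub)
    }
    memo[[key]] <- val
    val
  }
  rec(a, b)
}

# All strings up to length `max_len` over `alphabet`.
all_strings <- function(alphabet, max_len) {
  out <- ""
  cur <- ""
  for (l in seq_len(max_len)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

random_string <- function(alphabet, max_len) {
  n <- sample(0:max_len, 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

small_world <- function(seed = 42L, n_docs = 400L, ...) {
  cfg <- generator_config(seed = seed, n_docs = n_docs, ...)
  lex <- generate_lexicon(cfg)
  gen <- generate_corpus(cfg, lex$lexicon)
  list(config = cfg, lexicon = lex$lexicon, registry = lex$registry,
       corpus = gen$corpus, truth = gen$truth)
}

# Exact (Clopper-Pearson) binomial 99% CI for a planted probability p at n
# draws, on the fraction scale.
binom_ci99 <- function(p, n) {
  lo <- stats::qbinom(0.005, n, p) / n
  hi <- stats::qbinom(0.995, n, p) / n
  c(lo, hi)
}
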