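# Cell-line mention detection (dictionary + context channels) and the
# evaluation harness (precision/recall/F1, repeated splits, paper-level
# agreement).

#' Context-trigger configuration for the mention recognizer
#'
#' The recognizer has two channels: a dictionary channel that finds token
#' sequences whose normalized form equals a lexicon name, and a context
#' channel that finds name-like tokens adjoining a trigger phrase such as
#' "cells" or "cell line". The context channel can find names absent from
#' the dictionary (e.g. newly described lines), at the price of occasional
#' false positives.
#'
#' @param triggers Trigger phrases (matched case-insensitively on word
#'   boundaries). Phrases like "cells were cultured/grown/seeded" are covered
#'   by the "cells" trigger.
#' @param window Maximum number of tokens scanned leftwards from a trigger
#'   for candidate names.
#' @param max_ngram Longest token n-gram tried by the dictionary channel.
#' @param enabled Optional character subset of `triggers` to use (set by
#'   trigger tuning); `NULL` means all.
#' @return An object of class `cellaudit_trigger_config`.
#' @export
trigger_config <- function(triggers = c("cells", "cell line", "cell lines"),
                           window = 6L, max_ngram = 4L, enabled = NULL) {
  stopifnot(length(triggers) >= 1L, window >= 1L, max_ngram >= 1L)
  if (!is.null(enabled)) stopifnot(all(enabled %in% triggers))
  structure(list(triggers = triggers, window = as.integer(window),
                 max_ngram = as.integer(max_ngram), enabled = enabled),
            class = "cellaudit_trigger_config")
}

# Token positions: list with surface, start, end (0-based half-open).
tokenize_text <- function(text) {
  m <- gregexpr("[A-Za-z0-9](?:[A-Za-z0-9._/+-]*[A-Za-z0-9])?", text,
                perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0)))
  len <- attr(m, "match.length")
  data.frame(surface = regmatches(text, list(m))[[1]],
             start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + len,
             stringsAsFactors = FALSE)
}

# A token looks like a cell-line name when it contains a letter and either a
# digit or at least two uppercase letters ("HeLa", "HCN-A94", "RAW264.7"),
# which rejects ordinary sentence-initial capitalized words.
is_name_like <- function(tok) {
  has_letter <- grepl("[A-Za-z]", tok)
  has_digit <- grepl("[0-9]", tok)
  n_upper <- vapply(gregexpr("[A-Z]", tok),
                    function(g) if (g[1] == -1L) 0L else length(g), integer(1))
  has_letter & (has_digit | n_upper >= 2L)
}

#' Detect cell-line mentions in a section text
#'
#' Runs the dictionary channel (normalized n-gram lookup against the lexicon)
#' and the context channel (name-like tokens adjoining a trigger phrase,
#' including coordinated lists such as "HeLa or RAW264.7 cells"). Overlapping
#' candidates are resolved leftmost-longest. Spans are 0-based half-open
#' offsets into `text`, and the returned `surface` always equals the text at
#' the span.
#'
#' @param text Section text (character scalar).
#' @param lexicon A `cellaudit_lexicon` used as the detection dictionary.
#' @param trigger_cfg A [trigger_config()].
#' @param doc_id,section Carried into the output for bookkeeping.
#' @param config A [match_config()] governing normalization.
#' @return data.frame: `doc_id`, `section`, `start`, `end`, `surface`,
#'   `channel` (`"dictionary"` or `"context"`).
#' @export
#' @examples
#' lex <- new_lexicon_from_entries(data.frame(
#'   accession = "CVCL_X001", primary_name = "HeLa", synonyms = "",
#'   problematic = TRUE, problem_category = "misidentified"))
#' detect_mentions("HeLa or HCN-A94 cells were grown in 24 well plates", lex)
detect_mentions <- function(text, lexicon, trigger_cfg = trigger_config(),
                            doc_id = NA_character_, section = NA_character_,
                            config = match_config()) {
  empty <- data.frame(doc_id = character(0), section = character(0),
                      start = integer(0), end = integer(0),
                      surface = character(0), channel = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  toks <- tokenize_text(text)
  if (nrow(toks) == 0L) return(empty)
  lex_norms <- unique(lexicon$names$norm)
  cand <- list()

  # dictionary channel: longest-first n-gram lookup on normalized forms
  i <- 1L
  while (i <= nrow(toks)) {
    hit_len <- 0L
    for (len in seq.int(min(trigger_cfg$max_ngram, nrow(toks) - i + 1L), 1L)) {
      j <- i + len - 1L
      surf <- substr(text, toks$start[i] + 1L, toks$end[j])
      if (normalize_name(surf, config) %in% lex_norms) { hit_len <- len; break }
    }
    if (hit_len > 0L) {
      j <- i + hit_len - 1L
      cand[[length(cand) + 1L]] <- data.frame(
        start = toks$start[i], end = toks$end[j],
        surface = substr(text, toks$start[i] + 1L, toks$end[j]),
        channel = "dictionary", stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }

  # context channel: walk left from each trigger over a coordinated list
  triggers <- trigger_cfg$enabled %||% trigger_cfg$triggers
  trigger_words <- unique(unlist(strsplit(tolower(triggers), "\\s+")))
  for (tr in triggers) {
    pat <- paste0("\\b", gsub(" ", "\\\\s+", tr), "\\b")
    m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (pos in as.integer(m)) {
      idx <- which(toks$end <= pos - 1L)     # tokens fully before the trigger
      if (!length(idx)) next
      k <- max(idx)
      scanned <- 0L
      while (k >= 1L && scanned < trigger_cfg$window) {
        tok <- toks$surface[k]
        low <- tolower(tok)
        if (low %in% trigger_words) break
        if (is_name_like(tok)) {
          cand[[length(cand) + 1L]] <- data.frame(
            start = toks$start[k], end = toks$end[k], surface = tok,
            channel = paste0("context:", tr), stringsAsFactors = FALSE)
          # continue only across coordination (or/and/comma in the gap)
          if (k == 1L) break
          gap <- substr(text, toks$end[k - 1L] + 1L, toks$start[k])
          prev <- tolower(toks$surface[k - 1L])
          if (!(prev %in% c("or", "and") || grepl(",", gap))) break
        } else if (!(low %in% c("or", "and"))) {
          break
        }
        k <- k - 1L
        scanned <- scanned + 1L
      }
    }
  }

  if (!length(cand)) return(empty)
  all_c <- do.call(rbind, cand)
  # leftmost-longest, dictionary preferred on equal spans
  all_c <- all_c[order(all_c$start, -all_c$end,
                       all_c$channel != "dictionary"), , drop = FALSE]
  keep <- logical(nrow(all_c))
  cur_end <- -1L
  for (r in seq_len(nrow(all_c))) {
    if (all_c$start[r] >= cur_end) {
      keep[r] <- TRUE
      cur_end <- all_c$end[r]
    }
  }
  out <- all_c[keep, , drop = FALSE]
  out$channel <- sub("^context:.*$", "context", out$channel)
  out <- data.frame(doc_id = doc_id, section = section,
                    start = out$start, end = out$end, surface = out$surface,
                    channel = out$channel, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect mentions across a whole corpus
#'
#' Scopes each document to its methods-like sections and runs
#' [detect_mentions()] on each, keeping per-section spans.
#'
#' @param corpus A `cellaudit_corpus`.
#' @param lexicon A `cellaudit_lexicon`.
#' @param trigger_cfg A [trigger_config()].
#' @param config A [match_config()].
#' @param labels Methods-section label substrings (see
#'   [extract_methods_section()]).
#' @return data.frame of mentions (`doc_id`, `section`, `start`, `end`,
#'   `surface`, `channel`).
#' @export
detect_corpus_mentions <- function(corpus, lexicon,
                                   trigger_cfg = trigger_config(),
                                   config = match_config(),
                                   labels = c("method", "materials")) {
  out <- lapply(corpus$docs$doc_id, function(id) {
    secs <- methods_sections(corpus, id, labels)
    if (!length(secs)) return(NULL)
    parts <- lapply(names(secs), function(lab)
      detect_mentions(secs[[lab]], lexicon, trigger_cfg,
                      doc_id = id, section = lab, config = config))
    do.call(rbind, parts)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(doc_id = character(0), section = character(0),
                      start = integer(0), end = integer(0),
                      surface = character(0), channel = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Precision, recall and F1 of predicted mentions against gold
#'
#' Matches predicted to gold mentions greedily within each document section.
#' In `"overlap"` mode (default) any character overlap counts; `"exact"`
#' requires identical spans. True positives are predicted mentions matching
#' an as-yet-unmatched gold mention; the remainder are false positives, and
#' unmatched gold mentions are false negatives. Precision with zero
#' predictions and recall with zero gold are defined as 0 (not NaN) so that
#' aggregation never propagates undefined values.
#'
#' @param gold,predicted data.frames with `doc_id`, `section`, `start`, `end`.
#' @param match_mode `"overlap"` or `"exact"`.
#' @return An object of class `cellaudit_eval`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluate_ner <- function(gold, predicted, match_mode = c("overlap", "exact")) {
  match_mode <- match.arg(match_mode)
  gold <- as.data.frame(gold); predicted <- as.data.frame(predicted)
  tp <- 0L
  used <- rep(FALSE, nrow(gold))
  if (nrow(predicted)) {
    gkey <- paste(gold$doc_id, gold$section)
    pkey <- paste(predicted$doc_id, predicted$section)
    for (i in seq_len(nrow(predicted))) {
      js <- which(!used & gkey == pkey[i])
      if (!length(js)) next
      hit <- if (match_mode == "exact") {
        js[gold$start[js] == predicted$start[i] &
           gold$end[js] == predicted$end[i]]
      } else {
        js[gold$start[js] < predicted$end[i] &
           gold$end[js] > predicted$start[i]]
      }
      if (length(hit)) {
        used[hit[1]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(predicted) - tp
  fn <- nrow(gold) - tp
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, match_mode = match_mode),
            class = "cellaudit_eval")
}

#' @export
print.cellaudit_eval <- function(x, ...) {
  cat(sprintf("NER evaluation (%s spans): tp=%d fp=%d fn=%d | P=%.3f R=%.3f F1=%.3f\n",
              x$match_mode, x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

# Context-channel-only recognizer restricted to one enabled trigger set;
# used for trigger tuning.
detect_with_triggers <- function(corpus, lexicon, trigger_cfg, enabled,
                                 config, doc_ids) {
  cfg <- trigger_cfg
  cfg$enabled <- enabled
  sub <- corpus
  keep <- corpus$docs$doc_id %in% doc_ids
  sub$docs <- corpus$docs[keep, , drop = FALSE]
  detect_corpus_mentions(sub, lexicon, cfg, config)
}

#' Repeated train/test evaluation of the recognizer
#'
#' Splits the gold-annotated documents into train and test fractions
#' `n_repeats` times (repeat `r` reseeds the generator with `seed + r`, so
#' each repeat is independently reproducible). On each train part the context
#' channel is tuned: a trigger is kept when its train precision reaches the
#' cutoff chosen (from `precision_grid`) to maximize train F1 of the combined
#' recognizer; the dictionary channel is fixed. Metrics are computed on the
#' held-out part.
#'
#' @param corpus A `cellaudit_corpus` whose `gold` annotations are non-empty.
#' @param lexicon Detection dictionary.
#' @param n_repeats Number of random splits (default 10).
#' @param train_fraction Fraction of annotated documents used for tuning
#'   (default 0.9).
#' @param seed Integer base seed.
#' @param trigger_cfg A [trigger_config()].
#' @param match_mode Span matching mode for [evaluate_ner()].
#' @param precision_grid Candidate per-trigger precision cutoffs.
#' @param config A [match_config()].
#' @return list with `per_repeat` (data.frame of P/R/F1 per repeat) and
#'   `summary` (data.frame: metric, mean, sd).
#' @export
repeated_split_eval <- function(corpus, lexicon, n_repeats = 10L,
                                train_fraction = 0.9, seed = 1L,
                                trigger_cfg = trigger_config(),
                                match_mode = "overlap",
                                precision_grid = c(0, 0.5, 0.8),
                                config = match_config()) {
  stopifnot(n_repeats >= 1L, train_fraction > 0, train_fraction < 1)
  if (is.null(corpus$gold) || nrow(corpus$gold) == 0L)
    stop("corpus has no gold annotations", call. = FALSE)
  # the split pool is the annotated documents (those carrying gold mentions)
  pool <- unique(corpus$gold$doc_id)
  if (length(pool) < 10L)
    stop("need at least 10 annotated documents for repeated splits",
         call. = FALSE)

  one_repeat <- function(r) {
    set.seed(seed + r)
    n_train <- max(1L, round(train_fraction * length(pool)))
    train_ids <- sample(pool, n_train)
    test_ids <- setdiff(pool, train_ids)
    gold_of <- function(ids)
      corpus$gold[corpus$gold$doc_id %in% ids, , drop = FALSE]

    # per-trigger train precision of the context channel alone
    trig_prec <- vapply(trigger_cfg$triggers, function(tr) {
      pred <- detect_with_triggers(corpus, empty_lexicon(config), trigger_cfg,
                                   tr, config, train_ids)
      ev <- evaluate_ner(gold_of(train_ids), pred, match_mode)
      ev$precision
    }, numeric(1))

    best <- NULL
    for (cut in precision_grid) {
      enabled <- trigger_cfg$triggers[trig_prec >= cut]
      cfg <- trigger_cfg; cfg$enabled <- enabled
      sub <- corpus
      sub$docs <- corpus$docs[corpus$docs$doc_id %in% train_ids, , drop = FALSE]
      pred <- detect_corpus_mentions(sub, lexicon, cfg, config)
      ev <- evaluate_ner(gold_of(train_ids), pred, match_mode)
      if (is.null(best) || ev$f1 > best$f1 + 1e-12)
        best <- list(f1 = ev$f1, enabled = enabled)
    }

    cfg <- trigger_cfg; cfg$enabled <- best$enabled
    sub <- corpus
    sub$docs <- corpus$docs[corpus$docs$doc_id %in% test_ids, , drop = FALSE]
    pred <- detect_corpus_mentions(sub, lexicon, cfg, config)
    ev <- evaluate_ner(gold_of(test_ids), pred, match_mode)
    c(precision = ev$precision, recall = ev$recall, f1 = ev$f1)
  }

  per <- t(vapply(seq_len(n_repeats), one_repeat, numeric(3)))
  per_repeat <- data.frame(repeat_id = seq_len(n_repeats), per)
  summary <- data.frame(
    metric = c("precision", "recall", "f1"),
    mean = colMeans(per),
    sd = apply(per, 2, stats::sd),
    row.names = NULL
  )
  if (n_repeats == 1L) summary$sd <- 0
  list(per_repeat = per_repeat, summary = summary)
}

# A lexicon with no names: disables the dictionary channel.
empty_lexicon <- function(config = match_config()) {
  structure(list(
    entries = data.frame(accession = character(0), primary_name = character(0),
                         synonyms = character(0), problematic = logical(0),
                         problem_category = character(0)),
    names = data.frame(accession = character(0), name = character(0),
                       problematic = logical(0), norm = character(0),
                       lower = character(0)),
    config = config), class = "cellaudit_lexicon")
}

#' Paper-level curator/algorithm agreement
#'
#' Cross-tabulates, for each paper, whether a curator and the algorithm found
#' any cell line, and reports the confusion counts plus the agreement
#' fraction (papers where both agree, divided by all papers).
#'
#' @param curator_labels,algorithm_labels Named logical vectors keyed by
#'   `doc_id`; the key sets must coincide.
#' @return An object of class `cellaudit_agreement`: `both_found`,
#'   `both_absent`, `only_algorithm`, `only_curator`, `total`,
#'   `agreement_fraction`.
#' @export
#' @examples
#' cur <- c(a = TRUE, b = FALSE); alg <- c(a = TRUE, b = TRUE)
#' paper_level_agreement(cur, alg)$agreement_fraction  # 0.5
paper_level_agreement <- function(curator_labels, algorithm_labels) {
  if (is.null(names(curator_labels)) || is.null(names(algorithm_labels)))
    stop("labels must be named by doc_id", call. = FALSE)
  miss_alg <- setdiff(names(curator_labels), names(algorithm_labels))
  miss_cur <- setdiff(names(algorithm_labels), names(curator_labels))
  if (length(miss_alg) || length(miss_cur))
    stop("doc_id mismatch; missing from algorithm: ",
         paste(utils::head(miss_alg, 5), collapse = ", "),
         "; missing from curator: ",
         paste(utils::head(miss_cur, 5), collapse = ", "), call. = FALSE)
  alg <- algorithm_labels[names(curator_labels)]
  cur <- curator_labels
  out <- list(
    both_found = sum(cur & alg),
    both_absent = sum(!cur & !alg),
    only_algorithm = sum(!cur & alg),
    only_curator = sum(cur & !alg),
    total = length(cur)
  )
  out$agreement_fraction <- (out$both_found + out$both_absent) / out$total
  structure(out, class = "cellaudit_agreement")
}

#' @export
print.cellaudit_agreement <- function(x, ...) {
  cat(sprintf(paste0("Curator vs algorithm agreement on %d papers\n",
                     "  both found: %d | both absent: %d | only algorithm: %d",
                     " | only curator: %d\n  agreement: %.2f%%\n"),
              x$total, x$both_found, x$both_absent, x$only_algorithm,
              x$only_curator, 100 * x$agreement_fraction))
  invisible(x)
}
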