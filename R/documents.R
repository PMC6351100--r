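# Document corpus container and JSONL input/output.

#' Construct a document corpus
#'
#' A corpus bundles per-document metadata, section texts and optional gold
#' (curated) mention annotations. Spans are 0-based, half-open character
#' offsets into the named section's text.
#'
#' @param docs data.frame with columns `doc_id` (unique), `journal`, `year`
#'   (integer calendar year), `minable` (logical; license permits mining).
#' @param sections Named list keyed by `doc_id`; each element a named
#'   character vector of section label -> text.
#' @param gold Optional data.frame of curated mentions: `doc_id`, `section`,
#'   `start`, `end`, `surface`.
#' @return An object of class `cellaudit_corpus`.
#' @export
new_corpus <- function(docs, sections, gold = NULL) {
  stopifnot(is.data.frame(docs),
            all(c("doc_id", "journal", "year", "minable") %in% names(docs)))
  docs$doc_id <- as.character(docs$doc_id)
  if (anyDuplicated(docs$doc_id))
    stop("duplicate doc_id in corpus", call. = FALSE)
  if (!all(docs$doc_id %in% names(sections)))
    stop("every doc_id needs a sections entry", call. = FALSE)
  if (!is.null(gold)) {
    stopifnot(all(c("doc_id", "section", "start", "end") %in% names(gold)))
    if (is.null(gold$surface)) {
      gold$surface <- vapply(seq_len(nrow(gold)), function(i) {
        txt <- sections[[gold$doc_id[i]]][[gold$section[i]]]
        substr(txt, gold$start[i] + 1L, gold$end[i])
      }, character(1))
    }
  }
  structure(list(docs = docs, sections = sections[docs$doc_id], gold = gold),
            class = "cellaudit_corpus")
}

#' @export
print.cellaudit_corpus <- function(x, ...) {
  cat("Document corpus: ", nrow(x$docs), " documents, ",
      length(unique(x$docs$journal)), " journals, years ",
      min(x$docs$year), "-", max(x$docs$year), sep = "")
  if (!is.null(x$gold)) cat(", ", nrow(x$gold), " gold mentions", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a corpus from JSON Lines
#'
#' One JSON object per line with keys `doc_id`, `journal`, `year`, `minable`,
#' `sections` (label -> text) and optional `gold_mentions`
#' (`[{section, start, end}]`, 0-based half-open; `surface` recomputed from
#' the section text).
#'
#' @param path Path to the JSONL file.
#' @return A `cellaudit_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  docs <- data.frame(
    doc_id = vapply(recs, function(r) as.character(r$doc_id), character(1)),
    journal = vapply(recs, function(r) as.character(r$journal), character(1)),
    year = vapply(recs, function(r) as.integer(r$year), integer(1)),
    minable = vapply(recs, function(r) isTRUE(r$minable) || identical(r$minable, 1L),
                     logical(1)),
    stringsAsFactors = FALSE
  )
  sections <- lapply(recs, function(r) unlist(r$sections))
  names(sections) <- docs$doc_id
  gold_list <- lapply(recs, function(r) {
    g <- r$gold_mentions
    if (is.null(g) || (is.data.frame(g) && nrow(g) == 0L)) return(NULL)
    g <- as.data.frame(g, stringsAsFactors = FALSE)
    g$doc_id <- as.character(r$doc_id)
    g
  })
  gold_list <- gold_list[!vapply(gold_list, is.null, logical(1))]
  gold <- if (length(gold_list)) {
    g <- do.call(rbind, gold_list)
    g$start <- as.integer(g$start); g$end <- as.integer(g$end)
    g[, intersect(c("doc_id", "section", "start", "end", "surface"), names(g))]
  } else NULL
  new_corpus(docs, sections, gold)
}

#' Write a corpus to JSON Lines
#'
#' @param corpus A `cellaudit_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus$docs))) {
    d <- corpus$docs[i, ]
    rec <- list(doc_id = d$doc_id, journal = d$journal, year = d$year,
                minable = d$minable,
                sections = as.list(corpus$sections[[d$doc_id]]))
    if (!is.null(corpus$gold)) {
      g <- corpus$gold[corpus$gold$doc_id == d$doc_id, , drop = FALSE]
      if (nrow(g))
        rec$gold_mentions <- lapply(seq_len(nrow(g)), function(j)
          list(section = g$section[j], start = g$start[j], end = g$end[j],
               surface = g$surface[j]))
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Extract the methods section of a document
#'
#' Concatenates the text of every section whose label matches the configured
#' methods-label patterns (by default any label containing "method" or
#' "materials", case-insensitively). Returns `NA` when no such section
#' exists; such documents contribute zero mentions downstream.
#'
#' @param sections Named character vector of section label -> text (one
#'   document's sections), or a `cellaudit_corpus` plus `doc_id`.
#' @param doc_id When `sections` is a corpus, the document to extract.
#' @param labels Character vector of label substrings identifying
#'   methods-like sections.
#' @return The concatenated methods text, or `NA_character_` if absent.
#' @export
extract_methods_section <- function(sections, doc_id = NULL,
                                    labels = c("method", "materials")) {
  if (inherits(sections, "cellaudit_corpus")) {
    stopifnot(!is.null(doc_id))
    sections <- sections$sections[[as.character(doc_id)]]
  }
  hit <- methods_like(names(sections), labels)
  if (!any(hit)) return(NA_character_)
  paste(sections[hit], collapse = "\n")
}

methods_like <- function(labels_present, labels = c("method", "materials")) {
  if (is.null(labels_present)) return(logical(0))
  Reduce(`|`, lapply(labels, function(l)
    grepl(l, labels_present, ignore.case = TRUE)))
}

# Named list of the methods-like sections of one document (label -> text),
# preserving per-section offsets for span bookkeeping.
methods_sections <- function(corpus, doc_id,
                             labels = c("method", "materials")) {
  s <- corpus$sections[[as.character(doc_id)]]
  keep <- methods_like(names(s), labels)
  as.list(s[keep])
}

#' Systematic sample of an ordered collection
#'
#' Returns the records at 1-based positions `interval`, `2*interval`, ...;
#' the deterministic every-nth sampling used when drawing a curation set from
#' a publication-date-ordered list.
#'
#' @param records A vector or data.frame ordered by date of publication.
#' @param interval Positive integer sampling interval (default 65).
#' @return The sampled subset (same type as `records`).
#' @export
#' @examples
#' length(systematic_sample(seq_len(130), 65))  # 2
systematic_sample <- function(records, interval = 65L) {
  if (!is.numeric(interval) || length(interval) != 1L || interval < 1)
    stop("`interval` must be a positive integer", call. = FALSE)
  interval <- as.integer(interval)
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  idx <- seq.int(interval, n, by = interval)
  if (n < interval) idx <- integer(0)
  if (is.data.frame(records)) records[idx, , drop = FALSE] else records[idx]
}

# PMID-like document identifiers anchor the paper-level RRID analysis.
is_pmid_like <- function(doc_id) grepl("^(PMID:)?[0-9]+$", doc_id)
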