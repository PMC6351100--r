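# RRID extraction, resolution against a local registry snapshot, and the
# filtered analysis set.

# Break characters ending the raw RRID capture. Closing brackets are
# included because RRIDs typically sit inside parentheses.
default_break_class <- "[,.;[:space:])\\]]"

#' Extract RRID tokens from text
#'
#' Finds every occurrence of the literal token `RRID` and captures the text
#' that follows up to the first break character (comma, period, semicolon,
#' whitespace, closing bracket). A leading colon and one optional space after
#' it are tolerated. From the capture an accession of shape
#' `PREFIX_IDENTIFIER` is parsed; syntax deviations that still leave the
#' identifier parseable (an extra underscore, a missing colon, a stray space)
#' are recorded but the record is kept.
#'
#' @param text Character scalar to scan.
#' @param doc_id Carried into the output.
#' @param break_class Regex character class of break characters.
#' @return data.frame of RRID mentions: `doc_id`, `raw` (text after "RRID",
#'   break exclusive), `identifier` (canonical accession or `NA`),
#'   `authority_prefix`, `syntax_ok`, `curator_supplied` (always `FALSE`
#'   here), `status` (`NA` until resolved).
#' @export
#' @examples
#' extract_rrids("SH-SY5Y cells (RRID:CVCL_0019), cultured ...")$identifier
extract_rrids <- function(text, doc_id = NA_character_,
                          break_class = default_break_class) {
  empty <- data.frame(doc_id = character(0), raw = character(0),
                      identifier = character(0),
                      authority_prefix = character(0),
                      syntax_ok = logical(0), curator_supplied = logical(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  occ <- gregexpr("RRID", text, fixed = TRUE)[[1]]
  if (occ[1] == -1L) return(empty)
  cap_pat <- paste0("^(?::[ ]?)?[^", substr(break_class, 2, nchar(break_class) - 1),
                    "]*")
  rows <- lapply(as.integer(occ), function(pos) {
    rest <- substring(text, pos + 4L)
    raw <- regmatches(rest, regexpr(cap_pat, rest, perl = TRUE))
    if (!length(raw)) raw <- ""
    idm <- regexpr("([A-Za-z]+)_+([A-Za-z0-9]+)", raw, perl = TRUE)
    if (idm[1] == -1L) {
      identifier <- NA_character_; prefix <- NA_character_; ok <- FALSE
    } else {
      tok <- regmatches(raw, idm)
      parts <- regmatches(tok, regexec("([A-Za-z]+)_+([A-Za-z0-9]+)", tok))[[1]]
      prefix <- toupper(parts[2])
      identifier <- paste0(prefix, "_", parts[3])
      ok <- identical(raw, paste0(":", identifier))
    }
    data.frame(doc_id = doc_id, raw = raw, identifier = identifier,
               authority_prefix = prefix, syntax_ok = ok,
               curator_supplied = FALSE, status = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # drop self-hits on the bare word RRID with nothing parseable and no raw
  out[nzchar(out$raw) | !is.na(out$identifier), , drop = FALSE]
}

#' Extract RRIDs across a corpus
#'
#' Scans the full text (all sections) of every document.
#'
#' @param corpus A `cellaudit_corpus`.
#' @param break_class See [extract_rrids()].
#' @return data.frame as in [extract_rrids()].
#' @export
extract_corpus_rrids <- function(corpus, break_class = default_break_class) {
  out <- lapply(corpus$docs$doc_id, function(id) {
    txt <- paste(corpus$sections[[id]], collapse = "\n")
    extract_rrids(txt, doc_id = id, break_class = break_class)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- extract_rrids("", doc_id = NA_character_)
  rownames(res) <- NULL
  res
}

#' Load a registry snapshot
#'
#' Reads a tab-separated local snapshot of the RRID registry: columns
#' `accession`, `exists` (0/1), `problematic` (0/1), `warning_text`.
#' A problematic accession must exist.
#'
#' @param path Path to the TSV file.
#' @return data.frame of class `cellaudit_registry`.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), fileEncoding = "UTF-8")
  required <- c("accession", "exists", "problematic", "warning_text")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("registry is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(raw$accession))
    stop("duplicate accession in registry", call. = FALSE)
  out <- data.frame(accession = raw$accession,
                    exists = raw$exists %in% c("1", "TRUE", "true"),
                    problematic = raw$problematic %in% c("1", "TRUE", "true"),
                    warning_text = raw$warning_text,
                    stringsAsFactors = FALSE)
  if (any(out$problematic & !out$exists))
    stop("registry marks a non-existent accession problematic", call. = FALSE)
  class(out) <- c("cellaudit_registry", "data.frame")
  out
}

#' Write a registry snapshot
#' @param registry A registry data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  r <- as.data.frame(registry)
  r$exists <- as.integer(r$exists)
  r$problematic <- as.integer(r$problematic)
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolve RRID mentions against the registry
#'
#' Pure function of (identifier, registry): `unresolved` when no identifier
#' was parseable or the accession is absent from the registry; `verified`
#' when present with clean syntax; `syntax_error_recoverable` when present
#' but the raw capture deviated from canonical `:ACCESSION` syntax (such
#' records stay in the analysis). Mentions flagged `curator_supplied` get
#' status `curator_supplied` and are excluded from researcher-usage counts
#' downstream.
#'
#' @param mentions data.frame from [extract_rrids()].
#' @param registry A registry data.frame (see [load_registry()]).
#' @return `mentions` with `status` and `problematic` filled in.
#' @export
resolve_rrid <- function(mentions, registry) {
  m <- as.data.frame(mentions)
  idx <- match(m$identifier, registry$accession)
  present <- !is.na(idx) & registry$exists[pmax(idx, 1L)]
  present[is.na(idx)] <- FALSE
  m$status <- ifelse(!present, "unresolved",
                     ifelse(m$syntax_ok, "verified", "syntax_error_recoverable"))
  m$status[m$curator_supplied] <- "curator_supplied"
  m$problematic <- ifelse(present, registry$problematic[idx], FALSE)
  m$problematic[is.na(m$problematic)] <- FALSE
  m
}

#' Build the filtered RRID analysis set
#'
#' Keeps resolved mentions carrying the cell-line authority prefix, drops
#' curator-supplied records, and applies the PMID filter: mentions in
#' documents without a PMID-like identifier are dropped from the mention
#' count, and such documents are excluded from the paper-level set. All drop
#' counts are logged so the trimming is auditable.
#'
#' @param mentions Resolved mentions (see [resolve_rrid()]).
#' @param docs data.frame of corpus documents (needs `doc_id`).
#' @param authority Authority prefix to keep (default `"CVCL"`, cell lines).
#' @return list with `mentions` (the analysis mentions), `papers` (data.frame
#'   of distinct papers with >= 1 analysis mention and a PMID-like id) and
#'   `counts` (named list of sizes at each trimming step).
#' @export
build_rrid_analysis_set <- function(mentions, docs, authority = "CVCL") {
  m <- as.data.frame(mentions)
  counts <- list(mentions_initial = nrow(m))
  keep_auth <- !is.na(m$authority_prefix) & m$authority_prefix == authority
  counts$dropped_other_authority <- sum(!keep_auth)
  m <- m[keep_auth, , drop = FALSE]
  keep_res <- !is.na(m$status) & m$status %in% c("verified",
                                                 "syntax_error_recoverable")
  counts$dropped_curator_supplied <- sum(m$status == "curator_supplied",
                                         na.rm = TRUE)
  counts$dropped_unresolved <- sum(m$status == "unresolved", na.rm = TRUE)
  m <- m[keep_res, , drop = FALSE]
  counts$mentions_resolved <- nrow(m)
  counts$papers_resolved <- length(unique(m$doc_id))
  pmid_ok <- is_pmid_like(m$doc_id)
  counts$dropped_no_pmid_mentions <- sum(!pmid_ok)
  m <- m[pmid_ok, , drop = FALSE]
  counts$mentions_final <- nrow(m)
  papers <- unique(m$doc_id)
  counts$papers_final <- length(papers)
  pdf <- docs[docs$doc_id %in% papers, , drop = FALSE]
  list(mentions = m, papers = pdf, counts = counts)
}

#' Problematic rate among RRID-identified cell lines
#'
#' Counts analysis mentions whose identifier maps to a problematic registry
#' entry. With an empty analysis set the fraction is `NA` (undefined), not
#' an error.
#'
#' @param mentions Analysis mentions (see [build_rrid_analysis_set()]).
#' @param registry A registry data.frame.
#' @return list: `problematic` (count), `total`, `fraction`.
#' @export
#' @examples
#' # 50 problematic of 1,502 ~ 3.3%
rrid_problematic_rate <- function(mentions, registry) {
  m <- as.data.frame(mentions)
  idx <- match(m$identifier, registry$accession)
  prob <- !is.na(idx) & registry$problematic[pmax(idx, 1L)]
  prob[is.na(idx)] <- FALSE
  total <- nrow(m)
  list(problematic = sum(prob), total = total,
       fraction = if (total > 0L) sum(prob) / total else NA_real_)
}
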