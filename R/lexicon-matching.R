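# Lexicon loading and the three name-matching criteria (strict, loose,
# weighted edit distance).

#' Matching configuration
#'
#' Collects the tunable parameters of the name matcher. The defaults encode
#' the weighted edit-distance convention used throughout the package:
#' insertion or deletion of a "special" (non-alphanumeric) character is free,
#' any other insertion/deletion costs 1, a substitution costs 2 (a deletion
#' plus an addition), and a candidate name matches when its distance to a
#' lexicon name is strictly below 1 -- i.e. exactly 0 under integer weights.
#'
#' @param zero_weight_chars Characters whose insertion or deletion costs
#'   nothing. `NULL` (the default) means every character that is not a letter
#'   or digit.
#' @param indel_weight Cost of inserting or deleting a non-zero-weight
#'   character. Must be positive.
#' @param substitution_weight Cost of substituting one character for another.
#'   Must be positive. The default 2 keeps the distance a metric
#'   (substitution never cheaper than delete+insert at default weights).
#' @param threshold A mention matches a lexicon name under the edit criterion
#'   when their distance is strictly less than `threshold`. Must be positive.
#' @param case_sensitive Compare names case-sensitively? Default `FALSE`:
#'   "HeLa" and "HELA" are the same name.
#' @param loose_two_way If `TRUE`, the loose criterion also fires when the
#'   normalized mention is a prefix of a lexicon name (the wildcard reading);
#'   by default only the lexicon-name-is-prefix-of-mention direction is used,
#'   which is the direction the worked example
#'   ("CF-1 mouse embryonic fibroblasts" matches "CF-1") requires.
#' @return An object of class `cellaudit_match_config`.
#' @export
#' @examples
#' cfg <- match_config()
#' weighted_edit_distance("CF1", "CF-1", cfg)  # 0: hyphen is free
match_config <- function(zero_weight_chars = NULL,
                         indel_weight = 1,
                         substitution_weight = 2,
                         threshold = 1,
                         case_sensitive = FALSE,
                         loose_two_way = FALSE) {
  stopifnot(indel_weight > 0, substitution_weight > 0, threshold > 0,
            is.logical(case_sensitive), length(case_sensitive) == 1L,
            is.logical(loose_two_way), length(loose_two_way) == 1L)
  if (!is.null(zero_weight_chars)) {
    zero_weight_chars <- unique(as.character(zero_weight_chars))
    if (any(nchar(zero_weight_chars) != 1L))
      stop("`zero_weight_chars` must be single characters", call. = FALSE)
  }
  structure(
    list(zero_weight_chars = zero_weight_chars,
         indel_weight = indel_weight,
         substitution_weight = substitution_weight,
         threshold = threshold,
         case_sensitive = case_sensitive,
         loose_two_way = loose_two_way),
    class = "cellaudit_match_config"
  )
}

#' @export
print.cellaudit_match_config <- function(x, ...) {
  zw <- if (is.null(x$zero_weight_chars)) "all non-alphanumeric"
        else paste(x$zero_weight_chars, collapse = " ")
  cat("Match configuration\n",
      "  zero-weight characters: ", zw, "\n",
      "  indel weight: ", x$indel_weight,
      " | substitution weight: ", x$substitution_weight,
      " | threshold: ", x$threshold, "\n",
      "  case sensitive: ", x$case_sensitive, "\n", sep = "")
  invisible(x)
}

# TRUE for characters that cost nothing to insert or delete.
is_zero_weight <- function(chars, config) {
  if (is.null(config$zero_weight_chars)) {
    !grepl("[[:alnum:]]", chars)
  } else {
    chars %in% config$zero_weight_chars
  }
}

#' Normalize a cell-line name
#'
#' Applies Unicode NFC normalization, removes all zero-weight (special)
#' characters and, unless the configuration is case-sensitive, folds case.
#' Two names have weighted edit distance 0 exactly when their normalized
#' forms are equal, so "EF 1", "EF-1" and "ef1" all normalize identically.
#' The function is idempotent.
#'
#' @param name Character vector of names (empty strings allowed).
#' @param config A [match_config()].
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_name(c("EF 1", "EF-1", "HELA"))
normalize_name <- function(name, config = match_config()) {
  x <- stringi::stri_trans_nfc(as.character(name))
  if (is.null(config$zero_weight_chars)) {
    x <- gsub("[^[:alnum:]]+", "", x)
  } else if (length(config$zero_weight_chars)) {
    cls <- paste0("[", gsub("([][\\^-])", "\\\\\\1",
                            paste(config$zero_weight_chars, collapse = "")),
                  "]")
    x <- gsub(cls, "", x)
  }
  if (!config$case_sensitive) x <- stringi::stri_trans_tolower(x)
  x
}

#' Weighted edit distance between two names
#'
#' Minimum total weight over edit scripts transforming `a` into `b`, where
#' inserting or deleting a zero-weight character is free, other insertions
#' and deletions cost `indel_weight`, and substitutions cost
#' `substitution_weight`. Case is folded first unless the configuration is
#' case-sensitive. The distance is symmetric and equals 0 exactly when
#' the two normalized names are equal. With the default weights it is a
#' metric (substitution weight does not exceed twice the indel weight).
#'
#' @param a,b Character scalars.
#' @param config A [match_config()].
#' @return A single non-negative number.
#' @export
#' @examples
#' weighted_edit_distance("CF1", "CF-1")    # 0
#' weighted_edit_distance("CF-1", "CF-10")  # 1
#' weighted_edit_distance("abc", "abd")     # 2
weighted_edit_distance <- function(a, b, config = match_config()) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  a <- stringi::stri_trans_nfc(as.character(a))
  b <- stringi::stri_trans_nfc(as.character(b))
  if (!config$case_sensitive) {
    a <- stringi::stri_trans_tolower(a)
    b <- stringi::stri_trans_tolower(b)
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  del_a <- if (n) ifelse(is_zero_weight(av, config), 0, config$indel_weight) else numeric(0)
  ins_b <- if (m) ifelse(is_zero_weight(bv, config), 0, config$indel_weight) else numeric(0)
  # dp over prefixes; prev[j+1] = d(a[1..i-1], b[1..j])
  prev <- c(0, cumsum(ins_b))
  if (n == 0L) return(prev[m + 1L])
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- prev[1L] + del_a[i]
    if (m) {
      for (j in seq_len(m)) {
        sub <- if (av[i] == bv[j]) 0 else config$substitution_weight
        cur[j + 1L] <- min(prev[j] + sub,
                           prev[j + 1L] + del_a[i],
                           cur[j] + ins_b[j])
      }
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Load a problematic-cell-line lexicon
#'
#' Reads a tab-separated lexicon with header columns `accession`,
#' `primary_name`, `synonyms` (pipe-separated, may be empty), `problematic`
#' (0/1) and `problem_category` (one of `misidentified`,
#' `partially-contaminated`, `other`, or empty). All names and synonyms are
#' indexed for lookup; synonyms are de-duplicated after normalization.
#'
#' @param path Path to the TSV file.
#' @param config A [match_config()] governing normalization of the index.
#' @return An object of class `cellaudit_lexicon`: a list with `entries`
#'   (one row per accession) and `names` (one row per indexed name, with
#'   normalized and case-folded forms).
#' @seealso [write_lexicon()], [lexicon_subset()]
#' @export
load_lexicon <- function(path, config = match_config()) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), fileEncoding = "UTF-8")
  required <- c("accession", "primary_name", "synonyms", "problematic",
                "problem_category")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("lexicon is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!nzchar(trimws(raw$accession)))
  if (length(bad))
    stop("lexicon line ", bad[1] + 1L, ": empty accession", call. = FALSE)
  dup <- which(duplicated(raw$accession))
  if (length(dup))
    stop("lexicon line ", dup[1] + 1L, ": duplicate accession '",
         raw$accession[dup[1]], "'", call. = FALSE)
  bad <- which(!nzchar(trimws(raw$primary_name)))
  if (length(bad))
    stop("lexicon line ", bad[1] + 1L, ": empty primary_name", call. = FALSE)
  ok_cat <- c("", "misidentified", "partially-contaminated", "other")
  bad <- which(!(raw$problem_category %in% ok_cat))
  if (length(bad))
    stop("lexicon line ", bad[1] + 1L, ": unknown problem_category '",
         raw$problem_category[bad[1]], "'", call. = FALSE)
  entries <- data.frame(
    accession = raw$accession,
    primary_name = raw$primary_name,
    synonyms = raw$synonyms,
    problematic = raw$problematic %in% c("1", "TRUE", "true"),
    problem_category = raw$problem_category,
    stringsAsFactors = FALSE
  )
  new_lexicon(entries, config)
}

# Build the indexed lexicon object from an entries data frame.
new_lexicon <- function(entries, config = match_config()) {
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    syn <- strsplit(entries$synonyms[i], "|", fixed = TRUE)[[1]]
    syn <- syn[nzchar(syn)]
    # drop synonyms duplicated after normalization (keep first occurrence)
    if (length(syn)) syn <- syn[!duplicated(normalize_name(syn, config))]
    nm <- c(entries$primary_name[i], syn)
    data.frame(accession = entries$accession[i], name = nm,
               problematic = entries$problematic[i], stringsAsFactors = FALSE)
  })
  name_table <- do.call(rbind, rows)
  name_table$norm <- normalize_name(name_table$name, config)
  name_table$lower <- stringi::stri_trans_tolower(
    stringi::stri_trans_nfc(name_table$name))
  structure(list(entries = entries, names = name_table, config = config),
            class = "cellaudit_lexicon")
}

#' @export
print.cellaudit_lexicon <- function(x, ...) {
  cat("Problematic cell-line lexicon\n",
      "  entries: ", nrow(x$entries),
      " (", sum(x$entries$problematic), " problematic)\n",
      "  indexed names and synonyms: ", nrow(x$names), "\n", sep = "")
  invisible(x)
}

#' Write a lexicon back to its TSV form
#'
#' @param lexicon A `cellaudit_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  e <- lexicon$entries
  e$problematic <- as.integer(e$problematic)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset a lexicon by problematic status
#'
#' The detection dictionary typically uses every known name while the
#' problematic-use audit matches against flagged entries only.
#'
#' @param lexicon A `cellaudit_lexicon`.
#' @param problematic Keep problematic (`TRUE`, default) or clean entries.
#' @return A `cellaudit_lexicon` restricted to the requested entries.
#' @export
lexicon_subset <- function(lexicon, problematic = TRUE) {
  keep <- lexicon$entries$problematic == problematic
  new_lexicon(lexicon$entries[keep, , drop = FALSE], lexicon$config)
}

match_criteria <- c("strict", "loose", "edit")

# Vectorized matching of mention texts against a lexicon under one
# criterion. Returns a data.frame with matched_accession and distance.
# Ties (several matching entries) resolve to the lexicographically smallest
# accession, deterministically.
match_texts <- function(texts, lexicon, criterion, config) {
  criterion <- match.arg(criterion, match_criteria)
  nt <- lexicon$names
  n <- length(texts)
  acc <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  if (n == 0L)
    return(data.frame(matched_accession = acc, distance = dist,
                      stringsAsFactors = FALSE))
  if (criterion == "strict") {
    key <- stringi::stri_trans_tolower(stringi::stri_trans_nfc(texts))
    tab <- nt$lower
    for (i in seq_len(n)) {
      hit <- nt$accession[tab == key[i]]
      if (length(hit)) acc[i] <- min(hit)
    }
  } else if (criterion == "loose") {
    mn <- normalize_name(texts, config)
    ln <- nt$norm
    for (i in seq_len(n)) {
      hit <- startsWith(mn[i], ln)
      if (config$loose_two_way) hit <- hit | startsWith(ln, mn[i])
      hit <- hit & nzchar(ln)
      if (any(hit)) acc[i] <- min(nt$accession[hit])
    }
  } else { # edit
    fast <- config$threshold <= min(config$indel_weight,
                                    config$substitution_weight)
    mn <- normalize_name(texts, config)
    if (fast) {
      # distance < threshold can only mean distance 0, i.e. equal normals
      for (i in seq_len(n)) {
        hit <- nt$accession[nt$norm == mn[i]]
        if (length(hit)) { acc[i] <- min(hit); dist[i] <- 0 }
      }
    } else {
      for (i in seq_len(n)) {
        d <- vapply(nt$name, weighted_edit_distance, numeric(1),
                    b = texts[i], config = config)
        ok <- d < config$threshold
        if (any(ok)) {
          best <- min(nt$accession[ok])
          acc[i] <- best
          dist[i] <- min(d[ok & nt$accession == best])
        }
      }
    }
  }
  data.frame(matched_accession = acc, distance = dist, stringsAsFactors = FALSE)
}

#' Match one mention against the lexicon
#'
#' Tests a detected name against every lexicon name and synonym under one of
#' the three criteria:
#' \describe{
#'   \item{strict}{exact, case-insensitive equality; special characters are
#'     significant ("CF1" does not strictly match "CF-1").}
#'   \item{loose}{the normalized lexicon name is a prefix of the normalized
#'     mention, so "CF-1 mouse embryonic fibroblasts" matches "CF-1".}
#'   \item{edit}{weighted edit distance below the configured threshold;
#'     with default weights this means the names agree on letters and digits
#'     once special characters are skipped ("CF1" matches "CF-1" but
#'     "CAF-1" and "CF-10" do not).}
#' }
#' When several entries match, the lexicographically smallest accession is
#' reported.
#'
#' @param mention_text The detected name (character scalar).
#' @param lexicon A `cellaudit_lexicon` (non-empty).
#' @param criterion `"strict"`, `"loose"` or `"edit"`.
#' @param config A [match_config()].
#' @return A one-row data.frame: `mention_text`, `criterion`,
#'   `matched_accession` (`NA` if no entry satisfied the criterion) and
#'   `distance` (edit criterion only; `NA` otherwise).
#' @export
#' @examples
#' lex <- new_lexicon_from_entries(data.frame(
#'   accession = "CVCL_TEST", primary_name = "CF-1", synonyms = "",
#'   problematic = TRUE, problem_category = "misidentified"))
#' match_mention("CF1", lex, "edit")$matched_accession
match_mention <- function(mention_text, lexicon,
                          criterion = c("edit", "strict", "loose"),
                          config = match_config()) {
  criterion <- match.arg(criterion, c(match_criteria, "edit"))
  stopifnot(inherits(lexicon, "cellaudit_lexicon"))
  if (nrow(lexicon$names) == 0L) stop("lexicon is empty", call. = FALSE)
  res <- match_texts(as.character(mention_text), lexicon, criterion, config)
  data.frame(mention_text = as.character(mention_text),
             criterion = criterion,
             matched_accession = res$matched_accession,
             distance = res$distance,
             stringsAsFactors = FALSE)
}

#' Construct a lexicon from an in-memory entries table
#'
#' Convenience constructor used by the synthetic generator and in examples:
#' takes the same columns as the TSV schema and returns an indexed lexicon.
#'
#' @param entries data.frame with columns `accession`, `primary_name`,
#'   `synonyms` (pipe-separated), `problematic` (logical), `problem_category`.
#' @param config A [match_config()].
#' @return A `cellaudit_lexicon`.
#' @export
new_lexicon_from_entries <- function(entries, config = match_config()) {
  stopifnot(is.data.frame(entries))
  entries$accession <- as.character(entries$accession)
  entries$primary_name <- as.character(entries$primary_name)
  entries$synonyms <- as.character(entries$synonyms)
  entries$problematic <- as.logical(entries$problematic)
  entries$problem_category <- as.character(entries$problem_category)
  if (anyDuplicated(entries$accession))
    stop("duplicate accession in entries", call. = FALSE)
  if (any(!nzchar(entries$accession)) || any(!nzchar(entries$primary_name)))
    stop("empty accession or primary_name in entries", call. = FALSE)
  new_lexicon(entries, config)
}

#' Match a collection of mentions against the lexicon
#'
#' Applies [match_mention()] to every mention and returns per-mention results
#' together with summary counts. Unique-name counts are computed on
#' normalized surface forms.
#'
#' @param mentions A data.frame of mentions with at least a `surface` (or
#'   `mention_text`) column; a `doc_id` column is carried through if present.
#' @param lexicon A `cellaudit_lexicon`.
#' @param criterion `"strict"`, `"loose"` or `"edit"`.
#' @param config A [match_config()].
#' @return A list with `results` (data.frame: `doc_id`, `mention_text`,
#'   `criterion`, `matched_accession`, `distance`) and `summary` (list:
#'   `total_mentions`, `matched_mentions`, `unique_names`,
#'   `matched_unique_names`).
#' @export
match_corpus <- function(mentions, lexicon,
                         criterion = c("edit", "strict", "loose"),
                         config = match_config()) {
  criterion <- match.arg(criterion, c(match_criteria, "edit"))
  stopifnot(inherits(lexicon, "cellaudit_lexicon"))
  texts <- if (!is.null(mentions$surface)) mentions$surface
           else mentions$mention_text
  texts <- as.character(texts %||% character(0))
  doc_id <- if (!is.null(mentions$doc_id)) as.character(mentions$doc_id)
            else rep(NA_character_, length(texts))
  res <- match_texts(texts, lexicon, criterion, config)
  results <- data.frame(doc_id = doc_id, mention_text = texts,
                        criterion = rep(criterion, length(texts)),
                        matched_accession = res$matched_accession,
                        distance = res$distance, stringsAsFactors = FALSE)
  norm <- normalize_name(texts, config)
  matched <- !is.na(results$matched_accession)
  summary <- list(
    total_mentions = length(texts),
    matched_mentions = sum(matched),
    unique_names = length(unique(norm)),
    matched_unique_names = length(unique(norm[matched]))
  )
  list(results = results, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
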