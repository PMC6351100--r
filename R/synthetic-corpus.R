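# Seeded synthetic lexicons, registries and document corpora with exact
# ground truth. The generator's defaults encode the corpus conditions the
# audit emulates: ~7.7% of papers use cell lines, a cell-line paper describes
# about two unique lines each mentioned about twice, problematic-use rates
# near 8.7% (non-RRID cohort) and 3.3% (RRID cohort), plus name-corruption
# noise (hyphen/space variants, suffix words, case changes, typos).

#' Generator configuration
#'
#' @param seed Integer seed; identical configurations (including the seed)
#'   produce byte-identical lexicon, registry, corpus and truth.
#' @param n_docs Number of documents.
#' @param year_range Integer vector `c(min, max)` of publication years.
#' @param journals Named numeric vector of journal sampling weights.
#' @param p_cellline_paper Probability a paper uses cell lines (default
#'   0.077).
#' @param mean_unique_lines Mean number of unique cell lines per cell-line
#'   paper (default 2; drawn as `1 + Poisson(mean - 1)`).
#' @param mean_mentions_per_line Mean mentions of each line (default 2,
#'   same law).
#' @param p_problematic_nonrrid Probability a planted line is problematic in
#'   a paper without RRIDs (default 0.087).
#' @param p_problematic_rrid Same for RRID-using papers (default 0.033).
#' @param p_rrid_adoption Probability a cell-line paper uses RRIDs (default
#'   0.2; a desk-scale choice that populates both cohorts).
#' @param corruption Named rates for the per-line name-corruption operators
#'   `spacehyphen`, `suffix`, `case`, `typo`; their sum must be <= 1.
#' @param p_no_methods Rate of (non-cell-line) documents lacking a methods
#'   section.
#' @param p_no_pmid Rate of documents without a PMID-like identifier.
#' @param p_unresolvable_rrid Probability a planted RRID uses an accession
#'   absent from the registry (exercises the unresolved path; default 0).
#' @param p_software_rrid Probability a document with a methods section also
#'   carries a non-cell-line (software) RRID.
#' @param lexicon_size Number of lexicon entries.
#' @param problematic_fraction Fraction of lexicon entries flagged
#'   problematic.
#' @return An object of class `cellaudit_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_docs = 1000L,
                             year_range = c(1997L, 2018L),
                             journals = c("Scientific Reports" = 5,
                                          "PLoS ONE" = 4,
                                          "Oncotarget" = 3,
                                          "Cell Reports" = 2,
                                          "J Virol" = 2,
                                          "Front Plant Sci" = 1,
                                          "Breast Cancer Res" = 1,
                                          "Nat Chem Biol" = 1),
                             p_cellline_paper = 0.077,
                             mean_unique_lines = 2,
                             mean_mentions_per_line = 2,
                             p_problematic_nonrrid = 0.087,
                             p_problematic_rrid = 0.033,
                             p_rrid_adoption = 0.2,
                             corruption = c(spacehyphen = 0.10,
                                            suffix = 0.05,
                                            case = 0.05,
                                            typo = 0.02),
                             p_no_methods = 0.02,
                             p_no_pmid = 0.03,
                             p_unresolvable_rrid = 0,
                             p_software_rrid = 0.05,
                             lexicon_size = 120L,
                             problematic_fraction = 0.3) {
  fr <- c(p_cellline_paper, p_problematic_nonrrid, p_problematic_rrid,
          p_rrid_adoption, p_no_methods, p_no_pmid, p_unresolvable_rrid,
          p_software_rrid, problematic_fraction, corruption)
  if (any(fr < 0 | fr > 1)) stop("all rates must lie in [0,1]", call. = FALSE)
  if (sum(corruption) > 1) stop("corruption rates must sum to <= 1", call. = FALSE)
  stopifnot(n_docs >= 1L, lexicon_size >= 2L,
            length(year_range) == 2L, year_range[1] <= year_range[2],
            mean_unique_lines >= 1, mean_mentions_per_line >= 1,
            !is.null(names(journals)), all(journals > 0))
  ops <- c("spacehyphen", "suffix", "case", "typo")
  if (!all(names(corruption) %in% ops))
    stop("unknown corruption operator", call. = FALSE)
  full <- stats::setNames(numeric(4), ops)
  full[names(corruption)] <- corruption
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 year_range = as.integer(year_range), journals = journals,
                 p_cellline_paper = p_cellline_paper,
                 mean_unique_lines = mean_unique_lines,
                 mean_mentions_per_line = mean_mentions_per_line,
                 p_problematic_nonrrid = p_problematic_nonrrid,
                 p_problematic_rrid = p_problematic_rrid,
                 p_rrid_adoption = p_rrid_adoption,
                 corruption = full,
                 p_no_methods = p_no_methods, p_no_pmid = p_no_pmid,
                 p_unresolvable_rrid = p_unresolvable_rrid,
                 p_software_rrid = p_software_rrid,
                 lexicon_size = as.integer(lexicon_size),
                 problematic_fraction = problematic_fraction),
            class = "cellaudit_generator_config")
}

# Draw one synthetic cell-line-style name: a 2-3 letter block, a separator,
# 1-3 digits ("QX-17"). Normalized forms across the whole lexicon are kept
# prefix-free so that loose matches always identify the planted entry.
draw_name <- function(norm_set) {
  repeat {
    block <- paste(sample(LETTERS, sample(2:3, 1), replace = TRUE),
                   collapse = "")
    digits <- as.character(sample(1:999, 1))
    sep <- sample(c("-", "", " "), 1, prob = c(0.6, 0.3, 0.1))
    name <- paste0(block, sep, digits)
    norm <- tolower(paste0(block, digits))
    clash <- any(startsWith(norm_set, norm) | startsWith(norm, norm_set))
    if (!clash) return(list(name = name, norm = norm))
  }
}

#' Generate a synthetic lexicon and matching registry snapshot
#'
#' Produces `lexicon_size` entries with cell-line-style names (letter block,
#' separator, digits), one to three synonyms each, and
#' `round(lexicon_size * problematic_fraction)` entries flagged problematic
#' with a problem category. Accessions are shared with the returned registry
#' snapshot. Normalized names are unique (and prefix-free) across the whole
#' lexicon. Deterministic in `config$seed`.
#'
#' @param config A [generator_config()].
#' @return list with `lexicon` (a `cellaudit_lexicon`) and `registry`
#'   (a registry data.frame).
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "cellaudit_generator_config"))
  set.seed(config$seed)
  n <- config$lexicon_size
  norm_set <- character(0)
  entries <- vector("list", n)
  n_prob <- round(n * config$problematic_fraction)
  prob_idx <- if (n_prob > 0) sample(n, n_prob) else integer(0)
  cats <- c("misidentified", "partially-contaminated", "other")
  for (i in seq_len(n)) {
    prim <- draw_name(norm_set)
    norm_set <- c(norm_set, prim$norm)
    n_syn <- sample(1:3, 1)
    syn <- character(n_syn)
    for (s in seq_len(n_syn)) {
      sy <- draw_name(norm_set)
      norm_set <- c(norm_set, sy$norm)
      syn[s] <- sy$name
    }
    problematic <- i %in% prob_idx
    entries[[i]] <- data.frame(
      accession = sprintf("CVCL_Z%04d", i),
      primary_name = prim$name,
      synonyms = paste(syn, collapse = "|"),
      problematic = problematic,
      problem_category = if (problematic) sample(cats, 1, prob = c(.7, .2, .1))
                         else "",
      stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, entries)
  registry <- data.frame(
    accession = entries$accession,
    exists = TRUE,
    problematic = entries$problematic,
    warning_text = ifelse(entries$problematic,
                          paste("Problematic cell line:",
                                entries$problem_category), ""),
    stringsAsFactors = FALSE)
  class(registry) <- c("cellaudit_registry", "data.frame")
  list(lexicon = new_lexicon_from_entries(entries), registry = registry)
}

suffix_phrases <- c("mouse embryonic fibroblasts",
                    "human carcinoma derivative",
                    "clone expressing the reporter",
                    "stable transfectant")

#' Corrupt a cell-line name with one noise operator
#'
#' Models the surface variants the matching criteria distinguish:
#' \describe{
#'   \item{spacehyphen}{changes only zero-weight characters (swap or drop a
#'     hyphen/space, or insert one before the digit block), so the weighted
#'     edit distance to the original stays 0.}
#'   \item{suffix}{appends a descriptor phrase; the original remains a
#'     normalized prefix (loose-matchable) but the distance becomes positive.}
#'   \item{case}{upper- or lower-cases the whole name; all criteria are
#'     case-insensitive by default, so this is noise only for case-sensitive
#'     configurations.}
#'   \item{typo}{substitutes one alphanumeric character (letter for letter,
#'     digit for digit): edit distance 2 under default weights, matched by no
#'     criterion. When a `lexicon` is supplied the result is re-drawn until
#'     it matches no lexicon entry under any criterion.}
#' }
#' Uses the current RNG state.
#'
#' @param name The original name.
#' @param operator One of `"spacehyphen"`, `"suffix"`, `"case"`, `"typo"`,
#'   or `"none"` (identity).
#' @param lexicon Optional `cellaudit_lexicon` used to keep typos free of
#'   accidental matches.
#' @return The corrupted name.
#' @export
corrupt_name <- function(name, operator = c("none", "spacehyphen", "suffix",
                                            "case", "typo"),
                         lexicon = NULL) {
  operator <- match.arg(operator)
  if (operator == "none") return(name)
  if (operator == "spacehyphen") {
    if (grepl("-", name, fixed = TRUE))
      return(sub("-", sample(c(" ", ""), 1), name, fixed = TRUE))
    if (grepl(" ", name, fixed = TRUE))
      return(sub(" ", sample(c("-", ""), 1), name, fixed = TRUE))
    return(sub("([0-9])", "-\\1", name))   # insert before first digit
  }
  if (operator == "suffix")
    return(paste(name, sample(suffix_phrases, 1)))
  if (operator == "case")
    return(if (stats::runif(1) < 0.5) toupper(name) else tolower(name))
  # typo: substitute one alphanumeric character within its class
  chars <- strsplit(name, "", fixed = TRUE)[[1]]
  alnum <- grep("[[:alnum:]]", chars)
  for (attempt in 1:50) {
    out <- chars
    i <- if (length(alnum) > 1L) sample(alnum, 1) else alnum
    pool <- if (grepl("[0-9]", chars[i])) setdiff(as.character(0:9), chars[i])
            else setdiff(if (chars[i] %in% letters) letters else LETTERS,
                         c(tolower(chars[i]), toupper(chars[i])))
    out[i] <- sample(pool, 1)
    cand <- paste(out, collapse = "")
    if (is.null(lexicon)) return(cand)
    cn <- normalize_name(cand, lexicon$config)
    ln <- lexicon$names$norm
    if (!any(ln == cn | startsWith(cn, ln))) return(cand)
  }
  stop("could not produce a collision-free typo for '", name, "'",
       call. = FALSE)
}

# Sentence templates; each is prefix/suffix around the planted name, with an
# optional RRID slot before the final period. Prefix words are ordinary
# capitalized words so only the planted name looks name-like.
mention_templates <- list(
  c("The ", " cells were grown in modified Eagle medium with fetal bovine serum"),
  c("", " cells were seeded into 96-well plates and incubated overnight"),
  c("Cultures of ", " cells were transfected with the luciferase reporter construct"),
  c("Stocks of the ", " cell line were maintained under standard conditions")
)

filler_intro <- paste("This study addresses a question of broad interest.",
                      "Previous work motivated the present experiments.")
filler_results <- paste("The measurements were consistent across replicates.",
                        "Statistical summaries are reported in the tables.")
filler_methods <- paste("Samples were processed following standard protocols.",
                        "Reagents were obtained from commercial suppliers.",
                        "Data analysis used published software.")

#' Generate a synthetic document corpus with ground truth
#'
#' Each document receives a journal, a year and filler sections. With
#' probability `p_cellline_paper` a document becomes a cell-line paper: its
#' methods section embeds planted mentions drawn from the lexicon in
#' trigger-bearing template sentences, with gold spans recorded exactly.
#' RRID-adopting papers additionally embed `RRID:<accession>` tokens (one per
#' planted line, at its first mention) and draw problematic lines at
#' `p_problematic_rrid`; other cell-line papers draw at
#' `p_problematic_nonrrid`. One corruption operator is applied per planted
#' line at the configured rates (all mentions of the line share the corrupted
#' surface). Deterministic in `config$seed`.
#'
#' @param config A [generator_config()].
#' @param lexicon A `cellaudit_lexicon` with both problematic and clean
#'   entries (see [generate_lexicon()]).
#' @return list with `corpus` (a `cellaudit_corpus` whose `gold` holds every
#'   planted mention) and `truth` (a `cellaudit_truth` object: `docs`,
#'   `lines`, `mentions`, `rrids` data.frames plus the configured rates).
#' @export
generate_corpus <- function(config, lexicon) {
  stopifnot(inherits(config, "cellaudit_generator_config"),
            inherits(lexicon, "cellaudit_lexicon"))
  prob_entries <- which(lexicon$entries$problematic)
  clean_entries <- which(!lexicon$entries$problematic)
  if (!length(prob_entries) || !length(clean_entries))
    stop("lexicon needs both problematic and clean entries", call. = FALSE)
  set.seed(config$seed + 1L)
  n <- config$n_docs
  ops <- names(config$corruption)
  op_prob <- c(1 - sum(config$corruption), config$corruption)

  docs <- vector("list", n)
  sections <- vector("list", n)
  gold <- list()
  lines_tr <- list()
  mentions_tr <- list()
  rrids_tr <- list()

  for (i in seq_len(n)) {
    journal <- sample(names(config$journals), 1, prob = config$journals)
    year <- sample(config$year_range[1]:config$year_range[2], 1)
    no_pmid <- stats::runif(1) < config$p_no_pmid
    doc_id <- if (no_pmid) sprintf("OA-%05d", i)
              else as.character(2000000L + i)
    cellline <- stats::runif(1) < config$p_cellline_paper
    has_methods <- if (cellline) TRUE
                   else stats::runif(1) >= config$p_no_methods
    secs <- c(Introduction = filler_intro)

    if (cellline) {
      rrid_doc <- stats::runif(1) < config$p_rrid_adoption
      p_prob <- if (rrid_doc) config$p_problematic_rrid
                else config$p_problematic_nonrrid
      k <- 1L + stats::rpois(1, config$mean_unique_lines - 1)
      text <- "Cell culture procedures were as follows."
      for (l in seq_len(k)) {
        problematic <- stats::runif(1) < p_prob
        e <- if (problematic) sample(prob_entries, 1)
             else sample(clean_entries, 1)
        syn <- strsplit(lexicon$entries$synonyms[e], "|", fixed = TRUE)[[1]]
        base <- sample(c(lexicon$entries$primary_name[e], syn[nzchar(syn)]), 1)
        op <- sample(c("none", ops), 1, prob = op_prob)
        surface <- corrupt_name(base, op, lexicon)
        acc <- lexicon$entries$accession[e]
        m <- 1L + stats::rpois(1, config$mean_mentions_per_line - 1)
        rrid_acc <- NA_character_
        if (rrid_doc) {
          rrid_acc <- if (stats::runif(1) < config$p_unresolvable_rrid)
            sprintf("CVCL_U%04d", sample(5000:9999, 1)) else acc
        }
        for (occ in seq_len(m)) {
          tpl <- mention_templates[[sample(length(mention_templates), 1)]]
          pre <- paste0(text, " ", tpl[1])
          start <- nchar(pre)
          text <- paste0(pre, surface, tpl[2])
          end <- start + nchar(surface)
          if (occ == 1L && rrid_doc) {
            text <- paste0(text, " (RRID:", rrid_acc, ")")
            rrids_tr[[length(rrids_tr) + 1L]] <- data.frame(
              doc_id = doc_id, accession = rrid_acc,
              resolvable = rrid_acc == acc, problematic = problematic,
              stringsAsFactors = FALSE)
          }
          text <- paste0(text, ".")
          gold[[length(gold) + 1L]] <- data.frame(
            doc_id = doc_id, section = "Methods", start = start, end = end,
            surface = surface, stringsAsFactors = FALSE)
          mentions_tr[[length(mentions_tr) + 1L]] <- data.frame(
            doc_id = doc_id, accession = acc, surface = surface,
            operator = op, problematic = problematic,
            cohort = if (rrid_doc) "rrid" else "nonrrid",
            start = start, end = end, stringsAsFactors = FALSE)
        }
        lines_tr[[length(lines_tr) + 1L]] <- data.frame(
          doc_id = doc_id, accession = acc, surface = surface, operator = op,
          problematic = problematic,
          cohort = if (rrid_doc) "rrid" else "nonrrid",
          n_mentions = m, stringsAsFactors = FALSE)
      }
      secs <- c(secs, Methods = text)
    } else if (has_methods) {
      secs <- c(secs, Methods = filler_methods)
      rrid_doc <- FALSE
    } else {
      rrid_doc <- FALSE
    }

    if (has_methods && stats::runif(1) < config$p_software_rrid) {
      secs["Methods"] <- paste0(
        secs["Methods"],
        " Image analysis used AnalyzerTool (RRID:SCR_0", sample(1000:9999, 1),
        ").")
    }
    secs <- c(secs, Results = filler_results)

    docs[[i]] <- data.frame(doc_id = doc_id, journal = journal, year = year,
                            minable = TRUE, cellline = cellline,
                            rrid_doc = rrid_doc, has_methods = has_methods,
                            stringsAsFactors = FALSE)
    sections[[i]] <- secs
  }

  docs <- do.call(rbind, docs)
  names(sections) <- docs$doc_id
  gold <- if (length(gold)) do.call(rbind, gold) else NULL
  corpus <- new_corpus(docs[c("doc_id", "journal", "year", "minable")],
                       sections, gold)
  truth <- structure(list(
    docs = docs,
    lines = if (length(lines_tr)) do.call(rbind, lines_tr) else
      data.frame(doc_id = character(0), accession = character(0),
                 surface = character(0), operator = character(0),
                 problematic = logical(0), cohort = character(0),
                 n_mentions = integer(0)),
    mentions = if (length(mentions_tr)) do.call(rbind, mentions_tr) else
      data.frame(doc_id = character(0), accession = character(0),
                 surface = character(0), operator = character(0),
                 problematic = logical(0), cohort = character(0),
                 start = integer(0), end = integer(0)),
    rrids = if (length(rrids_tr)) do.call(rbind, rrids_tr) else
      data.frame(doc_id = character(0), accession = character(0),
                 resolvable = logical(0), problematic = logical(0)),
    config = config), class = "cellaudit_truth")
  list(corpus = corpus, truth = truth)
}

#' Corpus-level summary of planted ground truth
#'
#' Exact planted quantities for comparison against pipeline estimates.
#'
#' @param truth A `cellaudit_truth` from [generate_corpus()].
#' @return list: `n_docs`, `n_cellline_docs`, `cellline_fraction`, `cohorts`
#'   (data.frame of planted line counts and problematic fractions per
#'   cohort), `by_journal`, `by_year`, `rrids` (planted RRID mention counts
#'   and problematic fraction among resolvable ones).
#' @export
planted_truth <- function(truth) {
  stopifnot(inherits(truth, "cellaudit_truth"))
  d <- truth$docs; ln <- truth$lines
  cohorts <- do.call(rbind, lapply(c("nonrrid", "rrid"), function(co) {
    sub <- ln[ln$cohort == co, , drop = FALSE]
    data.frame(cohort = co, lines = nrow(sub),
               problematic_lines = sum(sub$problematic),
               fraction = if (nrow(sub)) mean(sub$problematic) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  jmap <- d$journal[match(ln$doc_id, d$doc_id)]
  by_journal <- do.call(rbind, lapply(sort(unique(d$journal)), function(j) {
    sub <- ln[jmap == j, , drop = FALSE]
    data.frame(journal = j, lines = nrow(sub),
               problematic_lines = sum(sub$problematic),
               stringsAsFactors = FALSE)
  }))
  ymap <- d$year[match(ln$doc_id, d$doc_id)]
  by_year <- do.call(rbind, lapply(sort(unique(d$year)), function(y) {
    sub <- ln[ymap == y, , drop = FALSE]
    data.frame(year = y, lines = nrow(sub),
               mentions = sum(sub$n_mentions),
               problematic_lines = sum(sub$problematic),
               stringsAsFactors = FALSE)
  }))
  res <- truth$rrids[truth$rrids$resolvable, , drop = FALSE]
  list(n_docs = nrow(d), n_cellline_docs = sum(d$cellline),
       cellline_fraction = mean(d$cellline),
       cohorts = cohorts, by_journal = by_journal, by_year = by_year,
       rrids = list(planted = nrow(truth$rrids), resolvable = nrow(res),
                    problematic = sum(res$problematic),
                    fraction = if (nrow(res)) mean(res$problematic)
                               else NA_real_))
}

#' Write the canonical fixture files
#'
#' Emits `lexicon.tsv`, `registry.tsv` and `corpus.jsonl` (the exact schemas
#' the other modules consume) into a directory and returns the paths together
#' with the in-memory objects and ground truth.
#'
#' @param dir Output directory (created if needed).
#' @param config A [generator_config()].
#' @return list: `paths`, `lexicon`, `registry`, `corpus`, `truth`.
#' @export
generate_fixtures <- function(dir, config = generator_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lex <- generate_lexicon(config)
  gen <- generate_corpus(config, lex$lexicon)
  paths <- list(lexicon = file.path(dir, "lexicon.tsv"),
                registry = file.path(dir, "registry.tsv"),
                corpus = file.path(dir, "corpus.jsonl"))
  write_lexicon(lex$lexicon, paths$lexicon)
  write_registry(lex$registry, paths$registry)
  write_corpus(gen$corpus, paths$corpus)
  list(paths = paths, lexicon = lex$lexicon, registry = lex$registry,
       corpus = gen$corpus, truth = gen$truth)
}
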