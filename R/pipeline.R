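# End-to-end audit pipeline: methods extraction -> mention detection ->
# matching under all three criteria -> RRID audit -> corpus analytics.

#' Pipeline configuration
#'
#' @param corpus A `cellaudit_corpus` or path to a corpus JSONL file.
#' @param lexicon A `cellaudit_lexicon` or path to a lexicon TSV. The full
#'   lexicon serves as the detection dictionary; problematic-use matching
#'   runs against its problematic subset.
#' @param registry A registry data.frame or path to a registry TSV.
#' @param output_dir Optional directory for intermediate artifacts (detected
#'   mentions, match results, RRID audit) and report files; `NULL` disables
#'   writing.
#' @param criteria Criteria to compute (default all three).
#' @param primary_criterion Criterion used for headline and cohort numbers
#'   (default `"edit"`, the intermediate estimate).
#' @param match_cfg A [match_config()].
#' @param trigger_cfg A [trigger_config()].
#' @param min_year Earliest year in yearly summaries (default 1997).
#' @param authority RRID authority prefix for cell lines (default `"CVCL"`).
#' @param mentions `"detect"` (run the recognizer) or `"gold"` (use the
#'   corpus's curated annotations, when present).
#' @param weight_by Weighting convention for the across-journal average of
#'   problematic paper rates: `"papers"` (RRID papers per journal) or
#'   `"cell_lines"` (detected lines per journal).
#' @return An object of class `cellaudit_audit_config`.
#' @export
audit_config <- function(corpus, lexicon, registry, output_dir = NULL,
                         criteria = c("strict", "loose", "edit"),
                         primary_criterion = "edit",
                         match_cfg = match_config(),
                         trigger_cfg = trigger_config(),
                         min_year = 1997L, authority = "CVCL",
                         mentions = c("detect", "gold"),
                         weight_by = c("papers", "cell_lines")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  stopifnot(primary_criterion %in% criteria)
  structure(list(corpus = corpus, lexicon = lexicon, registry = registry,
                 output_dir = output_dir, criteria = criteria,
                 primary_criterion = primary_criterion,
                 match_cfg = match_cfg, trigger_cfg = trigger_cfg,
                 min_year = as.integer(min_year), authority = authority,
                 mentions = match.arg(mentions),
                 weight_by = match.arg(weight_by)),
            class = "cellaudit_audit_config")
}

load_input <- function(x, loader) if (is.character(x)) loader(x) else x

# Stable hash of the run configuration (paths replaced by basenames so the
# hash survives relocation).
config_hash <- function(config) {
  c2 <- config
  for (f in c("corpus", "lexicon", "registry"))
    if (is.character(c2[[f]])) c2[[f]] <- basename(c2[[f]])
  c2$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(c2, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full problematic-cell-line audit
#'
#' Executes methods extraction, mention detection, matching under every
#' configured criterion (against the problematic subset of the lexicon), the
#' RRID audit, and corpus analytics. The pipeline is deterministic for fixed
#' inputs and configuration. When `output_dir` is set, intermediate artifacts
#' are written per stage so every headline number is auditable.
#'
#' @param config An [audit_config()].
#' @return An object of class `cellaudit_report`: list with `overall`,
#'   `yearly`, `journal`, `cohorts` (auto-detected vs RRID rates and z-tests),
#'   `rrid` (audit counts), `metadata`.
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "cellaudit_audit_config"))
  corpus <- load_input(config$corpus, read_corpus)
  lexicon <- load_input(config$lexicon, load_lexicon)
  registry <- load_input(config$registry, load_registry)
  problematic_lex <- lexicon_subset(lexicon, problematic = TRUE)

  mentions <- if (config$mentions == "gold") {
    if (is.null(corpus$gold)) stop("corpus carries no gold mentions",
                                   call. = FALSE)
    corpus$gold
  } else {
    detect_corpus_mentions(corpus, lexicon, config$trigger_cfg,
                           config$match_cfg)
  }

  matches <- lapply(config$criteria, function(cr)
    match_corpus(mentions, problematic_lex, cr, config$match_cfg))
  names(matches) <- config$criteria
  primary <- matches[[config$primary_criterion]]

  rrid_mentions <- resolve_rrid(extract_corpus_rrids(corpus), registry)
  rrid_set <- build_rrid_analysis_set(rrid_mentions, corpus$docs,
                                      config$authority)
  rrid_rate <- rrid_problematic_rate(rrid_set$mentions, registry)

  yearly <- aggregate_yearly(matches, corpus$docs, config$min_year)
  journal <- aggregate_by_journal(primary, corpus$docs,
                                  config = config$match_cfg)
  paper_rate <- paper_level_rate(primary)

  # cohort comparison (auto-detected vs RRID), mention and paper level
  auto_x <- primary$summary$matched_mentions
  auto_n <- primary$summary$total_mentions
  mention_test <- if (auto_n > 0 && rrid_rate$total > 0 &&
                      (auto_x + rrid_rate$problematic) > 0 &&
                      (auto_x + rrid_rate$problematic) <
                        (auto_n + rrid_rate$total)) {
    two_proportion_ztest(auto_x, auto_n, rrid_rate$problematic,
                         rrid_rate$total, "greater")
  } else NULL
  rrid_paper_prob <- length(unique(
    rrid_set$mentions$doc_id[rrid_set$mentions$problematic]))
  rrid_paper_n <- rrid_set$counts$papers_final
  paper_test <- if (paper_rate$papers_total > 0 && rrid_paper_n > 0 &&
                    (paper_rate$papers_matched + rrid_paper_prob) > 0 &&
                    (paper_rate$papers_matched + rrid_paper_prob) <
                      (paper_rate$papers_total + rrid_paper_n)) {
    two_proportion_ztest(paper_rate$papers_matched, paper_rate$papers_total,
                         rrid_paper_prob, rrid_paper_n, "greater")
  } else NULL

  # weighted across-journal average of the paper-level problematic rate
  rates <- stats::setNames(journal$pct_papers / 100, journal$journal)
  weights <- if (config$weight_by == "papers") {
    tab <- table(corpus$docs$journal[corpus$docs$doc_id %in%
                                       rrid_set$papers$doc_id])
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    stats::setNames(journal$cell_lines_detected, journal$journal)
  }
  weighted_avg <- tryCatch(
    suppressMessages(weighted_average_rate(rates, weights)),
    error = function(e) NA_real_)

  overall <- list(
    documents = nrow(corpus$docs),
    mentions_total = auto_n,
    unique_names = primary$summary$unique_names,
    matched = lapply(matches, function(m) m$summary$matched_mentions),
    pct_matched = lapply(matches, function(m)
      if (auto_n > 0) 100 * m$summary$matched_mentions / auto_n else NA_real_),
    paper_rate = paper_rate,
    weighted_avg_paper_rate = weighted_avg
  )
  report <- structure(list(
    overall = overall,
    yearly = yearly,
    journal = journal,
    cohorts = list(
      auto_mentions = list(x = auto_x, n = auto_n,
                           fraction = if (auto_n > 0) auto_x / auto_n
                                      else NA_real_),
      rrid_mentions = rrid_rate,
      auto_papers = paper_rate,
      rrid_papers = list(problematic = rrid_paper_prob, total = rrid_paper_n,
                         fraction = if (rrid_paper_n > 0)
                           rrid_paper_prob / rrid_paper_n else NA_real_),
      mention_ztest = mention_test,
      paper_ztest = paper_test
    ),
    rrid = rrid_set$counts,
    metadata = list(package_version = as.character(
                      utils::packageVersion("cellaudit")),
                    primary_criterion = config$primary_criterion,
                    criteria = config$criteria,
                    mentions_source = config$mentions,
                    config_hash = config_hash(config))
  ), class = "cellaudit_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(mentions,
                     file.path(config$output_dir, "mentions.csv"),
                     row.names = FALSE)
    for (cr in config$criteria)
      utils::write.csv(matches[[cr]]$results,
                       file.path(config$output_dir,
                                 paste0("matches_", cr, ".csv")),
                       row.names = FALSE)
    utils::write.csv(rrid_mentions,
                     file.path(config$output_dir, "rrid_audit.csv"),
                     row.names = FALSE)
    write_report(report, config$output_dir)
  }
  report
}

#' @export
print.cellaudit_report <- function(x, ...) {
  o <- x$overall
  cat("Problematic cell-line audit\n")
  cat(sprintf("  documents: %d | detected mentions: %d (%d unique names)\n",
              o$documents, o$mentions_total, o$unique_names))
  for (cr in names(o$matched))
    cat(sprintf("  %-6s criterion: %d matched (%s%%)\n", cr, o$matched[[cr]],
                fmt_num(o$pct_matched[[cr]], 1)))
  cat(sprintf("  papers with a problematic line: %d of %d (%s%%)\n",
              o$paper_rate$papers_matched, o$paper_rate$papers_total,
              fmt_num(100 * o$paper_rate$fraction, 1)))
  co <- x$cohorts
  cat(sprintf("  RRID cohort: %d of %d problematic (%s%%)\n",
              co$rrid_mentions$problematic, co$rrid_mentions$total,
              fmt_num(100 * co$rrid_mentions$fraction, 1)))
  if (!is.null(co$mention_ztest))
    cat(sprintf("  cohort z-test (mentions): z = %.4f, p = %s\n",
                co$mention_ztest$z,
                format.pval(co$mention_ztest$p_value, digits = 4)))
  invisible(x)
}

fmt_num <- function(x, digits) {
  if (is.null(x) || length(x) == 0 || is.na(x)) "NA"
  else formatC(round(x, digits), format = "f", digits = digits)
}

#' Write report files
#'
#' Emits a machine-readable JSON rendering plus one CSV per table (yearly and
#' journal summaries). Numbers are serialized at full precision; display
#' rounding (percentages to 1 decimal, z to 4) is applied only in
#' `print()` methods.
#'
#' @param report A `cellaudit_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "csv")`.
#' @return Named list of written paths, invisibly.
#' @export
write_report <- function(report, dir, formats = c("json", "csv")) {
  stopifnot(inherits(report, "cellaudit_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    body <- unclass(report)
    body$cohorts$mention_ztest <- ztest_as_list(body$cohorts$mention_ztest)
    body$cohorts$paper_ztest <- ztest_as_list(body$cohorts$paper_ztest)
    jsonlite::write_json(body, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    out$json <- p
  }
  if ("csv" %in% formats) {
    p1 <- file.path(dir, "yearly.csv")
    utils::write.csv(report$yearly, p1, row.names = FALSE)
    p2 <- file.path(dir, "journal.csv")
    utils::write.csv(report$journal, p2, row.names = FALSE)
    out$yearly_csv <- p1
    out$journal_csv <- p2
  }
  invisible(out)
}

ztest_as_list <- function(z) {
  if (is.null(z)) return(NULL)
  list(z = z$z, p_value = z$p_value, alternative = z$alternative,
       p1 = unname(z$estimate["p1"]), p2 = unname(z$estimate["p2"]),
       inputs = as.list(z$inputs), degenerate = z$degenerate)
}

#' Read back a JSON report
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return The report as a plain list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
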