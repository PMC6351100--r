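# Yearly / journal / paper-level aggregation, the pooled two-proportion
# z-test, weighted average rates, and linear trend fits.

#' Pooled two-proportion z-test
#'
#' Tests whether two sample proportions differ using the population
#' proportion z statistic with the pooled standard error:
#' \deqn{z = (p_1 - p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p = (x_1 + x_2)/(n_1 + n_2)}. The default alternative is
#' one-tailed (`"greater"`: first proportion exceeds the second), matching
#' the directional hypothesis that RRID users report fewer problematic
#' lines; `"less"` and `"two.sided"` are available.
#'
#' @param x1,n1 Successes and trials in the first sample.
#' @param x2,n2 Successes and trials in the second sample.
#' @param alternative `"greater"` (one-tailed, default), `"less"` or
#'   `"two.sided"`.
#' @return An object of class `cellaudit_ztest`: `z`, `p_value`,
#'   `alternative`, `estimate` (the two proportions), `inputs`, `degenerate`.
#'   When the pooled proportion is 0 or 1 the test is degenerate: `z = 0`
#'   (both proportions are equal) and `p_value = NA` with a warning.
#' @export
#' @examples
#' two_proportion_ztest(26418, 305161, 50, 1502)$z  # ~7.3353
two_proportion_ztest <- function(x1, n1, x2, n2,
                                 alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(n1, n2) <= 0)) stop("sample sizes must be positive", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("counts must satisfy 0 <= x <= n", call. = FALSE)
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  degenerate <- pool %in% c(0, 1)
  if (degenerate) {
    warning("degenerate test: pooled proportion is ", pool, call. = FALSE)
    z <- 0; p <- NA_real_
  } else {
    se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
    z <- (p1 - p2) / se
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }
  structure(list(z = z, p_value = p, alternative = alternative,
                 estimate = c(p1 = p1, p2 = p2),
                 inputs = c(x1 = x1, n1 = n1, x2 = x2, n2 = n2),
                 degenerate = degenerate),
            class = "cellaudit_ztest")
}

#' @export
print.cellaudit_ztest <- function(x, ...) {
  cat(sprintf(paste0("Two-proportion z-test (pooled SE, %s)\n",
                     "  p1 = %d/%d = %.4f | p2 = %d/%d = %.4f\n",
                     "  z = %.4f, p = %s\n"),
              x$alternative,
              x$inputs["x1"], x$inputs["n1"], x$estimate["p1"],
              x$inputs["x2"], x$inputs["n2"], x$estimate["p2"],
              x$z, format.pval(x$p_value, digits = 4)))
  invisible(x)
}

#' Ordinary least-squares trend with R-squared
#'
#' Fits percentage-on-year by OLS and reports the coefficient of
#' determination. A zero-variance response yields `r_squared = 0` with a
#' warning (rather than an undefined value) so degenerate synthetic data do
#' not crash pipelines.
#'
#' @param x Predictor (e.g. calendar years); at least 3 points, not all equal.
#' @param y Response (e.g. problematic percentage per year).
#' @return list of class `cellaudit_trend`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
linear_trend_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) {
    warning("response has zero variance; R^2 defined as 0", call. = FALSE)
    0
  } else summary(fit)$r.squared
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = length(x)),
            class = "cellaudit_trend")
}

#' @export
print.cellaudit_trend <- function(x, ...) {
  cat(sprintf("Linear trend on %d points: slope %.4g, intercept %.4g, R^2 = %.3f\n",
              x$n_points, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

# Helper shared by the aggregators: results must be a named list with one
# match_corpus() result data.frame per criterion.
check_results_list <- function(results) {
  stopifnot(is.list(results))
  res <- lapply(results, function(r) if (is.list(r) && !is.data.frame(r)) r$results else r)
  ns <- vapply(res, nrow, integer(1))
  if (length(unique(ns)) > 1L)
    stop("per-criterion results must cover the same mention set", call. = FALSE)
  res
}

#' Yearly aggregation of match results
#'
#' One summary row per calendar year at or after `min_year` (years in range
#' with zero mentions are reported with zero counts). Data before `min_year`
#' (default 1997, when yearly paper counts become non-negligible) are
#' excluded.
#'
#' @param results Named list of per-criterion match results (data.frames or
#'   [match_corpus()] outputs) with names among `strict`, `loose`, `edit`,
#'   all computed on the same mention set with a `doc_id` column.
#' @param docs Corpus documents data.frame (`doc_id`, `year`).
#' @param min_year Earliest year retained.
#' @return data.frame: `year`, `papers_total` (papers with >= 1 mention),
#'   `mentions_total`, `matched_<criterion>` and `pct_<criterion>` columns.
#' @export
aggregate_yearly <- function(results, docs, min_year = 1997L) {
  res <- check_results_list(results)
  base <- res[[1]]
  year <- docs$year[match(base$doc_id, docs$doc_id)]
  yrs_all <- docs$year[docs$year >= min_year]
  years <- if (length(yrs_all)) seq(min_year, max(yrs_all)) else integer(0)
  out <- data.frame(year = years)
  out$papers_total <- vapply(years, function(y)
    length(unique(base$doc_id[!is.na(year) & year == y])), integer(1))
  out$mentions_total <- vapply(years, function(y)
    sum(year == y, na.rm = TRUE), integer(1))
  for (cr in names(res)) {
    matched <- !is.na(res[[cr]]$matched_accession)
    cnt <- vapply(years, function(y)
      sum(matched & !is.na(year) & year == y), integer(1))
    out[[paste0("matched_", cr)]] <- cnt
    out[[paste0("pct_", cr)]] <-
      ifelse(out$mentions_total > 0, 100 * cnt / out$mentions_total, NA_real_)
  }
  out
}

#' Per-journal aggregation of match results
#'
#' Counts, per journal, the unique cell-line names detected (normalized
#' surface forms), how many of those are on the problematic list, the papers
#' with at least one detected mention, and the papers with at least one
#' match. Journals are ordered by `cell_lines_detected` descending, ties
#' alphabetically; journals with zero detected lines are included (with zero
#' counts) unless truncated by `top_n`.
#'
#' @param results One criterion's match results (data.frame or
#'   [match_corpus()] output) with `doc_id` and `mention_text`.
#' @param docs Corpus documents data.frame (`doc_id`, `journal`).
#' @param top_n Optional truncation after ordering.
#' @param config A [match_config()] for name normalization.
#' @return data.frame: `journal`, `cell_lines_detected`,
#'   `cell_lines_problematic`, `papers_total`, `papers_with_problematic`,
#'   `pct_cell_lines`, `pct_papers`.
#' @export
aggregate_by_journal <- function(results, docs, top_n = NULL,
                                 config = match_config()) {
  r <- if (is.list(results) && !is.data.frame(results)) results$results else results
  journal <- docs$journal[match(r$doc_id, docs$doc_id)]
  norm <- normalize_name(r$mention_text, config)
  matched <- !is.na(r$matched_accession)
  js <- sort(unique(docs$journal))
  rows <- lapply(js, function(j) {
    in_j <- !is.na(journal) & journal == j
    detected <- length(unique(norm[in_j]))
    prob <- length(unique(norm[in_j & matched]))
    papers <- length(unique(r$doc_id[in_j]))
    papers_prob <- length(unique(r$doc_id[in_j & matched]))
    data.frame(journal = j, cell_lines_detected = detected,
               cell_lines_problematic = prob, papers_total = papers,
               papers_with_problematic = papers_prob,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(journal = character(0), cell_lines_detected = integer(0),
                      cell_lines_problematic = integer(0),
                      papers_total = integer(0),
                      papers_with_problematic = integer(0),
                      pct_cell_lines = numeric(0), pct_papers = numeric(0)))
  out <- do.call(rbind, rows)
  out$pct_cell_lines <- ifelse(out$cell_lines_detected > 0,
                               100 * out$cell_lines_problematic /
                                 out$cell_lines_detected, NA_real_)
  out$pct_papers <- ifelse(out$papers_total > 0,
                           100 * out$papers_with_problematic /
                             out$papers_total, NA_real_)
  out <- out[order(-out$cell_lines_detected, out$journal), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

#' Fraction of papers with at least one problematic match
#'
#' The denominator is the number of papers with at least one detected
#' mention (the population under analysis), not all papers in the corpus.
#'
#' @param results One criterion's match results (data.frame or
#'   [match_corpus()] output).
#' @return list: `papers_matched`, `papers_total`, `fraction` (`NA` when no
#'   paper has a detected mention).
#' @export
paper_level_rate <- function(results) {
  r <- if (is.list(results) && !is.data.frame(results)) results$results else results
  total <- length(unique(r$doc_id))
  matched <- length(unique(r$doc_id[!is.na(r$matched_accession)]))
  list(papers_matched = matched, papers_total = total,
       fraction = if (total > 0L) matched / total else NA_real_)
}

#' Weighted average of per-journal rates
#'
#' Computes \eqn{\sum_j w_j r_j / \sum_j w_j} over the journals present in
#' both inputs; journals missing a weight are skipped with a message. The
#' weighting convention (papers per journal vs cell lines per journal) is the
#' caller's choice.
#'
#' @param rates Named numeric vector of per-journal rates.
#' @param weights Named non-negative numeric vector of weights; at least one
#'   shared journal must have positive weight.
#' @return The weighted average (single number).
#' @export
#' @examples
#' weighted_average_rate(c(A = 0.1, B = 0.2), c(A = 3, B = 1))  # 0.125
weighted_average_rate <- function(rates, weights) {
  if (is.null(names(rates)) || is.null(names(weights)))
    stop("rates and weights must be named by journal", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  shared <- intersect(names(rates), names(weights))
  skipped <- setdiff(names(rates), shared)
  if (length(skipped))
    message("skipping journal(s) without a weight: ",
            paste(skipped, collapse = ", "))
  w <- weights[shared]; r <- rates[shared]
  ok <- !is.na(r)
  w <- w[ok]; r <- r[ok]
  if (!length(w) || sum(w) == 0)
    stop("no journal with positive weight and a defined rate", call. = FALSE)
  sum(w * r) / sum(w)
}

#' Percentage at printed precision
#'
#' Formats a count ratio as the percentage a report would print:
#' `100 * x / n` rounded to `digits` decimals.
#'
#' @param x Numerator count.
#' @param n Denominator count.
#' @param digits Decimal places (default 1).
#' @return A number.
#' @export
#' @examples
#' rate_percent(26418, 305161)      # 8.7
#' rate_percent(15615, 305130, 2)   # 5.12
rate_percent <- function(x, n, digits = 1) {
  if (n <= 0) stop("denominator must be positive", call. = FALSE)
  round(100 * x / n, digits)
}
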