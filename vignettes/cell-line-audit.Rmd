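---
title: "Auditing problematic cell-line usage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing problematic cell-line usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellaudit)
```

## The problem

Misidentified and cross-contaminated cell lines — classically, cultures
overgrown by aggressive cancer lines such as HeLa — keep propagating through
the biomedical literature because authentication testing (STR profiling) is
not routine. Registries (the ICLAC register of misidentified cell lines, and
the Cellosaurus knowledgebase that integrates it) flag such *problematic*
lines, and Research Resource Identifiers (RRIDs, e.g. `RRID:CVCL_0019`) let
authors point unambiguously at the registry record — and so see its warning —
while writing their methods section.

`cellaudit` implements a corpus-scale audit of this situation: find cell-line
name mentions in the methods sections of papers, decide which mentions are on
the problematic list, extract and resolve the RRIDs that authors used, and
ask whether RRID-using papers report problematic lines at a lower rate than
the rest of the corpus.

## The matching model

A detected name is tested against every lexicon name and synonym under three
criteria that bracket the truth from below and above:

* **strict** — exact, case-insensitive equality. Special characters are
  significant: `CF1` does not strictly match `CF-1`, but `HELA` strictly
  matches `HeLa`. A lower bound: name variants escape it.
* **loose** — the normalized lexicon name is a prefix of the normalized
  mention, so `CF-1 mouse embryonic fibroblasts` matches `CF-1`. An upper
  bound: over-matches short names embedded in longer ones.
* **edit** — a weighted edit distance in which inserting or deleting a
  special (non-alphanumeric) character costs 0, any other insertion/deletion
  costs 1, and a substitution costs 2 (one deletion plus one addition). A
  mention matches when its distance to some lexicon name is strictly below 1,
  i.e. exactly 0 under the default integer weights: the names agree on their
  letters and digits once separators are skipped. `CF1` = `CF-1` = `CF 1`,
  while `CAF-1` and `CF-10` (distance 1) and any single-character typo
  (distance 2) stay unmatched. The intermediate, headline criterion.

With the default weights the distance is a metric (the substitution weight
does not exceed twice the indel weight), it is symmetric, and it vanishes
exactly when the two normalized forms coincide — which licenses a fast
hash-lookup path whenever `threshold <= min(indel, substitution)`. The full
dynamic program is retained so that non-default weights and thresholds
remain usable.

Two genuinely open points in the loose semantics were decided as follows.
The wildcard description ("append `*` to the detected name") and the worked
example (lexicon `CF-1` matching the longer detected phrase) pull in opposite
directions; we follow the worked example — lexicon name as prefix of the
mention — because it also preserves the ordering strict ⊆ edit ⊆ loose that
makes the edit criterion "intermediate". The alternative direction is
available as `match_config(loose_two_way = TRUE)` for sensitivity analysis.
Second, loose matching operates on *normalized* strings; raw-prefix matching
would let an edit match fail the loose criterion and break the bracketing.
Ties across lexicon entries resolve to the lexicographically smallest
accession, deterministically. Names are NFC-normalized and case-folded; the
zero-weight character set (default: everything non-alphanumeric) is
configurable.

## The recognizer and its evaluation

The original audit used a trained named-entity recognizer whose training
data are not available; this package substitutes a deterministic
dictionary-plus-context recognizer with the same inputs, outputs and
evaluation harness. The *dictionary channel* finds token n-grams whose
normalized form equals a lexicon name. The *context channel* finds name-like
tokens (containing a digit or at least two capitals) adjoining a trigger
phrase such as "cells" or "cell line", walking leftwards across coordination
("HeLa or RAW264.7 cells") — this channel can find lines absent from the
dictionary. Candidates merge leftmost-longest. Because the recognizer is a
surrogate, the original model's precision/recall are *not* reproduction
targets; the harness itself is:

* `evaluate_ner()` computes P = tp/(tp+fp), R = tp/(tp+fn),
  F1 = 2PR/(P+R), with span overlap (default) or exact spans as the match
  mode — the source audit does not state its granularity, so the laxer mode
  is the default. Degenerate cases (no predictions, or no gold) define the
  affected metric as 0 rather than NaN so aggregation never propagates
  undefined values.
* `repeated_split_eval()` draws ten 90/10 train/test splits (split *r*
  reseeds with `seed + r`); on the train part the only fitted quantity is
  which context triggers to keep (per-trigger precision cutoff chosen from a
  small grid by train F1 — the dictionary channel is fixed), and metrics are
  reported on the held-out part as mean ± sd.
* `paper_level_agreement()` cross-tabulates curator vs algorithm presence
  calls per paper; `systematic_sample()` implements deterministic
  every-nth-record sampling. Note that 65,085 records sampled at every 65th
  yield 1,001 — our semantics is positions 65, 130, …; the source's slightly
  larger count is not recoverable from its description and is not asserted.

## The RRID audit

`extract_rrids()` captures, after each literal `RRID` token, the text up to
the first break character (comma, period, semicolon, whitespace, closing
bracket — configurable; brackets are included because RRIDs typically sit in
parentheses). A leading colon with one optional space is tolerated, and an
accession of shape `PREFIX_ALNUM` is parsed from the capture. Records whose
syntax deviates (extra underscore, missing colon, stray space) but whose
identifier is still parseable are kept and labelled
`syntax_error_recoverable`, mirroring curatorial practice. Resolution against
a local registry snapshot is a pure function of (identifier, registry):
`verified`, `syntax_error_recoverable`, or `unresolved`; curator-supplied
records are excluded from researcher-usage statistics. The analysis set
keeps the cell-line authority (`CVCL`) and applies the PMID filter to both
the mention-level and the paper-level sets, logging every drop so the
trimming is auditable.

## Statistics

Cohorts are compared with the *pooled* two-proportion z statistic,

$$z = \frac{p_1 - p_2}{\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}},
\qquad \hat p = \frac{x_1 + x_2}{n_1 + n_2},$$

one-tailed by default (the directional hypothesis is that RRID users report
*fewer* problematic lines). The pooled rather than unpooled standard error
reproduces all three z values printed in the source audit from its printed
counts, which identifies the calculator it used; the unpooled form does not.
Degenerate inputs (pooled proportion 0 or 1) return z = 0 with an `NA`
p-value and a warning rather than crashing. Yearly trends are summarized by
OLS of percentage on year with R²; a zero-variance response defines R² = 0
with a warning. Yearly aggregation excludes years before 1997 by default
(too few papers per year to be informative); the cutoff is a configuration
default, not hard-coded. Paper-level rates use papers with at least one
detected mention as the denominator — the population actually under
analysis. The across-journal weighted average exposes both weighting
conventions (RRID papers per journal, or detected lines per journal), since
the source does not state which it used.

```{r ztest}
two_proportion_ztest(26418, 305161, 50, 1502)
```

## The synthetic world

Because the real corpus (about two million open-access papers) is far beyond
desk scale, every stage is validated against a seeded generator whose
defaults *are* the documented corpus conditions, fixed once and not tuned:

| parameter | default | why |
|---|---|---|
| `p_cellline_paper` | 0.077 | documented prevalence of cell-line papers |
| `mean_unique_lines` | 2 | documented mean unique lines per cell-line paper |
| `mean_mentions_per_line` | 2 | documented mean mentions per line |
| `p_problematic_nonrrid` | 0.087 | documented non-RRID problematic rate |
| `p_problematic_rrid` | 0.033 | documented RRID-cohort problematic rate |
| `p_rrid_adoption` | 0.2 | desk-scale choice: corpus-level adoption (~700 of 2M papers) would leave the RRID cohort empty at n ≈ 10³; 0.2 populates both cohorts |
| `corruption` | 0.10/0.05/0.05/0.02 | plausible rates for separator variants, descriptor suffixes, case changes and typos; each operator maps onto exactly one matching criterion |
| `lexicon_size`, `problematic_fraction` | 120, 0.3 | enough distinct names for a 10³-document corpus while keeping both problematic and clean pools non-trivial |

Counts of lines and mentions are drawn as 1 + Poisson(mean − 1). Corruption
operators have exact contracts the tests assert exhaustively: separator
variants keep edit distance 0; suffixes keep the name a normalized prefix
(loose-only); case changes are invisible to all default criteria; typos
escape all three (re-drawn, when a lexicon is supplied, until no accidental
match exists). One operator is drawn per planted *line* — all its mentions
share the corrupted surface — so line-level recovery tests have clean
binomial structure. Lexicon names are generated globally prefix-free on
normalized forms, which guarantees that a loose match always identifies the
planted entry. Documents without methods sections occur only among
non-cell-line papers (planted mentions need a methods section to live in).
RRID tokens themselves are planted clean (no corruption channel), so the
RRID route recovers its planted counts exactly.

What a green test does **not** establish: the generator emulates corpus
*statistics*, not scientific prose — real papers have richer section
structure, OCR noise in older entries, ambiguous short names, and a
recognizer trained on real context would face genuine lexical ambiguity the
template sentences avoid. Recognizer metrics of 1.0 on uncorrupted synthetic
corpora are the perfect-oracle limit used to validate the harness, not a
performance claim.

## Numerical and degenerate-input choices

* Distance threshold semantics are strict (`distance < threshold`); with
  default integer weights "below 1" means exactly 0, and the tests assert the
  equivalence *edit match ⇔ equal normalized forms* at these settings.
* Empty mention sets, empty corpora and empty RRID analysis sets yield
  zero-count summaries and `NA` rates ("undefined-rate signal"), never
  errors; genuinely unusable inputs (zero sample sizes, all-zero weights,
  fewer than 3 trend points) are usage errors.
* All randomness flows from a single integer seed per generator/evaluator
  call; derived seeds stay within 32-bit range. Identical configurations
  produce byte-identical artifact files.

## Known limitations

* The recognizer is a deliberately simple surrogate; its context channel
  only scans leftward from triggers and will miss constructions like
  "cultures of the line QX-17" where no trigger follows the name.
* The loose criterion's second reading (detected name as prefix of a lexicon
  name) is implemented but off by default; corpora where authors abbreviate
  lexicon names would need it.
* Journal-level and yearly R² figures from the original corpus depend on the
  full literature and cannot be reproduced at desk scale; the package
  reproduces their *machinery* (aggregation, trend fits) against planted
  truth instead.
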