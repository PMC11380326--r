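# Per-item accounting, the DIV statistic, rankings and the corpus crosstab.
#
# Irrelevant (I) scores are counted first and then excluded from every
# percentage denominator: an RQ item's percentage reported is 100 * Y /
# (Y + N), and RoB level percentages are taken over the scored L/U/H cells.

#' Distinctive informative value (DIV)
#'
#' `div(p) = 50 - |p - 50|` for a percentage reported `p`. The statistic is
#' maximal (50) when an element is reported in exactly half of the studies —
#' where reporting varies most and subgroup analyses are possible — and zero
#' when reporting is universal or absent. It is used only for ranking
#' reporting-quality items, never as a composite quality score.
#'
#' @param pct_reported Numeric percentage(s) in \[0, 100\]; `NA` passes
#'   through (an item with no scored assessments has no DIV).
#' @return Numeric DIV score(s) in \[0, 50\].
#' @export
#' @examples
#' div(64.6) # 35.4
#' div(c(0, 50, 100)) # 0 50 0
div <- function(pct_reported) {
  bad <- !is.na(pct_reported) & (pct_reported < 0 | pct_reported > 100)
  if (any(bad)) {
    stop("pct_reported must lie in [0, 100]; got ",
      paste(pct_reported[bad], collapse = ", "),
      call. = FALSE
    )
  }
  50 - abs(pct_reported - 50)
}

#' Summarise a score table per item
#'
#' Computes, for each instrument item over the selected studies: total,
#' irrelevant and scored assessment counts; for RQ items the number and
#' percentage reported plus the DIV (from the unrounded percentage); for RoB
#' items the low/unclear/high counts and percentages. Also returns per-kind
#' corpus totals and the population-by-design crosstab with margins.
#'
#' Items with no scored (non-irrelevant) assessments carry `NA` percentages
#' and DIV — not computable, deliberately distinct from 0.
#'
#' @param x A `robdiv_scores` object.
#' @param population,design Optional stratum filters (`"animal"`/`"human"`,
#'   `"baseline"`/`"treatment"`).
#' @return A `robdiv_summary`: list with `items` (per-item tibble), `totals`
#'   (per-kind tibble), `crosstab` (matrix with margins) and `n_studies`.
#' @export
#' @examples
#' x <- generate_scores(preset_calibrated(seed = 1))
#' s <- summarise_scores(x)
#' s$crosstab
summarise_scores <- function(x, population = NULL, design = NULL) {
  stopifnot(inherits(x, "robdiv_scores"))
  studies <- x$studies
  if (!is.null(population)) studies <- studies[studies$population %in% population, ]
  if (!is.null(design)) studies <- studies[studies$design %in% design, ]
  if (nrow(studies) == 0) {
    stop("the study selection is empty; nothing to summarise", call. = FALSE)
  }
  av <- x$assessments[x$assessments$study_id %in% studies$study_id, ]

  counts <- table(
    factor(av$item_id, levels = x$instrument$item_id),
    factor(av$value, levels = c("Y", "N", "L", "U", "H", "I"))
  )
  counts <- as.data.frame.matrix(counts)
  items <- tibble::tibble(
    item_id = x$instrument$item_id,
    kind = x$instrument$kind,
    text = x$instrument$text,
    n_total = as.integer(rowSums(counts)),
    n_irrelevant = as.integer(counts$I),
    n_scored = as.integer(rowSums(counts)) - as.integer(counts$I),
    n_reported = ifelse(x$instrument$kind == "RQ", as.integer(counts$Y), NA_integer_),
    n_low = ifelse(x$instrument$kind == "RoB", as.integer(counts$L), NA_integer_),
    n_unclear = ifelse(x$instrument$kind == "RoB", as.integer(counts$U), NA_integer_),
    n_high = ifelse(x$instrument$kind == "RoB", as.integer(counts$H), NA_integer_)
  )
  sc <- ifelse(items$n_scored > 0, items$n_scored, NA_integer_)
  items$pct_reported <- 100 * items$n_reported / sc
  items$div <- div(items$pct_reported)
  items$pct_low <- 100 * items$n_low / sc
  items$pct_unclear <- 100 * items$n_unclear / sc
  items$pct_high <- 100 * items$n_high / sc

  totals <- dplyr::summarise(
    dplyr::group_by(items, .data$kind),
    n_total = sum(.data$n_total),
    n_irrelevant = sum(.data$n_irrelevant),
    n_scored = sum(.data$n_scored),
    n_reported = sum(.data$n_reported),
    n_low = sum(.data$n_low),
    n_unclear = sum(.data$n_unclear),
    n_high = sum(.data$n_high),
    .groups = "drop"
  )

  ct <- table(
    factor(studies$population, levels = POPULATIONS),
    factor(studies$design, levels = DESIGNS)
  )
  crosstab <- stats::addmargins(ct)
  dimnames(crosstab) <- list(
    population = c(POPULATIONS, "total"),
    design = c(DESIGNS, "total")
  )

  structure(
    list(
      items = items, totals = totals, crosstab = crosstab,
      n_studies = nrow(studies),
      population = population, design = design
    ),
    class = "robdiv_summary"
  )
}

#' Rank summarised items by an informativeness key
#'
#' Stable descending order; ties are broken by instrument (topic) order.
#' RQ items rank by `pct_reported` or `div`; RoB items by `pct_low`,
#' `pct_unclear` or `pct_high`. Items whose percentage is not computable
#' (no scored assessments) are dropped from the ranking.
#'
#' @param summary A `robdiv_summary`.
#' @param key One of `"pct_reported"`, `"div"`, `"pct_low"`,
#'   `"pct_unclear"`, `"pct_high"`.
#' @param top_k Keep only the first `top_k` rows (default: all). The
#'   conventional report uses the top and bottom 5 for RQ and 3 for RoB.
#' @param decreasing Rank from the highest value down (default) or up.
#' @return Tibble of ranked item summaries.
#' @export
rank_items <- function(summary, key = c(
                         "pct_reported", "div", "pct_low",
                         "pct_unclear", "pct_high"
                       ),
                       top_k = NULL, decreasing = TRUE) {
  stopifnot(inherits(summary, "robdiv_summary"))
  key <- match.arg(key)
  kind <- if (key %in% c("pct_reported", "div")) "RQ" else "RoB"
  items <- summary$items[summary$items$kind == kind, ]
  items <- items[!is.na(items[[key]]), ]
  ord <- order(if (decreasing) -items[[key]] else items[[key]])
  items <- items[ord, ]
  if (!is.null(top_k)) items <- utils::head(items, top_k)
  items
}

#' Irrelevant-score accounting and kind-level percentages
#'
#' Condenses a `robdiv_summary` into the headline corpus figures: counts
#' and display percentages of irrelevant scores overall and per kind, the
#' fraction of scored RQ elements reported, and the fractions of scored RoB
#' elements at each level.
#'
#' @param summary A `robdiv_summary`.
#' @return A one-row tibble of corpus-level figures.
#' @export
corpus_overview <- function(summary) {
  stopifnot(inherits(summary, "robdiv_summary"))
  t <- summary$totals
  rq <- t[t$kind == "RQ", ]
  rob <- t[t$kind == "RoB", ]
  n_total <- sum(t$n_total)
  n_irr <- sum(t$n_irrelevant)
  tibble::tibble(
    n_studies = summary$n_studies,
    n_assessments = n_total,
    n_irrelevant = n_irr,
    pct_irrelevant = percent(n_irr, n_total),
    rq_n_total = rq$n_total,
    rq_n_irrelevant = rq$n_irrelevant,
    rq_pct_irrelevant = percent(rq$n_irrelevant, rq$n_total),
    rq_n_scored = rq$n_scored,
    rq_n_reported = rq$n_reported,
    rq_pct_reported = percent(rq$n_reported, rq$n_scored),
    rob_n_total = rob$n_total,
    rob_n_irrelevant = rob$n_irrelevant,
    rob_pct_irrelevant = percent(rob$n_irrelevant, rob$n_total),
    rob_n_scored = rob$n_scored,
    rob_pct_low = percent(rob$n_low, rob$n_scored),
    rob_pct_unclear = percent(rob$n_unclear, rob$n_scored),
    rob_pct_high = percent(rob$n_high, rob$n_scored)
  )
}

#' Table of RQ items at or above a DIV cut
#'
#' The display convention: percentage reported and DIV rounded half-up to
#' one decimal, sorted by DIV descending (instrument order on ties), cut at
#' `min_div` (default 10).
#'
#' @param summary A `robdiv_summary`.
#' @param min_div Minimum (displayed) DIV to keep.
#' @return Tibble with `item_id`, `text`, `pct_reported`, `div`.
#' @export
div_table <- function(summary, min_div = 10) {
  ranked <- rank_items(summary, "div")
  out <- tibble::tibble(
    item_id = ranked$item_id,
    text = ranked$text,
    pct_reported = round_half_up(ranked$pct_reported, 1),
    div = round_half_up(ranked$div, 1)
  )
  out[out$div >= min_div, ]
}

#' @export
print.robdiv_summary <- function(x, ...) {
  ov <- corpus_overview(x)
  cat("<robdiv_summary> ", ov$n_studies, " studies, ", ov$n_assessments,
    " assessments (", ov$pct_irrelevant, "% irrelevant)\n",
    sep = ""
  )
  cat(
    "  RQ : ", ov$rq_pct_reported, "% of ", ov$rq_n_scored, " scored elements reported\n",
    "  RoB: ", ov$rob_pct_low, "% low / ", ov$rob_pct_unclear, "% unclear / ",
    ov$rob_pct_high, "% high of ", ov$rob_n_scored, " scored elements\n",
    sep = ""
  )
  invisible(x)
}
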