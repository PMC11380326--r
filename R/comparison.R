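# Explorative stratified comparisons: per-item contingency tables and
# chi-square tests between animal vs human and baseline vs treatment strata.
# Irrelevant scores never enter a contingency table.

#' Per-item contingency table across a stratum variable
#'
#' Cross-tabulates one item's scored (non-irrelevant) assessments by stratum
#' level: RQ items yield a 2x2 table (Y/N), RoB items a 2x3 table (L/U/H).
#'
#' @param x A `robdiv_scores` object.
#' @param item_id One item short code.
#' @param by `"population"` (animal vs human) or `"design"` (baseline vs
#'   treatment).
#' @return A `robdiv_contingency`: the count matrix plus item metadata.
#' @export
#' @examples
#' x <- generate_scores(preset_calibrated(seed = 1))
#' contingency(x, "A14", "population")
contingency <- function(x, item_id, by = c("population", "design")) {
  stopifnot(inherits(x, "robdiv_scores"))
  by <- match.arg(by)
  idx <- match(item_id, x$instrument$item_id)
  if (is.na(idx)) stop("unknown item_id: ", item_id, call. = FALSE)
  kind <- x$instrument$kind[idx]
  levels_resp <- if (kind == "RQ") c("Y", "N") else c("L", "U", "H")
  av <- x$assessments[x$assessments$item_id == item_id & x$assessments$value != "I", ]
  stratum <- x$studies[[by]][match(av$study_id, x$studies$study_id)]
  row_levels <- if (by == "population") POPULATIONS else DESIGNS
  m <- table(
    factor(stratum, levels = row_levels),
    factor(av$value, levels = levels_resp)
  )
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty)) {
    stop("no scored assessments for item ", item_id, " in stratum level(s): ",
      paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      item_id = item_id, kind = kind, stratum_variable = by,
      counts = unclass(as.matrix(m))
    ),
    class = "robdiv_contingency"
  )
}

#' @export
print.robdiv_contingency <- function(x, ...) {
  cat("<robdiv_contingency> ", x$item_id, " (", x$kind, ") by ",
    x$stratum_variable, "\n",
    sep = ""
  )
  print(x$counts)
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Wraps `stats::chisq.test()`. With `correction = "auto"` the Yates
#' continuity correction is applied exactly when the table is 2x2 — the
#' default behaviour of that function — and never otherwise; `"on"` and
#' `"off"` force either behaviour. The smallest expected cell count is
#' reported, with a flag when it falls below 5 (where the chi-square
#' approximation is doubtful).
#'
#' @param ct A `robdiv_contingency` or a plain count matrix.
#' @param correction `"auto"`, `"on"` or `"off"`.
#' @return One-row tibble: `item_id`, `statistic`, `df`, `p`,
#'   `correction_applied`, `expected_min`, `small_expected`.
#' @export
#' @examples
#' chi_square(matrix(c(20, 10, 10, 20), 2), correction = "off") # X2 = 6.667
chi_square <- function(ct, correction = c("auto", "on", "off")) {
  correction <- match.arg(correction)
  if (inherits(ct, "robdiv_contingency")) {
    m <- ct$counts
    item_id <- ct$item_id
  } else {
    m <- as.matrix(ct)
    item_id <- NA_character_
  }
  if (any(m < 0)) stop("contingency cells must be non-negative", call. = FALSE)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("contingency table has a zero marginal", call. = FALSE)
  }
  correct <- switch(correction,
    auto = nrow(m) == 2 && ncol(m) == 2,
    on = TRUE,
    off = FALSE
  )
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  expected_min <- min(res$expected)
  tibble::tibble(
    item_id = item_id,
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p = unname(res$p.value),
    correction_applied = correct && nrow(m) == 2 && ncol(m) == 2,
    expected_min = expected_min,
    small_expected = expected_min < 5
  )
}

#' Chi-square comparison of every item across a stratum variable
#'
#' Runs [contingency()] + [chi_square()] for each instrument item. Items
#' that cannot be tested (a stratum level with no scored assessments, or a
#' degenerate table with a zero column marginal) are skipped; the skip
#' reasons are attached as the `"skipped"` attribute. No multiplicity
#' adjustment is applied by default, matching the explorative character of
#' these tests; `adjust = "BH"` adds Benjamini-Hochberg adjusted p-values.
#'
#' @param x A `robdiv_scores` object.
#' @param by `"population"` or `"design"`.
#' @param correction Passed to [chi_square()].
#' @param adjust `"none"` or `"BH"`.
#' @return Tibble of test results (one row per testable item) with a
#'   `skipped` attribute (tibble of `item_id`, `reason`).
#' @export
compare_all <- function(x, by = c("population", "design"),
                        correction = c("auto", "on", "off"),
                        adjust = c("none", "BH")) {
  stopifnot(inherits(x, "robdiv_scores"))
  by <- match.arg(by)
  correction <- match.arg(correction)
  adjust <- match.arg(adjust)
  results <- list()
  skipped <- list()
  for (item in x$instrument$item_id) {
    row <- tryCatch(
      chi_square(contingency(x, item, by), correction = correction),
      error = function(e) conditionMessage(e)
    )
    if (is.character(row)) {
      skipped[[item]] <- tibble::tibble(item_id = item, reason = row)
    } else {
      results[[item]] <- row
    }
  }
  out <- dplyr::bind_rows(results)
  if (nrow(out) && adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  }
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  attr(out, "stratum_variable") <- by
  out
}
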