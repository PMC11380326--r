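# Partial-assessment strategies: a rule-based recommender for how much of a
# review's included literature to assess (and with which elements), and a
# Monte-Carlo evaluator of how well a partial assessment estimates the
# full-corpus per-item summaries.

#' Define a partial-assessment sampling plan
#'
#' @param study_fraction Proportion of included studies to assess, in
#'   (0, 1].
#' @param min_studies Floor on the number of assessed studies (subset size
#'   is `min(N, max(min_studies, ceiling(fraction * N)))`).
#' @param element_selection `"all"` (score every item), `"high_div"` (score
#'   only items whose full-corpus DIV reaches `div_threshold`) or
#'   `"named_subset"` (score the items in `items`).
#' @param div_threshold DIV cut used by `"high_div"` (default 10, the
#'   conventional reporting cut).
#' @param items Item codes for `"named_subset"`.
#' @param tools Which source checklists the plan scores (informational).
#' @return A `robdiv_sampling_plan`.
#' @export
sampling_plan <- function(study_fraction, min_studies = 1L,
                          element_selection = c("all", "high_div", "named_subset"),
                          div_threshold = 10, items = NULL,
                          tools = c("ARRIVE", "CONSORT", "SYRCLE", "Cochrane")) {
  element_selection <- match.arg(element_selection)
  if (!is.numeric(study_fraction) || study_fraction <= 0 || study_fraction > 1) {
    stop("study_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (min_studies < 1) stop("min_studies must be at least 1", call. = FALSE)
  if (div_threshold < 0 || div_threshold > 50) {
    stop("div_threshold must lie in [0, 50]", call. = FALSE)
  }
  if (element_selection == "named_subset" && !length(items)) {
    stop("named_subset requires a non-empty items vector", call. = FALSE)
  }
  structure(
    list(
      study_fraction = study_fraction,
      min_studies = as.integer(min_studies),
      element_selection = element_selection,
      div_threshold = div_threshold,
      items = items,
      tools = tools
    ),
    class = "robdiv_sampling_plan"
  )
}

# log-linear interpolation between the two published anchors:
# reviews with <= 50 papers sample 50%, reviews with >= 1000 sample 5%
interpolate_fraction <- function(n_studies) {
  if (n_studies <= 50) {
    return(0.5)
  }
  if (n_studies >= 1000) {
    return(0.05)
  }
  exp(log(0.5) + (log(n_studies) - log(50)) / (log(1000) - log(50)) *
    (log(0.05) - log(0.5)))
}

#' Recommend a partial-assessment procedure
#'
#' Deterministic mapping from a review's size and the reviewers' interest
#' in study quality to a sampling plan, following the published decision
#' table:
#'
#' * `"guidelines"` — results will inform treatment guidelines or future
#'   experiments: assess 100% of studies with the full RoB tools.
#' * `"reporting_effects"` — demonstrating the effect of reporting measures:
#'   assess 100% of studies, restricted to high-DIV reporting elements.
#' * `"field_comparison"` — checking whether reporting in a field differs
#'   from others: random 5-50% of studies, high-DIV elements.
#' * `"all_aspects"` — general interest in all aspects of study quality:
#'   random 5-50% of studies, full RoB/RQ assessment.
#' * `"specific_aspects"` — interest in specific aspects only: random
#'   25-50% of studies, high-DIV elements.
#'
#' For the sampled interests the point fraction is interpolated
#' log-linearly between the published anchors (reviews of <= 50 papers
#' sample 50% with at least 25 studies assessed; reviews of >= 1000 sample
#' 5%), then clamped into the row's admissible range; the range endpoints
#' are returned alongside.
#'
#' @param n_studies Number of studies included in the review.
#' @param interest One of the five interest levels above.
#' @return A `robdiv_sampling_plan` with extra fields `interest`,
#'   `fraction_range` and `procedure`.
#' @export
#' @examples
#' recommend_plan(1000, "all_aspects")$study_fraction # 0.05
recommend_plan <- function(n_studies,
                           interest = c(
                             "guidelines", "reporting_effects",
                             "field_comparison", "all_aspects",
                             "specific_aspects"
                           )) {
  if (n_studies < 1) stop("n_studies must be at least 1", call. = FALSE)
  interest <- match.arg(interest)
  rows <- list(
    guidelines = list(
      range = c(1, 1), elements = "all",
      tools = c("Cochrane", "SYRCLE"),
      procedure = "Full RoB analysis of every included study"
    ),
    reporting_effects = list(
      range = c(1, 1), elements = "high_div",
      tools = c("ARRIVE", "CONSORT"),
      procedure = "All studies, restricted to elements with high DIV"
    ),
    field_comparison = list(
      range = c(0.05, 0.5), elements = "high_div",
      tools = c("ARRIVE", "CONSORT"),
      procedure = "Random subset of studies, elements with high DIV"
    ),
    all_aspects = list(
      range = c(0.05, 0.5), elements = "all",
      tools = c("Cochrane", "SYRCLE", "ARRIVE", "CONSORT"),
      procedure = "Full RoB/RQ analysis of a random subset for a crude overall picture"
    ),
    specific_aspects = list(
      range = c(0.25, 0.5), elements = "high_div",
      tools = c("Cochrane", "SYRCLE", "ARRIVE", "CONSORT"),
      procedure = "Random subset of studies, elements with high DIV"
    )
  )
  row <- rows[[interest]]
  sampled <- row$range[2] < 1
  fraction <- if (sampled) {
    min(max(interpolate_fraction(n_studies), row$range[1]), row$range[2])
  } else {
    1
  }
  plan <- sampling_plan(
    study_fraction = fraction,
    min_studies = if (sampled) min(25L, as.integer(n_studies)) else 1L,
    element_selection = row$elements,
    tools = row$tools
  )
  plan$interest <- interest
  plan$fraction_range <- row$range
  plan$procedure <- row$procedure
  plan
}

# proportional stratified allocation of m draws over stratum sizes,
# largest-remainder apportionment, every non-empty stratum gets >= 1
allocate_stratified <- function(sizes, m) {
  sizes <- sizes[sizes > 0]
  quota <- m * sizes / sum(sizes)
  base <- pmax(1L, floor(quota))
  base <- pmin(base, sizes)
  diff <- m - sum(base)
  if (diff > 0) {
    room <- sizes - base
    frac <- quota - floor(quota)
    ord <- order(-frac, -room)
    for (i in ord) {
      if (diff == 0) break
      add <- min(room[i], diff)
      base[i] <- base[i] + add
      diff <- diff - add
    }
  } else if (diff < 0) {
    ord <- order(quota - floor(quota))
    for (i in ord) {
      if (diff == 0) break
      take <- min(base[i] - 1L, -diff)
      base[i] <- base[i] - take
      diff <- diff + take
    }
  }
  base
}

#' Monte-Carlo evaluation of a sampling plan
#'
#' Repeatedly draws study subsets according to the plan (by default
#' stratified by population x design with proportional allocation, so small
#' strata are never empty), recomputes per-item summaries on each subset,
#' and compares them with the full-corpus values. For RQ items the tracked
#' metrics are the percentage reported and the DIV; for RoB items the three
#' level percentages.
#'
#' Replicates use independent substreams derived once from `seed`, so the
#' evaluation is fully reproducible and replicate order does not matter.
#'
#' @param x A `robdiv_scores` object (the full corpus).
#' @param plan A `robdiv_sampling_plan` (or a bare fraction in (0, 1]).
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param seed Integer seed.
#' @param stratified Stratified proportional subsampling (default) or
#'   simple random sampling.
#' @return A `robdiv_sampling_evaluation`: list with `metrics` (per item x
#'   metric: `truth`, `mean_est`, `bias`, `mae`, `ci_half_width`),
#'   `subset_size`, `n_replicates`, `seed`, `plan`.
#' @export
evaluate_plan <- function(x, plan, n_replicates = 500, seed = 1,
                          stratified = TRUE) {
  stopifnot(inherits(x, "robdiv_scores"))
  if (is.numeric(plan)) plan <- sampling_plan(plan)
  stopifnot(inherits(plan, "robdiv_sampling_plan"))
  full <- summarise_scores(x)

  item_ids <- switch(plan$element_selection,
    all = x$instrument$item_id,
    high_div = c(
      full$items$item_id[full$items$kind == "RQ" &
        !is.na(full$items$div) & full$items$div >= plan$div_threshold],
      full$items$item_id[full$items$kind == "RoB"]
    ),
    named_subset = plan$items
  )
  truth_long <- item_metrics_long(full$items, item_ids)

  N <- nrow(x$studies)
  m <- min(N, max(plan$min_studies, ceiling(plan$study_fraction * N)))
  if (m < 1) stop("subset size is smaller than 1 study", call. = FALSE)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  stratum <- stratum_label(x$studies$population, x$studies$design)
  sizes <- table(stratum)

  est <- matrix(NA_real_, nrow = nrow(truth_long), ncol = n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    if (m == N) {
      chosen <- x$studies$study_id
    } else if (stratified) {
      alloc <- allocate_stratified(as.integer(sizes), m)
      names(alloc) <- names(sizes)[as.integer(sizes) > 0]
      chosen <- unlist(lapply(names(alloc), function(s) {
        ids <- x$studies$study_id[stratum == s]
        ids[sample.int(length(ids), alloc[[s]])]
      }), use.names = FALSE)
    } else {
      chosen <- x$studies$study_id[sample.int(N, m)]
    }
    sub <- summarise_scores(subset_studies(x, chosen))
    est[, r] <- item_metrics_long(sub$items, item_ids)$value
  }

  err <- est - truth_long$value
  q <- t(apply(est, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  metrics <- tibble::tibble(
    item_id = truth_long$item_id,
    kind = truth_long$kind,
    metric = truth_long$metric,
    truth = truth_long$value,
    mean_est = rowMeans(est, na.rm = TRUE),
    bias = rowMeans(err, na.rm = TRUE),
    mae = rowMeans(abs(err), na.rm = TRUE),
    ci_half_width = (q[, 2] - q[, 1]) / 2
  )
  structure(
    list(
      metrics = metrics, subset_size = m, n_replicates = n_replicates,
      seed = seed, stratified = stratified, plan = plan
    ),
    class = "robdiv_sampling_evaluation"
  )
}

# long view of the tracked per-item metrics, fixed row order
item_metrics_long <- function(items, item_ids) {
  items <- items[match(item_ids, items$item_id), ]
  rq <- items[items$kind == "RQ", ]
  rob <- items[items$kind == "RoB", ]
  out <- rbind(
    data.frame(
      item_id = rq$item_id, kind = "RQ", metric = "pct_reported",
      value = rq$pct_reported, stringsAsFactors = FALSE
    ),
    data.frame(
      item_id = rq$item_id, kind = "RQ", metric = "div",
      value = rq$div, stringsAsFactors = FALSE
    ),
    data.frame(
      item_id = rob$item_id, kind = "RoB", metric = "pct_low",
      value = rob$pct_low, stringsAsFactors = FALSE
    ),
    data.frame(
      item_id = rob$item_id, kind = "RoB", metric = "pct_unclear",
      value = rob$pct_unclear, stringsAsFactors = FALSE
    ),
    data.frame(
      item_id = rob$item_id, kind = "RoB", metric = "pct_high",
      value = rob$pct_high, stringsAsFactors = FALSE
    )
  )
  tibble::as_tibble(out)
}

#' @export
print.robdiv_sampling_evaluation <- function(x, ...) {
  cat("<robdiv_sampling_evaluation> fraction ", x$plan$study_fraction,
    " -> ", x$subset_size, " studies, ", x$n_replicates, " replicates\n",
    "  mean |bias| = ", signif(mean(abs(x$metrics$bias), na.rm = TRUE), 3),
    " pp, mean MAE = ", signif(mean(x$metrics$mae, na.rm = TRUE), 3), " pp\n",
    sep = ""
  )
  invisible(x)
}
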