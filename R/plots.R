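# Figure builders: a reporting heatmap (RQ items x the four study strata,
# shaded so intermediate percentages — high DIV — get the intermediate
# shades) and an RoB traffic-light plot (stacked low/unclear/high bars per
# item and stratum). The data behind every figure is built by a pure
# function so figures are auditable and testable without rendering.

ROB_COLOURS <- c(
  low = "#1a9850", unclear = "#fee08b", high = "#d73027",
  not_computable = "grey70"
)

stratum_display <- function(stratum, sizes) {
  paste0(
    sub("_", " ", stratum), "\n(n = ", as.integer(sizes[stratum]), ")"
  )
}

per_stratum_summaries <- function(x) {
  sizes <- stats::setNames(
    as.integer(table(factor(
      stratum_label(x$studies$population, x$studies$design),
      levels = STRATA
    ))),
    STRATA
  )
  present <- STRATA[sizes > 0]
  summaries <- lapply(present, function(s) {
    summarise_scores(x,
      population = sub("_.*$", "", s),
      design = sub("^.*_", "", s)
    )
  })
  names(summaries) <- present
  list(summaries = summaries, sizes = sizes)
}

#' Data behind the reporting heatmap
#'
#' One row per RQ item x stratum with the percentage reported, its DIV and
#' a `not_computable` flag (no scored assessments in that stratum — kept
#' distinct from 0% reported). Items appear in instrument order; strata in
#' the fixed order animal baseline, human baseline, animal treatment, human
#' treatment, labelled with their study counts.
#'
#' @param x A `robdiv_scores` object.
#' @return A `robdiv_heatmap_data` tibble.
#' @export
heatmap_data <- function(x) {
  stopifnot(inherits(x, "robdiv_scores"))
  ps <- per_stratum_summaries(x)
  rows <- lapply(names(ps$summaries), function(s) {
    items <- ps$summaries[[s]]$items
    items <- items[items$kind == "RQ", ]
    tibble::tibble(
      item_id = items$item_id,
      text = items$text,
      stratum = s,
      n_studies = as.integer(ps$sizes[s]),
      n_scored = items$n_scored,
      pct_reported = items$pct_reported,
      div = items$div,
      not_computable = items$n_scored == 0
    )
  })
  out <- dplyr::bind_rows(rows)
  out$stratum <- factor(out$stratum, levels = STRATA)
  item_order <- x$instrument$item_id[x$instrument$kind == "RQ"]
  out$item_id <- factor(out$item_id, levels = rev(item_order))
  structure(out, class = c("robdiv_heatmap_data", class(out)))
}

#' Render the reporting heatmap
#'
#' Diverging shading: fully reported cells are green, fully unreported red,
#' and the intermediate shades mark high-DIV cells; not-computable cells
#' are grey, never drawn as 0%.
#'
#' @param data A `robdiv_heatmap_data` (from [heatmap_data()]), or a
#'   `robdiv_scores` object to build it from.
#' @param sort_by `"instrument"` (topic order, default) or `"div"`
#'   (pooled DIV descending).
#' @return A ggplot object.
#' @export
plot_reporting_heatmap <- function(data, sort_by = c("instrument", "div")) {
  sort_by <- match.arg(sort_by)
  if (inherits(data, "robdiv_scores")) data <- heatmap_data(data)
  if (sort_by == "div") {
    pooled <- stats::aggregate(div ~ item_id, data = data, FUN = mean, na.rm = TRUE)
    data$item_id <- factor(
      as.character(data$item_id),
      levels = pooled$item_id[order(pooled$div)]
    )
  }
  data$fill_value <- ifelse(data$not_computable, NA_real_, data$pct_reported)
  data$stratum_lab <- factor(
    stratum_display(as.character(data$stratum), table_sizes(data)),
    levels = stratum_display(STRATA, table_sizes(data))
  )
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$stratum_lab, y = .data$item_id, fill = .data$fill_value)
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(
      low = ROB_COLOURS[["high"]], mid = "#ffffbf", high = ROB_COLOURS[["low"]],
      midpoint = 50, limits = c(0, 100),
      na.value = ROB_COLOURS[["not_computable"]],
      name = "% reported"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

table_sizes <- function(data) {
  sizes <- stats::setNames(rep(0L, length(STRATA)), STRATA)
  got <- unique(data.frame(
    s = as.character(data$stratum),
    n = data$n_studies
  ))
  sizes[got$s] <- got$n
  sizes
}

#' Data behind the RoB traffic-light plot
#'
#' One row per RoB item x stratum x level with the percentage of scored
#' assessments at that level. Segments of one bar sum to 100 (up to
#' floating point) unless the cell is not computable.
#'
#' @param x A `robdiv_scores` object.
#' @return A `robdiv_rob_plot_data` tibble.
#' @export
rob_plot_data <- function(x) {
  stopifnot(inherits(x, "robdiv_scores"))
  ps <- per_stratum_summaries(x)
  rows <- lapply(names(ps$summaries), function(s) {
    items <- ps$summaries[[s]]$items
    items <- items[items$kind == "RoB", ]
    long <- tidyr::pivot_longer(
      items[c("item_id", "text", "n_scored", "pct_low", "pct_unclear", "pct_high")],
      dplyr::all_of(c("pct_low", "pct_unclear", "pct_high")),
      names_to = "level", values_to = "pct"
    )
    long$level <- sub("^pct_", "", long$level)
    long$stratum <- s
    long$n_studies <- as.integer(ps$sizes[s])
    long$not_computable <- long$n_scored == 0
    long
  })
  out <- dplyr::bind_rows(rows)
  out$stratum <- factor(out$stratum, levels = STRATA)
  out$level <- factor(out$level, levels = c("high", "unclear", "low"))
  item_order <- x$instrument$item_id[x$instrument$kind == "RoB"]
  out$item_id <- factor(out$item_id, levels = rev(item_order))
  structure(out, class = c("robdiv_rob_plot_data", class(out)))
}

#' Render the RoB traffic-light plot
#'
#' Horizontal stacked bars (green = low, yellow = unclear, red = high risk
#' of bias) per item, faceted by study stratum.
#'
#' @param data A `robdiv_rob_plot_data` (from [rob_plot_data()]), or a
#'   `robdiv_scores` object to build it from.
#' @return A ggplot object.
#' @export
plot_rob_summary <- function(data) {
  if (inherits(data, "robdiv_scores")) data <- rob_plot_data(data)
  data <- data[!data$not_computable, ]
  data$stratum_lab <- factor(
    stratum_display(as.character(data$stratum), table_sizes(data)),
    levels = stratum_display(STRATA, table_sizes(data))
  )
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$pct, y = .data$item_id, fill = .data$level)
  ) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::scale_fill_manual(
      values = c(
        low = ROB_COLOURS[["low"]], unclear = ROB_COLOURS[["unclear"]],
        high = ROB_COLOURS[["high"]]
      ),
      breaks = c("low", "unclear", "high"),
      name = "Risk of bias"
    ) +
    ggplot2::facet_wrap(~stratum_lab, nrow = 1) +
    ggplot2::labs(x = "% of scored assessments", y = NULL) +
    ggplot2::theme_minimal()
}
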