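test_that("DIV is the tent function peaking at 50% reported", {
  expect_equal(div(64.6), 35.4)
  expect_equal(div(74.4), 25.6)
  expect_equal(div(0), 0)
  expect_equal(div(100), 0)
  expect_equal(div(50), 50)
  # symmetry: div(p) == div(100 - p), range always [0, 50]
  p <- seq(0, 100, by = 0.25)
  expect_equal(div(p), div(100 - p))
  expect_true(all(div(p) >= 0 & div(p) <= 50))
  expect_error(div(101), "0, 100")
  expect_error(div(-3), "0, 100")
  expect_true(is.na(div(NA_real_)))
})

test_that("display percentages use one-decimal half-up rounding", {
  expect_equal(percent(1493, 5621), 26.6)
  expect_equal(round_half_up(26.55, 1), 26.6)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(c(12.34, 12.35, 12.36), 1), c(12.3, 12.4, 12.4))
})

test_that("per-item summaries count irrelevant first and score the rest", {
  instr <- toy_instrument()
  studies <- toy_studies(rep("animal", 4), rep("baseline", 4))
  # R1 reported in 1 of 4 studies -> 25% reported, DIV 25
  av <- toy_assessments(
    rep(studies$study_id, each = 3),
    rep(c("R1", "R2", "B1"), 4),
    c("Y", "I", "L",  "N", "N", "U",  "N", "Y", "U",  "N", "N", "H")
  )
  s <- summarise_scores(score_table(instr, studies, av))
  r1 <- s$items[s$items$item_id == "R1", ]
  expect_equal(r1$n_total, 4)
  expect_equal(r1$n_irrelevant, 0)
  expect_equal(r1$pct_reported, 25)
  expect_equal(r1$div, 25)
  r2 <- s$items[s$items$item_id == "R2", ]
  expect_equal(r2$n_irrelevant, 1)
  expect_equal(r2$n_scored, 3)
  b1 <- s$items[s$items$item_id == "B1", ]
  expect_equal(b1$n_low + b1$n_unclear + b1$n_high, b1$n_scored)
  expect_equal(b1$pct_low + b1$pct_unclear + b1$pct_high, 100, tolerance = 1e-9)
  # per-kind totals equal the sums over their items
  expect_equal(s$totals$n_total[s$totals$kind == "RQ"],
               sum(s$items$n_total[s$items$kind == "RQ"]))
  expect_equal(sum(s$items$n_irrelevant), 1)
})

test_that("a single all-reported study collapses DIV to zero", {
  instr <- toy_instrument()
  studies <- toy_studies("animal", "treatment")
  av <- toy_assessments(rep("s01", 3), c("R1", "R2", "B1"), c("Y", "Y", "L"))
  s <- summarise_scores(score_table(instr, studies, av))
  rq <- s$items[s$items$kind == "RQ", ]
  expect_true(all(rq$pct_reported == 100))
  expect_true(all(rq$div == 0))
})

test_that("items with no scored assessments report NA, not zero", {
  instr <- toy_instrument()
  studies <- toy_studies("human", "baseline") # R2 structurally inapplicable
  av <- toy_assessments(rep("s01", 2), c("R1", "B1"), c("N", "U"))
  s <- summarise_scores(score_table(instr, studies, av))
  r2 <- s$items[s$items$item_id == "R2", ]
  expect_equal(r2$n_scored, 0)
  expect_true(is.na(r2$pct_reported))
  expect_true(is.na(r2$div))
})

test_that("stratum filters partition the corpus additively", {
  x <- generate_scores(preset_calibrated(seed = 11))
  pooled <- summarise_scores(x)
  parts <- list(
    summarise_scores(x, population = "animal", design = "baseline"),
    summarise_scores(x, population = "human", design = "baseline"),
    summarise_scores(x, population = "animal", design = "treatment"),
    summarise_scores(x, population = "human", design = "treatment")
  )
  for (col in c("n_total", "n_irrelevant", "n_scored", "n_reported")) {
    part_sum <- Reduce(`+`, lapply(parts, function(p) {
      v <- p$items[[col]]
      ifelse(is.na(v), 0L, v)
    }))
    pooled_v <- pooled$items[[col]]
    expect_equal(part_sum, ifelse(is.na(pooled_v), 0L, pooled_v))
  }
  expect_error(summarise_scores(x, population = "animal", design = "nope"),
               "empty")
})

test_that("crosstab margins equal row and column sums", {
  x <- generate_scores(preset_calibrated(seed = 2))
  ct <- summarise_scores(x)$crosstab
  expect_equal(ct["total", "total"], sum(ct[1:2, 1:2]))
  expect_equal(unname(ct[, "total"][1:2]), unname(rowSums(ct[1:2, 1:2])))
  expect_equal(unname(ct["total", ][1:2]), unname(colSums(ct[1:2, 1:2])))
})

test_that("rankings are stable with instrument order breaking ties", {
  instr <- new_instrument(tibble::tibble(
    item_id = c("R1", "R2", "R3"),
    kind = "RQ",
    source_tool = "ARRIVE",
    response_domain = "YN",
    merged_from = "",
    app_animal_baseline = TRUE, app_human_baseline = TRUE,
    app_animal_treatment = TRUE, app_human_treatment = TRUE,
    text = c("a", "b", "c"),
    operationalisation = "-"
  ), name = "rank-toy")
  # 10 studies: R1 reported 1/10, R2 5/10, R3 9/10 -> DIV 10, 50, 10
  studies <- toy_studies(rep("animal", 10), rep("baseline", 10))
  vals <- c(rep("Y", 1), rep("N", 9), rep("Y", 5), rep("N", 5), rep("Y", 9), "N")
  av <- toy_assessments(
    rep(studies$study_id, times = 3),
    rep(c("R1", "R2", "R3"), each = 10),
    vals
  )
  s <- summarise_scores(score_table(instr, studies, av))
  ranked <- rank_items(s, "div")
  expect_equal(ranked$item_id, c("R2", "R1", "R3")) # tie R1/R3 by instrument order
  expect_equal(ranked$div, c(50, 10, 10))
  top1 <- rank_items(s, "pct_reported", top_k = 1)
  expect_equal(top1$item_id, "R3")
  # all equal -> ranking is the instrument order
  av_eq <- toy_assessments(
    rep(studies$study_id, times = 3),
    rep(c("R1", "R2", "R3"), each = 10),
    rep(c(rep("Y", 5), rep("N", 5)), 3)
  )
  s_eq <- summarise_scores(score_table(instr, studies, av_eq))
  expect_equal(rank_items(s_eq, "div")$item_id, c("R1", "R2", "R3"))
})

test_that("a summary calibrated to the published percentages ranks the published top five", {
  # deterministic: build an exact-percentage corpus summary via counts out of 1000
  instr <- default_instrument()
  pooled <- readr::read_csv(
    system.file("extdata", "preset_calibrated.csv", package = "robdiv"),
    show_col_types = FALSE
  )
  rq <- pooled[!is.na(pooled$p_y), ]
  studies <- toy_studies(rep("animal", 1000), rep("treatment", 1000))
  av <- do.call(rbind, lapply(seq_len(nrow(instr)), function(i) {
    id <- instr$item_id[i]
    if (instr$kind[i] == "RoB") {
      value <- rep("U", 1000)
    } else {
      n_y <- round(1000 * rq$p_y[match(id, rq$item_id)])
      value <- c(rep("Y", n_y), rep("N", 1000 - n_y))
    }
    tibble::tibble(study_id = studies$study_id, item_id = id, value = value)
  }))
  s <- summarise_scores(score_table(instr, studies, av))
  top5 <- rank_items(s, "div", top_k = 5)
  expect_setequal(
    top5$item_id,
    c("A14", "A21a", "A17b", "C15", "A1b") # ethics, conflicts, limitations,
  ) #                                         baseline values, unit of analysis
})

test_that("the DIV table applies the display cut", {
  x <- generate_scores(preset_calibrated(seed = 5))
  s <- summarise_scores(x)
  tab <- div_table(s, min_div = 10)
  expect_true(all(tab$div >= 10))
  expect_true(all(diff(tab$div) <= 0))
  # displayed DIV derives from the unrounded percentage, rounded once
  src <- summarise_scores(x)$items
  expect_equal(tab$div,
               round_half_up(src$div[match(tab$item_id, src$item_id)], 1))
})
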