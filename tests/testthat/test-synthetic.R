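test_that("the default preset emulates the corpus dimensions", {
  x <- generate_scores(preset_calibrated(seed = 1))
  expect_equal(n_studies(x), 164)
  expect_equal(n_assessments(x), 7872)
  ct <- summarise_scores(x)$crosstab
  expect_equal(unname(ct["animal", "total"]), 78)
  expect_equal(unname(ct["human", "total"]), 86)
  expect_equal(unname(ct["total", "baseline"]), 130)
  expect_equal(unname(ct["total", "treatment"]), 34)
  # some manuscripts describe a study in each review arm
  expect_lt(length(unique(x$studies$manuscript_id)), 164)
  expect_true(all(x$studies$year >= 1981 & x$studies$year <= 2020))
})

test_that("generated corpora always pass validation with a fixed irrelevant count", {
  # structural irrelevance is deterministic: sum of inapplicable cells over
  # the default applicability map and stratum sizes
  instr <- default_instrument()
  sizes <- c(animal_baseline = 56, human_baseline = 74,
             animal_treatment = 22, human_treatment = 12)
  app <- sapply(names(sizes), function(s) {
    applicable(instr, instr$item_id,
               sub("_.*$", "", s), sub("^.*_", "", s))
  })
  expected_irr <- sum((!app) %*% sizes)
  for (seed in c(2, 3)) {
    x <- generate_scores(preset_calibrated(seed = seed))
    expect_equal(sum(x$assessments$value == "I"), expected_irr)
  }
  expect_equal(expected_irr, 882) # derivable from the bundled applicability map
})

test_that("degenerate probabilities generate deterministic cells", {
  instr <- default_instrument()
  probs <- tidyr::expand_grid(
    tibble::tibble(
      item_id = instr$item_id,
      p_y = ifelse(instr$kind == "RQ", 1, NA_real_),
      p_l = ifelse(instr$kind == "RoB", 0, NA_real_),
      p_u = ifelse(instr$kind == "RoB", 1, NA_real_),
      p_h = ifelse(instr$kind == "RoB", 0, NA_real_)
    ),
    stratum = c("animal_baseline", "human_baseline",
                "animal_treatment", "human_treatment")
  )
  x <- generate_scores(generator_config(probs, instrument = instr), seed = 5)
  av <- x$assessments
  kind <- instr$kind[match(av$item_id, instr$item_id)]
  expect_true(all(av$value[kind == "RQ" & av$value != "I"] == "Y"))
  expect_true(all(av$value[kind == "RoB" & av$value != "I"] == "U"))
})

test_that("identical seeds give byte-identical corpora", {
  cfg <- preset_calibrated()
  a <- generate_scores(cfg, seed = 123)
  b <- generate_scores(cfg, seed = 123)
  expect_identical(a$assessments, b$assessments)
  expect_identical(a$studies, b$studies)
  c <- generate_scores(cfg, seed = 124)
  expect_false(identical(a$assessments, c$assessments))
})

test_that("configurations reject invalid probabilities", {
  instr <- toy_instrument()
  good <- tidyr::expand_grid(
    tibble::tibble(
      item_id = c("R1", "R2", "B1"),
      p_y = c(0.5, 0.2, NA),
      p_l = c(NA, NA, 0.2), p_u = c(NA, NA, 0.5), p_h = c(NA, NA, 0.3)
    ),
    stratum = c("animal_baseline", "human_baseline",
                "animal_treatment", "human_treatment")
  )
  expect_s3_class(generator_config(good, instrument = instr),
                  "robdiv_generator_config")
  bad_simplex <- good
  bad_simplex$p_l[bad_simplex$item_id == "B1"] <- 0.9 # sums to 1.7
  expect_error(generator_config(bad_simplex, instrument = instr), "simplex")
  bad_p <- good
  bad_p$p_y[1] <- 1.2
  expect_error(generator_config(bad_p, instrument = instr), "p_y")
  incomplete <- good[good$item_id != "B1", ]
  expect_error(generator_config(incomplete, instrument = instr), "missing item")
})

test_that("raising P(Y) never lowers the expected reporting percentage", {
  instr <- toy_instrument()
  make_cfg <- function(p) {
    generator_config(
      tidyr::expand_grid(
        tibble::tibble(
          item_id = c("R1", "R2", "B1"),
          p_y = c(p, 0.5, NA),
          p_l = c(NA, NA, 1 / 3), p_u = c(NA, NA, 1 / 3), p_h = c(NA, NA, 1 / 3)
        ),
        stratum = c("animal_baseline", "human_baseline",
                    "animal_treatment", "human_treatment")
      ),
      instrument = instr
    )
  }
  for (pair in list(c(0.2, 0.5), c(0.5, 0.8))) {
    lo <- mean(vapply(1:8, function(s) {
      x <- generate_scores(make_cfg(pair[1]), seed = s)
      s1 <- summarise_scores(x)
      s1$items$pct_reported[s1$items$item_id == "R1"]
    }, numeric(1)))
    hi <- mean(vapply(1:8, function(s) {
      x <- generate_scores(make_cfg(pair[2]), seed = s)
      s1 <- summarise_scores(x)
      s1$items$pct_reported[s1$items$item_id == "R1"]
    }, numeric(1)))
    expect_gt(hi, lo)
  }
})

test_that("recovery is exact for degenerate probabilities", {
  instr <- toy_instrument()
  cfg <- generator_config(
    tidyr::expand_grid(
      tibble::tibble(
        item_id = c("R1", "R2", "B1"),
        p_y = c(0, 1, NA),
        p_l = c(NA, NA, 0), p_u = c(NA, NA, 1), p_h = c(NA, NA, 0)
      ),
      stratum = c("animal_baseline", "human_baseline",
                  "animal_treatment", "human_treatment")
    ),
    instrument = instr,
    stratum_sizes = c(animal_baseline = 10, human_baseline = 10,
                      animal_treatment = 5, human_treatment = 5)
  )
  rec <- recover_params(cfg, n_corpora = 10, seed = 8)
  r1 <- rec$cells[rec$cells$item_id == "R1", ]
  expect_true(all(r1$mean_est == 0))
  expect_true(all(r1$abs_dev == 0))
  u <- rec$cells[rec$cells$item_id == "B1" & rec$cells$level == "U", ]
  expect_true(all(u$mean_est == 100))
})

test_that("recovery of a fair coin sits within binomial sampling error", {
  instr <- toy_instrument()
  cfg <- generator_config(
    tidyr::expand_grid(
      tibble::tibble(
        item_id = c("R1", "R2", "B1"),
        p_y = c(0.5, 0.5, NA),
        p_l = c(NA, NA, 0.1), p_u = c(NA, NA, 0.8), p_h = c(NA, NA, 0.1)
      ),
      stratum = c("animal_baseline", "human_baseline",
                  "animal_treatment", "human_treatment")
    ),
    instrument = instr,
    stratum_sizes = c(animal_baseline = 0, human_baseline = 74,
                      animal_treatment = 0, human_treatment = 0)
  )
  rec <- recover_params(cfg, n_corpora = 200, seed = 17)
  r1 <- rec$cells[rec$cells$item_id == "R1" & rec$cells$stratum == "human_baseline", ]
  se_mean <- 100 * sqrt(0.25 / 74) / sqrt(200)
  expect_lt(abs(r1$mean_est - 50), 3 * se_mean)
  # multinomial levels of the RoB item likewise
  for (lev in c("L", "U", "H")) {
    cell <- rec$cells[rec$cells$item_id == "B1" & rec$cells$level == lev &
                        rec$cells$stratum == "human_baseline", ]
    p <- cell$truth_pct / 100
    se <- 100 * sqrt(p * (1 - p) / 74) / sqrt(200)
    expect_lt(abs(cell$mean_est - cell$truth_pct), 3 * se)
  }
})
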