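# Fixture builders and independent oracles shared across the suite.

# minimal 3-item instrument: two RQ items (one with an irrelevant-capable
# domain and a stratum restriction) and one RoB item
toy_instrument <- function() {
  new_instrument(tibble::tibble(
    item_id = c("R1", "R2", "B1"),
    kind = c("RQ", "RQ", "RoB"),
    source_tool = c("ARRIVE", "CONSORT", "SYRCLE"),
    response_domain = c("YN", "YNI", "LUH"),
    merged_from = c("", "", ""),
    app_animal_baseline = c(TRUE, TRUE, TRUE),
    app_human_baseline = c(TRUE, FALSE, TRUE),
    app_animal_treatment = c(TRUE, TRUE, TRUE),
    app_human_treatment = c(TRUE, TRUE, TRUE),
    text = c("toy one", "toy two", "toy bias"),
    operationalisation = c("-", "-", "-")
  ), name = "toy")
}

toy_studies <- function(population, design) {
  n <- length(population)
  tibble::tibble(
    study_id = sprintf("s%02d", seq_len(n)),
    manuscript_id = sprintf("m%02d", seq_len(n)),
    population = population,
    design = design,
    year = 2000L + seq_len(n)
  )
}

toy_assessments <- function(study_ids, item_ids, values) {
  tibble::tibble(study_id = study_ids, item_id = item_ids, value = values)
}

# independent chi-square oracle: expected counts from the margins,
# plain Pearson sum (no continuity correction)
chisq_bruteforce <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Yates-corrected 2x2 closed form (correction capped so the statistic
# cannot go negative)
chisq_yates_closed <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  num <- max(0, abs(a * d - b * c) - n / 2)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

random_table <- function(nrow, ncol, max_count = 30) {
  repeat {
    m <- matrix(sample.int(max_count, nrow * ncol, replace = TRUE), nrow)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      return(m)
    }
  }
}

# the published DIV table: percentage reported -> DIV, one row per element
published_div_rows <- function() {
  tibble::tibble(
    pct = c(64.6, 34.8, 29.3, 26.2, 26.2, 74.4, 23.9, 81.1, 83.5, 15.9,
            15.2, 86.0, 12.8, 12.3, 12.2, 10.4),
    div = c(35.4, 34.8, 29.3, 26.2, 26.2, 25.6, 23.9, 18.9, 16.5, 15.9,
            15.2, 14.0, 12.8, 12.3, 12.2, 10.4)
  )
}
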