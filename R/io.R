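# Score-table ingestion and validation.
#
# The canonical on-disk layout is long format (study_id, item_id, value,
# note); wide format (one column per item short code, as deposited exports
# tend to be) is supported read-only. Free-text response tokens from
# different extractors are harmonised to the canonical single letters before
# validation.

#' Harmonise raw response tokens
#'
#' Maps extractor spellings to the canonical single-letter tokens:
#' `Y` (reported), `N` (not reported), `I` (irrelevant), `L` (low),
#' `U` (unclear), `H` (high). Matching is case-insensitive and
#' whitespace-trimmed; the mapping is idempotent.
#'
#' @param raw Character vector of raw tokens.
#' @return Character vector of canonical tokens.
#' @export
#' @examples
#' harmonise_tokens(c(" Low ", "YES", "n/a")) # "L" "Y" "I"
harmonise_tokens <- function(raw) {
  key <- tolower(trimws(raw))
  map <- c(
    y = "Y", yes = "Y", reported = "Y",
    n = "N", no = "N", "not reported" = "N", unreported = "N",
    i = "I", irrelevant = "I", "n/a" = "I", na = "I", "not applicable" = "I",
    l = "L", low = "L",
    u = "U", unclear = "U",
    h = "H", high = "H"
  )
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    stop("cannot harmonise response token(s): ",
      paste(sprintf("'%s'", bad), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Read a study-metadata table
#'
#' @param path CSV with columns `study_id`, `manuscript_id`, `population`
#'   (`animal`/`human`), `design` (`baseline`/`treatment`) and optionally
#'   `year`.
#' @param delim Field delimiter; `NULL` auto-detects comma vs semicolon.
#' @return A validated tibble of study records.
#' @export
read_studies <- function(path, delim = NULL) {
  studies <- read_delim_auto(path, delim)
  validate_studies(studies)
}

validate_studies <- function(studies) {
  studies <- tibble::as_tibble(studies)
  required <- c("study_id", "manuscript_id", "population", "design")
  missing <- setdiff(required, names(studies))
  if (length(missing)) {
    stop("studies table is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"year" %in% names(studies)) studies$year <- NA_integer_
  studies$study_id <- as.character(studies$study_id)
  studies$manuscript_id <- as.character(studies$manuscript_id)
  studies$population <- tolower(trimws(studies$population))
  studies$design <- tolower(trimws(studies$design))
  if (anyDuplicated(studies$study_id)) {
    dup <- unique(studies$study_id[duplicated(studies$study_id)])
    stop("duplicate study_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_pop <- setdiff(unique(studies$population), POPULATIONS)
  bad_des <- setdiff(unique(studies$design), DESIGNS)
  if (length(bad_pop) || length(bad_des)) {
    stop("invalid population/design value(s): ",
      paste(c(bad_pop, bad_des), collapse = ", "),
      call. = FALSE
    )
  }
  studies[c("study_id", "manuscript_id", "population", "design", "year")]
}

read_delim_auto <- function(path, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (!grepl(",", header) && grepl(";", header)) ";" else ","
  }
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE
  )
}

#' Load and validate a score table
#'
#' Reads assessments in long format (`study_id`, `item_id`, `value`,
#' optional `note`) or wide format (`study_id` plus one column per item
#' short code), harmonises tokens, materialises structurally inapplicable
#' cells as `I`, and validates the result against the instrument.
#'
#' Validation errors (with cell coordinates) are raised for: unknown item
#' codes, values outside an item's response domain, conflicting duplicate
#' rows, and missing cells for applicable items — a missing cell is never
#' silently treated as irrelevant.
#'
#' @param scores_path Path to the scores CSV.
#' @param studies_path Path to the study-metadata CSV (see [read_studies()]).
#' @param instrument A `robdiv_instrument` (default: bundled instrument).
#' @param format `"auto"`, `"long"` or `"wide"`.
#' @param delim Field delimiter; `NULL` auto-detects comma vs semicolon.
#' @return A `robdiv_scores` object (see [score_table()]).
#' @export
load_scores <- function(scores_path, studies_path, instrument = default_instrument(),
                        format = c("auto", "long", "wide"), delim = NULL) {
  format <- match.arg(format)
  studies <- read_studies(studies_path, delim)
  raw <- read_delim_auto(scores_path, delim)
  long_cols <- c("study_id", "item_id", "value")
  if (format == "auto") {
    format <- if (all(long_cols %in% names(raw))) "long" else "wide"
  }
  if (format == "long") {
    missing <- setdiff(long_cols, names(raw))
    if (length(missing)) {
      stop("long-format scores file is missing columns: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    assessments <- tibble::tibble(
      study_id = as.character(raw$study_id),
      item_id = as.character(raw$item_id),
      value = harmonise_tokens(raw$value),
      note = if ("note" %in% names(raw)) as.character(raw$note) else NA_character_
    )
  } else {
    assessments <- pivot_wide_scores(raw, instrument)
  }
  score_table(instrument, studies, assessments)
}

# wide layout: one line per study, one column per short code
pivot_wide_scores <- function(raw, instrument) {
  if (!"study_id" %in% names(raw)) {
    stop("wide-format scores file must have a study_id column", call. = FALSE)
  }
  value_cols <- setdiff(names(raw), "study_id")
  # headers matched against item codes case-insensitively, whitespace-trimmed
  matched <- instrument$item_id[match(
    tolower(trimws(value_cols)),
    tolower(instrument$item_id)
  )]
  if (anyNA(matched)) {
    stop("wide-format column(s) match no instrument item: ",
      paste(value_cols[is.na(matched)], collapse = ", "),
      call. = FALSE
    )
  }
  names(raw)[match(value_cols, names(raw))] <- matched
  long <- tidyr::pivot_longer(raw, -"study_id",
    names_to = "item_id", values_to = "value",
    values_transform = as.character
  )
  tibble::tibble(
    study_id = as.character(long$study_id),
    item_id = long$item_id,
    value = harmonise_tokens(long$value),
    note = NA_character_
  )
}

#' Assemble a validated score table
#'
#' The central container of the package: an instrument, a set of study
#' records and one assessment per (study, item) cell. During normalisation
#' every structurally inapplicable cell (per the instrument's applicability
#' map) is materialised with value `I`, so the dense accounting
#' `n_assessments = n_items * n_studies` always holds.
#'
#' @param instrument A `robdiv_instrument`.
#' @param studies Study-metadata tibble (see [read_studies()]).
#' @param assessments Tibble with `study_id`, `item_id`, `value` and
#'   optionally `note`; cells for inapplicable pairs may be omitted.
#' @param validate Set to `FALSE` only for internally pre-validated input.
#' @return A `robdiv_scores` object: `list(instrument, studies, assessments)`.
#' @export
score_table <- function(instrument, studies, assessments, validate = TRUE) {
  studies <- validate_studies(studies)
  assessments <- tibble::as_tibble(assessments)
  if (!"note" %in% names(assessments)) assessments$note <- NA_character_
  assessments <- assessments[c("study_id", "item_id", "value", "note")]
  if (validate) {
    assessments <- normalise_assessments(instrument, studies, assessments)
  }
  structure(
    list(instrument = instrument, studies = studies, assessments = assessments),
    class = "robdiv_scores"
  )
}

normalise_assessments <- function(instrument, studies, assessments) {
  unknown_items <- setdiff(unique(assessments$item_id), instrument$item_id)
  if (length(unknown_items)) {
    stop("unknown item_id in scores: ", paste(unknown_items, collapse = ", "),
      call. = FALSE
    )
  }
  unknown_studies <- setdiff(unique(assessments$study_id), studies$study_id)
  if (length(unknown_studies)) {
    stop("scores reference unknown study_id: ",
      paste(unknown_studies, collapse = ", "),
      call. = FALSE
    )
  }
  key <- paste(assessments$study_id, assessments$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    conflict <- tapply(assessments$value[dup], key[dup], function(v) length(unique(v)) > 1)
    if (any(conflict)) {
      cells <- sub("\r", " x ", names(conflict)[conflict])
      stop("conflicting duplicate assessments for cell(s): ",
        paste(cells, collapse = "; "),
        call. = FALSE
      )
    }
    assessments <- assessments[!duplicated(key), ]
    key <- key[!duplicated(key)]
  }
  # dense grid in instrument-within-study order
  grid <- tibble::tibble(
    study_id = rep(studies$study_id, each = nrow(instrument)),
    item_id = rep(instrument$item_id, times = nrow(studies))
  )
  gkey <- paste(grid$study_id, grid$item_id, sep = "\r")
  pos <- match(gkey, key)
  grid$value <- assessments$value[pos]
  grid$note <- assessments$note[pos]

  app <- applicability_map(instrument)
  stratum <- stratum_label(studies$population, studies$design)
  grid_app <- app[cbind(
    match(grid$item_id, rownames(app)),
    match(rep(stratum, each = nrow(instrument)), colnames(app))
  )]

  missing_app <- is.na(grid$value) & grid_app
  if (any(missing_app)) {
    cells <- paste(grid$study_id[missing_app], grid$item_id[missing_app], sep = " x ")
    stop("missing assessment for applicable cell(s): ",
      paste(utils::head(cells, 20), collapse = "; "),
      if (sum(missing_app) > 20) sprintf(" ... (%d total)", sum(missing_app)) else "",
      call. = FALSE
    )
  }
  # inapplicable cells: absent rows become I; recorded values must be I
  inapp_bad <- !grid_app & !is.na(grid$value) & grid$value != "I"
  if (any(inapp_bad)) {
    cells <- paste(grid$study_id[inapp_bad], grid$item_id[inapp_bad], sep = " x ")
    stop("non-irrelevant value recorded for structurally inapplicable cell(s): ",
      paste(utils::head(cells, 20), collapse = "; "),
      call. = FALSE
    )
  }
  grid$value[is.na(grid$value)] <- "I"

  # domain check on applicable cells (I additionally allowed where the
  # domain carries it; never allowed for plain YN / LUH applicable cells)
  domain_of <- stats::setNames(instrument$response_domain, instrument$item_id)
  valid_pairs <- unlist(lapply(names(RESPONSE_DOMAINS), function(d) {
    paste(d, RESPONSE_DOMAINS[[d]])
  }))
  ok <- paste(domain_of[grid$item_id], grid$value) %in% valid_pairs | !grid_app
  if (!all(ok)) {
    cells <- paste0(
      grid$study_id[!ok], " x ", grid$item_id[!ok], " = '", grid$value[!ok], "'"
    )
    stop("value outside the item's response domain: ",
      paste(utils::head(cells, 20), collapse = "; "),
      call. = FALSE
    )
  }
  grid
}

#' Write a score table to long-format CSV files
#'
#' @param x A `robdiv_scores` object.
#' @param scores_path,studies_path Output CSV paths.
#' @return `scores_path`, invisibly.
#' @export
write_scores <- function(x, scores_path, studies_path) {
  stopifnot(inherits(x, "robdiv_scores"))
  readr::write_csv(x$assessments, scores_path, progress = FALSE, na = "")
  readr::write_csv(x$studies, studies_path, progress = FALSE, na = "")
  invisible(scores_path)
}

#' Merge two score tables extracted with the same instrument
#'
#' Used to combine separately extracted projects (e.g. the baseline-arm and
#' treatment-arm extractions of one review) into a single corpus. Studies
#' assessed in both arms must already carry distinct study ids.
#'
#' @param a,b `robdiv_scores` objects sharing an identical instrument and
#'   disjoint study ids.
#' @return A merged, re-validated `robdiv_scores`.
#' @export
merge_projects <- function(a, b) {
  stopifnot(inherits(a, "robdiv_scores"), inherits(b, "robdiv_scores"))
  if (!identical(
    tibble::as_tibble(a$instrument),
    tibble::as_tibble(b$instrument)
  )) {
    stop("cannot merge: the two score tables use different instruments", call. = FALSE)
  }
  shared <- intersect(a$studies$study_id, b$studies$study_id)
  if (length(shared)) {
    stop("cannot merge: shared study_id(s): ", paste(shared, collapse = ", "),
      call. = FALSE
    )
  }
  score_table(
    a$instrument,
    dplyr::bind_rows(a$studies, b$studies),
    dplyr::bind_rows(a$assessments, b$assessments)
  )
}

#' Number of studies / assessments in a score table
#'
#' @param x A `robdiv_scores` object.
#' @return Integer count.
#' @export
n_studies <- function(x) nrow(x$studies)

#' @rdname n_studies
#' @export
n_assessments <- function(x) nrow(x$assessments)

#' @export
print.robdiv_scores <- function(x, ...) {
  cat("<robdiv_scores> ", nrow(x$studies), " studies x ", nrow(x$instrument),
    " items = ", nrow(x$assessments), " assessments\n",
    sep = ""
  )
  tab <- table(x$studies$population, x$studies$design)
  print(tab)
  invisible(x)
}

# restrict a validated table to a subset of studies (no re-validation needed)
subset_studies <- function(x, study_ids) {
  structure(
    list(
      instrument = x$instrument,
      studies = x$studies[x$studies$study_id %in% study_ids, ],
      assessments = x$assessments[x$assessments$study_id %in% study_ids, ]
    ),
    class = "robdiv_scores"
  )
}
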