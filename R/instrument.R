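# The merged 48-item assessment instrument.
#
# The default instrument combines reporting-quality (RQ) items from the ARRIVE
# and CONSORT checklists with risk-of-bias (RoB) items from SYRCLE's tool
# (which itself subsumes the Cochrane RoB items for this corpus). Each item
# carries a short code whose leading letter names the source tool (A = ARRIVE,
# C = CONSORT, S = SYRCLE). Duplicate questions across tools were merged; the
# absorbed codes are tracked in `merged_from`. Where a source table listed
# several merge targets for one absorbed code, the code is recorded under the
# first-listed surviving item so every absorbed code has exactly one home.

#' Load an assessment instrument from a CSV definition
#'
#' Reads a flat instrument definition (one row per item) and validates it.
#' The expected columns are `item_id`, `kind` (`RQ` or `RoB`), `source_tool`,
#' `response_domain` (`YN`, `YNI`, `LUH`, `LUHI`), `merged_from`
#' (semicolon-joined absorbed codes, possibly empty), four logical
#' applicability columns `app_animal_baseline`, `app_human_baseline`,
#' `app_animal_treatment`, `app_human_treatment`, plus free-text `text` and
#' `operationalisation`. Row order is preserved and defines the instrument
#' (topic) order used for display and tie-breaking.
#'
#' @param path Path to the CSV file. Defaults to the bundled instrument.
#' @param name,version Instrument metadata strings.
#' @return A `robdiv_instrument`: a tibble of items with metadata attributes.
#' @export
#' @examples
#' instr <- default_instrument()
#' nrow(instr) # 48
#' table(instr$kind)
load_instrument <- function(path = NULL,
                            name = "merged-arrive-consort-syrcle",
                            version = "1") {
  path <- path %||% system.file("extdata", "instrument_default.csv",
    package = "robdiv", mustWork = TRUE
  )
  items <- readr::read_csv(
    path,
    col_types = readr::cols(
      item_id = readr::col_character(),
      kind = readr::col_character(),
      source_tool = readr::col_character(),
      response_domain = readr::col_character(),
      merged_from = readr::col_character(),
      app_animal_baseline = readr::col_logical(),
      app_human_baseline = readr::col_logical(),
      app_animal_treatment = readr::col_logical(),
      app_human_treatment = readr::col_logical(),
      text = readr::col_character(),
      operationalisation = readr::col_character()
    ),
    progress = FALSE
  )
  items$merged_from <- ifelse(is.na(items$merged_from), "", items$merged_from)
  new_instrument(items, name = name, version = version)
}

#' @rdname load_instrument
#' @export
default_instrument <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_instrument()
    cache
  }
})

#' Construct and validate an instrument from an item table
#'
#' @param items Tibble/data.frame of items (see [load_instrument()] for the
#'   column contract).
#' @param name,version Metadata strings.
#' @return A validated `robdiv_instrument`.
#' @export
new_instrument <- function(items, name = "custom", version = "1") {
  items <- tibble::as_tibble(items)
  required <- c(
    "item_id", "kind", "source_tool", "response_domain", "merged_from",
    paste0("app_", STRATA), "text", "operationalisation"
  )
  missing <- setdiff(required, names(items))
  if (length(missing)) {
    stop("instrument definition is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- structure(items,
    class = c("robdiv_instrument", class(tibble::tibble()))
  )
  attr(out, "name") <- name
  attr(out, "version") <- version
  validate_instrument(out)
  out
}

validate_instrument <- function(instrument) {
  items <- instrument
  if (anyDuplicated(items$item_id)) {
    dup <- unique(items$item_id[duplicated(items$item_id)])
    stop("duplicate item_id in instrument: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_domain <- setdiff(unique(items$response_domain), names(RESPONSE_DOMAINS))
  if (length(bad_domain)) {
    stop("unknown response_domain token: ", paste(bad_domain, collapse = ", "), call. = FALSE)
  }
  bad_kind <- setdiff(unique(items$kind), c("RQ", "RoB"))
  if (length(bad_kind)) {
    stop("unknown kind: ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  # kind and response domain must agree: RQ <-> Y/N(-I), RoB <-> L/U/H(-I)
  rq_dom <- items$response_domain %in% c("YN", "YNI")
  mismatch <- items$item_id[(items$kind == "RQ") != rq_dom]
  if (length(mismatch)) {
    stop("kind/response_domain mismatch for: ", paste(mismatch, collapse = ", "), call. = FALSE)
  }
  absorbed <- unlist(strsplit(items$merged_from[items$merged_from != ""], ";"),
    use.names = FALSE
  )
  twice <- unique(absorbed[duplicated(absorbed)])
  # a code absorbed twice by the SAME item (e.g. two sub-letters) is fine;
  # absorption by two different items is not
  per_item <- strsplit(items$merged_from, ";")
  homes <- rep(items$item_id, lengths(per_item))
  codes <- unlist(per_item, use.names = FALSE)
  keep <- codes != ""
  homes <- homes[keep]
  codes <- codes[keep]
  multi_home <- tapply(homes, codes, function(h) length(unique(h)))
  bad <- names(multi_home)[multi_home > 1]
  if (length(bad)) {
    stop("absorbed code(s) listed under more than one item: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  self <- intersect(codes, items$item_id)
  if (length(self)) {
    stop("absorbed code(s) are themselves item_ids: ", paste(self, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(instrument)
}

#' Write an instrument definition back to CSV
#'
#' @param instrument A `robdiv_instrument`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instrument, path) {
  readr::write_csv(tibble::as_tibble(instrument), path, progress = FALSE)
  invisible(path)
}

#' Is an item applicable to a study stratum?
#'
#' Encodes the stratum-level applicability notes of the instrument: e.g.
#' animal-housing items are never scored for human studies and
#' randomisation-procedure items are irrelevant for studies without an
#' intervention. Per-study idiosyncratic irrelevance (a study with a single
#' prespecified analysis, say) is expressed by an extractor recording the
#' value `I`, not by this predicate.
#'
#' @param instrument A `robdiv_instrument`.
#' @param item_id Item short code(s).
#' @param population `"animal"` or `"human"` (recycled against `item_id`).
#' @param design `"baseline"` or `"treatment"`.
#' @return Logical vector: can the item be scored at all in that stratum?
#' @export
#' @examples
#' instr <- default_instrument()
#' applicable(instr, "S4", "human", "baseline") # FALSE: housing, human study
#' applicable(instr, "A1a", "human", "baseline") # TRUE: no restriction
applicable <- function(instrument, item_id, population, design) {
  if (!all(population %in% POPULATIONS)) {
    stop("population must be one of: ", paste(POPULATIONS, collapse = ", "), call. = FALSE)
  }
  if (!all(design %in% DESIGNS)) {
    stop("design must be one of: ", paste(DESIGNS, collapse = ", "), call. = FALSE)
  }
  idx <- match(item_id, instrument$item_id)
  if (anyNA(idx)) {
    stop("unknown item_id: ", paste(unique(item_id[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  n <- max(length(item_id), length(population), length(design))
  idx <- rep_len(idx, n)
  col <- paste0("app_", stratum_label(rep_len(population, n), rep_len(design, n)))
  app <- as.matrix(instrument[, paste0("app_", STRATA)])
  app[cbind(idx, match(col, colnames(app)))]
}

# applicability matrix: items x strata (logical), used by normalisation
applicability_map <- function(instrument) {
  m <- as.matrix(instrument[, paste0("app_", STRATA)])
  rownames(m) <- instrument$item_id
  colnames(m) <- STRATA
  m
}

#' @export
print.robdiv_instrument <- function(x, ...) {
  cat(
    "<robdiv_instrument> ", attr(x, "name"), " v", attr(x, "version"), ": ",
    nrow(x), " items (", sum(x$kind == "RQ"), " RQ, ", sum(x$kind == "RoB"),
    " RoB)\n",
    sep = ""
  )
  NextMethod()
}
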