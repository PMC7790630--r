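#' Refinement configuration
#'
#' Settings for the three dataset refinement rules applied before web
#' construction: austral-summer-only (winter months April--October excluded),
#' Southern-Ocean-only (south of 40 degrees S, plus explicit manual
#' exclusions for coastal records), and taxon quality (nonliving items and
#' taxa too coarse to place, such as "Fish", dropped together with their
#' links).
#'
#' The manual geographic and taxonomic judgements of the original database
#' curation cannot be recomputed from a record alone, so they are carried as
#' explicit configuration lists (`excluded_records`, `excluded_taxa`),
#' keeping the manual step reproducible.
#'
#' @param retained_months integer months kept by the season filter; default
#'   the austral summer months November--March.
#' @param latitude_max records must have latitude <= this (degrees; default
#'   -40, i.e. south of 40S).
#' @param excluded_taxa character vector of taxon names to drop (either role).
#' @param excluded_records character vector of record_ids to drop manually.
#' @param drop_missing_month logical; drop records whose collection month is
#'   unknown (default TRUE: season cannot be certified).
#' @return an object of class `refinement_config`.
#' @export
refinement_config <- function(retained_months = c(11L, 12L, 1L, 2L, 3L),
                              latitude_max = -40,
                              excluded_taxa = character(),
                              excluded_records = character(),
                              drop_missing_month = TRUE) {
  retained_months <- as.integer(retained_months)
  if (!all(retained_months %in% 1:12)) {
    stop("retained_months must be a subset of 1..12")
  }
  structure(
    list(retained_months = retained_months,
         latitude_max = latitude_max,
         excluded_taxa = as.character(excluded_taxa),
         excluded_records = as.character(excluded_records),
         drop_missing_month = isTRUE(drop_missing_month)),
    class = "refinement_config"
  )
}

#' Season filter
#'
#' Keeps records collected in the retained (summer) months. Records with an
#' unknown month are dropped when `drop_missing_month` is set.
#'
#' @param records validated records data.frame.
#' @param config a [refinement_config()].
#' @return the surviving records.
#' @export
filter_season <- function(records, config = refinement_config()) {
  keep <- records$month %in% config$retained_months
  if (!config$drop_missing_month) keep <- keep | is.na(records$month)
  records[keep, , drop = FALSE]
}

#' Region filter
#'
#' Keeps records at or south of `latitude_max` whose record_id is not on the
#' manual exclusion list (coastal South America / Australia / New Zealand
#' samples in the original curation).
#'
#' @inheritParams filter_season
#' @return the surviving records.
#' @export
filter_region <- function(records, config = refinement_config()) {
  keep <- !is.na(records$latitude) &
    records$latitude <= config$latitude_max &
    !(records$record_id %in% config$excluded_records)
  records[keep, , drop = FALSE]
}

#' Taxon-quality filter
#'
#' Drops records whose predator or prey is on the excluded-taxon list
#' (nonliving items, names with too little taxonomic resolution), together
#' with the links they carried.
#'
#' @inheritParams filter_season
#' @return the surviving records.
#' @export
filter_taxa <- function(records, config = refinement_config()) {
  keep <- !(records$predator_name %in% config$excluded_taxa) &
    !(records$prey_name %in% config$excluded_taxa)
  records[keep, , drop = FALSE]
}

#' Apply all refinement rules
#'
#' Composition of the season, region and taxon filters (each a pure
#' predicate, so the order does not affect the surviving set). Drops are
#' attributed to the first rule a record violates, in the order season,
#' region, taxa.
#'
#' @inheritParams filter_season
#' @return a list with `records` (survivors) and `report`, a data.frame with
#'   columns `record_id`, `rule`, `reason` (one row per dropped record).
#' @export
apply_refinement <- function(records, config = refinement_config()) {
  stages <- list(
    season = filter_season,
    region = filter_region,
    taxa = filter_taxa
  )
  reasons <- c(
    season = "month outside retained summer months (or unknown)",
    region = "north of latitude_max or manually excluded location",
    taxa = "predator or prey taxon excluded"
  )
  current <- records
  report <- data.frame(record_id = character(), rule = character(),
                       reason = character(), stringsAsFactors = FALSE)
  for (rule in names(stages)) {
    survived <- stages[[rule]](current, config)
    dropped <- setdiff(current$record_id, survived$record_id)
    if (length(dropped)) {
      report <- rbind(report, data.frame(
        record_id = dropped, rule = rule, reason = reasons[[rule]],
        stringsAsFactors = FALSE
      ))
    }
    current <- survived
  }
  rownames(current) <- NULL
  rownames(report) <- NULL
  list(records = current, report = report)
}

#' Write a refinement report to CSV
#'
#' @param report the `report` element of [apply_refinement()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_refinement_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
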