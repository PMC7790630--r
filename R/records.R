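#' Canonical diet-record columns
#'
#' Column names of the tabular interchange format for predator-diet
#' observation records. One row is one predator--prey dietary observation.
#'
#' @format A character vector of length 10.
#' @export
diet_record_columns <- c(
  "record_id", "source_id", "predator_name", "prey_name",
  "latitude", "longitude", "month",
  "fraction_occurrence", "fraction_diet_weight", "method"
)

.diet_methods <- c("stomach", "stomach_flush", "scat", "other")

#' Normalize longitudes to [-180, 180)
#'
#' Degrees east positive. Values reported on the [0, 360) convention (or any
#' multiple of 360 away) are mapped onto [-180, 180). Idempotent.
#'
#' @param longitude numeric vector of longitudes in decimal degrees.
#' @return numeric vector in [-180, 180).
#' @examples
#' normalize_longitude(c(350, -10, 180))
#' @export
normalize_longitude <- function(longitude) {
  ((longitude + 180) %% 360) - 180
}

## Validate a raw record data frame. Returns list(records, rejections).
## Rejected rows never reach downstream modules; each carries a reason.
validate_diet_records <- function(df, percent_mode = FALSE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(diet_record_columns, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[diet_record_columns]
  for (col in c("record_id", "source_id", "predator_name", "prey_name", "method")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  for (col in c("latitude", "longitude", "month",
                "fraction_occurrence", "fraction_diet_weight")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  if (percent_mode) {
    for (col in c("fraction_occurrence", "fraction_diet_weight")) {
      df[[col]] <- df[[col]] / 100
    }
  }
  df$longitude <- normalize_longitude(df$longitude)

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- flag(df$source_id == "", "empty source_id")
  reason <- flag(df$predator_name == "" | df$prey_name == "",
                 "predator and prey names must both be non-empty")
  reason <- flag(is.na(df$latitude) | df$latitude < -90 | df$latitude > 90,
                 "latitude out of range [-90, 90]")
  reason <- flag(is.na(df$longitude), "missing longitude")
  reason <- flag(!is.na(df$month) & (df$month < 1 | df$month > 12 |
                                       df$month != round(df$month)),
                 "month not an integer in 1..12")
  for (col in c("fraction_occurrence", "fraction_diet_weight")) {
    reason <- flag(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1),
                   paste(col, "outside [0, 1]"))
  }
  reason <- flag(duplicated(df$record_id), "duplicate record_id")

  df$method[!(df$method %in% .diet_methods)] <- "other"
  df$month <- as.integer(df$month)

  keep <- is.na(reason)
  rejections <- data.frame(
    record_id = df$record_id[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  records <- df[keep, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, rejections = rejections)
}

#' Read diet records from CSV
#'
#' Reads the canonical record CSV (UTF-8, header row, missing values as empty
#' fields), validates every row, and returns the surviving records. Longitudes
#' given on [0, 360) are normalized to [-180, 180). With `percent_mode = TRUE`
#' the two diet metrics are read as percentages and divided by 100. Rows that
#' fail validation (latitude out of range, metric outside [0, 1], duplicate
#' record_id, missing predator or prey name, ...) are dropped and reported,
#' not fatal; missing mandatory columns are a format error.
#'
#' @param path path to a CSV file with the columns in [diet_record_columns].
#' @param percent_mode logical; are the diet metrics given as percentages?
#' @return a data.frame of validated records with a `"rejections"` attribute
#'   (a data.frame with columns `record_id`, `reason`); see
#'   [rejection_report()].
#' @seealso [write_diet_records()]
#' @export
read_diet_records <- function(path, percent_mode = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", fileEncoding = "UTF-8")
  out <- validate_diet_records(raw, percent_mode = percent_mode)
  attr(out$records, "rejections") <- out$rejections
  out$records
}

#' Per-row rejection report from a read
#'
#' @param records a data.frame returned by [read_diet_records()].
#' @return data.frame with columns `record_id`, `reason` (zero rows if all
#'   input rows validated).
#' @export
rejection_report <- function(records) {
  rep <- attr(records, "rejections")
  if (is.null(rep)) {
    rep <- data.frame(record_id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  }
  rep
}

#' Write diet records to CSV
#'
#' Inverse of [read_diet_records()]: numeric fields are written with 17
#' significant digits so that a read of the written file reproduces the
#' records field for field. Missing values are written as empty fields.
#'
#' @param records validated records data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_diet_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records[intersect(diet_record_columns, names(records))]
  missing_cols <- setdiff(diet_record_columns, names(out))
  for (col in missing_cols) out[[col]] <- NA
  out <- out[diet_record_columns]
  for (col in c("latitude", "longitude", "fraction_occurrence",
                "fraction_diet_weight")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
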