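#' Sector scheme: named longitude intervals on the circle
#'
#' A sector scheme is an ordered set of half-open longitude intervals
#' `[west, east)` proceeding eastward, jointly covering the full circle.
#' An interval whose eastern bound is numerically west of its western bound
#' wraps across the dateline.
#'
#' The default is the four major Southern Ocean sectors: Atlantic
#' (55W--55E), Indian (55E--145E), West Pacific (145E--115W, wrapping the
#' dateline), and East Pacific (115W--55W).
#'
#' @param name character vector of sector names.
#' @param west,east numeric western/eastern bounds in degrees, each in
#'   [-180, 180).
#' @return a `sector_scheme` data.frame with columns `name`, `west`, `east`.
#' @export
sector_scheme <- function(name = c("Atlantic", "Indian",
                                   "West Pacific", "East Pacific"),
                          west = c(-55, 55, 145, -115),
                          east = c(55, 145, -115, -55)) {
  stopifnot(length(name) == length(west), length(west) == length(east))
  scheme <- data.frame(name = as.character(name),
                       west = normalize_longitude(west),
                       east = normalize_longitude(east),
                       stringsAsFactors = FALSE)
  widths <- (scheme$east - scheme$west) %% 360
  widths[widths == 0] <- 360  # a single full-circle sector
  if (sum(widths) != 360) {
    stop("sector intervals must jointly cover the full circle exactly once ",
         "(widths sum to ", sum(widths), " degrees)")
  }
  class(scheme) <- c("sector_scheme", "data.frame")
  scheme
}

.in_sector <- function(longitude, west, east) {
  if (west < east) {
    longitude >= west & longitude < east
  } else {
    # wraps across the dateline
    longitude >= west | longitude < east
  }
}

#' Assign longitudes to sectors
#'
#' @param longitude numeric vector, already normalized to [-180, 180)
#'   (see [normalize_longitude()]); non-normalized values are an error.
#' @param scheme a [sector_scheme()].
#' @return character vector of sector names, one per longitude.
#' @examples
#' assign_sector(c(0, -120, 70))
#' @export
assign_sector <- function(longitude, scheme = sector_scheme()) {
  if (any(is.na(longitude)) ||
      any(longitude < -180 | longitude >= 180)) {
    stop("longitudes must be normalized to [-180, 180); ",
         "see normalize_longitude()")
  }
  out <- rep(NA_character_, length(longitude))
  for (i in seq_len(nrow(scheme))) {
    hit <- .in_sector(longitude, scheme$west[i], scheme$east[i])
    if (any(hit & !is.na(out))) {
      stop("sector intervals overlap at longitude ",
           longitude[which(hit & !is.na(out))[1]])
    }
    out[hit] <- scheme$name[i]
  }
  if (anyNA(out)) {
    stop("sector scheme leaves longitude ", longitude[which(is.na(out))[1]],
         " unassigned")
  }
  out
}

#' Partition records by sector
#'
#' Every record lands in exactly one sector (allocation is by the record's
#' own coordinates).
#'
#' @param records validated (typically refined) records data.frame.
#' @param scheme a [sector_scheme()].
#' @return named list of record data.frames, one per sector, in scheme
#'   order; sectors with no records get a zero-row data.frame.
#' @export
split_by_sector <- function(records, scheme = sector_scheme()) {
  out <- stats::setNames(vector("list", nrow(scheme)), scheme$name)
  if (nrow(records) == 0) {
    for (nm in scheme$name) out[[nm]] <- records
    return(out)
  }
  sec <- assign_sector(records$longitude, scheme)
  for (nm in scheme$name) {
    sub <- records[sec == nm, , drop = FALSE]
    rownames(sub) <- NULL
    out[[nm]] <- sub
  }
  out
}
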