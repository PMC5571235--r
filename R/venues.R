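# Offline venue lookup: a local venue database plus a low-level to
# high-level category hierarchy stand in for a live place-search service,
# behind the same query semantics (nearest match to a coordinate, limit 1).

stop_no_venue <- function(msg) {
  stop(structure(class = c("NoVenue", "semloc_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_unknown_category <- function(msg) {
  stop(structure(class = c("UnknownCategory", "semloc_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Nearest venue lookup
#'
#' Returns the venue in \code{db} minimising the great-circle distance to the
#' queried coordinate, mirroring a limit-1 place-search query.  Ties are
#' broken by \code{venue_id} order.
#'
#' @param lat,lon queried coordinate in degrees.
#' @param db data.frame with columns \code{venue_id}, \code{lat}, \code{lon},
#'   \code{low_level_category}.
#' @param limit number of matches to return (default 1, the best match).
#' @return list with \code{venue} (the matched row(s)) and \code{distance_m}.
#' @export
nearest_venue <- function(lat, lon, db, limit = 1) {
  if (is.null(db) || !nrow(db)) stop_no_venue("venue database is empty")
  d <- dist_m(db$lat, db$lon, lat, lon)
  ord <- order(d, db$venue_id)
  take <- ord[seq_len(min(limit, nrow(db)))]
  list(venue = db[take, , drop = FALSE], distance_m = d[take])
}

#' Map a low-level venue category to its high-level category
#'
#' Venue databases tag places with very specific categories ("Cambodian
#' Restaurant", "College Math Building"); the classifier and the baseline
#' operate on the nine high-level categories (\code{\link{venue_categories}}).
#' The hierarchy is a named character vector mapping low to high.
#'
#' @param low low-level category string.
#' @param hierarchy named character vector; values must be drawn from
#'   \code{venue_categories()}.
#' @return the high-level category string.
#' @export
map_category <- function(low, hierarchy) {
  if (!low %in% names(hierarchy))
    stop_unknown_category(sprintf("unknown low-level category '%s'", low))
  high <- unname(hierarchy[[low]])
  if (!high %in% venue_categories())
    stop_unknown_category(sprintf(
      "hierarchy maps '%s' to '%s', not a high-level category", low, high))
  high
}

#' Venue features for one visit
#'
#' The venue-derived feature block: a 9-element one-hot vector over the
#' high-level venue categories (exactly one element set) plus the distance in
#' meters from the visit centre to the matched venue.
#'
#' @param venue one-row venue record (from \code{\link{nearest_venue}}).
#' @param distance_m distance to the venue in meters.
#' @param hierarchy low-to-high category mapping.
#' @return named numeric vector of the 10 venue slots.
#' @export
venue_features <- function(venue, distance_m, hierarchy) {
  high <- map_category(venue$low_level_category[1], hierarchy)
  hot <- as.numeric(venue_categories() == high)
  nm <- feature_registry(venue = TRUE)
  setNames(c(hot, distance_m), nm[39:48])
}

#' Venue-only baseline prediction
#'
#' Predicts a visit's high-level category purely from the venue database:
#' the mapped category of the venue nearest to the visit centre.  This is the
#' baseline the sensor classifier is compared against.  Visits whose diary
#' label is Work, Another's Home or Spiritual have no venue-side counterpart
#' and are excluded from baseline scoring (see
#' \code{\link{baseline_skipped_categories}}).
#'
#' @param visit a \code{semloc_visit}.
#' @param db venue database.
#' @param hierarchy low-to-high category mapping.
#' @return high-level category string.
#' @export
baseline_predict <- function(visit, db, hierarchy) {
  nv <- nearest_venue(visit$center_lat, visit$center_lon, db)
  map_category(nv$venue$low_level_category[1], hierarchy)
}

#' Read / write venue databases and hierarchies
#'
#' CSV formats: venues as (\code{venue_id}, \code{lat}, \code{lon},
#' \code{low_level_category}); hierarchies as two columns (\code{low},
#' \code{high}).
#'
#' @param path CSV file path.
#' @param db,hierarchy objects to write.
#' @return \code{read_venue_db} a data.frame; \code{read_hierarchy} a named
#'   character vector.
#' @export
read_venue_db <- function(path) {
  db <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("venue_id", "lat", "lon", "low_level_category")
  if (!all(need %in% names(db)))
    stop_parse("venue db must have columns %s", paste(need, collapse = ", "))
  db[need]
}

#' @rdname read_venue_db
#' @export
write_venue_db <- function(db, path) {
  write.csv(db, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_venue_db
#' @export
read_hierarchy <- function(path) {
  h <- read.csv(path, stringsAsFactors = FALSE)
  setNames(h$high, h$low)
}

#' @rdname read_venue_db
#' @export
write_hierarchy <- function(hierarchy, path) {
  write.csv(data.frame(low = names(hierarchy), high = unname(hierarchy)),
            path, row.names = FALSE)
  invisible(path)
}

#' Default low-level category hierarchy
#'
#' A compact hierarchy covering the low-level venue categories emitted by the
#' synthetic cohort generator plus a few well-known examples.  Real
#' deployments would load the full provider hierarchy with
#' \code{\link{read_hierarchy}}.
#'
#' @return named character vector (low-level name -> high-level category).
#' @export
default_hierarchy <- function() {
  c("Cambodian Restaurant" = "Food",
    "Diner"                = "Food",
    "Coffee Shop"          = "Food",
    "Pizza Place"          = "Food",
    "Bar"                  = "Nightlife Spot",
    "Nightclub"            = "Nightlife Spot",
    "Pub"                  = "Nightlife Spot",
    "Park"                 = "Outdoors & Recreation",
    "Trail"                = "Outdoors & Recreation",
    "Playground"           = "Outdoors & Recreation",
    "Movie Theater"        = "Arts & Entertainment",
    "Music Venue"          = "Arts & Entertainment",
    "Art Gallery"          = "Arts & Entertainment",
    "Doctor's Office"      = "Professional & Other Places",
    "Dentist's Office"     = "Professional & Other Places",
    "Law Office"           = "Professional & Other Places",
    "Office"               = "Professional & Other Places",
    "Church"               = "Professional & Other Places",
    "Home (private)"       = "Residence",
    "Apartment Building"   = "Residence",
    "Grocery Store"        = "Shop & Service",
    "Department Store"     = "Shop & Service",
    "Pharmacy"             = "Shop & Service",
    "Bus Stop"             = "Travel & Transport",
    "Train Station"        = "Travel & Transport",
    "Airport"              = "Travel & Transport",
    "College Math Building" = "College & University",
    "University Library"   = "College & University")
}
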