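#' Place category vocabularies
#'
#' Participants label each visited place with one of twelve categories in the
#' daily location diary; eleven of them (everything except \code{"Other"}) are
#' the classes of the semantic-location classification problem.  Venue
#' databases use a separate, coarser vocabulary of nine high-level categories;
#' \code{ema_to_venue_category()} gives the fixed translation between the two
#' where one exists.  \code{Work}, \code{Another's Home} and \code{Spiritual}
#' have no venue-side counterpart and translate to \code{NA}; they are skipped
#' whenever diary labels are compared against venue lookups.
#'
#' @return Character vectors of category names, or for
#'   \code{ema_to_venue_category()} a named character vector mapping diary
#'   labels to venue categories (\code{NA} where no counterpart exists).
#' @examples
#' semloc_categories()
#' ema_to_venue_category()[["Home"]]   # "Residence"
#' @export
semloc_categories <- function() {
  c("Nightlife Spot", "Outdoors & Recreation", "Arts & Entertainment",
    "Professional or Medical Office", "Food", "Home", "Shop or Store",
    "Travel or Transport", "Spiritual", "Work", "Another's Home", "Other")
}

#' @rdname semloc_categories
#' @export
classifiable_categories <- function() {
  setdiff(semloc_categories(), "Other")
}

#' @rdname semloc_categories
#' @export
venue_categories <- function() {
  c("Nightlife Spot", "Outdoors & Recreation", "Arts & Entertainment",
    "Professional & Other Places", "Food", "Residence", "Shop & Service",
    "Travel & Transport", "College & University")
}

#' @rdname semloc_categories
#' @export
ema_to_venue_category <- function() {
  c("Nightlife Spot"                 = "Nightlife Spot",
    "Outdoors & Recreation"          = "Outdoors & Recreation",
    "Arts & Entertainment"           = "Arts & Entertainment",
    "Professional or Medical Office" = "Professional & Other Places",
    "Food"                           = "Food",
    "Home"                           = "Residence",
    "Shop or Store"                  = "Shop & Service",
    "Travel or Transport"            = "Travel & Transport",
    "Spiritual"                      = NA_character_,
    "Work"                           = NA_character_,
    "Another's Home"                 = NA_character_)
}

#' @rdname semloc_categories
#' @export
baseline_skipped_categories <- function() {
  c("Work", "Another's Home", "Spiritual")
}

# Activity-recognition states and communication event kinds (closed sets).
activity_states <- function() {
  c("Still", "Walking", "Running", "Tilting", "OnBike", "InVehicle", "Unknown")
}

comm_kinds <- function() {
  c("call_in", "call_out", "call_missed", "sms_in", "sms_out")
}
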