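# Daily GPS stay detection: adaptive k-means with a 100 m maximum cluster
# radius, then removal of dwells shorter than 10 minutes.

M_PER_DEG <- pi / 180 * 6378137   # meters per degree of great-circle arc

# Project fixes onto a local tangent plane (meters), centred on (lat0, lon0).
project_plane <- function(lat, lon, lat0, lon0) {
  cbind(x = (lon - lon0) * M_PER_DEG * cos(lat0 * pi / 180),
        y = (lat - lat0) * M_PER_DEG)
}

unproject_plane <- function(xy, lat0, lon0) {
  c(lat = lat0 + xy[2] / M_PER_DEG,
    lon = lon0 + xy[1] / (M_PER_DEG * cos(lat0 * pi / 180)))
}

stop_empty_input <- function(msg) {
  stop(structure(class = c("EmptyInput", "semloc_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Adaptive k-means clustering of GPS fixes
#'
#' Clusters one day's GPS fixes with the smallest number of centres such that
#' every fix lies within \code{max_radius_m} (great-circle) of its assigned
#' centre: \code{k} starts at 1 and is incremented while any cluster's radius
#' exceeds the bound (capped at the number of fixes).  Lloyd iterations run in
#' a local tangent plane with deterministic farthest-point initialisation, so
#' results are reproducible without a seed.
#'
#' @param fixes data.frame with columns \code{t}, \code{lat}, \code{lon}
#'   (sorted by \code{t}).
#' @param max_radius_m maximum allowed cluster radius in meters (default 100,
#'   the radius used by the daily location diary's clustering step).
#' @return list with \code{centers} (data.frame \code{lat}, \code{lon}),
#'   \code{assignment} (integer vector, one entry per fix), \code{k}, and
#'   \code{radius} (per-cluster max member distance in meters).
#' @export
adaptive_kmeans <- function(fixes, max_radius_m = 100) {
  n <- nrow(fixes)
  if (is.null(n) || n == 0) stop_empty_input("no GPS fixes to cluster")
  lat0 <- mean(fixes$lat); lon0 <- mean(fixes$lon)
  xy <- project_plane(fixes$lat, fixes$lon, lat0, lon0)
  centers <- xy[1, , drop = FALSE]
  repeat {
    km <- lloyd_kmeans(xy, centers)
    centers <- km$centers
    k <- nrow(centers)
    centers_ll <- matrix(t(apply(centers, 1, unproject_plane, lat0, lon0)),
                         ncol = 2)
    radius <- vapply(seq_len(k), function(j) {
      m <- km$assignment == j
      if (!any(m)) return(0)
      max(dist_m(fixes$lat[m], fixes$lon[m],
                 centers_ll[j, 1], centers_ll[j, 2]))
    }, 0)
    if (all(radius <= max_radius_m) || k == n) break
    # one more centre at the fix farthest from its assigned centre
    d2 <- nearest_center_dist2(xy, centers)
    centers <- rbind(centers, xy[which.max(d2), ])
  }
  list(centers = data.frame(lat = centers_ll[, 1], lon = centers_ll[, 2]),
       assignment = km$assignment, k = k, radius = radius)
}

# Lloyd iterations in the plane from the given initial centres (the
# adaptive scheme warm-starts each k from the converged k-1 solution plus
# one farthest-point centre, so clustering is deterministic without a
# seed).
lloyd_kmeans <- function(xy, centers, max_iter = 50) {
  n <- nrow(xy)
  k <- nrow(centers)
  assignment <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    new_assign <- assign_nearest(xy, centers)
    # re-seed any emptied cluster at the point farthest from its centre
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {
        d2 <- nearest_center_dist2(xy, centers)
        centers[j, ] <- xy[which.max(d2), ]
        new_assign <- assign_nearest(xy, centers)
      }
    }
    if (identical(new_assign, assignment)) break
    assignment <- new_assign
    for (j in seq_len(k))
      centers[j, ] <- colMeans(xy[assignment == j, , drop = FALSE])
  }
  list(centers = centers, assignment = assignment)
}

nearest_center_dist2 <- function(xy, centers) {
  d2 <- rep(Inf, nrow(xy))
  for (j in seq_len(nrow(centers)))
    d2 <- pmin(d2, (xy[, 1] - centers[j, 1])^2 + (xy[, 2] - centers[j, 2])^2)
  d2
}

assign_nearest <- function(xy, centers) {
  d2 <- vapply(seq_len(nrow(centers)), function(j)
    (xy[, 1] - centers[j, 1])^2 + (xy[, 2] - centers[j, 2])^2,
    numeric(nrow(xy)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  max.col(-d2, ties.method = "first")
}

new_visit <- function(id, day, center_lat, center_lon, intervals,
                      fix_idx = integer(0), label = NA_character_) {
  intervals <- matrix(as.numeric(intervals), ncol = 2,
                      dimnames = list(NULL, c("enter", "exit")))
  duration <- sum(intervals[, 2] - intervals[, 1])
  timespan <- max(intervals[, 2]) - min(intervals[, 1])
  structure(list(id = id, day = day, center_lat = unname(center_lat),
                 center_lon = unname(center_lon), intervals = intervals,
                 duration_s = duration, timespan_s = timespan,
                 fix_idx = fix_idx, label = label),
            class = "semloc_visit")
}

#' @export
print.semloc_visit <- function(x, ...) {
  cat(sprintf("<visit %s %s (%.5f, %.5f) %d interval(s), %.0f s dwell%s>\n",
              x$id, format(x$day), x$center_lat, x$center_lon,
              nrow(x$intervals), x$duration_s,
              if (is.na(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' Detect location visits in one day of GPS fixes
#'
#' Clusters the day's fixes with \code{\link{adaptive_kmeans}}, turns maximal
#' runs of consecutive fixes assigned to the same cluster into dwell
#' intervals, and drops clusters whose total dwell over the day is shorter
#' than \code{min_dwell_s} (default 10 minutes) -- these are typically
#' pseudo-clusters produced by slow movement rather than real places.  An
#' interval's length is the time between its first and last fix; a gap longer
#' than \code{gap_factor} times the median sampling interval breaks an
#' interval so that recording outages do not inflate dwell.
#'
#' @inheritParams adaptive_kmeans
#' @param min_dwell_s minimum summed dwell per cluster in seconds.
#' @param gap_factor sampling-gap multiplier that splits an interval.
#' @param id participant identifier carried into the visits.
#' @param day local calendar day (\code{Date}) of the fixes.
#' @return list of \code{semloc_visit} objects ordered by first entry time.
#' @export
detect_visits <- function(fixes, min_dwell_s = 600, max_radius_m = 100,
                          gap_factor = 3, id = NA_character_, day = NULL) {
  if (is.null(fixes) || !nrow(fixes)) return(list())
  if (is.unsorted(fixes$t)) stop_parse("fixes must be sorted by t")
  if (is.null(day))
    day <- as.Date(as.POSIXct(fixes$t[1], origin = "1970-01-01", tz = "UTC"))
  km <- adaptive_kmeans(fixes, max_radius_m)
  t <- fixes$t
  si <- if (length(t) > 1) median(diff(t)) else Inf
  brk <- c(TRUE, diff(km$assignment) != 0 | diff(t) > gap_factor * si)
  run <- cumsum(brk)
  visits <- list()
  for (j in seq_len(km$k)) {
    runs <- unique(run[km$assignment == j])
    ivs <- t(vapply(runs, function(r) {
      idx <- which(run == r)
      c(t[idx[1]], t[idx[length(idx)]])
    }, c(0, 0)))
    fix_idx <- which(km$assignment == j)
    if (sum(ivs[, 2] - ivs[, 1]) < min_dwell_s) next
    # refine the centre to the centroid of member fixes
    lat0 <- mean(fixes$lat); lon0 <- mean(fixes$lon)
    xy <- project_plane(fixes$lat[fix_idx], fixes$lon[fix_idx], lat0, lon0)
    ctr <- unproject_plane(colMeans(xy), lat0, lon0)
    visits[[length(visits) + 1]] <-
      new_visit(id, day, ctr[1], ctr[2], ivs, fix_idx)
  }
  if (length(visits))
    visits <- visits[order(vapply(visits, function(v) min(v$intervals[, 1]),
                                  0))]
  visits
}

#' Detect visits over a whole study
#'
#' Splits a participant's GPS stream into local calendar days (using the
#' participant's \code{tz_offset}) and runs \code{\link{detect_visits}} on
#' each day.
#'
#' @param p a \code{\link{participant}}.
#' @inheritParams detect_visits
#' @return list of \code{semloc_visit}.
#' @export
detect_visits_study <- function(p, min_dwell_s = 600, max_radius_m = 100) {
  g <- p$gps
  if (!nrow(g)) return(list())
  day <- as.Date(floor((g$t + p$tz_offset * 3600) / 86400),
                 origin = "1970-01-01")
  out <- list()
  for (d in split(seq_len(nrow(g)), day)) {
    vs <- detect_visits(g[d, , drop = FALSE], min_dwell_s, max_radius_m,
                        id = p$id, day = day[d[1]])
    out <- c(out, vs)
  }
  out
}

#' Match a detected visit to a diary report
#'
#' Finds, among the day's diary reports, the one whose saved cluster centre is
#' nearest to the visit centre; returns its category label if it lies within
#' \code{radius_m} meters, otherwise \code{NA}.  Used to attach supervised
#' labels to detected visits.
#'
#' @param v a \code{semloc_visit}.
#' @param reports data.frame of diary reports (see \code{\link{participant}}).
#' @param radius_m maximum centre-to-centre match distance in meters.
#' @return a category string or \code{NA_character_}.
#' @export
match_visit_to_report <- function(v, reports, radius_m = 100) {
  if (is.null(reports) || !nrow(reports)) return(NA_character_)
  same_day <- reports[as.Date(reports$date) == v$day, , drop = FALSE]
  if (!nrow(same_day)) return(NA_character_)
  d <- dist_m(same_day$center_lat, same_day$center_lon,
              v$center_lat, v$center_lon)
  i <- which.min(d)
  if (d[i] <= radius_m) same_day$category[i] else NA_character_
}
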