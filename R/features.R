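# Per-visit sensor features.  Every extractor takes the stream already
# restricted to the visit's dwell intervals (build_feature_vector does the
# restriction) and returns named numeric values; NA encodes "missing", which
# the classifier handles natively through its missing-value branches.

#' Feature registry
#'
#' Names, in fixed order, of the per-visit feature slots: 38 sensor features
#' (light 6, sound 2, screen 3, activity 8, communication 5, GPS 5, Wi-Fi 1,
#' time 5, weather 3) and optionally the 10 venue features (a 9-element
#' one-hot venue-category vector plus the distance to the nearest venue).
#'
#' @param venue if \code{TRUE}, append the 10 venue slots.
#' @return character vector of feature names.
#' @export
feature_registry <- function(venue = FALSE) {
  nm <- c("light_mean", "light_var", "light_skew", "light_kurt",
          "light_frac_zero", "light_crossings_per_s",
          "sound_power", "sound_dom_freq",
          "screen_n_on", "screen_on_mean_s", "screen_on_sd_s",
          "act_frac_still", "act_frac_tilting", "act_frac_walking",
          "act_frac_unknown", "act_trans_still_walking",
          "act_trans_still_tilting", "act_trans_still_unknown",
          "act_trans_walking_unknown",
          "n_call_in", "n_call_out", "n_call_missed", "n_sms_in", "n_sms_out",
          "gps_mean_lat", "gps_mean_lon", "gps_location_variance",
          "gps_visit_frequency", "gps_mean_visit_gap_s",
          "wifi_mean_n_networks",
          "time_duration_s", "time_timespan_s", "time_mid_hour",
          "time_dow_start", "time_dow_end",
          "wx_temperature", "wx_dew_point", "wx_condition")
  if (venue)
    nm <- c(nm, paste0("venue_", gsub("[^A-Za-z]+", "_",
                                      tolower(venue_categories()))),
            "venue_distance_m")
  nm
}

#' Light features
#'
#' Mean, variance, skewness and kurtosis of illuminance, the fraction of
#' samples at exactly zero lux, and the rate at which the series crosses its
#' own mean (sign changes of \code{lux - mean} per second of observed
#' recording span, so the value does not depend on the device's sampling
#' frequency).
#'
#' @param samples data.frame with columns \code{t}, \code{lux}.
#' @return named numeric vector of the 6 light slots (NA where undefined:
#'   all slots when no samples, variance with fewer than 2 samples, shape
#'   moments when the variance is zero).
#' @export
light_features <- function(samples) {
  out <- setNames(rep(NA_real_, 6), feature_registry()[1:6])
  n <- nrow(samples)
  if (!n) return(out)
  x <- samples$lux
  m <- mean(x)
  out["light_mean"] <- m
  out["light_frac_zero"] <- mean(x == 0)
  if (n >= 2) out["light_var"] <- var(x)
  m2 <- mean((x - m)^2)
  if (m2 > 0) {
    out["light_skew"] <- mean((x - m)^3) / m2^1.5
    out["light_kurt"] <- mean((x - m)^4) / m2^2
  }
  span <- samples$t[n] - samples$t[1]
  s <- sign(x - m)
  crossings <- sum(s[-1] * s[-n] < 0)
  out["light_crossings_per_s"] <- if (span > 0) crossings / span
                                  else if (crossings == 0) 0 else NA_real_
  out
}

# Per-clip reductions of a raw audio clip: mean squared amplitude and the
# frequency (Hz) maximising the FFT amplitude spectrum, zero-frequency bin
# excluded.
clip_power <- function(samples) mean(samples^2)

clip_dom_freq <- function(samples, rate) {
  n <- length(samples)
  amp <- Mod(fft(samples))
  bins <- 2:(n %/% 2 + 1)           # positive frequencies only, DC excluded
  (bins[which.max(amp[bins])] - 1) * rate / n
}

#' Sound features
#'
#' Per-visit mean of the per-clip power (mean of squared amplitude over the
#' clip's samples) and dominant frequency (argmax of the FFT amplitude
#' spectrum, excluding the zero-frequency bin).  Accepts raw clips, already
#' summarised clips, or both; clips with fewer than 2 samples are skipped
#' with a warning.
#'
#' @param clips list of raw clips (\code{t_start}, \code{rate},
#'   \code{samples}).
#' @param summary data.frame of per-clip summaries (\code{t_start},
#'   \code{power}, \code{dom_freq}).
#' @return named numeric vector \code{c(sound_power, sound_dom_freq)}; NA if
#'   no usable clips.
#' @export
sound_features <- function(clips = NULL, summary = NULL) {
  pw <- fq <- numeric(0)
  for (cl in clips %||% list()) {
    if (length(cl$samples) < 2) {
      warnf("skipping audio clip with %d sample(s)", length(cl$samples))
      next
    }
    pw <- c(pw, clip_power(cl$samples))
    fq <- c(fq, clip_dom_freq(cl$samples, cl$rate))
  }
  if (!is.null(summary) && nrow(summary)) {
    pw <- c(pw, summary$power)
    fq <- c(fq, summary$dom_freq)
  }
  c(sound_power = if (length(pw)) mean(pw) else NA_real_,
    sound_dom_freq = if (length(fq)) mean(fq) else NA_real_)
}

#' Screen features
#'
#' Number of OFF-to-ON transitions and the mean and SD of the screen-ON
#' durations.  Consecutive duplicate states are dropped first; an ON period
#' left open at the end of the visit is censored at \code{visit_end} when
#' given, otherwise discarded.  The SD is NA with fewer than 2 ON periods.
#'
#' @param events data.frame with columns \code{t}, \code{state}.
#' @param visit_end censoring time for an unterminated final ON period.
#' @return named numeric vector \code{c(screen_n_on, screen_on_mean_s,
#'   screen_on_sd_s)}.
#' @export
screen_features <- function(events, visit_end = NULL) {
  out <- c(screen_n_on = 0, screen_on_mean_s = NA_real_,
           screen_on_sd_s = NA_real_)
  if (!nrow(events)) return(out)
  keep <- c(TRUE, events$state[-1] != events$state[-nrow(events)])
  ev <- events[keep, , drop = FALSE]
  on_idx <- which(ev$state == "ON")
  out["screen_n_on"] <- length(on_idx)
  durations <- numeric(0)
  for (i in on_idx) {
    if (i < nrow(ev)) durations <- c(durations, ev$t[i + 1] - ev$t[i])
    else if (!is.null(visit_end)) durations <- c(durations,
                                                 visit_end - ev$t[i])
  }
  if (length(durations) >= 1) out["screen_on_mean_s"] <- mean(durations)
  if (length(durations) >= 2) out["screen_on_sd_s"] <- sd(durations)
  out
}

#' Activity features
#'
#' Occupancy fractions of the Still, Tilting, Walking and Unknown states
#' (samples in state / total samples) and the fraction of consecutive-sample
#' transitions that are Still-to-Walking, Still-to-Tilting, Still-to-Unknown
#' and Walking-to-Unknown (count / total consecutive pairs; 0 when the visit
#' has fewer than 2 samples).
#'
#' @param samples data.frame with columns \code{t}, \code{state}.
#' @return named numeric vector of the 8 activity slots (all NA if no
#'   samples).
#' @export
activity_features <- function(samples) {
  nm <- feature_registry()[12:19]
  out <- setNames(rep(NA_real_, 8), nm)
  n <- nrow(samples)
  if (!n) return(out)
  st <- samples$state
  out["act_frac_still"]   <- mean(st == "Still")
  out["act_frac_tilting"] <- mean(st == "Tilting")
  out["act_frac_walking"] <- mean(st == "Walking")
  out["act_frac_unknown"] <- mean(st == "Unknown")
  pairs <- n - 1
  trans <- function(a, b)
    if (pairs == 0) 0 else sum(st[-n] == a & st[-1] == b) / pairs
  out["act_trans_still_walking"]   <- trans("Still", "Walking")
  out["act_trans_still_tilting"]   <- trans("Still", "Tilting")
  out["act_trans_still_unknown"]   <- trans("Still", "Unknown")
  out["act_trans_walking_unknown"] <- trans("Walking", "Unknown")
  out
}

#' Communication features
#'
#' Counts of incoming, outgoing and missed calls and incoming and outgoing
#' SMS messages during the visit.
#'
#' @param events data.frame with columns \code{t}, \code{kind}.
#' @return named numeric vector of the 5 communication counts.
#' @export
comm_features <- function(events) {
  k <- events$kind
  c(n_call_in = sum(k == "call_in"), n_call_out = sum(k == "call_out"),
    n_call_missed = sum(k == "call_missed"), n_sms_in = sum(k == "sms_in"),
    n_sms_out = sum(k == "sms_out"))
}

#' GPS features
#'
#' Mean latitude and longitude of the visit's member fixes, the location
#' variance \eqn{\ln(\mathrm{var}(lat) + \mathrm{var}(lon))} (NA when the
#' variance sum is zero), and -- over the whole study -- the number of
#' distinct dwell episodes whose fixes fall within 50 m of this visit's
#' centre (\emph{visit frequency}) and the mean start-to-start interval
#' between consecutive such episodes in seconds.
#'
#' @param visit a \code{semloc_visit}.
#' @param all_fixes the participant's full-study GPS data.frame.
#' @param revisit_radius_m radius for counting revisits (50 m).
#' @param episode_gap_s minimum time gap separating two dwell episodes.
#' @return named numeric vector of the 5 GPS slots.
#' @export
gps_features <- function(visit, all_fixes, revisit_radius_m = 50,
                         episode_gap_s = 3600) {
  within <- in_intervals(all_fixes$t, visit$intervals)
  lat <- all_fixes$lat[within]; lon <- all_fixes$lon[within]
  out <- setNames(rep(NA_real_, 5), feature_registry()[25:29])
  if (!length(lat)) return(out)
  out["gps_mean_lat"] <- mean(lat)
  out["gps_mean_lon"] <- mean(lon)
  if (length(lat) >= 2) {
    vsum <- var(lat) + var(lon)
    if (vsum > 0) out["gps_location_variance"] <- log(vsum)
  }
  near <- dist_m(all_fixes$lat, all_fixes$lon,
                 visit$center_lat, visit$center_lon) <= revisit_radius_m
  tn <- all_fixes$t[near]
  if (length(tn)) {
    ep_start <- tn[c(TRUE, diff(tn) > episode_gap_s)]
    out["gps_visit_frequency"] <- length(ep_start)
    if (length(ep_start) >= 2)
      out["gps_mean_visit_gap_s"] <- mean(diff(ep_start))
  }
  out
}

#' Wi-Fi feature
#'
#' Mean number of visible Wi-Fi networks over the visit's scans.
#'
#' @param scans data.frame with columns \code{t}, \code{n_networks}.
#' @return named numeric vector \code{c(wifi_mean_n_networks)}.
#' @export
wifi_features <- function(scans) {
  c(wifi_mean_n_networks =
      if (nrow(scans)) mean(scans$n_networks) else NA_real_)
}

epoch_dow <- function(t_local) (floor(t_local / 86400) + 4) %% 7  # 0 = Sunday

#' Time features
#'
#' Visit duration (summed dwell), timespan (first entry to last exit on the
#' day), the local hour of the visit mid-time (first entry + timespan / 2),
#' and the day of week (0 = Sunday .. 6 = Saturday, local time) at the start
#' and end of the visit.
#'
#' @param visit a \code{semloc_visit}.
#' @param tz_offset local-time offset from UTC in hours.
#' @return named numeric vector of the 5 time slots.
#' @export
time_features <- function(visit, tz_offset = 0) {
  enter <- min(visit$intervals[, 1]); exit <- max(visit$intervals[, 2])
  mid <- enter + visit$timespan_s / 2 + tz_offset * 3600
  c(time_duration_s = visit$duration_s, time_timespan_s = visit$timespan_s,
    time_mid_hour = (mid %% 86400) / 3600,
    time_dow_start = epoch_dow(enter + tz_offset * 3600),
    time_dow_end = epoch_dow(exit + tz_offset * 3600))
}

#' Weather features
#'
#' Temperature, dew point and condition code of the weather report closest in
#' time to the visit's mid-time.
#'
#' @param reports data.frame with columns \code{t}, \code{temperature},
#'   \code{dew_point}, \code{condition}.
#' @param visit a \code{semloc_visit}.
#' @return named numeric vector of the 3 weather slots (all NA if no
#'   reports).
#' @export
weather_features <- function(reports, visit) {
  out <- setNames(rep(NA_real_, 3), feature_registry()[36:38])
  if (!nrow(reports)) return(out)
  mid <- min(visit$intervals[, 1]) + visit$timespan_s / 2
  i <- which.min(abs(reports$t - mid))
  out["wx_temperature"] <- reports$temperature[i]
  out["wx_dew_point"] <- reports$dew_point[i]
  out["wx_condition"] <- reports$condition[i]
  out
}

in_intervals <- function(t, intervals) {
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals)))
    hit <- hit | (t >= intervals[i, 1] & t <= intervals[i, 2])
  hit
}

# first index with t[i] >= v (length(t) + 1 if none)
bin_first_ge <- function(t, v) {
  lo <- 1L; hi <- length(t) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (t[mid] < v) lo <- mid + 1L else hi <- mid
  }
  lo
}

# last index with t[i] <= v (0 if none)
bin_last_le <- function(t, v) {
  lo <- 0L; hi <- length(t)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (t[mid] <= v) lo <- mid else hi <- mid - 1L
  }
  lo
}

# Rows of a time-sorted stream falling inside any interval (binary search;
# interval endpoints inclusive, matching in_intervals()).
restrict <- function(df, intervals, tcol = "t") {
  t <- df[[tcol]]
  idx <- integer(0)
  for (i in seq_len(nrow(intervals))) {
    lo <- bin_first_ge(t, intervals[i, 1])
    hi <- bin_last_le(t, intervals[i, 2])
    if (hi >= lo) idx <- c(idx, lo:hi)
  }
  df[unique(idx), , drop = FALSE]
}

#' Build the per-visit feature vector
#'
#' Applies every feature extractor to the participant's streams restricted to
#' the visit's dwell intervals and returns one named numeric vector in
#' registry order.  GPS revisit features use the full-study GPS stream;
#' weather uses the report closest to the visit mid-time regardless of
#' interval membership.  When \code{venue} is supplied (a named vector from
#' \code{\link{venue_features}}), its 10 slots are appended.
#'
#' @param visit a \code{semloc_visit}.
#' @param p the owning \code{\link{participant}}.
#' @param venue optional venue feature vector to append.
#' @return named numeric vector of length 38 (or 48 with venue slots).
#' @export
build_feature_vector <- function(visit, p, venue = NULL) {
  iv <- visit$intervals
  end <- max(iv[, 2])
  clips <- p$audio_clips[vapply(p$audio_clips, function(cl)
    any(cl$t_start >= iv[, 1] & cl$t_start <= iv[, 2]), TRUE)]
  x <- c(light_features(restrict(p$light, iv)),
         sound_features(clips,
                        restrict(p$audio_summary, iv, tcol = "t_start")),
         screen_features(restrict(p$screen, iv), visit_end = end),
         activity_features(restrict(p$activity, iv)),
         comm_features(restrict(p$comm, iv)),
         gps_features(visit, p$gps),
         wifi_features(restrict(p$wifi, iv)),
         time_features(visit, p$tz_offset),
         weather_features(p$weather, visit))
  if (!is.null(venue)) x <- c(x, venue)
  stopifnot(identical(names(x), feature_registry(venue = !is.null(venue))))
  x
}
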