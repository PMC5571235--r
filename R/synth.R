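# Synthetic cohort generator: place-dependent sensor signatures, a daily
# schedule (home overnight, work on weekdays for employed participants,
# stochastic outings), ground-truth visit logs, diary reports, a venue
# database, and three-wave symptom scores with optional planted effects.
#
# No quantitative place signatures exist to copy; every profile default
# below is this package's own choice of a plausible signature (bright shops,
# loud nightlife, still offices, ...), documented in the methods vignette.

#' Place emission profile
#'
#' Per-category sensor signature used by the cohort generator: ambient light
#' by day/night with a phone-in-pocket (zero lux) probability, audio power
#' and dominant tone frequency, an activity-state transition matrix (sticky
#' Markov chain over the 7 recogniser states), screen-unlock and call/SMS
#' rates, Wi-Fi network count, visit duration distribution, and time-of-day
#' and day-of-week visit propensities.
#'
#' @param category the place category the profile emulates.
#' @param light_day,light_night,light_sd lux levels (08:00-20:00 local vs
#'   night) and within-visit SD.
#' @param pocket_prob probability a light burst reads zero (phone pocketed).
#' @param sound_power mean of squared audio amplitude at this place.
#' @param sound_freq dominant tone frequency (Hz).
#' @param act_probs length-7 stationary activity distribution
#'   (Still, Walking, Running, Tilting, OnBike, InVehicle, Unknown).
#' @param act_stick self-transition stickiness in [0, 1).
#' @param screen_rate_h screen unlocks per hour.
#' @param screen_on_s mean screen-ON duration (s).
#' @param call_rate_h,sms_rate_h communication events per hour.
#' @param wifi_lambda Poisson mean of visible Wi-Fi networks.
#' @param dur_mean_h,dur_sdlog lognormal visit duration (hours); NA for
#'   schedule-driven places (Home, Work).
#' @param tod_mean,tod_sd preferred local start hour; NA for schedule-driven
#'   places.
#' @param dow_w length-7 day-of-week visit weights (Sunday first).
#' @return list of class \code{semloc_place_profile} (with the transition
#'   matrix in \code{$trans}).
#' @export
place_profile <- function(category, light_day, light_night, light_sd,
                          pocket_prob, sound_power, sound_freq, act_probs,
                          act_stick, screen_rate_h, screen_on_s = 90,
                          call_rate_h = 0.3, sms_rate_h = 0.7, wifi_lambda,
                          dur_mean_h = NA, dur_sdlog = 0.35, tod_mean = NA,
                          tod_sd = 2, dow_w = rep(1, 7)) {
  act_probs <- act_probs / sum(act_probs)
  stopifnot(length(act_probs) == 7, act_stick >= 0, act_stick < 1,
            screen_rate_h >= 0, call_rate_h >= 0, sms_rate_h >= 0,
            wifi_lambda >= 0, length(dow_w) == 7)
  trans <- act_stick * diag(7) +
    (1 - act_stick) * matrix(act_probs, 7, 7, byrow = TRUE)
  structure(list(category = category, light_day = light_day,
                 light_night = light_night, light_sd = light_sd,
                 pocket_prob = pocket_prob, sound_power = sound_power,
                 sound_freq = sound_freq, act_probs = act_probs,
                 act_stick = act_stick,
                 trans = trans, screen_rate_h = screen_rate_h,
                 screen_on_s = screen_on_s, call_rate_h = call_rate_h,
                 sms_rate_h = sms_rate_h, wifi_lambda = wifi_lambda,
                 dur_mean_h = dur_mean_h, dur_sdlog = dur_sdlog,
                 tod_mean = tod_mean, tod_sd = tod_sd, dow_w = dow_w),
            class = "semloc_place_profile")
}

#' @rdname place_profile
#' @export
default_place_profiles <- function() {
  pr <- list(
    place_profile("Home", 150, 5, 60, 0.15, 100, 200,
                  c(.82, .06, .01, .05, 0, 0, .06), 0.90, 5, 120,
                  0.25, 0.9, 6),
    place_profile("Work", 420, 60, 90, 0.30, 250, 300,
                  c(.70, .15, 0, .05, 0, 0, .10), 0.85, 2.5, 60,
                  0.5, 0.5, 12),
    place_profile("Food", 280, 180, 70, 0.40, 900, 400,
                  c(.60, .25, 0, .05, 0, 0, .10), 0.80, 4, 70,
                  0.2, 0.6, 8, dur_mean_h = 1.1, dur_sdlog = 0.3,
                  tod_mean = 12.5, tod_sd = 4),
    place_profile("Shop or Store", 750, 600, 150, 0.50, 1100, 500,
                  c(.35, .50, 0, .05, 0, 0, .10), 0.75, 2, 50,
                  0.2, 0.5, 9, dur_mean_h = 0.8, dur_sdlog = 0.4,
                  tod_mean = 15, tod_sd = 3,
                  dow_w = c(1.6, 1, 1, 1, 1, 1.2, 1.6)),
    place_profile("Nightlife Spot", 25, 15, 12, 0.40, 4000, 150,
                  c(.50, .35, 0, .05, 0, 0, .10), 0.70, 6, 45,
                  0.3, 1.0, 5, dur_mean_h = 2.3, dur_sdlog = 0.3,
                  tod_mean = 21.5, tod_sd = 1.2,
                  dow_w = c(0.5, 0.3, 0.3, 0.5, 0.8, 2.5, 2.5)),
    place_profile("Outdoors & Recreation", 6000, 30, 1800, 0.60, 300, 250,
                  c(.25, .50, .10, .03, 0, 0, .12), 0.70, 1.5, 40,
                  0.15, 0.4, 1, dur_mean_h = 1.4, dur_sdlog = 0.4,
                  tod_mean = 10.5, tod_sd = 2.5,
                  dow_w = c(2, 0.7, 0.7, 0.7, 0.7, 1, 2)),
    place_profile("Arts & Entertainment", 80, 50, 30, 0.45, 2000, 350,
                  c(.75, .15, 0, .04, 0, 0, .06), 0.85, 1, 40,
                  0.1, 0.3, 4, dur_mean_h = 2.0, dur_sdlog = 0.3,
                  tod_mean = 19, tod_sd = 2,
                  dow_w = c(1.5, 0.5, 0.5, 0.6, 0.8, 1.8, 2)),
    place_profile("Spiritual", 220, 150, 60, 0.55, 420, 450,
                  c(.80, .12, 0, .03, 0, 0, .05), 0.88, 0.4, 30,
                  0.05, 0.15, 2, dur_mean_h = 1.5, dur_sdlog = 0.25,
                  tod_mean = 10.5, tod_sd = 1,
                  dow_w = c(6, 0.2, 0.2, 0.5, 0.2, 0.2, 0.6)),
    place_profile("Professional or Medical Office", 460, 350, 90, 0.35,
                  260, 320, c(.70, .18, 0, .05, 0, 0, .07), 0.85, 3, 60,
                  0.4, 0.5, 7, dur_mean_h = 0.9, dur_sdlog = 0.35,
                  tod_mean = 13.5, tod_sd = 2,
                  dow_w = c(0.1, 1.3, 1.3, 1.3, 1.3, 1.3, 0.4)),
    place_profile("Another's Home", 140, 8, 55, 0.25, 160, 220,
                  c(.75, .12, 0, .05, 0, 0, .08), 0.88, 3.5, 100,
                  0.3, 0.9, 5, dur_mean_h = 2.2, dur_sdlog = 0.4,
                  tod_mean = 17.5, tod_sd = 2.5,
                  dow_w = c(1.8, 0.7, 0.7, 0.7, 0.8, 1.5, 1.8)),
    place_profile("Travel or Transport", 350, 80, 150, 0.55, 2600, 120,
                  c(.40, .20, 0, .03, 0, .30, .07), 0.80, 7, 50,
                  0.3, 0.8, 3, dur_mean_h = 0.6, dur_sdlog = 0.4,
                  tod_mean = 12, tod_sd = 5))
  setNames(pr, vapply(pr, `[[`, "", "category"))
}

# Low-level venue categories plausibly found at each place category.
venue_lowlevels_for <- function(category) {
  switch(category,
         "Home" = c("Home (private)", "Apartment Building"),
         "Another's Home" = c("Home (private)", "Apartment Building"),
         "Work" = "Office",
         "Food" = c("Diner", "Coffee Shop", "Pizza Place",
                    "Cambodian Restaurant"),
         "Nightlife Spot" = c("Bar", "Nightclub", "Pub"),
         "Outdoors & Recreation" = c("Park", "Trail", "Playground"),
         "Arts & Entertainment" = c("Movie Theater", "Music Venue",
                                    "Art Gallery"),
         "Spiritual" = "Church",
         "Professional or Medical Office" = c("Doctor's Office",
                                              "Dentist's Office",
                                              "Law Office"),
         "Shop or Store" = c("Grocery Store", "Department Store",
                             "Pharmacy"),
         "Travel or Transport" = c("Bus Stop", "Train Station", "Airport"),
         stop_config("no venue low-levels for '%s'", category))
}

#' World configuration for the cohort generator
#'
#' Sampling cadences default to the study's collection design: GPS and Wi-Fi
#' every 5 min, activity every 10 s, one 15-s audio clip every 5 min, light
#' at 10 Hz (emitted in short bursts each light interval rather than
#' continuously; the feature extractors are cadence-robust by design).
#'
#' @param n_participants cohort size.
#' @param study_days study length in days (the study design is 6 weeks).
#' @param seed master RNG seed; fixes all generated randomness.
#' @param gps_noise_m GPS position noise SD in meters.
#' @param place_separation_m minimum distance between a participant's
#'   places.
#' @param gps_s,wifi_s,activity_s,audio_every_s,light_every_s,weather_s
#'   sampling cadences in seconds.
#' @param light_hz,light_burst_s light sampling rate and burst length.
#' @param audio_clip_s,audio_rate audio clip length (s) and sample rate
#'   (Hz) for raw-clip mode.
#' @param audio_mode \code{"summary"} (per-clip power and dominant
#'   frequency) or \code{"clips"} (raw tone-plus-noise series).
#' @param employed_prob probability a participant has a Work place on
#'   weekdays (about 61\% of the study sample was employed).
#' @param person_sd SD of the per-participant lognormal perturbation of the
#'   emission profiles (0 disables heterogeneity).
#' @param outing_rate mean number of non-home, non-work outings per day.
#' @param travel_min travel buffer between places, minutes.
#' @param tz_offset participants' local-time offset from UTC (hours).
#' @param center_lat,center_lon city centre around which participants live.
#' @param n_distractor_venues extra unrelated venues per participant in the
#'   venue database.
#' @return list of class \code{semloc_world_config}.
#' @export
world_config <- function(n_participants = 12, study_days = 42, seed = 1,
                         gps_noise_m = 10, place_separation_m = 600,
                         gps_s = 300, wifi_s = 300, activity_s = 10,
                         audio_every_s = 300, light_every_s = 300,
                         weather_s = 3600, light_hz = 10, light_burst_s = 2,
                         audio_clip_s = 15, audio_rate = 400,
                         audio_mode = c("summary", "clips"),
                         employed_prob = 0.61, outing_rate = 1.2,
                         person_sd = 0.3, travel_min = 10, tz_offset = -6,
                         center_lat = 41.88, center_lon = -87.63,
                         n_distractor_venues = 2) {
  audio_mode <- match.arg(audio_mode)
  cfg <- as.list(environment())
  if (place_separation_m < 2 * gps_noise_m)
    warning(structure(class = c("ConfigWarning", "warning", "condition"),
                      list(message = paste0(
                        "places closer than twice the GPS noise; distinct ",
                        "places may be indistinguishable"), call = NULL)))
  structure(cfg, class = "semloc_world_config")
}

#' Planted score-behavior effect
#'
#' Describes an effect to plant in the generated cohort: the target
#' instrument, the predictor (hours spent at one place category), and either
#' a population correlation \code{r_target} (used by
#' \code{\link{generate_cohort}}: scores become a linear function of
#' realised hours plus noise, with the slope set so the population
#' correlation equals \code{r_target}) or a standardised group mean
#' difference \code{d} (used by \code{\link{generate_budget_cohort}}).
#'
#' @param score \code{"PHQ-9"} or \code{"GAD-7"}.
#' @param predictor a place category.
#' @param r_target correlation in (-1, 1).
#' @param d standardised mean difference between score-defined groups.
#' @param noise_sd residual score SD (score points).
#' @return list of class \code{semloc_effect_spec}.
#' @export
effect_spec <- function(score = c("PHQ-9", "GAD-7"), predictor = "Spiritual",
                        r_target = NULL, d = NULL, noise_sd = 4.5) {
  score <- match.arg(score)
  if (!is.null(r_target) && abs(r_target) >= 1)
    stop_config("|r_target| must be < 1")
  structure(list(score = score, predictor = predictor, r_target = r_target,
                 d = d, noise_sd = noise_sd),
            class = "semloc_effect_spec")
}

# Lay out one participant's places: Home at a jittered city coordinate and
# one place per remaining classifiable category, pairwise separated by at
# least cfg$place_separation_m.
layout_places <- function(cfg) {
  cats <- classifiable_categories()
  home_lat <- cfg$center_lat + runif(1, -0.05, 0.05)
  home_lon <- cfg$center_lon + runif(1, -0.05, 0.05)
  lat <- home_lat; lon <- home_lon
  for (i in seq_along(cats)[-1]) {
    for (try in 1:100) {
      d <- runif(1, cfg$place_separation_m, 6 * cfg$place_separation_m)
      a <- runif(1, 0, 2 * pi)
      la <- home_lat + d * sin(a) / M_PER_DEG
      lo <- home_lon + d * cos(a) / (M_PER_DEG * cos(home_lat * pi / 180))
      if (all(dist_m(lat, lon, la, lo) >= cfg$place_separation_m)) break
    }
    lat <- c(lat, la); lon <- c(lon, lo)
  }
  data.frame(category = c("Home", setdiff(cats, "Home")), lat = lat,
             lon = lon, stringsAsFactors = FALSE)
}

#' Build a participant's generator state
#'
#' Draws the participant's place layout, employment status, and a
#' person-specific perturbation of every emission profile (multiplicative
#' lognormal effects with SD \code{cfg$person_sd} on light levels, sound
#' power, Wi-Fi density, screen/communication rates and activity mixture):
#' two people's homes are alike but not identical, which is what makes
#' generalising to unseen participants non-trivial.
#'
#' @param cfg a \code{\link{world_config}}.
#' @param profiles named list of \code{\link{place_profile}}s covering the
#'   classifiable categories.
#' @param id participant id.
#' @return list with the participant's places, employment flag, perturbed
#'   profiles and configuration, consumed by \code{\link{generate_day}}.
#' @export
make_participant_state <- function(cfg, profiles, id) {
  list(id = id, cfg = cfg,
       profiles = lapply(profiles, perturb_profile, sd = cfg$person_sd),
       places = layout_places(cfg),
       employed = runif(1) < cfg$employed_prob)
}

perturb_profile <- function(pr, sd) {
  if (sd <= 0) return(pr)
  lf <- function(s = sd) stats::rlnorm(1, 0, s)
  f <- lf()
  pr$light_day <- pr$light_day * f
  pr$light_night <- pr$light_night * f
  pr$sound_power <- pr$sound_power * lf()
  pr$sound_freq <- pr$sound_freq * lf(sd / 3)
  pr$wifi_lambda <- pr$wifi_lambda * lf()
  pr$screen_rate_h <- pr$screen_rate_h * lf()
  pr$call_rate_h <- pr$call_rate_h * lf()
  pr$sms_rate_h <- pr$sms_rate_h * lf()
  p <- pr$act_probs * stats::rlnorm(7, 0, sd)
  pr$act_probs <- p / sum(p)
  pr$trans <- pr$act_stick * diag(7) +
    (1 - pr$act_stick) * matrix(pr$act_probs, 7, 7, byrow = TRUE)
  pr
}

# ---- daily schedule ---------------------------------------------------------

# Away visits (start_h, end_h, category) for one local day; Home fills the
# complement, with a travel buffer around every away visit.
schedule_day <- function(state, dow) {
  cfg <- state$cfg
  away <- data.frame(category = character(0), start_h = numeric(0),
                     end_h = numeric(0))
  if (state$employed && dow %in% 1:5) {
    s <- rnorm(1, 8.75, 0.25); e <- rnorm(1, 17, 0.3)
    away <- rbind(away, data.frame(category = "Work", start_h = s,
                                   end_h = e))
  }
  n_out <- rpois(1, cfg$outing_rate)
  cats <- setdiff(classifiable_categories(), c("Home", "Work"))
  w <- vapply(cats, function(cc) state$profiles[[cc]]$dow_w[dow + 1], 0)
  tr_h <- cfg$travel_min / 60
  for (k in seq_len(n_out)) {
    cc <- sample(cats, 1, prob = w)
    pr <- state$profiles[[cc]]
    s <- rnorm(1, pr$tod_mean, pr$tod_sd)
    dur <- min(6, max(0.3, stats::rlnorm(1, log(pr$dur_mean_h),
                                         pr$dur_sdlog)))
    e <- s + dur
    if (s < 7 || e > 23.5) next
    if (nrow(away) &&
        any(s < away$end_h + 2 * tr_h & e > away$start_h - 2 * tr_h)) next
    away <- rbind(away, data.frame(category = cc, start_h = s, end_h = e))
  }
  away <- away[order(away$start_h), , drop = FALSE]
  # Home intervals: complement of away visits +/- travel buffer
  home <- list(); cursor <- 0
  for (i in seq_len(nrow(away))) {
    gap_end <- away$start_h[i] - tr_h
    if (gap_end - cursor >= 1 / 12) home[[length(home) + 1]] <-
        c(cursor, gap_end)
    cursor <- away$end_h[i] + tr_h
  }
  if (24 - cursor >= 1 / 12) home[[length(home) + 1]] <- c(cursor, 24)
  list(away = away, home = do.call(rbind, home))
}

# ---- stream emission --------------------------------------------------------

new_accumulator <- function() {
  env <- new.env(parent = emptyenv())
  env$gps_t <- env$gps_lat <- env$gps_lon <- list()
  env$light_t <- env$light_lux <- list()
  env$audio <- list(); env$clips <- list()
  env$screen_t <- env$screen_state <- list()
  env$act_t <- env$act_state <- list()
  env$comm_t <- env$comm_kind <- list()
  env$wifi_t <- env$wifi_n <- list()
  env
}

emit_visit_streams <- function(acc, pr, t0, t1, cfg, tz) {
  dur <- t1 - t0
  if (dur <= 0) return(invisible())
  # per-dwell conditions multiplier (weather, blinds, seat choice, ...)
  visit_f <- stats::rlnorm(1, 0, 0.2)
  # light bursts
  bs <- seq(t0, t1, by = cfg$light_every_s)
  nb <- length(bs)
  if (nb) {
    per <- max(1L, as.integer(cfg$light_hz * cfg$light_burst_s))
    tt <- rep(bs, each = per) + rep(seq_len(per) - 1, nb) / cfg$light_hz
    hour <- ((tt + tz * 3600) %% 86400) / 3600
    level <- visit_f * ifelse(hour >= 8 & hour < 20, pr$light_day,
                              pr$light_night)
    lux <- pmax(0, rnorm(length(tt), level, pr$light_sd))
    pocket <- rep(runif(nb) < pr$pocket_prob, each = per)
    lux[pocket] <- 0
    acc$light_t[[length(acc$light_t) + 1]] <- tt
    acc$light_lux[[length(acc$light_lux) + 1]] <- lux
  }
  # audio clips
  ats <- seq(t0, t1, by = cfg$audio_every_s)
  if (length(ats)) {
    if (cfg$audio_mode == "summary") {
      acc$audio[[length(acc$audio) + 1]] <- data.frame(
        t_start = ats,
        power = stats::rlnorm(length(ats), log(pr$sound_power), 0.4),
        dom_freq = abs(rnorm(length(ats), pr$sound_freq, 15)))
    } else {
      n <- as.integer(cfg$audio_clip_s * cfg$audio_rate)
      tt <- seq_len(n) / cfg$audio_rate
      for (ts in ats) {
        a <- sqrt(2 * 0.7 * pr$sound_power)
        noise_sd <- sqrt(0.3 * pr$sound_power)
        acc$clips[[length(acc$clips) + 1]] <- list(
          t_start = ts, rate = cfg$audio_rate,
          samples = a * sin(2 * pi * pr$sound_freq * tt) +
            rnorm(n, 0, noise_sd))
      }
    }
  }
  # activity (Markov chain over the 7 recogniser states)
  nact <- as.integer(dur / cfg$activity_s)
  if (nact > 0) {
    st <- markov_chain_cpp(nact, pr$act_probs, pr$trans)
    acc$act_t[[length(acc$act_t) + 1]] <- t0 + seq_len(nact) * cfg$activity_s
    acc$act_state[[length(acc$act_state) + 1]] <- activity_states()[st]
  }
  # screen sessions
  n_on <- rpois(1, pr$screen_rate_h * dur / 3600)
  if (n_on > 0) {
    on_t <- sort(runif(n_on, t0, t1))
    off_t <- pmin(on_t + stats::rexp(n_on, 1 / pr$screen_on_s), t1)
    keep <- off_t > on_t
    # drop overlapping sessions to keep states alternating
    if (any(keep)) {
      on_t <- on_t[keep]; off_t <- off_t[keep]
      ok <- rep(TRUE, length(on_t)); last_off <- -Inf
      for (i in seq_along(on_t)) {
        if (on_t[i] <= last_off) ok[i] <- FALSE else last_off <- off_t[i]
      }
      on_t <- on_t[ok]; off_t <- off_t[ok]
      acc$screen_t[[length(acc$screen_t) + 1]] <-
        as.vector(rbind(on_t, off_t))
      acc$screen_state[[length(acc$screen_state) + 1]] <-
        rep(c("ON", "OFF"), length(on_t))
    }
  }
  # calls and SMS
  kinds <- comm_kinds()
  kp <- c(0.45, 0.35, 0.2)   # in / out / missed among calls
  n_call <- rpois(1, pr$call_rate_h * dur / 3600)
  n_sms <- rpois(1, pr$sms_rate_h * dur / 3600)
  if (n_call + n_sms > 0) {
    kk <- c(sample(kinds[1:3], n_call, replace = TRUE, prob = kp),
            sample(kinds[4:5], n_sms, replace = TRUE))
    acc$comm_t[[length(acc$comm_t) + 1]] <- runif(n_call + n_sms, t0, t1)
    acc$comm_kind[[length(acc$comm_kind) + 1]] <- kk
  }
  # wifi scans
  wts <- seq(t0, t1, by = cfg$wifi_s)
  if (length(wts)) {
    acc$wifi_t[[length(acc$wifi_t) + 1]] <- wts
    acc$wifi_n[[length(acc$wifi_n) + 1]] <- rpois(length(wts),
                                                  pr$wifi_lambda)
  }
  invisible()
}

#' Generate one day of streams and ground-truth visits
#'
#' Draws the day's schedule (Home overnight, Work on weekdays for employed
#' participants, stochastic outings with travel gaps), emits every sensor
#' stream with the visited place's emission profile, and returns the
#' ground-truth visits.  GPS is emitted on a fixed grid all day: at the
#' occupied place during visits (with GPS noise) and interpolated between
#' places while travelling.
#'
#' @param state from \code{\link{make_participant_state}}.
#' @param date local calendar day (\code{Date}).
#' @return list with \code{streams} (named list of data.frames) and
#'   \code{visits} (list of labeled \code{semloc_visit}).
#' @export
generate_day <- function(state, date) {
  cfg <- state$cfg
  tz <- cfg$tz_offset
  epoch_day <- as.numeric(as.Date(date))
  day0 <- epoch_day * 86400 - tz * 3600   # UTC time of local midnight
  dow <- (epoch_day + 4) %% 7
  sch <- schedule_day(state, dow)
  acc <- new_accumulator()
  # table of (category, t0, t1) dwells
  dw <- rbind(
    if (!is.null(sch$home))
      data.frame(category = "Home", t0 = day0 + sch$home[, 1] * 3600,
                 t1 = day0 + sch$home[, 2] * 3600),
    if (nrow(sch$away))
      data.frame(category = sch$away$category,
                 t0 = day0 + sch$away$start_h * 3600,
                 t1 = day0 + sch$away$end_h * 3600))
  dw <- dw[order(dw$t0), , drop = FALSE]
  place_of <- match(dw$category, state$places$category)
  for (i in seq_len(nrow(dw)))
    emit_visit_streams(acc, state$profiles[[dw$category[i]]], dw$t0[i],
                       dw$t1[i], cfg, tz)
  # GPS grid over the whole day: at the dwelled place, or interpolated
  gt <- day0 + seq(0, 86399, by = cfg$gps_s)
  pos <- matrix(NA_real_, length(gt), 2)
  for (i in seq_len(nrow(dw))) {
    inside <- gt >= dw$t0[i] & gt <= dw$t1[i]
    pos[inside, 1] <- state$places$lat[place_of[i]]
    pos[inside, 2] <- state$places$lon[place_of[i]]
  }
  travel <- which(is.na(pos[, 1]))
  for (j in travel) {
    prev_i <- which(dw$t1 <= gt[j]); next_i <- which(dw$t0 >= gt[j])
    if (!length(prev_i) || !length(next_i)) next
    a <- prev_i[length(prev_i)]; b <- next_i[1]
    f <- (gt[j] - dw$t1[a]) / max(dw$t0[b] - dw$t1[a], 1)
    pos[j, 1] <- (1 - f) * state$places$lat[place_of[a]] +
      f * state$places$lat[place_of[b]]
    pos[j, 2] <- (1 - f) * state$places$lon[place_of[a]] +
      f * state$places$lon[place_of[b]]
  }
  keep <- !is.na(pos[, 1])
  noise <- cfg$gps_noise_m / M_PER_DEG
  gps <- data.frame(t = gt[keep],
                    lat = pos[keep, 1] + rnorm(sum(keep), 0, noise),
                    lon = pos[keep, 2] + rnorm(sum(keep), 0, noise) /
                      cos(cfg$center_lat * pi / 180))
  # ground-truth visits: one per place per day, possibly several intervals
  visits <- list()
  for (cc in unique(dw$category)) {
    rows <- dw[dw$category == cc, , drop = FALSE]
    pi_ <- match(cc, state$places$category)
    visits[[length(visits) + 1]] <- new_visit(
      state$id, as.Date(date), state$places$lat[pi_],
      state$places$lon[pi_], cbind(rows$t0, rows$t1), label = cc)
  }
  streams <- list(
    gps = gps,
    light = data.frame(t = unlist(acc$light_t),
                       lux = unlist(acc$light_lux)),
    audio_summary = if (length(acc$audio)) do.call(rbind, acc$audio)
                    else NULL,
    audio_clips = acc$clips,
    screen = data.frame(t = unlist(acc$screen_t),
                        state = unlist(acc$screen_state)),
    activity = data.frame(t = unlist(acc$act_t),
                          state = unlist(acc$act_state)),
    comm = data.frame(t = unlist(acc$comm_t),
                      kind = unlist(acc$comm_kind)),
    wifi = data.frame(t = unlist(acc$wifi_t),
                      n_networks = unlist(acc$wifi_n)))
  list(streams = streams, visits = visits)
}

empty_df_guard <- function(df, cols) {
  if (is.null(df) || !nrow(df)) return(NULL)
  df
}

# Weather for one participant over the study: smooth daily temperature cycle
# plus noise; dew point at or below temperature; condition coded 0..4.
generate_weather <- function(cfg, day_first, n_days) {
  t <- (day_first * 86400) + seq(0, n_days * 86400 - 1, by = cfg$weather_s)
  hour <- ((t + cfg$tz_offset * 3600) %% 86400) / 3600
  base <- rnorm(1, 8, 6)
  temp <- base + 7 * sin(2 * pi * (hour - 9) / 24) + rnorm(length(t), 0, 2)
  dew <- temp - abs(rnorm(length(t), 3, 2))
  cond <- sample(0:4, length(t), replace = TRUE,
                 prob = c(.35, .25, .2, .15, .05))
  data.frame(t = t, temperature = temp, dew_point = dew, condition = cond)
}

#' Generate a synthetic cohort
#'
#' Generates \code{cfg$n_participants} participants over
#' \code{cfg$study_days} days: all sensor streams with place-dependent
#' signatures, daily diary reports derived from the ground-truth visits
#' (dwell intervals shorter than 10 minutes dropped, matching the diary
#' app's filter), a shared venue database (one venue per generated place
#' plus unrelated distractors), and three-wave PHQ-9/GAD-7 scores.  With an
#' \code{\link{effect_spec}} carrying \code{r_target}, the target scores are
#' \eqn{a + b\,x + \epsilon} in the realised hours \eqn{x} at the predictor
#' category, with \eqn{b} set from the realised SD of \eqn{x} so the
#' population correlation equals \code{r_target}; otherwise scores are
#' effect-free draws centred near the study sample's means.
#'
#' @param cfg a \code{\link{world_config}}.
#' @param profiles named list of place profiles.
#' @param fx optional \code{\link{effect_spec}}.
#' @return list with \code{participants} (list of
#'   \code{\link{participant}}), \code{truth} (data.frame of ground-truth
#'   visit intervals), \code{venue_db}, \code{hierarchy} and \code{budgets}
#'   (true hours per participant per category).
#' @export
generate_cohort <- function(cfg = world_config(),
                            profiles = default_place_profiles(),
                            fx = NULL) {
  stopifnot(inherits(cfg, "semloc_world_config"))
  with_seed(cfg$seed, generate_cohort_impl(cfg, profiles, fx))
}

generate_cohort_impl <- function(cfg, profiles, fx) {
  day_first <- as.numeric(as.Date("2015-11-02"))
  participants <- list(); truth <- list(); venues <- list()
  for (i in seq_len(cfg$n_participants)) {
    id <- sprintf("P%03d", i)
    state <- make_participant_state(cfg, profiles, id)
    days <- lapply(seq_len(cfg$study_days) - 1, function(d)
      generate_day(state, as.Date(day_first + d, origin = "1970-01-01")))
    cat_bind <- function(extract) {
      parts <- lapply(days, function(d) empty_df_guard(extract(d)))
      parts <- parts[!vapply(parts, is.null, TRUE)]
      if (!length(parts)) NULL else do.call(rbind, parts)
    }
    visits <- unlist(lapply(days, `[[`, "visits"), recursive = FALSE)
    ema <- build_ema(visits)
    weather <- generate_weather(cfg, day_first, cfg$study_days)
    p <- participant(
      id = id, tz_offset = cfg$tz_offset,
      gps = cat_bind(function(d) d$streams$gps),
      light = cat_bind(function(d) d$streams$light),
      audio_summary = cat_bind(function(d) d$streams$audio_summary),
      audio_clips = unlist(lapply(days, function(d) d$streams$audio_clips),
                           recursive = FALSE),
      screen = cat_bind(function(d) d$streams$screen),
      activity = cat_bind(function(d) d$streams$activity),
      comm = cat_bind(function(d) d$streams$comm),
      wifi = {
        w <- cat_bind(function(d) d$streams$wifi)
        if (!is.null(w)) w$ap_id <- sprintf("ap%s", substr(hash_id(id), 1, 6))
        w
      },
      weather = weather, ema = ema)
    participants[[i]] <- p
    for (v in visits)
      truth[[length(truth) + 1]] <- data.frame(
        id = id, date = v$day, category = v$label, lat = v$center_lat,
        lon = v$center_lon, enter = v$intervals[, 1],
        exit = v$intervals[, 2])
    # venue database entries for this participant's places + distractors
    pl <- state$places
    jitter <- 5 / M_PER_DEG
    venues[[length(venues) + 1]] <- data.frame(
      lat = pl$lat + rnorm(nrow(pl), 0, jitter),
      lon = pl$lon + rnorm(nrow(pl), 0, jitter),
      low_level_category = vapply(pl$category, function(cc)
        sample(venue_lowlevels_for(cc), 1), ""))
    nd <- cfg$n_distractor_venues
    if (nd > 0) {
      # unrelated venues near every place (urban venue density is what lets
      # a coordinate-only lookup pick the wrong neighbour)
      n_all <- nd * nrow(pl)
      off <- runif(n_all, 30, 300) / M_PER_DEG
      ang <- runif(n_all, 0, 2 * pi)
      venues[[length(venues) + 1]] <- data.frame(
        lat = rep(pl$lat, each = nd) + off * sin(ang),
        lon = rep(pl$lon, each = nd) + off * cos(ang),
        low_level_category = sample(names(default_hierarchy()), n_all,
                                    replace = TRUE))
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(0), date = as.Date(character(0)),
               category = character(0), lat = numeric(0), lon = numeric(0),
               enter = numeric(0), exit = numeric(0))
  venue_db <- if (length(venues)) do.call(rbind, venues) else
    data.frame(lat = numeric(0), lon = numeric(0),
               low_level_category = character(0))
  if (nrow(venue_db))
    venue_db <- cbind(venue_id = sprintf("v%04d", seq_len(nrow(venue_db))),
                      venue_db)
  budgets <- time_budget_from_truth(truth,
                                    ids = vapply(participants, `[[`, "",
                                                 "id"))
  participants <- plant_scores(participants, budgets, fx)
  list(participants = participants, truth = truth, venue_db = venue_db,
       hierarchy = default_hierarchy(), budgets = budgets)
}

build_ema <- function(visits) {
  if (!length(visits)) return(NULL)
  rows <- list()
  for (v in visits) {
    iv <- v$intervals[v$intervals[, 2] - v$intervals[, 1] >= 600, ,
                      drop = FALSE]
    if (!nrow(iv)) next   # all dwells under the 10-minute diary filter
    rows[[length(rows) + 1]] <- list(
      date = v$day, center_lat = v$center_lat, center_lon = v$center_lon,
      category = v$label, free_text = "", intervals = iv)
  }
  if (!length(rows)) return(NULL)
  ema <- data.frame(
    date = as.Date(vapply(rows, function(r) as.character(r$date), "")),
    center_lat = vapply(rows, `[[`, 0, "center_lat"),
    center_lon = vapply(rows, `[[`, 0, "center_lon"),
    category = vapply(rows, `[[`, "", "category"),
    free_text = "", stringsAsFactors = FALSE)
  ema$intervals <- lapply(rows, `[[`, "intervals")
  ema
}

time_budget_from_truth <- function(truth, ids) {
  cats <- classifiable_categories()
  out <- matrix(0, length(ids), length(cats), dimnames = list(ids, cats))
  if (nrow(truth)) {
    h <- (truth$exit - truth$enter) / 3600
    agg <- tapply(h, list(truth$id, truth$category), sum)
    for (id in intersect(rownames(agg), ids))
      for (cc in intersect(colnames(agg), cats))
        if (!is.na(agg[id, cc])) out[id, cc] <- agg[id, cc]
  }
  as.data.frame(out)
}

# Three-wave scores; with fx$r_target, the target instrument follows
# a + b * hours + person effect + wave noise, b solving the population
# correlation.  Scores are rounded and clipped to the instrument range.
plant_scores <- function(participants, budgets, fx) {
  n <- length(participants)
  if (!n) return(participants)
  mk_plain <- function(mu, sdev, hi) {
    u <- rnorm(n, 0, sdev * 0.8)
    matrix(vapply(1:3, function(w)
      pmin(hi, pmax(0, round(mu + u + rnorm(n, 0, sdev * 0.6)))),
      numeric(n)), nrow = n)
  }
  phq <- mk_plain(9.7, 5.1, 27)
  gad <- mk_plain(9.0, 5.4, 21)
  if (!is.null(fx) && !is.null(fx$r_target)) {
    x <- budgets[[fx$predictor]]
    sx <- sd(x)
    if (is.na(sx) || sx == 0)
      stop_config("predictor category '%s' has zero variance", fx$predictor)
    b <- fx$r_target * fx$noise_sd / (sx * sqrt(1 - fx$r_target^2))
    hi <- if (fx$score == "PHQ-9") 27 else 21
    mu <- hi / 2
    u <- rnorm(n, 0, fx$noise_sd * sqrt(0.6))
    planted <- matrix(vapply(1:3, function(w)
      pmin(hi, pmax(0, round(mu + b * (x - mean(x)) + u +
                               rnorm(n, 0, fx$noise_sd * sqrt(0.4))))),
      numeric(n)), nrow = n)
    if (fx$score == "PHQ-9") phq <- planted else gad <- planted
  }
  for (i in seq_len(n)) {
    participants[[i]]$phq9 <- as.integer(phq[i, ])
    participants[[i]]$gad7 <- as.integer(gad[i, ])
  }
  participants
}

#' Generate score/time budgets directly (no sensor streams)
#'
#' Lightweight cohort generator at the time-budget level, used for
#' calibration studies of the association analyses where hundreds of
#' replicate cohorts are needed: hours per category are lognormal draws with
#' category-typical means, and either a correlation \code{r_target} or a
#' standardised group difference \code{d} is planted for the
#' \code{fx$predictor} category.  With \code{d}, participants are assigned
#' to a consistently-below group (all three scores < 10) or a
#' consistently-above group (all three > 10) and the predictor hours of the
#' above group are shifted by \code{d} pooled SDs.
#'
#' @param n participants (with \code{d}: per group).
#' @param fx an \code{\link{effect_spec}}.
#' @param seed RNG seed.
#' @param study_days scaling for typical hours.
#' @return list with \code{budgets} (data.frame participants x categories,
#'   hours), \code{phq9}, \code{gad7} (n x 3 integer matrices) and
#'   \code{group} (with \code{d}: "below"/"above").
#' @export
generate_budget_cohort <- function(n = 200, fx = effect_spec(r_target = 0.3),
                                   seed = 1, study_days = 42) {
  with_seed(seed, {
    cats <- classifiable_categories()
    typ_h_day <- c("Nightlife Spot" = 0.2, "Outdoors & Recreation" = 0.4,
                   "Arts & Entertainment" = 0.3,
                   "Professional or Medical Office" = 0.15, "Food" = 0.7,
                   "Home" = 14, "Shop or Store" = 0.5,
                   "Travel or Transport" = 0.4, "Spiritual" = 0.25,
                   "Work" = 5, "Another's Home" = 0.6)
    n_total <- if (!is.null(fx$d)) 2 * n else n
    budgets <- as.data.frame(vapply(cats, function(cc)
      stats::rlnorm(n_total, log(typ_h_day[[cc]] * study_days), 0.5),
      numeric(n_total)))
    names(budgets) <- cats
    rownames(budgets) <- sprintf("P%03d", seq_len(n_total))
    group <- NULL
    hi <- if (fx$score == "PHQ-9") 27 else 21
    if (!is.null(fx$d)) {
      group <- rep(c("below", "above"), each = n)
      s <- sd(budgets[[fx$predictor]])
      budgets[[fx$predictor]][group == "above"] <-
        budgets[[fx$predictor]][group == "above"] + fx$d * s
      below <- pmax(0, pmin(9, round(rnorm(n_total * 3, 5, 2))))
      above <- pmax(11, pmin(hi, round(rnorm(n_total * 3, 15, 2.5))))
      sc <- matrix(ifelse(rep(group == "below", 3), below, above),
                   n_total, 3)
    } else if (!is.null(fx$r_target)) {
      x <- budgets[[fx$predictor]]
      b <- fx$r_target * fx$noise_sd / (sd(x) * sqrt(1 - fx$r_target^2))
      sc <- vapply(1:3, function(w)
        pmin(hi, pmax(0, round(hi / 2 + b * (x - mean(x)) +
                                 rnorm(n_total, 0, fx$noise_sd)))),
        numeric(n_total))
    } else {
      sc <- matrix(pmax(0, pmin(hi, round(rnorm(n_total * 3, hi / 2.6,
                                                hi / 5)))), n_total, 3)
    }
    other <- matrix(pmax(0, pmin(21, round(rnorm(n_total * 3, 8, 5)))),
                    n_total, 3)
    storage.mode(sc) <- "integer"; storage.mode(other) <- "integer"
    if (fx$score == "PHQ-9") list(budgets = budgets, phq9 = sc,
                                  gad7 = other, group = group)
    else list(budgets = budgets, phq9 = other, gad7 = sc, group = group)
  })
}
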