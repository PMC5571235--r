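# Independent brute-force oracles for each extractor live inline; the
# randomized sweeps over all extractors at once are in test-acceptance.R.


test_that("light features handle degenerate inputs as specified", {
  const <- data.frame(t = seq(0, 9.9, by = 0.1), lux = 7)
  f <- light_features(const)
  expect_equal(unname(f), c(7, 0, NA, NA, 0, 0))
  zeros <- data.frame(t = 1:10, lux = 0)
  expect_equal(light_features(zeros)[["light_frac_zero"]], 1)
  expect_true(all(is.na(light_features(const[0, ]))))
  one <- data.frame(t = 5, lux = 3)
  f1 <- light_features(one)
  expect_equal(f1[["light_mean"]], 3)
  expect_true(is.na(f1[["light_var"]]))
})

test_that("mean-crossing rate matches a hand count on a square wave", {
  # 1 Hz square wave sampled at 10 Hz for 10 s: 2 mean crossings per cycle
  t <- seq(0, 9.9, by = 0.1)
  lux <- ifelse(t %% 1 < 0.5, 100, 300)
  f <- light_features(data.frame(t = t, lux = lux))
  expect_equal(f[["light_crossings_per_s"]], 19 / 9.9, tolerance = 0.11)
  expect_equal(unname(f[1:6]),
               light_oracle(t, lux), tolerance = 1e-12)
})

test_that("light features match the oracle on randomized inputs", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    t <- sort(runif(n, 0, 600))
    lux <- pmax(0, rnorm(n, runif(1, 0, 300), runif(1, 1, 100)))
    if (runif(1) < 0.3) lux[sample(n, ceiling(n / 4))] <- 0
    f <- light_features(data.frame(t = t, lux = lux))
    expect_equal(unname(f[1:6]), light_oracle(t, lux), tolerance = 1e-10)
  }
})

test_that("sound power and dominant frequency recover known signals", {
  # constant amplitude: power is the squared amplitude
  cl <- list(t_start = 0, rate = 100, samples = rep(3, 200))
  expect_equal(sound_features(list(cl))[["sound_power"]], 9)
  # pure 440 Hz tone, 15 s at 8 kHz: recovered within one FFT bin
  t <- seq(0, 15 - 1 / 8000, by = 1 / 8000)
  tone <- list(t_start = 0, rate = 8000, samples = sin(2 * pi * 440 * t))
  f <- sound_features(list(tone))
  expect_lte(abs(f[["sound_dom_freq"]] - 440), 1 / 15 + 1e-9)
  # two tones: the larger-amplitude one dominates
  mix <- list(t_start = 0, rate = 2000,
              samples = 2 * sin(2 * pi * 100 * t[1:4000] * 4) +
                1 * sin(2 * pi * 300 * t[1:4000] * 4))
  expect_equal(sound_features(list(mix))[["sound_dom_freq"]], 100,
               tolerance = 1)
  # short clip skipped with a warning; nothing usable -> NA
  expect_warning(out <- sound_features(list(list(t_start = 0, rate = 10,
                                                 samples = 1))))
  expect_true(all(is.na(out)))
})

test_that("dominant frequency matches a direct DFT argmax oracle", {
  set.seed(102)
  for (i in 1:20) {
    n <- 256
    rate <- sample(c(100, 200, 500), 1)
    x <- rnorm(n) + runif(1, 1, 4) *
      sin(2 * pi * sample(5:40, 1) * seq_len(n) / rate)
    # direct O(n^2) DFT
    ks <- 1:(n / 2)
    amp <- vapply(ks, function(k)
      Mod(sum(x * exp(-2i * pi * k * (seq_len(n) - 1) / n))), 0)
    expected <- ks[which.max(amp)] * rate / n
    got <- sound_features(list(list(t_start = 0, rate = rate,
                                    samples = x)))[["sound_dom_freq"]]
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("per-visit sound values average over clips and summaries", {
  s <- data.frame(t_start = c(0, 300), power = c(10, 30),
                  dom_freq = c(100, 200))
  f <- sound_features(summary = s)
  expect_equal(unname(f), c(20, 150))
  expect_true(all(is.na(sound_features())))
})


test_that("screen features count OFF-to-ON transitions and ON durations", {
  expect_equal(unname(screen_features(data.frame(t = numeric(0),
                                                 state = character(0)))),
               c(0, NA, NA))
  ev <- data.frame(t = c(0, 60, 120, 180),
                   state = c("ON", "OFF", "ON", "OFF"))
  expect_equal(unname(screen_features(ev)), c(2, 60, 0))
  # unterminated final ON censored at the visit end
  ev2 <- data.frame(t = c(0, 60, 100), state = c("ON", "OFF", "ON"))
  expect_equal(unname(screen_features(ev2, visit_end = 130)),
               c(2, 45, sd(c(60, 30))))
  set.seed(103)
  for (i in 1:30) {
    n <- sample(2:50, 1)
    ev <- data.frame(t = sort(runif(n, 0, 3600)),
                     state = sample(c("ON", "OFF"), n, replace = TRUE))
    end <- 3700
    expect_equal(unname(screen_features(ev, visit_end = end)),
                 screen_oracle(ev, end), tolerance = 1e-10)
  }
})

test_that("activity occupancy and transition fractions are as defined", {
  all_still <- data.frame(t = 1:10, state = "Still")
  expect_equal(unname(activity_features(all_still)),
               c(1, 0, 0, 0, 0, 0, 0, 0))
  seqv <- data.frame(t = 1:4,
                     state = c("Still", "Walking", "Still", "Walking"))
  f <- activity_features(seqv)
  expect_equal(f[["act_frac_still"]], 0.5)
  expect_equal(f[["act_trans_still_walking"]], 2 / 3)
  # uniform random states: occupancies near 1/7
  set.seed(104)
  n <- 1e4
  big <- data.frame(t = seq_len(n),
                    state = sample(semloc:::activity_states(), n,
                                   replace = TRUE))
  fb <- activity_features(big)
  se <- sqrt((1 / 7) * (6 / 7) / n)
  for (nm in c("act_frac_still", "act_frac_tilting", "act_frac_walking",
               "act_frac_unknown"))
    expect_lte(abs(fb[[nm]] - 1 / 7), 3 * se)
  # single sample: no transitions, fractions 0
  expect_equal(activity_features(all_still[1, ])[["act_trans_still_walking"]],
               0)
})

test_that("communication counts match a counting oracle", {
  empty <- data.frame(t = numeric(0), kind = character(0))
  expect_equal(unname(comm_features(empty)), rep(0, 5))
  ev <- data.frame(t = 1:3, kind = c("call_in", "call_in", "sms_out"))
  expect_equal(unname(comm_features(ev)), c(2, 0, 0, 0, 1))
  set.seed(105)
  kinds <- semloc:::comm_kinds()
  ev <- data.frame(t = runif(500), kind = sample(kinds, 500, replace = TRUE))
  f <- comm_features(ev)
  for (i in seq_along(kinds))
    expect_equal(unname(f[i]), sum(ev$kind == kinds[i]))
})

test_that("location variance uses the log of the coordinate variance sum", {
  t0 <- 1.45e9
  v <- simple_visit(t0, hours = 1)
  ident <- data.frame(t = t0 + 1:5 * 60, lat = rep(41.9, 5),
                      lon = rep(-87.6, 5))
  f <- gps_features(v, ident)
  expect_true(is.na(f[["gps_location_variance"]]))
  lat <- 41.9 + c(0, 0.001, 0.002)
  fx <- data.frame(t = t0 + 1:3 * 60, lat = lat, lon = rep(-87.6, 3))
  # independent two-pass variance oracle
  two_pass_var <- function(x) { m <- sum(x) / length(x)
    sum((x - m)^2) / (length(x) - 1) }
  v2 <- simple_visit(t0, hours = 1, lat = mean(lat))
  expect_equal(gps_features(v2, fx)[["gps_location_variance"]],
               log(two_pass_var(lat)), tolerance = 1e-12)
})

test_that("visit frequency counts 50 m revisit episodes across the study", {
  t0 <- 1.45e9
  # same place visited daily for 5 days, 1 h each
  fixes <- do.call(rbind, lapply(0:4, function(d)
    data.frame(t = t0 + d * 86400 + seq(0, 3600, by = 300),
               lat = 41.9, lon = -87.6)))
  v <- simple_visit(t0, hours = 1)
  f <- gps_features(v, fixes)
  expect_equal(f[["gps_visit_frequency"]], 5)
  expect_equal(f[["gps_mean_visit_gap_s"]], 86400)
  # fixes beyond 50 m do not count
  far <- fixes
  far$lat <- far$lat + 200 / semloc:::M_PER_DEG
  expect_equal(gps_features(v, rbind(fixes[1:13, ], far))[[
    "gps_visit_frequency"]], 1)
})

test_that("wifi feature is the mean network count", {
  expect_equal(unname(wifi_features(data.frame(t = 1, ap_id = "a",
                                               n_networks = 7))), 7)
  expect_equal(unname(wifi_features(data.frame(t = 1:2, ap_id = "a",
                                               n_networks = c(3, 5)))), 4)
  set.seed(106)
  n <- rpois(100, 6)
  expect_equal(unname(wifi_features(data.frame(t = 1:100, ap_id = "a",
                                               n_networks = n))), mean(n))
  expect_true(is.na(wifi_features(data.frame(t = numeric(0),
                                             ap_id = character(0),
                                             n_networks = numeric(0)))))
})

test_that("time features: duration, timespan, mid hour, day of week", {
  day0 <- as.numeric(as.Date("2015-11-05")) * 86400   # a Thursday
  v <- semloc:::new_visit("p", as.Date("2015-11-05"), 41.9, -87.6,
                          cbind(day0 + 10 * 3600, day0 + 12 * 3600))
  f <- time_features(v)
  expect_equal(unname(f), c(7200, 7200, 11, 4, 4))
  # split visit: 09:00-10:00 and 13:00-14:00
  v2 <- semloc:::new_visit("p", as.Date("2015-11-05"), 41.9, -87.6,
                           rbind(c(day0 + 9 * 3600, day0 + 10 * 3600),
                                 c(day0 + 13 * 3600, day0 + 14 * 3600)))
  f2 <- time_features(v2)
  expect_equal(unname(f2), c(7200, 18000, 11.5, 4, 4))
  # crossing midnight changes the day of week
  v3 <- semloc:::new_visit("p", as.Date("2015-11-05"), 41.9, -87.6,
                           cbind(day0 + 23 * 3600, day0 + 25 * 3600))
  f3 <- time_features(v3)
  expect_equal(f3[["time_dow_start"]], 4)
  expect_equal(f3[["time_dow_end"]], 5)
  # timezone offset shifts the local mid hour
  expect_equal(time_features(v, tz_offset = -6)[["time_mid_hour"]], 5)
})

test_that("weather features pick the report nearest the visit mid-time", {
  t0 <- 1.45e9
  v <- simple_visit(t0, hours = 2)           # mid at t0 + 3600
  mk <- function(ts) data.frame(t = ts, temperature = seq_along(ts),
                                dew_point = seq_along(ts) - 3,
                                condition = seq_along(ts) %% 5)
  one <- mk(t0)
  expect_equal(weather_features(one, v)[["wx_temperature"]], 1)
  two <- mk(c(t0 + 3600 - 3600, t0 + 3600 + 6 * 3600))
  expect_equal(weather_features(two, v)[["wx_temperature"]], 1)
  expect_true(all(is.na(weather_features(mk(numeric(0)), v))))
  set.seed(107)
  for (i in 1:30) {
    ts <- t0 + runif(50, -86400, 86400)
    r <- mk(ts)
    expect_equal(weather_features(r, v)[["wx_temperature"]],
                 r$temperature[which.min(abs(ts - (t0 + 3600)))])
  }
})

test_that("build_feature_vector restricts streams to the visit intervals", {
  p <- tiny_participant()
  t0 <- p$gps$t[1]
  v <- simple_visit(t0, hours = 1, lat = mean(p$gps$lat),
                    lon = mean(p$gps$lon))
  x <- build_feature_vector(v, p)
  expect_identical(names(x), feature_registry())
  # equality with extractors applied to pre-restricted streams
  iv <- v$intervals
  expect_equal(x[1:6], light_features(semloc:::restrict(p$light, iv)))
  expect_equal(x[9:11],
               screen_features(semloc:::restrict(p$screen, iv),
                               visit_end = max(iv[, 2])))
  expect_equal(x[20:24], comm_features(semloc:::restrict(p$comm, iv)))
  # a GPS-only bundle populates gps + time slots, everything else missing
  pg <- participant("gps-only", gps = p$gps)
  xg <- build_feature_vector(v, pg)
  expect_false(any(is.na(xg[c("gps_mean_lat", "time_duration_s",
                              "time_mid_hour")])))
  expect_true(all(is.na(xg[c("light_mean", "sound_power",
                             "wifi_mean_n_networks", "wx_temperature")])))
  # venue slots appended on request: 38 sensor + 10 venue
  vf <- venue_features(data.frame(venue_id = "v1", lat = 41.9, lon = -87.6,
                                  low_level_category = "Diner"),
                       12, default_hierarchy())
  xv <- build_feature_vector(v, p, venue = vf)
  expect_length(xv, length(feature_registry()) + 10)
  expect_identical(names(xv), feature_registry(venue = TRUE))
})

test_that("fraction-type features stay in [0, 1] on generated visits", {
  w <- generate_cohort(world_config(n_participants = 2, study_days = 3,
                                    seed = 77))
  frac_slots <- c("light_frac_zero", "act_frac_still", "act_frac_tilting",
                  "act_frac_walking", "act_frac_unknown",
                  "act_trans_still_walking", "act_trans_still_tilting",
                  "act_trans_still_unknown", "act_trans_walking_unknown")
  for (p in w$participants) {
    vs <- detect_visits_study(p)
    for (v in vs[seq_len(min(5, length(vs)))]) {
      x <- build_feature_vector(v, p)
      vals <- x[frac_slots]
      expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
      occ <- sum(x[c("act_frac_still", "act_frac_tilting",
                     "act_frac_walking", "act_frac_unknown")], na.rm = TRUE)
      expect_lte(occ, 1 + 1e-9)
      expect_true(x[["time_mid_hour"]] >= 0 && x[["time_mid_hour"]] < 24)
      expect_true(x[["time_dow_start"]] %in% 0:6)
    }
  }
})
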