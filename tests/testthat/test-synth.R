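test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- world_config(n_participants = 2, study_days = 3, seed = 101)
  w1 <- generate_cohort(cfg)
  w2 <- generate_cohort(cfg)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$participants[[1]]$gps, w2$participants[[1]]$gps)
  expect_identical(w1$participants[[2]]$light, w2$participants[[2]]$light)
  expect_identical(w1$venue_db, w2$venue_db)
  expect_identical(vapply(w1$participants, function(p) p$phq9[1], 0L),
                   vapply(w2$participants, function(p) p$phq9[1], 0L))
  # a different seed changes the data
  w3 <- generate_cohort(world_config(n_participants = 2, study_days = 3,
                                     seed = 102))
  expect_false(identical(w1$truth, w3$truth))
})

test_that("an empty cohort is allowed", {
  w <- generate_cohort(world_config(n_participants = 0, study_days = 3,
                                    seed = 1))
  expect_length(w$participants, 0)
  expect_equal(nrow(w$truth), 0)
})

test_that("implausible geometry warns without failing", {
  expect_warning(world_config(place_separation_m = 10, gps_noise_m = 20),
                 class = "ConfigWarning")
})

test_that("every ground-truth visit with a >= 10 min dwell has a report", {
  w <- generate_cohort(world_config(n_participants = 2, study_days = 4,
                                    seed = 103))
  for (p in w$participants) {
    tr <- w$truth[w$truth$id == p$id & (w$truth$exit - w$truth$enter) >= 600, ]
    for (i in seq_len(nrow(tr))) {
      same <- p$ema[as.Date(p$ema$date) == tr$date[i] &
                      p$ema$category == tr$category[i], , drop = FALSE]
      expect_gt(nrow(same), 0)
      d <- dist_oracle_m(same$center_lat, same$center_lon, tr$lat[i],
                         tr$lon[i])
      expect_lt(min(d), 50)
    }
    # diary intervals respect the 10-minute filter
    for (iv in p$ema$intervals)
      expect_true(all(iv[, 2] - iv[, 1] >= 600))
  }
})

test_that("streams obey their configured cadences within jitter", {
  cfg <- world_config(n_participants = 1, study_days = 2, seed = 104)
  w <- generate_cohort(cfg)
  p <- w$participants[[1]]
  expect_equal(median(diff(p$gps$t)), cfg$gps_s)
  expect_equal(median(diff(p$wifi$t)), cfg$wifi_s, tolerance = 0.2)
  expect_equal(median(diff(p$activity$t)), cfg$activity_s)
  expect_equal(median(diff(p$audio_summary$t_start)), cfg$audio_every_s,
               tolerance = 0.2)
  # light bursts: within-burst spacing at the sensor rate
  expect_equal(median(diff(p$light$t)), 1 / cfg$light_hz, tolerance = 1e-6)
})

test_that("GPS fixes during a visit stay within 3 noise SDs of the centre", {
  cfg <- world_config(n_participants = 1, study_days = 3, seed = 105,
                      gps_noise_m = 12)
  w <- generate_cohort(cfg)
  p <- w$participants[[1]]
  tr <- w$truth[w$truth$id == p$id, ]
  frac_in <- numeric(0)
  for (i in seq_len(nrow(tr))) {
    sel <- p$gps$t >= tr$enter[i] & p$gps$t <= tr$exit[i]
    if (!any(sel)) next
    d <- dist_oracle_m(p$gps$lat[sel], p$gps$lon[sel], tr$lat[i], tr$lon[i])
    frac_in <- c(frac_in, mean(d <= 3 * cfg$gps_noise_m * sqrt(2)))
  }
  expect_gte(mean(frac_in), 0.99)
})

test_that("ground-truth dwell times match the schedule within jitter", {
  w <- generate_cohort(world_config(n_participants = 2, study_days = 5,
                                    seed = 106))
  tr <- w$truth
  # visits never overlap within a participant-day
  for (key in unique(paste(tr$id, tr$date))) {
    rows <- tr[paste(tr$id, tr$date) == key, ]
    rows <- rows[order(rows$enter), ]
    if (nrow(rows) > 1)
      expect_true(all(rows$enter[-1] >= rows$exit[-nrow(rows)] - 1e-6),
                  info = key)
  }
  # work visits on weekdays fall inside plausible office hours
  work <- tr[tr$category == "Work", ]
  if (nrow(work)) {
    h0 <- ((work$enter - 6 * 3600 * -1) %% 86400)
    start_h <- ((work$enter + world_config(seed = 1)$tz_offset * 3600)
                %% 86400) / 3600
    end_h <- ((work$exit + world_config(seed = 1)$tz_offset * 3600)
              %% 86400) / 3600
    expect_true(all(start_h > 7.5 & start_h < 10))
    expect_true(all(end_h > 15.5 & end_h < 18.5))
    dow <- (floor((work$enter + world_config(seed = 1)$tz_offset * 3600) /
                    86400) + 4) %% 7
    expect_true(all(dow %in% 1:5))
  }
})

test_that("a home-only day yields one visit spanning the whole day", {
  cfg <- world_config(n_participants = 1, study_days = 1, seed = 107,
                      outing_rate = 0, employed_prob = 0)
  w <- generate_cohort(cfg)
  tr <- w$truth
  expect_true(all(tr$category == "Home"))
  expect_equal(sum(tr$exit - tr$enter), 86400, tolerance = 1)
})

test_that("an employed weekday contains home and work visits", {
  state_seedy <- function() {
    cfg <- world_config(n_participants = 1, study_days = 1, seed = 108,
                        outing_rate = 0, employed_prob = 1)
    generate_cohort(cfg)
  }
  w <- state_seedy()
  # 2015-11-02 is a Monday
  cats <- unique(w$truth$category)
  expect_true(all(c("Home", "Work") %in% cats))
  expect_gte(nrow(w$truth), 3)   # home-work-home at minimum
})

test_that("light is darker at home overnight than at a daytime shop", {
  profiles <- default_place_profiles()
  w <- generate_cohort(world_config(n_participants = 3, study_days = 10,
                                    seed = 109))
  home_night <- c(); shop_day <- c()
  for (p in w$participants) {
    tr <- w$truth[w$truth$id == p$id, ]
    for (i in seq_len(nrow(tr))) {
      sel <- p$light$t >= tr$enter[i] & p$light$t <= tr$exit[i]
      if (!any(sel)) next
      hour <- ((p$light$t[sel] + p$tz_offset * 3600) %% 86400) / 3600
      if (tr$category[i] == "Home")
        home_night <- c(home_night, p$light$lux[sel][hour < 6])
      if (tr$category[i] == "Shop or Store")
        shop_day <- c(shop_day, p$light$lux[sel][hour >= 8 & hour < 20])
    }
  }
  expect_gt(length(shop_day), 0)
  expect_lt(mean(home_night), mean(shop_day))
  expect_lt(mean(home_night), profiles$Home$light_day)
})

test_that("raw audio clips carry the profile tone and exercise the FFT path", {
  cfg <- world_config(n_participants = 1, study_days = 1, seed = 110,
                      audio_mode = "clips", outing_rate = 0,
                      employed_prob = 0)
  w <- generate_cohort(cfg)
  p <- w$participants[[1]]
  expect_gt(length(p$audio_clips), 0)
  expect_equal(nrow(p$audio_summary), 0)
  f <- sound_features(p$audio_clips[1:5])
  expect_equal(f[["sound_dom_freq"]],
               default_place_profiles()$Home$sound_freq, tolerance = 25)
})

test_that("planted correlations materialise in full generated cohorts", {
  fx <- effect_spec(score = "GAD-7", predictor = "Home", r_target = 0.45,
                    noise_sd = 4)
  w <- generate_cohort(world_config(n_participants = 30, study_days = 7,
                                    seed = 111), fx = fx)
  hours <- w$budgets$Home
  gad_w0 <- vapply(w$participants, function(p) p$gad7[1], 0L)
  r <- cor(hours, gad_w0)
  # n = 30 keeps the sampling noise of r wide; just demand the right sign
  # and rough magnitude
  expect_gt(r, 0.1)
  expect_lt(r, 0.8)
})
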