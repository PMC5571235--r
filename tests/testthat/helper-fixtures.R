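# Shared fixtures and independent oracles, all built in code.

# A small fully-populated participant with hand-sized streams.
tiny_participant <- function(id = "tiny", seed = 42) {
  withr_seed <- function(expr) {
    set.seed(seed); expr
  }
  withr_seed({
    t0 <- as.numeric(as.POSIXct("2015-11-05 06:00:00", tz = "UTC"))
    gps <- data.frame(t = t0 + seq(0, 3600 * 6, by = 300),
                      lat = 41.9 + rnorm(73, 0, 1e-5),
                      lon = -87.6 + rnorm(73, 0, 1e-5))
    light <- data.frame(t = t0 + seq(0, 600, by = 0.1),
                        lux = pmax(0, rnorm(6001, 100, 30)))
    audio <- data.frame(t_start = t0 + c(0, 300, 600),
                        power = c(100, 140, 90), dom_freq = c(200, 210, 190))
    clips <- list(list(t_start = t0 + 900, rate = 200,
                       samples = sin(2 * pi * 20 * seq(0, 2, by = 1 / 200))))
    screen <- data.frame(t = t0 + c(10, 70, 400, 520),
                         state = c("ON", "OFF", "ON", "OFF"))
    act <- data.frame(t = t0 + seq(0, 590, by = 10),
                      state = sample(c("Still", "Walking", "Tilting",
                                       "Unknown"), 60, replace = TRUE))
    comm <- data.frame(t = t0 + c(100, 200, 300),
                       kind = c("call_in", "sms_out", "call_missed"))
    wifi <- data.frame(t = t0 + seq(0, 3600, by = 300), ap_id = "ap01",
                       n_networks = rpois(13, 5))
    weather <- data.frame(t = t0 + seq(0, 6 * 3600, by = 3600),
                          temperature = rnorm(7, 10, 3),
                          dew_point = rnorm(7, 5, 2),
                          condition = sample(0:3, 7, replace = TRUE))
    ema <- data.frame(date = as.Date("2015-11-05"), center_lat = 41.9,
                      center_lon = -87.6, category = "Home",
                      free_text = "", stringsAsFactors = FALSE)
    ema$intervals <- list(cbind(t0, t0 + 6 * 3600))
    participant(id, gps = gps, light = light, audio_summary = audio,
                audio_clips = clips, screen = screen, activity = act,
                comm = comm, wifi = wifi, weather = weather, ema = ema,
                phq9 = c(5, 6, 4), gad7 = c(3, 4, 2))
  })
}

# A visit covering [t0, t0 + hours] at (lat, lon).
simple_visit <- function(t0, hours = 2, lat = 41.9, lon = -87.6,
                         id = "v", day = as.Date("2015-11-05"),
                         label = NA_character_) {
  semloc:::new_visit(id, day, lat, lon, cbind(t0, t0 + hours * 3600),
                     label = label)
}

# Great-circle distance oracle independent of the package's haversine:
# spherical law of cosines on the same radius.
dist_oracle_m <- function(lat1, lon1, lat2, lon2) {
  r <- 6378137
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  d <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  r * acos(pmin(1, pmax(-1, d)))
}

# All-pairs AUC oracle: P(s+ > s-) + P(s+ = s-)/2 by explicit enumeration.
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# GPS fixes clustered around given blob centres (meters offsets applied in
# the local tangent plane).
blob_fixes <- function(centers_m, n_per, sd_m, t0 = 1.45e9, dt = 300,
                      lat0 = 41.9, lon0 = -87.6) {
  m_deg <- semloc:::M_PER_DEG
  rows <- list()
  k <- 0
  for (i in seq_len(nrow(centers_m))) {
    for (j in seq_len(n_per)) {
      k <- k + 1
      rows[[k]] <- c(
        lat0 + (centers_m[i, 2] + rnorm(1, 0, sd_m)) / m_deg,
        lon0 + (centers_m[i, 1] + rnorm(1, 0, sd_m)) /
          (m_deg * cos(lat0 * pi / 180)))
    }
  }
  xy <- do.call(rbind, rows)
  data.frame(t = t0 + dt * (seq_len(nrow(xy)) - 1), lat = xy[, 1],
             lon = xy[, 2])
}

# Minimum number of clusters admitting a partition with all centroid radii
# <= bound, by exhaustive search over set partitions (small n only) with
# iterative deepening on k.  Pairwise diameter > 2 * bound prunes partial
# groups (a necessary condition for any feasible group); the exact
# centroid-radius check runs on complete partitions.
exhaustive_min_k <- function(fixes, max_radius_m = 100) {
  n <- nrow(fixes)
  pd <- as.matrix(dist(semloc:::project_plane(fixes$lat, fixes$lon,
                                              mean(fixes$lat),
                                              mean(fixes$lon))))
  group_ok <- function(idx) {
    lat0 <- mean(fixes$lat[idx]); lon0 <- mean(fixes$lon[idx])
    xy <- semloc:::project_plane(fixes$lat[idx], fixes$lon[idx], lat0, lon0)
    ctr <- semloc:::unproject_plane(colMeans(xy), lat0, lon0)
    all(geosphere::distHaversine(cbind(fixes$lon[idx], fixes$lat[idx]),
                                 cbind(ctr[2], ctr[1])) <= max_radius_m)
  }
  feasible_with_k <- function(k) {
    assign <- integer(n)
    res <- NULL
    rec <- function(i, maxg) {
      if (!is.null(res)) return()
      if (i > n) {
        groups <- split(seq_len(n), assign)
        if (all(vapply(groups, group_ok, TRUE))) res <<- assign
        return()
      }
      for (g in seq_len(min(maxg + 1, k))) {
        members <- which(assign[seq_len(i - 1)] == g)
        if (!length(members) || all(pd[i, members] <= 2 * max_radius_m)) {
          assign[i] <<- g
          rec(i + 1, max(maxg, g))
          assign[i] <<- 0L
        }
      }
    }
    rec(1, 0L)
    res
  }
  for (k in seq_len(n)) {
    a <- feasible_with_k(k)
    if (!is.null(a)) return(list(k = k, assignment = a))
  }
}

# Hand-built depth-3 decision tree over two features, used for routing
# tests.
hand_tree <- function() {
  leaf <- function(s) list(score = s)
  list(feature = "f1", threshold = 0.5, missing = "left",
       left = list(feature = "f2", threshold = 0.3, missing = "right",
                   left = leaf(0.1), right = leaf(0.2)),
       right = list(feature = "f2", threshold = 0.7, missing = "left",
                    left = leaf(0.3), right = leaf(0.4)))
}

# Small separable 3-class dataset: class depends on which of two features
# is large; optionally appends uninformative noise columns.
toy_classes <- function(n_per = 20, noise_cols = 0, seed = 1) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n_per, 0, 0.3), rnorm(n_per, 0, 0.3)),
             cbind(rnorm(n_per, 3, 0.3), rnorm(n_per, 0, 0.3)),
             cbind(rnorm(n_per, 0, 0.3), rnorm(n_per, 3, 0.3)))
  colnames(X) <- c("fa", "fb")
  if (noise_cols > 0) {
    Z <- matrix(rnorm(3 * n_per * noise_cols), ncol = noise_cols)
    colnames(Z) <- paste0("noise", seq_len(noise_cols))
    X <- cbind(X, Z)
  }
  list(X = X, y = rep(c("A", "B", "C"), each = n_per))
}

# Brute-force light-feature oracle (two-pass moments, loop-counted
# crossings).
light_oracle <- function(t, lux) {
  n <- length(lux)
  m <- sum(lux) / n
  m2 <- sum((lux - m)^2) / n
  crossings <- 0
  s <- lux - m
  for (i in seq_len(n - 1))
    if (s[i] * s[i + 1] < 0) crossings <- crossings + 1
  span <- t[n] - t[1]
  c(m, if (n >= 2) sum((lux - m)^2) / (n - 1) else NA,
    if (m2 > 0) sum((lux - m)^3) / n / m2^1.5 else NA,
    if (m2 > 0) sum((lux - m)^4) / n / m2^2 else NA,
    sum(lux == 0) / n,
    if (span > 0) crossings / span else if (crossings == 0) 0 else NA)
}

screen_oracle <- function(ev, visit_end) {
  # brute-force interval walk over deduplicated events
  n_on <- 0; durations <- c(); cur_on <- NA
  last_state <- "none"
  for (i in seq_len(nrow(ev))) {
    if (ev$state[i] == last_state) next
    last_state <- ev$state[i]
    if (ev$state[i] == "ON") { n_on <- n_on + 1; cur_on <- ev$t[i] }
    else if (!is.na(cur_on)) { durations <- c(durations, ev$t[i] - cur_on)
      cur_on <- NA }
  }
  if (!is.na(cur_on)) durations <- c(durations, visit_end - cur_on)
  c(n_on, if (length(durations)) mean(durations) else NA,
    if (length(durations) >= 2) sd(durations) else NA)
}
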