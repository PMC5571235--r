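#' Assemble a participant record
#'
#' A participant bundles every time-stamped stream the phone recorded over the
#' study -- GPS fixes, ambient light, audio clips (raw or summarised), screen
#' on/off events, recognised activity states, call/SMS events, Wi-Fi scans and
#' weather reports -- together with the daily location-diary reports and the
#' three-wave PHQ-9 and GAD-7 questionnaire scores (weeks 0, 3 and 6).
#' All timestamps are UTC epoch seconds; streams are stored sorted by time.
#'
#' @param id participant identifier (opaque string).
#' @param gps data.frame with columns \code{t}, \code{lat}, \code{lon}.
#' @param light data.frame with columns \code{t}, \code{lux}.
#' @param audio_summary data.frame with columns \code{t_start}, \code{power},
#'   \code{dom_freq}: one row per 15-s microphone clip, already reduced to its
#'   two per-clip features.
#' @param audio_clips list of raw clips, each a list with \code{t_start},
#'   \code{rate} (Hz) and \code{samples} (amplitude series, dB).
#' @param screen data.frame with columns \code{t}, \code{state}
#'   (\code{"ON"}/\code{"OFF"}).
#' @param activity data.frame with columns \code{t}, \code{state} (one of the
#'   seven recogniser states, see \code{semloc:::activity_states}).
#' @param comm data.frame with columns \code{t}, \code{kind} (call_in,
#'   call_out, call_missed, sms_in, sms_out).
#' @param wifi data.frame with columns \code{t}, \code{ap_id},
#'   \code{n_networks}.
#' @param weather data.frame with columns \code{t}, \code{temperature},
#'   \code{dew_point}, \code{condition} (small integer code).
#' @param ema data.frame of daily diary reports with columns \code{date}
#'   (\code{Date}), \code{center_lat}, \code{center_lon}, \code{category}
#'   (a diary category, see \code{\link{semloc_categories}}), optional
#'   \code{free_text}, and a list column \code{intervals} of two-column
#'   (enter, exit) matrices in UTC epoch seconds.
#' @param phq9,gad7 integer vectors of length 3 (weeks 0/3/6), ranges 0--27
#'   and 0--21.
#' @param tz_offset participant's local-time offset from UTC in hours; used
#'   only to place local-day boundaries and local-hour features.
#' @return An object of class \code{semloc_participant}.
#' @export
participant <- function(id, gps = NULL, light = NULL, audio_summary = NULL,
                        audio_clips = NULL, screen = NULL, activity = NULL,
                        comm = NULL, wifi = NULL, weather = NULL, ema = NULL,
                        phq9 = rep(NA_integer_, 3), gad7 = rep(NA_integer_, 3),
                        tz_offset = 0) {
  p <- structure(list(
    id = as.character(id), tz_offset = tz_offset,
    gps = empty_if_null(gps, c("t", "lat", "lon")),
    light = empty_if_null(light, c("t", "lux")),
    audio_summary = empty_if_null(audio_summary,
                                  c("t_start", "power", "dom_freq")),
    audio_clips = audio_clips %||% list(),
    screen = empty_if_null(screen, c("t", "state")),
    activity = empty_if_null(activity, c("t", "state")),
    comm = empty_if_null(comm, c("t", "kind")),
    wifi = empty_if_null(wifi, c("t", "ap_id", "n_networks")),
    weather = empty_if_null(weather,
                            c("t", "temperature", "dew_point", "condition")),
    ema = ema, phq9 = as.integer(phq9), gad7 = as.integer(gad7)),
    class = "semloc_participant")
  p <- sort_streams(p)
  validate_participant(p)
  p
}

empty_if_null <- function(df, cols) {
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    for (cc in intersect(cols, c("state", "kind", "ap_id")))
      df[[cc]] <- character(0)
    return(df)
  }
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop_parse("stream is missing columns: %s",
               paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), cols)
  if (length(extra)) {
    warnf("ignoring unknown fields: %s", paste(extra, collapse = ", "))
    df <- df[cols]
  }
  df[cols]
}

sort_streams <- function(p) {
  for (s in c("gps", "light", "screen", "activity", "comm", "wifi", "weather"))
    p[[s]] <- p[[s]][order(p[[s]]$t), , drop = FALSE]
  if (nrow(p$audio_summary))
    p$audio_summary <- p$audio_summary[order(p$audio_summary$t_start), ,
                                       drop = FALSE]
  if (length(p$audio_clips))
    p$audio_clips <-
      p$audio_clips[order(vapply(p$audio_clips, `[[`, 0, "t_start"))]
  for (s in names(p)[vapply(p, is.data.frame, TRUE)])
    rownames(p[[s]]) <- NULL
  p
}

validate_participant <- function(p) {
  g <- p$gps
  bad <- which(g$lat < -90 | g$lat > 90 | g$lon < -180 | g$lon > 180)
  if (length(bad))
    stop_parse("GPS row %d: coordinates out of range (lat %g, lon %g)",
               bad[1], g$lat[bad[1]], g$lon[bad[1]])
  if (any(p$light$lux < 0))
    stop_parse("light row %d: negative lux", which(p$light$lux < 0)[1])
  bad <- which(!p$activity$state %in% activity_states())
  if (length(bad))
    stop_parse("activity row %d: unknown state '%s'", bad[1],
               p$activity$state[bad[1]])
  bad <- which(!p$comm$kind %in% comm_kinds())
  if (length(bad))
    stop_parse("comm row %d: unknown kind '%s'", bad[1], p$comm$kind[bad[1]])
  if (any(p$wifi$n_networks < 0 | p$wifi$n_networks != round(p$wifi$n_networks)))
    stop_parse("wifi: n_networks must be a non-negative integer")
  if (any(!p$screen$state %in% c("ON", "OFF")))
    stop_parse("screen: state must be ON or OFF")
  if (!is.null(p$ema) && nrow(p$ema)) {
    if (any(!p$ema$category %in% semloc_categories()))
      stop_parse("ema: unknown category '%s'",
                 setdiff(p$ema$category, semloc_categories())[1])
  }
  ok_score <- function(x, hi) all(is.na(x) | (x >= 0 & x <= hi))
  if (length(p$phq9) != 3 || length(p$gad7) != 3 ||
      !ok_score(p$phq9, 27) || !ok_score(p$gad7, 21))
    stop_parse("phq9/gad7 must each hold 3 scores in range (0-27 / 0-21)")
  invisible(p)
}

#' @export
print.semloc_participant <- function(x, ...) {
  cat(sprintf("<semloc_participant %s>\n", x$id))
  for (s in c("gps", "light", "screen", "activity", "comm", "wifi", "weather"))
    cat(sprintf("  %-9s %6d rows\n", s, nrow(x[[s]])))
  cat(sprintf("  audio     %6d clips, %d summaries\n",
              length(x$audio_clips), nrow(x$audio_summary)))
  cat(sprintf("  ema       %6d reports; PHQ-9 %s; GAD-7 %s\n",
              if (is.null(x$ema)) 0L else nrow(x$ema),
              paste(x$phq9, collapse = "/"), paste(x$gad7, collapse = "/")))
  invisible(x)
}

stop_missing_stream <- function(fmt, ...) {
  stop(structure(class = c("MissingStream", "semloc_error", "error",
                           "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

stop_parse <- function(fmt, ...) {
  stop(structure(class = c("ParseError", "semloc_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

# ---- on-disk bundle format (schema version 1) -------------------------------
#
# One directory per participant: a `manifest.txt` of `key: value` lines plus
# one CSV per non-empty stream.  Timestamps are written as fixed-point epoch
# seconds with millisecond precision so writes are byte-deterministic.

BUNDLE_VERSION <- "1"

fmt_t <- function(t) sprintf("%.3f", t)
fmt_deg <- function(x) sprintf("%.8f", x)
fmt_num <- function(x) sprintf("%.6g", x)

write_stream_csv <- function(df, path, formats) {
  out <- df
  for (nm in names(formats)) out[[nm]] <- formats[[nm]](df[[nm]])
  write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' Write / read a participant bundle
#'
#' Serialises a participant to a directory of per-stream CSV files plus a
#' key-value \code{manifest.txt}, and reads it back.  Writing the same
#' participant twice produces byte-identical files; timestamps round-trip to
#' 1 ms.  Only non-empty streams produce a file; \code{read_bundle} treats an
#' absent stream file named in the manifest as a missing mandatory stream.
#'
#' @param p a \code{\link{participant}}.
#' @param path directory to write to (created) or read from.
#' @return \code{read_bundle} returns the \code{semloc_participant};
#'   \code{write_bundle} returns \code{path} invisibly.
#' @export
write_bundle <- function(p, path) {
  stopifnot(inherits(p, "semloc_participant"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  streams <- character(0)
  w <- function(name, df, formats) {
    if (!nrow(df)) return(invisible())
    write_stream_csv(df, file.path(path, paste0(name, ".csv")), formats)
    streams <<- c(streams, name)
  }
  w("gps", p$gps, list(t = fmt_t, lat = fmt_deg, lon = fmt_deg))
  w("light", p$light, list(t = fmt_t, lux = fmt_num))
  w("audio_summary", p$audio_summary,
    list(t_start = fmt_t, power = fmt_num, dom_freq = fmt_num))
  w("screen", p$screen, list(t = fmt_t))
  w("activity", p$activity, list(t = fmt_t))
  w("comm", p$comm, list(t = fmt_t))
  w("wifi", p$wifi, list(t = fmt_t, n_networks = function(x) sprintf("%d",
                                                            as.integer(x))))
  w("weather", p$weather, list(t = fmt_t, temperature = fmt_num,
                               dew_point = fmt_num,
                               condition = function(x) sprintf("%d",
                                                               as.integer(x))))
  if (length(p$audio_clips)) {
    hdr <- do.call(rbind, lapply(seq_along(p$audio_clips), function(i) {
      cl <- p$audio_clips[[i]]
      data.frame(clip_id = i, t_start = fmt_t(cl$t_start),
                 rate = fmt_num(cl$rate), n = length(cl$samples))
    }))
    write.csv(hdr, file.path(path, "audio_clips.csv"), row.names = FALSE)
    samp <- do.call(rbind, lapply(seq_along(p$audio_clips), function(i)
      data.frame(clip_id = i,
                 amp = fmt_num(p$audio_clips[[i]]$samples))))
    write.csv(samp, file.path(path, "audio_samples.csv"), row.names = FALSE)
    streams <- c(streams, "audio_clips")
  }
  if (!is.null(p$ema) && nrow(p$ema)) {
    rows <- do.call(rbind, lapply(seq_len(nrow(p$ema)), function(i) {
      iv <- p$ema$intervals[[i]]
      data.frame(report_id = i, date = as.character(p$ema$date[i]),
                 center_lat = fmt_deg(p$ema$center_lat[i]),
                 center_lon = fmt_deg(p$ema$center_lon[i]),
                 category = p$ema$category[i],
                 free_text = {
                   ft <- if ("free_text" %in% names(p$ema))
                     p$ema$free_text[i] else ""
                   if (is.na(ft) || !nzchar(ft)) "" else ft
                 },
                 enter = fmt_t(iv[, 1]), exit = fmt_t(iv[, 2]))
    }))
    write.csv(rows, file.path(path, "ema.csv"), row.names = FALSE)
    streams <- c(streams, "ema")
  }
  manifest <- c(
    paste0("format_version: ", BUNDLE_VERSION),
    paste0("id: ", p$id),
    paste0("tz_offset: ", fmt_num(p$tz_offset)),
    paste0("streams: ", paste(sort(streams), collapse = ",")),
    paste0("phq9: ", paste(p$phq9, collapse = ",")),
    paste0("gad7: ", paste(p$gad7, collapse = ",")))
  writeLines(manifest, file.path(path, "manifest.txt"))
  invisible(path)
}

read_manifest <- function(path) {
  f <- file.path(path, "manifest.txt")
  if (!file.exists(f)) stop_missing_stream("no manifest.txt in %s", path)
  lines <- readLines(f)
  kv <- regmatches(lines, regexec("^([^:]+): ?(.*)$", lines))
  setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
}

read_stream <- function(path, name, mandatory) {
  f <- file.path(path, paste0(name, ".csv"))
  if (!file.exists(f)) {
    if (mandatory) stop_missing_stream("stream file missing: %s", f)
    return(NULL)
  }
  tryCatch(read.csv(f, stringsAsFactors = FALSE),
           error = function(e) stop_parse("%s: %s", f, conditionMessage(e)))
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  man <- read_manifest(path)
  streams <- strsplit(man$streams %||% "", ",")[[1]]
  get <- function(name) read_stream(path, name, mandatory = name %in% streams)
  clips <- NULL
  if ("audio_clips" %in% streams) {
    hdr <- get("audio_clips")
    samp <- read_stream(path, "audio_samples", mandatory = TRUE)
    clips <- lapply(seq_len(nrow(hdr)), function(i) {
      list(t_start = hdr$t_start[i], rate = hdr$rate[i],
           samples = samp$amp[samp$clip_id == hdr$clip_id[i]])
    })
  }
  ema <- NULL
  if ("ema" %in% streams) {
    rows <- get("ema")
    rows$free_text[is.na(rows$free_text)] <- ""
    grp <- split(rows, factor(rows$report_id, levels = unique(rows$report_id)))
    ema <- do.call(rbind, lapply(grp, function(r) {
      data.frame(date = as.Date(r$date[1]), center_lat = r$center_lat[1],
                 center_lon = r$center_lon[1], category = r$category[1],
                 free_text = r$free_text[1], stringsAsFactors = FALSE)
    }))
    ema$intervals <- lapply(grp, function(r)
      cbind(enter = r$enter, exit = r$exit))
    rownames(ema) <- NULL
  }
  parse_scores <- function(key) {
    v <- suppressWarnings(as.integer(strsplit(man[[key]] %||% "NA,NA,NA",
                                              ",")[[1]]))
    if (length(v) != 3) stop_parse("manifest %s: expected 3 scores", key)
    v
  }
  participant(id = man$id, tz_offset = as.numeric(man$tz_offset %||% 0),
              gps = get("gps"), light = get("light"),
              audio_summary = get("audio_summary"), audio_clips = clips,
              screen = get("screen"), activity = get("activity"),
              comm = get("comm"), wifi = get("wifi"), weather = get("weather"),
              ema = ema, phq9 = parse_scores("phq9"),
              gad7 = parse_scores("gad7"))
}

#' Anonymise a participant identifier
#'
#' Deterministic one-way hash of a raw identifier using MD5, mirroring the
#' anonymisation applied before sensor data leave the device.  Always returns
#' a 32-character lowercase hex string.
#'
#' @param raw_id non-empty character string.
#' @return 32-character hex digest.
#' @examples
#' hash_id("participant-007")
#' @export
hash_id <- function(raw_id) {
  stopifnot(is.character(raw_id), length(raw_id) == 1, nzchar(raw_id))
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(charToRaw(raw_id), f)
  unname(tools::md5sum(f))
}
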