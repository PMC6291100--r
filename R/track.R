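## Track container: a tibble of timestamped fixes, one row per GPS fix, with
## planar coordinates and per-fix encounter flags. Kept deliberately plain --
## a tibble subclass -- so all dplyr verbs work on it.

#' Build a track object from a data frame of fixes
#'
#' A track is a tibble with one row per GPS fix and columns `trip_id`, `time`
#' (POSIXct, optional if `t` given), `t` (seconds since trip start), `lon`,
#' `lat` (optional if `x`, `y` given), `x`, `y` (metres, local planar frame),
#' `elev` (metres, optional), `E` (0/1 encounter flag) and `E_kind`
#' (`"none"`, `"hit"` or `"nonhit"`). Fixes are expected at a uniform cadence
#' (10 s by default); longer gaps are detected and the series is split into
#' `segment`s so that no step, turning angle or lag is computed across a gap
#' of more than one missed fix.
#'
#' @param fixes Data frame with at least `trip_id` plus either `time` or `t`,
#'   and either `lon`/`lat` or `x`/`y`.
#' @param cadence_s Nominal sampling interval in seconds.
#' @param origin Projection origin `c(lon0, lat0)`; defaults to the centroid
#'   of all fixes.
#' @return A `ars_track` tibble, ordered by trip and time, with a cadence
#'   report in `attr(, "cadence")` and the projection origin in
#'   `attr(, "origin")`.
#' @export
as_ars_track <- function(fixes, cadence_s = 10, origin = NULL) {
  df <- tibble::as_tibble(fixes)
  if (!"trip_id" %in% names(df)) df$trip_id <- "trip_1"
  df$trip_id <- as.character(df$trip_id)
  has_time <- "time" %in% names(df)
  if (!has_time && !"t" %in% names(df)) stop("untimed track: no `time` or `t` column")
  if (has_time) {
    if (anyNA(df$time)) stop("untimed track: missing timestamps")
    df <- dplyr::arrange(df, .data$trip_id, .data$time)
  } else {
    df <- dplyr::arrange(df, .data$trip_id, .data$t)
  }
  if (nrow(df) < 2) stop("degenerate track: fewer than 2 fixes")
  df <- dplyr::group_by(df, .data$trip_id)
  if (has_time) {
    df <- dplyr::mutate(df, t = as.numeric(.data$time) - as.numeric(.data$time[1]))
  }
  df <- dplyr::ungroup(df)
  bad <- dplyr::group_by(df, .data$trip_id) |>
    dplyr::summarise(ok = all(diff(.data$t) > 0)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("timestamps not strictly increasing in trip(s): ",
         paste(bad$trip_id, collapse = ", "))
  }
  if (!all(c("x", "y") %in% names(df))) {
    if (!all(c("lon", "lat") %in% names(df))) {
      stop("track needs either lon/lat or x/y coordinates")
    }
    xy <- project_lonlat(df$lon, df$lat, origin)
    origin <- attr(xy, "origin")
    df$x <- xy$x
    df$y <- xy$y
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("non-finite planar coordinates")
  }
  if (!"elev" %in% names(df)) df$elev <- NA_real_
  if (!"E" %in% names(df)) df$E <- 0L
  df$E <- as.integer(df$E)
  if (!"E_kind" %in% names(df)) df$E_kind <- ifelse(df$E == 1L, "hit", "none")
  stopifnot(all(df$E_kind %in% c("none", "hit", "nonhit")))
  if (any((df$E_kind == "none") != (df$E == 0L))) {
    stop("E_kind must be 'none' exactly where E = 0")
  }
  ## split trips at gaps of more than one missed fix
  df <- dplyr::group_by(df, .data$trip_id) |>
    dplyr::mutate(
      missed = c(0, pmax(round(diff(.data$t) / cadence_s) - 1, 0)),
      segment = paste0(.data$trip_id, ".", cumsum(.data$missed > 1) + 1)
    ) |>
    dplyr::ungroup()
  cadence <- dplyr::group_by(df, .data$trip_id) |>
    dplyr::summarise(
      n_fixes = dplyr::n(),
      median_dt_s = median(diff(.data$t)),
      n_gaps = sum(.data$missed >= 1),
      n_splits = sum(.data$missed > 1),
      cadence_ok = .data$n_gaps == 0 && isTRUE(all.equal(.data$median_dt_s, cadence_s))
    )
  df$missed <- NULL
  out <- df[, c("trip_id", "segment", "time"[has_time], "t",
                intersect(c("lon", "lat"), names(df)), "x", "y",
                "elev", "E", "E_kind")]
  class(out) <- c("ars_track", class(out))
  attr(out, "cadence_s") <- cadence_s
  attr(out, "cadence") <- cadence
  attr(out, "origin") <- origin
  out
}

#' Read a GPX file as a track
#'
#' Parses GPX 1.0/1.1 `<trkpt>` elements (latitude, longitude, `<time>`,
#' optional `<ele>`). Each `<trk>` in the file becomes one trip; the trip id
#' is taken from the track `<name>` when present, otherwise from the file
#' name.
#'
#' @param path Path to a GPX file, or a character vector of paths (one trip
#'   or more per file).
#' @param cadence_s Nominal sampling interval in seconds.
#' @param origin Optional projection origin `c(lon0, lat0)`.
#' @return A [as_ars_track()] tibble.
#' @export
read_gpx_track <- function(path, cadence_s = 10, origin = NULL) {
  parts <- purrr::map(path, read_gpx_one)
  as_ars_track(dplyr::bind_rows(parts), cadence_s = cadence_s, origin = origin)
}

read_gpx_one <- function(path) {
  doc <- xml2::read_xml(path)
  doc <- xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (length(trks) == 0) stop("degenerate track: no <trk> in ", path)
  base <- tools::file_path_sans_ext(basename(path))
  purrr::imap_dfr(as.list(trks), function(trk, i) {
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    if (is.na(nm) || nm == "") {
      nm <- if (length(trks) == 1) base else paste0(base, "_", i)
    }
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    if (length(pts) < 2) stop("degenerate track: fewer than 2 trackpoints in ", path)
    times <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
    if (anyNA(times)) stop("untimed track: trackpoint without <time> in ", path)
    ele <- suppressWarnings(as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./ele"))))
    tibble::tibble(
      trip_id = nm,
      time = parse_iso8601(times),
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      lat = as.numeric(xml2::xml_attr(pts, "lat")),
      elev = ele
    )
  })
}

parse_iso8601 <- function(x) {
  out <- as.POSIXct(sub("Z$", "", x), tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(out)) stop("untimed track: unparseable timestamp(s): ",
                       paste(utils::head(x[is.na(out)], 3), collapse = ", "))
  out
}

#' Write a track to a GPX 1.1 file
#'
#' One `<trk>` per trip; encounter-flagged fixes are also written as `<wpt>`
#' waypoints whose `<name>` holds the encounter kind, so a written file
#' round-trips through [read_gpx_track()] + [read_gpx_waypoints()].
#'
#' @param track An `ars_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gpx_track <- function(track, path) {
  stopifnot(inherits(track, "ars_track"))
  if (!all(c("lon", "lat") %in% names(track))) {
    ll <- unproject_xy(track$x, track$y, attr(track, "origin") %||% c(0, 0))
    track$lon <- ll$lon
    track$lat <- ll$lat
  }
  if (!"time" %in% names(track)) {
    ## synthesise timestamps: one day per trip so trips never overlap
    t0 <- as.POSIXct("2017-04-01 06:00:00", tz = "UTC")
    day <- match(track$trip_id, unique(track$trip_id))
    track$time <- t0 + 86400 * (day - 1) + track$t
  }
  fmt_time <- function(tt) strftime(tt, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<gpx version="1.1" creator="arsearch">')
  wpt <- track[track$E == 1L, ]
  if (nrow(wpt) > 0) {
    lines <- c(lines, sprintf(
      '  <wpt lat="%.8f" lon="%.8f"><time>%s</time><name>%s</name></wpt>',
      wpt$lat, wpt$lon, fmt_time(wpt$time), wpt$E_kind))
  }
  for (trip in unique(track$trip_id)) {
    tr <- track[track$trip_id == trip, ]
    lines <- c(lines, "  <trk>", paste0("    <name>", trip, "</name>"), "    <trkseg>")
    ele <- ifelse(is.na(tr$elev), "",
                  sprintf("<ele>%.2f</ele>", tr$elev))
    lines <- c(lines, sprintf(
      '      <trkpt lat="%.8f" lon="%.8f">%s<time>%s</time></trkpt>',
      tr$lat, tr$lon, ele, fmt_time(tr$time)))
    lines <- c(lines, "    </trkseg>", "  </trk>")
  }
  lines <- c(lines, "</gpx>")
  writeLines(lines, path)
  invisible(path)
}

#' Read encounter annotations
#'
#' `read_annotations_csv()` reads a CSV with columns `trip_id`,
#' `timestamp_iso8601` and `kind` (`"hit"` or `"nonhit"`); optional numeric
#' columns `shots`, `hits` and `recovered` are carried through for
#' [hunt_summary()]. `read_gpx_waypoints()` extracts `<wpt>` elements from a
#' GPX file, using `<name>` as the kind (anything other than `"hit"` is
#' treated as `"nonhit"`).
#'
#' @param path File path.
#' @return A tibble with columns `trip_id` (possibly `NA` for waypoints),
#'   `time`, `kind` and any count columns present.
#' @export
read_annotations_csv <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("trip_id", "timestamp_iso8601", "kind") %in% names(ann)))
  ann$time <- parse_iso8601(ann$timestamp_iso8601)
  ann$timestamp_iso8601 <- NULL
  ann$trip_id <- as.character(ann$trip_id)
  stopifnot(all(ann$kind %in% c("hit", "nonhit")))
  ann
}

#' @rdname read_annotations_csv
#' @export
read_gpx_waypoints <- function(path) {
  doc <- xml2::xml_ns_strip(xml2::read_xml(path))
  wpts <- xml2::xml_find_all(doc, ".//wpt")
  nm <- xml2::xml_text(xml2::xml_find_first(wpts, "./name"))
  tibble::tibble(
    trip_id = NA_character_,
    time = parse_iso8601(xml2::xml_text(xml2::xml_find_first(wpts, "./time"))),
    kind = ifelse(tolower(nm) == "hit", "hit", "nonhit")
  )
}

#' Attach encounter annotations to a track
#'
#' Each annotation flags exactly one fix: the fix nearest in time (within the
#' same trip when the annotation carries a `trip_id`), ties resolved to the
#' earlier fix. Annotations falling outside the track's time range by more
#' than `tolerance_s` are an error.
#'
#' @param track An `ars_track`.
#' @param annotations Tibble from [read_annotations_csv()] or
#'   [read_gpx_waypoints()], with columns `time`, `kind` and optionally
#'   `trip_id`.
#' @param tolerance_s Maximum allowed excursion of an annotation time beyond
#'   the track's time range, seconds.
#' @return The track with `E`/`E_kind` set, the annotation table stored in
#'   `attr(, "annotations")`.
#' @export
align_encounters <- function(track, annotations, tolerance_s = 10) {
  stopifnot(inherits(track, "ars_track"), "time" %in% names(track))
  ann <- tibble::as_tibble(annotations)
  stopifnot(all(c("time", "kind") %in% names(ann)))
  if (!"trip_id" %in% names(ann)) ann$trip_id <- NA_character_
  tt <- as.numeric(track$time)
  at <- as.numeric(ann$time)
  idx <- integer(nrow(ann))
  offenders <- character(0)
  for (i in seq_len(nrow(ann))) {
    in_trip <- if (is.na(ann$trip_id[i])) rep(TRUE, nrow(track)) else track$trip_id == ann$trip_id[i]
    cand <- which(in_trip)
    if (length(cand) == 0 ||
        at[i] < min(tt[cand]) - tolerance_s || at[i] > max(tt[cand]) + tolerance_s) {
      offenders <- c(offenders, format(ann$time[i], tz = "UTC"))
      next
    }
    d <- abs(tt[cand] - at[i])
    idx[i] <- cand[which(d == min(d))[1]] # ties -> earlier fix
  }
  if (length(offenders) > 0) {
    stop("annotation(s) outside track time range + tolerance: ",
         paste(offenders, collapse = ", "))
  }
  track$E <- 0L
  track$E_kind <- "none"
  track$E[idx] <- 1L
  track$E_kind[idx] <- ann$kind
  attr(track, "annotations") <- ann
  track
}

#' Per-trip descriptive statistics
#'
#' Summarises each trip: number of fixes, planar path distance (km), duration
#' (hours), average speed (km/h), elevation range (max minus min, metres; `NA`
#' when no elevation was recorded), and encounter counts. Shot/hit/recovery
#' totals are taken from annotation count columns when the track was annotated
#' with them, otherwise reported `NA` -- never silently zero.
#'
#' @param track An `ars_track`.
#' @return A tibble with one row per trip.
#' @export
#' @examples
#' tr <- as_ars_track(data.frame(t = c(0, 10), x = c(0, 5), y = c(0, 0)))
#' hunt_summary(tr) # 5 m in 10 s -> 1.8 km/h
hunt_summary <- function(track) {
  stopifnot(inherits(track, "ars_track"))
  out <- dplyr::group_by(track, .data$trip_id) |>
    dplyr::summarise(
      n_fixes = dplyr::n(),
      dist_km = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)) / 1000,
      duration_hr = (max(.data$t) - min(.data$t)) / 3600,
      avg_speed_kmh = .data$dist_km / .data$duration_hr,
      elev_change_m = if (all(is.na(.data$elev))) NA_real_ else
        diff(range(.data$elev, na.rm = TRUE)),
      n_encounters = sum(.data$E),
      n_hit = sum(.data$E_kind == "hit"),
      n_nonhit = sum(.data$E_kind == "nonhit")
    )
  ann <- attr(track, "annotations")
  for (col in c("shots", "hits", "recovered")) {
    out[[paste0("n_", col)]] <- if (!is.null(ann) && col %in% names(ann)) {
      cnt <- dplyr::group_by(ann, .data$trip_id) |>
        dplyr::summarise(v = sum(.data[[col]]))
      cnt$v[match(out$trip_id, cnt$trip_id)]
    } else {
      NA_real_
    }
  }
  out
}
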