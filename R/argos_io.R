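#' Column mapping for delimited Argos location files
#'
#' Describes which columns of a delimited text file hold the tag identifier,
#' timestamp, coordinates and Argos location class. The default matches the
#' CSV dialect written by [write_tracks_csv()] and [simulate_track()];
#' [wc_argos_format()] matches the Wildlife Computers Argos export.
#'
#' @param tag_id,time,lon,lat,lc column names in the input file.
#' @param time_format optional `strptime` format; when `NULL` common ISO-8601
#'   variants are tried. Times are always interpreted as UTC.
#' @return A list of class `argos_format`.
#' @export
argos_format <- function(tag_id = "tag_id", time = "time", lon = "lon",
                         lat = "lat", lc = "lc", time_format = NULL) {
  structure(list(tag_id = tag_id, time = time, lon = lon, lat = lat,
                 lc = lc, time_format = time_format),
            class = "argos_format")
}

#' @rdname argos_format
#' @export
wc_argos_format <- function() {
  argos_format(tag_id = "DeployID", time = "Date", lon = "Longitude",
               lat = "Latitude", lc = "Quality")
}

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B")

#' Construct a validated Argos track
#'
#' A track is a time-ordered sequence of Argos fixes from a single tag. Fixes
#' are sorted; duplicated timestamps are collapsed keeping the fix with the
#' better location class (tie: first wins).
#'
#' @param tag_id tag identifier (scalar character).
#' @param time `POSIXct` timestamps (UTC).
#' @param lon,lat coordinates in decimal degrees; longitudes are normalised
#'   into `[-180, 180)`.
#' @param lc Argos location class, one of `"3","2","1","0","A","B"`.
#' @param track_id track identifier; defaults to `tag_id` (gap splitting
#'   appends alphabetic suffixes).
#' @return An object of class `argos_track`: a list with `track_id`, `tag_id`
#'   and a data frame `fixes` (`time`, `lon`, `lat`, `lc`).
#' @export
argos_track <- function(tag_id, time, lon, lat, lc, track_id = tag_id) {
  stopifnot(length(tag_id) == 1L)
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct (UTC)")
  n <- length(time)
  if (n < 2L) stop("a track needs at least 2 fixes")
  lc <- as.character(lc)
  bad <- !lc %in% ARGOS_CLASSES
  if (any(bad)) stop("unknown Argos location class: ", lc[which(bad)[1L]])
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
  lon <- wrap_lon(lon)
  fixes <- data.frame(time = as.POSIXct(time, tz = "UTC"),
                      lon = lon, lat = lat, lc = lc,
                      stringsAsFactors = FALSE)
  fixes <- fixes[order(fixes$time,
                       match(fixes$lc, ARGOS_CLASSES)), , drop = FALSE]
  fixes <- fixes[!duplicated(fixes$time), , drop = FALSE]
  rownames(fixes) <- NULL
  if (nrow(fixes) < 2L) stop("a track needs at least 2 distinct fix times")
  structure(list(track_id = track_id, tag_id = tag_id, fixes = fixes),
            class = "argos_track")
}

wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

#' @export
print.argos_track <- function(x, ...) {
  cat(sprintf("<argos_track %s> %d fixes, %s to %s\n", x$track_id,
              nrow(x$fixes), format(x$fixes$time[1L], tz = "UTC"),
              format(x$fixes$time[nrow(x$fixes)], tz = "UTC")))
  invisible(x)
}

parse_argos_time <- function(x, time_format = NULL) {
  fmts <- if (is.null(time_format))
    c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M",
      "%Y-%m-%d", "%m/%d/%Y %H:%M:%S")
  else time_format
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  left <- seq_along(x)
  for (f in fmts) {
    if (!length(left)) break
    p <- as.POSIXct(x[left], format = f, tz = "UTC")
    hit <- !is.na(p)
    out[left[hit]] <- p[hit]
    left <- left[!hit]
  }
  out
}

#' Read raw Argos locations into tracks
#'
#' Reads a delimited file of Argos fixes and returns one [argos_track()] per
#' tag. Rows with unparseable time, coordinates or location class are skipped
#' with a reported count; duplicated (tag, time) rows are collapsed keeping
#' the better location class.
#'
#' @param path path to a CSV/TSV file.
#' @param format_spec an [argos_format()] column mapping.
#' @param sep field separator (default `","`).
#' @return A named list of `argos_track` objects (possibly empty). The number
#'   of skipped rows is attached as attribute `"skipped"`.
#' @export
read_argos <- function(path, format_spec = argos_format(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("tag_id", "time", "lon", "lat", "lc")
  for (fld in need) {
    col <- format_spec[[fld]]
    if (!col %in% names(df))
      stop(sprintf("required column '%s' (%s) missing from %s",
                   col, fld, path))
  }
  if (nrow(df) == 0L) {
    warning("no data rows in ", path)
    return(structure(list(), skipped = 0L))
  }
  tag <- as.character(df[[format_spec$tag_id]])
  tm <- parse_argos_time(as.character(df[[format_spec$time]]),
                         format_spec$time_format)
  lon <- suppressWarnings(as.numeric(df[[format_spec$lon]]))
  lat <- suppressWarnings(as.numeric(df[[format_spec$lat]]))
  lc <- toupper(trimws(as.character(df[[format_spec$lc]])))
  ok <- !is.na(tm) & !is.na(lon) & !is.na(lat) & lc %in% ARGOS_CLASSES &
    lat >= -90 & lat <= 90
  n_skip <- sum(!ok)
  if (n_skip > 0L)
    message(n_skip, " unparseable/invalid row(s) skipped from ", path)
  tracks <- list()
  for (id in unique(tag[ok])) {
    sel <- ok & tag == id
    if (sum(sel) < 2L) {
      warning("tag ", id, " has < 2 usable fixes; dropped")
      next
    }
    tracks[[id]] <- argos_track(id, tm[sel], lon[sel], lat[sel], lc[sel])
  }
  structure(tracks, skipped = n_skip)
}

track_speeds_kmh <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2L) return(numeric(0))
  d_km <- geosphere::distHaversine(
    cbind(fixes$lon[-n], fixes$lat[-n]),
    cbind(fixes$lon[-1L], fixes$lat[-1L]), r = 6371000) / 1000
  dt_h <- as.numeric(difftime(fixes$time[-1L], fixes$time[-n],
                              units = "hours"))
  d_km / dt_h
}

#' Remove biologically implausible fixes by implied speed
#'
#' Iteratively removes the fix whose minimum implied great-circle speed to its
#' temporal neighbours most exceeds `max_speed` (end fixes are judged by the
#' speed to their sole neighbour), until no fix exceeds the threshold. The
#' default 30 km/h is roughly three times the fastest transit speed blue
#' whales show, so only clear location-error artefacts are cut.
#'
#' @param track an [argos_track()].
#' @param max_speed speed threshold in km/h.
#' @param max_fraction_removed if the removed fraction exceeds this a warning
#'   flags a data-quality problem (the filtered track is still returned).
#' @return The filtered track, with attribute `"removed_fraction"`.
#' @export
filter_implausible <- function(track, max_speed = 30,
                               max_fraction_removed = 0.04) {
  stopifnot(inherits(track, "argos_track"), max_speed > 0)
  fixes <- track$fixes
  n0 <- nrow(fixes)
  repeat {
    n <- nrow(fixes)
    if (n < 3L) break
    sp <- track_speeds_kmh(fixes)                 # speed of segment i: i->i+1
    implied <- pmin(c(Inf, sp), c(sp, Inf))       # min speed to both neighbours
    bad <- which(implied > max_speed)
    if (!length(bad)) break
    # interior fixes (flagged by both neighbours) are cut before endpoints,
    # which only ever have one neighbour's worth of evidence
    interior <- bad[bad != 1L & bad != n]
    pool <- if (length(interior)) interior else bad
    worst <- pool[which.max(implied[pool])]
    fixes <- fixes[-worst, , drop = FALSE]
  }
  removed <- (n0 - nrow(fixes)) / n0
  if (removed > max_fraction_removed)
    warning(sprintf("track %s: %.1f%% of fixes removed (> %.1f%%)",
                    track$track_id, 100 * removed,
                    100 * max_fraction_removed))
  out <- track
  out$fixes <- fixes
  rownames(out$fixes) <- NULL
  attr(out, "removed_fraction") <- removed
  out
}

#' Split a track at transmission gaps
#'
#' Cuts a track wherever the interval between consecutive fixes exceeds
#' `gap_days` (default 28 days, roughly one month — the gap that separates a
#' track into independently analysed segments). Segments receive alphabetic
#' suffixes (`"a"`, `"b"`, ...) in temporal order; if no gap exceeds the
#' threshold the single track is returned unsuffixed. Segments left with
#' fewer than 2 fixes are dropped with a warning.
#'
#' @param track an [argos_track()].
#' @param gap_days gap threshold in days (> 0).
#' @return A list of `argos_track` objects.
#' @export
split_on_gap <- function(track, gap_days = 28) {
  stopifnot(inherits(track, "argos_track"), gap_days > 0)
  fixes <- track$fixes
  dt_d <- as.numeric(difftime(fixes$time[-1L],
                              fixes$time[-nrow(fixes)], units = "days"))
  cuts <- which(dt_d > gap_days)
  if (!length(cuts)) return(list(track))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nrow(fixes))
  segs <- list()
  suffix <- letters
  k <- 0L
  for (i in seq_along(starts)) {
    part <- fixes[starts[i]:ends[i], , drop = FALSE]
    if (nrow(part) < 2L) {
      warning("segment with < 2 fixes dropped from track ", track$track_id)
      next
    }
    k <- k + 1L
    segs[[k]] <- argos_track(track$tag_id, part$time, part$lon, part$lat,
                             part$lc,
                             track_id = paste0(track$track_id, suffix[k]))
  }
  segs
}

#' Inclusive track duration in days
#'
#' The day count includes both the start and end calendar dates (UTC), the
#' convention under which a deployment transmitting 2013-04-01 to 2013-05-15
#' lasts 45 days.
#'
#' @param track an [argos_track()], or anything with `$fixes$time`; the
#'   start/end may also be passed directly as `start`/`end`.
#' @param start,end optional `POSIXct`/`Date` overriding the track's span.
#' @return Integer number of days.
#' @export
track_duration <- function(track = NULL, start = NULL, end = NULL) {
  if (is.null(start)) {
    start <- track$fixes$time[1L]
    end <- track$fixes$time[nrow(track$fixes)]
  }
  d0 <- as.Date(start, tz = "UTC")
  d1 <- as.Date(end, tz = "UTC")
  if (d1 < d0) stop("end date precedes start date")
  as.integer(d1 - d0) + 1L
}

#' Write tracks to a single CSV
#'
#' Emits the package's canonical Argos CSV dialect (`tag_id`, `track_id`,
#' `time`, `lon`, `lat`, `lc`), readable again with [read_argos()].
#'
#' @param tracks a list of [argos_track()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    cbind(tag_id = tr$tag_id, track_id = tr$track_id,
          data.frame(time = format(tr$fixes$time, "%Y-%m-%d %H:%M:%S",
                                   tz = "UTC"),
                     lon = tr$fixes$lon, lat = tr$fixes$lat,
                     lc = tr$fixes$lc, stringsAsFactors = FALSE))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a track (or fitted path) as a GeoJSON LineString
#'
#' @param lon,lat coordinate vectors (degrees), or pass an [argos_track()]
#'   as `track`.
#' @param path output file.
#' @param track optional `argos_track`; overrides `lon`/`lat`.
#' @param properties named list stored in the feature's properties.
#' @return `path`, invisibly.
#' @export
write_track_geojson <- function(path, lon = NULL, lat = NULL, track = NULL,
                                properties = list()) {
  if (!is.null(track)) {
    lon <- track$fixes$lon
    lat <- track$fixes$lat
    properties <- c(list(track_id = track$track_id), properties)
  }
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = properties,
      geometry = list(type = "LineString",
                      coordinates = unname(Map(c, lon, lat))))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
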