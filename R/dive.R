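#' Archival-tag depth bout
#'
#' A bout is a continuous depth recording at a fixed sampling resolution
#' (75 s for the MK10 programming emulated here), typically 1-4 h long.
#' Sample spacing is validated strictly: series with gaps must be split into
#' separate bouts first (see [read_depth_series()]).
#'
#' @param tag_id tag identifier.
#' @param time `POSIXct` sample times (UTC), equally spaced.
#' @param depth depths in metres, `>= 0`.
#' @param resolution_s sampling resolution in seconds.
#' @param bout_id optional identifier.
#' @return An object of class `dive_bout`.
#' @export
dive_bout <- function(tag_id, time, depth, resolution_s = 75,
                      bout_id = NULL) {
  stopifnot(length(time) == length(depth), length(time) >= 2)
  if (any(depth < 0)) stop("depths must be >= 0")
  dt <- as.numeric(difftime(time[-1L], time[-length(time)], units = "secs"))
  if (any(abs(dt - resolution_s) > 1e-6))
    stop("irregular sample spacing in bout (expected ", resolution_s, " s)")
  structure(list(tag_id = tag_id,
                 bout_id = if (is.null(bout_id))
                   paste0(tag_id, "_", format(time[1L], "%Y%m%d%H%M%S"))
                 else bout_id,
                 samples = data.frame(time = time, depth = depth),
                 resolution_s = resolution_s),
            class = "dive_bout")
}

#' Detect true dives in a depth bout
#'
#' A true dive is a maximal run of consecutive samples strictly exceeding the
#' depth threshold (default 10 m, about half a blue whale body length,
#' disregarding surface breathing activity). Duration is the run length times
#' the sampling resolution — the shortest reportable dive is one sample
#' (75 s). The post-dive (inter-diving) interval is the surface time between
#' the end of one dive and the start of the next within the same bout; it is
#' `NA` for the last dive of a bout. Dives never span bouts.
#'
#' @param bout a [dive_bout()].
#' @param threshold depth threshold in metres (> 0).
#' @return Data frame with one row per dive: `tag_id`, `bout_id`, `start`,
#'   `end`, `max_depth_m`, `duration_s`, `post_dive_interval_s`.
#' @export
detect_dives <- function(bout, threshold = 10) {
  stopifnot(inherits(bout, "dive_bout"), threshold > 0)
  res <- bout$resolution_s
  sub <- bout$samples$depth > threshold
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(tag_id = character(), bout_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      max_depth_m = numeric(), duration_s = numeric(),
                      post_dive_interval_s = numeric()))
  n <- length(keep)
  start_i <- starts[keep]
  end_i <- ends[keep]
  pdi <- c((start_i[-1L] - end_i[-n] - 1L) * res, NA_real_)
  data.frame(
    tag_id = bout$tag_id, bout_id = bout$bout_id,
    start = bout$samples$time[start_i],
    end = bout$samples$time[end_i] + res,
    max_depth_m = vapply(seq_len(n), function(k)
      max(bout$samples$depth[start_i[k]:end_i[k]]), 0),
    duration_s = (end_i - start_i + 1L) * res,
    post_dive_interval_s = pdi,
    stringsAsFactors = FALSE)
}

#' Solar elevation angle
#'
#' Standard low-precision solar position (NOAA formulas): geometric
#' elevation of the sun, no atmospheric refraction or twilight allowance.
#'
#' @param time `POSIXct` (UTC).
#' @param lon,lat position in degrees.
#' @return Elevation(s) in degrees; positive means the sun is up.
#' @export
solar_elevation <- function(time, lon, lat) {
  d <- as.numeric(difftime(time, as.POSIXct("2000-01-01 12:00:00",
                                            tz = "UTC"), units = "days"))
  deg <- pi / 180
  L <- (280.460 + 0.9856474 * d) %% 360
  g <- ((357.528 + 0.9856003 * d) %% 360) * deg
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * deg
  eps <- (23.439 - 4e-7 * d) * deg
  sindec <- sin(eps) * sin(lambda)
  dec <- asin(sindec)
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda)) / deg   # degrees
  gmst_h <- (18.697374558 + 24.06570982441908 * d) %% 24
  ha <- ((gmst_h * 15 + lon - ra + 180) %% 360 - 180) * deg
  elev <- asin(sin(lat * deg) * sindec + cos(lat * deg) * cos(dec) * cos(ha))
  elev / deg
}

#' Day/night tag from solar geometry
#'
#' A timestamped position is `"day"` iff the sun is above the geometric
#' horizon there; polar day/night resolve naturally through the elevation
#' sign. Dives are conventionally tagged at their start time.
#'
#' @inheritParams solar_elevation
#' @return Character vector, `"day"` or `"night"`.
#' @export
diel_tag <- function(time, lon, lat) {
  ifelse(solar_elevation(time, lon, lat) > 0, "day", "night")
}

#' Interpolate a fitted track position at arbitrary times
#'
#' @param path data frame with `time`, `lon`, `lat` (e.g. [fitted_path()]).
#' @param time `POSIXct` times (clamped to the path span).
#' @return Data frame with `lon`, `lat`.
#' @export
interp_position <- function(path, time) {
  data.frame(
    lon = stats::approx(path$time, path$lon, xout = time, rule = 2)$y,
    lat = stats::approx(path$time, path$lat, xout = time, rule = 2)$y)
}

#' Attach diel class to detected dives
#'
#' Tags each dive day/night at its start time, at the position interpolated
#' from the fitted track.
#'
#' @param dives output of [detect_dives()] (rows from several bouts may be
#'   row-bound).
#' @param path fitted track data frame (`time`, `lon`, `lat`).
#' @return `dives` with a `diel` column.
#' @export
add_diel <- function(dives, path) {
  if (nrow(dives) == 0L) {
    dives$diel <- character(0)
    return(dives)
  }
  pos <- interp_position(path, dives$start)
  dives$diel <- diel_tag(dives$start, pos$lon, pos$lat)
  dives
}

#' Bin dive statistics onto the state-space model grid
#'
#' Assigns each dive to the regular grid interval containing its start time
#' and summarises, per (bin, diel class), the three dive statistics —
#' maximum depth, duration, post-dive interval — as mean, sample SD and
#' range. Bins without data are omitted; post-dive intervals that are `NA`
#' (last dive of a bout) are excluded from the interval summaries.
#'
#' @param dives dive table with a `diel` column (see [add_diel()]).
#' @param grid an [build_grid()] result (`ssm_grid`).
#' @return Data frame keyed by `bin` (1-based grid interval) and `diel`.
#' @export
bin_dive_stats <- function(dives, grid) {
  stopifnot(inherits(grid, "ssm_grid"))
  if (nrow(dives) == 0L) return(data.frame())
  h <- as.numeric(difftime(dives$start, grid$times[1L], units = "hours"))
  bin <- floor(h / grid$step_hours) + 1L
  keep <- bin >= 1L & bin <= grid$n_steps
  dives <- dives[keep, , drop = FALSE]
  bin <- bin[keep]
  if (!nrow(dives)) return(data.frame())
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(mean = NA_real_, sd = NA_real_,
                             min = NA_real_, max = NA_real_))
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
      min = min(v), max = max(v))
  }
  out <- do.call(rbind, lapply(
    split(seq_len(nrow(dives)), list(bin = bin, diel = dives$diel),
          drop = TRUE),
    function(i) {
      de <- agg(dives$max_depth_m[i])
      du <- agg(dives$duration_s[i])
      pd <- agg(dives$post_dive_interval_s[i])
      data.frame(bin = bin[i][1L], diel = dives$diel[i][1L], n_dives = length(i),
                 depth_mean = de["mean"], depth_sd = de["sd"],
                 depth_min = de["min"], depth_max = de["max"],
                 duration_mean = du["mean"], duration_sd = du["sd"],
                 duration_min = du["min"], duration_max = du["max"],
                 postdive_mean = pd["mean"], postdive_sd = pd["sd"],
                 postdive_min = pd["min"], postdive_max = pd["max"],
                 row.names = NULL)
    }))
  out[order(out$bin, out$diel), , drop = FALSE]
}

#' Per-tag day/night dive summary
#'
#' The whole-deployment aggregation (one day and one night summary per tag)
#' complementing the per-bin output of [bin_dive_stats()].
#'
#' @param dives dive table with `diel`.
#' @return Data frame keyed by `tag_id` and `diel` with mean, SD and range
#'   of depth, duration and post-dive interval.
#' @export
summarize_dives <- function(dives) {
  if (nrow(dives) == 0L) return(data.frame())
  # one all-enclosing bin per tag reuses the per-bin aggregation
  res <- do.call(rbind, lapply(split(dives, dives$tag_id), function(dd) {
    s <- bin_dive_stats(dd, structure(list(times = min(dd$start) - 1,
                                           step_hours = 1e9, n_steps = 1L),
                                      class = "ssm_grid"))
    s$tag_id <- dd$tag_id[1L]
    s$bin <- NULL
    s
  }))
  rownames(res) <- NULL
  res[, c("tag_id", setdiff(names(res), "tag_id"))]
}

#' Read archival depth series into bouts
#'
#' Reads a CSV of (tag, timestamp, depth) samples — the layout of a Wildlife
#' Computers "time series" export with configurable column names — and cuts
#' each tag's series into constant-spacing bouts wherever the sampling
#' interval deviates from `resolution_s` (missing samples split a bout).
#'
#' @param path CSV path.
#' @param tag_col,time_col,depth_col column names.
#' @param resolution_s expected sampling resolution in seconds.
#' @return List of [dive_bout()] objects (bouts with < 2 samples dropped).
#' @export
read_depth_series <- function(path, tag_col = "tag_id", time_col = "time",
                              depth_col = "depth", resolution_s = 75) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(tag_col, time_col, depth_col))
    if (!col %in% names(df))
      stop("required column '", col, "' missing from ", path)
  tm <- parse_argos_time(as.character(df[[time_col]]))
  bouts <- list()
  for (id in unique(df[[tag_col]])) {
    sel <- which(df[[tag_col]] == id & !is.na(tm))
    sel <- sel[order(tm[sel])]
    t_i <- tm[sel]
    d_i <- as.numeric(df[[depth_col]][sel])
    dt <- as.numeric(difftime(t_i[-1L], t_i[-length(t_i)], units = "secs"))
    brk <- c(0L, which(abs(dt - resolution_s) > 1e-6), length(t_i))
    for (k in seq_len(length(brk) - 1L)) {
      i0 <- brk[k] + 1L
      i1 <- brk[k + 1L]
      if (i1 - i0 + 1L < 2L) next
      bouts[[length(bouts) + 1L]] <-
        dive_bout(id, t_i[i0:i1], d_i[i0:i1], resolution_s)
    }
  }
  bouts
}

#' Write a dive table to CSV
#' @param dives dive table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dives_csv <- function(dives, path) {
  dives$start <- format(dives$start, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  dives$end <- format(dives$end, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(dives, path, row.names = FALSE)
  invisible(path)
}
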