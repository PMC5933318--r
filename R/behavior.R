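#' Classify a continuous behavioral mode
#'
#' The posterior mean of the sampled discrete state is a continuous mode `m`
#' in `[1, 2]`. Values up to 1.25 are classified as transit (persistent,
#' low-turn movement, here associated with migration); values of 1.75 and
#' above as area-restricted search (ARS; high turning and speed/direction
#' variability, associated with foraging); values between the thresholds are
#' left unclassified. Threshold values themselves take the classified label.
#'
#' @param m numeric vector of modes in `[1, 2]`.
#' @param lower,upper classification thresholds (defaults 1.25 and 1.75).
#' @return Factor with levels `transit`, `unclassified`, `ARS`.
#' @export
classify_mode <- function(m, lower = 1.25, upper = 1.75) {
  if (any(is.na(m)) || any(m < 1 | m > 2))
    stop("behavioral mode must lie in [1, 2]")
  lab <- cut(m, breaks = c(1, lower, upper, 2),
             labels = c("transit", "unclassified", "ARS"),
             include.lowest = TRUE, right = TRUE)
  lab[m >= upper] <- "ARS"   # threshold values take the classified label
  lab
}

#' Great-circle step speed
#'
#' Haversine distance (sphere radius 6371 km) between consecutive grid
#' locations, divided by the step duration.
#'
#' @param x_t,x_t1 length-2 (lon, lat) locations, or two-column matrices.
#' @param step_hours step duration in hours.
#' @return Speed(s) in km/h.
#' @export
step_speed <- function(x_t, x_t1, step_hours) {
  d_km <- geosphere::distHaversine(rbind(x_t), rbind(x_t1), r = 6371000) / 1000
  d_km / step_hours
}

#' Movement descriptors of a fitted track
#'
#' Computes, from the posterior mean path, the total great-circle distance
#' travelled, distance per day (total distance over the inclusive track
#' duration in days), and per-state step-speed summaries (mean, sample SD,
#' min-max) for transit and ARS separately. Each step takes the label of its
#' ending grid point; states with no steps report `NA` speeds (printed as
#' "na" in the descriptors table).
#'
#' @param path data frame with `time`, `lon`, `lat` and `mode` columns (a
#'   [fitted_path()]), or a `dcrws_fit` (its first track).
#' @param step_hours grid step in hours; taken from the fit when `path` is a
#'   `dcrws_fit`.
#' @param track_id descriptor row label.
#' @return A one-row data frame of class `movement_descriptors`:
#'   `track_id`, `n_steps`, `duration_days`, `distance_km`, `km_per_day`,
#'   and for each of `transit`/`ars`: `speed_mean`, `speed_sd`, `speed_min`,
#'   `speed_max`, `n` (step counts; also `n_unclassified`).
#' @export
summarize_track <- function(path, step_hours, track_id = "track") {
  if (inherits(path, "dcrws_fit")) {
    step_hours <- path$step_hours
    track_id <- names(path$tracks)[1L]
    path <- fitted_path(path)
  }
  stopifnot(nrow(path) >= 2, !missing(step_hours) || !is.null(step_hours))
  n <- nrow(path)
  p0 <- cbind(path$lon[-n], path$lat[-n])
  p1 <- cbind(path$lon[-1L], path$lat[-1L])
  d_km <- geosphere::distHaversine(p0, p1, r = 6371000) / 1000
  sp <- d_km / step_hours
  lab <- classify_mode(path$mode)[-1L]   # step label = state at its end point
  dur <- track_duration(start = path$time[1L], end = path$time[n])

  one <- function(keep) {
    v <- sp[keep]
    if (!length(v)) return(c(mean = NA_real_, sd = NA_real_,
                             min = NA_real_, max = NA_real_, n = 0))
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
      min = min(v), max = max(v), n = length(v))
  }
  tr <- one(lab == "transit")
  ar <- one(lab == "ARS")
  out <- data.frame(
    track_id = track_id, n_steps = n - 1L, duration_days = dur,
    distance_km = sum(d_km), km_per_day = sum(d_km) / dur,
    transit_speed_mean = tr["mean"], transit_speed_sd = tr["sd"],
    transit_speed_min = tr["min"], transit_speed_max = tr["max"],
    transit_n = tr["n"],
    ars_speed_mean = ar["mean"], ars_speed_sd = ar["sd"],
    ars_speed_min = ar["min"], ars_speed_max = ar["max"],
    ars_n = ar["n"],
    n_unclassified = sum(lab == "unclassified"),
    row.names = NULL)
  class(out) <- c("movement_descriptors", "data.frame")
  out
}

#' Descriptor table for every track of a fit
#'
#' @param fit a `dcrws_fit`.
#' @return Row-bound [summarize_track()] results, one row per track.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "dcrws_fit"))
  do.call(rbind, lapply(names(fit$tracks), function(id)
    summarize_track(fit$tracks[[id]]$summary, fit$step_hours, id)))
}

#' Format a descriptor table like a deployment summary
#'
#' Renders speeds as `mean +/- SD (min-max)` with `na` for absent states,
#' matching the layout of published movement-descriptor tables.
#'
#' @param desc output of [summarize_track()] / [summarize_fit()].
#' @return A character data frame.
#' @export
format_descriptors <- function(desc) {
  fmt <- function(m, s, lo, hi)
    ifelse(is.na(m), "na",
           sprintf("%.2f ± %.2f (%.2f–%.2f)", m, s, lo, hi))
  data.frame(
    track_id = desc$track_id,
    duration_days = desc$duration_days,
    distance_km = round(desc$distance_km, 1),
    km_per_day = round(desc$km_per_day, 1),
    ars_speed = fmt(desc$ars_speed_mean, desc$ars_speed_sd,
                    desc$ars_speed_min, desc$ars_speed_max),
    transit_speed = fmt(desc$transit_speed_mean, desc$transit_speed_sd,
                        desc$transit_speed_min, desc$transit_speed_max),
    stringsAsFactors = FALSE)
}
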