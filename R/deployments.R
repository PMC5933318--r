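#' Published deployment summary of the ten tagged blue whales
#'
#' The printed deployment table (tag type, transmission start/end dates,
#' track duration, distance travelled and per-state speed summaries) for the
#' ten blue whales satellite-tagged in Chilean Northern Patagonia in 2013,
#' 2015 and 2016 (whale #2's track is split into segments 2a/2b by a
#' month-long transmission gap). Shipped as plain CSV in `inst/extdata`;
#' used to check the inclusive day-count convention.
#'
#' @return Data frame with columns `id`, `tag_type`, `start`, `end` (Date),
#'   `duration_days`, `distance_km`, `ars_speed`, `transit_speed`.
#' @export
table1_deployments <- function() {
  path <- system.file("extdata", "table1_deployments.csv", package = "dcrws",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$start <- as.Date(df$start)
  df$end <- as.Date(df$end)
  df
}
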