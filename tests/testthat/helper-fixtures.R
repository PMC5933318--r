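# shared fixtures and independent oracles

utc <- function(x) as.POSIXct(x, tz = "UTC")

# independent haversine oracle (R = 6371 km), distinct from the geosphere path
hav_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  a <- sin((lat2 - lat1) * rad / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin((lon2 - lon1) * rad / 2)^2
  2 * 6371 * asin(sqrt(a))
}

# independent t log-density via the gamma-function closed form
lt_dens <- function(x, nu) {
  lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi) -
    (nu + 1) / 2 * log1p(x^2 / nu)
}

# a small hand-built track: `hours` offsets from a base time
mk_track <- function(hours, lon, lat, lc = "3", tag = "w1") {
  argos_track(tag, utc("2015-04-01 00:00:00") + hours * 3600,
              lon, lat, rep_len(lc, length(hours)))
}

# fraction of classified grid steps whose label matches the true state
state_accuracy <- function(fit, b_true) {
  m <- fitted_path(fit)$mode[-1]
  lab <- classify_mode(m)
  known <- lab != "unclassified"
  list(accuracy = mean((as.integer(lab[known] == "ARS") + 1) == b_true[known]),
       classified = mean(known))
}

# fast MCMC settings for smoke-level fits
fast_mcmc <- function(seed, n_iter = 2000, n_burnin = 1000, thin = 2)
  mcmc_config(2, n_iter, n_burnin, thin, seed = seed)
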