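#' Fit the hierarchical switching DCRWS model by MCMC
#'
#' Estimates, jointly across tracks, the shared movement parameters
#' (persistence `gamma`, mean turning angle `theta`, switching probabilities
#' `alpha`, process-noise covariance) and, per track, the latent regular-step
#' locations and behavioral states. States are updated by single-site Gibbs,
#' locations and parameters by adaptive random-walk Metropolis (adaptation
#' during burn-in only), and the switching probabilities by conjugate Beta
#' draws. Chains start from over-dispersed points using sub-seeds
#' `seed + chain`. Grid intervals containing no fixes contribute process
#' terms only; a run of empty intervals longer than `missing_run_cap` steps
#' splits the track into separately fitted segments rather than bridging the
#' gap.
#'
#' @param tracks an [argos_track()] or list of them.
#' @param step_hours regular grid step in hours (48 broad-scale, 6
#'   fine-scale).
#' @param mcmc an [mcmc_config()].
#' @param priors a [dcrws_priors()].
#' @param tdist Argos class error table from [argos_tdist()] (fixed, not
#'   estimated).
#' @param missing_run_cap maximum tolerated run of fix-less grid steps before
#'   the track is split.
#' @return An object of class `dcrws_fit`: per-track posterior summaries
#'   (`$tracks[[id]]$summary`: time, posterior mean location, 95% credible
#'   bounds, continuous behavioral mode `m` in `[1,2]`), parameter draws
#'   (`$params`, with a `chain` column), parameter summaries with R-hat
#'   (`$param_summary`), acceptance rates and configuration. If any R-hat
#'   exceeds 1.1 the fit is flagged `converged = FALSE` with a warning.
#' @export
fit_dcrws <- function(tracks, step_hours, mcmc = mcmc_config(),
                      priors = dcrws_priors(), tdist = argos_tdist(),
                      missing_run_cap = 10) {
  if (inherits(tracks, "argos_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1)
  tracks <- split_missing_runs(tracks, step_hours, missing_run_cap)
  grids <- lapply(tracks, build_grid, step_hours = step_hours)
  ids <- vapply(tracks, function(tr) tr$track_id, "")
  names(grids) <- ids

  cdat <- lapply(seq_along(tracks), function(i)
    track_cdata(tracks[[i]], grids[[i]], tdist))

  n_ret_chain <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch)
    init <- overdispersed_init(ch)
    cdat_ch <- lapply(cdat, function(d) {
      # over-dispersed location starts, but proportionate to the observation
      # scale: a fixed jitter would strand chains thousands of SDs from the
      # posterior when fixes are very precise
      jit <- min(0.02 * ch, 20 * stats::median(pmin(d$tau[, 1], d$tau[, 2])))
      d$x0 <- d$x0 + stats::rnorm(length(d$x0), 0, jit)
      d$b0 <- sample(1:2, d$T, replace = TRUE)
      d
    })
    chains[[ch]] <- .dcrws_chain(
      cdat_ch, init, list(sd_df = priors$sd_df, sd_scale = priors$sd_scale),
      list(n_iter = mcmc$n_iter, n_burn = mcmc$n_burnin, thin = mcmc$thin))
  }

  par_mats <- lapply(chains, function(c0) c0$params)
  rhat <- if (mcmc$n_chains >= 2) gelman_rubin(par_mats) else
    stats::setNames(rep(NA_real_, ncol(par_mats[[1]])),
                    colnames(par_mats[[1]]))
  params <- do.call(rbind, lapply(seq_along(par_mats), function(ch)
    data.frame(chain = ch, par_mats[[ch]])))
  stopifnot(nrow(params) == mcmc$n_chains * n_ret_chain)

  pars <- colnames(par_mats[[1]])
  param_summary <- data.frame(
    parameter = pars,
    mean = vapply(pars, function(p) mean(params[[p]]), 0),
    lo95 = vapply(pars, function(p) unname(stats::quantile(params[[p]], 0.025)), 0),
    hi95 = vapply(pars, function(p) unname(stats::quantile(params[[p]], 0.975)), 0),
    rhat = unname(rhat[pars]),
    row.names = NULL)

  fits <- lapply(seq_along(tracks), function(i) {
    lon <- do.call(rbind, lapply(chains, function(c0) c0$tracks[[i]]$lon))
    lat <- do.call(rbind, lapply(chains, function(c0) c0$tracks[[i]]$lat))
    b_mean <- rowMeans(vapply(chains, function(c0) c0$tracks[[i]]$b_mean,
                              numeric(grids[[i]]$n_steps)))
    m <- c(b_mean[1L], b_mean)      # grid point 0 inherits the first step's state
    summary <- data.frame(
      time = grids[[i]]$times,
      lon = colMeans(lon), lat = colMeans(lat),
      lon_lo = apply(lon, 2, stats::quantile, 0.025),
      lon_hi = apply(lon, 2, stats::quantile, 0.975),
      lat_lo = apply(lat, 2, stats::quantile, 0.025),
      lat_hi = apply(lat, 2, stats::quantile, 0.975),
      mode = m, row.names = NULL)
    list(track_id = ids[i], summary = summary, grid = grids[[i]])
  })
  names(fits) <- ids

  converged <- all(is.na(rhat) | rhat <= 1.1)
  if (!converged)
    warning("non-convergence: R-hat > 1.1 for ",
            paste(pars[!is.na(rhat) & rhat > 1.1], collapse = ", "))

  structure(list(tracks = fits, params = params,
                 param_summary = param_summary,
                 accept = rowMeans(vapply(chains, function(c0) c0$accept,
                                          numeric(2))),
                 converged = converged, step_hours = step_hours,
                 mcmc = mcmc, priors = priors, tdist = tdist),
            class = "dcrws_fit")
}

# split tracks whose fixes leave more than `cap` consecutive empty grid steps
split_missing_runs <- function(tracks, step_hours, cap) {
  out <- list()
  for (tr in tracks) {
    gap_days <- cap * step_hours / 24
    segs <- split_on_gap(tr, gap_days = gap_days)
    if (length(segs) > 1L)
      message("track ", tr$track_id, " split into ", length(segs),
              " segments at gaps > ", cap, " empty steps")
    out <- c(out, segs)
  }
  out
}

# package one track+grid for the C++ sampler
track_cdata <- function(track, grid, tdist) {
  f <- track$fixes
  row <- tdist[match(f$lc, tdist$lc), ]
  x0 <- cbind(
    stats::approx(f$time, f$lon, xout = grid$times, rule = 2)$y,
    stats::approx(f$time, f$lat, xout = grid$times, rule = 2)$y)
  list(T = grid$n_steps,
       obs = cbind(f$lon, f$lat),
       idx = grid$assign$interval - 1L,
       j = grid$assign$j,
       nu = cbind(row$nu_lon, row$nu_lat),
       tau = cbind(row$tau_lon, row$tau_lat),
       x0 = x0,
       b0 = rep(1L, grid$n_steps))
}

overdispersed_init <- function(chain) {
  base <- list(
    list(gamma = c(0.70, 0.30), theta = c(0.3, -0.3), alpha = c(0.7, 0.3),
         sd1 = 0.15, sd2 = 0.15, rho = 0),
    list(gamma = c(0.95, 0.05), theta = c(-0.3, 0.3), alpha = c(0.95, 0.05),
         sd1 = 0.03, sd2 = 0.03, rho = 0))
  if (chain <= 2) return(base[[chain]])
  g <- sort(stats::runif(2), decreasing = TRUE)
  list(gamma = g, theta = stats::runif(2, -pi / 2, pi / 2),
       alpha = stats::runif(2), sd1 = stats::runif(1, 0.02, 0.2),
       sd2 = stats::runif(1, 0.02, 0.2), rho = 0)
}

#' @export
print.dcrws_fit <- function(x, ...) {
  cat(sprintf("<dcrws_fit> %d track(s), step %g h, %d retained samples, %s\n",
              length(x$tracks), x$step_hours, nrow(x$params),
              if (isTRUE(x$converged)) "converged (all R-hat <= 1.1)"
              else "NOT converged"))
  print(x$param_summary, digits = 3)
  invisible(x)
}

#' Posterior mean path of a fitted track
#'
#' @param fit a `dcrws_fit`.
#' @param track_id which track (default: first).
#' @return The per-grid-time summary data frame.
#' @export
fitted_path <- function(fit, track_id = names(fit$tracks)[1L]) {
  stopifnot(inherits(fit, "dcrws_fit"))
  fit$tracks[[track_id]]$summary
}

#' Write fitted-track outputs
#'
#' Writes the per-track posterior summary CSV, a parameter-posterior CSV, a
#' diagnostics JSON (R-hat, acceptance rates, retained sample count) and one
#' GeoJSON LineString per track.
#'
#' @param fit a `dcrws_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(fit$tracks)) {
    s <- fit$tracks[[id]]$summary
    s$time <- format(s$time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    utils::write.csv(s, file.path(dir, paste0("track_", id, ".csv")),
                     row.names = FALSE)
    write_track_geojson(file.path(dir, paste0("track_", id, ".geojson")),
                        lon = fit$tracks[[id]]$summary$lon,
                        lat = fit$tracks[[id]]$summary$lat,
                        properties = list(track_id = id))
  }
  utils::write.csv(fit$params, file.path(dir, "parameter_posterior.csv"),
                   row.names = FALSE)
  diag <- list(rhat = as.list(stats::setNames(fit$param_summary$rhat,
                                              fit$param_summary$parameter)),
               accept = as.list(fit$accept),
               n_retained = nrow(fit$params),
               converged = fit$converged)
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(dir)
}
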