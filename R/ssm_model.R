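#' Argos location-class t-distribution error parameters
#'
#' Per location class (3, 2, 1, 0, A, B) and coordinate, the degrees of
#' freedom `nu` and scale `tau` (degrees) of the t-distributed observation
#' error. The defaults are calibrated to the error magnitudes commonly
#' reported for the Argos system — sub-kilometre for class 3 growing to
#' several kilometres with increasingly heavy tails for classes 0, A and B
#' (1 km is roughly 0.009 degrees of latitude) — and are deliberately
#' overridable: pass your own table to [fit_dcrws()] or [simulate_track()]
#' when class-error fits estimated for your tag programme are available.
#'
#' @param tbl optional replacement table with columns `lc`, `nu_lon`,
#'   `tau_lon`, `nu_lat`, `tau_lat`, one row per class in
#'   `c("3","2","1","0","A","B")`.
#' @return A data frame with one row per location class.
#' @export
argos_tdist <- function(tbl = NULL) {
  if (is.null(tbl)) {
    tbl <- data.frame(
      lc = c("3", "2", "1", "0", "A", "B"),
      nu_lon = c(6, 5, 4, 2, 1.6, 1.2),
      tau_lon = c(0.003, 0.005, 0.010, 0.018, 0.028, 0.045),
      nu_lat = c(6, 5, 4, 2, 1.6, 1.2),
      tau_lat = c(0.002, 0.004, 0.008, 0.015, 0.023, 0.038),
      stringsAsFactors = FALSE)
  }
  need <- c("lc", "nu_lon", "tau_lon", "nu_lat", "tau_lat")
  if (!all(need %in% names(tbl))) stop("t table needs columns: ",
                                       paste(need, collapse = ", "))
  if (!setequal(tbl$lc, ARGOS_CLASSES)) stop("t table must cover classes ",
                                             paste(ARGOS_CLASSES, collapse = ","))
  num <- unlist(tbl[c("nu_lon", "tau_lon", "nu_lat", "tau_lat")])
  if (any(num <= 0)) stop("all nu and tau must be > 0")
  ord <- tbl[match(ARGOS_CLASSES, tbl$lc), ]
  if (is.unsorted(ord$tau_lon) || is.unsorted(ord$tau_lat))
    stop("tau must be non-increasing with nominal Argos quality")
  rownames(ord) <- NULL
  ord
}

#' Regular time grid for state-space fitting
#'
#' Lays a grid of `T + 1` times, spaced `step_hours` apart, from the first
#' fix, with `T = ceiling(span / step)`, and assigns every fix an interval
#' index and fractional position `j` within it. Intervals are half-open, so a
#' fix exactly on a grid time starts that interval (`j = 0`); only a fix at
#' the final grid time carries `j = 1` in the last interval.
#'
#' @param track an [argos_track()].
#' @param step_hours grid step (48 for the broad-scale model, 6 for the
#'   fine-scale model).
#' @return A list of class `ssm_grid`: `times` (POSIXct), `step_hours`,
#'   `n_steps` (`T`), and `assign` (data frame `interval` 1-based, `j`).
#' @export
build_grid <- function(track, step_hours) {
  stopifnot(inherits(track, "argos_track"), step_hours > 0)
  t0 <- track$fixes$time[1L]
  span_h <- as.numeric(difftime(track$fixes$time[nrow(track$fixes)], t0,
                                units = "hours"))
  if (span_h < 2 * step_hours)
    stop("track ", track$track_id, " spans less than 2 grid steps")
  T_ <- ceiling(span_h / step_hours)
  times <- t0 + seq(0, T_) * step_hours * 3600
  h <- as.numeric(difftime(track$fixes$time, t0, units = "hours"))
  interval <- pmin(floor(h / step_hours), T_ - 1)
  j <- h / step_hours - interval
  structure(list(times = times, step_hours = step_hours, n_steps = T_,
                 assign = data.frame(interval = as.integer(interval) + 1L,
                                     j = j)),
            class = "ssm_grid")
}

#' Deterministic mean of one first-difference CRW step
#'
#' The process model moves by the previous displacement rotated by the
#' state's mean turning angle and damped by its persistence:
#' `x_next = x_prev + gamma_b R(theta_b) (x_prev - x_prev2) + noise`.
#'
#' @param x_prev2,x_prev numeric length-2 locations (lon, lat degrees) at the
#'   two preceding grid times.
#' @param b behavioral state, 1 (transit) or 2 (area-restricted search).
#' @param params a [dcrws_params()] list.
#' @param noise length-2 process noise draw (default zero, giving the
#'   conditional mean).
#' @return Length-2 numeric, the next location.
#' @export
process_model_step <- function(x_prev2, x_prev, b, params,
                               noise = c(0, 0)) {
  stopifnot(b %in% c(1, 2))
  g <- params$gamma[b]
  th <- params$theta[b]
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  d <- x_prev - x_prev2
  as.numeric(x_prev + g * (R %*% d) + noise)
}

#' Movement-parameter bundle
#'
#' @param gamma length-2 persistence in `[0,1]`, `gamma[1] >= gamma[2]`
#'   (state 1, transit, is the more persistent state; estimation enforces the
#'   strict ordering, equality is allowed here for degenerate simulations).
#' @param theta length-2 mean turning angles in `(-pi, pi]`.
#' @param alpha length-2 switching probabilities,
#'   `alpha[k] = P(b_t = 1 | b_{t-1} = k)`.
#' @param sigma length-2 process-noise SDs (degrees, lon/lat).
#' @param rho process-noise correlation in `(-1, 1)`.
#' @return A list of class `dcrws_params`.
#' @export
dcrws_params <- function(gamma = c(0.85, 0.15), theta = c(0, 0),
                         alpha = c(0.9, 0.1), sigma = c(0.08, 0.08),
                         rho = 0) {
  stopifnot(length(gamma) == 2, all(gamma >= 0 & gamma <= 1),
            gamma[1] >= gamma[2],
            length(theta) == 2, all(theta > -pi & theta <= pi),
            length(alpha) == 2, all(alpha >= 0 & alpha <= 1),
            length(sigma) == 2, all(sigma >= 0), abs(rho) < 1)
  structure(list(gamma = gamma, theta = theta, alpha = alpha,
                 sigma = sigma, rho = rho), class = "dcrws_params")
}

#' Observation log-likelihood of one Argos fix
#'
#' The fix is predicted by linear interpolation between the latent locations
#' bounding its grid interval, `(1 - j) x_prev + j x_t`, and each coordinate
#' residual follows a scaled t distribution whose `nu` and `tau` depend on
#' the fix's Argos location class.
#'
#' @param fix list/row with `lon`, `lat` and `lc`.
#' @param x_t,x_prev latent locations (lon, lat) at the interval end/start.
#' @param j fractional position of the fix in its interval, in `[0, 1]`.
#' @param tdist a class-error table from [argos_tdist()].
#' @return The log-density (sum over the two coordinates).
#' @export
observation_loglik <- function(fix, x_t, x_prev, j, tdist = argos_tdist()) {
  stopifnot(j >= 0, j <= 1)
  row <- tdist[tdist$lc == as.character(fix$lc), ]
  if (nrow(row) != 1L) stop("unknown Argos location class: ", fix$lc)
  pred <- (1 - j) * x_prev + j * x_t
  stats::dt((fix$lon - pred[1]) / row$tau_lon, df = row$nu_lon, log = TRUE) -
    log(row$tau_lon) +
    stats::dt((fix$lat - pred[2]) / row$tau_lat, df = row$nu_lat, log = TRUE) -
    log(row$tau_lat)
}

#' Markov behavioral-state transition
#'
#' @param b_prev state at the previous step (1 or 2).
#' @param params a [dcrws_params()]; `alpha[k]` is the probability of moving
#'   to state 1 from state `k`.
#' @param u uniform(0,1) draw (default fresh).
#' @return The next state, 1 or 2.
#' @export
switch_states <- function(b_prev, params, u = stats::runif(1)) {
  stopifnot(b_prev %in% c(1, 2))
  if (u < params$alpha[b_prev]) 1L else 2L
}

#' MCMC settings
#'
#' Defaults follow the estimation protocol used for the whale tracks: two
#' parallel chains of 120,000 iterations, 100,000 burn-in, thinning by 20 —
#' 2,000 retained samples in total.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations discarded per chain.
#' @param thin retention stride.
#' @param seed integer seed; chain `c` uses `seed + c`.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_iter = 120000, n_burnin = 100000,
                        thin = 20, seed = 1) {
  stopifnot(n_burnin < n_iter, n_chains >= 1, thin >= 1)
  if ((n_iter - n_burnin) %% thin != 0)
    stop("thin must divide n_iter - n_burnin for exact sample bookkeeping")
  n_ret <- (n_iter - n_burnin) / thin
  if (n_ret < 100)
    stop("fewer than 100 retained samples per chain; lengthen the run")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 n_retained = as.integer(n_chains * n_ret)),
            class = "mcmc_config")
}

#' Prior specification for the DCRWS parameters
#'
#' Flat Beta(1,1) priors on the persistences and switching probabilities, a
#' uniform prior on the mean turning angles over `(-pi, pi]`, half-t priors
#' on the process-noise SDs and a uniform prior on their correlation. All
#' hyperparameters are configurable.
#'
#' @param sd_df,sd_scale degrees of freedom and scale (degrees) of the
#'   half-t prior on each process-noise SD.
#' @return A list of class `dcrws_priors`.
#' @export
dcrws_priors <- function(sd_df = 3, sd_scale = 1) {
  stopifnot(sd_df > 0, sd_scale > 0)
  structure(list(sd_df = sd_df, sd_scale = sd_scale),
            class = "dcrws_priors")
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Computes `sqrt(((n-1)/n * W + B/n) / W)` where `W` is the mean
#' within-chain variance and `B/n` the variance of the chain means, per
#' parameter. Values near 1 indicate the chains have mixed; above about 1.1
#' they have not.
#'
#' @param chains a list (length >= 2) of equal-length numeric vectors, or of
#'   matrices with one column per parameter.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least 2 chains")
  if (is.null(dim(chains[[1L]])))
    chains <- lapply(chains, function(v) matrix(v, ncol = 1))
  n <- nrow(chains[[1L]])
  if (n < 10L) stop("chains too short for a meaningful diagnostic")
  if (!all(vapply(chains, nrow, 1L) == n)) stop("chains must have equal length")
  m <- length(chains)
  p <- ncol(chains[[1L]])
  rhat <- numeric(p)
  for (k in seq_len(p)) {
    draws <- vapply(chains, function(ch) ch[, k], numeric(n))
    means <- colMeans(draws)
    W <- mean(apply(draws, 2, stats::var))
    B_over_n <- stats::var(means)          # = B / n
    var_plus <- (n - 1) / n * W + B_over_n
    rhat[k] <- if (W == 0) 1 else sqrt(var_plus / W)
  }
  names(rhat) <- colnames(chains[[1L]])
  rhat
}
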