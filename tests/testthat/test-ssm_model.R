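test_that("process model mean follows the rotated damped displacement", {
  p <- dcrws_params(gamma = c(1, 0), theta = c(0, 0))
  # full persistence, no turn: straight-line continuation
  expect_equal(process_model_step(c(0, 0), c(1, 0.5), 1, p), c(2, 1))
  # zero persistence: pure random walk about the previous location
  expect_equal(process_model_step(c(0, 0), c(1, 0.5), 2, p), c(1, 0.5))
  # quarter-turn rotation maps displacement (1,0) to (0,1)
  p2 <- dcrws_params(gamma = c(1, 0.5), theta = c(pi / 2, 0))
  expect_equal(process_model_step(c(0, 0), c(1, 0), 1, p2), c(1, 1))
  # noise enters additively
  expect_equal(process_model_step(c(0, 0), c(1, 0), 1, p2,
                                  noise = c(0.3, -0.2)), c(1.3, 0.8))
  expect_error(process_model_step(c(0, 0), c(1, 0), 3, p2), "b")
})

test_that("observation log-likelihood matches the t-density closed form", {
  td <- argos_tdist()
  set.seed(99)
  for (i in 1:100) {
    lc <- sample(td$lc, 1)
    row <- td[td$lc == lc, ]
    x_prev <- stats::runif(2, -80, -70)
    x_t <- x_prev + stats::rnorm(2, 0, 0.5)
    j <- stats::runif(1)
    pred <- (1 - j) * x_prev + j * x_t
    fix <- list(lon = pred[1] + stats::rnorm(1, 0, 0.1),
                lat = pred[2] + stats::rnorm(1, 0, 0.1), lc = lc)
    expected <- lt_dens((fix$lon - pred[1]) / row$tau_lon, row$nu_lon) -
      log(row$tau_lon) +
      lt_dens((fix$lat - pred[2]) / row$tau_lat, row$nu_lat) -
      log(row$tau_lat)
    expect_equal(observation_loglik(fix, x_t, x_prev, j, td), expected,
                 tolerance = 1e-10)
  }
})

test_that("observation model scale and tail behavior", {
  td <- argos_tdist()
  x_prev <- c(-75, -40)
  x_t <- c(-74.5, -39.5)
  j <- 0.25
  pred <- (1 - j) * x_prev + j * x_t
  fix0 <- list(lon = pred[1], lat = pred[2], lc = "3")
  ll0 <- observation_loglik(fix0, x_t, x_prev, j, td)
  # zero residual is the mode: any perturbation lowers the density
  fix1 <- list(lon = pred[1] + 0.01, lat = pred[2], lc = "3")
  expect_lt(observation_loglik(fix1, x_t, x_prev, j, td), ll0)
  # doubling both scales at zero residual costs exactly 2 log 2
  td2 <- td
  td2$tau_lon <- td$tau_lon * 2
  td2$tau_lat <- td$tau_lat * 2
  expect_equal(observation_loglik(fix0, x_t, x_prev, j, td2),
               ll0 - 2 * log(2), tolerance = 1e-12)
  # heavy class-B tail beats a Normal of matching scale at 5 scale units out
  rowB <- td[td$lc == "B", ]
  t_tail <- lt_dens(5, rowB$nu_lon) - log(rowB$tau_lon)
  n_tail <- stats::dnorm(5, log = TRUE) - log(rowB$tau_lon)
  expect_gt(t_tail, n_tail)
  # unknown class is a configuration error
  expect_error(observation_loglik(list(lon = 0, lat = 0, lc = "Z"),
                                  x_t, x_prev, j, td), "class")
})

test_that("class error table validates scale ordering and coverage", {
  td <- argos_tdist()
  expect_setequal(td$lc, c("3", "2", "1", "0", "A", "B"))
  expect_true(all(diff(td$tau_lon) >= 0) && all(diff(td$tau_lat) >= 0))
  bad <- td
  bad$tau_lon[1] <- 1   # class 3 scale above class B
  expect_error(argos_tdist(bad), "non-increasing")
  bad2 <- td[td$lc != "B", ]
  expect_error(argos_tdist(bad2), "cover")
})

test_that("state switching follows the two-state Markov chain", {
  absorbing <- dcrws_params(alpha = c(1, 0))
  expect_equal(switch_states(1, absorbing, u = 0.99), 1L)
  expect_equal(switch_states(2, absorbing, u = 0.01), 2L)
  p <- dcrws_params(alpha = c(0.9, 0.2))
  expect_equal(switch_states(1, p, u = 0.89), 1L)
  expect_equal(switch_states(1, p, u = 0.91), 2L)
  # stationary distribution: pi_1 = alpha_2 / (1 - alpha_1 + alpha_2)
  set.seed(4)
  b <- integer(10000)
  b[1] <- 1L
  for (t in 2:10000) b[t] <- switch_states(b[t - 1], p)
  expect_equal(mean(b == 1), 0.2 / 0.3, tolerance = 0.05)
  sym <- dcrws_params(alpha = c(0.5, 0.5))
  set.seed(5)
  b <- integer(10000)
  b[1] <- 2L
  for (t in 2:10000) b[t] <- switch_states(b[t - 1], sym)
  expect_equal(mean(b == 1), 0.5, tolerance = 0.05)
})

test_that("potential scale reduction factor behaves at its reference points", {
  set.seed(8)
  x <- stats::rnorm(1000)
  expect_equal(unname(gelman_rubin(list(x, x))), 1, tolerance = 1e-3)
  # independent chains from one distribution: near 1
  ch <- lapply(1:3, function(i) stats::rnorm(10000))
  expect_lt(unname(gelman_rubin(ch)), 1.01)
  # well-separated chains: far above the 1.1 convergence bar
  a <- stats::rnorm(500)
  b <- stats::rnorm(500, 10)
  r <- unname(gelman_rubin(list(a, b)))
  n <- 500
  expected <- sqrt(((n - 1) / n * mean(c(stats::var(a), stats::var(b))) +
                      stats::var(c(mean(a), mean(b)))) /
                     mean(c(stats::var(a), stats::var(b))))
  expect_equal(r, expected, tolerance = 1e-12)
  expect_gt(r, 3)
  expect_error(gelman_rubin(list(a)), "2 chains")
  expect_error(gelman_rubin(list(a[1:5], b[1:5])), "short")
})

test_that("MCMC bookkeeping enforces retained-sample invariants", {
  expect_error(mcmc_config(2, 1000, 990, 1), "100 retained")
  expect_error(mcmc_config(2, 1000, 1200, 1), "n_burnin")
  cfg <- mcmc_config(3, 5000, 2000, 10, seed = 2)
  expect_equal(cfg$n_retained, 3L * 300L)
})
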