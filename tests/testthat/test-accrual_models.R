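test_that("conjugate update arithmetic matches the stated form", {
  post <- fit_posterior(accrual_prior(n = 200, T = 24, P = 0.5),
                        interim_state(m = 1, t = 0.1, n = 200))
  expect_equal(post$shape, 101)
  expect_equal(post$scale, 12.1)

  flat <- fit_posterior(accrual_prior(n = 200, T = 1, P = 0),
                        interim_state(m = 50, t = 5, n = 200))
  expect_equal(flat$shape, 50)
  expect_equal(flat$scale, 5)
  expect_equal(posterior_mean_theta(flat), 5 / 49)

  expect_error(fit_posterior(accrual_prior(200, 1, 0),
                             interim_state(0, 2, 200)),
               "improper")
})

test_that("fit_posterior agrees with a brute-force gridded Bayes update", {
  set.seed(20)
  for (i in 1:20) {
    P <- runif(1, 0.1, 1); n <- sample(50:400, 1); T <- runif(1, 6, 48)
    m <- sample(5:min(200, n), 1); t <- runif(1, 1, 30)
    post <- fit_posterior(accrual_prior(n, T, P), interim_state(m, t, n))
    analytic <- posterior_mean_theta(post)
    oracle <- grid_posterior_mean(P, n, T, m, t)
    expect_lt(abs(analytic - oracle) / oracle, 1e-4)
  }
})

test_that("prior and data-dominated posteriors converge as accrual accumulates", {
  # with m = 5000 simulated observations the prior weight washes out
  set.seed(4)
  theta <- 0.1
  m <- 5000
  t <- sum(rexp(m, rate = 1 / theta))
  inf <- fit_posterior(accrual_prior(200, 24, 0.5), interim_state(m, t, m))
  flat <- fit_posterior(accrual_prior(200, 1, 0), interim_state(m, t, m))
  expect_lt(abs(posterior_mean_theta(inf) / posterior_mean_theta(flat) - 1),
            0.01)
})

test_that("completion-time prediction matches the closed-form expectation", {
  post <- structure(list(shape = 50, scale = 5, m = 50, t = 5),
                    class = "posterior_state")
  pred <- predict_completion_time(post, remaining = 150, draws = 50000,
                                  seed = 2)
  closed <- 5 + 150 * 5 / 49
  se <- stats::sd(pred$draws) / sqrt(length(pred$draws))
  expect_lt(abs(pred$mean - closed), 3 * se)
  expect_true(pred$interval[1] <= pred$point &&
                pred$point <= pred$interval[2])

  # degenerate: nothing left to recruit
  done <- predict_completion_time(post, remaining = 0)
  expect_equal(done$point, 5)
  expect_equal(done$interval, c(5, 5))

  # sqrt-law: quadrupling draws roughly halves the Monte-Carlo SE of the
  # point estimate
  pts <- function(d) vapply(1:40, function(s) {
    predict_completion_time(post, 150, draws = d, seed = 100 + s)$point
  }, numeric(1))
  ratio <- stats::sd(pts(8000)) / stats::sd(pts(2000))
  expect_lt(ratio, 0.8)
  expect_gt(ratio, 0.3)
})

test_that("accrual prediction matches E[1/theta] and is over-dispersed", {
  post <- structure(list(shape = 50, scale = 5, m = 50, t = 5),
                    class = "posterior_state")
  pred <- predict_accrual(post, horizon = 10, draws = 50000, seed = 6)
  extra <- pred$draws - 50
  se <- stats::sd(extra) / sqrt(length(extra))
  expect_lt(abs(mean(extra) - 5 * 50 / 5), 3 * se)  # (horizon-t)*shape/scale

  # variance exceeds that of a Poisson at the posterior-mean rate
  expect_gt(stats::var(extra), 1.2 * mean(extra))
  expect_error(predict_accrual(post, horizon = 5), "horizon")
})

test_that("P_late honours its limits, matches quadrature, and is monotone", {
  post <- structure(list(shape = 50, scale = 5, m = 50, t = 5),
                    class = "posterior_state")
  expect_equal(p_late(post, 150, T = 1e6, draws = 5000, seed = 1), 0)
  expect_equal(p_late(post, 150, T = 5, draws = 5000, seed = 1), 1)

  mc <- p_late(post, 150, T = 24, draws = 50000, seed = 9)
  oracle <- grid_p_late(50, 5, 5, 150, 24)
  se <- sqrt(oracle * (1 - oracle) / 50000)
  expect_lt(abs(mc - oracle), 3 * se + 1e-6)

  grid_T <- seq(6, 60, by = 3)
  ps <- vapply(grid_T, function(Tm) p_late(post, 150, Tm, draws = 20000,
                                           seed = 5), numeric(1))
  expect_true(all(diff(ps) <= 0))
  # non-decreasing in the number still to recruit
  pr <- vapply(c(50, 100, 150, 200), function(r) {
    p_late(post, r, 24, draws = 20000, seed = 5)
  }, numeric(1))
  expect_true(all(diff(pr) >= 0))
})

test_that("slow-accrual flag uses a strict boundary", {
  pred <- structure(list(kind = "completion_time", interval = c(18, 30)),
                    class = "prediction_result")
  expect_true(flag_slow_accrual(pred, 12))
  expect_false(flag_slow_accrual(pred, 24))
  expect_false(flag_slow_accrual(pred, 18))
})

test_that("the linear comparator reproduces the exact Poisson-rate interval", {
  lp <- linear_predict(interim_state(50, 5, 200), n = 200)
  expect_equal(lp$point, 20)
  done <- linear_predict(interim_state(200, 20, 200), n = 200)
  expect_equal(done$point, 20)
  expect_error(linear_predict(interim_state(0, 5, 200), 200), "inestimable")

  # brute-force inversion of the Poisson CDF at m = 50, t = 5
  m <- 50; t <- 5
  lo <- stats::uniroot(function(r) {
    stats::ppois(m - 1, r * t, lower.tail = FALSE) - 0.025
  }, c(1e-6, 100), tol = 1e-12)$root
  hi <- stats::uniroot(function(r) stats::ppois(m, r * t) - 0.025,
                       c(1e-6, 100), tol = 1e-12)$root
  expect_equal(lp$interval[2], 200 / lo, tolerance = 1e-6)
  expect_equal(lp$interval[1], 200 / hi, tolerance = 1e-6)
})

test_that("site-aware prediction reduces to the pooled model under simultaneous activation", {
  prior <- accrual_prior(n = 200, T = 24, P = 0.5)
  k <- 4
  interim <- interim_state(m = 60, t = 3, n = 200)
  site_pred <- predict_with_sites(prior, interim, site_schedule = rep(0, k),
                                  draws = 20000, seed = 42)
  # equivalent pooled model: exposure in site-months, t -> k*t, T -> k*T
  pooled_post <- fit_posterior(accrual_prior(200, k * 24, 0.5),
                               interim_state(60, k * 3, 200))
  expect_equal(site_pred$posterior$shape, pooled_post$shape)
  expect_equal(site_pred$posterior$scale, pooled_post$scale)
  pooled <- predict_completion_time(pooled_post, 140, draws = 20000,
                                    seed = 42)
  # identical RNG stream: calendar draws are the exact site-month mapping
  expect_equal(site_pred$draws, 3 + (pooled$draws - k * 3) / k,
               tolerance = 1e-12)

  expect_error(predict_with_sites(prior, interim, numeric(0)),
               "capacity")
})

test_that("knowing the future activation schedule shortens predictions under staggering", {
  # half of the sites activate at month 6; evaluated at month 3 the
  # site-aware model anticipates the capacity increase
  set.seed(15)
  wins <- 0L
  reps <- 60
  for (i in 1:reps) {
    sched <- c(0, 0, 6, 6)
    rate <- 2   # per site-month
    # simulate a trial path to month 3 with only the first two sites
    m3 <- rpois(1, 2 * rate * 3)
    if (m3 < 1) next
    interim <- interim_state(m = m3, t = 3, n = 100)
    prior <- accrual_prior(100, 12, P = 0.3)
    aware <- predict_with_sites(prior, interim, sched, draws = 3000,
                                seed = 1000 + i)
    naive <- predict_completion_time(fit_posterior(prior, interim),
                                     interim$remaining, draws = 3000,
                                     seed = 1000 + i)
    wins <- wins + (aware$point < naive$point)
  }
  expect_gt(wins / reps, 0.5)
})

test_that("interval width shrinks as accrual accumulates along a constant-rate path", {
  set.seed(8)
  reps <- 40
  widths <- matrix(NA_real_, reps, 3)
  for (i in 1:reps) {
    times <- cumsum(rexp(200, rate = 10))
    for (j in 1:3) {
      m <- c(50, 100, 150)[j]
      post <- fit_posterior(accrual_prior(200, 1, 0),
                            interim_state(m, times[m], 200))
      pred <- predict_completion_time(post, 200 - m, draws = 4000,
                                      seed = i * 10 + j)
      widths[i, j] <- diff(pred$interval)
    }
  }
  expect_true(all(diff(colMeans(widths)) < 0))
})
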