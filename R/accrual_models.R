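# Conjugate Bayesian accrual prediction. Waiting times between
# successive randomizations are modelled i.i.d. exponential with unknown
# mean theta (months/patient); the prior on theta is inverse-gamma with
# shape P*n and scale P*T, so the posterior after observing m patients in
# t months is inverse-gamma(P*n + m, P*T + t). P = 0 is the
# scale-invariant non-informative limit (posterior proper once m >= 1).

#' Informative accrual prior
#'
#' Encodes the planning assumptions: planned sample size `n`, anticipated
#' recruitment time `T`, and a prior confidence weight `P` in `[0, 1]`
#' interpreted as the fraction of the planned trial the prior is worth
#' (`P = 0` gives the non-informative prior).
#'
#' @param n planned sample size (patients), at least 1.
#' @param T anticipated recruitment time (months); required positive when
#'   `P > 0`.
#' @param P prior confidence weight in `[0, 1]`.
#' @return object of class `accrual_prior`.
#' @export
accrual_prior <- function(n, T, P) {
  stopifnot(n >= 1, P >= 0, P <= 1)
  if (P > 0) stopifnot(T > 0)
  structure(list(n = n, T = T, P = P), class = "accrual_prior")
}

#' Interim recruitment state
#'
#' @param m patients recruited so far.
#' @param t elapsed recruitment time (months).
#' @param n recruitment target.
#' @return list with `m`, `t`, `n`, `remaining = n - m`.
#' @export
interim_state <- function(m, t, n) {
  stopifnot(m >= 0, t >= 0, n >= 1, m <= n)
  list(m = m, t = t, n = n, remaining = n - m)
}

#' Conjugate posterior update for the mean waiting time
#'
#' @param prior an [accrual_prior()].
#' @param interim an [interim_state()] (or the list returned by
#'   [landmark_state()]).
#' @return object of class `posterior_state` with inverse-gamma `shape`
#'   (`P*n + m`) and `scale` (`P*T + t`), plus the interim `m` and `t`.
#' @export
fit_posterior <- function(prior, interim) {
  stopifnot(inherits(prior, "accrual_prior"))
  if (prior$P == 0 && interim$m == 0) {
    stop("posterior improper: non-informative prior requires m >= 1",
         call. = FALSE)
  }
  if (interim$t <= 0 && prior$P == 0) {
    stop("posterior improper: zero elapsed time with non-informative prior",
         call. = FALSE)
  }
  shape <- prior$P * prior$n + interim$m
  scale <- (if (prior$P > 0) prior$P * prior$T else 0) + interim$t
  structure(list(shape = shape, scale = scale,
                 m = interim$m, t = interim$t),
            class = "posterior_state")
}

#' @export
print.posterior_state <- function(x, ...) {
  cat(sprintf("<posterior_state> theta ~ inverse-gamma(shape = %.3f, scale = %.3f); m = %g, t = %.3f months\n",
              x$shape, x$scale, x$m, x$t))
  if (x$shape > 1) {
    cat(sprintf("  posterior mean waiting time: %.4f months/patient\n",
                x$scale / (x$shape - 1)))
  }
  invisible(x)
}

#' Posterior mean of the mean waiting time
#'
#' `scale / (shape - 1)`, defined for `shape > 1`.
#' @param post a `posterior_state`.
#' @return months per patient.
#' @export
posterior_mean_theta <- function(post) {
  stopifnot(inherits(post, "posterior_state"), post$shape > 1)
  post$scale / (post$shape - 1)
}

rinvgamma <- function(n, shape, scale) scale / stats::rgamma(n, shape = shape)

new_prediction <- function(kind, point, mean, interval, level, draws, seed,
                           t, p_late = NA_real_) {
  structure(list(kind = kind, point = point, mean = mean,
                 interval = interval, level = level, draws = draws,
                 seed = seed, t = t, p_late = p_late),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  unit <- if (x$kind == "completion_time") "months" else "patients"
  cat(sprintf("<prediction_result> %s: %.2f %s, %.0f%% interval (%.2f, %.2f)\n",
              x$kind, x$point, unit, 100 * x$level,
              x$interval[1], x$interval[2]))
  if (!is.na(x$p_late)) cat(sprintf("  P_late = %.3f\n", x$p_late))
  invisible(x)
}

#' Predict the trial completion time
#'
#' Monte-Carlo posterior predictive: draw the mean waiting time theta from
#' its inverse-gamma posterior, then the time to recruit the remaining
#' patients as a gamma sum of exponential waiting times with mean theta.
#' The predicted completion time is `t` plus that remaining time; the
#' point estimate is the predictive median and the interval equal-tailed.
#'
#' @param post a `posterior_state` from [fit_posterior()].
#' @param remaining number of patients still to recruit.
#' @param draws Monte-Carlo sample size (default 50,000).
#' @param seed integer seed for reproducibility.
#' @param level credibility level of the equal-tailed interval.
#' @return a `prediction_result` with `kind = "completion_time"`; the
#'   predictive draws are retained in `$draws`.
#' @export
predict_completion_time <- function(post, remaining, draws = 50000,
                                    seed = 1L, level = 0.95) {
  stopifnot(inherits(post, "posterior_state"), remaining >= 0, draws >= 1,
            level > 0, level < 1)
  if (remaining == 0) {
    return(new_prediction("completion_time", post$t, post$t,
                          c(post$t, post$t), level, rep(post$t, 0), seed,
                          post$t))
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  theta <- rinvgamma(draws, post$shape, post$scale)
  t_pred <- post$t + stats::rgamma(draws, shape = remaining, rate = 1) * theta
  alpha <- (1 - level) / 2
  qs <- stats::quantile(t_pred, c(alpha, 1 - alpha), names = FALSE)
  new_prediction("completion_time", stats::median(t_pred), mean(t_pred),
                 qs, level, t_pred, seed, post$t)
}

#' Predict accrual over a horizon
#'
#' Draw theta from the posterior, then the number of additional patients
#' recruited in `(t, horizon]` as Poisson with mean `(horizon - t)/theta`.
#'
#' @inheritParams predict_completion_time
#' @param horizon calendar time (months from the trial origin), must
#'   exceed the interim time `post$t`.
#' @return a `prediction_result` with `kind = "accrual_count"`; draws are
#'   total counts `m +` additional.
#' @export
predict_accrual <- function(post, horizon, draws = 50000, seed = 1L,
                            level = 0.95) {
  stopifnot(inherits(post, "posterior_state"), draws >= 1)
  if (horizon <= post$t) {
    stop("horizon must exceed the interim time t", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  theta <- rinvgamma(draws, post$shape, post$scale)
  extra <- stats::rpois(draws, (horizon - post$t) / theta)
  total <- post$m + extra
  alpha <- (1 - level) / 2
  qs <- stats::quantile(total, c(alpha, 1 - alpha), names = FALSE)
  new_prediction("accrual_count", stats::median(total), mean(total), qs,
                 level, total, seed, post$t)
}

#' Posterior probability of finishing late
#'
#' `P_late = Pr(T_pred > T | data)`: the fraction of posterior-predictive
#' completion-time draws exceeding the anticipated completion time `T`.
#'
#' @inheritParams predict_completion_time
#' @param T anticipated completion time (months).
#' @return probability in `[0, 1]`.
#' @export
p_late <- function(post, remaining, T, draws = 50000, seed = 1L) {
  stopifnot(T > 0, remaining >= 0)
  if (remaining == 0) return(as.numeric(post$t > T))
  pred <- predict_completion_time(post, remaining, draws = draws, seed = seed)
  mean(pred$draws > T)
}

#' Flag slow accrual
#'
#' A trial is flagged when its anticipated completion time `T` lies
#' strictly below the lower bound of the predicted completion-time
#' interval.
#'
#' @param pred a completion-time `prediction_result`.
#' @param T anticipated completion time (months).
#' @return logical.
#' @export
flag_slow_accrual <- function(pred, T) {
  stopifnot(inherits(pred, "prediction_result"),
            pred$kind == "completion_time")
  T < pred$interval[1]
}

#' Constant-rate frequentist comparator
#'
#' Estimates the accrual rate as `m / t` and extrapolates the total
#' recruitment time for `n` patients as `n * t / m`. The interval comes
#' from the exact (Garwood) Poisson confidence interval for the rate,
#' propagated to time: the lower rate bound gives the upper time bound.
#'
#' @param interim an [interim_state()] with `m >= 1` and `t > 0`.
#' @param n total number of patients to recruit.
#' @param level confidence level.
#' @return a `prediction_result` with `kind = "completion_time"` (no
#'   predictive draws; the interval is a confidence interval for the
#'   expected completion time).
#' @export
linear_predict <- function(interim, n, level = 0.95) {
  if (interim$m < 1) stop("rate inestimable: m = 0", call. = FALSE)
  stopifnot(interim$t > 0, n >= 1)
  m <- interim$m; t <- interim$t
  alpha <- 1 - level
  rate_lo <- stats::qgamma(alpha / 2, shape = m) / t
  rate_hi <- stats::qgamma(1 - alpha / 2, shape = m + 1) / t
  point <- n * t / m
  new_prediction("completion_time", point, point,
                 c(n / rate_hi, n / rate_lo), level, numeric(0), NA_integer_,
                 t)
}

#' Site-activation-aware completion-time prediction
#'
#' Re-expresses exposure in site-months: with activation times known, the
#' observed exposure is the summed active time of all sites, and theta
#' becomes the mean waiting time per site-month of exposure. The
#' posterior is inverse-gamma with `shape = P*n + m` and
#' `scale = P*S_planned + s_observed`, where `S_planned` is the planned
#' site-month exposure over the anticipated time `T`. Predictive draws of
#' the required future site-month exposure are mapped back to calendar
#' time through the (piecewise-linear) future activation schedule.
#'
#' @param prior an [accrual_prior()].
#' @param interim an [interim_state()].
#' @param site_schedule numeric vector of site activation times in months
#'   from the trial origin (one entry per site; 0 = active from the
#'   start).
#' @param draws,seed,level as in [predict_completion_time()].
#' @return a `prediction_result` with `kind = "completion_time"`.
#' @export
predict_with_sites <- function(prior, interim, site_schedule, draws = 50000,
                               seed = 1L, level = 0.95) {
  stopifnot(inherits(prior, "accrual_prior"))
  if (!length(site_schedule)) stop("no future capacity: empty site schedule",
                                   call. = FALSE)
  stopifnot(all(site_schedule >= 0))
  t <- interim$t; m <- interim$m
  s_obs <- sum(pmax(0, t - site_schedule))
  if (s_obs <= 0 && prior$P == 0) {
    stop("posterior improper: zero observed site-month exposure with non-informative prior",
         call. = FALSE)
  }
  s_planned <- if (prior$P > 0) sum(pmax(0, prior$T - site_schedule)) else 0
  shape <- prior$P * prior$n + m
  scale <- prior$P * s_planned + s_obs
  if (shape <= 0) stop("posterior improper", call. = FALSE)
  remaining <- interim$remaining
  if (remaining == 0) {
    return(new_prediction("completion_time", t, t, c(t, t), level,
                          numeric(0), seed, t))
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  theta <- scale / stats::rgamma(draws, shape = shape)
  w <- stats::rgamma(draws, shape = remaining, rate = 1) * theta

  # Cumulative site-month exposure beyond time t: piecewise linear with
  # slope = number of active sites, kinks at future activations.
  future <- sort(site_schedule[site_schedule > t])
  brk <- c(t, future)
  slope <- vapply(brk, function(b) sum(site_schedule <= b), numeric(1))
  exposure_at_brk <- cumsum(c(0, slope[-length(slope)] * diff(brk)))
  # segment holding each draw: largest breakpoint whose accumulated
  # exposure does not exceed w (ties resolve to the last, skipping
  # zero-slope segments)
  seg <- findInterval(w, exposure_at_brk)
  t_pred <- brk[seg] + (w - exposure_at_brk[seg]) / slope[seg]

  alpha <- (1 - level) / 2
  qs <- stats::quantile(t_pred, c(alpha, 1 - alpha), names = FALSE)
  res <- new_prediction("completion_time", stats::median(t_pred),
                        mean(t_pred), qs, level, t_pred, seed, t)
  res$posterior <- structure(list(shape = shape, scale = scale, m = m,
                                  t = t), class = "posterior_state")
  res
}
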