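# Multicenter recruitment simulator: per-site Poisson processes with
# staggered site activation, gamma cross-site rate heterogeneity, optional
# sinusoidal seasonality (exact thinning) and a discontinuation cutoff.

#' Configure the recruitment simulator
#'
#' Defaults describe a portfolio of moderately sized multicenter RCTs:
#' statistical sample sizes lognormal around 150 patients, recruitment
#' targets inflated 10% above them, a handful of sites per trial with
#' gamma-heterogeneous rates averaging 1.5 patients/site/month, site
#' activation staggered with exponential lags, and 15% of trials subject
#' to an early stopping cutoff that induces poor recruitment.
#'
#' @param n_trials number of trials in a simulated portfolio.
#' @param sample_size_meanlog,sample_size_sdlog lognormal parameters of
#'   the statistical sample size.
#' @param sample_size_min floor on the statistical sample size.
#' @param target_inflation multiplicative inflation of the recruitment
#'   target over the statistical sample size.
#' @param sites_mean mean number of sites per trial; the count is
#'   `1 + Poisson(sites_mean - 1)`.
#' @param rate_mean mean per-site recruitment rate (patients/site/month).
#' @param rate_shape gamma shape of the cross-site rate distribution;
#'   `Inf` fixes every site's rate at `rate_mean`.
#' @param activation_lag_mean mean months between trial start and the
#'   activation of each non-first site (exponential lags; first site
#'   activates at month 0).
#' @param seasonal_amplitude seasonal modulation amplitude in `[0, 1)`;
#'   the instantaneous rate is
#'   `base * (1 + A * cos(2 * pi * (calendar_month - phase) / 12))`.
#' @param seasonal_phase calendar month (0 = January) of the seasonal
#'   peak.
#' @param anticipated_multiplier anticipated recruitment time as a
#'   multiple of the rate-implied duration `target / sum(site rates)`.
#' @param cutoff_fraction fraction of trials subject to the
#'   discontinuation cutoff.
#' @param cutoff_multiplier cutoff as a multiple of the rate-implied
#'   duration; `NULL` disables the cutoff entirely.
#' @param origin_window `Date` vector of length 2; trial origins are
#'   drawn uniformly over it so calendar seasonality is identifiable.
#' @param seed integer seed governing the whole portfolio.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_trials = 300,
                              sample_size_meanlog = log(150),
                              sample_size_sdlog = 0.5,
                              sample_size_min = 20,
                              target_inflation = 1.1,
                              sites_mean = 4,
                              rate_mean = 1.5,
                              rate_shape = 2,
                              activation_lag_mean = 2,
                              seasonal_amplitude = 0,
                              seasonal_phase = 0,
                              anticipated_multiplier = 1,
                              cutoff_fraction = 0.15,
                              cutoff_multiplier = 0.6,
                              origin_window = as.Date(c("2015-01-01",
                                                        "2019-12-31")),
                              seed = 1L) {
  stopifnot(n_trials >= 1, sample_size_min >= 1, target_inflation >= 1,
            sites_mean >= 1, rate_mean > 0, rate_shape > 0,
            activation_lag_mean >= 0,
            seasonal_amplitude >= 0, seasonal_amplitude < 1,
            seasonal_phase >= 0, seasonal_phase < 12,
            anticipated_multiplier > 0,
            cutoff_fraction >= 0, cutoff_fraction <= 1,
            length(origin_window) == 2)
  structure(as.list(environment()), class = "simulation_config")
}

# Deterministic per-trial seed derived from (portfolio seed, trial index):
# a multiplicative hash folded into the 32-bit signed range.
trial_seed <- function(seed, index) {
  h <- (as.double(seed) * 1000003 + as.double(index) * 7919 + 12345) %%
    2147483647
  as.integer(h) + 1L
}

# Fractional calendar-month position (0 = Jan 1) of a Date.
calendar_month_frac <- function(date) {
  start <- as.Date(format(date, "%Y-01-01"))
  as.numeric(date - start) / 365.25 * 12
}

# Event times (months from site activation start) for one site observed up
# to `horizon` months. Seasonality by thinning a dominating homogeneous
# process at rate * (1 + A).
site_event_times <- function(rate, activation, horizon, amplitude, phase,
                             cal_anchor) {
  if (horizon <= activation) return(numeric(0))
  span <- horizon - activation
  rate_max <- rate * (1 + amplitude)
  n_cand <- stats::rpois(1, rate_max * span)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, activation, horizon))
  if (amplitude > 0) {
    cal <- (cal_anchor + cand) %% 12
    accept_p <- (1 + amplitude * cos(2 * pi * (cal - phase) / 12)) /
      (1 + amplitude)
    cand <- cand[stats::runif(n_cand) < accept_p]
  }
  cand
}

#' Simulate a single trial
#'
#' Each site recruits as a Poisson process (i.i.d. exponential waiting
#' times) at its drawn rate from its activation time; recruitment stops at
#' the recruitment target or at the discontinuation cutoff.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed for this trial.
#' @param trial_id identifier for the generated trial.
#' @param apply_cutoff whether the discontinuation cutoff applies to this
#'   trial.
#' @return list with elements `events` (tibble), `sites` (tibble),
#'   `trial` (one-row tibble) and `truth` (generating parameters,
#'   including continuous event times in months).
#' @export
simulate_trial <- function(config, seed, trial_id = "T1",
                           apply_cutoff = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  ss <- max(config$sample_size_min,
            round(stats::rlnorm(1, config$sample_size_meanlog,
                                config$sample_size_sdlog)))
  target <- ceiling(ss * config$target_inflation)
  n_sites <- 1L + stats::rpois(1, config$sites_mean - 1)
  rates <- if (is.infinite(config$rate_shape)) {
    rep(config$rate_mean, n_sites)
  } else {
    stats::rgamma(n_sites, shape = config$rate_shape,
                  rate = config$rate_shape / config$rate_mean)
  }
  activation <- c(0, if (n_sites > 1) {
    stats::rexp(n_sites - 1, rate = 1 / max(config$activation_lag_mean, 1e-9))
  })
  rate_implied <- target / sum(rates)
  if (rate_implied > 1e4) {
    stop("configuration implies expected duration > 10^4 months", call. = FALSE)
  }
  origin <- config$origin_window[1] +
    floor(stats::runif(1) *
            (as.numeric(diff(config$origin_window)) + 1))
  cal_anchor <- calendar_month_frac(origin)

  cutoff <- if (apply_cutoff && !is.null(config$cutoff_multiplier)) {
    config$cutoff_multiplier * rate_implied
  } else {
    Inf
  }

  # Simulate each site's Poisson process up to a working horizon; if the
  # target is not reached, extend over the next disjoint interval (process
  # increments are independent, so appending is exact).
  horizon <- min(cutoff, 1.5 * rate_implied + max(activation) + 6)
  times <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    times[[s]] <- site_event_times(rates[s], activation[s], horizon,
                                   config$seasonal_amplitude,
                                   config$seasonal_phase, cal_anchor)
  }
  while (sum(lengths(times)) < target && horizon < cutoff &&
         horizon <= 1.2e4) {
    new_horizon <- min(cutoff, horizon * 2)
    for (s in seq_len(n_sites)) {
      times[[s]] <- c(times[[s]],
                      site_event_times(rates[s], max(activation[s], horizon),
                                       new_horizon,
                                       config$seasonal_amplitude,
                                       config$seasonal_phase, cal_anchor))
    }
    horizon <- new_horizon
  }

  ev <- dplyr::arrange(
    tibble::tibble(
      site = rep(seq_len(n_sites), lengths(times)),
      time = unlist(times)
    ),
    .data$time
  )
  ev <- ev[ev$time <= cutoff, , drop = FALSE]
  ev <- utils::head(ev, target)
  achieved <- nrow(ev)

  event_dates <- origin + floor(ev$time * days_per_month())
  events <- tibble::tibble(
    trial_id = trial_id,
    site_id = paste0(trial_id, "_S", ev$site),
    date = event_dates
  )
  sites <- tibble::tibble(
    trial_id = trial_id,
    site_id = paste0(trial_id, "_S", seq_len(n_sites)),
    activation_date = origin + floor(activation * days_per_month()),
    closure_date = as.Date(NA),
    country = NA_character_,
    n_randomized = as.numeric(tabulate(ev$site, nbins = n_sites)),
    pi_institution = NA
  )

  cls <- classify_completion(
    list(recruitment_target = target, statistical_sample_size = ss),
    achieved
  )
  trial <- tibble::tibble(
    trial_id = trial_id,
    recruitment_target = target,
    statistical_sample_size = ss,
    anticipated_recruitment_time_months =
      config$anticipated_multiplier * rate_implied,
    n_sites = n_sites,
    completion_status = cls$status,
    discontinuation_reason = if (cls$status == "discontinued") {
      if (is.finite(cutoff)) "poor_recruitment" else cls$reason
    } else {
      "none"
    },
    medical_field = NA_character_, intervention_type = NA_character_,
    blinding = NA_character_, setting = NA_character_,
    funding = NA_character_
  )
  truth <- list(
    trial_id = trial_id, seed = seed, rates = rates,
    activation = activation, origin = origin,
    rate_implied_duration = rate_implied,
    cutoff_months = if (is.finite(cutoff)) cutoff else NA_real_,
    event_times = ev$time, event_sites = ev$site,
    true_time = if (achieved) max(ev$time) else NA_real_,
    achieved = achieved, target = target, discontinued = is.finite(cutoff)
  )
  list(events = events, sites = sites, trial = trial, truth = truth)
}

#' Simulate a portfolio of independent trials
#'
#' Trial seeds are derived deterministically from `config$seed` so the
#' portfolio reproduces exactly; a seeded subset of trials (fraction
#' `cutoff_fraction`) is stopped at the discontinuation cutoff so
#' completion classification is exercised.
#'
#' @param config a [simulation_config()].
#' @return list with `portfolio` (a [new_portfolio()]) and `truth`
#'   (per-trial generating parameters).
#' @export
simulate_portfolio <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_trials
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  n_cut <- round(config$cutoff_fraction * n)
  cut_idx <- if (n_cut > 0) sample.int(n, n_cut) else integer(0)

  ids <- sprintf("T%03d", seq_len(n))
  sims <- lapply(seq_len(n), function(i) {
    simulate_trial(config, seed = trial_seed(config$seed, i),
                   trial_id = ids[i], apply_cutoff = i %in% cut_idx)
  })
  portfolio <- new_portfolio(
    trials = dplyr::bind_rows(lapply(sims, `[[`, "trial")),
    events = dplyr::bind_rows(lapply(sims, `[[`, "events")),
    sites = dplyr::bind_rows(lapply(sims, `[[`, "sites"))
  )
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- ids
  list(portfolio = portfolio, truth = truth)
}

#' Write a portfolio to delimited text tables
#'
#' Emits `patients.csv`, `sites.csv` and `trials.csv` in the dialect read
#' by [read_portfolio()]; dates are serialized as ISO-8601.
#'
#' @param portfolio a [new_portfolio()] object.
#' @param directory output directory (created if absent).
#' @return (invisibly) the paths written.
#' @export
write_portfolio <- function(portfolio, directory) {
  stopifnot(inherits(portfolio, "portfolio"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) {
    if (inherits(x, "Date")) ifelse(is.na(x), "", format(x, "%Y-%m-%d"))
    else if (is.logical(x)) ifelse(is.na(x), "", ifelse(x, "true", "false"))
    else ifelse(is.na(x), "", as.character(x))
  }
  write_one <- function(df, cols, path) {
    out <- as.data.frame(lapply(df[cols], fmt), check.names = FALSE)
    names(out) <- cols
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    path
  }
  pat <- tibble::tibble(trial_id = portfolio$events$trial_id,
                        site_id = portfolio$events$site_id,
                        randomization_date = portfolio$events$date)
  if (nrow(pat) == 0) {
    pat <- tibble::tibble(trial_id = character(), site_id = character(),
                          randomization_date = as.Date(character()))
  }
  paths <- c(
    write_one(pat, patients_cols, file.path(directory, "patients.csv")),
    write_one(portfolio$trials, trials_cols,
              file.path(directory, "trials.csv"))
  )
  sites <- portfolio$sites
  if (is.null(sites)) {
    sites <- tibble::tibble(trial_id = character(), site_id = character(),
                            activation_date = as.Date(character()),
                            closure_date = as.Date(character()),
                            country = character(), n_randomized = numeric(),
                            pi_institution = logical())
  }
  paths <- c(paths, write_one(sites, sites_cols,
                              file.path(directory, "sites.csv")))
  invisible(paths)
}

#' Simulate a portfolio matched to an informative accrual prior
#'
#' Single-site trials whose mean waiting time is drawn from the
#' inverse-gamma prior implied by `(n, T, P)` — the generative model the
#' Bayesian accrual predictor assumes. Used for calibration experiments
#' (interval coverage, P_late calibration, model comparison under
#' prior-consistent conditions).
#'
#' @param n_trials number of trials.
#' @param n planned sample size per trial (also the recruitment target).
#' @param T_anticipated anticipated recruitment time in months.
#' @param P prior confidence weight in (0, 1].
#' @param seed integer seed.
#' @param origin common first-randomization date.
#' @return list with `portfolio`, and `truth` holding each trial's true
#'   mean waiting time and continuous event times.
#' @export
simulate_prior_consistent_portfolio <- function(n_trials, n = 200,
                                                T_anticipated = 24, P = 0.5,
                                                seed = 1L,
                                                origin = as.Date("2018-01-01")) {
  stopifnot(n_trials >= 1, n >= 2, T_anticipated > 0, P > 0)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  ids <- sprintf("C%04d", seq_len(n_trials))
  theta <- (P * T_anticipated) / stats::rgamma(n_trials, shape = P * n)
  events <- vector("list", n_trials)
  truth <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    times <- cumsum(stats::rexp(n, rate = 1 / theta[i]))
    events[[i]] <- tibble::tibble(
      trial_id = ids[i], site_id = paste0(ids[i], "_S1"),
      date = origin + floor(times * days_per_month())
    )
    truth[[i]] <- list(theta = theta[i], event_times = times,
                       true_time = times[n])
  }
  names(truth) <- ids
  trials <- tibble::tibble(
    trial_id = ids, recruitment_target = n, statistical_sample_size = n,
    anticipated_recruitment_time_months = T_anticipated, n_sites = 1,
    completion_status = "completed", discontinuation_reason = "none",
    medical_field = NA_character_, intervention_type = NA_character_,
    blinding = NA_character_, setting = NA_character_, funding = NA_character_
  )
  sites <- tibble::tibble(
    trial_id = ids, site_id = paste0(ids, "_S1"),
    activation_date = origin, closure_date = as.Date(NA),
    country = NA_character_, n_randomized = as.numeric(n),
    pi_institution = NA
  )
  list(portfolio = new_portfolio(trials, dplyr::bind_rows(events), sites),
       truth = truth)
}
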