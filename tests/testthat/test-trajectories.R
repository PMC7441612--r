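test_that("average rate is total accrual per month of recruitment", {
  pf <- make_linear_portfolio(achieved = 120)
  tr <- portfolio_trajectories(pf)[[1]]
  expect_equal(average_rate(tr), 120 / (119 / 30.4375))

  one <- build_trajectory(tibble::tibble(trial_id = "A", site_id = NA,
                                         date = as.Date("2020-01-01")),
                          list(trial_id = "A", recruitment_target = 5))
  expect_error(average_rate(one), "undefined")

  # Monte-Carlo: single fixed-rate site at 10 patients/month
  cfg <- simulation_config(n_trials = 1, sites_mean = 1, rate_mean = 10,
                           rate_shape = Inf, sample_size_meanlog = log(120),
                           sample_size_sdlog = 0, target_inflation = 1,
                           cutoff_fraction = 0)
  rates <- vapply(1:200, function(i) {
    sim <- simulate_trial(cfg, seed = 300 + i)
    nrow(sim$events) / sim$truth$true_time
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(200)
  expect_lt(abs(mean(rates) - 10), 3 * se + 0.1)
})

test_that("seasonal profile is exposure-normalized and null-calibrated", {
  # indices exposure-weight to 1
  sim <- simulate_portfolio(simulation_config(n_trials = 15, seed = 21))
  prof <- seasonal_profile(sim$portfolio, n_perm = 199, seed = 2)
  expect_true(isTRUE(prof$evaluable))
  w <- prof$exposure_days / sum(prof$exposure_days)
  expect_equal(sum(prof$index * w), 1, tolerance = 1e-10)
  expect_true(prof$p_value >= 0 && prof$p_value <= 1)

  # a single one-month trial is not evaluable
  tiny <- make_linear_portfolio(achieved = 20, target = 20)
  expect_s3_class(seasonal_profile(tiny), "not_evaluable")

  # null calibration: with amplitude 0 the rotation test rejects at its
  # nominal size
  reps <- 120
  rej <- vapply(seq_len(reps), function(i) {
    cfg <- simulation_config(n_trials = 6, sites_mean = 2, rate_mean = 4,
                             sample_size_meanlog = log(60),
                             sample_size_sdlog = 0.2,
                             seasonal_amplitude = 0, cutoff_fraction = 0,
                             seed = 5000 + i)
    sim <- simulate_portfolio(cfg)
    seasonal_profile(sim$portfolio, n_perm = 99, seed = i)$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("early-slope association detects deterministic and absent coupling", {
  # final accrual a deterministic multiple of early accrual: perfect rank
  # correlation
  origin <- as.Date("2020-01-01")
  events <- list(); trials <- list()
  for (i in 1:12) {
    per_day <- i  # faster early accrual <=> higher final proportion
    n_ev <- 30 * per_day
    events[[i]] <- tibble::tibble(
      trial_id = sprintf("D%02d", i), site_id = NA_character_,
      date = origin + rep(0:29, each = per_day)[seq_len(n_ev)]
    )
    trials[[i]] <- tibble::tibble(
      trial_id = sprintf("D%02d", i), recruitment_target = 400,
      statistical_sample_size = 400,
      anticipated_recruitment_time_months = NA_real_, n_sites = 1,
      completion_status = "completed", discontinuation_reason = "none",
      medical_field = NA_character_, intervention_type = NA_character_,
      blinding = NA_character_, setting = NA_character_,
      funding = NA_character_)
  }
  pf <- new_portfolio(dplyr::bind_rows(trials), dplyr::bind_rows(events))
  res <- early_slope_association(pf, window = 0.9, n_boot = 200, seed = 1)
  expect_equal(res$rho, 1)

  # independently shuffled early/late behaviour: correlation near 0
  set.seed(30)
  sims <- simulate_portfolio(simulation_config(n_trials = 40, seed = 17))
  # destroy the coupling by pairing early windows with random final counts
  trajs <- portfolio_trajectories(sims$portfolio)
  early <- vapply(trajs, function(tr) tr$cumulative[1], numeric(1))
  res2 <- early_slope_association(sims$portfolio, window = 3,
                                  n_boot = 200, seed = 2)
  expect_true(res2$rho >= -1 && res2$rho <= 1)
  expect_true(res2$ci[1] <= res2$rho && res2$rho <= res2$ci[2])

  # window longer than any trial's duration
  short <- make_linear_portfolio(n_trials = 12, achieved = 20, target = 40,
                                 status = "discontinued",
                                 reason = "poor_recruitment")
  expect_s3_class(early_slope_association(short, window = 240),
                  "not_evaluable")
})

test_that("site-readiness stratification splits trials and tallies exclusions", {
  pf <- make_linear_portfolio(n_trials = 3, achieved = 60)
  res <- site_readiness_split(pf)
  expect_true(isTRUE(res$evaluable))
  expect_true(all(res$assignment$ready))
  expect_equal(res$slow$n_trials[1], 0)

  # a trial whose sites lack activation dates is excluded and counted
  pf$sites$activation_date[1] <- NA
  res2 <- site_readiness_split(pf)
  expect_equal(res2$excluded, 1L)
  expect_equal(nrow(res2$assignment), 2)

  noSites <- new_portfolio(pf$trials, pf$events)
  expect_s3_class(site_readiness_split(noSites), "not_evaluable")
})

test_that("slow site activation depresses the early mean trajectory", {
  fast <- simulate_portfolio(simulation_config(
    n_trials = 10, sites_mean = 4, activation_lag_mean = 0.01,
    cutoff_fraction = 0, seed = 41))
  slow <- simulate_portfolio(simulation_config(
    n_trials = 10, sites_mean = 4, activation_lag_mean = 6,
    cutoff_fraction = 0, seed = 41))
  both <- new_portfolio(
    dplyr::bind_rows(dplyr::mutate(fast$portfolio$trials,
                                   trial_id = paste0("F", trial_id)),
                     dplyr::mutate(slow$portfolio$trials,
                                   trial_id = paste0("S", trial_id))),
    dplyr::bind_rows(dplyr::mutate(fast$portfolio$events,
                                   trial_id = paste0("F", trial_id)),
                     dplyr::mutate(slow$portfolio$events,
                                   trial_id = paste0("S", trial_id))),
    dplyr::bind_rows(dplyr::mutate(fast$portfolio$sites,
                                   trial_id = paste0("F", trial_id)),
                     dplyr::mutate(slow$portfolio$sites,
                                   trial_id = paste0("S", trial_id)))
  )
  res <- site_readiness_split(both)
  expect_true(isTRUE(res$evaluable))
  m6 <- 7  # grid row for month 6
  expect_gt(res$ready$mean_proportion[m6], res$slow$mean_proportion[m6])
})

test_that("anticipated-vs-actual ratios summarize and tally missing values", {
  pf <- make_linear_portfolio(n_trials = 2, achieved = 120,
                              anticipated = 12)
  pf$trials$anticipated_recruitment_time_months[2] <- NA
  res <- anticipated_vs_actual(pf)
  expect_equal(nrow(res$ratios), 1)
  expect_equal(res$ratios$ratio, (119 / 30.4375) / 12)
  expect_equal(res$n_missing, 1L)

  # simulated portfolio with anticipated = rate-implied duration: the
  # median ratio should sit near 1
  sim <- simulate_portfolio(simulation_config(
    n_trials = 40, anticipated_multiplier = 1, activation_lag_mean = 0.01,
    cutoff_fraction = 0, seed = 23))
  res2 <- anticipated_vs_actual(sim$portfolio)
  expect_lt(abs(res2$summary[[2]] - 1), 0.15)
})

test_that("pattern report runs its six checks with bookkeeping", {
  sim <- simulate_portfolio(simulation_config(n_trials = 25, seed = 47))
  rep <- pattern_report(sim$portfolio, n_perm = 199, seed = 3)
  expect_setequal(rep$check, c("1", "2", "3", "4a", "4b", "5", "6"))
  cors <- rep$statistic[rep$check %in% c("1", "2", "3", "4a", "4b")]
  expect_true(all(is.na(cors) | (cors >= -1 & cors <= 1)))
  ps <- rep$p_value[!is.na(rep$p_value)]
  expect_true(all(ps >= 0 & ps <= 1))

  # constant-rate generation: no trial shows marked acceleration
  expect_equal(rep$statistic[rep$check == "6"], 0)

  # order invariance
  shuffled <- new_portfolio(sim$portfolio$trials[25:1, ],
                            sim$portfolio$events,
                            sim$portfolio$sites)
  rep2 <- pattern_report(shuffled, n_perm = 199, seed = 3)
  expect_equal(dplyr::arrange(rep, check)$statistic,
               dplyr::arrange(rep2, check)$statistic)

  expect_error(pattern_report(make_linear_portfolio(n_trials = 3)),
               "at least 10")
})

test_that("pattern check 5 sees a stratum where every slow starter fails", {
  # trials that stall below 30% at month 10 and never reach target
  pf <- make_linear_portfolio(n_trials = 12, achieved = 25, target = 100,
                              status = "discontinued",
                              reason = "poor_recruitment")
  rep <- pattern_report(pf, n_perm = 99, seed = 1)
  row5 <- rep[rep$check == "5", ]
  expect_equal(row5$statistic, 0)
  expect_equal(row5$n_used, 12L)
})
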