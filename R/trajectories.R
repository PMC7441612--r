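# Descriptive recruitment-pattern analyses: averaged rates, seasonal
# profiles, early-slope associations, site-readiness stratification,
# anticipated-vs-actual comparison, and the six classical accrual-pattern
# checks (first-months speed, early-late correlation, acceleration ratio,
# the 30%-at-10-months rule, marked acceleration).

not_evaluable <- function(reason) {
  structure(list(evaluable = FALSE, reason = reason), class = "not_evaluable")
}

#' @export
print.not_evaluable <- function(x, ...) {
  cat("not evaluable:", x$reason, "\n")
  invisible(x)
}

#' Overall averaged recruitment rate
#'
#' Total number of recruited patients divided by the recruitment time in
#' months.
#'
#' @param traj a [build_trajectory()] object.
#' @return patients per month.
#' @export
average_rate <- function(traj) {
  stopifnot(inherits(traj, "recruitment_trajectory"))
  if (traj$recruitment_time <= 0) {
    stop("average rate undefined: recruitment time is zero", call. = FALSE)
  }
  max(traj$cumulative) / traj$recruitment_time
}

# Per-trial calendar-month tallies: observed events and exposure days in
# each calendar month (0 = January) over the trial's recruitment window.
trial_calendar_profile <- function(traj) {
  dates <- traj$origin_date + rep(traj$offsets, diff(c(0L, traj$cumulative)))
  obs <- tabulate(as.integer(format(dates, "%m")), nbins = 12)
  window <- seq(traj$origin_date,
                traj$origin_date + max(traj$offsets), by = "day")
  expo <- tabulate(as.integer(format(window, "%m")), nbins = 12)
  list(obs = obs, expo = as.numeric(expo))
}

seasonal_chisq <- function(obs, expo) {
  expected <- sum(obs) * expo / sum(expo)
  keep <- expected > 0
  sum((obs[keep] - expected[keep])^2 / expected[keep])
}

#' Seasonal recruitment profile
#'
#' Calendar-month recruitment indices for a portfolio: the index for
#' month `c` is the observed share of accrual in that month divided by
#' the share expected under uniform recruitment given each trial's active
#' window (exposure-weighted indices average to 1). Significance by a
#' permutation test that rotates each trial's calendar anchor uniformly
#' over the 12 month offsets.
#'
#' @param portfolio a [new_portfolio()] object.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation draw.
#' @return list with `index` (length 12, January first), `observed`,
#'   `exposure_days`, `p_value`, `n_trials`; or a `not_evaluable` object
#'   when total exposure is under 12 months.
#' @export
seasonal_profile <- function(portfolio, n_perm = 1000, seed = 1L) {
  trajs <- portfolio_trajectories(portfolio)
  if (!length(trajs)) return(not_evaluable("no trials with events"))
  profs <- lapply(trajs, trial_calendar_profile)
  expo_total <- Reduce(`+`, lapply(profs, `[[`, "expo"))
  if (sum(expo_total) < 12 * days_per_month()) {
    return(not_evaluable("under 12 months of total recruitment exposure"))
  }
  obs_total <- Reduce(`+`, lapply(profs, `[[`, "obs"))
  n_total <- sum(obs_total)
  index <- (obs_total / n_total) / (expo_total / sum(expo_total))
  stat_obs <- seasonal_chisq(obs_total, expo_total)

  rotate <- function(v, k) if (k == 0) v else c(v[-seq_len(k)], v[seq_len(k)])
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    ks <- sample.int(12, length(profs), replace = TRUE) - 1L
    ob <- numeric(12); ex <- numeric(12)
    for (i in seq_along(profs)) {
      ob <- ob + rotate(profs[[i]]$obs, ks[i])
      ex <- ex + rotate(profs[[i]]$expo, ks[i])
    }
    if (seasonal_chisq(ob, ex) >= stat_obs) exceed <- exceed + 1L
  }
  list(index = as.numeric(index), observed = as.numeric(obs_total),
       exposure_days = expo_total,
       p_value = (exceed + 1) / (n_perm + 1),
       n_trials = length(profs), evaluable = TRUE)
}

# Fraction of target recruited by `months` after origin (1 if ended
# earlier having recruited everything it ever will).
fraction_at_month <- function(traj, months) {
  cut_days <- months * days_per_month()
  before <- traj$offsets < cut_days
  m <- if (any(before)) traj$cumulative[max(which(before))] else 0L
  m / traj$target
}

spearman_perm_p <- function(x, y, n_perm, seed) {
  obs <- abs(stats::cor(x, y, method = "spearman"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  exceed <- sum(vapply(seq_len(n_perm), function(b) {
    abs(stats::cor(x, sample(y), method = "spearman")) >= obs - 1e-12
  }, logical(1)))
  (exceed + 1) / (n_perm + 1)
}

#' Association between early recruitment slope and recruitment success
#'
#' Spearman rank correlation between the fraction of target recruited
#' within the first `window` months and the final proportion of target
#' achieved, with a seeded bootstrap percentile interval, plus the
#' proportion of trials achieving more than 90% of target by tercile of
#' early slope.
#'
#' @param portfolio a [new_portfolio()] object.
#' @param window early window in months (default 3).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with `rho`, `ci` (percentile 95%), `terciles` (tibble),
#'   `n_trials`; `not_evaluable` when fewer than 10 usable trials.
#' @export
early_slope_association <- function(portfolio, window = 3, n_boot = 1000,
                                    seed = 1L) {
  trajs <- portfolio_trajectories(portfolio)
  usable <- Filter(function(tr) {
    tr$recruitment_time >= window || max(tr$cumulative) >= tr$target
  }, trajs)
  if (length(usable) < 10) {
    return(not_evaluable("fewer than 10 trials with the required follow-up"))
  }
  early <- vapply(usable, fraction_at_month, numeric(1), months = window)
  final <- vapply(usable, function(tr) max(tr$cumulative) / tr$target,
                  numeric(1))
  rho <- stats::cor(early, final, method = "spearman")

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(early), replace = TRUE)
    suppressWarnings(stats::cor(early[i], final[i], method = "spearman"))
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, na.rm = TRUE)

  terc <- dplyr::mutate(
    tibble::tibble(early = early, success = final > 0.90),
    tercile = dplyr::ntile(early, 3)
  )
  terciles <- dplyr::summarise(dplyr::group_by(terc, .data$tercile),
                               n = dplyr::n(),
                               prop_success = mean(.data$success),
                               .groups = "drop")
  list(rho = rho, ci = ci, terciles = terciles, n_trials = length(usable),
       evaluable = TRUE)
}

#' Stratify mean trajectories by site readiness
#'
#' Trials are split by whether more than `readiness_fraction` of their
#' sites activated within `window` months of the trial origin; the mean
#' proportion-of-target trajectory on a common monthly grid is returned
#' for each stratum.
#'
#' @param portfolio a [new_portfolio()] with site activation dates.
#' @param readiness_fraction threshold fraction of sites (default 0.80).
#' @param window readiness window in months (default 1).
#' @return list with tibbles `ready` and `slow` (columns `month`,
#'   `mean_proportion`, `n_trials`), the per-trial assignment, and the
#'   count of trials excluded for missing site data.
#' @export
site_readiness_split <- function(portfolio, readiness_fraction = 0.80,
                                 window = 1) {
  if (is.null(portfolio$sites) || nrow(portfolio$sites) == 0) {
    return(not_evaluable("no site records in portfolio"))
  }
  trajs <- portfolio_trajectories(portfolio)
  sites <- split(portfolio$sites, portfolio$sites$trial_id)
  assign_rows <- list(); excluded <- 0L
  for (id in names(trajs)) {
    st <- sites[[id]]
    if (is.null(st) || any(is.na(st$activation_date))) {
      excluded <- excluded + 1L
      next
    }
    frac <- mean(st$activation_date <=
                   trajs[[id]]$origin_date + window * days_per_month())
    assign_rows[[id]] <- tibble::tibble(trial_id = id,
                                        ready = frac > readiness_fraction)
  }
  if (!length(assign_rows)) {
    return(not_evaluable("no trial has complete site activation dates"))
  }
  assignment <- dplyr::bind_rows(assign_rows)

  grid_max <- ceiling(max(vapply(trajs[assignment$trial_id],
                                 `[[`, numeric(1), "recruitment_time")))
  grid <- 0:grid_max
  mean_traj <- function(ids) {
    if (!length(ids)) return(tibble::tibble(month = grid,
                                            mean_proportion = NA_real_,
                                            n_trials = 0L))
    mat <- vapply(ids, function(id) {
      vapply(grid, fraction_at_month, numeric(1), traj = trajs[[id]])
    }, numeric(length(grid)))
    tibble::tibble(month = grid,
                   mean_proportion = rowMeans(matrix(mat, nrow = length(grid))),
                   n_trials = length(ids))
  }
  list(ready = mean_traj(assignment$trial_id[assignment$ready]),
       slow = mean_traj(assignment$trial_id[!assignment$ready]),
       assignment = assignment, excluded = excluded, evaluable = TRUE)
}

#' Actual versus anticipated recruitment time
#'
#' @param portfolio a [new_portfolio()] object.
#' @return list with per-trial `ratios` (actual/anticipated), summary
#'   quartiles, and the count of trials excluded for missing anticipated
#'   time.
#' @export
anticipated_vs_actual <- function(portfolio) {
  trajs <- portfolio_trajectories(portfolio)
  rows <- list(); n_missing <- 0L
  for (i in seq_len(nrow(portfolio$trials))) {
    tr <- portfolio$trials[i, ]
    traj <- trajs[[tr$trial_id]]
    if (is.null(traj)) next
    ant <- tr$anticipated_recruitment_time_months
    if (is.na(ant) || ant <= 0) {
      n_missing <- n_missing + 1L
      next
    }
    rows[[tr$trial_id]] <- tibble::tibble(
      trial_id = tr$trial_id, actual = traj$recruitment_time,
      anticipated = ant, ratio = traj$recruitment_time / ant
    )
  }
  if (!length(rows)) {
    return(list(ratios = tibble::tibble(), summary = NULL,
                n_missing = n_missing, evaluable = TRUE))
  }
  ratios <- dplyr::bind_rows(rows)
  list(ratios = ratios,
       summary = stats::quantile(ratios$ratio, c(0.25, 0.5, 0.75)),
       n_missing = n_missing, evaluable = TRUE)
}

# Per-trial monthly summary used by pattern_report.
trial_pattern_stats <- function(traj) {
  mc <- aggregate_monthly(traj)$count
  total <- max(traj$cumulative)
  dur <- traj$recruitment_time
  pad <- function(k) if (length(mc) >= k) mc[k] else 0L
  list(
    total = total, target = traj$target, duration = dur,
    attained = total >= traj$target,
    final_prop = total / traj$target,
    speed3 = sum(mc[seq_len(min(3, length(mc)))]) / 3,
    first2 = sum(mc[seq_len(min(2, length(mc)))]),
    month1 = pad(1), month2 = pad(2),
    subsequent_rate = if (dur > 2) (total - sum(mc[seq_len(min(2, length(mc)))])) /
      (dur - 2) else NA_real_,
    frac_at_10 = fraction_at_month(traj, 10),
    counts = mc
  )
}

marked_acceleration <- function(counts) {
  if (length(counts) < 13) return(FALSE)
  months <- seq_along(counts)
  fit <- stats::lm(counts ~ months)
  sl <- summary(fit)$coefficients
  slope_sig <- sl["months", "Estimate"] > 0 &&
    sl["months", "Estimate"] > 2 * sl["months", "Std. Error"]
  late_up <- mean(counts[13:length(counts)]) >
    1.5 * mean(counts[1:3])
  slope_sig && late_up
}

pattern_row <- function(check, label, statistic, p_value = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        n_used = NA_integer_, note = NA_character_) {
  tibble::tibble(check = check, label = label, statistic = statistic,
                 p_value = p_value, ci_lower = ci_lower,
                 ci_upper = ci_upper, n_used = as.integer(n_used),
                 note = note)
}

#' Classical accrual-pattern report
#'
#' Six checks on a portfolio of classified trials: (1) rank correlation
#' of first-3-month accrual speed with target attainment; (2) rank
#' correlation of months-1-2 accrual with the subsequent per-month
#' accrual rate; (3) rank correlation of the month-2/month-1 acceleration
#' ratio with eventual accrual; (4) rank correlations of the 2-month
#' count with final absolute accrual (4a) and with final proportion of
#' target (4b); (5) among trials below 30% of target at month 10, the
#' proportion eventually reaching target; (6) the number of trials with
#' marked acceleration of accrual over time (positive monthly-count slope
#' exceeding twice its standard error and a month-13+ mean rate more than
#' 1.5 times the months-1-3 mean).
#'
#' @param portfolio a [new_portfolio()] object with at least 10 trials.
#' @param n_perm permutations for correlation p-values.
#' @param seed integer seed.
#' @return tibble with one row per check (checks on empty strata carry a
#'   `not evaluable` note and `NA` statistic).
#' @export
pattern_report <- function(portfolio, n_perm = 1000, seed = 1L) {
  trajs <- portfolio_trajectories(portfolio)
  if (length(trajs) < 10) {
    stop("pattern report requires at least 10 classified trials",
         call. = FALSE)
  }
  st <- lapply(trajs, trial_pattern_stats)
  g <- function(field) vapply(st, function(x) as.numeric(x[[field]]),
                              numeric(1))
  cor_row <- function(check, label, x, y, seed_off) {
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3 || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
      return(pattern_row(check, label, NA_real_, n_used = sum(keep),
                         note = "not evaluable"))
    }
    rho <- stats::cor(x[keep], y[keep], method = "spearman")
    p <- spearman_perm_p(x[keep], y[keep], n_perm, seed + seed_off)
    pattern_row(check, label, rho, p_value = p, n_used = sum(keep))
  }

  rows <- list(
    cor_row("1", "3-month speed vs target attainment",
            g("speed3"), g("attained"), 101L),
    cor_row("2", "months 1-2 accrual vs subsequent monthly rate",
            g("first2"), g("subsequent_rate"), 102L)
  )

  m1 <- g("month1"); m2 <- g("month2")
  ratio <- ifelse(m1 > 0, m2 / m1, NA_real_)
  r3 <- cor_row("3", "acceleration ratio (month 2 / month 1) vs eventual accrual",
                ratio, g("total"), 103L)
  r3$note <- ifelse(is.na(r3$note),
                    sprintf("%d trial(s) excluded (no month-1 accrual)",
                            sum(m1 == 0)),
                    r3$note)
  rows <- c(rows, list(
    r3,
    cor_row("4a", "2-month count vs final absolute accrual",
            g("first2"), g("total"), 104L),
    cor_row("4b", "2-month count vs final proportion of target",
            g("first2"), g("final_prop"), 105L)
  ))

  low10 <- g("frac_at_10") < 0.30
  if (any(low10)) {
    att <- g("attained")[low10]
    bt <- stats::binom.test(sum(att), length(att))
    rows <- c(rows, list(pattern_row(
      "5", "proportion reaching target among trials < 30% at month 10",
      mean(att), ci_lower = bt$conf.int[1], ci_upper = bt$conf.int[2],
      n_used = sum(low10))))
  } else {
    rows <- c(rows, list(pattern_row(
      "5", "proportion reaching target among trials < 30% at month 10",
      NA_real_, n_used = 0L, note = "not evaluable")))
  }

  flags <- vapply(st, function(x) marked_acceleration(x$counts), logical(1))
  rows <- c(rows, list(pattern_row(
    "6", "trials with marked acceleration of accrual", sum(flags),
    n_used = length(flags))))

  dplyr::bind_rows(rows)
}
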