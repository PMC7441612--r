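# Landmark validation engine: run the Bayesian and constant-rate models
# over every (trial, landmark) pair, score percent relative bias and
# interval coverage against the realized recruitment time, compare models,
# and check P_late calibration.

#' Percent relative bias
#'
#' `%Rbias = |Predicted - True| / True * 100`.
#'
#' @param predicted predicted value.
#' @param true_value realized value; must be positive.
#' @return non-negative percent.
#' @export
percent_rbias <- function(predicted, true_value) {
  if (any(true_value <= 0)) stop("true_value must be positive", call. = FALSE)
  abs(predicted - true_value) / true_value * 100
}

landmark_label <- function(lm) {
  if (lm$kind == "time_based") sprintf("month %g", lm$value)
  else sprintf("%g%% accrual", 100 * lm$value)
}

#' Validate accrual predictions at interim landmarks
#'
#' For every trial, landmark and model, extracts the interim state,
#' predicts the time to reach the trial's achieved final count, and
#' scores the prediction against the realized recruitment time (time to
#' the last randomized patient): percent relative bias, whether the
#' interval covers the realized time, and — when an anticipated
#' recruitment time is recorded — `P_late` against it.
#'
#' The primary run keeps trials that completed or were discontinued for
#' poor recruitment (including the below-threshold "unknown reason"
#' category); trials stopped for other reasons are scored only when
#' `include_other_reasons = TRUE`, labelled as a sensitivity run.
#' Landmarks a trial never reaches, or at which recruitment had already
#' finished, are skipped and tallied.
#'
#' @param portfolio a [new_portfolio()] object.
#' @param models subset of `"bayes_informative"`, `"bayes_noninformative"`,
#'   `"bayes_sites"`, `"linear"`.
#' @param landmarks list of [landmark()]s (default [default_landmarks()]).
#' @param draws Monte-Carlo draws per Bayesian prediction.
#' @param seed integer seed; per-prediction seeds are derived from it.
#' @param prior_weight prior confidence weight `P` for the informative
#'   models.
#' @param level interval level.
#' @param include_other_reasons include trials stopped for reasons other
#'   than poor recruitment as sensitivity rows.
#' @return tibble of validation rows (attribute `"skipped"` records the
#'   tally of skipped combinations).
#' @export
landmark_validate <- function(portfolio,
                              models = c("bayes_informative",
                                         "bayes_noninformative", "linear"),
                              landmarks = default_landmarks(),
                              draws = 50000, seed = 1L, prior_weight = 0.5,
                              level = 0.95, include_other_reasons = FALSE) {
  models <- match.arg(models, c("bayes_informative", "bayes_noninformative",
                                "bayes_sites", "linear"),
                      several.ok = TRUE)
  trajs <- portfolio_trajectories(portfolio)
  sites <- if (!is.null(portfolio$sites)) {
    split(portfolio$sites, portfolio$sites$trial_id)
  }
  all_models <- c("bayes_informative", "bayes_noninformative",
                  "bayes_sites", "linear")
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(portfolio$trials))) {
    tr <- portfolio$trials[i, ]
    traj <- trajs[[tr$trial_id]]
    if (is.null(traj)) next
    poor <- !is.na(tr$discontinuation_reason) &&
      tr$discontinuation_reason %in% c("poor_recruitment", "unknown")
    primary <- identical(tr$completion_status, "completed") || poor
    if (!primary && !include_other_reasons) next
    run <- if (primary) "primary" else "sensitivity"

    achieved <- max(traj$cumulative)
    true_time <- traj$recruitment_time
    anticipated <- tr$anticipated_recruitment_time_months
    if (achieved < 2 || true_time <= 0) next

    for (lm in landmarks) {
      interim <- tryCatch(landmark_state(traj, lm), error = function(e) NULL)
      if (is.null(interim)) { skipped <- skipped + 1L; next }
      if (interim$t <= 0 || interim$t >= true_time ||
          interim$m >= achieved) {
        skipped <- skipped + 1L; next
      }
      remaining <- achieved - interim$m
      for (model in models) {
        # seed derived from stable coordinates so a row's draws do not
        # depend on which other trials or models are in the run
        lm_idx <- which(vapply(landmarks, identical, logical(1), lm))[1]
        pseed <- as.integer((as.double(seed) * 1009 + i * 524287 +
                               lm_idx * 8191 +
                               match(model, all_models) * 127) %%
                              2147483647)
        pred <- switch(
          model,
          linear = {
            if (interim$m < 1) NULL
            else linear_predict(interim, n = achieved, level = level)
          },
          bayes_noninformative = {
            if (interim$m < 1) NULL
            else predict_completion_time(
              fit_posterior(accrual_prior(tr$recruitment_target, 1, 0),
                            interim),
              remaining, draws = draws, seed = pseed, level = level)
          },
          bayes_informative = {
            if (is.na(anticipated) || anticipated <= 0) NULL
            else predict_completion_time(
              fit_posterior(accrual_prior(tr$recruitment_target,
                                          anticipated, prior_weight),
                            interim),
              remaining, draws = draws, seed = pseed, level = level)
          },
          bayes_sites = {
            st <- sites[[tr$trial_id]]
            if (is.null(st) || any(is.na(st$activation_date)) ||
                is.na(anticipated) || anticipated <= 0) NULL
            else {
              sched <- pmax(0, as.numeric(st$activation_date -
                                            traj$origin_date)) /
                days_per_month()
              prior <- accrual_prior(tr$recruitment_target, anticipated,
                                     prior_weight)
              im <- interim
              im$remaining <- remaining
              predict_with_sites(prior, im, sched, draws = draws,
                                 seed = pseed, level = level)
            }
          }
        )
        if (is.null(pred)) { skipped <- skipped + 1L; next }
        pl <- if (!is.na(anticipated) && anticipated > 0 &&
                  length(pred$draws)) {
          mean(pred$draws > anticipated)
        } else {
          NA_real_
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          trial_id = tr$trial_id,
          landmark_kind = lm$kind,
          landmark_value = lm$value,
          landmark = landmark_label(lm),
          model = model,
          run = run,
          m = interim$m, t = interim$t,
          predicted = pred$point,
          true_value = true_time,
          rbias_pct = percent_rbias(pred$point, true_time),
          covered = true_time >= pred$interval[1] &
            true_time <= pred$interval[2],
          p_late = pl,
          late = if (!is.na(anticipated) && anticipated > 0) {
            true_time > anticipated
          } else {
            NA
          },
          t_pred_point = pred$point
        )
      }
    }
  }
  if (!length(rows)) stop("empty validation: no evaluable (trial, landmark) pairs",
                          call. = FALSE)
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Compare two models' percent relative bias across landmarks
#'
#' Restricted to (trial, landmark) pairs scored by both models; reports
#' per landmark the median and interquartile %Rbias of each model, the
#' median paired difference, and the fraction of trials where
#' `model_a`'s %Rbias is lower.
#'
#' @param rows output of [landmark_validate()].
#' @param model_a,model_b the two models (defaults: informative Bayesian
#'   vs linear).
#' @return tibble with one row per landmark.
#' @export
compare_models <- function(rows, model_a = "bayes_informative",
                           model_b = "linear") {
  a <- rows[rows$model == model_a, ]
  b <- rows[rows$model == model_b, ]
  merged <- dplyr::inner_join(
    a[, c("trial_id", "landmark", "landmark_kind", "landmark_value",
          "rbias_pct")],
    b[, c("trial_id", "landmark", "rbias_pct")],
    by = c("trial_id", "landmark"), suffix = c("_a", "_b")
  )
  if (!nrow(merged)) stop("no common (trial, landmark) pairs", call. = FALSE)
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(merged, .data$landmark, .data$landmark_kind,
                      .data$landmark_value),
      n = dplyr::n(),
      median_rbias_a = stats::median(.data$rbias_pct_a),
      iqr_rbias_a = stats::IQR(.data$rbias_pct_a),
      median_rbias_b = stats::median(.data$rbias_pct_b),
      iqr_rbias_b = stats::IQR(.data$rbias_pct_b),
      median_paired_diff = stats::median(.data$rbias_pct_a -
                                           .data$rbias_pct_b),
      frac_a_lower = mean(.data$rbias_pct_a < .data$rbias_pct_b),
      .groups = "drop"
    ),
    .data$landmark_kind, .data$landmark_value
  )
}

#' Empirical interval coverage by model and landmark
#'
#' @param rows output of [landmark_validate()].
#' @return tibble with the covered fraction and an exact binomial 95%
#'   confidence interval per (model, landmark).
#' @export
coverage_summary <- function(rows) {
  rows <- rows[!is.na(rows$covered), ]
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(rows, .data$model, .data$landmark,
                      .data$landmark_kind, .data$landmark_value),
      n = dplyr::n(),
      n_covered = sum(.data$covered),
      coverage = mean(.data$covered),
      ci_lower = stats::binom.test(sum(.data$covered),
                                   dplyr::n())$conf.int[1],
      ci_upper = stats::binom.test(sum(.data$covered),
                                   dplyr::n())$conf.int[2],
      .groups = "drop"
    ),
    .data$model, .data$landmark_kind, .data$landmark_value
  )
}

#' P_late calibration table
#'
#' Bins validation rows by predicted `P_late` and compares the bin-mean
#' prediction with the empirical fraction of trials that finished later
#' than anticipated. Bins with fewer than 10 rows are flagged unstable.
#'
#' @param rows output of [landmark_validate()] (needs `p_late` and the
#'   realized `late` indicator, i.e. anticipated times recorded).
#' @param breaks bin boundaries on `[0, 1]`.
#' @return tibble per bin, or `not_evaluable` when no row has both
#'   quantities.
#' @export
p_late_calibration <- function(rows, breaks = seq(0, 1, by = 0.1)) {
  rows <- rows[!is.na(rows$p_late) & !is.na(rows$late), ]
  if (!nrow(rows)) {
    return(not_evaluable("no rows with both P_late and an anticipated time"))
  }
  rows$bin <- cut(rows$p_late, breaks = breaks, include.lowest = TRUE)
  out <- dplyr::summarise(
    dplyr::group_by(rows, .data$bin, .drop = FALSE),
    n = dplyr::n(),
    mean_p_late = mean(.data$p_late),
    frac_late = mean(.data$late),
    .groups = "drop"
  )
  out$unstable <- out$n < 10
  out
}

#' Interval-coverage and P_late calibration experiment
#'
#' Simulates trials from the generative model the Bayesian predictor
#' assumes — i.i.d. exponential waiting times whose mean is drawn from
#' the informative inverse-gamma prior implied by `(n, T, P)` — then, at
#' the first time each trial reaches `landmark_fraction` of its target,
#' fits the conjugate posterior and computes the equal-tailed
#' posterior-predictive interval for the total recruitment time and
#' `P_late` against `T`. Everything is done in continuous time.
#'
#' @param n_trials number of simulated trials.
#' @param n planned sample size (= recruitment target).
#' @param T anticipated recruitment time (months).
#' @param P prior confidence weight.
#' @param landmark_fraction accrual fraction defining the interim
#'   landmark (default 0.5).
#' @param draws posterior-predictive draws per trial (default 50,000).
#' @param level interval level (default 0.95).
#' @param seed integer seed.
#' @return list with per-trial tibble `trials` (columns `theta`,
#'   `t_interim`, `true_time`, `lower`, `upper`, `covered`, `p_late`,
#'   `late`) and the scalar `coverage` (fraction covered).
#' @export
calibration_experiment <- function(n_trials = 1000, n = 200, T = 24,
                                   P = 0.5, landmark_fraction = 0.5,
                                   draws = 50000, level = 0.95, seed = 1L) {
  stopifnot(n_trials >= 1, landmark_fraction > 0, landmark_fraction < 1)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  theta <- (P * T) / stats::rgamma(n_trials, shape = P * n)
  m_lm <- ceiling(landmark_fraction * n)
  prior <- accrual_prior(n, T, P)
  pred_seeds <- sample.int(2147483646L, n_trials)

  res <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    times <- cumsum(stats::rexp(n, rate = 1 / theta[i]))
    t_int <- times[m_lm]
    post <- fit_posterior(prior, interim_state(m_lm, t_int, n))
    pred <- predict_completion_time(post, remaining = n - m_lm,
                                    draws = draws, seed = pred_seeds[i],
                                    level = level)
    res[[i]] <- tibble::tibble(
      theta = theta[i], t_interim = t_int, true_time = times[n],
      lower = pred$interval[1], upper = pred$interval[2],
      covered = times[n] >= pred$interval[1] & times[n] <= pred$interval[2],
      p_late = mean(pred$draws > T),
      late = times[n] > T
    )
  }
  trials <- dplyr::bind_rows(res)
  list(trials = trials, coverage = mean(trials$covered),
       n_trials = n_trials, level = level)
}
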