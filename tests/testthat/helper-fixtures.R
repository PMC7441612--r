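# Fixtures built in code: small deterministic portfolios and oracles.

# A portfolio of trials that each recruit exactly `per_day` patient(s) per
# day from day 0, stopping at `achieved` patients.
make_linear_portfolio <- function(n_trials = 1, achieved = 120, target = 120,
                                  anticipated = NA_real_,
                                  origin = as.Date("2020-01-01"),
                                  reason = "none",
                                  status = "completed") {
  ids <- sprintf("L%02d", seq_len(n_trials))
  events <- dplyr::bind_rows(lapply(ids, function(id) {
    tibble::tibble(trial_id = id, site_id = paste0(id, "_S1"),
                   date = origin + 0:(achieved - 1))
  }))
  trials <- tibble::tibble(
    trial_id = ids, recruitment_target = target,
    statistical_sample_size = target,
    anticipated_recruitment_time_months = anticipated, n_sites = 1,
    completion_status = status, discontinuation_reason = reason,
    medical_field = NA_character_, intervention_type = NA_character_,
    blinding = NA_character_, setting = NA_character_,
    funding = NA_character_
  )
  sites <- tibble::tibble(
    trial_id = ids, site_id = paste0(ids, "_S1"), activation_date = origin,
    closure_date = as.Date(NA), country = NA_character_,
    n_randomized = as.numeric(achieved), pi_institution = NA
  )
  new_portfolio(trials, events, sites)
}

# Independent gridded-Bayes oracle for the conjugate posterior mean of the
# mean waiting time: prior density ~ theta^-(P*n)-1 * exp(-P*T/theta),
# likelihood for m patients observed at elapsed time t ~
# theta^-m * exp(-t/theta). Trapezoid quadrature on the log scale.
grid_posterior_mean <- function(P, n, T, m, t, n_grid = 40001) {
  a_loc <- P * n + m          # used only to place the grid
  b_loc <- P * T + t
  center <- log(b_loc / a_loc)
  span <- 14 / sqrt(a_loc)
  u <- seq(center - span, center + span, length.out = n_grid)
  theta <- exp(u)
  log_f <- -(P * n + 1) * log(theta) - (P * T) / theta -
    m * log(theta) - t / theta + u   # + u: Jacobian of theta = exp(u)
  log_f <- log_f - max(log_f)
  f <- exp(log_f)
  sum(f * theta) / sum(f)
}

# Quadrature oracle for P(T_pred > T): integrate the gamma tail of the
# remaining recruitment time against the inverse-gamma posterior density.
grid_p_late <- function(shape, scale, t, remaining, T, n_grid = 20001) {
  center <- log(scale / shape)
  span <- 12 / sqrt(shape)
  u <- seq(center - span, center + span, length.out = n_grid)
  theta <- exp(u)
  log_w <- -(shape + 1) * log(theta) - scale / theta + u
  log_w <- log_w - max(log_w)
  w <- exp(log_w)
  tail_p <- stats::pgamma(T - t, shape = remaining, scale = theta,
                          lower.tail = FALSE)
  sum(w * tail_p) / sum(w)
}
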