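# Data model for trial portfolios: ingestion, validation, completion
# classification, trajectory construction and interim-landmark extraction.

#' Days per month used for all day/month conversions
#'
#' Fixed at 365.25 / 12 = 30.4375 days so that time-based landmarks,
#' monthly aggregation and recruitment times are mutually consistent.
#' @export
days_per_month <- function() 30.4375

# ---- portfolio container ----------------------------------------------------

patients_cols <- c("trial_id", "site_id", "randomization_date")
sites_cols <- c("trial_id", "site_id", "activation_date", "closure_date",
                "country", "n_randomized", "pi_institution")
trials_cols <- c("trial_id", "recruitment_target", "statistical_sample_size",
                 "anticipated_recruitment_time_months", "n_sites",
                 "completion_status", "discontinuation_reason",
                 "medical_field", "intervention_type", "blinding",
                 "setting", "funding")

#' Construct a portfolio of trials
#'
#' A portfolio bundles trial-level metadata, patient-level randomization
#' events and (optionally) site-level activation records.
#'
#' @param trials tibble with one row per trial (see [read_portfolio()] for
#'   the column dialect).
#' @param events tibble of randomization events: `trial_id`, `site_id`,
#'   `date` (a `Date`).
#' @param sites optional tibble of site records with `Date` columns
#'   `activation_date`, `closure_date`.
#' @return An object of class `portfolio`.
#' @export
new_portfolio <- function(trials, events, sites = NULL) {
  stopifnot(is.data.frame(trials), is.data.frame(events))
  if (!inherits(events$date, "Date")) {
    stop("`events$date` must be a Date vector", call. = FALSE)
  }
  structure(
    list(trials = tibble::as_tibble(trials),
         events = tibble::as_tibble(events),
         sites = if (!is.null(sites)) tibble::as_tibble(sites)),
    class = "portfolio"
  )
}

#' @export
print.portfolio <- function(x, ...) {
  cat(sprintf("<portfolio> %d trial(s), %d randomization event(s), %s site record(s)\n",
              nrow(x$trials), nrow(x$events),
              if (is.null(x$sites)) "no" else nrow(x$sites)))
  invisible(x)
}

parse_iso_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  # as.Date() silently rolls nothing; invalid components yield NA already
  out
}

check_dates <- function(x, column, file, required = FALSE) {
  parsed <- parse_iso_date(x)
  blank <- is.na(x) | x == ""
  bad <- which(is.na(parsed) & !blank)
  if (required) bad <- sort(unique(c(bad, which(blank))))
  if (length(bad)) {
    vals <- ifelse(blank[bad], "<missing>", x[bad])
    stop(sprintf("%s: column '%s' has unparseable ISO-8601 date(s) at row(s) %s: %s",
                 file, column,
                 paste(utils::head(bad, 10), collapse = ", "),
                 paste(utils::head(vals, 10), collapse = ", ")),
         call. = FALSE)
  }
  parsed
}

read_table_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character())
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing mandatory column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

num_or_na <- function(x) {
  x[x == ""] <- NA
  suppressWarnings(as.numeric(x))
}

#' Read a trial portfolio from delimited text tables
#'
#' Reads the three-file comma-delimited dialect (`patients.csv`,
#' `sites.csv`, `trials.csv`). Dates must be ISO-8601 (`YYYY-MM-DD`);
#' rows with unparseable values are reported with their row numbers.
#'
#' @param patient_table path to the patient-level table with columns
#'   `trial_id`, `site_id` (may be empty), `randomization_date`.
#' @param site_table optional path to the site-level table (`trial_id`,
#'   `site_id`, `activation_date`, `closure_date`, `country`,
#'   `n_randomized`, `pi_institution`).
#' @param trial_table path to the trial-level table (`trial_id`,
#'   `recruitment_target`, `statistical_sample_size`,
#'   `anticipated_recruitment_time_months`, `n_sites`,
#'   `completion_status`, `discontinuation_reason`, ...).
#' @return A [new_portfolio()] object.
#' @export
read_portfolio <- function(patient_table, site_table = NULL, trial_table) {
  pat <- read_table_checked(patient_table, patients_cols)
  if (nrow(pat) && any(pat$trial_id == "")) {
    stop(sprintf("%s: empty trial_id at row(s) %s", basename(patient_table),
                 paste(which(pat$trial_id == ""), collapse = ", ")),
         call. = FALSE)
  }
  events <- tibble::tibble(
    trial_id = pat$trial_id,
    site_id = ifelse(pat$site_id == "", NA_character_, pat$site_id),
    date = check_dates(pat$randomization_date, "randomization_date",
                       basename(patient_table), required = TRUE)
  )

  tri <- read_table_checked(trial_table, trials_cols)
  trials <- tibble::tibble(
    trial_id = tri$trial_id,
    recruitment_target = num_or_na(tri$recruitment_target),
    statistical_sample_size = num_or_na(tri$statistical_sample_size),
    anticipated_recruitment_time_months =
      num_or_na(tri$anticipated_recruitment_time_months),
    n_sites = num_or_na(tri$n_sites),
    completion_status = ifelse(tri$completion_status == "", NA_character_,
                               tri$completion_status),
    discontinuation_reason = ifelse(tri$discontinuation_reason == "",
                                    "none", tri$discontinuation_reason),
    medical_field = tri$medical_field,
    intervention_type = tri$intervention_type,
    blinding = tri$blinding,
    setting = tri$setting,
    funding = tri$funding
  )
  bad_target <- which(is.na(trials$recruitment_target) |
                        trials$recruitment_target <= 0)
  if (length(bad_target)) {
    stop(sprintf("%s: recruitment_target missing or non-positive at row(s) %s",
                 basename(trial_table), paste(bad_target, collapse = ", ")),
         call. = FALSE)
  }
  inflated <- which(!is.na(trials$statistical_sample_size) &
                      trials$statistical_sample_size > trials$recruitment_target)
  if (length(inflated)) {
    warning(sprintf("statistical_sample_size exceeds recruitment_target for trial(s) %s",
                    paste(trials$trial_id[inflated], collapse = ", ")),
            call. = FALSE)
  }

  sites <- NULL
  if (!is.null(site_table)) {
    st <- read_table_checked(site_table, sites_cols)
    sites <- tibble::tibble(
      trial_id = st$trial_id,
      site_id = st$site_id,
      activation_date = check_dates(st$activation_date, "activation_date",
                                    basename(site_table)),
      closure_date = check_dates(st$closure_date, "closure_date",
                                 basename(site_table)),
      country = ifelse(st$country == "", NA_character_, st$country),
      n_randomized = num_or_na(st$n_randomized),
      pi_institution = dplyr::case_when(
        tolower(st$pi_institution) == "true" ~ TRUE,
        tolower(st$pi_institution) == "false" ~ FALSE,
        .default = NA
      )
    )
    bad_order <- which(!is.na(sites$activation_date) &
                         !is.na(sites$closure_date) &
                         sites$closure_date < sites$activation_date)
    if (length(bad_order)) {
      stop(sprintf("%s: closure_date before activation_date at row(s) %s",
                   basename(site_table), paste(bad_order, collapse = ", ")),
           call. = FALSE)
    }
  }

  unknown <- setdiff(unique(events$trial_id), trials$trial_id)
  if (length(unknown)) {
    warning("randomization events reference trial_id(s) absent from the trial table: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  new_portfolio(trials, events, sites)
}

# ---- completion classification ---------------------------------------------

#' Classify a trial as completed or discontinued
#'
#' A trial with a stated discontinuation reason is discontinued for that
#' reason. Otherwise it is discontinued "due to unknown reason" when the
#' achieved sample size falls below `threshold` times the reference size
#' (the statistical sample size when recorded, else the recruitment
#' target), and completed otherwise. The primary rule is strict
#' (below 90%); the 80% sensitivity rule is inclusive ("80% or less"),
#' selected with `inclusive = TRUE`.
#'
#' @param trial a list or one-row data frame with `recruitment_target`,
#'   and optionally `statistical_sample_size` and
#'   `discontinuation_reason`.
#' @param achieved number of patients actually randomized.
#' @param threshold completion threshold as a fraction of the reference
#'   size (default 0.90).
#' @param inclusive logical; if `TRUE` the rule is
#'   `achieved <= threshold * reference` (sensitivity analysis
#'   convention), else strict `<`.
#' @return A list with elements `status` (`"completed"` or
#'   `"discontinued"`) and `reason`.
#' @export
classify_completion <- function(trial, achieved, threshold = 0.90,
                                inclusive = FALSE) {
  stopifnot(achieved >= 0, threshold > 0, threshold <= 1)
  reasons <- c("poor_recruitment", "benefit", "futility", "external_evidence",
               "harm", "administrative", "unknown")
  stated <- trial$discontinuation_reason
  if (!is.null(stated) && length(stated) == 1 && !is.na(stated) &&
      stated %in% reasons) {
    return(list(status = "discontinued", reason = stated))
  }
  ref <- trial$statistical_sample_size
  if (is.null(ref) || length(ref) == 0 || is.na(ref)) ref <- trial$recruitment_target
  if (is.null(ref) || length(ref) == 0 || is.na(ref)) {
    stop("unclassifiable: neither statistical_sample_size nor recruitment_target available",
         call. = FALSE)
  }
  below <- if (inclusive) achieved <= threshold * ref else achieved < threshold * ref
  if (below) list(status = "discontinued", reason = "unknown")
  else list(status = "completed", reason = "none")
}

# ---- trajectories -----------------------------------------------------------

#' Build a recruitment trajectory from randomization events
#'
#' The trajectory is the cumulative number of randomized patients as a
#' step function of day offsets from the time origin. Same-day events
#' collapse into a single step of the corresponding height. The
#' recruitment time is the last offset converted to months.
#'
#' @param events tibble of randomization events for one trial (`date`
#'   column of class `Date`).
#' @param trial trial record (list or one-row data frame) providing
#'   `trial_id` and `recruitment_target`.
#' @param origin `"first_randomization"` (default) or `"activation"`; the
#'   latter measures time from `activation_date`.
#' @param activation_date trial activation date, required when
#'   `origin = "activation"`.
#' @return An object of class `recruitment_trajectory` with fields
#'   `trial_id`, `origin_date`, `offsets` (days), `cumulative`,
#'   `recruitment_time` (months) and `target`.
#' @export
build_trajectory <- function(events, trial,
                             origin = c("first_randomization", "activation"),
                             activation_date = NULL) {
  origin <- match.arg(origin)
  if (nrow(events) == 0) stop("no randomizations", call. = FALSE)
  dates <- sort(events$date)
  origin_date <- if (origin == "activation") {
    if (is.null(activation_date)) {
      stop("activation origin requires `activation_date`", call. = FALSE)
    }
    as.Date(activation_date)
  } else {
    dates[1]
  }
  offs <- as.integer(dates - origin_date)
  if (any(offs < 0)) stop("events precede the time origin", call. = FALSE)
  steps <- table(offs)
  offsets <- as.integer(names(steps))
  cumulative <- cumsum(as.integer(steps))
  structure(
    list(trial_id = trial$trial_id,
         origin_date = origin_date,
         offsets = offsets,
         cumulative = cumulative,
         recruitment_time = offsets[length(offsets)] / days_per_month(),
         target = as.integer(trial$recruitment_target)),
    class = "recruitment_trajectory"
  )
}

#' @export
print.recruitment_trajectory <- function(x, ...) {
  cat(sprintf("<recruitment_trajectory> trial %s: %d patients over %.2f months (target %d)\n",
              x$trial_id, max(x$cumulative), x$recruitment_time, x$target))
  invisible(x)
}

#' Define an interim landmark
#'
#' @param kind `"time_based"` (value in months, conventionally one of
#'   1, 3, 6, 9, 12) or `"proportion_based"` (fraction of the recruitment
#'   target in (0, 1], conventionally a multiple of 0.10).
#' @param value the landmark value.
#' @return An object of class `landmark`.
#' @export
landmark <- function(kind = c("time_based", "proportion_based"), value) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(value), length(value) == 1, value > 0)
  if (kind == "proportion_based" && value > 1) {
    stop("proportion-based landmark must lie in (0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, value = value), class = "landmark")
}

#' Default landmark grid
#'
#' Months 1, 3, 6, 9 and 12 plus proportions 10% through 90%.
#' @return list of [landmark()] objects.
#' @export
default_landmarks <- function() {
  c(lapply(c(1, 3, 6, 9, 12), function(v) landmark("time_based", v)),
    lapply(seq(0.1, 0.9, by = 0.1), function(v) landmark("proportion_based", v)))
}

#' Interim recruitment state at a landmark
#'
#' For a time-based landmark, `m` counts events with day offset strictly
#' less than the landmark converted to days (half-open window) and `t`
#' equals the landmark. For a proportion-based landmark, `t` is the first
#' offset at which the cumulative count reaches `ceiling(value * target)`
#' and `m` the cumulative count there.
#'
#' @param traj a [build_trajectory()] object.
#' @param lm a [landmark()].
#' @return list with `m` (patients recruited), `t` (elapsed months),
#'   `n` (recruitment target) and `remaining` (`n - m`).
#' @export
landmark_state <- function(traj, lm) {
  stopifnot(inherits(traj, "recruitment_trajectory"), inherits(lm, "landmark"))
  n <- traj$target
  if (lm$kind == "time_based") {
    cut_days <- lm$value * days_per_month()
    before <- traj$offsets < cut_days
    m <- if (any(before)) traj$cumulative[max(which(before))] else 0L
    t <- lm$value
  } else {
    need <- ceiling(lm$value * n)
    idx <- which(traj$cumulative >= need)
    if (!length(idx)) stop("landmark not reached", call. = FALSE)
    idx <- idx[1]
    m <- traj$cumulative[idx]
    t <- traj$offsets[idx] / days_per_month()
  }
  list(m = as.integer(m), t = t, n = n, remaining = as.integer(n - m))
}

#' Aggregate a trajectory into monthly counts
#'
#' Counts events per month bin `[k, k+1)` months from the origin; months
#' interior to the recruitment window with no events are emitted as 0.
#'
#' @param traj a [build_trajectory()] object.
#' @return tibble with columns `month` (0-based bin index) and `count`.
#' @export
aggregate_monthly <- function(traj) {
  stopifnot(inherits(traj, "recruitment_trajectory"))
  heights <- diff(c(0L, traj$cumulative))
  bins <- floor(traj$offsets / days_per_month())
  grid <- 0:max(bins)
  counts <- vapply(grid, function(k) sum(heights[bins == k]), integer(1))
  tibble::tibble(month = grid, count = counts)
}

#' Build trajectories for every trial in a portfolio
#'
#' @param portfolio a [new_portfolio()] object.
#' @return named list of `recruitment_trajectory` objects (trials with no
#'   events are omitted).
#' @export
portfolio_trajectories <- function(portfolio) {
  stopifnot(inherits(portfolio, "portfolio"))
  split_ev <- split(portfolio$events, portfolio$events$trial_id)
  out <- list()
  for (i in seq_len(nrow(portfolio$trials))) {
    tr <- portfolio$trials[i, ]
    ev <- split_ev[[tr$trial_id]]
    if (is.null(ev) || nrow(ev) == 0) next
    out[[tr$trial_id]] <- build_trajectory(ev, tr)
  }
  out
}
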