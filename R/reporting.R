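# Plots, the pipeline report, and the command-line entry point.

#' Spaghetti plot of normalized recruitment trajectories
#'
#' @param portfolio a [new_portfolio()] object.
#' @return a ggplot object: proportion of recruitment target over months
#'   since first randomization, one line per trial.
#' @export
plot_trajectories <- function(portfolio) {
  trajs <- portfolio_trajectories(portfolio)
  df <- dplyr::bind_rows(lapply(trajs, function(tr) {
    tibble::tibble(trial_id = tr$trial_id,
                   month = c(0, tr$offsets / days_per_month()),
                   proportion = c(0, tr$cumulative / tr$target))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$month, .data$proportion,
                                   group = .data$trial_id)) +
    ggplot2::geom_step(alpha = 0.4) +
    ggplot2::labs(x = "Months since first randomization",
                  y = "Proportion of recruitment target") +
    ggplot2::theme_minimal()
}

#' Bar chart of seasonal recruitment indices
#'
#' @param profile result of [seasonal_profile()].
#' @return a ggplot object.
#' @export
plot_seasonal <- function(profile) {
  stopifnot(isTRUE(profile$evaluable))
  df <- tibble::tibble(month = factor(month.abb, levels = month.abb),
                       index = profile$index)
  ggplot2::ggplot(df, ggplot2::aes(.data$month, .data$index)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Recruitment index (1 = uniform)") +
    ggplot2::theme_minimal()
}

#' %Rbias across landmarks, by model
#'
#' @param rows output of [landmark_validate()].
#' @param kind landmark kind to display.
#' @return a ggplot object of median %Rbias per landmark and model.
#' @export
plot_rbias <- function(rows, kind = "time_based") {
  df <- dplyr::summarise(
    dplyr::group_by(rows[rows$landmark_kind == kind, ],
                    .data$landmark_value, .data$model),
    median_rbias = stats::median(.data$rbias_pct), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$landmark_value, .data$median_rbias,
                                   colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = if (kind == "time_based") "Landmark (months)" else
      "Landmark (fraction of target)",
      y = "Median %Rbias", colour = NULL) +
    ggplot2::theme_minimal()
}

#' P_late calibration plot
#'
#' @param calib output of [p_late_calibration()].
#' @return a ggplot object (bin-mean predicted vs empirical lateness).
#' @export
plot_calibration <- function(calib) {
  df <- calib[!is.na(calib$mean_p_late), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_p_late, .data$frac_late)) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted P_late", y = "Empirical fraction late",
                  size = "rows") +
    ggplot2::theme_minimal()
}

md_table <- function(df, digits = 3) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
    df[[j]] <- as.character(df[[j]])
    df[[j]][is.na(df[[j]])] <- ""
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  c(header, sep, body)
}

#' Render a Markdown summary report for a validated portfolio
#'
#' Combines the descriptive analyses and the landmark validation into a
#' single Markdown document: portfolio summary, accrual-pattern table,
#' seasonal profile, %Rbias comparison, interval coverage and P_late
#' calibration. Sections whose inputs are missing render as
#' "not evaluable".
#'
#' @param portfolio a [new_portfolio()] object.
#' @param rows optional output of [landmark_validate()].
#' @param out path of the Markdown file to write.
#' @param seed seed recorded in (and used by) the descriptive resampling.
#' @return (invisibly) the path written.
#' @export
render_report <- function(portfolio, rows = NULL, out = "report.md",
                          seed = 1L) {
  lines <- c(
    "# Recruitment portfolio report",
    "",
    sprintf("- package: recruitcast %s",
            as.character(utils::packageVersion("recruitcast"))),
    sprintf("- seed: %d", seed),
    sprintf("- trials: %d; randomization events: %d",
            nrow(portfolio$trials), nrow(portfolio$events)),
    ""
  )
  section <- function(title, body) c(sprintf("## %s", title), "", body, "")

  pat <- tryCatch(pattern_report(portfolio, seed = seed),
                  error = function(e) NULL)
  lines <- c(lines, section("Accrual patterns", if (is.null(pat)) {
    "not evaluable"
  } else {
    md_table(pat[, c("check", "label", "statistic", "p_value", "n_used",
                     "note")])
  }))

  seas <- seasonal_profile(portfolio, seed = seed)
  lines <- c(lines, section("Seasonal profile", if (!isTRUE(seas$evaluable)) {
    paste("not evaluable:", seas$reason)
  } else {
    c(md_table(tibble::tibble(month = month.abb,
                              index = seas$index)),
      "", sprintf("Permutation p-value: %.4f (%d trials)",
                  seas$p_value, seas$n_trials))
  }))

  readiness <- site_readiness_split(portfolio)
  lines <- c(lines, section("Site readiness", if (!isTRUE(readiness$evaluable)) {
    paste("not evaluable:", readiness$reason)
  } else {
    sprintf("%d trial(s) with >80%% of sites ready within month 1, %d without, %d excluded for missing site data.",
            sum(readiness$assignment$ready),
            sum(!readiness$assignment$ready), readiness$excluded)
  }))

  ava <- anticipated_vs_actual(portfolio)
  lines <- c(lines, section("Anticipated vs actual recruitment time",
    if (!nrow(ava$ratios)) {
      "not evaluable: no anticipated recruitment times recorded"
    } else {
      sprintf("Median ratio actual/anticipated: %.2f (IQR %.2f-%.2f); %d trial(s) missing an anticipated time.",
              ava$summary[[2]], ava$summary[[1]], ava$summary[[3]],
              ava$n_missing)
    }))

  if (!is.null(rows)) {
    cmp <- tryCatch(compare_models(rows), error = function(e) NULL)
    lines <- c(lines, section("Model comparison (%Rbias)", if (is.null(cmp)) {
      "not evaluable"
    } else {
      md_table(cmp[, c("landmark", "n", "median_rbias_a", "median_rbias_b",
                       "median_paired_diff", "frac_a_lower")])
    }))
    cov <- coverage_summary(rows)
    lines <- c(lines, section("Interval coverage",
                              md_table(cov[, c("model", "landmark", "n",
                                               "coverage", "ci_lower",
                                               "ci_upper")])))
    calib <- p_late_calibration(rows)
    lines <- c(lines, section("P_late calibration",
      if (!is.data.frame(calib)) paste("not evaluable:", calib$reason)
      else md_table(calib)))
  } else {
    lines <- c(lines, section("Model validation", "not evaluable: no validation rows supplied"))
  }
  writeLines(lines, out)
  invisible(out)
}

cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i],
                                         call. = FALSE)
    out[[key]] <- if (i < length(args) && !startsWith(args[i + 1], "--")) {
      i <- i + 1
      args[i]
    } else {
      TRUE
    }
    i <- i + 1
  }
  out
}

cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic portfolio),
#' `describe` (descriptive report), `predict` (one-off prediction from
#' summary inputs), `validate` (landmark validation to CSV), `report`
#' (full Markdown report). Invoked by the `inst/cli/recruitcast`
#' Rscript; see that file for flag details.
#'
#' @param args character vector of command-line arguments (first element
#'   the subcommand).
#' @return exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: recruitcast <simulate|describe|predict|validate|report> [--flags]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- cli_args(args[-1])
  seed <- as.integer(cli_num(opts, "seed", 1))
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- simulation_config(
          n_trials = as.integer(cli_num(opts, "n-trials", 50)),
          seasonal_amplitude = cli_num(opts, "amplitude", 0),
          seed = seed)
        sim <- simulate_portfolio(cfg)
        out <- opts[["out"]] %||% "."
        write_portfolio(sim$portfolio, out)
        manifest <- list(package = "recruitcast",
                         version = as.character(
                           utils::packageVersion("recruitcast")),
                         subcommand = "simulate", seed = seed,
                         n_trials = cfg$n_trials)
        jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        message(sprintf("wrote %d trial(s) to %s", cfg$n_trials, out))
        0L
      },
      describe = ,
      validate = ,
      report = {
        dir <- opts[["data"]] %||% "."
        pfile <- file.path(dir, "patients.csv")
        if (!file.exists(pfile)) stop("no trials found in ", dir,
                                      call. = FALSE)
        pf <- read_portfolio(pfile,
                             site_table = {
                               sf <- file.path(dir, "sites.csv")
                               if (file.exists(sf)) sf
                             },
                             trial_table = file.path(dir, "trials.csv"))
        if (cmd == "describe") {
          rep <- pattern_report(pf, seed = seed)
          out <- opts[["out"]] %||% "describe.json"
          jsonlite::write_json(rep, out, auto_unbox = TRUE, pretty = TRUE,
                               na = "null")
          message("wrote ", out)
        } else {
          rows <- landmark_validate(
            pf, draws = as.integer(cli_num(opts, "draws", 50000)),
            seed = seed)
          if (cmd == "validate") {
            out <- opts[["out"]] %||% "validation.csv"
            utils::write.csv(
              rows[, c("trial_id", "landmark_kind", "landmark_value",
                       "model", "predicted", "true_value", "rbias_pct",
                       "covered", "p_late")],
              out, row.names = FALSE)
            message("wrote ", out)
          } else {
            out <- opts[["out"]] %||% "report.md"
            render_report(pf, rows, out, seed = seed)
            message("wrote ", out)
          }
        }
        0L
      },
      predict = {
        prior <- accrual_prior(n = cli_num(opts, "n", stop("--n required")),
                               T = cli_num(opts, "T", 0),
                               P = cli_num(opts, "P", 0))
        interim <- interim_state(m = cli_num(opts, "recruited", 0),
                                 t = cli_num(opts, "elapsed-months", 0),
                                 n = cli_num(opts, "n", 1))
        post <- fit_posterior(prior, interim)
        pred <- predict_completion_time(
          post, interim$remaining,
          draws = as.integer(cli_num(opts, "draws", 50000)), seed = seed,
          level = cli_num(opts, "level", 0.95))
        result <- list(
          point_months = pred$point, mean_months = pred$mean,
          interval = pred$interval, level = pred$level, seed = seed)
        if (!is.null(opts[["T"]])) {
          result$p_late <- mean(pred$draws > as.numeric(opts[["T"]]))
          result$slow_accrual <- flag_slow_accrual(pred,
                                                   as.numeric(opts[["T"]]))
        }
        json <- jsonlite::toJSON(result, auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE)
        if (!is.null(opts[["out"]])) writeLines(json, opts[["out"]])
        else cat(json, "\n")
        0L
      },
      {
        message("unknown subcommand: ", cmd)
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
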