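#' Read / write a participant-level trial table as CSV
#'
#' One row per participant x timepoint; missing values are encoded as empty
#' fields. `read_trial_data()` validates the schema (required identifier
#' columns, known arm labels) and reports malformed input with column
#' diagnostics.
#'
#' @param data Participant table.
#' @param path CSV path.
#' @return `read_trial_data()` returns a validated tibble.
#' @export
write_trial_data <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, guess_max = 1e5)
  if ("participant_id" %in% names(data)) {
    data$participant_id <- as.character(data$participant_id)
  }
  check_trial_table(data)
  data %>%
    mutate(
      arm = as_arm(.data$arm),
      timepoint = as_timepoint(.data$timepoint)
    )
}

#' Join outcomes and perspective cost totals into one analysis table
#'
#' Costs every record with [compute_costs()] and keeps the outcome columns,
#' producing the participant x timepoint table the inference and bootstrap
#' stages work on.
#'
#' @param data Participant table with outcomes and resource items.
#' @param tariff A [tariff_table()].
#' @return Tibble with `remission`, `eq5d_index` and `cost_*` columns.
#' @export
build_analysis_table <- function(data, tariff = tariff_table()) {
  costs <- compute_costs(data, tariff)
  data %>%
    select(all_of(c("participant_id", "arm", "timepoint", "remission",
                    "eq5d_index"))) %>%
    left_join(
      costs %>% select(all_of(c("participant_id", "arm", "timepoint")),
                       dplyr::starts_with("cost_")),
      by = c("participant_id", "arm", "timepoint")
    )
}

# arm x timepoint descriptives with Wald 95% CIs
descriptive_table <- function(analysis) {
  value_cols <- c("remission", "eq5d_index", grep("^cost_", names(analysis),
                                                  value = TRUE))
  analysis %>%
    tidyr::pivot_longer(all_of(value_cols), names_to = "measure") %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$measure, arm = as.character(.data$arm),
             timepoint = as.character(.data$timepoint)) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      .groups = "drop"
    ) %>%
    mutate(
      se = .data$sd / sqrt(.data$n),
      ci_lower = .data$mean - qnorm(0.975) * .data$se,
      ci_upper = .data$mean + qnorm(0.975) * .data$se
    )
}

#' Run the full cost-effectiveness pipeline
#'
#' End-to-end evaluation on supplied or simulated data: costing under the
#' nested perspectives, descriptive statistics, mixed-model
#' difference-in-differences contrasts with effect sizes, remission odds
#' ratios, point ICERs per outcome x perspective x timepoint,
#' bootstrap of incremental costs and effects, cost-effectiveness plane
#' quadrant proportions, acceptability curves, and the two sensitivity
#' variants (complete cases only; societal costs excluding unemployment).
#' Given the same config and seed, two runs produce identical outputs.
#'
#' @param config A [trial_config()]; used to simulate when `data` is NULL.
#' @param data Optional participant table (overrides simulation).
#' @param tariff A [tariff_table()].
#' @param B Bootstrap replications.
#' @param seed Integer seed controlling simulation, dropout and bootstrap.
#' @param lambda_grid Willingness-to-pay grid for the CEAC.
#' @param method Per-replicate estimator, see [bootstrap_cea()].
#' @param sensitivity Run the sensitivity variants?
#' @param sensitivity_method Per-replicate estimator for the sensitivity
#'   variants (defaults to `method`); the fast cell-mean mode is a common
#'   choice here since the variants are interpreted through their quadrant
#'   proportions.
#' @param out_dir Optional directory: writes `descriptives.csv`,
#'   `contrasts.csv`, `icer.csv`, `replicates.csv`, `ceac.csv`,
#'   `quadrants.json`, sensitivity files and `run_log.txt`.
#' @return A list of class `cea_report`.
#' @export
run_cea_pipeline <- function(config = trial_config(), data = NULL,
                             tariff = config$tariff, B = 1000,
                             seed = config$seed,
                             lambda_grid = default_lambda_grid(),
                             method = c("mixed", "cellmeans"),
                             sensitivity = TRUE, sensitivity_method = method,
                             out_dir = NULL) {
  method <- match.arg(method)
  sensitivity_method <- match.arg(sensitivity_method, c("mixed", "cellmeans"))
  if (is.null(data)) {
    data <- simulate_trial(config, seed = seed) %>%
      apply_missingness(config, seed = seed + 1L)
  }
  analysis <- build_analysis_table(data, tariff)
  persp <- c("societal", "health_care", "clinic")
  timepoints <- setdiff(levels(as_timepoint(analysis$timepoint)), "pre")

  descriptives <- descriptive_table(analysis)

  # columns constant within every cell (the clinic perspective when no other
  # category contributes) have no mixed model to fit; their contrasts come
  # from the exact cell-mean arithmetic in `incremental_estimates()`
  fit_cols <- c("eq5d_index", paste0("cost_", persp))
  fit_cols <- fit_cols[!purrr::map_lgl(fit_cols, is_degenerate_outcome,
                                       data = analysis)]
  fits <- lapply(setNames(fit_cols, fit_cols),
                 function(col) fit_outcome_model(analysis, col))
  contrasts <- purrr::map_dfr(fits, function(f) {
    purrr::map_dfr(timepoints, function(tp) did_contrast(f, tp))
  })
  effect_sizes <- purrr::map_dfr(timepoints, function(tp) {
    tibble(
      timepoint = tp,
      between_d = cohens_d(fits$eq5d_index, tp, type = "between"),
      within_d_intervention = cohens_d(fits$eq5d_index, tp, type = "within",
                                       arm = "intervention"),
      within_d_control = cohens_d(fits$eq5d_index, tp, type = "within",
                                  arm = "control")
    )
  })
  remission_or <- fit_remission_model(analysis)

  point <- estimate_increments(analysis, c("remission", "qaly"), persp,
                               timepoints, method = "mixed") %>%
    mutate(icer = icer(.data$delta_cost, .data$delta_effect))

  replicates <- bootstrap_cea(analysis, B = B, seed = seed + 2L,
                              perspectives = persp,
                              timepoints = timepoints, method = method)
  quadrants <- quadrant_proportions(replicates)
  curves <- ceac(replicates, lambda_grid)

  sens <- NULL
  if (sensitivity) {
    cc_qaly <- complete_case_filter(analysis, c("eq5d_index", "cost_societal"))
    cc_rem <- complete_case_filter(analysis, c("remission", "cost_societal"))
    cc_reps <- bind_rows(
      bootstrap_cea(cc_qaly, B = B, seed = seed + 3L, outcomes = "qaly",
                    perspectives = persp, timepoints = timepoints,
                    method = sensitivity_method) %>% as_tibble(),
      bootstrap_cea(cc_rem, B = B, seed = seed + 4L, outcomes = "remission",
                    perspectives = persp, timepoints = timepoints,
                    method = sensitivity_method) %>% as_tibble()
    ) %>%
      mutate(variant = "complete_case")
    excl <- run_excluding_unemployment(analysis, B = B, seed = seed + 5L,
                                       timepoints = timepoints,
                                       method = sensitivity_method)
    sens <- list(
      complete_case = list(
        replicates = cc_reps,
        quadrants = cc_reps %>%
          structure(class = c("cea_replicates", class(cc_reps))) %>%
          quadrant_proportions() %>%
          mutate(variant = "complete_case")
      ),
      exclude_unemployment = excl
    )
  }

  report <- structure(
    list(
      data = data,
      analysis = analysis,
      descriptives = descriptives,
      fits = fits,
      contrasts = contrasts,
      effect_sizes = effect_sizes,
      remission_or = remission_or,
      point_estimates = point,
      replicates = replicates,
      quadrants = quadrants,
      ceac = curves,
      sensitivity = sens,
      B = B, seed = seed, method = method
    ),
    class = "cea_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# write the report bundle as plain-text CSV/JSON plus a run log
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_csv(x, file.path(out_dir, name), na = "")
  w(report$descriptives, "descriptives.csv")
  w(report$contrasts, "contrasts.csv")
  w(report$point_estimates %>% mutate(icer = round(.data$icer)), "icer.csv")
  w(as_tibble(report$replicates), "replicates.csv")
  w(as_tibble(report$ceac), "ceac.csv")
  w(report$effect_sizes, "effect_sizes.csv")
  w(as_tibble(report$remission_or), "remission_odds_ratios.csv")
  jsonlite::write_json(report$quadrants, file.path(out_dir, "quadrants.json"),
                       digits = NA)
  if (!is.null(report$sensitivity)) {
    w(report$sensitivity$complete_case$replicates,
      "sensitivity_complete_case_replicates.csv")
    w(bind_rows(report$sensitivity$complete_case$quadrants,
                report$sensitivity$exclude_unemployment$quadrants),
      "sensitivity_quadrants.csv")
    w(report$sensitivity$exclude_unemployment$replicates,
      "sensitivity_excl_unemployment_replicates.csv")
  }
  log_lines <- c(
    paste0("seed: ", report$seed),
    paste0("B: ", report$B),
    paste0("method: ", report$method),
    paste0("bootstrap_redraws: ", attr(report$replicates, "n_redraws")),
    paste0("non_converged_fits: ",
           sum(!purrr::map_lgl(report$fits, "converged"))),
    paste0("R_version: ", R.version.string),
    paste0("package_versions: trialcea ",
           as.character(utils::packageVersion("trialcea")),
           ", lme4 ", as.character(utils::packageVersion("lme4")))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.cea_report <- function(x, ...) {
  cat("<cea_report> B =", x$B, " seed =", x$seed, " method =", x$method, "\n\n")
  cat("Point incremental estimates (mixed-model contrasts):\n")
  print(x$point_estimates %>%
          mutate(dplyr::across(c("delta_cost", "icer"), round),
                 delta_effect = round(.data$delta_effect, 3)),
        n = Inf)
  cat("\nCost-effectiveness plane quadrant proportions:\n")
  print(x$quadrants, n = Inf)
  invisible(x)
}
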