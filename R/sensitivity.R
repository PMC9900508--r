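#' Restrict to participants with complete data for an analysis
#'
#' Keeps only participants with no missing value in the given columns at
#' the analysed timepoints, i.e. the complete-case variant of an analysis
#' (no likelihood-based handling of dropout). Completeness is defined per
#' analysis: pass the columns that analysis uses, not all instruments.
#' Remission is undefined at pre-treatment by construction, so the
#' pre-treatment timepoint is never consulted for the `remission` column.
#'
#' @param data Participant x timepoint table.
#' @param cols Columns that must be observed.
#' @param timepoints Timepoints at which they must be observed; default all
#'   timepoints present.
#' @return The table restricted to complete participants (all their rows).
#' @export
complete_case_filter <- function(data, cols,
                                 timepoints = unique(as.character(data$timepoint))) {
  check_trial_table(data, cols)
  sub <- data %>% filter(as.character(.data$timepoint) %in% timepoints)
  miss <- rep(FALSE, nrow(sub))
  for (col in cols) {
    m <- is.na(sub[[col]])
    if (col == "remission") {
      m <- m & as.character(sub$timepoint) != "pre"
    }
    miss <- miss | m
  }
  incomplete <- unique(sub$participant_id[miss])
  out <- data %>% filter(!.data$participant_id %in% incomplete)
  if (nrow(out) == 0) abort("no complete cases remain")
  out
}

#' Re-run the cost-effectiveness analysis excluding unemployment costs
#'
#' The societal perspective with the unemployment category removed:
#' unemployment costs are large, fixed amounts that a few individual cases
#' can dominate, so the robustness of the societal results to this category
#' is checked by re-estimating the bootstrap distribution under
#' `societal_excl_unemployment` and comparing quadrant proportions side by
#' side with the full societal run. Clinic and health-care results are
#' unaffected by construction (unemployment is a societal-only category).
#'
#' @param data Analysis table with cost columns (see [bootstrap_cea()]).
#' @param B,seed,outcomes,timepoints,method Passed to [bootstrap_cea()].
#' @return List with `replicates` (both variants, `variant` column) and
#'   `quadrants` (side-by-side proportions).
#' @export
run_excluding_unemployment <- function(data, B = 1000, seed = NULL,
                                       outcomes = c("remission", "qaly"),
                                       timepoints = c("post", "followup"),
                                       method = c("mixed", "cellmeans")) {
  method <- match.arg(method)
  base <- bootstrap_cea(data, B = B, seed = seed, outcomes = outcomes,
                        perspectives = "societal",
                        timepoints = timepoints, method = method)
  excl <- bootstrap_cea(data, B = B, seed = seed, outcomes = outcomes,
                        perspectives = "societal_excl_unemployment",
                        timepoints = timepoints, method = method)
  replicates <- bind_rows(
    base %>% as_tibble() %>% mutate(variant = "societal"),
    excl %>% as_tibble() %>% mutate(variant = "societal_excl_unemployment")
  )
  quadrants <- bind_rows(
    quadrant_proportions(base) %>% mutate(variant = "societal"),
    quadrant_proportions(excl) %>% mutate(variant = "societal_excl_unemployment")
  )
  list(replicates = replicates, quadrants = quadrants)
}
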