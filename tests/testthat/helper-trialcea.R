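suppressMessages(library(dplyr))

# analysis table (outcomes + perspective costs) from a small complete trial
small_analysis <- function(n = 15, seed = 1, config = trial_config(n_per_arm = n)) {
  simulate_trial(config, seed = seed) %>%
    build_analysis_table(config$tariff)
}

# one participant x timepoint record with every resource item at zero
zero_record <- function(arm = "control", timepoint = "post", n = 1) {
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    arm = arm, timepoint = timepoint,
    primary_care_visits = 0, specialist_visits = 0, psychiatric_visits = 0,
    medication_units = 0, sick_leave_days = 0, domestic_cutback_hours = 0,
    unemployed = FALSE
  )
}

all_items <- function() {
  c("primary_care_visits", "specialist_visits", "psychiatric_visits",
    "medication_units", "sick_leave_days", "domestic_cutback_hours")
}

zero_unemployment <- function() {
  tidyr::expand_grid(
    arm = c("control", "intervention"),
    timepoint = c("pre", "post", "followup")
  ) %>% mutate(prob = 0)
}

# config whose only nonzero cost item is sick leave, with an exactly known
# total societal cost difference-in-differences at post-treatment (in USD,
# including the fixed treatment-provision contrast) and the default utility
# trajectories (QALY DiD 0.10 at post)
sickleave_config <- function(n_per_arm, delta_cost_post = 1200) {
  tariff <- tariff_table()
  usd_per_day <- tariff$hours_per_workday * tariff$hourly_wage_sek *
    (tariff$period_weeks / tariff$recall_weeks) / tariff$sek_per_usd
  treat_delta <- tariff$treatment_cost_usd[["intervention"]] -
    tariff$treatment_cost_usd[["control"]]
  delta_cost_post <- delta_cost_post - treat_delta
  items <- tidyr::expand_grid(
    arm = c("control", "intervention"),
    timepoint = c("pre", "post", "followup"),
    item = all_items()
  ) %>%
    mutate(rate = ifelse(.data$item == "sick_leave_days", 2, 0))
  bump <- items$item == "sick_leave_days" & items$arm == "intervention" &
    items$timepoint == "post"
  items$rate[bump] <- 2 + delta_cost_post / usd_per_day
  trial_config(n_per_arm = n_per_arm, cost_item_rates = items,
               unemployment_prob = zero_unemployment())
}

# config with no group x time effect on any outcome
null_config <- function(n_per_arm = 47) {
  um <- default_utility_mean()
  um$mean <- rep(c(0.75, 0.70, 0.72), 2)
  rp <- default_remission_prob()
  rp$prob <- rep(c(0.10, 0.20), 2)
  trial_config(n_per_arm = n_per_arm, utility_mean = um, remission_prob = rp)
}
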