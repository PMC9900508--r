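test_that("default trial has the published dimensions and structure", {
  trial <- simulate_trial(trial_config(), seed = 1)
  expect_equal(nrow(trial), 94 * 3)
  expect_equal(dplyr::n_distinct(trial$participant_id), 94)
  counts <- trial %>% dplyr::count(participant_id, timepoint)
  expect_true(all(counts$n == 1))
  # remission undefined at pre-treatment by construction, defined after
  expect_true(all(is.na(trial$remission[trial$timepoint == "pre"])))
  expect_true(all(!is.na(trial$remission[trial$timepoint != "pre"])))
  items <- trial %>% dplyr::select(dplyr::all_of(all_items()))
  expect_true(all(items >= 0))
})

test_that("seeded generation is reproducible and seeds differentiate", {
  cfg <- trial_config(n_per_arm = 30)
  expect_identical(simulate_trial(cfg, seed = 5), simulate_trial(cfg, seed = 5))
  expect_false(identical(simulate_trial(cfg, seed = 5),
                         simulate_trial(cfg, seed = 6)))
})

test_that("empirical rates converge to the generating parameters", {
  rp <- default_remission_prob()
  rp$prob[rp$arm == "intervention" & rp$timepoint == "post"] <- 0.32
  cfg <- trial_config(n_per_arm = 10000, remission_prob = rp)
  trial <- simulate_trial(cfg, seed = 7)
  post_int <- trial %>%
    filter(arm == "intervention", timepoint == "post")
  expect_equal(mean(post_int$remission), 0.32, tolerance = 0.01 / 0.32)

  means <- trial %>%
    filter(!is.na(eq5d_index)) %>%
    group_by(arm, timepoint) %>%
    summarise(m = mean(eq5d_index), .groups = "drop") %>%
    left_join(cfg$utility_mean,
              by = c("arm", "timepoint"),
              suffix = c("", "_target"))
  # mean-preserving clipping: cells near the upper bound stay on target too
  expect_true(all(abs(means$m - means$mean) < 0.02))

  unemp <- trial %>%
    group_by(arm, timepoint) %>%
    summarise(p = mean(unemployed), .groups = "drop") %>%
    left_join(cfg$unemployment_prob, by = c("arm", "timepoint"))
  expect_true(all(abs(unemp$p - unemp$prob) < 0.02))
})

test_that("invalid configurations are rejected", {
  expect_error(trial_config(n_per_arm = 0), "positive integer")
  expect_error(trial_config(n_per_arm = 2.5), "positive integer")
  rp <- default_remission_prob()
  rp$prob[1] <- 1.4
  expect_error(trial_config(remission_prob = rp), "\\[0, 1\\]")
  expect_error(trial_config(utility_sd = -0.1), "nonnegative")
})

test_that("dropout hits the configured marginal completion rates", {
  cfg <- trial_config(n_per_arm = 10000)
  trial <- simulate_trial(cfg, seed = 11) %>% apply_missingness(cfg, seed = 12)
  # published anchor: 85% diagnostic completion at follow-up, intervention
  fu_int <- trial %>% filter(arm == "intervention", timepoint == "followup")
  expect_equal(mean(!is.na(fu_int$remission)), 40 / 47, tolerance = 0.012)
  expect_equal(mean(!is.na(fu_int$eq5d_index)), 36 / 47, tolerance = 0.015)
  # TIC-P missingness blanks every resource item of the row together
  ticp_na <- is.na(fu_int$sick_leave_days)
  expect_identical(ticp_na, is.na(fu_int$primary_care_visits))
  # pre-treatment rows are never made missing
  pre <- trial %>% filter(timepoint == "pre")
  expect_true(all(!is.na(pre$eq5d_index)))
})

test_that("full completion leaves the table unchanged", {
  cfg <- trial_config(n_per_arm = 40,
                      completion_rate = default_completion_rate() %>%
                        mutate(rate = 1))
  trial <- simulate_trial(cfg, seed = 2)
  expect_identical(apply_missingness(trial, cfg, seed = 3), trial)
})

test_that("dropout is MAR: driven by baseline utility, not the unseen value", {
  cfg <- trial_config(n_per_arm = 10000, mar_slope = 4)
  complete <- simulate_trial(cfg, seed = 21)
  masked <- apply_missingness(complete, cfg, seed = 22)

  fu <- complete %>% filter(arm == "intervention", timepoint == "followup")
  base <- complete %>% filter(arm == "intervention", timepoint == "pre")
  miss <- is.na(masked$eq5d_index[masked$arm == "intervention" &
                                    masked$timepoint == "followup"])
  # missingness correlates with the observed baseline...
  expect_lt(cor(miss, base$eq5d_index), -0.05)
  # ...but given baseline it carries no information about the unseen value
  fit <- glm(miss ~ base$eq5d_index + fu$eq5d_index, family = binomial())
  z <- summary(fit)$coefficients[, "z value"]
  expect_lt(z[["base$eq5d_index"]], -10)
  expect_lt(abs(z[["fu$eq5d_index"]]), 4)
})

test_that("a configuration survives a YAML round trip", {
  cfg <- trial_config(n_per_arm = 12, mar_slope = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trial_config(cfg, path)
  cfg2 <- read_trial_config(path)
  expect_equal(cfg2$n_per_arm, 12L)
  expect_equal(cfg2$mar_slope, 3)
  expect_equal(as.data.frame(cfg2$cost_item_rates),
               as.data.frame(cfg$cost_item_rates))
  expect_identical(simulate_trial(cfg, seed = 4), simulate_trial(cfg2, seed = 4))
})
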