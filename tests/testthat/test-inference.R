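# cell-mean oracle: raw arm x timepoint means and their DiD arithmetic
cell_means <- function(data, col) {
  data %>%
    group_by(arm = as.character(arm), timepoint = as.character(timepoint)) %>%
    summarise(m = mean(.data[[col]], na.rm = TRUE), .groups = "drop")
}
did_oracle <- function(cells, tp) {
  g <- function(a, t) cells$m[cells$arm == a & cells$timepoint == t]
  (g("intervention", tp) - g("intervention", "pre")) -
    (g("control", tp) - g("control", "pre"))
}

test_that("LS means and contrasts equal cell-mean arithmetic on balanced data", {
  an <- small_analysis(n = 25, seed = 9)
  for (col in c("eq5d_index", "cost_societal")) {
    fit <- fit_outcome_model(an, col)
    cells <- cell_means(an, col)
    lsm <- fit$ls_means %>%
      mutate(arm = as.character(arm), timepoint = as.character(timepoint)) %>%
      left_join(cells, by = c("arm", "timepoint"))
    expect_equal(lsm$estimate, lsm$m, tolerance = 1e-6)
    for (tp in c("post", "followup")) {
      expect_equal(did_contrast(fit, tp)$estimate, did_oracle(cells, tp),
                   tolerance = 1e-6)
    }
  }
})

test_that("identical trajectories in both arms give a zero contrast", {
  base <- small_analysis(n = 20, seed = 4) %>% filter(arm == "control")
  mirrored <- dplyr::bind_rows(
    base,
    base %>% mutate(arm = "intervention",
                    participant_id = paste0(participant_id, "m"))
  )
  fit <- fit_outcome_model(mirrored, "eq5d_index")
  expect_equal(did_contrast(fit, "post")$estimate, 0, tolerance = 1e-6)
  expect_equal(qaly_effect(fit, "followup")$estimate, 0, tolerance = 1e-6)
  expect_equal(cohens_d(fit, "post", type = "between"), 0, tolerance = 1e-4)
})

test_that("contrasts are refused at the pre-treatment reference", {
  fit <- fit_outcome_model(small_analysis(n = 10, seed = 2), "eq5d_index")
  expect_error(did_contrast(fit, "pre"), "pre-treatment reference")
  expect_error(did_contrast(fit, "week52"), "must be one of")
  cost_fit <- fit_outcome_model(small_analysis(n = 10, seed = 2), "cost_societal")
  expect_error(qaly_effect(cost_fit, "post"), "EQ-5D")
})

test_that("the interaction coefficient recovers the generating effect", {
  cfg <- trial_config(n_per_arm = 1000) # post-treatment QALY DiD 0.10 by design
  an <- simulate_trial(cfg, seed = 31) %>% build_analysis_table(cfg$tariff)
  fit <- fit_outcome_model(an, "eq5d_index")
  expect_true(fit$converged)
  expect_lt(abs(did_contrast(fit, "post")$estimate - 0.10), 0.02)
  # sign convention: the costlier intervention arm gives a positive contrast
  cost_fit <- fit_outcome_model(an, "cost_societal")
  expect_gt(did_contrast(cost_fit, "post")$estimate, 0)
})

test_that("Cohen's d scales the contrast by the model sigma", {
  fit <- fit_outcome_model(small_analysis(n = 30, seed = 13), "eq5d_index")
  d_res <- cohens_d(fit, "followup", type = "between")
  expect_equal(d_res, did_contrast(fit, "followup")$estimate / fit$sigma)
  d_tot <- cohens_d(fit, "followup", type = "between", sigma = "total")
  expect_equal(d_tot * sqrt(fit$sigma^2 + fit$tau^2), d_res * fit$sigma)
  lsm <- fit$ls_means
  w <- cohens_d(fit, "post", type = "within", arm = "control")
  chg <- lsm$estimate[lsm$arm == "control" & lsm$timepoint == "post"] -
    lsm$estimate[lsm$arm == "control" & lsm$timepoint == "pre"]
  expect_equal(w, chg / fit$sigma)
})

test_that("a known standardised effect is recovered at large n", {
  um <- default_utility_mean()
  # residual-sd convention: d = 0.69 at follow-up needs DiD = 0.69 * 0.17
  um$mean <- c(0.50, 0.50, 0.50, 0.50, 0.50, 0.50 + 0.69 * 0.17)
  cfg <- trial_config(n_per_arm = 2000, utility_mean = um)
  an <- simulate_trial(cfg, seed = 17) %>% build_analysis_table(cfg$tariff)
  fit <- fit_outcome_model(an, "eq5d_index")
  expect_lt(abs(cohens_d(fit, "followup", type = "between") - 0.69), 0.05)
})

test_that("remission odds ratios behave at the null and match the 2x2 oracle", {
  rp <- default_remission_prob()
  rp$prob <- rep(c(0.15, 0.25), 2) # same in both arms
  cfg <- trial_config(n_per_arm = 3000, remission_prob = rp)
  trial <- simulate_trial(cfg, seed = 41)
  null_fit <- fit_remission_model(trial)
  expect_true(all(abs(log(null_fit$odds_ratio)) < 0.35))

  cfg2 <- trial_config(n_per_arm = 10000)
  trial2 <- simulate_trial(cfg2, seed = 43)
  or_2x2 <- remission_odds_ratio_2x2(trial2, "post")
  target <- (0.32 / 0.68) / (0.02 / 0.98)
  expect_lt(abs(log(or_2x2$odds_ratio) - log(target)), 0.3)
  expect_true(is.finite(or_2x2$std_error)) # Woolf SE defined despite rare control events
  expect_lt(or_2x2$p_value, 1e-10)
})

test_that("the mixed-logistic estimator reports its method and falls back cleanly", {
  trial <- simulate_trial(trial_config(n_per_arm = 200), seed = 47)
  fit <- fit_remission_model(trial)
  expect_s3_class(fit, "remission_fit")
  expect_true(all(fit$method %in% c("mixed_logistic", "marginal_2x2")))
  expect_true(all(fit$odds_ratio > 0))
  expect_true(all(fit$p_value >= 0 & fit$p_value <= 1))
  # separation-prone data (zero remitters in control) still yields estimates
  rp <- default_remission_prob()
  rp$prob[rp$arm == "control"] <- 0
  tiny <- simulate_trial(trial_config(n_per_arm = 25, remission_prob = rp),
                         seed = 48)
  fb <- fit_remission_model(tiny)
  expect_true(all(is.finite(fb$odds_ratio)))
})

test_that("likelihood-based estimation beats complete cases under MAR dropout", {
  um <- default_utility_mean()
  um$mean <- c(0.50, 0.48, 0.43, 0.50, 0.55, 0.60) # follow-up DiD 0.17
  cr <- default_completion_rate() %>%
    mutate(rate = case_when(
      instrument == "eq5d" & timepoint == "followup" & arm == "intervention" ~ 0.5,
      instrument == "eq5d" & timepoint == "followup" & arm == "control" ~ 0.9,
      TRUE ~ 1
    ))
  cfg <- trial_config(n_per_arm = 500, utility_mean = um,
                      completion_rate = cr, mar_slope = 8)
  est <- purrr::map_dfr(1:30, function(r) {
    masked <- simulate_trial(cfg, seed = 100 + r) %>%
      apply_missingness(cfg, seed = 200 + r) %>%
      build_analysis_table(cfg$tariff)
    ml <- incremental_estimates(masked, outcomes = "qaly", persp = "clinic",
                                timepoints = "followup", method = "mixed")
    cc <- complete_case_filter(masked, "eq5d_index") %>%
      incremental_estimates(outcomes = "qaly", persp = "clinic",
                            timepoints = "followup", method = "cellmeans")
    tibble::tibble(ml = ml$delta_effect, cc = cc$delta_effect)
  })
  bias_ml <- mean(est$ml) - 0.17
  bias_cc <- mean(est$cc) - 0.17
  expect_lt(abs(bias_ml), abs(bias_cc))
  expect_lt(abs(bias_ml), 0.012)
  expect_gt(abs(bias_cc), 0.015)
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- fit_outcome_model(small_analysis(n = 12, seed = 6), "eq5d_index")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "p_value") %in% names(td)))
  expect_true("armintervention:timepointpost" %in% td$term)
  lsm <- tidy(fit, effects = "ls_means")
  expect_equal(nrow(lsm), 6)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_gte(gl$sigma, 0)
  expect_equal(gl$method, "ML")
})
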