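# Mean of a normal variable clipped (not truncated) to [a, b].
# With z_a = (a - mu)/s, z_b = (b - mu)/s:
#   E = a P(X < a) + b P(X > b) + mu (Phi(z_b) - Phi(z_a)) - s (phi(z_b) - phi(z_a))
clipped_normal_mean <- function(mu, sigma, a, b) {
  if (sigma == 0) return(pmin(pmax(mu, a), b))
  za <- (a - mu) / sigma
  zb <- (b - mu) / sigma
  a * pnorm(za) + b * (1 - pnorm(zb)) +
    mu * (pnorm(zb) - pnorm(za)) - sigma * (dnorm(zb) - dnorm(za))
}

# Solve for the latent location whose clipped mean equals `target`;
# monotone in mu, so uniroot is safe.
solve_clip_location <- function(target, sigma, a, b) {
  if (sigma == 0) return(target)
  uniroot(
    function(mu) clipped_normal_mean(mu, sigma, a, b) - target,
    interval = c(a - 10 * sigma, b + 10 * sigma),
    tol = 1e-10
  )$root
}

#' Generate a complete synthetic two-arm trial
#'
#' Draws one record per participant x timepoint. Remission is Bernoulli with
#' the configured arm x timepoint probability, made persistent across
#' timepoints through a shared per-participant latent uniform (a participant
#' in remission at post stays in remission at follow-up whenever the
#' follow-up probability is at least the post probability). EQ-5D indices
#' follow a random-intercept model (participant intercept SD
#' `random_intercept_sd`, residual SD `utility_sd`) around the configured
#' cell means, clipped to the value-set range with a mean-preserving latent
#' location adjustment. Visit counts, medication units and sick-leave days
#' are negative binomial, domestic cutback hours gamma, and unemployment a
#' persistent Bernoulli flag — together reproducing the right skew and zero
#' inflation typical of resource-use questionnaire data.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; defaults to `config$seed`. The same seed always
#'   reproduces the same table.
#' @return A tibble of `2 * n_per_arm * length(timepoints)` rows with
#'   columns `participant_id`, `arm`, `timepoint`, `remission` (NA at
#'   pre-treatment by construction), `eq5d_index`, the four count items,
#'   `sick_leave_days`, `domestic_cutback_hours` and logical `unemployed`.
#' @examples
#' trial <- simulate_trial(trial_config(n_per_arm = 5), seed = 1)
#' @export
simulate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(seed)
  n <- config$n_per_arm
  n_tot <- 2L * n
  participants <- tibble(
    participant_id = sprintf("P%04d", seq_len(n_tot)),
    arm = rep(.arms, each = n),
    intercept = rnorm(n_tot, 0, config$random_intercept_sd),
    u_remit = runif(n_tot),
    u_unemp = runif(n_tot)
  )

  sigma_tot <- sqrt(config$random_intercept_sd^2 + config$utility_sd^2)
  cells <- config$utility_mean %>%
    mutate(location = purrr::map_dbl(
      .data$mean, solve_clip_location,
      sigma = sigma_tot,
      a = config$utility_range[1], b = config$utility_range[2]
    ))

  grid <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    timepoint = config$timepoints
  ) %>%
    left_join(participants, by = "participant_id") %>%
    left_join(cells, by = c("arm", "timepoint")) %>%
    left_join(config$remission_prob, by = c("arm", "timepoint")) %>%
    rename(p_remit = "prob") %>%
    left_join(config$unemployment_prob, by = c("arm", "timepoint")) %>%
    rename(p_unemp = "prob")

  m <- nrow(grid)
  eq5d <- grid$location + grid$intercept + rnorm(m, 0, config$utility_sd)
  eq5d <- pmin(pmax(eq5d, config$utility_range[1]), config$utility_range[2])

  items <- config$cost_item_rates %>%
    tidyr::pivot_wider(names_from = "item", values_from = "rate")
  grid <- grid %>% left_join(items, by = c("arm", "timepoint"))
  disp <- config$cost_dispersion
  draw_item <- function(item) {
    mu <- grid[[item]]
    if (item == "domestic_cutback_hours") {
      shape <- disp[[item]]
      out <- ifelse(mu > 0, rgamma(m, shape = shape, scale = mu / shape), 0)
    } else {
      out <- rnbinom(m, size = disp[[item]], mu = mu)
    }
    out
  }
  item_names <- setdiff(unique(config$cost_item_rates$item), "unemployed")
  item_draws <- lapply(setNames(item_names, item_names), draw_item)

  out <- tibble(
    participant_id = grid$participant_id,
    arm = as_arm(grid$arm),
    timepoint = as_timepoint(grid$timepoint, config$timepoints),
    remission = ifelse(is.na(grid$p_remit), NA_integer_,
                       as.integer(grid$u_remit < grid$p_remit)),
    eq5d_index = eq5d
  ) %>%
    dplyr::bind_cols(as_tibble(item_draws)) %>%
    mutate(unemployed = grid$u_unemp < grid$p_unemp) %>%
    arrange(.data$participant_id, .data$timepoint)
  out
}

#' Impose missing-at-random dropout on a complete trial table
#'
#' For each instrument (`diagnostic` for the remission interview, `eq5d`,
#' `ticp` for the resource-use questionnaire) and each post-baseline
#' timepoint, values are set missing so that (i) the marginal completion
#' rate matches the configured arm x timepoint x instrument rate and (ii)
#' the probability of completion depends on the participant's observed
#' baseline utility (logit-linear with slope `mar_slope`), giving a genuine
#' missing-at-random mechanism: missingness is related to the observed
#' baseline but conditionally independent of the unobserved value.
#' The intercept of the logistic model is solved numerically against the
#' empirical baseline-utility distribution so the target marginal holds.
#' Pre-treatment records are never made missing.
#'
#' @param data Complete table from [simulate_trial()].
#' @param config The [trial_config()] that produced it.
#' @param seed Integer seed (default `config$seed + 1` so that generation
#'   and dropout use distinct streams).
#' @return The table with NA values inserted; `ticp` missingness blanks all
#'   resource item columns of the row.
#' @export
apply_missingness <- function(data, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "trial_config"))
  check_trial_table(data, c("remission", "eq5d_index"))
  check_prob_tbl(config$completion_rate, "rate", "completion_rate")
  set.seed(seed)

  baseline <- data %>%
    filter(as.character(.data$timepoint) == config$timepoints[1]) %>%
    select(all_of(c("participant_id", "eq5d_index"))) %>%
    rename(u_base = "eq5d_index")
  out <- data %>% left_join(baseline, by = "participant_id")
  u_centred <- out$u_base - mean(out$u_base)

  instrument_cols <- list(
    diagnostic = "remission",
    eq5d = "eq5d_index",
    ticp = intersect(resource_item_cols(config$tariff), names(data))
  )

  for (i in seq_len(nrow(config$completion_rate))) {
    row <- config$completion_rate[i, ]
    if (row$rate >= 1 || row$timepoint == config$timepoints[1]) next
    idx <- which(as.character(out$arm) == row$arm &
                   as.character(out$timepoint) == row$timepoint)
    if (length(idx) == 0) next
    x <- config$mar_slope * u_centred[idx]
    # completion probability plogis(a + slope * centred baseline utility);
    # intercept solved so the in-sample mean completion hits the target
    a <- if (config$mar_slope == 0) qlogis(row$rate) else {
      uniroot(function(a) mean(plogis(a + x)) - row$rate,
              interval = c(-50, 50), tol = 1e-10)$root
    }
    observed <- runif(length(idx)) < plogis(a + x)
    cols <- instrument_cols[[row$instrument]]
    for (col in cols) {
      out[[col]][idx[!observed]] <- NA
    }
  }
  out %>% select(-all_of("u_base"))
}
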