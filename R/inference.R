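#' Fit the repeated-measures mixed model for an outcome or cost
#'
#' Fits, by maximum likelihood, a linear mixed model with fixed effects of
#' group, time (categorical, pre-treatment as reference), their interaction,
#' and a participant-level random intercept:
#' `outcome ~ arm * timepoint + (1 | participant_id)`. Missing outcome
#' values are handled by the likelihood (no imputation), which is valid
#' under missing-at-random dropout. The group x time interaction
#' coefficients are the difference-in-differences contrasts the
#' cost-effectiveness analysis is built on.
#'
#' @param data Participant x timepoint table.
#' @param outcome Name of the numeric outcome column (an EQ-5D index or a
#'   perspective cost column such as `cost_societal`).
#' @return An object of class `cea_mixed_fit`: the lme4 fit plus
#'   least-squares means per arm x timepoint (with Wald 95% CIs), residual
#'   and random-intercept SDs, and a convergence flag. Non-convergence is
#'   flagged, never silent.
#' @examples
#' trial <- simulate_trial(trial_config(n_per_arm = 20), seed = 1)
#' fit <- fit_outcome_model(trial, "eq5d_index")
#' did_contrast(fit, "followup")
#' @export
fit_outcome_model <- function(data, outcome) {
  check_trial_table(data, outcome)
  df <- tibble(
    participant_id = data$participant_id,
    arm = as_arm(data$arm),
    timepoint = droplevels(as_timepoint(data$timepoint)),
    y = data[[outcome]]
  )
  if (!is.numeric(df$y)) abort("`outcome` must be a numeric column")
  if (nlevels(df$arm) < 2 || nlevels(df$timepoint) < 2) {
    abort("need >= 2 arms and >= 2 timepoints")
  }
  obs <- df %>% filter(!is.na(.data$y))
  cell_n <- obs %>% dplyr::count(.data$arm, .data$timepoint, .drop = FALSE)
  if (any(cell_n$n == 0)) abort("an arm x timepoint cell has no observed values")

  converged <- TRUE
  model <- withCallingHandlers(
    lme4::lmer(
      y ~ arm * timepoint + (1 | participant_id),
      data = df, REML = FALSE,
      control = lme4::lmerControl(optCtrl = list(maxfun = 200000)),
      na.action = na.omit
    ),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )

  vc <- as.data.frame(lme4::VarCorr(model))
  tau <- sqrt(vc$vcov[vc$grp == "participant_id"])
  res_sigma <- stats::sigma(model)

  structure(
    list(
      model = model,
      outcome = outcome,
      ls_means = ls_means_grid(model),
      sigma = res_sigma,
      tau = tau,
      converged = converged,
      method = "ML",
      n_obs = nrow(obs),
      n_participants = dplyr::n_distinct(obs$participant_id)
    ),
    class = "cea_mixed_fit"
  )
}

# fixed-effect cell means (least-squares means): X beta on the full
# arm x timepoint grid, Wald SEs from the fixed-effect covariance
ls_means_grid <- function(model) {
  fr <- model@frame
  grid <- tidyr::expand_grid(
    arm = factor(levels(fr$arm), levels = levels(fr$arm)),
    timepoint = factor(levels(fr$timepoint), levels = levels(fr$timepoint))
  )
  X <- model.matrix(~ arm * timepoint, data = grid)
  beta <- lme4::fixef(model)
  V <- as.matrix(vcov(model))
  est <- unname(drop(X %*% beta))
  se <- unname(sqrt(diag(X %*% V %*% t(X))))
  grid %>%
    mutate(
      estimate = est,
      std_error = se,
      ci_lower = est - qnorm(0.975) * se,
      ci_upper = est + qnorm(0.975) * se
    )
}

#' Difference-in-differences contrast at a timepoint
#'
#' Returns the group x time interaction coefficient at the requested
#' timepoint: the intervention arm's change from pre-treatment minus the
#' control arm's change. Positive values mean larger increases under the
#' intervention (for costs: intervention costlier).
#'
#' @param fit A `cea_mixed_fit`.
#' @param timepoint A post-baseline timepoint label (not the reference).
#' @return One-row tibble `(outcome, timepoint, estimate, std_error)`.
#' @export
did_contrast <- function(fit, timepoint) {
  stopifnot(inherits(fit, "cea_mixed_fit"))
  tps <- levels(fit$model@frame$timepoint)
  if (length(timepoint) != 1 || !timepoint %in% tps) {
    abort(paste0("`timepoint` must be one of: ", paste(tps, collapse = ", ")))
  }
  if (timepoint == tps[1]) {
    abort("no change from baseline is defined at the pre-treatment reference")
  }
  term <- paste0("armintervention:timepoint", timepoint)
  beta <- lme4::fixef(fit$model)
  if (!term %in% names(beta)) abort(paste0("coefficient ", term, " not in model"))
  tibble(
    outcome = fit$outcome,
    timepoint = timepoint,
    estimate = unname(beta[term]),
    std_error = sqrt(as.matrix(vcov(fit$model))[term, term])
  )
}

#' Incremental QALY effect from a utility model
#'
#' The incremental QALY at a timepoint is the difference-in-differences of
#' EQ-5D index values: the arm contrast of change from pre-treatment,
#' i.e. the group x time interaction coefficient.
#'
#' @inheritParams did_contrast
#' @return One-row tibble as [did_contrast()].
#' @export
qaly_effect <- function(fit, timepoint) {
  stopifnot(inherits(fit, "cea_mixed_fit"))
  if (!grepl("eq5d", fit$outcome)) {
    abort("`qaly_effect()` expects a model fitted on an EQ-5D index outcome")
  }
  did_contrast(fit, timepoint)
}

#' Likelihood-ratio test of the group x time interaction
#'
#' Compares the ML fit against the same model without the interaction.
#'
#' @param fit A `cea_mixed_fit`.
#' @return Tibble `(statistic, df, p_value)`.
#' @export
interaction_test <- function(fit) {
  stopifnot(inherits(fit, "cea_mixed_fit"))
  reduced <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ arm + timepoint + (1 | participant_id),
               data = fit$model@frame, REML = FALSE)
  ))
  chisq <- as.numeric(2 * (logLik(fit$model) - logLik(reduced)))
  chisq <- max(chisq, 0)
  df <- attr(logLik(fit$model), "df") - attr(logLik(reduced), "df")
  tibble(
    statistic = chisq,
    df = df,
    p_value = pchisq(chisq, df, lower.tail = FALSE)
  )
}

#' Standardised effect sizes from the mixed model
#'
#' Cohen's d for model-based contrasts: between-group d divides the
#' difference-in-differences contrast at `timepoint` by sigma; within-group
#' d divides one arm's change from pre-treatment (difference of
#' least-squares means) by sigma. The default sigma is the model's residual
#' SD; `sigma = "total"` uses `sqrt(intercept variance + residual variance)`
#' instead (both conventions are found in practice — the residual-SD default
#' is this package's primary convention).
#'
#' @param fit A `cea_mixed_fit`.
#' @param timepoint Post-baseline timepoint.
#' @param type `"between"` (difference-in-differences) or `"within"` (one
#'   arm's change).
#' @param arm Arm for `type = "within"`.
#' @param sigma `"residual"` or `"total"`.
#' @return Numeric effect size.
#' @export
cohens_d <- function(fit, timepoint, type = c("between", "within"),
                     arm = "intervention", sigma = c("residual", "total")) {
  stopifnot(inherits(fit, "cea_mixed_fit"))
  type <- match.arg(type)
  sigma <- match.arg(sigma)
  s <- if (sigma == "residual") fit$sigma else sqrt(fit$sigma^2 + fit$tau^2)
  if (!is.finite(s) || s <= 0) abort("sigma of the fitted model is zero")
  if (type == "between") {
    est <- did_contrast(fit, timepoint)$estimate
  } else {
    lm <- fit$ls_means
    tps <- levels(lm$timepoint)
    if (timepoint == tps[1]) abort("no within-arm change at the reference timepoint")
    est <- lm$estimate[lm$arm == arm & lm$timepoint == timepoint] -
      lm$estimate[lm$arm == arm & lm$timepoint == tps[1]]
  }
  est / s
}

#' Mixed-effects logistic model for remission
#'
#' Fits `remission ~ arm * timepoint + (1 | participant_id)` by Laplace
#' approximation on the post-baseline timepoints and returns the
#' arm odds ratio at each timepoint with a delta-method SE on the OR scale.
#' If the fit fails or does not converge (e.g. quasi-separation when one
#' arm has almost no remitters), the estimator falls back to per-timepoint
#' marginal 2x2 odds ratios with the Haldane-Anscombe 0.5 correction; the
#' `method` column records which estimator produced each row.
#'
#' @param data Participant table with `remission` in \{0, 1, NA\}.
#' @return Tibble of class `remission_fit`:
#'   `(timepoint, odds_ratio, std_error, statistic, p_value, method)`.
#' @export
fit_remission_model <- function(data) {
  check_trial_table(data, "remission")
  df <- data %>%
    filter(!is.na(.data$remission)) %>%
    mutate(
      arm = as_arm(.data$arm),
      timepoint = droplevels(as_timepoint(.data$timepoint))
    )
  tps <- levels(df$timepoint)

  mixed <- tryCatch({
    converged <- TRUE
    model <- withCallingHandlers(
      lme4::glmer(remission ~ arm * timepoint + (1 | participant_id),
                  data = df, family = binomial()),
      warning = function(w) {
        if (grepl("converge|Hessian|unable to evaluate", conditionMessage(w),
                  ignore.case = TRUE)) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage")
    )
    beta <- lme4::fixef(model)
    if (!converged || any(abs(beta) > 15)) NULL else model
  }, error = function(e) NULL)

  if (!is.null(mixed)) {
    V <- as.matrix(vcov(mixed))
    beta <- lme4::fixef(mixed)
    rows <- purrr::map_dfr(tps, function(tp) {
      terms <- "armintervention"
      if (tp != tps[1]) {
        terms <- c(terms, paste0("armintervention:timepoint", tp))
      }
      est <- sum(beta[terms])
      se_log <- sqrt(sum(V[terms, terms]))
      tibble(
        timepoint = tp,
        odds_ratio = exp(est),
        std_error = exp(est) * se_log, # delta method, OR scale
        statistic = est / se_log,
        p_value = 2 * pnorm(-abs(est / se_log)),
        method = "mixed_logistic"
      )
    })
  } else {
    rows <- purrr::map_dfr(tps, function(tp) {
      remission_odds_ratio_2x2(df, tp) %>% mutate(method = "marginal_2x2")
    })
  }
  structure(rows, class = c("remission_fit", class(rows)))
}

#' Marginal 2x2 odds ratio of remission at one timepoint
#'
#' Model-free cross-check for [fit_remission_model()]: the odds ratio from
#' the arm x remission 2x2 table, with an optional Haldane-Anscombe
#' continuity correction applied when any cell is empty.
#'
#' @param data Participant table.
#' @param timepoint Timepoint to tabulate.
#' @param correction Amount added to every cell when a zero cell occurs.
#' @return One-row tibble `(timepoint, odds_ratio, std_error, statistic,
#'   p_value)` with Woolf (log-scale) standard errors mapped to the OR
#'   scale by the delta method.
#' @export
remission_odds_ratio_2x2 <- function(data, timepoint, correction = 0.5) {
  sub <- data %>%
    filter(as.character(.data$timepoint) == !!timepoint,
           !is.na(.data$remission))
  if (nrow(sub) == 0) abort("no observed remission values at this timepoint")
  counts <- sub %>%
    group_by(arm = as.character(.data$arm)) %>%
    summarise(events = sum(.data$remission), n = dplyr::n(), .groups = "drop")
  a <- counts$events[counts$arm == "intervention"]
  b <- counts$n[counts$arm == "intervention"] - a
  c <- counts$events[counts$arm == "control"]
  d <- counts$n[counts$arm == "control"] - c
  if (min(a, b, c, d) == 0) {
    a <- a + correction; b <- b + correction
    c <- c + correction; d <- d + correction
  }
  log_or <- log(a * d / (b * c))
  se_log <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(
    timepoint = timepoint,
    odds_ratio = exp(log_or),
    std_error = exp(log_or) * se_log,
    statistic = log_or / se_log,
    p_value = 2 * pnorm(-abs(log_or / se_log))
  )
}

# ---- broom-style methods ----

#' Tidy a mixed-model fit
#'
#' @param x A `cea_mixed_fit`.
#' @param effects `"fixed"` for coefficient rows, `"ls_means"` for the
#'   arm x timepoint least-squares means.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cea_mixed_fit <- function(x, effects = c("fixed", "ls_means"), ...) {
  effects <- match.arg(effects)
  if (effects == "ls_means") {
    return(x$ls_means %>% mutate(outcome = x$outcome, .before = 1))
  }
  beta <- lme4::fixef(x$model)
  se <- sqrt(diag(as.matrix(vcov(x$model))))
  tibble(
    outcome = x$outcome,
    term = names(beta),
    estimate = unname(beta),
    std_error = unname(se),
    statistic = unname(beta / se),
    p_value = 2 * pnorm(-abs(beta / se))
  )
}

#' Glance at a mixed-model fit
#'
#' @param x A `cea_mixed_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit summaries.
#' @export
glance.cea_mixed_fit <- function(x, ...) {
  tibble(
    outcome = x$outcome,
    sigma = x$sigma,
    tau = x$tau,
    log_lik = as.numeric(logLik(x$model)),
    aic = AIC(x$model),
    n_obs = x$n_obs,
    n_participants = x$n_participants,
    converged = x$converged,
    method = x$method
  )
}

#' @export
print.cea_mixed_fit <- function(x, ...) {
  cat("<cea_mixed_fit> outcome:", x$outcome, "(ML",
      if (!x$converged) "- DID NOT CONVERGE" else "", ")\n")
  cat("  residual SD:", format(x$sigma, digits = 4),
      " intercept SD:", format(x$tau, digits = 4), "\n")
  print(x$ls_means, n = Inf)
  invisible(x)
}
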