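#' Incremental cost-effectiveness ratio
#'
#' The between-group difference in mean cost divided by the between-group
#' difference in mean effect. Undefined when the incremental effect is
#' zero: such elements are returned as `NA` with a warning, never as a
#' silent infinity.
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_effect Incremental effect (remission proportion difference
#'   or QALY difference); recycled against `delta_cost`.
#' @return USD per unit effect.
#' @examples
#' icer(1231, 0.30)
#' @export
icer <- function(delta_cost, delta_effect) {
  out <- delta_cost / delta_effect
  zero <- !is.na(delta_effect) & delta_effect == 0
  if (any(zero)) {
    warn("ICER undefined where `delta_effect` is zero; returning NA")
    out[zero] <- NA_real_
  }
  out
}

#' Net monetary benefit
#'
#' `lambda * delta_effect - delta_cost`: positive means cost-effective at a
#' willingness-to-pay of `lambda` per unit effect. For a positive
#' incremental effect the net benefit is zero exactly at `lambda = ICER`.
#'
#' @param lambda Willingness to pay (USD per unit effect, >= 0).
#' @param delta_effect Incremental effect.
#' @param delta_cost Incremental cost (USD).
#' @return USD.
#' @export
net_benefit <- function(lambda, delta_effect, delta_cost) {
  if (any(lambda < 0, na.rm = TRUE)) abort("`lambda` must be nonnegative")
  lambda * delta_effect - delta_cost
}

#' Default willingness-to-pay grid
#'
#' $0 to $60,000 in $1,000 steps, covering commonly cited thresholds for a
#' QALY and for a case in remission.
#'
#' @return Ascending numeric vector.
#' @export
default_lambda_grid <- function() seq(0, 60000, by = 1000)

#' Nonparametric bootstrap of incremental costs and effects
#'
#' Resamples participants (all their timepoints) with replacement,
#' stratified by arm with arm sizes preserved, and re-estimates the
#' incremental cost and incremental effect on each replicate:
#' * costs and QALYs via the group x time interaction of the
#'   random-intercept mixed model (`method = "mixed"`), or via observed
#'   cell-mean difference-in-differences (`method = "cellmeans"`, a fast
#'   approximation);
#' * remission effects via the model-free difference in observed arm
#'   remission proportions at each timepoint (the scale on which
#'   cost-effectiveness ICERs per case in remission are expressed).
#'
#' The clinic perspective books its one-off treatment-provision cost at
#' post-treatment, so its incremental cost at follow-up reuses the
#' post-treatment contrast (a cumulative one-off cost, not a recurring
#' flow). Replicates whose mixed-model refit fails are redrawn; the number
#' of redraws is recorded in the `n_redraws` attribute.
#'
#' @param data Analysis table: one row per participant x timepoint with
#'   `eq5d_index`, `remission` and `cost_<perspective>` columns (see
#'   [compute_costs()]).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; same seed, same replicate set.
#' @param outcomes Subset of `c("remission", "qaly")`.
#' @param perspectives Subset of [perspectives()].
#' @param timepoints Post-baseline timepoints to contrast.
#' @param method `"mixed"` (refit mixed models per replicate) or
#'   `"cellmeans"`.
#' @return Tibble of class `cea_replicates`: `(replicate, timepoint,
#'   perspective, outcome, delta_cost, delta_effect)`.
#' @examples
#' cfg <- trial_config(n_per_arm = 15)
#' trial <- simulate_trial(cfg, seed = 1)
#' tab <- dplyr::left_join(trial, compute_costs(trial, cfg$tariff),
#'                         by = c("participant_id", "arm", "timepoint"))
#' reps <- bootstrap_cea(tab, B = 20, seed = 1, method = "cellmeans")
#' quadrant_proportions(reps)
#' @export
bootstrap_cea <- function(data, B = 1000, seed = NULL,
                          outcomes = c("remission", "qaly"),
                          perspectives = c("societal", "health_care", "clinic"),
                          timepoints = c("post", "followup"),
                          method = c("mixed", "cellmeans")) {
  method <- match.arg(method)
  outcomes <- match.arg(outcomes, c("remission", "qaly"), several.ok = TRUE)
  bad <- setdiff(perspectives, perspectives())
  if (length(bad) > 0) {
    abort(paste0("unknown perspective(s): ", paste(bad, collapse = ", ")))
  }
  cost_cols <- paste0("cost_", perspectives)
  check_trial_table(data, c("eq5d_index", "remission", cost_cols))
  if (B < 1) abort("`B` must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  ids <- data %>% distinct(.data$participant_id, .data$arm)
  ids_by_arm <- split(ids$participant_id, as.character(ids$arm))
  rows_by_id <- split(seq_len(nrow(data)), data$participant_id)

  one_replicate <- function(b) {
    sampled <- unlist(lapply(ids_by_arm, function(x) {
      sample(x, length(x), replace = TRUE)
    }), use.names = FALSE)
    idx <- rows_by_id[sampled]
    boot <- data[unlist(idx, use.names = FALSE), ]
    # resampled participants get fresh ids so duplicates stay distinct
    boot$participant_id <- rep(seq_along(sampled), lengths(idx))
    estimate_increments(boot, outcomes, perspectives, timepoints, method) %>%
      mutate(replicate = b, .before = 1)
  }

  n_redraws <- 0L
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    est <- NULL
    for (try in 1:10) {
      est <- tryCatch(one_replicate(b), error = function(e) NULL)
      if (!is.null(est)) break
      n_redraws <- n_redraws + 1L
    }
    if (is.null(est)) abort("bootstrap replicate failed after 10 redraws")
    reps[[b]] <- est
  }
  out <- bind_rows(reps)
  structure(out,
            class = c("cea_replicates", class(out)),
            B = B, seed = seed, method = method, n_redraws = n_redraws)
}

#' Incremental cost and effect estimates on one dataset
#'
#' The estimator applied to the full sample and to every bootstrap
#' replicate: incremental costs and QALYs as group x time
#' difference-in-differences (mixed-model interaction coefficients, or
#' observed cell-mean arithmetic in the fast `"cellmeans"` mode) and
#' incremental remission as the difference in observed arm proportions.
#' The clinic perspective's one-off treatment cost at post-treatment
#' carries forward to follow-up.
#'
#' @inheritParams bootstrap_cea
#' @param persp Perspectives to cost.
#' @return Tibble `(timepoint, perspective, outcome, delta_cost,
#'   delta_effect)`.
#' @export
incremental_estimates <- function(data, outcomes = c("remission", "qaly"),
                                  persp = c("societal", "health_care", "clinic"),
                                  timepoints = c("post", "followup"),
                                  method = c("mixed", "cellmeans")) {
  method <- match.arg(method)
  estimate_increments(data, outcomes, persp, timepoints, method)
}

# constant within every arm x timepoint cell (no residual variation)?
is_degenerate_outcome <- function(data, col) {
  v <- data %>%
    filter(!is.na(.data[[col]])) %>%
    group_by(.data$arm, .data$timepoint) %>%
    summarise(v = var(.data[[col]]), .groups = "drop") %>%
    pull(.data$v)
  all(is.na(v) | v == 0)
}

# point/replicate estimator of (delta_cost, delta_effect) per
# timepoint x perspective x outcome
estimate_increments <- function(data, outcomes, persp, timepoints, method) {
  did_of <- function(col) {
    # a column that is constant within every arm x timepoint cell (e.g. the
    # fixed per-arm treatment-provision cost) makes the mixed model
    # degenerate; cell-mean arithmetic is exact there
    if (method == "mixed" && !is_degenerate_outcome(data, col)) {
      fit <- fit_outcome_model(data, col)
      purrr::map_dbl(timepoints, function(tp) did_contrast(fit, tp)$estimate)
    } else {
      cells <- data %>%
        group_by(arm = as.character(.data$arm),
                 timepoint = as.character(.data$timepoint)) %>%
        summarise(m = mean(.data[[col]], na.rm = TRUE), .groups = "drop")
      cell <- function(a, tp) cells$m[cells$arm == a & cells$timepoint == tp]
      purrr::map_dbl(timepoints, function(tp) {
        (cell("intervention", tp) - cell("intervention", "pre")) -
          (cell("control", tp) - cell("control", "pre"))
      })
    }
  }

  dcost <- purrr::map_dfr(persp, function(p) {
    est <- did_of(paste0("cost_", p))
    # clinic: one-off treatment cost booked at post carries forward
    if (p == "clinic" && "post" %in% timepoints) {
      est[] <- est[timepoints == "post"]
    }
    tibble(timepoint = timepoints, perspective = p, delta_cost = est)
  })

  deff <- list()
  if ("qaly" %in% outcomes) {
    q <- did_of("eq5d_index")
    deff$qaly <- tibble(timepoint = timepoints, outcome = "qaly",
                        delta_effect = q)
  }
  if ("remission" %in% outcomes) {
    props <- data %>%
      filter(!is.na(.data$remission),
             as.character(.data$timepoint) %in% timepoints) %>%
      group_by(arm = as.character(.data$arm),
               timepoint = as.character(.data$timepoint)) %>%
      summarise(p = mean(.data$remission), .groups = "drop")
    r <- purrr::map_dbl(timepoints, function(tp) {
      pi <- props$p[props$arm == "intervention" & props$timepoint == tp]
      pc <- props$p[props$arm == "control" & props$timepoint == tp]
      if (length(pi) == 0 || length(pc) == 0) {
        abort("no observed remission values in an arm")
      }
      pi - pc
    })
    deff$remission <- tibble(timepoint = timepoints, outcome = "remission",
                             delta_effect = r)
  }
  tidyr::expand_grid(persp = persp, eff = bind_rows(deff)) %>%
    tidyr::unpack("eff") %>%
    rename(perspective = "persp") %>%
    left_join(dcost, by = c("timepoint", "perspective")) %>%
    select(all_of(c("timepoint", "perspective", "outcome",
                    "delta_cost", "delta_effect")))
}

#' Cost-effectiveness plane quadrant proportions
#'
#' Classifies each bootstrap replicate by the signs of its incremental
#' effect (x-axis) and incremental cost (y-axis): northeast = more
#' effective and more costly, northwest = less effective and more costly,
#' southeast = more effective and cost-saving, southwest = less effective
#' and cost-saving. Exact zeroes (a measure-zero event) are assigned to the
#' positive side of the axis. Proportions sum to exactly 1 within each
#' timepoint x perspective x outcome stratum.
#'
#' @param replicates A `cea_replicates` tibble.
#' @return Tibble with grouping columns and `ne`, `nw`, `se`, `sw`.
#' @export
quadrant_proportions <- function(replicates) {
  if (nrow(replicates) == 0) abort("empty replicate set")
  replicates %>%
    group_by(.data$timepoint, .data$perspective, .data$outcome) %>%
    summarise(
      ne = mean(.data$delta_effect >= 0 & .data$delta_cost >= 0),
      nw = mean(.data$delta_effect < 0 & .data$delta_cost >= 0),
      se = mean(.data$delta_effect >= 0 & .data$delta_cost < 0),
      sw = mean(.data$delta_effect < 0 & .data$delta_cost < 0),
      .groups = "drop"
    )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value the probability of cost-effectiveness
#' is the fraction of bootstrap replicates with strictly positive net
#' benefit (ties at exactly zero count as not cost-effective). At
#' `lambda = 0` the curve equals the fraction of cost-saving replicates;
#' as `lambda` grows it approaches the fraction with a positive
#' incremental effect, and it is monotone non-decreasing whenever every
#' replicate's incremental effect is nonnegative.
#'
#' @param replicates A `cea_replicates` tibble.
#' @param lambda_grid Strictly ascending nonnegative grid (USD per unit
#'   effect).
#' @return Tibble of class `ceac_curve`: grouping columns plus `lambda`
#'   and `probability` in `[0, 1]`.
#' @export
ceac <- function(replicates, lambda_grid = default_lambda_grid()) {
  if (nrow(replicates) == 0) abort("empty replicate set")
  if (length(lambda_grid) == 0) abort("empty `lambda_grid`")
  if (any(diff(lambda_grid) <= 0)) abort("`lambda_grid` must be strictly ascending")
  out <- replicates %>%
    as_tibble() %>%
    tidyr::expand_grid(lambda = lambda_grid) %>%
    group_by(.data$timepoint, .data$perspective, .data$outcome, .data$lambda) %>%
    summarise(
      probability = mean(
        net_benefit(.data$lambda[1], .data$delta_effect, .data$delta_cost) > 0
      ),
      .groups = "drop"
    ) %>%
    arrange(.data$timepoint, .data$perspective, .data$outcome, .data$lambda)
  structure(out, class = c("ceac_curve", class(out)))
}
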