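#' Tariff table of unit costs and costing rates
#'
#' Bundles every monetary constant needed to turn TIC-P style resource-use
#' counts into money: Swedish-tariff unit costs per visit/medication item,
#' the human-capital hourly wage for productivity losses, the hourly rate
#' for domestic work cutback, the fixed per-period cost of unemployment,
#' the purchasing-power SEK/USD conversion, and the per-arm cost of
#' providing treatment.
#'
#' Defaults reflect 2014 Swedish conditions: a gross hourly wage of 188 SEK,
#' domestic work at 14 EUR/hour, unemployment fixed at 24000 SEK per 12-week
#' period (80% of a mean monthly salary), and 6.861 SEK per USD (purchasing
#' power parity). Visit and medication unit costs are editable placeholders
#' in the style of official Swedish health-care tariff listings.
#'
#' @param unit_cost_sek Named numeric, SEK per unit for count items
#'   (visits, medication).
#' @param hourly_wage_sek Gross hourly wage in SEK used by the human-capital
#'   approach for sick-leave days.
#' @param domestic_hourly_eur Hourly rate in EUR for domestic work cutback.
#' @param eur_to_sek EUR to SEK exchange rate.
#' @param unemployment_fixed_sek Fixed cost of unemployment in SEK per
#'   12-week assessment period (not recall-extrapolated).
#' @param sek_per_usd SEK paid per USD (purchasing power parity).
#' @param hours_per_workday Hours of work lost per sick-leave day.
#' @param treatment_cost_usd Named numeric (control, intervention): cost of
#'   providing treatment per participant in USD, booked once at
#'   post-treatment.
#' @param recall_weeks Recall window of the resource-use questionnaire.
#' @param period_weeks Full period between assessments that recall-window
#'   amounts are extrapolated to.
#'
#' @return A list of class `tariff_table`.
#' @examples
#' tariff <- tariff_table()
#' convert_sek_to_usd(tariff$unemployment_fixed_sek, tariff$sek_per_usd)
#' @export
tariff_table <- function(unit_cost_sek = c(
                           primary_care_visits = 1700,
                           specialist_visits = 2600,
                           psychiatric_visits = 2400,
                           medication_units = 300
                         ),
                         hourly_wage_sek = 188,
                         domestic_hourly_eur = 14,
                         eur_to_sek = 9.10,
                         unemployment_fixed_sek = 24000,
                         sek_per_usd = 6.861,
                         hours_per_workday = 8,
                         treatment_cost_usd = c(control = 461, intervention = 946),
                         recall_weeks = 4,
                         period_weeks = 12) {
  scalars <- c(hourly_wage_sek, domestic_hourly_eur, eur_to_sek,
               unemployment_fixed_sek, sek_per_usd, hours_per_workday,
               recall_weeks, period_weeks)
  if (any(!is.finite(scalars)) || any(scalars <= 0)) {
    abort("all tariff rates must be strictly positive and finite")
  }
  if (is.null(names(unit_cost_sek)) || any(unit_cost_sek <= 0)) {
    abort("`unit_cost_sek` must be a named vector of strictly positive costs")
  }
  if (!all(.arms %in% names(treatment_cost_usd)) || any(treatment_cost_usd < 0)) {
    abort("`treatment_cost_usd` needs nonnegative 'control' and 'intervention' entries")
  }
  structure(
    list(
      unit_cost_sek = unit_cost_sek,
      hourly_wage_sek = hourly_wage_sek,
      domestic_hourly_eur = domestic_hourly_eur,
      eur_to_sek = eur_to_sek,
      unemployment_fixed_sek = unemployment_fixed_sek,
      sek_per_usd = sek_per_usd,
      hours_per_workday = hours_per_workday,
      treatment_cost_usd = treatment_cost_usd,
      recall_weeks = recall_weeks,
      period_weeks = period_weeks
    ),
    class = "tariff_table"
  )
}

#' Read visit/medication unit costs from a tariff CSV
#'
#' The CSV must have columns `item` and `unit_cost_sek`; all other tariff
#' scalars are taken from `...` (passed to [tariff_table()]).
#'
#' @param path Path to a CSV file.
#' @param ... Scalar tariff overrides forwarded to [tariff_table()].
#' @return A `tariff_table`.
#' @export
read_tariff_table <- function(path, ...) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    item = readr::col_character(),
    unit_cost_sek = readr::col_double()
  ))
  tariff_table(unit_cost_sek = setNames(tab$unit_cost_sek, tab$item), ...)
}

#' Extrapolate a recall-window amount to the full assessment period
#'
#' Resource use is recorded over a short recall window (e.g. "in the past 4
#' weeks") and scaled linearly to cover the full period between assessments.
#'
#' @param amount Numeric amount(s) recorded over the recall window.
#' @param recall_weeks Length of the recall window in weeks (> 0).
#' @param period_weeks Length of the full period in weeks.
#' @return `amount * period_weeks / recall_weeks`.
#' @examples
#' extrapolate_recall(100) # 4-week recall to 12 weeks: 300
#' @export
extrapolate_recall <- function(amount, recall_weeks = 4, period_weeks = 12) {
  if (length(recall_weeks) != 1 || !is.finite(recall_weeks) || recall_weeks <= 0) {
    abort("`recall_weeks` must be a single positive number")
  }
  amount * period_weeks / recall_weeks
}

#' Convert SEK to USD at a purchasing-power rate
#'
#' @param amount_sek Amount(s) in Swedish crowns.
#' @param rate SEK paid per USD (> 0); the default is the 2014 purchasing
#'   power parity of 6.861.
#' @return Amount in USD.
#' @examples
#' convert_sek_to_usd(24000) # ~3498
#' @export
convert_sek_to_usd <- function(amount_sek, rate = 6.861) {
  if (length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number")
  }
  amount_sek / rate
}

#' Value sick-leave days by the human-capital approach
#'
#' Lost productivity is valued as hours lost times the gross hourly wage.
#'
#' @param sick_days Nonnegative number of sick-leave days.
#' @param tariff A [tariff_table()].
#' @return Productivity loss in SEK (not extrapolated, not converted).
#' @examples
#' productivity_loss(1) # 8 h x 188 SEK = 1504 SEK
#' @export
productivity_loss <- function(sick_days, tariff = tariff_table()) {
  if (any(sick_days < 0, na.rm = TRUE)) abort("`sick_days` must be nonnegative")
  sick_days * tariff$hours_per_workday * tariff$hourly_wage_sek
}

# resource item columns expected in a participant table
resource_item_cols <- function(tariff = tariff_table()) {
  c(names(tariff$unit_cost_sek),
    "sick_leave_days", "domestic_cutback_hours", "unemployed")
}

#' Perspectives of the costing analysis
#'
#' Cost categories are additive and nested: the clinic perspective counts
#' only treatment provision; health care adds other health-care visits and
#' medication; societal adds productivity losses (sick leave), domestic work
#' cutback and unemployment. `societal_excl_unemployment` is the societal
#' perspective with the unemployment category removed (a sensitivity
#' analysis).
#'
#' @return Character vector of perspective names.
#' @export
perspectives <- function() {
  c("clinic", "health_care", "societal", "societal_excl_unemployment")
}

#' Compute per-participant cost breakdowns in USD
#'
#' Applies the full costing chain to each participant x timepoint row:
#' counts are multiplied by SEK unit costs, sick-leave days valued by the
#' human-capital approach, domestic cutback hours at the EUR hourly rate
#' converted to SEK, all recall-window amounts extrapolated to the full
#' assessment period, and everything converted to USD. Unemployment is a
#' fixed per-period amount (converted, never extrapolated). Treatment
#' provision is the arm's fixed USD cost, booked once at post-treatment.
#'
#' If any TIC-P item in a row is missing, all questionnaire-derived
#' categories of that row are missing; treatment provision (an
#' administrative cost, not questionnaire-derived) is always defined.
#'
#' @param data Participant table with `participant_id`, `arm`, `timepoint`
#'   and the resource item columns (visit/medication counts matching the
#'   tariff's `unit_cost_sek` names, `sick_leave_days`,
#'   `domestic_cutback_hours`, logical/0-1 `unemployed`).
#' @param tariff A [tariff_table()].
#' @param resource_items Optional character vector of item columns to cost;
#'   defaults to every item the tariff knows. Unknown names are an error.
#' @return A tibble with one row per input row: id columns, the six USD cost
#'   categories (`treatment_provision`, `other_health_care`, `medication`,
#'   `sick_leave`, `domestic_cutback`, `unemployment`) and the nested
#'   perspective totals `cost_clinic`, `cost_health_care`, `cost_societal`,
#'   `cost_societal_excl_unemployment`.
#' @export
compute_costs <- function(data, tariff = tariff_table(), resource_items = NULL) {
  known <- resource_item_cols(tariff)
  if (is.null(resource_items)) {
    resource_items <- known
  } else {
    unknown <- setdiff(resource_items, known)
    if (length(unknown) > 0) {
      abort(paste0("unknown resource item(s): ", paste(unknown, collapse = ", ")))
    }
  }
  check_trial_table(data, cols = resource_items)
  counts <- data[intersect(resource_items, setdiff(known, "unemployed"))]
  if (any(unlist(counts) < 0, na.rm = TRUE)) {
    abort("resource counts must be nonnegative")
  }

  extrap_usd <- function(sek) {
    convert_sek_to_usd(
      extrapolate_recall(sek, tariff$recall_weeks, tariff$period_weeks),
      tariff$sek_per_usd
    )
  }
  visit_items <- setdiff(names(tariff$unit_cost_sek), "medication_units")
  visit_sek <- rep(0, nrow(data))
  for (item in visit_items) {
    visit_sek <- visit_sek + data[[item]] * tariff$unit_cost_sek[[item]]
  }
  medication_sek <- data$medication_units * tariff$unit_cost_sek[["medication_units"]]
  sick_sek <- productivity_loss(data$sick_leave_days, tariff)
  domestic_sek <- data$domestic_cutback_hours *
    tariff$domestic_hourly_eur * tariff$eur_to_sek

  out <- data %>%
    select(all_of(c("participant_id", "arm", "timepoint"))) %>%
    mutate(
      treatment_provision = ifelse(
        as.character(.data$timepoint) == "post",
        unname(tariff$treatment_cost_usd[as.character(.data$arm)]),
        0
      ),
      other_health_care = extrap_usd(visit_sek),
      medication = extrap_usd(medication_sek),
      sick_leave = extrap_usd(sick_sek),
      domestic_cutback = extrap_usd(domestic_sek),
      unemployment = as.numeric(data$unemployed) *
        convert_sek_to_usd(tariff$unemployment_fixed_sek, tariff$sek_per_usd)
    )
  add_perspective_totals(out)
}

# derive the nested perspective totals from the six category columns
add_perspective_totals <- function(breakdown) {
  breakdown %>%
    mutate(
      cost_clinic = .data$treatment_provision,
      cost_health_care = .data$cost_clinic + .data$other_health_care +
        .data$medication,
      cost_societal = .data$cost_health_care + .data$sick_leave +
        .data$domestic_cutback + .data$unemployment,
      cost_societal_excl_unemployment = .data$cost_societal - .data$unemployment
    )
}

#' Total cost under one perspective
#'
#' @param breakdown A cost-breakdown tibble from [compute_costs()] (or any
#'   data frame with the six category columns).
#' @param perspective One of [perspectives()].
#' @return Numeric vector of per-row totals in USD.
#' @export
cost_perspective_total <- function(breakdown, perspective) {
  if (length(perspective) != 1 || !perspective %in% perspectives()) {
    abort(paste0("`perspective` must be one of: ",
                 paste(perspectives(), collapse = ", ")))
  }
  b <- add_perspective_totals(breakdown)
  b[[paste0("cost_", perspective)]]
}
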