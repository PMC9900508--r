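#' EQ-5D value sets
#'
#' A value set translates a five-domain EQ-5D profile (mobility, self-care,
#' usual activities, pain/discomfort, anxiety/depression; levels 1 = no
#' problems upward) into a single utility index: the full-health constant
#' minus the summed decrements of each reported level. Which national value
#' set to use is an analysis choice; any table with columns
#' `domain`, `level`, `decrement` can be supplied.
#'
#' `toy_value_set()` ships a simple documented three-level set with uniform
#' decrements (0 / 0.10 / 0.25 per domain) and a floor at 0, so that the
#' index ranges from 0 (worst) to 1 (full health). It is intended for
#' testing and examples, not for valuing real profiles.
#'
#' @param floor Lowest index the set can produce; real national sets that
#'   allow states worse than dead use a negative floor.
#' @return A tibble `(domain, level, decrement)` with attributes
#'   `full_health` and `floor`, class `value_set`.
#' @examples
#' vs <- toy_value_set()
#' eq5d_index(data.frame(mobility = 2, self_care = 1, usual_activities = 1,
#'                       pain_discomfort = 1, anxiety_depression = 2), vs)
#' @export
toy_value_set <- function(floor = 0) {
  vs <- tidyr::expand_grid(
    domain = eq5d_domains(),
    level = 1:3
  ) %>%
    mutate(decrement = c(0, 0.10, 0.25)[.data$level])
  new_value_set(vs, full_health = 1, floor = floor)
}

#' @rdname toy_value_set
#' @export
eq5d_domains <- function() {
  c("mobility", "self_care", "usual_activities", "pain_discomfort",
    "anxiety_depression")
}

new_value_set <- function(table, full_health = 1, floor = -Inf) {
  if (!all(c("domain", "level", "decrement") %in% names(table))) {
    abort("a value set needs columns domain, level, decrement")
  }
  lvl1 <- table$decrement[table$level == 1]
  if (any(lvl1 != 0)) {
    abort("level-1 (no problems) decrements must be zero so full health maps to 1")
  }
  structure(as_tibble(table), full_health = full_health, floor = floor,
            class = c("value_set", class(as_tibble(table))))
}

#' Read a value set from CSV
#'
#' @param path CSV with columns `domain`, `level`, `decrement`.
#' @param full_health Index of the all-level-1 profile.
#' @param floor Lowest attainable index.
#' @return A `value_set`.
#' @export
read_value_set <- function(path, full_health = 1, floor = -Inf) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    domain = readr::col_character(),
    level = readr::col_integer(),
    decrement = readr::col_double()
  ))
  new_value_set(tab, full_health = full_health, floor = floor)
}

#' Compute the EQ-5D utility index from domain levels
#'
#' The index is the value set's full-health constant minus the summed
#' decrement of each domain's reported level, floored at the value set's
#' lowest attainable index. Deterministic lookup; monotone non-increasing
#' in every domain level for value sets with nonnegative decrements.
#'
#' @param profiles Data frame with one column per domain named as in the
#'   value set (see [eq5d_domains()]), one row per profile; integer levels.
#' @param value_set A `value_set` (default [toy_value_set()]).
#' @return Numeric vector of utility indices, never exceeding the
#'   full-health constant.
#' @export
eq5d_index <- function(profiles, value_set = toy_value_set()) {
  domains <- unique(value_set$domain)
  missing_cols <- setdiff(domains, names(profiles))
  if (length(missing_cols) > 0) {
    abort(paste0("`profiles` lacks domain column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  total <- rep(0, nrow(profiles))
  for (d in domains) {
    sub <- value_set[value_set$domain == d, ]
    dec <- sub$decrement[match(profiles[[d]], sub$level)]
    if (any(is.na(dec) & !is.na(profiles[[d]]))) {
      abort(paste0("unknown level in domain '", d, "'"))
    }
    total <- total + dec
  }
  pmax(attr(value_set, "full_health") - total, attr(value_set, "floor"))
}
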