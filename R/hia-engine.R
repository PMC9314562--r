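#' Build a period life table from age-specific death probabilities
#'
#' Chiang-style construction on one-year age intervals. `q` is the vector of
#' annual death probabilities for ages `0, 1, ..., length(q) - 1`; the final
#' age acts as the closure interval and its probability is treated as 1, so
#' survivorship reaches zero at the end of the table.
#'
#' @param q Numeric vector of annual death probabilities in `[0, 1]`, one per
#'   age starting at age 0.
#' @param a_fraction Average fraction of the interval lived by those dying in
#'   it (0.5 by default, the conventional mid-interval assumption).
#' @return A tibble with columns `age`, `q` (closure applied), `lx` (survivors
#'   from a radix of 1), `Lx` (person-years lived in the interval) and `ex`
#'   (residual life expectancy).
#' @examples
#' lt <- build_life_table(rep(0.1, 111))
#' lt$ex[1] # close to 9.5
#' @export
build_life_table <- function(q, a_fraction = 0.5) {
  if (length(q) == 0) stop("empty mortality schedule")
  if (any(!is.finite(q)) || any(q < 0 | q > 1)) {
    stop("death probabilities must lie in [0, 1]")
  }
  if (!is.numeric(a_fraction) || a_fraction < 0 || a_fraction > 1) {
    stop("a_fraction must lie in [0, 1]")
  }
  n <- length(q)
  q <- c(q[-n], 1)
  lx <- cumprod(c(1, 1 - q)) # length n + 1, last element 0 by closure
  l_lo <- lx[-(n + 1)]
  l_hi <- lx[-1]
  Lx <- l_hi + a_fraction * (l_lo - l_hi)
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(l_lo > 0, Tx / l_lo, 0)
  tibble::tibble(age = 0:(n - 1), q = q, lx = l_lo, Lx = Lx, ex = ex)
}

#' Residual life expectancy at every age for a mortality schedule
#'
#' Thin wrapper over [build_life_table()] returning only the `ex` column,
#' used as the single source of truth for residual life expectancy wherever
#' the pipeline needs it (including the synthetic demography generator).
#'
#' @inheritParams build_life_table
#' @return Numeric vector of residual life expectancies by age.
#' @export
residual_life_expectancy <- function(q, a_fraction = 0.5) {
  build_life_table(q, a_fraction)$ex
}

#' Premature deaths prevented by active transport
#'
#' Applies a relative-risk surface to a demographic projection: at each
#' (year, age, mode) the number of deaths prevented is
#' `population * q * (1 - rr)`, the HEAT-style attribution on projected
#' mortality. Ages outside the effect window contribute zero.
#'
#' @param demo Demography table with columns `year`, `age`, `population`,
#'   `mortality_q`, `residual_le`.
#' @param rr Relative-risk surface from [rr_surface()]: columns `year`, `age`,
#'   `mode`, `rr` (per-mode rows plus a combined `"all"` row).
#' @param age_window Inclusive age range `[low, high]` over which physical
#'   activity is allowed to reduce mortality (default 20-84).
#' @return Impact tibble: `year`, `age`, `mode`, `deaths_prevented`.
#' @export
deaths_prevented <- function(demo, rr, age_window = c(20L, 84L)) {
  joined <- dplyr::inner_join(rr, demo, by = c("year", "age"))
  if (nrow(joined) != nrow(rr)) {
    stop("relative-risk surface and demography are misaligned on (year, age)")
  }
  in_window <- joined$age >= age_window[1] & joined$age <= age_window[2]
  joined$deaths_prevented <- ifelse(
    in_window,
    joined$population * joined$mortality_q * (1 - joined$rr),
    0
  )
  dplyr::select(joined, "year", "age", "mode", "deaths_prevented")
}

#' Years of life lost averted
#'
#' Multiplies deaths prevented by the residual life expectancy at the age and
#' year of the averted death.
#'
#' @param impact Impact tibble from [deaths_prevented()].
#' @param demo Demography table carrying `residual_le` for every (year, age).
#' @return The impact tibble with an added `yll_prevented` column.
#' @export
yll_prevented <- function(impact, demo) {
  le <- dplyr::select(demo, "year", "age", "residual_le")
  joined <- dplyr::inner_join(impact, le, by = c("year", "age"))
  if (nrow(joined) != nrow(impact) || anyNA(joined$residual_le)) {
    stop("residual life expectancy missing for some (year, age)")
  }
  joined$yll_prevented <- joined$deaths_prevented * joined$residual_le
  dplyr::select(joined, "year", "age", "mode", "deaths_prevented", "yll_prevented")
}

#' Scenario difference of impact tables
#'
#' Per-key subtraction (intervention minus reference) of deaths and YLL
#' prevented. Negative values are reported as such, e.g. where classical-bike
#' mileage falls below its reference level late in the horizon.
#'
#' @param scenario,reference Impact tibbles sharing the same
#'   (year, age, mode) key set.
#' @return Impact tibble of per-key differences.
#' @export
scenario_delta <- function(scenario, reference) {
  by <- c("year", "age", "mode")
  joined <- dplyr::inner_join(
    scenario, reference,
    by = by, suffix = c("", "_ref")
  )
  if (nrow(joined) != nrow(scenario) || nrow(joined) != nrow(reference)) {
    stop("impact tables do not share the same (year, age, mode) keys")
  }
  joined$deaths_prevented <- joined$deaths_prevented - joined$deaths_prevented_ref
  if ("yll_prevented" %in% names(scenario)) {
    joined$yll_prevented <- joined$yll_prevented - joined$yll_prevented_ref
    return(dplyr::select(joined, "year", "age", "mode", "deaths_prevented", "yll_prevented"))
  }
  dplyr::select(joined, "year", "age", "mode", "deaths_prevented")
}

rr_all_wide <- function(rr) {
  out <- rr[rr$mode == "all", c("year", "age", "rr")]
  if (nrow(out) == 0) stop("relative-risk surface has no combined 'all' rows")
  out
}

#' Period life-expectancy gain between two scenarios
#'
#' For each calendar year, builds two period life tables with the baseline
#' death probabilities multiplied by each scenario's combined relative risk
#' (clamped to probabilities at most 1) and reports the difference in life
#' expectancy at birth, in months.
#'
#' @param demo Demography table (`year`, `age`, `mortality_q`).
#' @param rr_scenario,rr_reference Relative-risk surfaces from [rr_surface()].
#' @param years Calendar years to evaluate; defaults to all years in `demo`.
#' @param a_fraction Passed to [build_life_table()].
#' @return Tibble with columns `year` and `le_gain_months`.
#' @export
life_expectancy_gain <- function(demo, rr_scenario, rr_reference,
                                 years = NULL, a_fraction = 0.5) {
  if (is.null(years)) years <- sort(unique(demo$year))
  rrs <- rr_all_wide(rr_scenario)
  rrr <- rr_all_wide(rr_reference)
  e0_under <- function(year, rr_tab) {
    d <- demo[demo$year == year, c("age", "mortality_q")]
    d <- d[order(d$age), ]
    r <- rr_tab[rr_tab$year == year, c("age", "rr")]
    rr_by_age <- r$rr[match(d$age, r$age)]
    rr_by_age[is.na(rr_by_age)] <- 1
    q <- pmin(d$mortality_q * rr_by_age, 1)
    build_life_table(q, a_fraction)$ex[1]
  }
  gain <- vapply(years, function(y) {
    if (!any(demo$year == y)) stop("year ", y, " missing from demography")
    12 * (e0_under(y, rrs) - e0_under(y, rrr))
  }, numeric(1))
  tibble::tibble(year = years, le_gain_months = gain)
}
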