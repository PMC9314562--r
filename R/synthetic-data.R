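#' Parameters of the synthetic demographic projection
#'
#' The synthetic projection emulates national demographic projections with a
#' Gompertz-Makeham mortality hazard, a constant multiplicative mortality
#' improvement per calendar year, and a smooth base-year population pyramid.
#' The hazard at age `a` and year `y` is
#' `m(a, y) = (makeham_c + gompertz_b * exp(gompertz_theta * a)) *
#' (1 - annual_improvement)^(y - base_year)`, converted to an annual death
#' probability by `q = 1 - exp(-m)`.
#'
#' The base pyramid is the stationary population of the base-year life table,
#' modulated by a Gaussian cohort bulge (emulating the post-war generations,
#' aged around their early sixties at a 2021 base year), a logistic deficit at
#' the oldest ages, and a smooth seeded wobble. As the bulge ages into high
#' mortality the share of the population above 75 grows over the projection,
#' as in national projections of ageing populations.
#'
#' @param base_year,horizon_year First and last calendar years (horizon after
#'   base).
#' @param a_max Highest age in the tables (at least 100).
#' @param makeham_c Background hazard (per year, age-independent), >= 0.
#' @param gompertz_b Hazard scale (per year), >= 0.
#' @param gompertz_theta Hazard slope (per year of age), > 0.
#' @param annual_improvement Multiplicative mortality decline per calendar
#'   year, in `[0, 1)`.
#' @param pyramid_shape List with `bulge_age`, `bulge_width`, `bulge_amp`
#'   (centre, width in years and relative amplitude of the cohort bulge),
#'   `old_age_drop` (age of the logistic deficit), `drop_width` (its width in
#'   years) and `wobble_sd` (log-scale standard deviation of the smooth
#'   pyramid wobble); any element may be `NULL` to disable it.
#' @param total_population Base-year population, > 0.
#' @param seed RNG seed controlling the pyramid wobble.
#' @return A `demography_params` list.
#' @export
demography_params <- function(base_year = 2021L,
                              horizon_year = 2050L,
                              a_max = 110L,
                              makeham_c = 2e-4,
                              gompertz_b = 1.6e-5,
                              gompertz_theta = 0.1,
                              annual_improvement = 0.005,
                              pyramid_shape = list(
                                bulge_age = 63, bulge_width = 16, bulge_amp = 0.32,
                                old_age_drop = 88, drop_width = 5, wobble_sd = 0.02
                              ),
                              total_population = 65e6,
                              seed = 1L) {
  if (horizon_year < base_year) stop("horizon_year must not precede base_year")
  if (a_max < 100) stop("a_max must be at least 100")
  if (makeham_c < 0) stop("makeham_c must be non-negative")
  if (gompertz_b < 0) stop("gompertz_b must be non-negative")
  if (gompertz_theta <= 0) stop("gompertz_theta must be positive")
  if (annual_improvement < 0 || annual_improvement >= 1) {
    stop("annual_improvement must lie in [0, 1)")
  }
  if (total_population <= 0) stop("total_population must be positive")
  structure(
    list(
      base_year = as.integer(base_year), horizon_year = as.integer(horizon_year),
      a_max = as.integer(a_max), makeham_c = makeham_c, gompertz_b = gompertz_b,
      gompertz_theta = gompertz_theta, annual_improvement = annual_improvement,
      pyramid_shape = pyramid_shape, total_population = total_population,
      seed = as.integer(seed)
    ),
    class = "demography_params"
  )
}

#' Generate a synthetic demographic projection
#'
#' One row per (year, age) over the full horizon and age range, with
#' population counts evolved from the base pyramid by ageing and survival
#' under a constant annual birth cohort (equal to the base-year age-0 count),
#' annual death probabilities from the Gompertz-Makeham hazard, and residual
#' life expectancy computed from the same probabilities via
#' [build_life_table()].
#'
#' @param params A [demography_params()] object.
#' @return Tibble `year`, `age`, `population`, `mortality_q`, `residual_le`.
#' @export
gen_demography <- function(params) {
  if (!inherits(params, "demography_params")) params <- do.call(demography_params, params)
  p <- params
  years <- p$base_year:p$horizon_year
  ages <- 0:p$a_max
  hazard0 <- p$makeham_c + p$gompertz_b * exp(p$gompertz_theta * ages)
  improvement <- (1 - p$annual_improvement)^(years - p$base_year)
  m <- outer(hazard0, improvement)
  q <- 1 - exp(-m)
  if (any(q >= 1 - 1e-12)) {
    stop("mortality parameters too aggressive: death probability reaches 1")
  }

  # base pyramid: stationary population of the base-year rates, modulated
  w <- build_life_table(q[, 1])$lx
  ps <- p$pyramid_shape
  if (!is.null(ps$bulge_age)) {
    w <- w * (1 + ps$bulge_amp * exp(-0.5 * ((ages - ps$bulge_age) / ps$bulge_width)^2))
  }
  if (!is.null(ps$old_age_drop)) {
    w <- w * stats::plogis((ps$old_age_drop - ages) / ps$drop_width)
  }
  if (!is.null(ps$wobble_sd) && ps$wobble_sd > 0) {
    set.seed(p$seed)
    knots <- seq(0, p$a_max, by = 15)
    dev <- stats::rnorm(length(knots), 0, ps$wobble_sd)
    w <- w * exp(stats::spline(knots, dev, xout = ages)$y)
  }
  if (all(w == 0)) stop("degenerate pyramid: all-zero weights")

  n_age <- length(ages)
  pop <- matrix(0, n_age, length(years))
  pop[, 1] <- p$total_population * w / sum(w)
  for (j in seq_along(years)[-1]) {
    pop[1, j] <- pop[1, 1]
    pop[-1, j] <- pop[-n_age, j - 1] * (1 - q[-n_age, j - 1])
  }
  ex <- vapply(
    seq_along(years),
    function(j) build_life_table(q[, j])$ex,
    numeric(n_age)
  )
  tibble::tibble(
    year = rep(years, each = n_age),
    age = rep(ages, length(years)),
    population = as.vector(pop),
    mortality_q = as.vector(q),
    residual_le = as.vector(ex)
  )
}

#' Anchor points for synthetic mileage trajectories
#'
#' @param walking,cycling Data frames with columns `year` and `km` (weekly km
#'   per inhabitant) at anchor years.
#' @param ebike_share Data frame with columns `year` and `share` (fraction of
#'   cycled kilometres by e-bike).
#' @return A `mileage_anchors` list.
#' @export
mileage_anchors <- function(walking, cycling, ebike_share) {
  check_series <- function(df, value_col, lo = 0, hi = Inf, what) {
    if (anyDuplicated(df$year)) stop("duplicate anchor years in ", what)
    if (is.unsorted(df$year, strictly = TRUE)) stop("anchor years must be strictly increasing in ", what)
    v <- df[[value_col]]
    if (any(v < lo | v > hi)) stop(what, " anchor values out of range")
    df
  }
  structure(
    list(
      walking = check_series(walking, "km", what = "walking"),
      cycling = check_series(cycling, "km", what = "cycling"),
      ebike_share = check_series(ebike_share, "share", hi = 1, what = "ebike_share")
    ),
    class = "mileage_anchors"
  )
}

#' Bundled scenario anchors
#'
#' Reads the packaged anchor fixture mirroring the energy-transition
#' scenario's printed active-travel values: weekly cycling per inhabitant of
#' 2.4 km in 2021, 17.1 km in 2040, a peak of 17.5 km in 2045 and 17.1 km in
#' 2050; walking rising by 11% over 2021-2050; and an e-bike share of cycled
#' kilometres of 3.3% in 2021 reaching 70% in 2040 and constant thereafter.
#' The walking level (3.4 km/week in 2021) is a synthetic choice, documented
#' in the methods vignette.
#'
#' @return A [mileage_anchors()] object.
#' @export
negawatt_anchors <- function() {
  path <- system.file("extdata", "scenario_anchors.csv", package = "activehia")
  raw <- utils::read.csv(path, comment.char = "#")
  pick <- function(series, value_col) {
    out <- raw[raw$series == series, c("year", "value")]
    names(out) <- c("year", value_col)
    out[order(out$year), , drop = FALSE]
  }
  mileage_anchors(
    walking = pick("walking", "km"),
    cycling = pick("cycling", "km"),
    ebike_share = pick("ebike_share", "share")
  )
}

interp_series <- function(df, value_col, years, interpolation) {
  yr <- df$year
  v <- df[[value_col]]
  if (any(yr < min(years) | yr > max(years))) {
    stop("anchor years outside the scenario horizon")
  }
  if (length(yr) == 1) return(rep(v, length(years)))
  # constant extension outside the anchor range, exact at anchors
  x <- pmin(pmax(years, min(yr)), max(yr))
  out <- if (interpolation == "linear") {
    stats::approx(yr, v, xout = x, rule = 2)$y
  } else {
    stats::splinefun(yr, v, method = "monoH.FC")(x)
  }
  # segments between equal-valued anchors are exactly constant (the spline
  # can be off by one ulp there)
  for (i in seq_len(length(yr) - 1)) {
    if (v[i] == v[i + 1]) out[x >= yr[i] & x <= yr[i + 1]] <- v[i]
  }
  out
}

#' Generate per-year mileage trajectories from anchor points
#'
#' Interpolates each series through its anchors (exactly) with either
#' monotone piecewise-cubic Hermite interpolation (default; no overshoot
#' between anchors) or linear interpolation, extends the series as constant
#' outside the anchor range, and clips the e-bike share to `[0, 1]`.
#'
#' @param anchors A [mileage_anchors()] object.
#' @param years Integer vector of calendar years to cover.
#' @param interpolation `"monotone"` or `"linear"`.
#' @return Tibble `year`, `walk_km_pc`, `cycle_km_pc`, `ebike_share`.
#' @export
gen_mileage <- function(anchors, years, interpolation = c("monotone", "linear")) {
  interpolation <- match.arg(interpolation)
  tibble::tibble(
    year = as.integer(years),
    walk_km_pc = interp_series(anchors$walking, "km", years, interpolation),
    cycle_km_pc = interp_series(anchors$cycling, "km", years, interpolation),
    ebike_share = pmin(pmax(interp_series(anchors$ebike_share, "share", years, interpolation), 0), 1)
  )
}

#' Generate a reference age distribution of mileage
#'
#' A smooth normalized share-by-age curve: a constant floor plus a Gaussian
#' bump at `peak_age`, optionally tapered at old ages by a logistic factor
#' (people cycle little beyond their 80s). With `peak_weight = 0` and no
#' taper the distribution is uniform.
#'
#' @param ages Integer ages covered (e.g. `0:110`).
#' @param peak_age Age of the bump maximum.
#' @param spread Bump standard deviation in years.
#' @param floor Constant baseline weight, >= 0.
#' @param peak_weight Bump weight relative to the floor, >= 0.
#' @param taper_age Age at which the old-age logistic taper reaches 1/2;
#'   `NULL` disables the taper.
#' @param taper_width Taper width in years.
#' @return Tibble `age`, `share` with shares summing to 1.
#' @export
gen_age_distribution <- function(ages, peak_age = 25, spread = 16, floor = 0.25,
                                 peak_weight = 1, taper_age = NULL, taper_width = 5) {
  if (spread <= 0 || floor < 0 || peak_weight < 0) {
    stop("shape parameters must be positive (spread) and non-negative (floor, peak_weight)")
  }
  w <- floor + peak_weight * exp(-0.5 * ((ages - peak_age) / spread)^2)
  if (!is.null(taper_age)) {
    w <- w * stats::plogis((taper_age - ages) / taper_width)
  }
  total <- sum(w)
  if (total <= 0) stop("cannot normalize an all-zero age distribution")
  tibble::tibble(age = as.integer(ages), share = w / total)
}

#' Default age-distribution shapes per mode
#'
#' Cycling mileage is unimodal, peaking in young adulthood and tapering at
#' old ages; walking is distributed much more homogeneously across ages.
#'
#' @return Named list of shape-parameter lists for `cycle` and `walk`.
#' @export
default_age_shapes <- function() {
  list(
    cycle = list(peak_age = 25, spread = 16, floor = 0.25, peak_weight = 1,
                 taper_age = 80, taper_width = 6),
    walk = list(peak_age = 45, spread = 30, floor = 1, peak_weight = 0.25,
                taper_age = 88, taper_width = 6)
  )
}

#' Generate a value-of-statistical-life-year series
#'
#' Compounds a base value forward at a constant growth rate, emulating
#' official VSLY projections that track economic growth:
#' `vsly(y) = base_value * (1 + growth_rate)^(y - base_year)`.
#'
#' @param base_value VSLY at `base_year` (139,000 euros-2020 by default).
#' @param base_year Year the base value refers to.
#' @param growth_rate Annual growth fraction.
#' @param years Calendar years to cover.
#' @return Tibble `year`, `vsly_eur`.
#' @export
gen_vsly <- function(base_value = 139000, base_year = 2020L,
                     growth_rate = 0.012, years = 2021:2050) {
  if (base_value <= 0) stop("base_value must be positive")
  tibble::tibble(
    year = as.integer(years),
    vsly_eur = base_value * (1 + growth_rate)^(years - base_year)
  )
}
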