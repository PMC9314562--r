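# Shared fixtures: one default synthetic input bundle and one central
# pipeline run, generated once per test session.

fixture_config <- hia_config()
fixture_inputs <- synth_inputs(fixture_config, seed = 42L)
fixture_run <- run_hia(fixture_inputs, fixture_config)

# A tiny hand-checkable demography: one year, three ages.
toy_demo <- function() {
  tibble::tibble(
    year = 2030L,
    age = c(20L, 30L, 40L),
    population = c(1000, 2000, 500),
    mortality_q = c(0.001, 0.002, 0.005),
    residual_le = c(60, 50, 40)
  )
}

# Smooth random allocation instance for property tests: returns a
# demography-like table, a normalized age distribution, and a trajectory.
random_allocation_instance <- function(ages = 0:90, year = 2030L) {
  pop <- 1000 + 5000 * exp(-0.5 * ((ages - stats::runif(1, 30, 50)) / 30)^2) +
    stats::runif(length(ages), 0, 200)
  peak <- stats::runif(1, 25, 60)
  spread <- stats::runif(1, 8, 25)
  dist_c <- gen_age_distribution(ages, peak_age = peak, spread = spread,
                                 floor = stats::runif(1, 0.05, 0.4))
  dist_w <- gen_age_distribution(ages, peak_age = stats::runif(1, 35, 55),
                                 spread = 30, floor = 1, peak_weight = 0.3)
  demo <- tibble::tibble(
    year = year, age = ages, population = pop,
    mortality_q = 0.01, residual_le = 40
  )
  dist <- dplyr::bind_rows(
    dplyr::mutate(dist_c, mode = "cycle"),
    dplyr::mutate(dist_w, mode = "walk")
  )[, c("mode", "age", "share")]
  traj <- tibble::tibble(
    year = year,
    walk_km_pc = stats::runif(1, 1, 10),
    cycle_km_pc = stats::runif(1, 1, 20),
    ebike_share = stats::runif(1, 0.1, 0.9)
  )
  list(demo = demo, dist = dist, traj = traj)
}

# Input bundle with no active travel at all (null scenario).
zero_mileage_inputs <- function(config = fixture_config) {
  anchors <- mileage_anchors(
    walking = data.frame(year = config$base_year, km = 0),
    cycling = data.frame(year = config$base_year, km = 0),
    ebike_share = data.frame(year = config$base_year, share = 0.5)
  )
  inp <- fixture_inputs
  inp$mileage <- gen_mileage(anchors, config$base_year:config$end_year)
  inp
}
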