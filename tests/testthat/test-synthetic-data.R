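test_that("Gompertz-Makeham hazards convert to annual probabilities by the closed form", {
  p <- demography_params(
    base_year = 2021, horizon_year = 2023, makeham_c = 0.001, gompertz_b = 0,
    annual_improvement = 0,
    pyramid_shape = list(wobble_sd = 0), total_population = 1e6
  )
  d <- gen_demography(p)
  expect_equal(unique(d$mortality_q), 1 - exp(-0.001), tolerance = 1e-12)
  # no secular improvement: every calendar year carries the same schedule
  q_by_year <- split(d$mortality_q, d$year)
  expect_identical(q_by_year[[1]], q_by_year[[2]])
  expect_identical(q_by_year[[1]], q_by_year[[3]])

  # pure Gompertz: q(70)/q(40) close to exp(3) in the small-hazard limit,
  # and equal to the exact ratio of converted hazards
  p2 <- demography_params(
    base_year = 2021, horizon_year = 2022, makeham_c = 0, gompertz_b = 1e-5,
    gompertz_theta = 0.1, annual_improvement = 0,
    pyramid_shape = list(wobble_sd = 0), total_population = 1e6
  )
  d2 <- gen_demography(p2)
  y1 <- d2[d2$year == 2021, ]
  m40 <- 1e-5 * exp(0.1 * 40)
  m70 <- 1e-5 * exp(0.1 * 70)
  exact_ratio <- (1 - exp(-m70)) / (1 - exp(-m40))
  got_ratio <- y1$mortality_q[y1$age == 70] / y1$mortality_q[y1$age == 40]
  expect_equal(got_ratio, exact_ratio, tolerance = 1e-12)
  expect_equal(got_ratio, exp(3), tolerance = 1e-2)
})

test_that("demographic projection is deterministic, conserves cohorts, and is life-table consistent", {
  p <- demography_params(seed = 7, horizon_year = 2026)
  d1 <- gen_demography(p)
  d2 <- gen_demography(p)
  expect_identical(d1, d2)
  d3 <- gen_demography(demography_params(seed = 8, horizon_year = 2026))
  expect_false(identical(d1$population, d3$population))

  # cohort conservation: population(a+1, y+1) = population(a, y) * (1 - q(a, y))
  for (y in 2021:2025) {
    now <- d1[d1$year == y, ]
    nxt <- d1[d1$year == y + 1, ]
    expect_identical(
      nxt$population[match(1:110, nxt$age)],
      (now$population * (1 - now$mortality_q))[match(0:109, now$age)]
    )
  }
  # constant annual birth cohort
  expect_identical(
    unique(d1$population[d1$age == 0]),
    d1$population[d1$age == 0 & d1$year == 2021]
  )
  # residual LE column equals the life-table engine on the same rates
  y24 <- d1[d1$year == 2024, ]
  y24 <- y24[order(y24$age), ]
  expect_equal(y24$residual_le, residual_life_expectancy(y24$mortality_q),
               tolerance = 1e-12)
})

test_that("invalid demography parameters are rejected", {
  expect_error(demography_params(total_population = 0), "positive")
  expect_error(demography_params(horizon_year = 2019), "precede")
  expect_error(demography_params(annual_improvement = 1), "0, 1")
  expect_error(demography_params(gompertz_theta = 0), "positive")
  # hazard so steep that q reaches 1 before the top age
  expect_error(
    gen_demography(demography_params(gompertz_b = 1e-3, gompertz_theta = 0.3)),
    "too aggressive"
  )
})

test_that("mileage interpolation passes exactly through anchors and stays bounded", {
  years <- 2021:2050
  mil <- gen_mileage(negawatt_anchors(), years)
  expect_equal(mil$cycle_km_pc[mil$year == 2021], 2.4)
  expect_equal(mil$cycle_km_pc[mil$year == 2040], 17.1)
  expect_equal(mil$cycle_km_pc[mil$year == 2045], 17.5)
  expect_equal(mil$cycle_km_pc[mil$year == 2050], 17.1)
  expect_equal(mil$ebike_share[mil$year == 2021], 0.033)
  expect_true(all(mil$ebike_share[mil$year >= 2040] == 0.70))
  # monotone interpolation: bounded by neighbouring anchors, no overshoot
  ramp <- mil$cycle_km_pc[mil$year <= 2040]
  expect_true(all(diff(ramp) >= 0))
  expect_true(all(ramp >= 2.4 & ramp <= 17.1))
  expect_true(all(mil$ebike_share >= 0 & mil$ebike_share <= 1))

  # single anchor extends as a constant
  one <- mileage_anchors(
    walking = data.frame(year = 2021, km = 5),
    cycling = data.frame(year = 2021, km = 3),
    ebike_share = data.frame(year = 2021, share = 0.2)
  )
  m1 <- gen_mileage(one, years)
  expect_true(all(m1$walk_km_pc == 5) && all(m1$cycle_km_pc == 3))

  # linear interpolation hits the midpoint
  lin <- mileage_anchors(
    walking = data.frame(year = c(2021, 2041), km = c(0, 10)),
    cycling = data.frame(year = 2021, km = 1),
    ebike_share = data.frame(year = 2021, share = 0)
  )
  m2 <- gen_mileage(lin, years, interpolation = "linear")
  expect_equal(m2$walk_km_pc[m2$year == 2031], 5)
})

test_that("malformed anchors are rejected", {
  expect_error(
    mileage_anchors(
      walking = data.frame(year = c(2021, 2021), km = c(1, 2)),
      cycling = data.frame(year = 2021, km = 1),
      ebike_share = data.frame(year = 2021, share = 0)
    ),
    "duplicate"
  )
  expect_error(
    mileage_anchors(
      walking = data.frame(year = 2021, km = 1),
      cycling = data.frame(year = 2021, km = 1),
      ebike_share = data.frame(year = 2021, share = 1.5)
    ),
    "out of range"
  )
  ok <- mileage_anchors(
    walking = data.frame(year = 2019, km = 1),
    cycling = data.frame(year = 2021, km = 1),
    ebike_share = data.frame(year = 2021, share = 0)
  )
  expect_error(gen_mileage(ok, 2021:2030), "horizon")
})

test_that("age distributions normalize, respect the floor-only uniform limit, and peak where asked", {
  u <- gen_age_distribution(0:100, peak_weight = 0, floor = 1, taper_age = NULL)
  expect_equal(u$share, rep(1 / 101, 101), tolerance = 1e-15)

  grid <- expand.grid(peak_age = c(20, 35, 60), spread = c(5, 15, 30),
                      floor = c(0, 0.1, 0.5))
  for (i in seq_len(nrow(grid))) {
    d <- gen_age_distribution(0:110, peak_age = grid$peak_age[i],
                              spread = grid$spread[i], floor = grid$floor[i],
                              taper_age = 85)
    expect_equal(sum(d$share), 1, tolerance = 1e-12)
    expect_true(all(d$share >= 0))
  }
  d25 <- gen_age_distribution(0:110, peak_age = 25, spread = 16, floor = 0.25,
                              taper_age = 80)
  expect_true(d25$age[which.max(d25$share)] >= 20 &&
              d25$age[which.max(d25$share)] <= 30)
  expect_error(gen_age_distribution(0:10, peak_weight = 0, floor = 0, taper_age = NULL),
               "all-zero")
})

test_that("the VSLY series compounds growth from its base year", {
  flat <- gen_vsly(139000, 2020, growth_rate = 0, years = 2021:2050)
  expect_true(all(flat$vsly_eur == 139000))
  one_step <- gen_vsly(139000, 2020, growth_rate = 0.01, years = 2021)
  expect_equal(one_step$vsly_eur, 140390)
  v <- gen_vsly(139000, 2020, growth_rate = 0.01, years = c(2020, 2030))
  expect_equal(v$vsly_eur[2] / v$vsly_eur[1], 1.01^10, tolerance = 1e-12)
  expect_error(gen_vsly(0), "positive")
})
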