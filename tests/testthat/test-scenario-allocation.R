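test_that("the reference scenario freezes base-year values", {
  mil <- fixture_inputs$mileage
  ref <- build_reference_scenario(mil, 2021)
  expect_true(all(ref$cycle_km_pc == 2.4))
  expect_true(all(ref$ebike_share == 0.033))
  expect_true(all(ref$walk_km_pc == mil$walk_km_pc[mil$year == 2021]))
  # idempotent on an already-constant trajectory
  expect_equal(build_reference_scenario(ref, 2021), ref)
  expect_error(build_reference_scenario(mil, 1999), "missing")
})

test_that("mileage allocation reproduces forced arithmetic examples", {
  demo2 <- tibble::tibble(year = 2030L, age = c(20L, 21L),
                          population = c(100, 100),
                          mortality_q = 0.01, residual_le = 40)
  dist2 <- tibble::tibble(mode = "cycle", age = c(20L, 21L), share = c(0.8, 0.2))
  dist2 <- dplyr::bind_rows(dist2, dplyr::mutate(dist2, mode = "walk"))
  traj2 <- tibble::tibble(year = 2030L, walk_km_pc = 0, cycle_km_pc = 10,
                          ebike_share = 0.5)
  out <- allocate_mileage(traj2, dist2, demo2)
  bike <- out[out$mode == "bike_total", ]
  expect_equal(bike$km_pc[bike$age == 20], 16)
  expect_equal(bike$km_pc[bike$age == 21], 4)
  # weighted mean recovers the national value
  expect_equal(sum(bike$km_pc * demo2$population) / sum(demo2$population), 10)

  # equal populations with proportional shares: flat per-capita mileage
  demo3 <- tibble::tibble(year = 2030L, age = 20:22,
                          population = c(50, 100, 50),
                          mortality_q = 0.01, residual_le = 40)
  dist3 <- tibble::tibble(mode = "cycle", age = 20:22, share = c(0.25, 0.5, 0.25))
  dist3 <- dplyr::bind_rows(dist3, dplyr::mutate(dist3, mode = "walk"))
  traj3 <- tibble::tibble(year = 2030L, walk_km_pc = 8, cycle_km_pc = 8,
                          ebike_share = 0.5)
  out3 <- allocate_mileage(traj3, dist3, demo3)
  expect_equal(out3$km_pc, rep(8, 6))
})

test_that("allocation conserves national mileage and scales linearly on random instances", {
  set.seed(101)
  for (i in 1:20) {
    inst <- random_allocation_instance()
    out <- allocate_mileage(inst$traj, inst$dist, inst$demo)
    for (m in c("walk", "bike_total")) {
      sub <- out[out$mode == m, ]
      got <- sum(sub$km_pc * inst$demo$population) / sum(inst$demo$population)
      nat <- if (m == "walk") inst$traj$walk_km_pc else inst$traj$cycle_km_pc
      expect_equal(got, nat, tolerance = 1e-9)
    }
    # homogeneous scaling: doubling the national trajectory doubles every age
    traj2 <- inst$traj
    traj2$walk_km_pc <- 2 * traj2$walk_km_pc
    traj2$cycle_km_pc <- 2 * traj2$cycle_km_pc
    out2 <- allocate_mileage(traj2, inst$dist, inst$demo)
    expect_equal(out2$km_pc, 2 * out$km_pc, tolerance = 1e-12)
  }
})

test_that("allocation rejects zero population where mileage must go", {
  demo <- tibble::tibble(year = 2030L, age = c(20L, 21L), population = c(100, 0),
                         mortality_q = 0.01, residual_le = 40)
  dist <- tibble::tibble(mode = c("cycle", "cycle", "walk", "walk"),
                         age = c(20L, 21L, 20L, 21L),
                         share = c(0.5, 0.5, 0.5, 0.5))
  traj <- tibble::tibble(year = 2030L, walk_km_pc = 1, cycle_km_pc = 1,
                         ebike_share = 0.5)
  expect_error(allocate_mileage(traj, dist, demo), "zero population")
  expect_error(
    allocate_mileage(traj, dplyr::mutate(dist, share = c(0.9, 0.2, 0.5, 0.5)), demo),
    "not normalized"
  )
})

test_that("mileage-weighted mean age matches hand calculations", {
  expect_equal(mean_age_of_mileage(5, 100, 30), 30)
  expect_equal(mean_age_of_mileage(c(2, 1), c(50, 100), c(20, 40)), 30)
  expect_equal(mean_age_of_mileage(c(1, 2, 1), c(1, 1, 1), c(20, 30, 40)), 30)
  expect_error(mean_age_of_mileage(c(0, 0), c(1, 1), c(20, 40)), "zero")
})

test_that("two-age e-bike split matches the closed form", {
  # equal km and population at ages 20 and 70, share 1/2, gap 6.7:
  # s20 + s70 = 1 forces gap = 50 - 100 * s20, so s20 = (50 - 6.7) / 100
  demo <- tibble::tibble(year = 2030L, age = c(20L, 70L), population = c(100, 100),
                         mortality_q = 0.01, residual_le = 40)
  bike <- tibble::tibble(year = 2030L, age = c(20L, 70L), km_pc = c(5, 5))
  shares <- tibble::tibble(year = 2030L, ebike_share = 0.5)
  sp <- split_ebike(bike, shares, 6.7, demo)
  s <- plogis(sp$solution$alpha + sp$solution$beta * c(20, 70))
  expect_equal(s[1], 0.433, tolerance = 1e-6)
  expect_equal(s[2], 0.567, tolerance = 1e-6)
  expect_equal(sp$solution$achieved_share, 0.5, tolerance = 1e-9)
  expect_equal(sp$solution$achieved_age_gap, 6.7, tolerance = 1e-6)
})

test_that("a zero age-gap target yields a flat share", {
  demo <- fixture_inputs$demography
  bike <- allocate_mileage(fixture_inputs$mileage, fixture_inputs$age_distribution, demo)
  bike <- bike[bike$mode == "bike_total" & bike$year == 2040, ]
  sp <- split_ebike(bike, tibble::tibble(year = 2040L, ebike_share = 0.7), 0, demo)
  expect_equal(sp$solution$beta, 0)
  e <- sp$mileage[sp$mileage$mode == "bike_e", ]
  tot <- bike[match(e$age, bike$age), ]
  expect_equal(e$km_pc, 0.7 * tot$km_pc, tolerance = 1e-12)
})

test_that("the split solver recovers share and mean-age-gap targets on random instances", {
  set.seed(202)
  for (i in 1:10) {
    inst <- random_allocation_instance()
    out <- allocate_mileage(inst$traj, inst$dist, inst$demo)
    bike <- out[out$mode == "bike_total", ]
    target_share <- runif(1, 0.1, 0.9)
    target_gap <- runif(1, 0, 10)
    sp <- split_ebike(bike, tibble::tibble(year = inst$demo$year[1], ebike_share = target_share),
                      target_gap, inst$demo)
    expect_equal(sp$solution$achieved_share, target_share, tolerance = 1e-6)
    expect_equal(sp$solution$achieved_age_gap, target_gap, tolerance = 0.05)
    # e-bike share skews older when the gap target is non-negative
    expect_true(sp$solution$beta >= 0)
    # additivity to within one ulp (km_c is computed as the difference)
    wide <- tidyr::pivot_wider(sp$mileage, names_from = "mode", values_from = "km_pc")
    tot <- bike$km_pc[match(wide$age, bike$age)]
    expect_equal(wide$bike_e + wide$bike_classical, tot, tolerance = 1e-14)
  }
})

test_that("degenerate share targets fall back to a constant share with a warning", {
  demo <- tibble::tibble(year = 2030L, age = c(20L, 70L), population = c(100, 100),
                         mortality_q = 0.01, residual_le = 40)
  bike <- tibble::tibble(year = 2030L, age = c(20L, 70L), km_pc = c(5, 5))
  expect_warning(
    sp <- split_ebike(bike, tibble::tibble(year = 2030L, ebike_share = 0), 6.7, demo),
    "degenerate"
  )
  expect_true(all(sp$mileage$km_pc[sp$mileage$mode == "bike_e"] == 0))
  expect_true(is.na(sp$solution$achieved_age_gap))
})
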