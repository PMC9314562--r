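#' Freeze a trajectory at its base-year values
#'
#' The reference (business-as-usual) scenario keeps walking and cycling
#' mileage and the e-bike share constant at their base-year levels over the
#' whole horizon, while sharing the age distribution and split machinery of
#' the main scenario.
#'
#' @param traj Mileage trajectory (`year`, `walk_km_pc`, `cycle_km_pc`,
#'   `ebike_share`).
#' @param base_year Year whose values are frozen; must be present in `traj`.
#' @return A trajectory with every year carrying the base-year values.
#' @export
build_reference_scenario <- function(traj, base_year) {
  i <- match(base_year, traj$year)
  if (is.na(i)) stop("base year ", base_year, " missing from trajectory")
  out <- traj
  out$walk_km_pc <- traj$walk_km_pc[i]
  out$cycle_km_pc <- traj$cycle_km_pc[i]
  out$ebike_share <- traj$ebike_share[i]
  out
}

#' Allocate national mileage across ages
#'
#' Distributes each year's national weekly mileage (per-capita value times
#' total population) across one-year ages according to a reference age
#' distribution: age `a` receives the fraction `d(a)` of the national
#' kilometres, converted back to per-capita terms with that age's population.
#' The population-weighted mean over ages recovers the national per-capita
#' value, so the overall relative increase affects all ages homogeneously.
#'
#' @param traj Mileage trajectory.
#' @param dist Age distribution tibble (`mode` in `walk`/`cycle`, `age`,
#'   `share`), normalized per mode.
#' @param demo Demography table covering every (year, age).
#' @return Tibble `year`, `age`, `mode` (`walk`, `bike_total`), `km_pc`.
#' @export
allocate_mileage <- function(traj, dist, demo) {
  for (m in unique(dist$mode)) {
    s <- dist$share[dist$mode == m]
    if (any(s < 0) || abs(sum(s) - 1) > 1e-9) {
      stop("age distribution for mode '", m, "' is not normalized")
    }
  }
  pop <- demo[, c("year", "age", "population")]
  totals <- dplyr::summarise(
    dplyr::group_by(pop, .data$year),
    total_pop = sum(.data$population), .groups = "drop"
  )
  long <- tidyr::pivot_longer(
    traj[, c("year", "walk_km_pc", "cycle_km_pc")],
    c("walk_km_pc", "cycle_km_pc"),
    names_to = "mode", values_to = "km_pc_national"
  )
  long$mode <- ifelse(long$mode == "walk_km_pc", "walk", "cycle")
  out <- dplyr::inner_join(long, totals, by = "year")
  out <- dplyr::inner_join(out, dist, by = "mode", relationship = "many-to-many")
  out <- dplyr::inner_join(out, pop, by = c("year", "age"))
  bad <- out$population <= 0 & out$share > 0 & out$km_pc_national > 0
  if (any(bad)) {
    stop(
      "cannot allocate mileage: zero population at age(s) ",
      paste(unique(out$age[bad]), collapse = ", "),
      " with positive mileage share"
    )
  }
  out$km_pc <- ifelse(
    out$population > 0,
    out$km_pc_national * out$total_pop * out$share / out$population,
    0
  )
  out$mode <- ifelse(out$mode == "walk", "walk", "bike_total")
  out <- out[order(out$year, out$mode, out$age), c("year", "age", "mode", "km_pc")]
  tibble::as_tibble(out)
}

#' Mileage-weighted mean age
#'
#' The mean age of the national kilometres: `sum(a * km(a) * N(a)) /
#' sum(km(a) * N(a))`.
#'
#' @param km_pc Per-capita weekly km by age.
#' @param population Population by age.
#' @param age Ages.
#' @return Mean age in years.
#' @export
mean_age_of_mileage <- function(km_pc, population, age) {
  stopifnot(length(km_pc) == length(population), length(km_pc) == length(age))
  w <- km_pc * population
  total <- sum(w)
  if (total <= 0) stop("total mileage is zero; mean age undefined")
  sum(age * w) / total
}

solve_ebike_year <- function(age, km_national, share_target, gap_target,
                             tol_share = 1e-10, tol_gap = 1e-3, max_iter = 200L) {
  total <- sum(km_national)
  constant_solution <- function(s, gap = NA_real_) {
    list(alpha = if (s > 0 && s < 1) stats::qlogis(s) else if (s <= 0) -Inf else Inf,
         beta = 0, s = rep(s, length(age)),
         achieved_share = s, achieved_gap = gap)
  }
  if (total <= 0) {
    # nothing to split: zero mileage stays zero under any share profile
    return(constant_solution(share_target))
  }
  if (share_target <= 0 || share_target >= 1) {
    if (gap_target != 0) {
      warning("degenerate e-bike share target ", share_target,
              ": mean-age gap undefined, using a constant share")
    }
    return(constant_solution(share_target))
  }
  if (gap_target == 0) {
    sol <- constant_solution(share_target, gap = 0)
    return(sol)
  }

  weighted_share <- function(alpha, beta) {
    sum(km_national * stats::plogis(alpha + beta * age)) / total
  }
  alpha_for <- function(beta) {
    centre <- stats::qlogis(share_target) - beta * sum(age * km_national) / total
    stats::uniroot(
      function(a) weighted_share(a, beta) - share_target,
      interval = centre + c(-2, 2), extendInt = "upX",
      tol = 1e-12, maxiter = max_iter
    )$root
  }
  gap_of <- function(beta) {
    s <- stats::plogis(alpha_for(beta) + beta * age)
    we <- s * km_national
    wc <- km_national - we
    sum(age * we) / sum(we) - sum(age * wc) / sum(wc)
  }
  root <- tryCatch(
    stats::uniroot(
      function(b) gap_of(b) - gap_target,
      interval = c(-0.1, 0.1), extendInt = "upX",
      tol = 1e-10, maxiter = max_iter
    ),
    error = function(e) {
      stop("e-bike split solver failed (share target ", share_target,
           ", gap target ", gap_target, " years): ", conditionMessage(e))
    }
  )
  beta <- root$root
  alpha <- alpha_for(beta)
  s <- stats::plogis(alpha + beta * age)
  we <- s * km_national
  wc <- km_national - we
  achieved_share <- sum(we) / total
  achieved_gap <- sum(age * we) / sum(we) - sum(age * wc) / sum(wc)
  if (abs(achieved_share - share_target) > max(tol_share, 1e-6)) {
    stop("e-bike split solver did not reach the share target")
  }
  if (abs(achieved_gap - gap_target) > max(tol_gap, 0.05)) {
    warning("mean-age gap off target by ",
            format(achieved_gap - gap_target), " years")
  }
  list(alpha = alpha, beta = beta, s = s,
       achieved_share = achieved_share, achieved_gap = achieved_gap)
}

#' Split total cycling into classical and e-bike mileage
#'
#' Within each calendar year, the e-bike share of cycled kilometres at age
#' `a` follows a two-parameter logistic `s(a) = plogis(alpha + beta * a)`.
#' `(alpha, beta)` are solved per year so that (i) the mileage-weighted
#' national e-bike share matches the trajectory's share for that year and
#' (ii) the mean age of e-bike kilometres exceeds the mean age of classical
#' kilometres by `age_gap_target` years. The solver nests a share-matching
#' root-find on `alpha` inside a gap-matching root-find on `beta`. Degenerate
#' share targets (0 or 1) fall back to a constant share with an undefined
#' gap and a warning. Additivity `km_e + km_c = km_total` holds to floating
#' point by construction (`km_c` is computed as the difference).
#'
#' @param bike Per-age total cycling mileage: tibble `year`, `age`, `km_pc`
#'   (mode column, if present, is ignored).
#' @param shares Tibble `year`, `ebike_share` giving each year's target.
#' @param age_gap_target Target mean-age difference (e-bike minus classical)
#'   in years.
#' @param demo Demography table providing populations.
#' @param gap_mode `"every_year"` solves both constraints in every year;
#'   `"base_year"` calibrates `beta` once in the first year and only re-solves
#'   the share constraint (via `alpha`) afterwards, letting the gap drift.
#' @param tol_share,tol_gap,max_iter Solver controls.
#' @return List with `solution` (per-year tibble `year`, `alpha`, `beta`,
#'   `achieved_share`, `achieved_age_gap`) and `mileage` (tibble `year`,
#'   `age`, `mode` in `bike_classical`/`bike_e`, `km_pc`).
#' @export
split_ebike <- function(bike, shares, age_gap_target, demo,
                        gap_mode = c("every_year", "base_year"),
                        tol_share = 1e-10, tol_gap = 1e-3, max_iter = 200L) {
  gap_mode <- match.arg(gap_mode)
  if (any(shares$ebike_share < 0 | shares$ebike_share > 1)) {
    stop("e-bike share targets must lie in [0, 1]")
  }
  df <- dplyr::inner_join(
    bike[, c("year", "age", "km_pc")],
    demo[, c("year", "age", "population")],
    by = c("year", "age")
  )
  years <- sort(unique(df$year))
  beta_fixed <- NULL
  sol_rows <- vector("list", length(years))
  mil_rows <- vector("list", length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    d <- df[df$year == y, ]
    d <- d[order(d$age), ]
    target <- shares$ebike_share[match(y, shares$year)]
    if (is.na(target)) stop("no e-bike share target for year ", y)
    km_national <- d$km_pc * d$population
    if (gap_mode == "base_year" && !is.null(beta_fixed) &&
        target > 0 && target < 1 && sum(km_national) > 0) {
      total <- sum(km_national)
      weighted_share <- function(alpha) {
        sum(km_national * stats::plogis(alpha + beta_fixed * d$age)) / total
      }
      alpha <- stats::uniroot(
        function(a) weighted_share(a) - target,
        interval = stats::qlogis(target) + c(-40, 40), extendInt = "upX",
        tol = 1e-12, maxiter = max_iter
      )$root
      s <- stats::plogis(alpha + beta_fixed * d$age)
      we <- s * km_national
      wc <- km_national - we
      sol <- list(
        alpha = alpha, beta = beta_fixed, s = s,
        achieved_share = sum(we) / total,
        achieved_gap = sum(d$age * we) / sum(we) - sum(d$age * wc) / sum(wc)
      )
    } else {
      sol <- solve_ebike_year(d$age, km_national, target, age_gap_target,
                              tol_share, tol_gap, max_iter)
      if (gap_mode == "base_year") beta_fixed <- sol$beta
    }
    sol_rows[[k]] <- tibble::tibble(
      year = y, alpha = sol$alpha, beta = sol$beta,
      achieved_share = sol$achieved_share, achieved_age_gap = sol$achieved_gap
    )
    km_e <- sol$s * d$km_pc
    mil_rows[[k]] <- tibble::tibble(
      year = y,
      age = rep(d$age, 2),
      mode = rep(c("bike_e", "bike_classical"), each = nrow(d)),
      km_pc = c(km_e, d$km_pc - km_e)
    )
  }
  list(
    solution = dplyr::bind_rows(sol_rows),
    mileage = dplyr::bind_rows(mil_rows)
  )
}
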