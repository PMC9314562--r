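#' Run configuration for the health impact assessment
#'
#' Collects every tunable of the pipeline with defaults equal to the main
#' analysis: a 2021-2050 horizon, a 20-84 effect window, a 6.7-year mean-age
#' gap between e-bike and classical-bike kilometres, an e-bike MET ratio of
#' 0.90, the capped linear dose-response functions of [drf_defaults()], the
#' speeds of [default_speeds()], a VSLY of 139,000 euros-2020 grown at 1.2%
#' per year, and the synthetic-demography parameters of
#' [demography_params()].
#'
#' @param base_year,end_year Scenario horizon (inclusive).
#' @param a_max Highest age in the tables.
#' @param age_window Inclusive age range of the mortality effect.
#' @param age_gap_target Mean-age gap (years) between e-bike and classical
#'   cycled kilometres.
#' @param met_ratio E-bike MET ratio.
#' @param speeds Named speed vector.
#' @param drf Named list of dose-response specs.
#' @param a_fraction Life-table interval fraction.
#' @param interpolation Mileage interpolation method.
#' @param gap_mode See [split_ebike()].
#' @param yll_le `"reference"` uses the common projected residual life
#'   expectancy for YLL in both scenarios; `"scenario"` recomputes residual
#'   life expectancy under each scenario's modified mortality.
#' @param vsly List `base_value`, `base_year`, `growth_rate`.
#' @param demography Synthetic-demography parameter list (see
#'   [demography_params()]).
#' @param age_shapes Age-distribution shapes per mode (see
#'   [default_age_shapes()]).
#' @return A configuration list of class `hia_config`.
#' @export
hia_config <- function(base_year = 2021L,
                       end_year = 2050L,
                       a_max = 110L,
                       age_window = c(20L, 84L),
                       age_gap_target = 6.7,
                       met_ratio = 0.90,
                       speeds = default_speeds(),
                       drf = drf_defaults(),
                       a_fraction = 0.5,
                       interpolation = "monotone",
                       gap_mode = "every_year",
                       yll_le = c("reference", "scenario"),
                       vsly = list(base_value = 139000, base_year = 2020L, growth_rate = 0.012),
                       demography = list(
                         makeham_c = 2e-4, gompertz_b = 1.6e-5, gompertz_theta = 0.1,
                         annual_improvement = 0.005,
                         pyramid_shape = list(
                           bulge_age = 63, bulge_width = 16, bulge_amp = 0.32,
                           old_age_drop = 88, drop_width = 5, wobble_sd = 0.02
                         ),
                         total_population = 65e6
                       ),
                       age_shapes = default_age_shapes()) {
  yll_le <- match.arg(yll_le)
  if (end_year < base_year) stop("empty horizon")
  structure(
    list(
      base_year = as.integer(base_year), end_year = as.integer(end_year),
      a_max = as.integer(a_max), age_window = as.integer(age_window),
      age_gap_target = age_gap_target, met_ratio = met_ratio,
      speeds = speeds, drf = drf, a_fraction = a_fraction,
      interpolation = interpolation, gap_mode = gap_mode, yll_le = yll_le,
      vsly = vsly, demography = demography, age_shapes = age_shapes
    ),
    class = "hia_config"
  )
}

#' Apply configuration overrides
#'
#' Recursively merges a named list of overrides into a configuration,
#' rejecting keys that do not already exist (so a variant cannot silently
#' invent parameters).
#'
#' @param config A configuration (or any named list).
#' @param overrides Named list of replacements; nested lists merge key-wise.
#' @return The updated configuration.
#' @export
apply_overrides <- function(config, overrides) {
  for (k in names(overrides)) {
    if (!k %in% names(config)) stop("unknown configuration key: ", k)
    v <- overrides[[k]]
    if (is.list(v) && is.list(config[[k]]) && !is.null(names(v))) {
      config[[k]] <- apply_overrides(config[[k]], v)
    } else {
      config[[k]] <- v
    }
  }
  config
}

#' Generate the full synthetic input bundle
#'
#' Produces the four inputs the pipeline consumes — demographic projection,
#' mileage trajectory, age distributions, and VSLY series — from a single
#' configuration and seed.
#'
#' @param config A [hia_config()].
#' @param seed Integer seed for the synthetic demography.
#' @param anchors Mileage anchors; defaults to the bundled scenario anchors.
#' @return List `demography`, `mileage`, `age_distribution`, `vsly`, `seed`.
#' @export
synth_inputs <- function(config = hia_config(), seed = 1L,
                         anchors = negawatt_anchors()) {
  dm <- config$demography
  dp <- demography_params(
    base_year = config$base_year, horizon_year = config$end_year,
    a_max = config$a_max, makeham_c = dm$makeham_c, gompertz_b = dm$gompertz_b,
    gompertz_theta = dm$gompertz_theta,
    annual_improvement = dm$annual_improvement,
    pyramid_shape = dm$pyramid_shape,
    total_population = dm$total_population, seed = seed
  )
  years <- config$base_year:config$end_year
  ages <- 0:config$a_max
  dist <- dplyr::bind_rows(lapply(names(config$age_shapes), function(m) {
    d <- do.call(gen_age_distribution, c(list(ages = ages), config$age_shapes[[m]]))
    d$mode <- m
    d[, c("mode", "age", "share")]
  }))
  list(
    demography = gen_demography(dp),
    mileage = gen_mileage(anchors, years, config$interpolation),
    age_distribution = dist,
    vsly = gen_vsly(config$vsly$base_value, config$vsly$base_year,
                    config$vsly$growth_rate, years),
    seed = as.integer(seed)
  )
}

scenario_impacts <- function(traj, inputs, config, bound) {
  demo <- inputs$demography
  allocated <- allocate_mileage(traj, inputs$age_distribution, demo)
  bike <- allocated[allocated$mode == "bike_total", ]
  split <- split_ebike(
    bike, traj[, c("year", "ebike_share")],
    config$age_gap_target, demo, gap_mode = config$gap_mode
  )
  mileage <- dplyr::bind_rows(allocated[allocated$mode == "walk", ], split$mileage)
  exposure <- exposure_surface(mileage, config$speeds, config$met_ratio)
  rr <- rr_surface(exposure, config$drf, config$age_window, bound)
  impact <- deaths_prevented(demo, rr, config$age_window)
  if (config$yll_le == "scenario") {
    demo <- scenario_demography(demo, rr, config$a_fraction)
  }
  impact <- yll_prevented(impact, demo)
  list(mileage = mileage, exposure = exposure, rr = rr,
       impact = impact, split = split$solution)
}

scenario_demography <- function(demo, rr, a_fraction) {
  rr_all <- rr_all_wide(rr)
  out <- demo
  for (y in sort(unique(demo$year))) {
    idx <- which(demo$year == y)
    idx <- idx[order(demo$age[idx])]
    r <- rr_all[rr_all$year == y, ]
    rr_by_age <- r$rr[match(demo$age[idx], r$age)]
    rr_by_age[is.na(rr_by_age)] <- 1
    q <- pmin(demo$mortality_q[idx] * rr_by_age, 1)
    out$residual_le[idx] <- residual_life_expectancy(q, a_fraction)
  }
  out
}

#' Run the full health impact assessment
#'
#' Executes the pipeline end to end for one dose-response bound: builds the
#' frozen reference scenario, allocates mileage across ages for both
#' scenarios, splits cycling into classical and e-bike, converts to
#' MET-adjusted exposure, scales relative risks, computes deaths and YLL
#' averted per scenario, differences them (scenario minus reference),
#' derives the period life-expectancy gain per year, and monetizes the YLL
#' delta.
#'
#' Totals per year use the multiplicative combination of per-mode relative
#' risks (the `"all"` rows); per-mode rows give the additive attribution by
#' travel mode used for mode contributions.
#'
#' @param inputs Input bundle from [synth_inputs()] or [read_hia_inputs()].
#' @param config A [hia_config()].
#' @param bound DRF reduction bound (`"central"`, `"low"`, `"high"`).
#' @return List with `annual` (tibble `year`, `deaths_prevented`,
#'   `yll_prevented`, `benefits_eur`, `le_gain_months` — all scenario minus
#'   reference, totals from the combined relative risk), `impact` (per
#'   (year, age, mode) delta), `mode_contributions` (per-mode cumulative
#'   deaths/YLL shares), `le_gain`, `benefits`, `split` (per-scenario solver
#'   diagnostics), `scenario`/`reference` (full per-scenario results),
#'   `bound` and `config`.
#' @export
run_hia <- function(inputs, config = hia_config(),
                    bound = c("central", "low", "high")) {
  bound <- match.arg(bound)
  traj <- inputs$mileage
  ref_traj <- build_reference_scenario(traj, config$base_year)
  scen <- scenario_impacts(traj, inputs, config, bound)
  ref <- scenario_impacts(ref_traj, inputs, config, bound)
  delta <- scenario_delta(scen$impact, ref$impact)
  le_gain <- life_expectancy_gain(inputs$demography, scen$rr, ref$rr,
                                  a_fraction = config$a_fraction)
  all_delta <- delta[delta$mode == "all", ]
  yll_by_year <- dplyr::summarise(
    dplyr::group_by(all_delta, .data$year),
    deaths = sum(.data$deaths_prevented),
    yll = sum(.data$yll_prevented), .groups = "drop"
  )
  benefits <- monetize(yll_by_year[, c("year", "yll")], inputs$vsly)
  annual <- tibble::tibble(
    year = yll_by_year$year,
    deaths_prevented = yll_by_year$deaths,
    yll_prevented = yll_by_year$yll,
    benefits_eur = benefits$annual$benefits_eur
  )
  annual <- dplyr::inner_join(annual, le_gain, by = "year")
  per_mode <- delta[delta$mode != "all", ]
  contrib <- dplyr::summarise(
    dplyr::group_by(per_mode, .data$mode),
    deaths_prevented = sum(.data$deaths_prevented),
    yll_prevented = sum(.data$yll_prevented), .groups = "drop"
  )
  contrib$deaths_share <- contrib$deaths_prevented / sum(contrib$deaths_prevented)
  contrib$yll_share <- contrib$yll_prevented / sum(contrib$yll_prevented)
  list(
    annual = annual, impact = delta, mode_contributions = contrib,
    le_gain = le_gain, benefits = benefits,
    split = list(scenario = scen$split, reference = ref$split),
    scenario = scen, reference = ref,
    bound = bound, config = config
  )
}

# ---- CSV input/output -------------------------------------------------------

input_schemas <- function() {
  list(
    demography = c("year", "age", "population", "mortality_q", "residual_le"),
    mileage = c("year", "walk_km_pc", "cycle_km_pc", "ebike_share"),
    age_distribution = c("mode", "age", "share"),
    vsly = c("year", "vsly_eur")
  )
}

#' Write the input bundle to CSV files
#'
#' Writes `demography.csv`, `mileage.csv`, `age_distribution.csv` and
#' `vsly.csv` into a directory, each with a header comment carrying the seed
#' and a content hash, so a run's inputs are self-describing and
#' reproducible byte for byte.
#'
#' @param inputs Input bundle.
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the headers (defaults to `inputs$seed`).
#' @return Invisibly, the paths written.
#' @export
write_hia_inputs <- function(inputs, dir, seed = inputs$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schemas <- input_schemas()
  paths <- character(0)
  for (name in names(schemas)) {
    tab <- inputs[[name]][, schemas[[name]]]
    path <- file.path(dir, paste0(name, ".csv"))
    body <- readr::format_csv(tab)
    # hash the serialized text, not the R object, so the fingerprint is
    # stable across internal vector representations
    header <- sprintf("# seed=%s hash=%s\n", seed, rlang::hash(body))
    cat(header, body, file = path, sep = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read an input bundle from CSV files
#'
#' Counterpart of [write_hia_inputs()]; validates each file against its
#' schema and reports the offending file and columns on mismatch.
#'
#' @param dir Directory containing the four input CSVs.
#' @return Input bundle list as produced by [synth_inputs()] (without the
#'   seed element).
#' @export
read_hia_inputs <- function(dir) {
  schemas <- input_schemas()
  out <- lapply(names(schemas), function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop("missing input file: ", path)
    # base read.csv: correctly-rounded double parsing, so the shortest
    # round-trippable representations written above re-read losslessly
    tab <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
    missing <- setdiff(schemas[[name]], names(tab))
    if (length(missing) > 0) {
      stop(name, ".csv missing column(s): ", paste(missing, collapse = ", "))
    }
    tab[, schemas[[name]]]
  })
  names(out) <- names(schemas)
  out
}

#' Write a run configuration to YAML
#'
#' @param config A [hia_config()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$speeds <- as.list(out$speeds) # YAML map keeps the mode names
  out$drf <- lapply(out$drf, unclass)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Values found in the file override the package defaults; unknown keys are
#' rejected. Vector-valued fields serialized as YAML sequences are coerced
#' back.
#'
#' @param path YAML file with (a subset of) configuration keys.
#' @return A [hia_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- apply_overrides(hia_config(), raw)
  cfg$age_window <- as.integer(unlist(cfg$age_window))
  cfg$speeds <- unlist(cfg$speeds)
  for (f in names(cfg$drf)) {
    if (!inherits(cfg$drf[[f]], "drf_spec")) {
      cfg$drf[[f]] <- do.call(drf_spec, cfg$drf[[f]][c("central", "low", "high", "ref_minutes", "cap")])
    }
  }
  cfg
}
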