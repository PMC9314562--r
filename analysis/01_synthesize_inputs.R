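#!/usr/bin/env Rscript

# Step 1 — generate the synthetic input bundle.
#
# Produces the four inputs the assessment consumes: a demographic projection
# (population, mortality, residual life expectancy by 1-year age and year),
# the scenario mileage trajectory (anchored at the printed walking/cycling
# values with monotone interpolation), reference age distributions of
# mileage per mode, and the VSLY series. Everything is written under
# results/inputs/ as self-describing CSVs (seed + content hash in the
# header).

suppressPackageStartupMessages(library(activehia))

seed <- 20260923L
config <- hia_config()
inputs <- synth_inputs(config, seed = seed)
write_hia_inputs(inputs, "results/inputs", seed = seed)
write_run_config(config, "results/inputs/run_config.yaml")

demo <- inputs$demography
base <- demo[demo$year == config$base_year, ]
y40 <- demo[demo$year == 2040, ]
share75 <- function(d) sum(d$population[d$age >= 75]) / sum(d$population)

cat(sprintf(
  paste0(
    "Synthetic inputs written to results/inputs (seed %d).\n",
    "Life expectancy at birth, %d: %.1f years\n",
    "Population share aged 75+: %.1f%% (%d) -> %.1f%% (2040)\n",
    "Cycling: %.1f km/inh/wk (%d) -> %.1f (2040), peak %.1f (2045)\n",
    "E-bike share of cycled km: %.1f%% (%d) -> %.0f%% (2040)\n"
  ),
  seed, config$base_year, base$residual_le[base$age == 0],
  100 * share75(base), config$base_year, 100 * share75(y40),
  inputs$mileage$cycle_km_pc[1], config$base_year,
  inputs$mileage$cycle_km_pc[inputs$mileage$year == 2040],
  inputs$mileage$cycle_km_pc[inputs$mileage$year == 2045],
  100 * inputs$mileage$ebike_share[1], config$base_year,
  100 * inputs$mileage$ebike_share[inputs$mileage$year == 2040]
))
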