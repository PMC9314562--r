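#!/usr/bin/env Rscript

# Step 2 — build the two scenarios' exposure surfaces.
#
# Allocates each year's national mileage across 1-year ages with the
# reference age distribution, splits cycling into classical and e-bike
# kilometres under the per-year share target and the 6.7-year mean-age-gap
# constraint, and does the same for the reference scenario (mileage frozen
# at base-year levels). Writes the per-age mileage and the split-solver
# diagnostics.

suppressPackageStartupMessages({
  library(activehia)
  library(dplyr)
})

if (!dir.exists("results/inputs")) stop("run analysis/01_synthesize_inputs.R first")
inputs <- read_hia_inputs("results/inputs")
config <- read_run_config("results/inputs/run_config.yaml")

build <- function(traj, label) {
  allocated <- allocate_mileage(traj, inputs$age_distribution, inputs$demography)
  bike <- allocated[allocated$mode == "bike_total", ]
  split <- split_ebike(bike, traj[, c("year", "ebike_share")],
                       config$age_gap_target, inputs$demography)
  mileage <- bind_rows(allocated[allocated$mode == "walk", ], split$mileage) |>
    mutate(scenario = label)
  diag <- mutate(split$solution, scenario = label)
  list(mileage = mileage, diag = diag)
}

scen <- build(inputs$mileage, "negawatt")
ref <- build(build_reference_scenario(inputs$mileage, config$base_year), "reference")

readr::write_csv(bind_rows(scen$mileage, ref$mileage), "results/age_mileage.csv")
readr::write_csv(bind_rows(scen$diag, ref$diag), "results/split_diagnostics.csv")

d <- scen$diag
cat(sprintf(
  paste0(
    "Scenario exposure written to results/age_mileage.csv.\n",
    "E-bike split solver: share hit to within %.1e, age gap %.2f-%.2f years\n",
    "Logistic age slope beta ranges %.4f-%.4f (e-bike skews older throughout)\n"
  ),
  max(abs(d$achieved_share - inputs$mileage$ebike_share)),
  min(d$achieved_age_gap), max(d$achieved_age_gap),
  min(d$beta), max(d$beta)
))
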