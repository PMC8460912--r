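#!/usr/bin/env Rscript
# Stage 1: simulate the reactor pair and write the "measured" data set.
#
# Produces noiseless ground-truth trajectories for both reactors, overlays
# measurement noise (5% CV on liquid concentrations, 0.005 absolute sd on
# gas fractions), and writes the liquid/gas series and gas event logs that
# the downstream stages consume, exactly as they would consume HPLC/GC
# monitoring data from a real campaign.

source("analysis/scenarios.R")

for (side in c("test", "control")) {
  sc <- if (side == "test") test_scenario() else control_scenario()
  traj <- simulate_reactor(sc)
  obs <- apply_noise(traj, seed = SEEDS[[side]])
  write_liquid_csv(obs$liquid, results_path(paste0("liquid_", side, ".csv")))
  write_gas_csv(obs$gas, results_path(paste0("gas_", side, ".csv")))
  write_events_json(obs$events, results_path(paste0("events_", side, ".json")))
  cat(sprintf(
    "%s reactor: %d liquid samples, %d gas samples, %d refills, true cumulative O2 ingress %.0f mL\n",
    side, nrow(obs$liquid), nrow(obs$gas), nrow(obs$events) - 1,
    traj$truth$cum_o2_leak_ml))
}

cat("\nGround truth for the contamination period (mmol L-1 d-1):\n")
tru <- true_rates(simulate_reactor(test_scenario()), CONTAMINATION)
print(round(tru[c("ch4", "n-caproate", "propionate", "n-butyrate",
                  "lactate", "h2")], 2))
cat("true O2 leak:",
    true_o2_rate(simulate_reactor(test_scenario()), CONTAMINATION),
    "mL O2 L-1 d-1\n")
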