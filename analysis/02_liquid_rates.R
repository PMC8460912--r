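#!/usr/bin/env Rscript
# Stage 2: dilution-corrected volumetric rates from the liquid series.
#
# Reads the measured liquid series written by stage 1 and computes the
# production/consumption rates over the pre-contamination and contamination
# periods (CSTR form r = slope + D(Cmean - Cfeed)), plus the concentration
# maxima in g/L for the product carboxylates.

source("analysis/scenarios.R")

feed <- c(lactate = 133, acetate = 200)
for (side in c("test", "control")) {
  series <- read_liquid_csv(results_path(paste0("liquid_", side, ".csv")))
  rt <- rate_table(series, periods = list(PRE_PERIOD, CONTAMINATION),
                   feed = feed, hrt = 14)
  utils::write.csv(rt, results_path(paste0("rates_", side, ".csv")),
                   row.names = FALSE)
  cat("\n", side, "reactor rates (mmol L-1 d-1):\n")
  print(rt[rt$compound %in% c("lactate", "acetate", "propionate",
                              "n-butyrate", "n-caproate"), ], digits = 3)

  maxima <- vapply(c("propionate", "n-butyrate", "n-caproate"), function(cn)
    as.numeric(max_concentration(series, cn, unit = "gL")), numeric(1))
  cat(side, "maxima (g/L):",
      paste(sprintf("%s %.1f", names(maxima), maxima), collapse = ", "), "\n")
}
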