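#!/usr/bin/env Rscript
# Stage 4: degree-of-reduction electron ledger for the test reactor.
#
# Combines the liquid rate table (stage 2) and the gas rates and O2 estimate
# (stage 3) into an electron-equivalent ledger per period: feed substrates
# and reservoir H2 in, products, residual substrates, CH4 and the O2
# electron-accepting sink out, with the percent closure error (negative =
# unexplained consumption of the supplied electron pool).

source("analysis/scenarios.R")

rt <- utils::read.csv(results_path("rates_test.csv"), check.names = FALSE)
class(rt) <- c("rate_table", class(rt))
gx <- utils::read.csv(results_path("gas_oxygen.csv"), check.names = FALSE)
feed <- c(lactate = 133, acetate = 200)

for (p in list(PRE_PERIOD, CONTAMINATION)) {
  g <- gx[gx$period == p$label, ]
  led <- build_ledger(rt, gas_rates = c(h2 = g$h2_rate, ch4 = g$ch4_rate),
                      o2_estimate = max(0, g$o2_rate), period = p,
                      feed = feed, hrt = 14, liquid_volume = 1)
  print(led)
  rep <- ledger_report(led)
  utils::write.csv(rep, results_path(
    paste0("ledger_", gsub("[^A-Za-z0-9]+", "_", p$label), ".csv")),
    row.names = FALSE)
  top <- rep[rep$side == "out", ][1:3, ]
  cat("  top electron outflows:",
      paste(sprintf("%s %.0f%%", top$compound, top$share_pct),
            collapse = ", "), "\n")
}
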