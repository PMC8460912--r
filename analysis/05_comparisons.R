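#!/usr/bin/env Rscript
# Stage 5: test-vs-control contrasts.
#
# Aligns the two rate tables into a contrast table (unrounded percent and
# fold changes stored; integer percent in the report column) and phrases the
# headline contrasts of the contamination period the way reactor studies
# report them.

source("analysis/scenarios.R")

rt_t <- utils::read.csv(results_path("rates_test.csv"), check.names = FALSE)
rt_c <- utils::read.csv(results_path("rates_control.csv"), check.names = FALSE)
tab <- comparison_table(rt_t, rt_c)
utils::write.csv(tab, results_path("contrasts.csv"), row.names = FALSE)

cat("Contamination-period contrasts (test vs control):\n")
sub <- tab[tab$period == CONTAMINATION$label &
             tab$compound %in% c("propionate", "n-butyrate", "n-caproate",
                                 "lactate"), ]
print(sub, digits = 3)

cat("\nPhrased:\n")
for (i in seq_len(nrow(sub))) {
  if (is.na(sub$pct_change[i]) || sub$control_rate[i] <= 0) next
  cat(" ", sub$compound[i], "production",
      contrast_phrase(sub$test_rate[i], sub$control_rate[i]), "\n")
}
cat("\npropionate fold change:",
    round_half_out(fold_change(
      sub$test_rate[sub$compound == "propionate"],
      sub$control_rate[sub$compound == "propionate"]), 1), "x control\n")
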