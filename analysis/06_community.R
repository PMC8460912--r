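#!/usr/bin/env Rscript
# Stage 6: synthetic community counts, rarefaction, and the significance-
# masked Spearman matrix.
#
# The correlation stage needs variation, so it runs on a multi-phase
# campaign: six 10-day operation phases of distinct methanogenic activity,
# three of them with air leaks of different strength (all scavenged by H2
# oxidation, as in the O2-below-detection regime). A genus count table is
# sampled with a softmax link (a methanogen-like genus follows the CH4 rate,
# an aerotolerant genus is favored when methanogenesis is suppressed),
# rarefied to the shallowest sample, and correlated with the campaign's
# process covariates at p < 0.01.

source("analysis/scenarios.R")

campaign_scenario <- function() {
  rs <- data.frame(
    reaction = c(rep("methanogenesis", 6), "h2_oxidation"),
    t_start = c(seq(0, 50, 10), 0),
    t_end   = c(seq(10, 60, 10), 60),
    extent  = c(16.5, 4, 14, 5.5, 19.5, 6.05, 25))
  leak <- data.frame(t_start = c(10, 30, 50), t_end = c(20, 40, 60),
                     o2_rate = c(220, 129, 471))
  reactor_scenario(duration = 60, rate_schedule = rs, leak_schedule = leak)
}

traj <- simulate_reactor(campaign_scenario())
stimes <- seq(5, 55, 10)

link <- community_link_spec(
  taxa = c("methanogen_like", "aerotolerant", "fermenter_1", "fermenter_2"),
  intercepts = c(0, 6.5, 2.6, 2.2),
  coefs = matrix(c(0.35, -0.25, 0, 0), 4, 1),
  rate_vars = "ch4",
  dispersion = 400, depth_range = c(4977, 15000), seed = SEEDS$community)
counts <- generate_community(traj, link, sample_times = stimes)
write_counts_tsv(counts, results_path("counts.tsv"))

rare <- rarefy_counts(counts, seed = SEEDS$rarefy)
write_counts_tsv(rare, results_path("counts_rarefied.tsv"))
cat("rarefied", nrow(rare), "samples to depth", sum(rare[1, ]), "\n")

rel <- filter_abundant(relative_abundance(rare))
ch4 <- vapply(stimes, function(t)
  true_rates(traj, rate_period(t - 2, t + 2))[["ch4"]], numeric(1))
o2 <- vapply(stimes, function(t)
  true_o2_rate(traj, rate_period(t - 2, t + 2)), numeric(1))
sm <- spearman_matrix(rel, cbind(ch4_production = ch4, o2_contamination = o2),
                      alpha = 0.01, seed = SEEDS$spearman)
print(sm)
utils::write.csv(as.data.frame(round(sm$rho, 3)),
                 results_path("spearman_rho.csv"))
utils::write.csv(as.data.frame(sm$mask), results_path("spearman_mask.csv"))
cat("significant at p < 0.01:\n")
sig <- which(sm$mask & upper.tri(sm$mask), arr.ind = TRUE)
for (k in seq_len(nrow(sig)))
  cat(sprintf("  %s ~ %s: rho = %.2f (p = %.4f)\n",
              rownames(sm$rho)[sig[k, 1]], colnames(sm$rho)[sig[k, 2]],
              sm$rho[sig[k, 1], sig[k, 2]],
              sm$p[sig[k, 1], sig[k, 2]]))
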