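# Shared study definition for the analysis scripts: a stirred-reactor pair
# over one air-contamination comparison period, mirroring the study design
# the simulator emulates (1 L, HRT 14 d, 133 mM lactate + 200 mM acetate
# feed, 10 L H2:CO2 80:20 + 240 mL ethylene + 120 mL He refills). The test
# reactor takes a 220 mL O2 L-1 d-1 air leak on days 27-59, scavenged by H2
# oxidation; reaction extents switch at day 27 to the contaminated-period
# rates (CH4 16.5 -> 6.05, n-caproate 2.12 -> 0.56, propionate
# 0.12 -> 0.76 mmol L-1 d-1).

library(o2balance)

DURATION <- 59
CONTAMINATION <- rate_period(27, 59, "days 27-59")
PRE_PERIOD <- rate_period(5, 27, "days 5-27")
SEEDS <- list(test = 101L, control = 102L, community = 7L,
              rarefy = 8L, spearman = 9L)

control_scenario <- function() {
  rs <- data.frame(
    reaction = c("methanogenesis", "lactate_to_propionate",
                 "elongation_c4", "elongation_c6"),
    t_start = 0, t_end = DURATION,
    extent = c(16.5, 0.06, 3.63, 2.12))
  reactor_scenario(duration = DURATION, rate_schedule = rs)
}

test_scenario <- function() {
  rs <- data.frame(
    reaction = c("methanogenesis", "lactate_to_propionate",
                 "elongation_c4", "elongation_c6",
                 "methanogenesis", "lactate_to_propionate",
                 "elongation_c4", "elongation_c6", "h2_oxidation"),
    t_start = c(rep(0, 4), rep(27, 5)),
    t_end   = c(rep(27, 4), rep(DURATION, 5)),
    extent  = c(16.5, 0.06, 3.63, 2.12,
                6.05, 0.38, 2.07, 0.56, 25))
  leak <- data.frame(t_start = 27, t_end = DURATION, o2_rate = 220)
  reactor_scenario(duration = DURATION, rate_schedule = rs,
                   leak_schedule = leak)
}

results_path <- function(...) {
  dir.create("results", showWarnings = FALSE)
  file.path("results", ...)
}
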