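test_that("helium dilution gives the system gas volume", {
  expect_equal(estimate_gas_volume(120, 0.012), 10000)
  expect_equal(estimate_gas_volume(240, 0.02), 12000)
  expect_error(estimate_gas_volume(120, 5e-5), "unreliable tracer")
  # against simulator truth, He fraction + refill log recover v_gas
  tr <- cached_trajectory("test")
  last <- tr$gas[nrow(tr$gas), ]
  he_added <- sum(tr$events$vol_he_ml[tr$events$time_d <= last$time_d])
  expect_equal(estimate_gas_volume(he_added, last$y_he) / last$v_gas_ml, 1,
               tolerance = 1e-6)
})

test_that("the N2-based estimator evaluates its closed form", {
  s1 <- list(time_d = 0, y_n2 = 0.1, v_gas_ml = 10000)
  s2 <- list(time_d = 10, y_n2 = 0.1, v_gas_ml = 10000)
  expect_equal(as.numeric(o2_contamination_rate(s1, s2, 1)), 0)
  s2$y_n2 <- 0.0373; s1$y_n2 <- 0
  expect_equal(as.numeric(o2_contamination_rate(s1, s2, 1)),
               0.0373 * 10000 / (3.73 * 10), tolerance = 1e-12)
  # validity warning once O2 is detectable
  s1$y_o2 <- 0.05
  expect_match(attr(o2_contamination_rate(s1, s2, 1), "validity_warning"),
               "detection threshold")
  expect_error(o2_contamination_rate(s2, s1, 1))
})

test_that("a constant true leak is recovered within 2% from the gas series", {
  tr <- cached_trajectory("test")
  est <- suppressWarnings(
    o2_rate_with_uncertainty(tr$gas, contamination_period(), 1))
  expect_equal(est$rate / 220, 1, tolerance = 0.02)
})

test_that("holding v_gas constant biases the estimate ever lower as air accumulates", {
  bias <- vapply(c(55, 220, 550, 1100), function(L) {
    leak <- data.frame(t_start = 0, t_end = 32, o2_rate = L)
    sc <- reactor_scenario(duration = 32, leak_schedule = leak)
    g <- simulate_reactor(sc)$gas
    g$v_gas_ml <- g$v_gas_ml[1]  # constant-volume approximation
    est <- suppressWarnings(o2_rate_with_uncertainty(g, rate_period(0, 32), 1))
    (est$rate - L) / L
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
  expect_true(all(bias <= 0))
})

test_that("control-derived standard errors match a Monte-Carlo reference", {
  tr <- cached_trajectory("test")
  ctl <- cached_trajectory("control")
  p <- contamination_period()
  # noiseless control: all interval rates are ~0, se ~ 0
  est0 <- o2_rate_with_uncertainty(tr$gas, p, 1, control_samples = ctl$gas)
  expect_lt(est0$se, 1e-6)
  # noisy: reported se within 30% of the spread of 200 replicate estimates
  rates <- ses <- numeric(200)
  for (s in 1:200) {
    ntr <- apply_noise(tr, seed = s)
    nctl <- apply_noise(ctl, seed = s + 5000)
    est <- o2_rate_with_uncertainty(ntr$gas, p, 1, control_samples = nctl$gas)
    rates[s] <- est$rate; ses[s] <- est$se
  }
  expect_lt(abs(mean(ses) - stats::sd(rates)) / stats::sd(rates), 0.3)
  # and the 2-se interval covers the true 220 in >= 90% of seeds
  expect_gte(sum(abs(rates - 220) <= 2 * ses), 180)
  expect_error(
    o2_rate_with_uncertainty(tr$gas, p, 1, control_samples = ctl$gas[1:3, ]),
    "fewer than 3 intervals")
})

test_that("gas species rates discount refills and keep the tracer at zero", {
  # hand-built series: one 8 L H2 refill, no reactions
  g <- data.frame(time_d = c(0, 10), y_h2 = c(0.5, 0.75),
                  v_gas_ml = c(8000, 12000))
  ev <- data.frame(time_d = 5, type = "refill", vol_h2_ml = 5000)
  expect_equal(gas_species_rate(g, ev, "h2", rate_period(0, 10), 1), 0)
  # simulator: methanogenesis extent is recovered exactly; He rate is 0
  tr <- cached_trajectory("control")
  p <- contamination_period()
  expect_equal(gas_species_rate(tr$gas, tr$events, "ch4", p, 1) / 16.5, 1,
               tolerance = 0.01)
  expect_equal(gas_species_rate(tr$gas, tr$events, "he", p, 1), 0,
               tolerance = 1e-9)
})

test_that("H2 attribution is the 4x methanogenesis discount, linearly", {
  a <- attribute_h2(80, 16.5)
  expect_equal(a$ch4_attributed_h2, 66)
  expect_equal(a$non_ch4_h2, 14)
  expect_equal(attribute_h2(10, 0), list(ch4_attributed_h2 = 0,
                                         non_ch4_h2 = 10))
  expect_equal(attribute_h2(66, 16.5)$non_ch4_h2, 0)
  # linearity in both arguments
  a1 <- attribute_h2(30, 4); a2 <- attribute_h2(12, 2.5)
  ab <- attribute_h2(42, 6.5)
  expect_equal(ab$ch4_attributed_h2, a1$ch4_attributed_h2 + a2$ch4_attributed_h2)
  expect_equal(ab$non_ch4_h2, a1$non_ch4_h2 + a2$non_ch4_h2)
})

test_that("the H2:O2 molar ratio reproduces the oxidation stoichiometry", {
  expect_equal(as.numeric(h2_o2_ratio(2, 22.414)), 2, tolerance = 1e-12)
  expect_error(h2_o2_ratio(2, 0), "undefined ratio")
  # scenario where only H2 oxidation consumes H2 at the leak's pace
  rs <- data.frame(reaction = "h2_oxidation", t_start = 0, t_end = 32,
                   extent = 25)
  leak <- data.frame(t_start = 0, t_end = 32, o2_rate = 220)
  sc <- reactor_scenario(duration = 32, rate_schedule = rs,
                         leak_schedule = leak)
  tr <- simulate_reactor(sc)
  p <- rate_period(0, 32)
  h2 <- gas_species_rate(tr$gas, tr$events, "h2", p, 1)
  o2 <- suppressWarnings(o2_rate_with_uncertainty(tr$gas, p, 1))$rate
  ratio <- h2_o2_ratio(attribute_h2(-h2, 0)$non_ch4_h2, o2)
  expect_equal(as.numeric(ratio) / 2, 1, tolerance = 0.02)
})
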