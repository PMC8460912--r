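test_that("zero extents with feed equal to initial state is a fixed point", {
  sc <- reactor_scenario(duration = 10)
  tr <- simulate_reactor(sc)
  for (cn in setdiff(names(tr$liquid), "time_d"))
    expect_equal(diff(range(tr$liquid[[cn]])), 0)
  expect_equal(diff(range(tr$gas$v_gas_ml)), 0)
  tru <- true_rates(tr, rate_period(0, 10))
  if (length(tru)) expect_true(all(tru == 0))
})

test_that("methanogenesis shrinks the gas loop by the stoichiometric volume", {
  # 4 H2 + 1 CO2 in, 1 CH4 out: net (4+1-1) * extent * 22.414 mL per day
  rs <- data.frame(reaction = "methanogenesis", t_start = 0, t_end = 3,
                   extent = 16.5)
  sc <- reactor_scenario(duration = 3, rate_schedule = rs,
                         sample_interval = 1)
  tr <- simulate_reactor(sc)
  expect_identical(nrow(tr$events), 1L)  # no refill inside the window
  dv <- diff(tr$gas$v_gas_ml[1:2])
  expect_equal(dv, -4 * 16.5 * 22.414 * 1, tolerance = 1e-9)
})

test_that("an air leak adds N2 at 3.73 times the O2 rate", {
  leak <- data.frame(t_start = 0, t_end = 32, o2_rate = 220)
  sc <- reactor_scenario(duration = 32, leak_schedule = leak)
  tr <- simulate_reactor(sc)
  expect_equal(tr$truth$cum_n2_leak_ml, 3.73 * 220 * 32, tolerance = 1e-9)
  # all of it is still in the loop (no N2 sinks)
  last <- tr$gas[nrow(tr$gas), ]
  expect_equal(last$y_n2 * last$v_gas_ml, 3.73 * 220 * 32, tolerance = 1e-6)
})

test_that("noiseless runs conserve every element and electron equivalents", {
  for (which in c("test", "control")) {
    expect_lt(element_closure_residual(cached_trajectory(which)), 1e-6)
  }
})

test_that("helium inventory equals cumulative refill helium exactly", {
  tr <- cached_trajectory("test")
  acc <- tr$truth$accounting
  expect_identical(unname(acc$final_gas_mmol["he"]),
                   unname(acc$refill_mmol["he"]))
  last <- tr$gas[nrow(tr$gas), ]
  he_before_last_sample <- sum(tr$events$vol_he_ml[
    tr$events$time_d <= last$time_d])
  expect_equal(last$y_he * last$v_gas_ml, he_before_last_sample,
               tolerance = 1e-9)
})

test_that("O2 stays at trace levels when scavenging matches the leak", {
  tr <- cached_trajectory("test")  # H2-oxidation extent 25 > leak 9.8 mmol
  expect_lt(max(tr$gas$y_o2), 1e-3)
  # without scavenging, O2 becomes plainly detectable
  leak <- data.frame(t_start = 0, t_end = 32, o2_rate = 220)
  sc <- reactor_scenario(duration = 32, leak_schedule = leak)
  tr2 <- simulate_reactor(sc)
  expect_gt(max(tr2$gas$y_o2), 0.05)
})

test_that("depleting an unlimited gas substrate raises a cited error", {
  rs <- data.frame(reaction = "methanogenesis", t_start = 0, t_end = 20,
                   extent = 16.5)
  sc <- reactor_scenario(duration = 20, rate_schedule = rs,
                         refill = list(volumes_ml = c(h2 = 8000, co2 = 2000,
                                                      ethylene = 240, he = 120),
                                       trigger_ml = 0))
  expect_error(simulate_reactor(sc),
               "gas reservoir driven negative for '(h2|co2)'")
})

test_that("driving a liquid concentration negative cites a step-size error", {
  rs <- data.frame(reaction = "elongation_c6", t_start = 0, t_end = 20,
                   extent = 5)  # consumes n-butyrate that is never produced
  sc <- reactor_scenario(duration = 20, rate_schedule = rs)
  expect_error(simulate_reactor(sc), "negative concentration for 'n-butyrate'")
})

test_that("measurement noise is seed-reproducible and vanishes at zero", {
  tr <- cached_trajectory("control")
  expect_equal(apply_noise(tr, liquid_cv = 0, gas_sd = 0, seed = 7),
               tr)
  n1 <- apply_noise(tr, seed = 42)
  n2 <- apply_noise(tr, seed = 42)
  expect_identical(n1$liquid, n2$liquid)
  expect_identical(n1$gas, n2$gas)
  expect_false(identical(apply_noise(tr, seed = 43)$liquid, n1$liquid))
})

test_that("lognormal liquid noise reproduces the requested CV", {
  flat <- data.frame(time_d = seq(0, 999), lactate = rep(100, 1000))
  tr <- cached_trajectory("control")
  tr$liquid <- flat
  noisy <- apply_noise(tr, liquid_cv = 0.05, gas_sd = 0, seed = 11)
  cv <- stats::sd(noisy$liquid$lactate) / mean(noisy$liquid$lactate)
  expect_gt(cv, 0.04)
  expect_lt(cv, 0.06)
})

test_that("gas fractions stay a composition after noise", {
  noisy <- apply_noise(cached_trajectory("test"), seed = 5)
  Y <- as.matrix(noisy$gas[, grep("^y_", names(noisy$gas))])
  expect_true(all(Y >= 0))
  expect_equal(unname(rowSums(Y)), rep(1, nrow(Y)), tolerance = 1e-12)
})
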