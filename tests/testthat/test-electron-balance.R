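.ledger_inputs <- function(tr, p, method = "endpoint") {
  sc <- tr$scenario
  rt <- rate_table(tr$liquid, periods = list(p), feed = sc$feed,
                   hrt = sc$hrt, method = method)
  ch4 <- gas_species_rate(tr$gas, tr$events, "ch4", p, sc$liquid_volume)
  h2 <- gas_species_rate(tr$gas, tr$events, "h2", p, sc$liquid_volume)
  o2 <- suppressWarnings(
    o2_rate_with_uncertainty(tr$gas, p, sc$liquid_volume))$rate
  list(rt = rt, gas = c(h2 = h2, ch4 = ch4), o2 = max(0, o2), sc = sc)
}

test_that("a lone balanced fermentation closes the ledger", {
  rs <- data.frame(reaction = "lactate_to_propionate", t_start = 0,
                   t_end = 40, extent = 2)
  sc <- reactor_scenario(duration = 40, rate_schedule = rs)
  tr <- simulate_reactor(sc)
  p <- rate_period(0, 40)
  x <- .ledger_inputs(tr, p)
  led <- build_ledger(x$rt, gas_rates = NULL, o2_estimate = NULL, period = p,
                      feed = sc$feed, hrt = sc$hrt, liquid_volume = 1)
  expect_lt(abs(led$error_pct), 0.1)
})

test_that("the full multi-reaction noiseless scenario closes within 0.1%", {
  tr <- cached_trajectory("test")
  p <- contamination_period()
  x <- .ledger_inputs(tr, p)
  led <- build_ledger(x$rt, gas_rates = x$gas, o2_estimate = x$o2, period = p,
                      feed = x$sc$feed, hrt = x$sc$hrt, liquid_volume = 1)
  expect_lt(abs(led$error_pct), 0.1)
})

test_that("dropping the CH4 outflow leaves exactly its share missing", {
  # methanogenesis extent chosen so CH4 carries ~10% of the inflow pool
  rs <- data.frame(reaction = "methanogenesis", t_start = 0, t_end = 40,
                   extent = 3.18)
  sc <- reactor_scenario(duration = 40, rate_schedule = rs)
  tr <- simulate_reactor(sc)
  p <- rate_period(0, 40)
  x <- .ledger_inputs(tr, p)
  full <- build_ledger(x$rt, gas_rates = x$gas, o2_estimate = NULL,
                       period = p, feed = sc$feed, hrt = sc$hrt,
                       liquid_volume = 1)
  no_ch4 <- build_ledger(x$rt, gas_rates = x$gas["h2"], o2_estimate = NULL,
                         period = p, feed = sc$feed, hrt = sc$hrt,
                         liquid_volume = 1)
  ch4_share <- 100 * full$flows$e_mmol[full$flows$compound == "ch4_produced"] /
    full$e_in
  expect_equal(ch4_share, 10, tolerance = 0.05)
  expect_equal(no_ch4$error_pct, full$error_pct - ch4_share,
               tolerance = 1e-9)
  expect_equal(no_ch4$error_pct, -10, tolerance = 0.2)
})

test_that("removing any single flow shifts the error by its signed share", {
  tr <- cached_trajectory("test")
  p <- contamination_period()
  x <- .ledger_inputs(tr, p)
  led <- build_ledger(x$rt, gas_rates = x$gas, o2_estimate = x$o2, period = p,
                      feed = x$sc$feed, hrt = x$sc$hrt, liquid_volume = 1)
  fl <- led$flows
  for (i in which(fl$side == "out")) {
    err_wo <- 100 * ((led$e_out - fl$e_mmol[i]) - led$e_in) / led$e_in
    expect_equal(err_wo, led$error_pct - 100 * fl$e_mmol[i] / led$e_in,
                 tolerance = 1e-9)
  }
})

test_that("noisy replicates keep the closure error within a few percent", {
  tr <- cached_trajectory("test")
  p <- contamination_period()
  hits <- 0L
  for (s in 1:100) {
    ntr <- apply_noise(tr, seed = s)
    x <- .ledger_inputs(ntr, p, method = "regression")
    led <- build_ledger(x$rt, gas_rates = x$gas, o2_estimate = x$o2,
                        period = p, feed = x$sc$feed, hrt = x$sc$hrt,
                        liquid_volume = 1)
    if (abs(led$error_pct) <= 3) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})

test_that("ledger reports rank flows with shares summing to 100 per side", {
  led <- structure(list(
    flows = data.frame(side = c("in", "out", "out"),
                       compound = c("feed_lactate", "propionate", "ch4"),
                       e_mmol = c(100, 75, 25)),
    e_in = 100, e_out = 100, error_pct = 0,
    period = rate_period(0, 1)), class = "electron_ledger")
  rep <- ledger_report(led)
  expect_equal(rep$share_pct[rep$side == "in"], 100)
  expect_equal(sum(rep$share_pct[rep$side == "out"]), 100)
  expect_identical(rep$compound[rep$side == "out"], c("propionate", "ch4"))
  # symmetric two-flow side splits 50/50
  led$flows$e_mmol <- c(100, 50, 50)
  expect_equal(ledger_report(led)$share_pct[2:3], c(50, 50))
  # three-compound toy against hand-computed shares
  led$flows <- data.frame(side = "out", compound = c("a", "b", "c"),
                          e_mmol = c(20, 30, 50))
  expect_equal(ledger_report(led)$share_pct, c(50, 30, 20))
})
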