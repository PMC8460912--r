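# End-to-end orchestration: simulate (or load) -> liquid rates -> gas
# accounting -> electron ledgers -> test-vs-control contrasts -> community
# correlations, with explicit seeds and deterministic outputs.

.as_schedule <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, as.data.frame))
}

#' Build a reactor scenario from a plain config list
#'
#' Accepts the nested-list form produced by [yaml::read_yaml()]: scalar
#' operating fields, `feed` as a named list, and `rate_schedule` /
#' `leak_schedule` as lists of rows. Reactions come from
#' [default_reactions()].
#'
#' @param cfg Named list.
#' @return A [reactor_scenario()].
#' @export
scenario_from_config <- function(cfg) {
  args <- list()
  for (f in c("liquid_volume", "hrt", "duration", "sample_interval", "dt"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$feed)) args$feed <- unlist(cfg$feed)
  if (!is.null(cfg$init_liquid)) args$init_liquid <- unlist(cfg$init_liquid)
  if (!is.null(cfg$rate_schedule)) args$rate_schedule <- .as_schedule(cfg$rate_schedule)
  if (!is.null(cfg$leak_schedule)) args$leak_schedule <- .as_schedule(cfg$leak_schedule)
  if (!is.null(cfg$refill)) {
    args$refill <- list(volumes_ml = unlist(cfg$refill$volumes_ml),
                        trigger_ml = cfg$refill$trigger_ml)
  }
  if (!is.null(cfg$noise)) args$noise <- cfg$noise
  do.call(reactor_scenario, args)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_pipeline()]'s `config`.
#' @return Config list with scenarios and periods materialized.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scenario)) cfg$scenario <- scenario_from_config(cfg$scenario)
  if (!is.null(cfg$control_scenario))
    cfg$control_scenario <- scenario_from_config(cfg$control_scenario)
  if (!is.null(cfg$periods))
    cfg$periods <- lapply(cfg$periods, function(p)
      rate_period(p$t_start, p$t_end, p$label))
  cfg
}

.stage_msg <- function(...) message("[o2balance] ", ...)

#' Run the whole analysis pipeline
#'
#' Stages: simulate the test (and optional control) scenario with measurement
#' noise; estimate liquid production/consumption rates per period; track the
#' gas loop (He volume, O2 contamination with control-derived standard
#' errors, CH4/H2 rates, H2 attribution); build electron ledgers; contrast
#' test against control; and, when a community link is configured, generate,
#' rarefy, and correlate a genus count table. All tables are written as
#' CSV/TSV/JSON under `outdir`; identical config and seeds give identical
#' outputs.
#'
#' @param config List with elements `scenario` (a [reactor_scenario()]),
#'   optional `control_scenario`, `periods` (list of [rate_period()]s),
#'   optional `noise` (logical, default TRUE), optional `community` (a
#'   [community_link_spec()]), optional `community_pairing` (`"period_mean"`,
#'   the default, or `"same_day"`), and `seeds` (list with `test`, `control`,
#'   `rarefy`, `spearman`).
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a result bundle: trajectories, rate tables, O2
#'   estimates, ledgers, contrasts, correlation matrix, and the summary list.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(!is.null(config$scenario), length(config$periods) >= 1)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- config$seeds %||% list()
  seeds$test <- seeds$test %||% 101L
  seeds$control <- seeds$control %||% 102L
  seeds$rarefy <- seeds$rarefy %||% 103L
  seeds$spearman <- seeds$spearman %||% 104L
  noisy <- config$noise %||% TRUE
  periods <- config$periods
  sc <- config$scenario
  V <- sc$liquid_volume
  hrt <- sc$hrt
  summary <- list(periods = vapply(periods, `[[`, character(1), "label"))

  .stage_msg("simulate: test scenario (", sc$duration, " d)")
  traj <- simulate_reactor(sc)
  obs <- if (noisy) apply_noise(traj, seed = seeds$test) else traj
  write_liquid_csv(obs$liquid, file.path(outdir, "liquid_test.csv"))
  write_gas_csv(obs$gas, file.path(outdir, "gas_test.csv"))
  write_events_json(obs$events, file.path(outdir, "events_test.json"))

  ctl <- obs_ctl <- NULL
  if (!is.null(config$control_scenario)) {
    .stage_msg("simulate: control scenario")
    ctl <- simulate_reactor(config$control_scenario)
    obs_ctl <- if (noisy) apply_noise(ctl, seed = seeds$control) else ctl
    write_liquid_csv(obs_ctl$liquid, file.path(outdir, "liquid_control.csv"))
    write_gas_csv(obs_ctl$gas, file.path(outdir, "gas_control.csv"))
    write_events_json(obs_ctl$events, file.path(outdir, "events_control.json"))
  }

  .stage_msg("liquid rates over ", length(periods), " period(s)")
  rt_test <- rate_table(obs$liquid, periods = periods, feed = sc$feed,
                        hrt = hrt)
  utils::write.csv(rt_test, file.path(outdir, "rates_test.csv"),
                   row.names = FALSE)
  rt_ctl <- NULL
  if (!is.null(obs_ctl)) {
    rt_ctl <- rate_table(obs_ctl$liquid, periods = periods,
                         feed = config$control_scenario$feed, hrt = hrt)
    utils::write.csv(rt_ctl, file.path(outdir, "rates_control.csv"),
                     row.names = FALSE)
  }

  .stage_msg("gas accounting")
  o2_rows <- list(); gas_rows <- list(); o2_by_period <- list()
  for (p in periods) {
    est <- o2_rate_with_uncertainty(
      obs$gas, p, V,
      control_samples = if (!is.null(obs_ctl)) obs_ctl$gas,
      events = obs$events,
      control_events = if (!is.null(obs_ctl)) obs_ctl$events,
      control_liquid_volume = if (!is.null(ctl))
        config$control_scenario$liquid_volume else V)
    o2_by_period[[p$label]] <- est
    o2_rows[[p$label]] <- data.frame(
      period = p$label, o2_rate = est$rate, se = est$se,
      n_intervals = est$n_intervals)
    ch4 <- gas_species_rate(obs$gas, obs$events, "ch4", p, V)
    h2 <- gas_species_rate(obs$gas, obs$events, "h2", p, V)
    att <- attribute_h2(-h2, ch4)
    ratio <- if (est$rate > 0) h2_o2_ratio(att$non_ch4_h2, est$rate)
             else NA_real_
    gas_rows[[p$label]] <- data.frame(
      period = p$label, ch4_rate = ch4, h2_rate = h2,
      h2_consumption = -h2, ch4_attributed_h2 = att$ch4_attributed_h2,
      non_ch4_h2 = att$non_ch4_h2, h2_o2_ratio = as.numeric(ratio))
  }
  o2_df <- do.call(rbind, o2_rows); rownames(o2_df) <- NULL
  gas_df <- do.call(rbind, gas_rows); rownames(gas_df) <- NULL
  utils::write.csv(o2_df, file.path(outdir, "o2_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(gas_df, file.path(outdir, "gas_rates.csv"),
                   row.names = FALSE)

  .stage_msg("electron ledgers")
  ledgers <- list(); err <- list()
  for (p in periods) {
    g <- gas_rows[[p$label]]
    led <- build_ledger(rt_test,
                        gas_rates = c(h2 = g$h2_rate, ch4 = g$ch4_rate),
                        o2_estimate = max(0, o2_by_period[[p$label]]$rate),
                        period = p, feed = sc$feed, hrt = hrt,
                        liquid_volume = V)
    ledgers[[p$label]] <- led
    err[[p$label]] <- led$error_pct
    utils::write.csv(ledger_report(led),
                     file.path(outdir, paste0("ledger_",
                                              gsub("[^A-Za-z0-9]+", "_",
                                                   p$label), ".csv")),
                     row.names = FALSE)
  }
  summary$electron_error_pct <- err

  contrasts <- NULL
  if (!is.null(rt_ctl)) {
    .stage_msg("comparisons: test vs control")
    contrasts <- comparison_table(rt_test, rt_ctl)
    utils::write.csv(contrasts, file.path(outdir, "contrasts.csv"),
                     row.names = FALSE)
  } else {
    .stage_msg("comparisons skipped: no control run configured")
  }

  cor_mat <- NULL
  if (!is.null(config$community)) {
    .stage_msg("community: generate, rarefy, correlate")
    pairing <- config$community_pairing %||% "period_mean"
    if (pairing == "period_mean") {
      # one community sample per period, paired with the period's mean rates
      stimes <- vapply(periods, function(p) (p$t_start + p$t_end) / 2,
                       numeric(1))
    } else {
      stimes <- obs$liquid$time_d
    }
    counts <- generate_community(traj, config$community, sample_times = stimes)
    write_counts_tsv(counts, file.path(outdir, "counts.tsv"))
    rare <- rarefy_counts(counts, seed = seeds$rarefy)
    write_counts_tsv(rare, file.path(outdir, "counts_rarefied.tsv"))
    rel <- filter_abundant(relative_abundance(rare))
    covs <- .community_covariates(traj, obs, periods, stimes, pairing, V)
    cor_mat <- spearman_matrix(rel, covs, seed = seeds$spearman)
    utils::write.csv(as.data.frame(cor_mat$rho),
                     file.path(outdir, "spearman_rho.csv"))
    utils::write.csv(as.data.frame(cor_mat$mask),
                     file.path(outdir, "spearman_mask.csv"))
  } else if (!is.null(config$counts)) {
    .stage_msg("community: rarefy and correlate supplied counts")
    rare <- rarefy_counts(config$counts, seed = seeds$rarefy)
    write_counts_tsv(rare, file.path(outdir, "counts_rarefied.tsv"))
    cor_mat <- spearman_matrix(filter_abundant(relative_abundance(rare)),
                               config$covariates, seed = seeds$spearman)
    utils::write.csv(as.data.frame(cor_mat$rho),
                     file.path(outdir, "spearman_rho.csv"))
    utils::write.csv(as.data.frame(cor_mat$mask),
                     file.path(outdir, "spearman_mask.csv"))
  } else {
    .stage_msg("community stage skipped: no counts or link configured")
  }

  summary$o2 <- o2_df
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(trajectory = traj, observed = obs,
                 control = ctl, observed_control = obs_ctl,
                 rates_test = rt_test, rates_control = rt_ctl,
                 o2 = o2_df, gas = gas_df, ledgers = ledgers,
                 contrasts = contrasts, correlations = cor_mat,
                 summary = summary))
}

# covariates paired to community samples: O2 contamination rate and the
# measured process rates over each sample's period (period-mean pairing) or
# a local window (same-day pairing)
.community_covariates <- function(traj, obs, periods, stimes, pairing, V) {
  hrt <- traj$scenario$hrt
  feed <- traj$scenario$feed
  rows <- lapply(seq_along(stimes), function(i) {
    p <- if (pairing == "period_mean") {
      periods[[which.min(vapply(periods, function(pp)
        abs((pp$t_start + pp$t_end) / 2 - stimes[i]), numeric(1)))]]
    } else {
      si <- traj$scenario$sample_interval
      rate_period(max(0, stimes[i] - 2 * si),
                  min(traj$scenario$duration, stimes[i] + 2 * si))
    }
    o2 <- tryCatch(
      sum(.interval_o2_rates(obs$gas, p, V, obs$events)$rates *
            .interval_o2_rates(obs$gas, p, V, obs$events)$dt) /
        (p$t_end - p$t_start),
      error = function(e) NA_real_)
    ch4 <- gas_species_rate(obs$gas, obs$events, "ch4", p, V)
    h2 <- gas_species_rate(obs$gas, obs$events, "h2", p, V)
    out <- c(o2_contamination = o2, ch4_production = ch4,
             non_ch4_h2_consumption = attribute_h2(-h2, ch4)$non_ch4_h2)
    for (cn in intersect(c("n-caproate", "propionate", "n-butyrate"),
                         names(obs$liquid))) {
      f <- if (cn %in% names(feed)) feed[[cn]] else 0
      out[[paste0(cn, "_production")]] <-
        as.numeric(volumetric_rate(obs$liquid, cn, p, f, hrt))
    }
    out
  })
  do.call(rbind, rows)
}
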