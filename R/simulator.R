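# Synthetic reactor: a well-mixed CSTR (liquid) coupled to a closed
# recirculating gas reservoir, advanced by explicit Euler steps with
# scenario-defined piecewise-constant reaction extents, air-leak intervals
# (O2 plus 3.73x N2), threshold-triggered reservoir refills, and exact
# element/electron bookkeeping for ground truth.

#' mL of ideal gas per mmol at the package's fixed reference (0 degC, 101.325 kPa)
#' @export
ML_PER_MMOL <- 22.414

#' Nitrogen-to-oxygen volumetric ratio of air
#' @export
N2_O2_RATIO <- 3.73

#' Define a comparison period
#'
#' @param t_start,t_end Period bounds in days (`t_end > t_start`).
#' @param label Optional label (defaults to `"t_start-t_end"`).
#' @return A `rate_period` list.
#' @export
rate_period <- function(t_start, t_end, label = NULL) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), t_end > t_start)
  if (is.null(label)) label <- paste0("days ", t_start, "-", t_end)
  structure(list(t_start = t_start, t_end = t_end, label = label),
            class = "rate_period")
}

#' Reactor scenario: operating parameters, schedules and ground truth inputs
#'
#' Default operating values follow the study conditions emulated by the
#' simulator: a 1 L stirred reactor at HRT 14 d, fed 133 mM lactate + 200 mM
#' acetate, with a closed gas loop refilled with 10 L H2:CO2 (80:20), 240 mL
#' ethylene and 120 mL He whenever the reservoir falls below 20% of the refill
#' volume.
#'
#' @param liquid_volume Working liquid volume, L.
#' @param hrt Hydraulic retention time, days (dilution rate D = 1/hrt).
#' @param feed Named feed concentrations, mM.
#' @param init_liquid Initial liquid concentrations, mM (defaults to `feed`).
#' @param duration Run length, days.
#' @param reactions Named list of balanced [reaction_spec()] objects.
#' @param rate_schedule Data frame `reaction, t_start, t_end, extent` with
#'   extents in mmol per L liquid per day (all >= 0).
#' @param leak_schedule Data frame `t_start, t_end, o2_rate` with the air-leak
#'   O2 ingress rate in mL O2 per L liquid per day; N2 enters at 3.73x.
#' @param refill List with `volumes_ml` (named mL per species at reference
#'   conditions) and `trigger_ml` (refill when total reservoir volume falls
#'   below this; default 20% of the refill volume).
#' @param noise List `liquid_cv`, `gas_sd`, `seed` used by [apply_noise()].
#' @param sample_interval Sampling interval for the output series, days.
#' @param dt Euler step, days.
#' @return A validated `reactor_scenario` object.
#' @export
reactor_scenario <- function(liquid_volume = 1,
                             hrt = 14,
                             feed = c(lactate = 133, acetate = 200),
                             init_liquid = feed,
                             duration = 56,
                             reactions = default_reactions(),
                             rate_schedule = NULL,
                             leak_schedule = NULL,
                             refill = list(
                               volumes_ml = c(h2 = 8000, co2 = 2000,
                                              ethylene = 240, he = 120),
                               trigger_ml = NULL),
                             noise = list(liquid_cv = 0.05, gas_sd = 0.005,
                                          seed = 1L),
                             sample_interval = 2,
                             dt = 0.05) {
  stopifnot(liquid_volume > 0, hrt > 0, duration > 0, dt > 0,
            sample_interval > 0)
  if (is.null(rate_schedule))
    rate_schedule <- data.frame(reaction = character(), t_start = numeric(),
                                t_end = numeric(), extent = numeric())
  if (is.null(leak_schedule))
    leak_schedule <- data.frame(t_start = numeric(), t_end = numeric(),
                                o2_rate = numeric())
  stopifnot(all(rate_schedule$extent >= 0),
            all(rate_schedule$reaction %in% names(reactions)))
  if (nrow(leak_schedule)) {
    stopifnot(all(leak_schedule$t_start >= 0),
              all(leak_schedule$t_end <= duration),
              all(leak_schedule$t_end > leak_schedule$t_start),
              all(leak_schedule$o2_rate >= 0))
  }
  if (is.null(refill$trigger_ml))
    refill$trigger_ml <- 0.2 * sum(refill$volumes_ml)
  structure(list(liquid_volume = liquid_volume, hrt = hrt, feed = feed,
                 init_liquid = init_liquid, duration = duration,
                 reactions = reactions, rate_schedule = rate_schedule,
                 leak_schedule = leak_schedule, refill = refill,
                 noise = noise, sample_interval = sample_interval, dt = dt),
            class = "reactor_scenario")
}

#' Simulate a gas-recirculation reactor scenario
#'
#' Advances the liquid concentrations and the gas-loop inventory with explicit
#' Euler steps. Liquid species follow dC/dt = sum(nu * extent) + D (C_feed -
#' C); gas-phase species produced or consumed by reactions are exchanged
#' instantly with the closed gas loop (no dissolved pools); air leaks add O2 at
#' the scheduled rate and N2 at 3.73 times it; a refill is appended to the
#' event log whenever the reservoir volume falls below the trigger. Reactions
#' flagged `limited` are capped by their available gas-phase substrates;
#' unlimited reactions that would drive the reservoir negative raise an error
#' naming the time and species. The noiseless run conserves every element and
#' electron equivalents exactly (up to floating point); measurement noise is a
#' separate step, [apply_noise()].
#'
#' @param scenario A [reactor_scenario()].
#' @return A `reactor_trajectory` with elements `liquid` (data frame, mM),
#'   `gas` (data frame of volumetric fractions plus true `v_gas_ml`), `events`
#'   (refill log), `truth` (realized extents, cumulative leak volumes, and
#'   element accounting), and the `scenario`.
#' @export
simulate_reactor <- function(scenario) {
  sc <- scenario
  reg <- .default_registry()
  V <- sc$liquid_volume
  D <- 1 / sc$hrt
  dt <- sc$dt

  rx_names <- unique(unlist(lapply(sc$reactions, function(r) names(r$stoichiometry))))
  phase <- setNames(reg[rx_names, "phase"], rx_names)
  liq_names <- unique(c(names(sc$feed), names(sc$init_liquid),
                        rx_names[phase == "liquid"], "water"))
  gas_names <- unique(c(rx_names[phase[rx_names] == "gas"],
                        names(sc$refill$volumes_ml), "o2", "n2", "he"))
  gas_names <- gas_names[!is.na(gas_names)]

  C <- setNames(numeric(length(liq_names)), liq_names)
  C[names(sc$init_liquid)] <- sc$init_liquid
  feed <- setNames(numeric(length(liq_names)), liq_names)
  feed[names(sc$feed)] <- sc$feed
  G <- setNames(numeric(length(gas_names)), gas_names)

  # accounting (mmol)
  feed_in <- withdrawn <- setNames(numeric(length(liq_names)), liq_names)
  refill_in <- setNames(numeric(length(gas_names)), gas_names)
  leak_in <- c(o2 = 0, n2 = 0)
  initial_liquid <- C * V

  refill_mmol <- setNames(numeric(length(gas_names)), gas_names)
  refill_mmol[names(sc$refill$volumes_ml)] <- sc$refill$volumes_ml / ML_PER_MMOL
  do_refill <- function(t) {
    G <<- G + refill_mmol
    refill_in <<- refill_in + refill_mmol
    events[[length(events) + 1L]] <<- list(time_d = t, type = "refill",
                                           volumes_ml = refill_mmol * ML_PER_MMOL)
  }
  events <- list()
  do_refill(0)

  n_steps <- round(sc$duration / dt)
  stopifnot(abs(n_steps * dt - sc$duration) < 1e-8)
  sched <- sc$rate_schedule
  nu_liq <- nu_gas <- vector("list", nrow(sched))
  limited <- logical(nrow(sched))
  for (i in seq_len(nrow(sched))) {
    r <- sc$reactions[[sched$reaction[i]]]
    s <- r$stoichiometry
    nu_liq[[i]] <- s[phase[names(s)] == "liquid"]
    nu_gas[[i]] <- s[phase[names(s)] == "gas"]
    limited[i] <- isTRUE(r$limited)
  }

  sample_every <- round(sc$sample_interval / dt)
  record_t <- record_C <- record_G <- list()
  rec <- function(t) {
    record_t[[length(record_t) + 1L]] <<- t
    record_C[[length(record_C) + 1L]] <<- C
    record_G[[length(record_G) + 1L]] <<- G
  }
  rec(0)

  realized <- matrix(0, nrow = n_steps, ncol = nrow(sched))
  leak <- sc$leak_schedule

  for (k in seq_len(n_steps)) {
    t0 <- (k - 1) * dt
    t_mid <- t0 + dt / 2
    t1 <- k * dt
    # reactions
    for (i in seq_len(nrow(sched))) {
      if (t_mid < sched$t_start[i] || t_mid > sched$t_end[i]) next
      ext <- sched$extent[i]
      if (ext <= 0) next
      nug <- nu_gas[[i]]
      if (limited[i] && length(nug)) {
        cons <- nug[nug < 0]
        if (length(cons)) {
          cap <- min(G[names(cons)] / (-cons * V * dt))
          ext <- max(0, min(ext, cap))
        }
      }
      if (ext <= 0) next
      nul <- nu_liq[[i]]
      if (length(nul)) C[names(nul)] <- C[names(nul)] + nul * ext * dt
      if (length(nug)) G[names(nug)] <- G[names(nug)] + nug * ext * dt * V
      realized[k, i] <- ext
    }
    if (any(G < -1e-9)) {
      sp <- names(G)[which(G < -1e-9)[1]]
      stop(sprintf("gas reservoir driven negative for '%s' at t = %.2f d",
                   sp, t1), call. = FALSE)
    }
    bad <- C < -1e-9 & names(C) != "water"
    if (any(bad)) {
      stop(sprintf("negative concentration for '%s' at t = %.2f d: reduce dt or extents",
                   names(C)[which(bad)[1]], t1), call. = FALSE)
    }
    # dilution (continuous feed and withdrawal)
    withdrawn <- withdrawn + dt * D * C * V
    feed_in <- feed_in + dt * D * feed * V
    C <- C + dt * D * (feed - C)
    # air leak
    if (nrow(leak)) {
      act <- t_mid >= leak$t_start & t_mid <= leak$t_end
      if (any(act)) {
        o2_mmol <- sum(leak$o2_rate[act]) * V * dt / ML_PER_MMOL
        G["o2"] <- G["o2"] + o2_mmol
        G["n2"] <- G["n2"] + N2_O2_RATIO * o2_mmol
        leak_in["o2"] <- leak_in["o2"] + o2_mmol
        leak_in["n2"] <- leak_in["n2"] + N2_O2_RATIO * o2_mmol
      }
    }
    # refill trigger: reservoir total below threshold, or any refilled
    # species below the same fraction of its own refill volume (inert CH4/N2
    # accumulating in the loop would otherwise mask carrier-gas depletion)
    low_total <- sum(G) * ML_PER_MMOL < sc$refill$trigger_ml
    frac <- sc$refill$trigger_ml / sum(sc$refill$volumes_ml)
    low_sp <- any(G[names(refill_mmol)[refill_mmol > 0]] <
                    frac * refill_mmol[refill_mmol > 0])
    if (low_total || low_sp) do_refill(t1)
    if (k %% sample_every == 0) rec(t1)
  }

  times <- unlist(record_t)
  Cm <- do.call(rbind, record_C)
  Gm <- do.call(rbind, record_G)
  keep_liq <- setdiff(liq_names, "water")
  liquid <- data.frame(time_d = times, Cm[, keep_liq, drop = FALSE],
                       check.names = FALSE)
  tot <- rowSums(Gm)
  Y <- Gm / tot
  colnames(Y) <- paste0("y_", gas_names)
  gas <- data.frame(time_d = times, Y, v_gas_ml = tot * ML_PER_MMOL,
                    check.names = FALSE)

  ev <- data.frame(
    time_d = vapply(events, `[[`, numeric(1), "time_d"),
    type = vapply(events, `[[`, character(1), "type"))
  vol <- do.call(rbind, lapply(events, `[[`, "volumes_ml"))
  colnames(vol) <- paste0("vol_", gas_names, "_ml")
  events_df <- cbind(ev, as.data.frame(vol))

  truth <- list(
    realized_extents = realized,
    schedule = sched,
    step_dt = dt,
    cum_o2_leak_ml = unname(leak_in["o2"]) * ML_PER_MMOL,
    cum_n2_leak_ml = unname(leak_in["n2"]) * ML_PER_MMOL,
    accounting = list(
      initial_liquid_mmol = initial_liquid,
      final_liquid_mmol = C * V,
      final_gas_mmol = G,
      feed_mmol = feed_in,
      withdrawn_mmol = withdrawn,
      refill_mmol = refill_in,
      leak_mmol = leak_in))

  structure(list(liquid = liquid, gas = gas, events = events_df,
                 truth = truth, scenario = sc),
            class = "reactor_trajectory")
}

#' @export
print.reactor_trajectory <- function(x, ...) {
  cat("reactor trajectory:", nrow(x$liquid), "samples over",
      max(x$liquid$time_d), "days;", nrow(x$events), "gas events\n")
  invisible(x)
}

#' Ground-truth volumetric rates of a simulated trajectory
#'
#' Time-averaged true production rate (mmol per L liquid per day, production
#' positive) of each compound over a period, from the realized reaction
#' extents. For O2 and N2 this covers reactions only; the air leak is reported
#' separately by [true_o2_rate()].
#'
#' @param trajectory A `reactor_trajectory`.
#' @param period A [rate_period()].
#' @return Named numeric vector of rates.
#' @export
true_rates <- function(trajectory, period) {
  tr <- trajectory$truth
  sc <- trajectory$scenario
  dt <- tr$step_dt
  n_steps <- nrow(tr$realized_extents)
  t_mid <- (seq_len(n_steps) - 0.5) * dt
  inside <- t_mid >= period$t_start & t_mid <= period$t_end
  dur <- period$t_end - period$t_start
  out <- numeric(0)
  for (i in seq_len(ncol(tr$realized_extents))) {
    avg_ext <- sum(tr$realized_extents[inside, i]) * dt / dur
    s <- sc$reactions[[tr$schedule$reaction[i]]]$stoichiometry
    for (cn in names(s)) {
      out[cn] <- (if (cn %in% names(out)) out[cn] else 0) + s[cn] * avg_ext
    }
  }
  out
}

#' True O2 ingress rate over a period
#'
#' @param trajectory A `reactor_trajectory`.
#' @param period A [rate_period()].
#' @return mL O2 per L liquid per day averaged over the period.
#' @export
true_o2_rate <- function(trajectory, period) {
  leak <- trajectory$scenario$leak_schedule
  if (!nrow(leak)) return(0)
  dur <- period$t_end - period$t_start
  tot <- 0
  for (i in seq_len(nrow(leak))) {
    ov <- max(0, min(period$t_end, leak$t_end[i]) -
                 max(period$t_start, leak$t_start[i]))
    tot <- tot + ov * leak$o2_rate[i]
  }
  tot / dur
}

#' Apply measurement noise to a simulated trajectory
#'
#' Liquid concentrations are multiplied by mean-1 lognormal noise with the
#' given coefficient of variation; gas fractions are perturbed additively
#' (sd `gas_sd`), clipped at zero and renormalized to sum to one. The ground
#' truth and event log are untouched. Same seed, same output.
#'
#' @param trajectory A `reactor_trajectory`.
#' @param liquid_cv,gas_sd Noise levels; default from the scenario's `noise`.
#' @param seed Integer seed; default from the scenario's `noise`.
#' @return The noisy `reactor_trajectory`.
#' @export
apply_noise <- function(trajectory, liquid_cv = NULL, gas_sd = NULL,
                        seed = NULL) {
  nz <- trajectory$scenario$noise
  if (is.null(liquid_cv)) liquid_cv <- nz$liquid_cv
  if (is.null(gas_sd)) gas_sd <- nz$gas_sd
  if (is.null(seed)) seed <- nz$seed
  stopifnot(liquid_cv >= 0, gas_sd >= 0)
  out <- trajectory
  set.seed(seed)
  if (liquid_cv > 0) {
    sdlog <- sqrt(log1p(liquid_cv^2))
    cols <- setdiff(names(out$liquid), "time_d")
    for (cn in cols) {
      n <- nrow(out$liquid)
      out$liquid[[cn]] <- out$liquid[[cn]] *
        exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    }
  }
  if (gas_sd > 0) {
    ycols <- grep("^y_", names(out$gas), value = TRUE)
    Y <- as.matrix(out$gas[, ycols, drop = FALSE])
    Y <- Y + matrix(stats::rnorm(length(Y), 0, gas_sd), nrow = nrow(Y))
    Y[Y < 0] <- 0
    Y <- Y / rowSums(Y)
    out$gas[, ycols] <- Y
  }
  out
}
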