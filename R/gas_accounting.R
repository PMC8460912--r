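# Closed gas-loop accounting: helium-tracer volume estimation, the indirect
# N2-based O2 contamination estimator with its control-derived uncertainty,
# gas species production rates net of refills, and H2 attribution.

#' Estimate total system gas volume from the helium tracer
#'
#' He is inert and fully retained in the closed loop, so the total gas volume
#' is the cumulative He added divided by the measured He fraction.
#'
#' @param cumulative_he_added Cumulative He added by refills, mL.
#' @param y_he Measured He volumetric fraction (> 1e-4).
#' @return Gas volume in mL.
#' @examples
#' estimate_gas_volume(120, 0.012)  # 10,000 mL
#' @export
estimate_gas_volume <- function(cumulative_he_added, y_he) {
  stopifnot(cumulative_he_added > 0)
  if (any(y_he <= 1e-4))
    stop("unreliable tracer: He fraction at or below the 1e-4 detection floor",
         call. = FALSE)
  cumulative_he_added / y_he
}

# cumulative He added (mL) strictly before-or-at each requested time
.cum_he_at <- function(events, times) {
  he_col <- "vol_he_ml"
  if (!he_col %in% names(events)) return(rep(0, length(times)))
  vapply(times, function(tt)
    sum(events[[he_col]][events$time_d <= tt + 1e-9]), numeric(1))
}

# ensure each gas sample row carries a usable v_gas (measured preferred,
# else He-tracer estimate from the event log)
.with_v_gas <- function(samples, events = NULL) {
  v <- samples$v_gas_ml
  if (is.null(v)) v <- rep(NA_real_, nrow(samples))
  need <- is.na(v)
  if (any(need)) {
    if (is.null(events))
      stop("gas volume missing and no event log available for a He estimate",
           call. = FALSE)
    cum_he <- .cum_he_at(events, samples$time_d[need])
    v[need] <- estimate_gas_volume(cum_he, samples$y_he[need])
  }
  samples$v_gas_ml <- v
  samples
}

#' O2 contamination rate between two gas samples
#'
#' Indirect estimate from the N2 inventory of the closed loop, using the
#' 3.73 N2:O2 volumetric ratio of air: `rate = (Y2 Vgas2 - Y1 Vgas1) /
#' (3.73 (t2 - t1))`, divided by the liquid volume. Valid when no N2 is formed
#' or consumed in the reactor; a validity warning is attached when the O2
#' fraction of either sample exceeds the 0.1% detection threshold (the
#' estimate "might not be accurate" in that regime). Negative values (noise)
#' are returned as-is.
#'
#' @param s1,s2 Gas samples: lists or one-row data frames with `time_d`,
#'   `y_n2`, `v_gas_ml` (and optionally `y_o2`).
#' @param liquid_volume Liquid working volume, L.
#' @return Rate in mL O2 per L liquid per day; attribute `validity_warning`
#'   (character) when the O2-detection condition is violated.
#' @examples
#' s1 <- list(time_d = 0, y_n2 = 0, v_gas_ml = 10000)
#' s2 <- list(time_d = 10, y_n2 = 0.0373, v_gas_ml = 10000)
#' o2_contamination_rate(s1, s2, liquid_volume = 1)  # 10
#' @export
o2_contamination_rate <- function(s1, s2, liquid_volume) {
  stopifnot(s2$time_d > s1$time_d, liquid_volume > 0)
  for (s in list(s1, s2)) {
    if (is.null(s$y_n2) || is.null(s$v_gas_ml) || is.na(s$v_gas_ml))
      stop("gas sample lacks N2 fraction or gas volume", call. = FALSE)
  }
  rate <- (s2$y_n2 * s2$v_gas_ml - s1$y_n2 * s1$v_gas_ml) /
    (N2_O2_RATIO * (s2$time_d - s1$time_d)) / liquid_volume
  warn <- NULL
  o2s <- c(s1$y_o2, s2$y_o2)
  if (length(o2s) && any(o2s > 0.001, na.rm = TRUE))
    warn <- "O2 above the 0.1% detection threshold: estimate might not be accurate"
  structure(unname(rate), validity_warning = warn)
}

.interval_o2_rates <- function(samples, period = NULL, liquid_volume,
                               events = NULL) {
  samples <- samples[order(samples$time_d), , drop = FALSE]
  if (!is.null(period)) {
    keep <- samples$time_d >= period$t_start - 1e-9 &
      samples$time_d <= period$t_end + 1e-9
    samples <- samples[keep, , drop = FALSE]
  }
  if (nrow(samples) < 2)
    stop("need at least 2 gas samples in the period", call. = FALSE)
  samples <- .with_v_gas(samples, events)
  n <- nrow(samples)
  rates <- numeric(n - 1)
  warns <- 0L
  for (i in seq_len(n - 1)) {
    r <- o2_contamination_rate(samples[i, ], samples[i + 1, ], liquid_volume)
    rates[i] <- r
    if (!is.null(attr(r, "validity_warning"))) warns <- warns + 1L
  }
  list(rates = rates, dt = diff(samples$time_d), warnings = warns)
}

#' O2 contamination rate with control-derived standard error
#'
#' Point estimate: duration-weighted mean of the per-interval two-sample
#' estimates within the period (negative intervals retained; truncation would
#' bias the mean upward). Standard error: the standard deviation of the
#' per-interval rates of an anoxic control reactor (true rate about zero),
#' scaled by `1/sqrt(n_intervals)` of the test period.
#'
#' @param samples Test-reactor gas series (data frame with `time_d`, `y_n2`,
#'   optionally `y_o2`, `v_gas_ml`).
#' @param period A [rate_period()].
#' @param liquid_volume Liquid volume of the test reactor, L.
#' @param control_samples Control-reactor gas series with >= 4 samples
#'   (>= 3 intervals); `NULL` gives a point estimate with `se = NA` and a
#'   warning condition.
#' @param events,control_events Event logs for He-based volume estimates when
#'   `v_gas_ml` is absent.
#' @param control_liquid_volume Liquid volume of the control reactor, L.
#' @return An `o2_estimate`: list with `rate`, `se` (mL O2 per L per day),
#'   `period`, `n_intervals`, `validity_warnings`.
#' @export
o2_rate_with_uncertainty <- function(samples, period, liquid_volume,
                                     control_samples = NULL,
                                     events = NULL, control_events = NULL,
                                     control_liquid_volume = liquid_volume) {
  iv <- .interval_o2_rates(samples, period, liquid_volume, events)
  rate <- sum(iv$rates * iv$dt) / sum(iv$dt)
  n_int <- length(iv$rates)
  se <- NA_real_
  if (is.null(control_samples)) {
    warning("uncertainty unavailable: no control series supplied")
  } else {
    civ <- .interval_o2_rates(control_samples, NULL, control_liquid_volume,
                              control_events)
    if (length(civ$rates) < 3)
      stop("uncertainty unavailable: control series has fewer than 3 intervals",
           call. = FALSE)
    se <- stats::sd(civ$rates) / sqrt(n_int)
  }
  structure(list(rate = rate, se = se, period = period, n_intervals = n_int,
                 validity_warnings = iv$warnings),
            class = "o2_estimate")
}

#' @export
print.o2_estimate <- function(x, ...) {
  cat(sprintf("O2 contamination %s: %.1f +/- %.1f mL O2 L-1 d-1 (%d intervals)\n",
              x$period$label, x$rate,
              if (is.na(x$se)) NA else x$se, x$n_intervals))
  if (x$validity_warnings > 0)
    cat("  note:", x$validity_warnings,
        "interval(s) with O2 above the detection threshold\n")
  invisible(x)
}

#' Net production rate of a gas species over a period
#'
#' Change of the species' gas-loop inventory between the first and last sample
#' of the period, with refill additions inside the interval discounted:
#' `rate = [delta(Y v_gas) - refills] / (22.414 dt V_liquid)`, production
#' positive, in mmol per L liquid per day.
#'
#' @param samples Gas series data frame (`time_d`, `y_<species>`, `v_gas_ml`).
#' @param events Event log data frame with `time_d`, `type`,
#'   `vol_<species>_ml` columns.
#' @param species Gas species name (e.g. `"ch4"`, `"h2"`, `"he"`).
#' @param period A [rate_period()].
#' @param liquid_volume Liquid volume, L.
#' @return Rate in mmol per L per day.
#' @export
gas_species_rate <- function(samples, events, species, period, liquid_volume) {
  ycol <- paste0("y_", species)
  if (!ycol %in% names(samples))
    stop("species '", species, "' not in gas series", call. = FALSE)
  samples <- samples[order(samples$time_d), , drop = FALSE]
  keep <- samples$time_d >= period$t_start - 1e-9 &
    samples$time_d <= period$t_end + 1e-9
  samples <- samples[keep, , drop = FALSE]
  if (nrow(samples) < 2)
    stop("need at least 2 gas samples in the period", call. = FALSE)
  samples <- .with_v_gas(samples, events)
  first <- samples[1, ]; last <- samples[nrow(samples), ]
  vcol <- paste0("vol_", species, "_ml")
  added <- 0
  if (!is.null(events) && vcol %in% names(events)) {
    inwin <- events$time_d > first$time_d + 1e-9 &
      events$time_d <= last$time_d + 1e-9
    added <- sum(events[[vcol]][inwin])
  }
  dtv <- last$time_d - first$time_d
  (last[[ycol]] * last$v_gas_ml - first[[ycol]] * first$v_gas_ml - added) /
    (ML_PER_MMOL * dtv * liquid_volume)
}

#' Attribute H2 consumption to methanogenesis
#'
#' Hydrogenotrophic methanogenesis consumes 4 mol H2 per mol CH4; the
#' remainder of the measured H2 consumption is "non-CH4 H2 consumption".
#'
#' @param h2_consumption Total H2 consumption rate, mmol per L per day
#'   (positive = consumed).
#' @param ch4_production CH4 production rate, mmol per L per day.
#' @return List with `ch4_attributed_h2` (= 4 x CH4) and `non_ch4_h2`.
#' @export
attribute_h2 <- function(h2_consumption, ch4_production) {
  attributed <- 4 * ch4_production
  list(ch4_attributed_h2 = attributed,
       non_ch4_h2 = h2_consumption - attributed)
}

#' Molar ratio of non-methanogenic H2 consumption to O2 consumption
#'
#' The H2-oxidation stoichiometry (2 H2 + O2 -> 2 H2O) predicts 2.0; observed
#' ratios above 2 indicate additional H2 sinks during O2 intrusion.
#'
#' @param non_ch4_h2 Non-CH4 H2 consumption, mmol per L per day.
#' @param o2_rate O2 contamination rate, mL O2 per L per day (> 0).
#' @return Dimensionless molar ratio, with attribute `reference` = 2
#'   (the H2-oxidation stoichiometric value).
#' @export
h2_o2_ratio <- function(non_ch4_h2, o2_rate) {
  if (o2_rate <= 0)
    stop("undefined ratio: O2 rate must be positive", call. = FALSE)
  structure(non_ch4_h2 / (o2_rate / ML_PER_MMOL), reference = 2)
}
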