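# Dilution-corrected volumetric production/consumption rates from liquid
# concentration time series of a CSTR, and concentration maxima.

.series_in_period <- function(series, compound, period) {
  col <- if (compound %in% names(series)) compound else paste0(compound, "_mM")
  if (!col %in% names(series))
    stop("compound '", compound, "' not found in series", call. = FALSE)
  t <- series$time_d
  if (is.unsorted(t, strictly = TRUE))
    stop("series time must be strictly increasing", call. = FALSE)
  keep <- t >= period$t_start - 1e-9 & t <= period$t_end + 1e-9
  list(t = t[keep], C = series[[col]][keep])
}

# duration-weighted (trapezoidal) time-mean of a sampled series
.time_mean <- function(t, C) {
  if (length(t) == 1) return(C)
  sum(diff(t) * (utils::head(C, -1) + utils::tail(C, -1)) / 2) /
    (t[length(t)] - t[1])
}

#' Volumetric production rate of a compound over a period
#'
#' CSTR accumulation-plus-washout form: `r = slope + D (C_mean - C_feed)` in
#' mmol per L per day, with `D = 1/hrt`, `slope` the least-squares (or
#' two-point endpoint) slope of concentration against time within the period,
#' and `C_mean` the trapezoidal time-mean concentration. Production is
#' positive, consumption negative; washout of unconsumed substrate is included
#' through the dilution term. The endpoint mode is an exact discrete
#' bookkeeping identity on noiseless data; the regression mode is the
#' noise-robust default.
#'
#' @param series Liquid series data frame with `time_d` and concentration
#'   columns in mM (bare compound name or `<compound>_mM`).
#' @param compound Compound name.
#' @param period A [rate_period()].
#' @param feed_mM Feed concentration of the compound, mM.
#' @param hrt Hydraulic retention time, days.
#' @param method `"regression"` (default) or `"endpoint"`.
#' @return Rate in mmol per L per day with attributes `slope_sd` and `n`.
#' @examples
#' s <- data.frame(time_d = 0:10, lactate = rep(160, 11))
#' volumetric_rate(s, "lactate", rate_period(0, 10), feed_mM = 200, hrt = 14)
#' @export
volumetric_rate <- function(series, compound, period, feed_mM, hrt,
                            method = c("regression", "endpoint")) {
  method <- match.arg(method)
  stopifnot(hrt > 0)
  sp <- .series_in_period(series, compound, period)
  n <- length(sp$t)
  if (n < 2)
    stop("insufficient data: fewer than 2 samples in period '",
         period$label, "'", call. = FALSE)
  slope_sd <- NA_real_
  if (method == "regression") {
    fit <- stats::lm(sp$C ~ sp$t)
    slope <- unname(stats::coef(fit)[2])
    if (n > 2)
      slope_sd <- sqrt(sum(stats::resid(fit)^2) / (n - 2) /
                         sum((sp$t - mean(sp$t))^2))
  } else {
    slope <- (sp$C[n] - sp$C[1]) / (sp$t[n] - sp$t[1])
  }
  r <- slope + (.time_mean(sp$t, sp$C) - feed_mM) / hrt
  structure(r, slope_sd = slope_sd, n = n)
}

#' Rate table over periods and compounds
#'
#' @param series Liquid series data frame (mM columns).
#' @param compounds Compound names; default all concentration columns.
#' @param periods List of [rate_period()]s.
#' @param feed Named feed concentrations, mM (absent compounds feed at 0).
#' @param hrt Hydraulic retention time, days.
#' @param method Passed to [volumetric_rate()].
#' @return Data frame of class `rate_table` with columns `period`, `compound`,
#'   `rate` (mmol per L per day, production positive), `slope_sd`, `n`.
#' @export
rate_table <- function(series, compounds = NULL, periods, feed, hrt,
                       method = "regression") {
  if (inherits(periods, "rate_period")) periods <- list(periods)
  if (is.null(compounds))
    compounds <- sub("_mM$", "", setdiff(names(series), "time_d"))
  rows <- list()
  for (p in periods) {
    for (cn in compounds) {
      f <- if (cn %in% names(feed)) feed[[cn]] else 0
      r <- volumetric_rate(series, cn, p, f, hrt, method)
      rows[[length(rows) + 1L]] <- data.frame(
        period = p$label, compound = cn, rate = as.numeric(r),
        slope_sd = attr(r, "slope_sd"), n = attr(r, "n"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(all(is.finite(out$rate)))
  class(out) <- c("rate_table", class(out))
  out
}

#' Maximum concentration of a compound in a series
#'
#' @param series Liquid series data frame (mM columns).
#' @param compound Compound name.
#' @param unit `"mM"` or `"gL"` for the returned maximum.
#' @param registry Registry data frame.
#' @return Maximum concentration in the requested unit, with attribute
#'   `time_d` (first time at which it is attained).
#' @export
max_concentration <- function(series, compound, unit = c("mM", "gL"),
                              registry = NULL) {
  unit <- match.arg(unit)
  col <- if (compound %in% names(series)) compound else paste0(compound, "_mM")
  if (!col %in% names(series))
    stop("compound '", compound, "' not found in series", call. = FALSE)
  C <- series[[col]]
  if (!length(C)) stop("empty series for '", compound, "'", call. = FALSE)
  i <- which.max(C)
  val <- C[i]
  if (unit == "gL") val <- molar_to_mass(val, compound, registry)
  structure(val, time_d = series$time_d[i])
}
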