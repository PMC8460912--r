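# Test-vs-control contrasts: signed percent changes, percent-of-control,
# fold changes, and aligned comparison tables. Stored values are unrounded;
# rounding (half away from zero, to integer percent) happens only in the
# report layer.

#' Round half away from zero
#'
#' Report-layer rounding used for printed percent figures (e.g. 45.8 -> 46,
#' -63.3 -> -63, 0.5 -> 1).
#'
#' @param x Numeric.
#' @param digits Decimal digits (default 0).
#' @return Rounded numeric.
#' @export
round_half_out <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Signed percent change of a test rate relative to a control rate
#'
#' @param test,control Rates in the same units; `control` must be nonzero.
#' @return `100 (test/control - 1)`, unrounded.
#' @examples
#' percent_change(6.05, 16.5)  # -63.3: reported "63% less"
#' @export
percent_change <- function(test, control) {
  if (any(control == 0))
    stop("undefined contrast: control rate is zero", call. = FALSE)
  100 * (test / control - 1)
}

#' Test rate as a percentage of the control rate
#'
#' @param test,control Rates; `control` must be positive.
#' @return `100 test/control`, unrounded.
#' @examples
#' rate_as_pct_of_control(5.33, 16.5)  # 32.3: reported "32%"
#' @export
rate_as_pct_of_control <- function(test, control) {
  if (any(control <= 0))
    stop("percent of control undefined for control <= 0", call. = FALSE)
  100 * test / control
}

#' Fold change of a test rate over a control rate
#'
#' @param test,control Rates; `control` must be positive.
#' @return `test/control`, unrounded (reports use one decimal).
#' @export
fold_change <- function(test, control) {
  if (any(control <= 0))
    stop("fold change undefined for control <= 0", call. = FALSE)
  test / control
}

#' Align two rate tables into a contrast table
#'
#' One contrast per (period, compound) present in both tables, in a
#' deterministic order (period label, then compound). Stored percent and fold
#' values are unrounded; `pct_change_report` carries the integer-rounded
#' report figure.
#'
#' @param test_rates,control_rates [rate_table()]s (or data frames with
#'   `period`, `compound`, `rate`).
#' @param periods Optional vector of period labels to keep; by default every
#'   label present in both tables. Labels present in one table only raise an
#'   alignment error naming them.
#' @return Data frame of class `contrast_table`: `period`, `compound`,
#'   `test_rate`, `control_rate`, `pct_change`, `pct_change_report`,
#'   `pct_of_control`, `fold`.
#' @export
comparison_table <- function(test_rates, control_rates, periods = NULL) {
  if (is.null(periods)) {
    lt <- unique(test_rates$period); lc <- unique(control_rates$period)
    unmatched <- c(setdiff(lt, lc), setdiff(lc, lt))
    if (length(unmatched))
      stop("period labels not present in both tables: ",
           paste(unmatched, collapse = ", "), call. = FALSE)
    periods <- lt
  }
  key <- function(d) paste(d$period, d$compound, sep = "\r")
  t2 <- test_rates[test_rates$period %in% periods, , drop = FALSE]
  c2 <- control_rates[control_rates$period %in% periods, , drop = FALSE]
  common <- intersect(key(t2), key(c2))
  t2 <- t2[match(common, key(t2)), , drop = FALSE]
  c2 <- c2[match(common, key(c2)), , drop = FALSE]
  ok <- c2$rate != 0
  out <- data.frame(
    period = t2$period, compound = t2$compound,
    test_rate = t2$rate, control_rate = c2$rate,
    pct_change = ifelse(ok, 100 * (t2$rate / c2$rate - 1), NA_real_),
    stringsAsFactors = FALSE)
  out$pct_change_report <- round_half_out(out$pct_change)
  out$pct_of_control <- ifelse(c2$rate > 0, 100 * t2$rate / c2$rate, NA_real_)
  out$fold <- ifelse(c2$rate > 0, t2$rate / c2$rate, NA_real_)
  out <- out[order(out$period, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contrast_table", class(out))
  out
}

#' Phrase a contrast the way reactor studies report it
#'
#' E.g. "63% less" / "18% higher", with the integer-rounded magnitude. When
#' `printed` is supplied and disagrees with the recomputed figure, the string
#' is flagged rather than silently matched.
#'
#' @param test,control Rates.
#' @param printed Optional percent figure as printed elsewhere, for a
#'   discrepancy flag.
#' @return Character report string.
#' @examples
#' contrast_phrase(0.56, 2.12, printed = 72)  # recomputes 74%, flags it
#' @export
contrast_phrase <- function(test, control, printed = NULL) {
  pc <- percent_change(test, control)
  mag <- abs(round_half_out(pc))
  word <- if (pc < 0) "less" else "higher"
  out <- sprintf("%d%% %s (%.2f of %.2f)", mag, word, test, control)
  if (!is.null(printed) && mag != abs(printed))
    out <- paste0(out, sprintf(" [recomputed %d%%, stated %d%%]", mag,
                               abs(printed)))
  out
}
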