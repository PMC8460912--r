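# Whole-period electron-equivalent ledger: degree-of-reduction-weighted
# inflows (feed substrates, H2 supplied from the gas loop) against outflows
# (products and residual substrates leaving via withdrawal, CH4, net H2
# formation, and the O2 electron-accepting sink), with percent closure error.

#' Build an electron-equivalent ledger for one period
#'
#' Each flow is a rate times the period duration times the compound's degree
#' of reduction (e-mmol). Feed compounds contribute a supply inflow
#' `D C_feed T V gamma` and a residual outflow `(D C_feed + r) T V gamma`
#' (their washout plus accumulation, via the signed net rate `r` from the rate
#' table); other liquid compounds contribute `r T V gamma` on the side given
#' by the sign of `r`; gas species likewise (H2 consumed from the reservoir is
#' an inflow); O2 ingress enters as electron-accepting capacity `4 n_O2` on
#' the outflow side. The closure error is `100 (out - in) / in`: negative
#' means unexplained consumption of the supplied electron pool. Ethylene
#' (inert inhibitor) is excluded; biomass only via `include_biomass`.
#'
#' @param rate_table A [rate_table()] (liquid rates, production positive).
#' @param gas_rates Named vector of gas species rates, mmol per L per day,
#'   production positive (e.g. `c(h2 = -66, ch4 = 16.5)`).
#' @param o2_estimate An `o2_estimate`, or a number in mL O2 per L per day,
#'   or `NULL` when no O2 entered.
#' @param period A [rate_period()]; must match the rate table's period label.
#' @param feed Named feed concentrations, mM.
#' @param hrt Hydraulic retention time, days.
#' @param liquid_volume Liquid volume, L.
#' @param include_biomass Include a biomass flow (composition CH1.8O0.5N0.2)
#'   when the rate table carries a `biomass` rate.
#' @param registry Registry data frame.
#' @return An `electron_ledger`: data frame `flows` (side, compound, e_mmol),
#'   `error_pct`, totals, and the period.
#' @export
build_ledger <- function(rate_table, gas_rates = NULL, o2_estimate = NULL,
                         period, feed, hrt, liquid_volume,
                         include_biomass = FALSE, registry = NULL) {
  stopifnot(hrt > 0, liquid_volume > 0)
  Tdur <- period$t_end - period$t_start
  V <- liquid_volume
  D <- 1 / hrt
  rt <- rate_table[rate_table$period == period$label, , drop = FALSE]
  if (!nrow(rt))
    stop("rate table has no rows for period '", period$label, "'",
         call. = FALSE)
  skip <- c("ethylene", "water", if (!include_biomass) "biomass")

  flows <- list()
  add <- function(side, name, e_mmol) {
    if (abs(e_mmol) < 1e-12) return()
    if (e_mmol < 0) {  # signed flow landing on the other side
      side <- if (side == "in") "out" else "in"
      e_mmol <- -e_mmol
    }
    flows[[length(flows) + 1L]] <<- data.frame(
      side = side, compound = name, e_mmol = e_mmol, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(rt))) {
    cn <- rt$compound[i]
    if (cn %in% skip) next
    gam <- degree_of_reduction(cn, registry)
    if (gam == 0) next
    r <- rt$rate[i]
    f <- if (cn %in% names(feed)) feed[[cn]] else 0
    if (f > 0) {
      add("in", paste0("feed_", cn), D * f * Tdur * V * gam)
      add("out", paste0("residual_", cn), (D * f + r) * Tdur * V * gam)
    } else {
      add(if (r >= 0) "out" else "in", cn, abs(r) * Tdur * V * gam)
    }
  }
  for (cn in names(gas_rates)) {
    if (cn %in% c(skip, "o2", "n2", "he")) next
    gam <- degree_of_reduction(cn, registry)
    if (gam == 0) next
    r <- gas_rates[[cn]]
    add(if (r >= 0) "out" else "in",
        paste0(cn, if (r >= 0) "_produced" else "_supplied"),
        abs(r) * Tdur * V * gam)
  }
  if (!is.null(o2_estimate)) {
    o2r <- if (inherits(o2_estimate, "o2_estimate")) o2_estimate$rate
           else o2_estimate
    add("out", "o2_sink", 4 * (o2r / ML_PER_MMOL) * Tdur * V)
  }

  flows <- do.call(rbind, flows)
  e_in <- sum(flows$e_mmol[flows$side == "in"])
  e_out <- sum(flows$e_mmol[flows$side == "out"])
  if (e_in <= 0) stop("ledger has no electron inflows", call. = FALSE)
  structure(list(flows = flows, e_in = e_in, e_out = e_out,
                 error_pct = 100 * (e_out - e_in) / e_in, period = period),
            class = "electron_ledger")
}

#' @export
print.electron_ledger <- function(x, ...) {
  cat(sprintf("electron ledger %s: in %.1f e-mmol, out %.1f e-mmol, error %+.2f%%\n",
              x$period$label, x$e_in, x$e_out, x$error_pct))
  invisible(x)
}

#' Ranked electron-flow report
#'
#' @param ledger An `electron_ledger`.
#' @return Data frame `side, compound, e_mmol, share_pct`, ordered within each
#'   side by decreasing share then name; shares sum to 100 per side.
#' @export
ledger_report <- function(ledger) {
  fl <- ledger$flows
  fl$share_pct <- NA_real_
  for (s in c("in", "out")) {
    i <- fl$side == s
    fl$share_pct[i] <- 100 * fl$e_mmol[i] / sum(fl$e_mmol[i])
  }
  fl <- fl[order(fl$side, -fl$share_pct, fl$compound), , drop = FALSE]
  rownames(fl) <- NULL
  fl
}
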