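# Stoichiometric reactions over registry compounds, and a balancer that
# solves unknown coefficients from element conservation (C, H, O, N, He).

#' Define a stoichiometric reaction
#'
#' A reaction is a named vector of signed coefficients over registry compounds:
#' negative = consumed, positive = produced, `NA` = unknown (to be solved by
#' [balance_reaction()]). At least one coefficient must be fixed to anchor the
#' scale.
#'
#' @param name Identifier.
#' @param stoichiometry Named numeric vector of signed coefficients; `NA`
#'   entries are unknowns.
#' @param limited If `TRUE` the simulator caps this reaction's per-step extent
#'   by the available amount of its gas-phase substrates (used for
#'   supply-limited O2 scavenging) instead of erroring on depletion.
#' @param registry Registry data frame.
#' @return An object of class `reaction_spec`.
#' @examples
#' reaction_spec("h2_oxidation", c(h2 = -2, o2 = -1, water = 2))
#' @export
reaction_spec <- function(name, stoichiometry, limited = FALSE, registry = NULL) {
  if (is.logical(stoichiometry) && all(is.na(stoichiometry)))
    storage.mode(stoichiometry) <- "double"
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  for (cn in names(stoichiometry)) compound(cn, registry)  # existence check
  known <- stoichiometry[!is.na(stoichiometry)]
  if (!length(known))
    stop("reaction '", name, "': all coefficients unknown", call. = FALSE)
  structure(list(name = name, stoichiometry = stoichiometry, limited = limited),
            class = "reaction_spec")
}

#' @export
print.reaction_spec <- function(x, ...) {
  s <- x$stoichiometry
  fmt <- function(v, n) paste0(ifelse(abs(v) == 1, "", paste0(abs(v), " ")), n)
  lhs <- s[!is.na(s) & s < 0]
  rhs <- s[!is.na(s) & s > 0]
  unk <- names(s)[is.na(s)]
  cat(x$name, ": ",
      paste(fmt(lhs, names(lhs)), collapse = " + "), " -> ",
      paste(fmt(rhs, names(rhs)), collapse = " + "),
      if (length(unk)) paste0("  [unknown: ", paste(unk, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

.element_matrix <- function(compounds, registry = NULL) {
  if (is.null(registry)) registry <- .default_registry()
  elems <- c("C", "H", "O", "N", "He")
  m <- t(vapply(compounds, function(cn)
    unlist(compound(cn, registry)[, elems]), numeric(length(elems))))
  colnames(m) <- elems
  m
}

#' Element and electron residuals of a reaction
#'
#' @param reaction A `reaction_spec` with all coefficients known.
#' @param registry Registry data frame.
#' @return Named vector of residuals (C, H, O, N, He, electrons); all zero for
#'   a balanced reaction.
#' @export
reaction_residuals <- function(reaction, registry = NULL) {
  s <- reaction$stoichiometry
  stopifnot(!anyNA(s))
  E <- .element_matrix(names(s), registry)
  res <- drop(s %*% E)
  gam <- vapply(names(s), degree_of_reduction, numeric(1), registry = registry)
  c(res, electrons = sum(s * gam))
}

# Resolve a rank-deficient element-balance system by looking for the unique
# minimal non-negative integer completion (the textbook convention when one
# net equation mixes parallel pathways, e.g. lactate disproportionation where
# decarboxylation couples acetate and CO2). Errors when no unique minimal
# integral solution exists, naming the deficient elements.
.integral_completion <- function(A, b, rxn_name, max_coef = 12L) {
  qrA <- qr(A)
  x0 <- qr.coef(qrA, b)                      # particular LS solution
  x0[is.na(x0)] <- 0
  if (max(abs(drop(A %*% x0) - b)) > 1e-8 * max(1, max(abs(b))))
    stop("reaction '", rxn_name, "': element balance inconsistent for [",
         paste(rownames(A), collapse = ", "), "]", call. = FALSE)
  ns <- .null_space(A)
  fail <- function() stop(
    "reaction '", rxn_name, "': underdetermined balance for elements [",
    paste(rownames(A), collapse = ", "), "] with no unique integral completion",
    call. = FALSE)
  if (ncol(ns) != 1) fail()                  # only 1-dim families supported
  v <- ns[, 1]
  cands <- list()
  for (i in which(abs(v) > 1e-9)) {
    for (m in 0:max_coef) {
      t <- (m - x0[i]) / v[i]
      x <- x0 + t * v
      if (all(x > -1e-9) && all(abs(x - round(x)) < 1e-9) &&
          all(round(x) <= max_coef)) {
        cands[[paste(round(x), collapse = ",")]] <- round(x)
      }
    }
  }
  if (!length(cands)) fail()
  sums <- vapply(cands, sum, numeric(1))
  best <- which(sums == min(sums))
  if (length(best) != 1) fail()
  cands[[best]]
}

.null_space <- function(A, tol = 1e-9) {
  sv <- svd(A, nv = ncol(A))
  rank <- sum(sv$d > tol * max(sv$d, 1e-300))
  if (rank >= ncol(A)) return(matrix(0, ncol(A), 0))
  sv$v[, (rank + 1):ncol(A), drop = FALSE]
}

# Snap x to the nearest rational p/q with q <= max_den when within tol.
.snap_rational <- function(x, max_den = 24L, tol = 1e-9) {
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (abs(x - p / q) < tol) return(p / q)
  }
  x
}

#' Solve unknown stoichiometric coefficients by element conservation
#'
#' Unknown (`NA`) coefficients are solved from the linear system requiring
#' every element (C, H, O, N, He) to be conserved, with the fixed coefficients
#' anchoring the scale. The solution is verified to close every element and the
#' degree-of-reduction electron balance to within 1e-9, and coefficients are
#' reduced to small rationals where they are. When element conservation leaves
#' a one-parameter family (a net equation mixing parallel pathways, as in
#' lactate disproportionation to propionate/acetate/CO2), the unique minimal
#' non-negative integer completion is returned; if none exists the balancing
#' error names the deficient elements.
#'
#' @param template A `reaction_spec` with one or more `NA` coefficients (a
#'   fully specified reaction is simply verified).
#' @param registry Registry data frame.
#' @return A balanced `reaction_spec`.
#' @examples
#' # hydrogenotrophic methanogenesis: a CO2 + b H2 -> CH4 + c H2O
#' balance_reaction(reaction_spec("methanogenesis",
#'   c(co2 = NA, h2 = NA, ch4 = 1, water = NA)))
#' @export
balance_reaction <- function(template, registry = NULL) {
  s <- template$stoichiometry
  E <- .element_matrix(names(s), registry)
  unknown <- is.na(s)
  if (any(unknown)) {
    A <- t(E[unknown, , drop = FALSE])                # elements x unknowns
    b <- -drop(s[!unknown] %*% E[!unknown, , drop = FALSE])
    use <- apply(A != 0, 1, any) | b != 0             # drop all-zero equations
    A2 <- A[use, , drop = FALSE]; b2 <- b[use]
    rank <- qr(A2)$rank
    if (rank < sum(unknown)) {
      sol <- .integral_completion(A2, b2, template$name)
    } else {
      sol <- qr.solve(A2, b2)
      resid <- drop(A2 %*% sol) - b2
      if (any(abs(resid) > 1e-8)) {
        bad <- rownames(A2)[abs(resid) > 1e-8]
        stop("reaction '", template$name,
             "': element balance inconsistent for [",
             paste(bad, collapse = ", "), "]", call. = FALSE)
      }
    }
    s[unknown] <- vapply(sol, .snap_rational, numeric(1))
  }
  out <- reaction_spec(template$name, s, limited = template$limited,
                       registry = registry)
  res <- reaction_residuals(out, registry)
  if (any(abs(res) > 1e-9)) {
    bad <- names(res)[abs(res) > 1e-9]
    stop("reaction '", template$name, "': residual imbalance in [",
         paste(bad, collapse = ", "), "]", call. = FALSE)
  }
  if (!any(s < 0) || !any(s > 0))
    stop("reaction '", template$name,
         "': needs at least one reactant and one product", call. = FALSE)
  out
}

#' Default reaction set for lactate/acetate fermentation under H2/CO2
#'
#' The stoichiometries active in a micro-aerated chain-elongation reactor:
#' lactate fermentation to propionate/acetate/CO2 (2:1:1), H2 oxidation by O2
#' (supply-limited scavenging), homopropionate fermentation of lactate with H2,
#' homoacetogenesis from H2/CO2, hydrogenotrophic methanogenesis (4 H2 per
#' CH4), and lactate-based chain elongation of acetate to n-butyrate and of
#' n-butyrate to n-caproate. All are verified balanced on construction.
#'
#' @param registry Registry data frame.
#' @return Named list of balanced `reaction_spec` objects.
#' @export
default_reactions <- function(registry = NULL) {
  specs <- list(
    reaction_spec("lactate_to_propionate",
      c(lactate = -3, propionate = 2, acetate = 1, co2 = 1, water = 1)),
    reaction_spec("h2_oxidation",
      c(h2 = -2, o2 = -1, water = 2), limited = TRUE),
    reaction_spec("homopropionate",
      c(lactate = -1, h2 = -1, propionate = 1, water = 1)),
    reaction_spec("homoacetogenesis",
      c(h2 = -4, co2 = -2, acetate = 1, water = 2)),
    reaction_spec("methanogenesis",
      c(co2 = -1, h2 = -4, ch4 = 1, water = 2)),
    reaction_spec("elongation_c4",
      c(lactate = -1, acetate = -1, `n-butyrate` = 1, co2 = 1, water = 1)),
    reaction_spec("elongation_c6",
      c(lactate = -1, `n-butyrate` = -1, `n-caproate` = 1, co2 = 1, water = 1))
  )
  out <- lapply(specs, balance_reaction, registry = registry)
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
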