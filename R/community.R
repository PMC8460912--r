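# Rarefaction of genus count tables to equal depth and significance-masked
# Spearman correlation between relative abundances and process variables.

#' Rarefy a count table to equal depth
#'
#' Random subsampling without replacement of each sample to exactly `depth`
#' reads (vegan's rarefaction draw, seeded). The default depth is that of the
#' shallowest sample.
#'
#' @param counts Integer matrix or data frame, samples x taxa.
#' @param depth Target depth; must not exceed any sample total.
#' @param seed Integer seed.
#' @return Integer matrix of the same shape with every row summing to `depth`.
#' @export
rarefy_counts <- function(counts, depth = NULL, seed = 1L) {
  m <- as.matrix(counts)
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- rowSums(m)
  if (is.null(depth)) depth <- min(tot)
  short <- tot < depth
  if (any(short))
    stop("depth ", depth, " exceeds the total of sample(s): ",
         paste(rownames(m)[short] %||% which(short), collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  out <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    # vegan flags any table whose smallest positive entry exceeds 1 as
    # "maybe not counts"; our tables are counts by construction
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative abundances of a count table
#'
#' @param counts Samples x taxa count matrix.
#' @return Matrix of row-wise proportions.
#' @export
relative_abundance <- function(counts) {
  m <- as.matrix(counts)
  m / rowSums(m)
}

#' Keep the most abundant taxa
#'
#' @param rel Samples x taxa relative-abundance matrix.
#' @param min_mean Minimum mean relative abundance (default 1%).
#' @return The filtered matrix.
#' @export
filter_abundant <- function(rel, min_mean = 0.01) {
  rel[, colMeans(rel) >= min_mean, drop = FALSE]
}

# two-sided p for Spearman rho: seeded permutation below n_exact observations,
# t-approximation otherwise
.spearman_p <- function(rx, ry, rho, n_perm, n_exact = 12) {
  n <- length(rx)
  if (n < n_exact) {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      rp <- stats::cor(rx, sample(ry))
      if (!is.na(rp) && abs(rp) >= abs(rho) - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
}

#' Significance-masked Spearman correlation matrix
#'
#' Correlates taxa relative abundances together with abiotic covariates
#' (O2 contamination rate, production/consumption rates) across samples.
#' rho is the tie-corrected Spearman coefficient (Pearson correlation of
#' mid-ranks). p-values are two-sided: seeded permutation (default 10,000
#' draws) for fewer than 12 paired observations, t-approximation otherwise.
#' Cells with p at or above `alpha` are masked but keep their rho; pairs
#' involving a constant vector get `NA` rho and are flagged, not an error.
#'
#' @param abundances Samples x taxa matrix of relative abundances.
#' @param covariates Samples x variables matrix/data frame of process rates.
#' @param alpha Significance threshold for the mask (default 0.01, no
#'   multiple-testing correction, mirroring a raw p < 0.01 mask).
#' @param n_perm Permutation count for small-n p-values.
#' @param seed Integer seed for the permutations.
#' @param fdr If `TRUE`, Benjamini-Hochberg-adjust the p-values before
#'   masking.
#' @return A `correlation_matrix`: list with square matrices `rho`, `p`,
#'   logical `mask` (TRUE = significant at `alpha`), and `alpha`.
#' @export
spearman_matrix <- function(abundances, covariates = NULL, alpha = 0.01,
                            n_perm = 10000, seed = 1L, fdr = FALSE) {
  X <- as.matrix(abundances)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  stopifnot(alpha > 0, alpha < 1)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 paired observations", call. = FALSE)
  K <- ncol(X)
  ranks <- apply(X, 2, rank)  # mid-ranks for ties
  rho <- p <- matrix(NA_real_, K, K, dimnames = list(colnames(X), colnames(X)))
  diag(rho) <- 1; diag(p) <- 0
  constant <- apply(X, 2, function(v) length(unique(v)) == 1)
  set.seed(seed)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      if (constant[i] || constant[j]) next  # undefined rho, flagged via NA
      r <- stats::cor(ranks[, i], ranks[, j])
      rho[i, j] <- rho[j, i] <- r
      pv <- .spearman_p(ranks[, i], ranks[, j], r, n_perm)
      p[i, j] <- p[j, i] <- pv
    }
  }
  if (fdr) {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  mask <- !is.na(p) & p < alpha
  structure(list(rho = rho, p = p, mask = mask, alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  k <- ncol(x$rho)
  cat("Spearman correlation matrix:", k, "variables;",
      sum(x$mask[upper.tri(x$mask)]), "significant pairs at p <", x$alpha, "\n")
  invisible(x)
}
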