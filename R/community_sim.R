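# Synthetic genus-level count tables whose expected composition is linked to
# the reactor's true process rates (softmax of an affine map), with
# Dirichlet-multinomial sampling noise. Input generator for the correlation
# stage; it emulates amplicon counts, not sequence processing.

#' Specify the taxa-to-rate link of the synthetic community
#'
#' Expected log-abundance of taxon j in a sample is `intercepts[j] +
#' sum_k coefs[j, k] * rate_k`, where the rates are the trajectory's true
#' volumetric rates of `rate_vars` at the sampling time; relative abundances
#' are the softmax over taxa. Counts are Dirichlet-multinomial with
#' concentration `dispersion` (larger = closer to multinomial around the
#' expected composition; `Inf` = deterministic largest-remainder counts).
#'
#' @param taxa Character vector of taxon names (>= 2).
#' @param intercepts Numeric vector, one per taxon.
#' @param coefs Matrix (taxa x rate variables) of link coefficients.
#' @param rate_vars Compound names whose true rates drive the link.
#' @param dispersion Dirichlet concentration parameter (> 0, may be `Inf`).
#' @param depth_range Integer range of reads per sample.
#' @param seed Integer seed.
#' @return A `community_link_spec`.
#' @export
community_link_spec <- function(taxa, intercepts, coefs, rate_vars,
                                dispersion = 200, depth_range = c(4977, 20000),
                                seed = 1L) {
  coefs <- as.matrix(coefs)
  stopifnot(length(taxa) >= 2, length(intercepts) == length(taxa),
            nrow(coefs) == length(taxa), ncol(coefs) == length(rate_vars),
            dispersion > 0, all(depth_range > 0),
            depth_range[2] >= depth_range[1])
  if (all(coefs == 0) && all(intercepts == intercepts[1]))
    stop("degenerate link: all-zero coefficients with constant intercepts",
         call. = FALSE)
  structure(list(taxa = taxa, intercepts = intercepts, coefs = coefs,
                 rate_vars = rate_vars, dispersion = dispersion,
                 depth_range = as.integer(depth_range), seed = seed),
            class = "community_link_spec")
}

# deterministic integer counts summing to depth (largest remainder)
.largest_remainder <- function(p, depth) {
  raw <- p * depth
  base <- floor(raw)
  short <- depth - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic genus count table linked to process rates
#'
#' @param trajectory A `reactor_trajectory`.
#' @param link A [community_link_spec()].
#' @param sample_times Times (days) at which community samples are drawn; must
#'   lie within the trajectory. Default: the trajectory's sampling times.
#' @return Integer matrix (samples x taxa) with rownames `"t<time>"` and a
#'   `"time_d"` attribute; class `community_counts`.
#' @export
generate_community <- function(trajectory, link,
                               sample_times = trajectory$liquid$time_d) {
  stopifnot(inherits(link, "community_link_spec"))
  dur <- trajectory$scenario$duration
  stopifnot(all(sample_times >= 0), all(sample_times <= dur))
  set.seed(link$seed)
  n <- length(sample_times)
  K <- length(link$taxa)
  counts <- matrix(0L, n, K, dimnames = list(paste0("t", sample_times),
                                             link$taxa))
  dt <- trajectory$scenario$dt
  for (i in seq_len(n)) {
    # true rates in a one-step window ending at the sampling time
    t0 <- max(0, sample_times[i] - dt)
    pr <- true_rates(trajectory, rate_period(t0, max(sample_times[i], t0 + dt)))
    r <- vapply(link$rate_vars, function(v)
      if (v %in% names(pr)) pr[[v]] else 0, numeric(1))
    eta <- link$intercepts + drop(link$coefs %*% r)
    p <- exp(eta - max(eta))
    p <- p / sum(p)
    depth <- if (link$depth_range[1] == link$depth_range[2]) link$depth_range[1]
             else sample(seq(link$depth_range[1], link$depth_range[2]), 1)
    if (is.infinite(link$dispersion)) {
      counts[i, ] <- .largest_remainder(p, depth)
    } else {
      g <- stats::rgamma(K, shape = link$dispersion * p, rate = 1)
      if (sum(g) <= 0) g <- p
      counts[i, ] <- drop(stats::rmultinom(1, depth, g / sum(g)))
    }
  }
  attr(counts, "time_d") <- sample_times
  class(counts) <- c("community_counts", class(counts))
  counts
}
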