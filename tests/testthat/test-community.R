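test_that("rarefied samples always sum to the target depth", {
  set.seed(99)
  for (rep in 1:5) {
    m <- matrix(rpois(40, 60), 4, 10,
                dimnames = list(paste0("s", 1:4), paste0("g", 1:10)))
    depth <- min(rowSums(m))
    r <- rarefy_counts(m, depth, seed = rep)
    expect_identical(unname(rowSums(r)), rep(depth, 4L))
    expect_true(all(r <= m))
  }
})

test_that("rarefaction edge cases behave", {
  # a sample already at depth keeps its counts
  m <- matrix(c(30L, 20L, 20L, 80L), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  r <- rarefy_counts(m, 50, seed = 1)
  expect_identical(r["a", ], m["a", ])
  # a one-taxon sample keeps everything in that taxon
  m1 <- matrix(c(500L, 0L), 1, 2, dimnames = list("s", c("x", "y")))
  expect_identical(rarefy_counts(m1, 100, seed = 1)[1, ],
                   c(x = 100L, y = 0L))
  # over-deep requests name the offending samples
  expect_error(rarefy_counts(m, 200), "a, b")
  # seed reproducibility
  big <- matrix(rpois(60, 100), 3, 20)
  expect_identical(rarefy_counts(big, 50, seed = 3),
                   rarefy_counts(big, 50, seed = 3))
})

test_that("subsampling means match the hypergeometric expectation", {
  m <- matrix(c(60L, 40L), 1, 2, dimnames = list("s", c("A", "B")))
  draws <- vapply(1:10000, function(s) rarefy_counts(m, 10, seed = s)[1, 1],
                  integer(1))
  expect_gt(mean(draws), 5.7)   # hypergeometric mean = 6.0
  expect_lt(mean(draws), 6.3)
})

test_that("Spearman rho matches monotone expectations and the mid-rank oracle", {
  x <- c(1, 3, 8, 9, 15, 20)
  sm <- spearman_matrix(cbind(a = x, b = x^3, c = -x + 2), alpha = 0.05,
                        n_perm = 500, seed = 1)
  expect_equal(sm$rho["a", "b"], 1)
  expect_equal(sm$rho["a", "c"], -1)
  # tie-bearing fixtures against the brute-force mid-rank oracle
  fixtures <- list(
    list(x = c(1, 2, 2, 3, 5, 5), y = c(2, 2, 4, 4, 4, 9)),
    list(x = c(0, 0, 0, 1, 1, 2), y = c(5, 3, 3, 2, 2, 1)),
    list(x = c(7, 1, 4, 4, 2, 9), y = c(1, 1, 6, 3, 3, 3)))
  for (f in fixtures) {
    sm <- spearman_matrix(cbind(x = f$x, y = f$y), n_perm = 2000, seed = 2)
    expect_equal(sm$rho["x", "y"], oracle_spearman(f$x, f$y),
                 tolerance = 1e-12)
  }
})

test_that("small-n permutation p-values agree with exhaustive enumeration", {
  fixtures <- list(
    list(x = c(1, 2, 2, 3, 5, 5), y = c(2, 2, 4, 4, 4, 9)),
    list(x = c(7, 1, 4, 4, 2, 9), y = c(1, 1, 6, 3, 3, 3)))
  for (f in fixtures) {
    p_exact <- oracle_perm_p(f$x, f$y)
    B <- 4000
    sm <- spearman_matrix(cbind(x = f$x, y = f$y), n_perm = B, seed = 7)
    # within 4 binomial standard errors of the exact enumeration
    tol <- 4 * sqrt(p_exact * (1 - p_exact) / B) + 2 / B
    expect_lt(abs(sm$p["x", "y"] - p_exact), tol)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(9); y <- rnorm(9)
    base <- spearman_matrix(cbind(x = x, y = y), seed = 1)$rho["x", "y"]
    f <- sample(list(function(v) exp(v), function(v) v^3,
                     function(v) atan(v) * 5 + 2))[[1]]
    tr <- spearman_matrix(cbind(x = f(x), y = y), seed = 1)$rho["x", "y"]
    expect_equal(tr, base, tolerance = 1e-12)
  }
})

test_that("constant vectors are flagged, not an error", {
  sm <- spearman_matrix(cbind(a = 1:6, b = rep(2, 6)), n_perm = 100, seed = 1)
  expect_true(is.na(sm$rho["a", "b"]))
  expect_false(sm$mask["a", "b"])
})

test_that("large-n p-values use the t approximation", {
  set.seed(5)
  x <- rnorm(30); y <- x + rnorm(30, sd = 0.5)
  sm <- spearman_matrix(cbind(x = x, y = y), seed = 1)
  rho <- sm$rho["x", "y"]
  tstat <- rho * sqrt((30 - 2) / (1 - rho^2))
  expect_equal(sm$p["x", "y"], 2 * pt(-abs(tstat), 28), tolerance = 1e-12)
  expect_true(sm$mask["x", "y"])
})
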