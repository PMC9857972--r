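# Two-bead instance with a single pair at controlled distance/count.
two_bead_instance <- function(count, d) {
  mat <- matrix(0L, 2, 2); mat[1, 2] <- mat[2, 1] <- count
  list(m = contact_matrix(mat),
       X = structure3d(rbind(c(0, 0, 0), c(d, 0, 0))))
}

test_that("NB log-PMF matches the closed-form geometric case", {
  expect_equal(nb_log_pmf(0, mu = 1, r = 1), log(0.5), tolerance = 1e-12)
  expect_equal(nb_log_pmf(1, mu = 1, r = 1), log(0.25), tolerance = 1e-12)
  # and agrees with R's own NB density in the same parameterization
  expect_equal(nb_log_pmf(0:20, mu = 2.5, r = 0.7),
               dnbinom(0:20, size = 0.7, mu = 2.5, log = TRUE),
               tolerance = 1e-12)
})

test_that("NB PMF sums to one over its support", {
  for (mu in c(0.5, 2, 10)) {
    for (r in c(0.1, 1, 10)) {
      total <- sum(exp(nb_log_pmf(0:50000, mu = mu, r = r)))
      expect_gte(total, 1 - 1e-8)
      expect_lte(total, 1 + 1e-8)
    }
  }
})

test_that("single-pair likelihoods reproduce closed forms", {
  tb <- two_bead_instance(0L, d = 1)  # mu = d^alpha = 1
  expect_equal(nb_log_likelihood(tb$X, tb$m, alpha = -3, r = 1),
               log(0.5), tolerance = 1e-12)
  tb1 <- two_bead_instance(1L, d = 1)
  expect_equal(nb_log_likelihood(tb1$X, tb1$m, alpha = -3, r = 1),
               log(0.25), tolerance = 1e-12)
  expect_equal(poisson_log_likelihood(tb$X, tb$m, alpha = -3), -1,
               tolerance = 1e-12)
  tb2 <- two_bead_instance(2L, d = 2^(-1 / 3))  # mu = 2
  expect_equal(poisson_log_likelihood(tb2$X, tb2$m, alpha = -3),
               2 * log(2) - 2 - log(2), tolerance = 1e-10)
})

test_that("the NB likelihood tends to the Poisson likelihood as r grows", {
  set.seed(7)
  n <- 10
  X <- structure3d(matrix(rnorm(3 * n), n, 3))
  mat <- matrix(0L, n, n)
  ut <- upper.tri(mat)
  mat[ut] <- rpois(sum(ut), 3)
  m <- contact_matrix(mat + t(mat))
  pois <- poisson_log_likelihood(X, m, alpha = -3)
  gaps <- sapply(c(1e4, 1e6, 1e8), function(r) {
    abs(nb_log_likelihood(X, m, alpha = -3, r = r) - pois)
  })
  expect_lt(gaps[3], 1e-3)
  expect_true(all(diff(gaps) < 0))  # monotone approach to the limit
})

test_that("analytic gradients agree with central finite differences", {
  for (n in c(5, 10, 20)) {
    set.seed(n)
    X <- structure3d(matrix(rnorm(3 * n), n, 3))
    mat <- matrix(0L, n, n)
    ut <- upper.tri(mat)
    mat[ut] <- rpois(sum(ut), 4)
    m <- contact_matrix(mat + t(mat))
    b <- generate_biases(n, "lognormal:0.2", seed = n)
    g <- nb_gradient(X, m, b, alpha = -2.2, r = 0.6)
    f <- function(par) {
      nb_log_likelihood(structure3d(matrix(par[1:(3 * n)], n, 3)), m, b,
                        alpha = par[3 * n + 1], r = 0.6)
    }
    fd <- numeric_gradient(f, c(as.vector(X$coords), -2.2))
    analytic <- c(as.vector(g$coords), g$alpha)
    expect_lt(max(abs(analytic - fd) / pmax(abs(fd), 1e-6)), 1e-4)
    # translation invariance: per-axis gradient sums vanish
    expect_lt(max(abs(colSums(g$coords))), 1e-9)
  }
})

test_that("the distance gradient vanishes at the single-pair NB MLE", {
  tb <- two_bead_instance(8L, d = 8^(-1 / 3))  # mu = d^-3 = 8 = c
  g <- nb_gradient(tb$X, tb$m, alpha = -3, r = 1)
  expect_lt(max(abs(g$coords)), 1e-9)
})

test_that("the likelihood is invariant under rigid motion", {
  inst <- helix_instance(n = 20, seed = 3)
  r <- 1.2
  base <- nb_log_likelihood(inst$truth, inst$counts, alpha = -3, r = r)
  for (sd in 1:3) {
    moved <- random_rigid_motion(inst$truth, seed = sd)
    expect_equal(nb_log_likelihood(moved, inst$counts, alpha = -3, r = r),
                 base, tolerance = 1e-9)
  }
})

test_that("zero-count pairs can be excluded from the objective", {
  inst <- helix_instance(n = 15, beta_rel = 0.05, seed = 5)
  ll_all <- nb_log_likelihood(inst$truth, inst$counts, alpha = -3, r = 1)
  ll_nz <- nb_log_likelihood(inst$truth, inst$counts, alpha = -3, r = 1,
                             include_zeros = FALSE)
  expect_gt(ll_nz, ll_all)  # fewer (negative) terms
})

test_that("parameter validation rejects degenerate inputs", {
  tb <- two_bead_instance(1L, d = 1)
  expect_error(nb_log_likelihood(tb$X, tb$m, alpha = 0.5, r = 1), "negative")
  expect_error(nb_log_likelihood(tb$X, tb$m, alpha = -3, r = 0), "positive")
  expect_error(nb_log_pmf(1, mu = -1, r = 1), "positive")
})
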