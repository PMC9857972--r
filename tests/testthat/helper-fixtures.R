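# Shared fixtures and independent oracles used across the test files.

# Random symmetric integer count matrix with zero diagonal.
random_count_matrix <- function(n, seed = 1, lambda = 5) {
  set.seed(seed)
  m <- matrix(0L, n, n)
  ut <- upper.tri(m)
  m[ut] <- rpois(sum(ut), lambda)
  m + t(m)
}

# Independent iterative-scaling oracle for ICE: square-root-damped updates,
# run to tight convergence. Shares only the fixed point (unique up to scale)
# with the package's implementation, not the iteration.
ice_oracle <- function(counts, iters = 10000, tol = 1e-12) {
  keep <- rowSums(counts) > 0
  cm <- counts[keep, keep, drop = FALSE]
  b <- rep(1, nrow(cm))
  for (it in seq_len(iters)) {
    s <- rowSums(cm / outer(b, b))
    ratio <- s / mean(s)
    if (max(abs(ratio - 1)) < tol) break
    b <- b * sqrt(ratio)
  }
  out <- rep(NA_real_, nrow(counts))
  out[keep] <- b / mean(b)
  out
}

# Central finite-difference gradient of a scalar function of a vector.
numeric_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Brute-force rigid (proper rotation only) superposition RMSD: numeric
# search over Euler angles from many starts. Used as an oracle for the
# no-reflection RMSD.
rigid_rmsd_oracle <- function(X, Y, n_starts = 40, seed = 1) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rotmat <- function(a) {
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
    Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
    Rx %*% Ry %*% Rz
  }
  obj <- function(a) sqrt(mean(rowSums((Xc %*% rotmat(a) - Yc)^2)))
  set.seed(seed)
  best <- Inf
  for (k in seq_len(n_starts)) {
    a0 <- runif(3, 0, 2 * pi)
    o <- optim(a0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  best
}

# Apply a random rigid motion (optionally a reflection) to a structure.
random_rigid_motion <- function(s, seed = 1, reflect = FALSE) {
  set.seed(seed)
  qr_r <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_r) < 0) qr_r[, 1] <- -qr_r[, 1]
  if (reflect) qr_r[, 1] <- -qr_r[, 1]
  t <- rnorm(3, sd = 10)
  structure3d(sweep(s$coords %*% qr_r, 2, -t), valid = s$valid,
              chrom = s$chrom, bin_index = s$bin_index)
}

# Standard simulated instance used by several inference tests.
helix_instance <- function(n = 50, gamma = 1, beta_rel = 1, alpha = -3,
                           seed = 1) {
  s <- generate_structure(n, "helix")
  cfg <- simulation_config(n, "helix", alpha = alpha, beta_rel = beta_rel,
                          gamma = gamma, seed = seed)
  list(truth = s, counts = simulate_counts(s, cfg = cfg), cfg = cfg,
       diameter = max(dist(s$coords)))
}

# Dispersion for a pipeline run: the moment estimate, or a moderate default
# when the estimator is clamped at zero (uninformative); inference is robust
# to an order of magnitude of dispersion misestimation.
pipeline_dispersion <- function(m, fallback = 1) {
  est <- suppressWarnings(
    tryCatch(estimate_dispersion(per_distance_stats(m))$r,
             error = function(e) 0))
  if (est > 0) est else fallback
}
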