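#' Negative binomial log probability mass
#'
#' Log PMF of the NB distribution parameterized by mean `mu` and dispersion
#' `r` (variance `mu + mu^2 / r`), evaluated through log-Gamma functions:
#' `lgamma(x + r) - lgamma(x + 1) - lgamma(r) + x * (log mu - log(r + mu)) +
#' r * (log r - log(r + mu))`. This is the per-pair term of the model
#' likelihood; exposed for diagnostics and testing.
#'
#' @param x Non-negative integer counts (vectorized).
#' @param mu Positive means.
#' @param r Positive dispersions.
#' @return Numeric vector of log probabilities.
#' @export
nb_log_pmf <- function(x, mu, r) {
  if (any(r <= 0)) stop("dispersion must be positive", call. = FALSE)
  if (any(mu <= 0)) stop("mean must be positive", call. = FALSE)
  lgamma(x + r) - lgamma(x + 1) - lgamma(r) +
    x * (log(mu) - log(r + mu)) + r * (log(r) - log(r + mu))
}

# Assemble the pair-level data entering the likelihood: all i < j among loci
# that are unfiltered, have coordinates, and (optionally) nonzero counts.
# Inter-chromosomal pairs are included; the diagonal never is.
pair_data <- function(m, bias, valid, include_zeros = TRUE) {
  n <- m$n
  keep <- which(valid & !bias$filtered)
  if (length(keep) < 2L) stop("fewer than 2 usable loci", call. = FALSE)
  pr <- utils::combn(keep, 2L)
  ii <- pr[1, ]; jj <- pr[2, ]
  cc <- m$counts[cbind(ii, jj)]
  if (!include_zeros) {
    nz <- cc > 0
    ii <- ii[nz]; jj <- jj[nz]; cc <- cc[nz]
    if (!length(ii)) stop("no nonzero pair among usable loci", call. = FALSE)
  }
  list(ii = ii, jj = jj, counts = cc, bb = bias$b[ii] * bias$b[jj],
       beads = keep)
}

# Distance floor: keeps mu finite when beads transiently coincide during
# optimization (alpha < 0 makes mu blow up as d -> 0).
DIST_EPS <- 1e-8

pair_dists <- function(coords, pd) {
  dx <- coords[pd$ii, , drop = FALSE] - coords[pd$jj, , drop = FALSE]
  d <- sqrt(rowSums(dx * dx))
  pmax(d, DIST_EPS)
}

check_model_args <- function(X, m, bias, alpha) {
  stopifnot(inherits(X, "structure3d"), inherits(m, "contact_matrix"),
            inherits(bias, "bias_vector"))
  if (X$n != m$n || bias$n != m$n) {
    stop("structure, counts and bias dimensions disagree", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha >= 0) {
    stop("`alpha` must be a finite negative number", call. = FALSE)
  }
  if (any(!is.finite(X$coords[X$valid, ]))) {
    stop("valid beads carry non-finite coordinates", call. = FALSE)
  }
}

#' Negative binomial log-likelihood of a structure
#'
#' Sums `nb_log_pmf` over all pairs `i < j` of unfiltered, valid loci, with
#' mean `mu_ij = beta * b_i * b_j * d_ij^alpha` and dispersion
#' `r_ij = b_i * b_j * r`. Zero-count pairs contribute by default; they are
#' informative (a zero count is evidence of a large distance) and excluding
#' them degrades inference.
#'
#' @param X A [structure3d()].
#' @param m A [contact_matrix()].
#' @param bias A [bias_vector()]; defaults to unit biases.
#' @param alpha Negative count-to-distance exponent.
#' @param r Positive global dispersion.
#' @param beta Positive scale factor; fixed at 1 during inference (the scale
#'   of the structure absorbs it).
#' @param include_zeros Include pairs with `c_ij = 0`? Default `TRUE`.
#' @return The total log-likelihood (a scalar).
#' @export
nb_log_likelihood <- function(X, m, bias = NULL, alpha, r, beta = 1,
                              include_zeros = TRUE) {
  if (is.null(bias)) bias <- unit_bias(m$n)
  check_model_args(X, m, bias, alpha)
  if (!is.finite(r) || r <= 0) stop("`r` must be positive", call. = FALSE)
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  pd <- pair_data(m, bias, X$valid, include_zeros)
  d <- pair_dists(X$coords, pd)
  mu <- beta * pd$bb * d^alpha
  rij <- pd$bb * r
  sum(nb_log_pmf(pd$counts, mu, rij))
}

#' Poisson log-likelihood of a structure
#'
#' The Poisson baseline: `sum(c_ij * log(mu_ij) - mu_ij - lgamma(c_ij + 1))`
#' with the same mean parameterization as [nb_log_likelihood()]. This is the
#' dispersion-to-infinity limit of the negative binomial model.
#'
#' @inheritParams nb_log_likelihood
#' @return The total log-likelihood (a scalar).
#' @export
poisson_log_likelihood <- function(X, m, bias = NULL, alpha, beta = 1,
                                   include_zeros = TRUE) {
  if (is.null(bias)) bias <- unit_bias(m$n)
  check_model_args(X, m, bias, alpha)
  pd <- pair_data(m, bias, X$valid, include_zeros)
  d <- pair_dists(X$coords, pd)
  mu <- beta * pd$bb * d^alpha
  sum(pd$counts * log(mu) - mu - lgamma(pd$counts + 1))
}

# Scatter per-pair contributions g * (x_i - x_j) into a per-bead gradient.
accumulate_pair_gradient <- function(g, coords, pd, n) {
  grad <- matrix(0, n, 3L)
  for (k in 1:3) {
    v <- g * (coords[pd$ii, k] - coords[pd$jj, k])
    sums <- rowsum(c(v, -v), group = c(pd$ii, pd$jj))
    grad[as.integer(rownames(sums)), k] <- sums
  }
  grad
}

#' Analytic gradient of the log-likelihood
#'
#' Gradient of the negative binomial (or Poisson) log-likelihood with
#' respect to the coordinates of all valid beads and to `alpha`, via the
#' chain rule through `mu_ij`: `dL/dmu = c/mu - (c + r_ij)/(r_ij + mu)`
#' (Poisson: `c/mu - 1`), `dmu/dx_i = mu * alpha * (x_i - x_j) / d^2`,
#' `dmu/dalpha = mu * log d`. The dispersion is held fixed, so no digamma
#' terms arise.
#'
#' @inheritParams nb_log_likelihood
#' @param model `"nb"` or `"poisson"`.
#' @return A list with `coords` (n-by-3 matrix, zero rows for invalid or
#'   filtered beads) and `alpha` (scalar).
#' @export
nb_gradient <- function(X, m, bias = NULL, alpha, r = NULL, beta = 1,
                        include_zeros = TRUE, model = c("nb", "poisson")) {
  model <- match.arg(model)
  if (is.null(bias)) bias <- unit_bias(m$n)
  check_model_args(X, m, bias, alpha)
  if (model == "nb" && (is.null(r) || r <= 0)) {
    stop("`r` must be positive for the NB model", call. = FALSE)
  }
  pd <- pair_data(m, bias, X$valid, include_zeros)
  d <- pair_dists(X$coords, pd)
  mu <- beta * pd$bb * d^alpha
  dldmu <- if (model == "nb") {
    rij <- pd$bb * r
    pd$counts / mu - (pd$counts + rij) / (rij + mu)
  } else {
    pd$counts / mu - 1
  }
  g <- dldmu * mu * alpha / d^2
  list(coords = accumulate_pair_gradient(g, X$coords, pd, X$n),
       alpha = sum(dldmu * mu * log(d)))
}
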