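#' Simulation configuration
#'
#' Bundles the parameters of the synthetic Hi-C generator. Counts are drawn
#' independently for each bead pair as negative binomial with mean
#' `mu_ij = beta * b_i * b_j * d_ij^alpha` and dispersion
#' `r_ij = gamma * b_i * b_j`, mirroring the inference model so that the
#' tuning parameter `gamma` is directly comparable to the estimated
#' dispersion. Smaller `gamma` means more overdispersion; large `gamma`
#' approaches Poisson noise. `beta_rel` scales a reference coverage
#' calibrated so the mean nearest-neighbour count is `target_nn` (default
#' 100) at `beta_rel = 1`, emulating sweeps from full to fractional coverage.
#'
#' @param n_beads Number of beads (>= 2).
#' @param structure_kind `"helix"` or `"random_walk"`.
#' @param alpha Negative count-to-distance exponent (default -3).
#' @param beta_rel Relative coverage in (0, Inf); 1 = reference coverage.
#' @param gamma Positive dispersion tuning parameter (default 1).
#' @param bias_spec `"unit"` or `"lognormal:<sd>"` (see [generate_biases()]).
#' @param target_nn Mean nearest-neighbour count at reference coverage.
#' @param seed Integer seed; identical configs give identical data.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_beads, structure_kind = c("helix", "random_walk"),
                              alpha = -3, beta_rel = 1, gamma = 1,
                              bias_spec = "unit", target_nn = 100,
                              seed = 0L) {
  structure_kind <- match.arg(structure_kind)
  if (n_beads < 2) stop("`n_beads` must be at least 2", call. = FALSE)
  if (alpha >= 0) stop("`alpha` must be negative", call. = FALSE)
  if (beta_rel <= 0) stop("`beta_rel` must be positive", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (target_nn <= 0) stop("`target_nn` must be positive", call. = FALSE)
  structure(
    list(n_beads = as.integer(n_beads), structure_kind = structure_kind,
         alpha = alpha, beta_rel = beta_rel, gamma = gamma,
         bias_spec = bias_spec, target_nn = target_nn,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate a ground-truth structure
#'
#' `helix`: a regular helix of radius 1 with ten beads per turn and unit rise
#' per turn, so all adjacent bead distances are equal. `random_walk`: the
#' cumulative sum of unit-length steps in uniformly random directions.
#'
#' @param n Number of beads (>= 2).
#' @param kind `"helix"` or `"random_walk"`.
#' @param seed Integer seed (used by `random_walk`).
#' @return A [structure3d()] with all beads valid.
#' @export
generate_structure <- function(n, kind = c("helix", "random_walk"),
                               seed = 0L) {
  kind <- match.arg(kind)
  if (n < 2) stop("need at least 2 beads", call. = FALSE)
  if (kind == "helix") {
    t <- (seq_len(n) - 1) * 2 * pi / 10
    coords <- cbind(cos(t), sin(t), (seq_len(n) - 1) / 10)
  } else {
    set.seed(as.integer(seed))
    theta <- stats::runif(n - 1, 0, 2 * pi)
    u <- stats::runif(n - 1, -1, 1)
    steps <- cbind(sqrt(1 - u^2) * cos(theta), sqrt(1 - u^2) * sin(theta), u)
    coords <- rbind(0, apply(steps, 2L, cumsum))
  }
  structure3d(coords)
}

#' Generate per-locus biases
#'
#' `"unit"` yields all-one biases. `"lognormal:<sd>"` draws i.i.d. log-normal
#' biases with `sdlog = sd`, rescaled to arithmetic mean exactly 1 (the same
#' convention ICE uses), emulating locus-specific visibility differences.
#'
#' @param n Number of loci.
#' @param bias_spec `"unit"` or `"lognormal:<sd>"` with `sd >= 0`.
#' @param seed Integer seed.
#' @return A [bias_vector()] with no filtered loci.
#' @export
generate_biases <- function(n, bias_spec = "unit", seed = 0L) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (identical(bias_spec, "unit")) {
    return(unit_bias(n))
  }
  if (grepl("^lognormal:", bias_spec)) {
    sd <- as.numeric(sub("^lognormal:", "", bias_spec))
    if (is.na(sd) || sd < 0) {
      stop("lognormal bias sd must be a non-negative number", call. = FALSE)
    }
    if (sd == 0) return(unit_bias(n))
    set.seed(as.integer(seed))
    b <- stats::rlnorm(n, meanlog = 0, sdlog = sd)
    return(bias_vector(b / mean(b)))
  }
  stop(sprintf("unknown bias_spec '%s'", bias_spec), call. = FALSE)
}

#' Reference coverage scale for a structure
#'
#' The coverage scale `beta` such that the mean count over adjacent
#' (nearest-neighbour along the chain) bead pairs equals `target_nn` under
#' `mu = beta * d^alpha` with unit biases.
#'
#' @param s A [structure3d()] with all beads valid.
#' @param alpha Negative exponent.
#' @param target_nn Target mean nearest-neighbour count.
#' @return A positive scalar.
#' @export
reference_beta <- function(s, alpha, target_nn = 100) {
  stopifnot(inherits(s, "structure3d"))
  d_nn <- sqrt(rowSums((s$coords[-1, , drop = FALSE] -
                          s$coords[-s$n, , drop = FALSE])^2))
  target_nn / mean(d_nn^alpha)
}

#' Simulate a synthetic Hi-C contact matrix
#'
#' Draws one independent negative binomial count per bead pair `i < j` with
#' mean `beta * b_i * b_j * d_ij^alpha` and dispersion `gamma * b_i * b_j`,
#' mirrors it to `(j, i)`, and zeroes the diagonal. Sampling uses the
#' gamma-Poisson mixture construction (a gamma-distributed rate with shape
#' `r_ij` and mean `mu_ij`, then a Poisson draw), which is the standard
#' mean/dispersion parameterization of the NB.
#'
#' @param s A [structure3d()]; all beads must be valid and distinct.
#' @param bias A [bias_vector()]; default generated from `cfg$bias_spec`.
#' @param cfg A [simulation_config()].
#' @return A [contact_matrix()].
#' @export
simulate_counts <- function(s, bias = NULL, cfg) {
  stopifnot(inherits(s, "structure3d"), inherits(cfg, "simulation_config"))
  if (s$n != cfg$n_beads) stop("structure size disagrees with config", call. = FALSE)
  if (!all(s$valid)) stop("ground-truth structure must have all beads valid", call. = FALSE)
  if (is.null(bias)) {
    bias <- generate_biases(s$n, cfg$bias_spec, seed = cfg$seed + 1000003L)
  }
  stopifnot(inherits(bias, "bias_vector"))
  pr <- utils::combn(s$n, 2L)
  ii <- pr[1, ]; jj <- pr[2, ]
  dx <- s$coords[ii, , drop = FALSE] - s$coords[jj, , drop = FALSE]
  d <- sqrt(rowSums(dx * dx))
  if (any(d == 0)) stop("coincident beads in the ground-truth structure", call. = FALSE)
  beta <- cfg$beta_rel * reference_beta(s, cfg$alpha, cfg$target_nn)
  bb <- bias$b[ii] * bias$b[jj]
  mu <- beta * bb * d^cfg$alpha
  rij <- cfg$gamma * bb
  set.seed(cfg$seed)
  lambda <- stats::rgamma(length(mu), shape = rij, scale = mu / rij)
  counts <- stats::rpois(length(mu), lambda)
  mat <- matrix(0, s$n, s$n)
  mat[cbind(ii, jj)] <- counts
  mat[cbind(jj, ii)] <- counts
  contact_matrix(mat, chrom = s$chrom, bin_index = s$bin_index)
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper: generates the ground-truth structure, biases and
#' counts from one [simulation_config()].
#'
#' @param cfg A [simulation_config()].
#' @return A list with `structure`, `bias`, `counts` and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  s <- generate_structure(cfg$n_beads, cfg$structure_kind,
                          seed = cfg$seed + 2000029L)
  b <- generate_biases(cfg$n_beads, cfg$bias_spec, seed = cfg$seed + 1000003L)
  m <- simulate_counts(s, b, cfg)
  list(structure = s, bias = b, counts = m, config = cfg)
}
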