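#' Per-genomic-distance moments of normalized counts
#'
#' For every intra-chromosomal genomic distance `l = |i - j|` (in bins),
#' computes the empirical mean and variance of the normalized counts
#' `c_ij / (b_i b_j)` over all unfiltered pairs at that distance, pooled
#' across chromosomes. The sample variance is corrected for bias-induced
#' inflation by dividing by the mean inverse bias product at that distance,
#' so that under the model the corrected variance matches
#' `mu + mu^2 / r` on the normalized scale. Distances with fewer than two
#' pairs, or with zero empirical mean or variance, are marked `discarded`.
#'
#' @param m A [contact_matrix()].
#' @param bias A [bias_vector()]; defaults to unit biases.
#' @return A tibble of class `distance_stats` with columns `l`, `n_pairs`
#'   (N_l, also the weight), `mean`, `var_raw` (uncorrected), `var`
#'   (corrected), `discarded`; attribute `l_max` is the largest distance with
#'   at least two pairs.
#' @export
per_distance_stats <- function(m, bias = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (is.null(bias)) bias <- unit_bias(m$n)
  stopifnot(inherits(bias, "bias_vector"))
  if (bias$n != m$n) stop("bias length does not match matrix size", call. = FALSE)

  keep <- !bias$filtered
  ii <- jj <- integer(0)
  for (ch in unique(m$chrom)) {
    ix <- which(m$chrom == ch & keep)
    if (length(ix) < 2L) next
    pr <- utils::combn(ix, 2L)
    ii <- c(ii, pr[1, ]); jj <- c(jj, pr[2, ])
  }
  if (!length(ii)) {
    stop("no valid intra-chromosomal pair available", call. = FALSE)
  }
  l <- abs(m$bin_index[ii] - m$bin_index[jj])
  bb <- bias$b[ii] * bias$b[jj]
  cn <- m$counts[cbind(ii, jj)] / bb
  inv_bb <- 1 / bb

  lev <- sort(unique(l))
  lf <- factor(l, levels = lev)
  n_pairs <- as.integer(table(lf))
  mu <- as.numeric(tapply(cn, lf, mean))
  var_raw <- as.numeric(tapply(cn, lf, stats::var))
  corr <- as.numeric(tapply(inv_bb, lf, mean))
  var_cor <- var_raw / corr

  stats <- tibble::tibble(
    l = lev, n_pairs = n_pairs, mean = mu,
    var_raw = var_raw, var = var_cor
  )
  stats <- stats[stats$n_pairs >= 2L, , drop = FALSE]
  if (!nrow(stats)) stop("no genomic distance with at least two pairs", call. = FALSE)
  stats$discarded <- stats$mean == 0 | stats$var == 0
  attr(stats, "l_max") <- max(stats$l)
  class(stats) <- c("distance_stats", class(stats))
  stats
}

#' Estimate the global negative binomial dispersion
#'
#' From per-distance moments, each retained genomic distance `l` yields a
#' dispersion estimate `r_l = mean_l^2 / (var_l - mean_l)` (negative when the
#' counts at that distance are underdispersed). The global dispersion is the
#' weighted average of the `r_l` with weights `N_l` (the number of pairs at
#' each distance, so short distances dominate), clamped at zero. Long
#' distances, where few pairs make the moments unreliable, are excluded:
#' only `l < cutoff_fraction * l_max` enters (strict inequality).
#'
#' @param stats A `distance_stats` tibble from [per_distance_stats()].
#' @param cutoff_fraction Fraction of the maximum genomic distance retained;
#'   default 2/3.
#' @return An object of class `dispersion_estimate` with elements `r`,
#'   `stats` (the retained per-distance table including `r_l`),
#'   `cutoff_fraction` and `l_max`. A warning recommends the Poisson model
#'   when `r` is clamped to (near) zero.
#' @export
#' @examples
#' s <- generate_structure(60, "helix")
#' m <- simulate_counts(s, cfg = simulation_config(60, gamma = 0.5, seed = 3))
#' estimate_dispersion(per_distance_stats(m))
estimate_dispersion <- function(stats, cutoff_fraction = 2 / 3) {
  stopifnot(inherits(stats, "distance_stats"))
  if (cutoff_fraction <= 0) stop("`cutoff_fraction` must be positive", call. = FALSE)
  l_max <- attr(stats, "l_max")
  keep <- stats[stats$l < cutoff_fraction * l_max & !stats$discarded, ,
                drop = FALSE]
  degenerate <- keep$var == keep$mean
  if (any(degenerate)) {
    keep <- keep[!degenerate, , drop = FALSE]
  }
  if (!nrow(keep)) stop("every genomic distance was discarded", call. = FALSE)
  keep$r_l <- keep$mean^2 / (keep$var - keep$mean)
  keep$weight <- keep$n_pairs
  r <- max(0, sum(keep$weight * keep$r_l) / sum(keep$weight))
  if (r < 1e-6) {
    warning(paste("estimated dispersion is (near) zero; the counts look",
                  "under- or equi-dispersed - consider the Poisson model"),
            call. = FALSE)
  }
  structure(
    list(r = r, stats = keep, cutoff_fraction = cutoff_fraction,
         l_max = l_max),
    class = "dispersion_estimate"
  )
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf(
    "<dispersion_estimate> r = %.6g from %d genomic distances (l < %.3g * %d)\n",
    x$r, nrow(x$stats), x$cutoff_fraction, x$l_max))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @importFrom generics tidy
tidy.dispersion_estimate <- function(x, ...) x$stats

#' @exportS3Method generics::glance
#' @importFrom generics glance
glance.dispersion_estimate <- function(x, ...) {
  tibble::tibble(r = x$r, n_distances = nrow(x$stats),
                 l_max = x$l_max, cutoff_fraction = x$cutoff_fraction)
}

#' Mean-variance diagnostic plot
#'
#' Plots the per-genomic-distance empirical variance against the mean of
#' normalized counts on log scales, with the Poisson reference line
#' `variance = mean`. Points above the line indicate overdispersion.
#'
#' @param object A `distance_stats` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.distance_stats <- function(object, ...) {
  df <- object[!object$discarded & object$mean > 0 & object$var > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$var)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean of normalized counts",
                  y = "variance of normalized counts",
                  title = "Mean-variance relationship by genomic distance") +
    ggplot2::theme_minimal()
}
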