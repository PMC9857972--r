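common_valid <- function(a, b) {
  stopifnot(inherits(a, "structure3d"), inherits(b, "structure3d"))
  if (a$n != b$n) stop("structures have different bead counts", call. = FALSE)
  a$valid & b$valid
}

# Least-squares superposition of X onto Y (rows are matched points).
# Returns the RMSD after the optimal rotation (optionally improper) and
# translation, with an optional least-squares scale applied to X.
kabsch_rmsd <- function(X, Y, allow_reflection = TRUE, allow_scaling = FALSE) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  sv <- svd(crossprod(Xc, Yc))
  d <- c(1, 1, 1)
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) d[3] <- -1
  R <- sv$u %*% diag(d) %*% t(sv$v)
  s <- if (allow_scaling) sum(sv$d * d) / sum(Xc^2) else 1
  sqrt(sum((s * Xc %*% R - Yc)^2) / n)
}

#' Superposition RMSD between two structures
#'
#' Root-mean-square deviation after the optimal least-squares superposition
#' (rotation + translation; optionally reflection and/or scale) of the beads
#' valid in both structures. Reflection is allowed by default because contact
#' data determine distances only, leaving chirality unidentifiable. With
#' `allow_scaling = TRUE` the superposition is asymmetric, so the average of
#' the two directed RMSDs is reported; without scaling the rigid RMSD is
#' already symmetric.
#'
#' @param a,b [structure3d()] objects with equal bead counts; at least 3
#'   beads must be valid in both.
#' @param allow_reflection Allow an improper rotation (default `TRUE`).
#' @param allow_scaling Fit a scale factor and average the two directed
#'   RMSDs (default `FALSE`).
#' @return A non-negative scalar.
#' @export
rmsd <- function(a, b, allow_reflection = TRUE, allow_scaling = FALSE) {
  ok <- common_valid(a, b)
  if (sum(ok) < 3L) stop("need at least 3 beads valid in both structures", call. = FALSE)
  X <- a$coords[ok, , drop = FALSE]
  Y <- b$coords[ok, , drop = FALSE]
  if (allow_scaling) {
    (kabsch_rmsd(X, Y, allow_reflection, TRUE) +
       kabsch_rmsd(Y, X, allow_reflection, TRUE)) / 2
  } else {
    kabsch_rmsd(X, Y, allow_reflection, FALSE)
  }
}

#' Spearman correlation of distance matrices
#'
#' Rank correlation between the upper-triangle pairwise distances of the two
#' structures, over beads valid in both. Invariant to any monotone
#' transformation of distances, including overall scale.
#'
#' @param a,b [structure3d()] objects with equal bead counts.
#' @return A scalar in `[-1, 1]`.
#' @export
distance_spearman <- function(a, b) {
  ok <- common_valid(a, b)
  if (sum(ok) < 3L) stop("need at least 3 beads valid in both structures", call. = FALSE)
  da <- stats::dist(a$coords[ok, , drop = FALSE])
  db <- stats::dist(b$coords[ok, , drop = FALSE])
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    stop("constant distance vector: correlation undefined", call. = FALSE)
  }
  stats::cor(c(da), c(db), method = "spearman")
}

#' Rescale a structure into a nucleus of given diameter
#'
#' Centers the valid beads at the origin and rescales uniformly so that the
#' `quantile` radius of the valid beads equals `diameter / 2`. With
#' `quantile = 0.99`, 99% of the beads fit in the sphere (robust to
#' outliers); with `quantile = 1` all beads fit exactly.
#'
#' @param s A [structure3d()].
#' @param diameter Target sphere diameter (positive).
#' @param quantile Radius quantile in (0, 1] used to define the fit.
#' @return A rescaled [structure3d()].
#' @export
rescale_structure <- function(s, diameter = 100, quantile = 0.99) {
  stopifnot(inherits(s, "structure3d"))
  if (diameter <= 0) stop("`diameter` must be positive", call. = FALSE)
  if (quantile <= 0 || quantile > 1) stop("`quantile` must be in (0, 1]", call. = FALSE)
  if (!any(s$valid)) stop("no valid bead", call. = FALSE)
  ctr <- colMeans(s$coords[s$valid, , drop = FALSE])
  coords <- sweep(s$coords, 2L, ctr)
  radii <- sqrt(rowSums(coords[s$valid, , drop = FALSE]^2))
  qr <- as.numeric(stats::quantile(radii, quantile, names = FALSE))
  if (qr == 0) stop("all beads coincident: cannot rescale", call. = FALSE)
  coords <- coords * (diameter / 2) / qr
  structure3d(coords, valid = s$valid, chrom = s$chrom,
              bin_index = s$bin_index)
}

#' Coarsen a structure to a lower resolution
#'
#' Averages the coordinates of each run of `factor` consecutive beads within
#' a chromosome (groups anchored at the chromosome start; a trailing partial
#' group averages its available beads). Invalid beads are skipped; a group
#' with no valid bead yields an invalid output bead.
#'
#' @param s A [structure3d()].
#' @param factor Positive integer coarsening factor.
#' @return A [structure3d()] with about `n / factor` beads.
#' @export
coarsen_structure <- function(s, factor) {
  stopifnot(inherits(s, "structure3d"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer", call. = FALSE)
  if (factor == 1L) return(s)
  out <- list()
  for (ch in unique(s$chrom)) {
    ix <- which(s$chrom == ch)
    grp <- (seq_along(ix) - 1L) %/% factor
    for (g in unique(grp)) {
      beads <- ix[grp == g]
      ok <- beads[s$valid[beads]]
      xyz <- if (length(ok)) colMeans(s$coords[ok, , drop = FALSE]) else rep(NA_real_, 3)
      out[[length(out) + 1L]] <- list(chrom = ch, bin = g, xyz = xyz,
                                      valid = length(ok) > 0L)
    }
  }
  coords <- do.call(rbind, lapply(out, `[[`, "xyz"))
  structure3d(coords,
              valid = vapply(out, `[[`, logical(1), "valid"),
              chrom = vapply(out, `[[`, character(1), "chrom"),
              bin_index = vapply(out, function(o) as.integer(o$bin), integer(1)))
}

#' Binomial downsampling of a contact matrix
#'
#' Thins each upper-triangle count with an independent binomial draw keeping
#' each read with probability `fraction`, then mirrors; emulates reduced
#' sequencing coverage. The expected total is `fraction` times the original.
#'
#' @param m A [contact_matrix()].
#' @param fraction Keep probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [contact_matrix()].
#' @export
downsample_counts <- function(m, fraction, seed = 0L) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("`fraction` must be in [0, 1]", call. = FALSE)
  }
  ut <- which(upper.tri(m$counts), arr.ind = TRUE)
  set.seed(as.integer(seed))
  thinned <- stats::rbinom(nrow(ut), size = as.integer(m$counts[ut]),
                           prob = fraction)
  mat <- matrix(0, m$n, m$n)
  mat[ut] <- thinned
  mat[ut[, c(2, 1)]] <- thinned
  contact_matrix(mat, chrom = m$chrom, bin_index = m$bin_index,
                 resolution = m$resolution)
}

#' Mask beads without contacts in either dataset
#'
#' Structures inferred from different datasets are only comparable on beads
#' that both datasets inform: beads with zero marginal count in either count
#' matrix are marked invalid in both returned structures.
#'
#' @param a,b [structure3d()] objects.
#' @param ma,mb Matching [contact_matrix()] objects.
#' @return A list with elements `a` and `b`.
#' @export
filter_common_beads <- function(a, b, ma, mb) {
  stopifnot(inherits(a, "structure3d"), inherits(b, "structure3d"),
            inherits(ma, "contact_matrix"), inherits(mb, "contact_matrix"))
  if (length(unique(c(a$n, b$n, ma$n, mb$n))) != 1L) {
    stop("structures and matrices must have matching dimensions", call. = FALSE)
  }
  drop <- marginal_counts(ma) == 0 | marginal_counts(mb) == 0
  keep_a <- a$valid & !drop
  keep_b <- b$valid & !drop
  if (!any(keep_a & keep_b)) stop("no surviving bead after filtering", call. = FALSE)
  list(
    a = structure3d(a$coords, valid = keep_a, chrom = a$chrom, bin_index = a$bin_index),
    b = structure3d(b$coords, valid = keep_b, chrom = b$chrom, bin_index = b$bin_index)
  )
}

#' Compare two structures with the replicate-stability protocol
#'
#' Applies the full comparison used for replicate experiments: optionally
#' mask beads with no contacts in either dataset, rescale both structures to
#' a common nucleus diameter, then report the scaled-superposition RMSD and
#' the distance Spearman correlation.
#'
#' @param a,b [structure3d()] objects.
#' @param ma,mb Optional [contact_matrix()] objects for bead filtering.
#' @param diameter,quantile Passed to [rescale_structure()].
#' @param allow_reflection Passed to [rmsd()].
#' @return A one-row tibble with `rmsd`, `spearman` and `n_common`.
#' @export
compare_structures <- function(a, b, ma = NULL, mb = NULL, diameter = 100,
                               quantile = 0.99, allow_reflection = TRUE) {
  if (!is.null(ma) && !is.null(mb)) {
    fb <- filter_common_beads(a, b, ma, mb)
    a <- fb$a; b <- fb$b
  }
  a <- rescale_structure(a, diameter, quantile)
  b <- rescale_structure(b, diameter, quantile)
  tibble::tibble(
    rmsd = rmsd(a, b, allow_reflection = allow_reflection, allow_scaling = TRUE),
    spearman = distance_spearman(a, b),
    n_common = sum(common_valid(a, b))
  )
}
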