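#' Per-locus bias vector
#'
#' @param b Numeric vector of multiplicative biases; `NA` for filtered loci.
#' @param filtered Logical vector, `TRUE` for loci excluded from balancing.
#' @return An object of class `bias_vector`.
#' @export
bias_vector <- function(b, filtered = NULL) {
  b <- as.numeric(b)
  if (is.null(filtered)) filtered <- is.na(b)
  filtered <- as.logical(filtered)
  if (length(filtered) != length(b)) {
    stop("`filtered` must match the length of `b`", call. = FALSE)
  }
  if (any(!filtered & (is.na(b) | b <= 0))) {
    stop("unfiltered biases must be positive", call. = FALSE)
  }
  b[filtered] <- NA_real_
  structure(list(b = b, filtered = filtered, n = length(b)),
            class = "bias_vector")
}

#' @export
print.bias_vector <- function(x, ...) {
  cat(sprintf("<bias_vector> %d loci (%d filtered)\n", x$n, sum(x$filtered)))
  invisible(x)
}

unit_bias <- function(n) bias_vector(rep(1, n))

#' ICE balancing of a contact matrix
#'
#' Iterative correction estimates one multiplicative bias per locus so that
#' the normalized matrix `c_ij / (b_i b_j)` has equal row sums on the
#' unfiltered loci. Loci with zero marginal count are always filtered;
#' optionally the sparsest `filter_fraction` of the remaining loci are
#' filtered as well (conventional for real Hi-C). Each sweep updates
#' `b_i <- b_i * S_i / mean(S)` where `S_i` is the current normalized row
#' sum, and stops when `max_i |S_i / mean(S) - 1| < tol`. Biases are rescaled
#' so their arithmetic mean over unfiltered loci is 1, which pins down the
#' scale degeneracy between the biases and overall coverage.
#'
#' @param m A [contact_matrix()].
#' @param max_iter Maximum number of balancing sweeps.
#' @param tol Relative row-sum spread at convergence.
#' @param filter_fraction Fraction (in `[0, 1)`) of the lowest-marginal
#'   nonzero loci to filter before balancing. Default 0.
#'
#' @return A list of class `ice_result` with elements `bias`
#'   ([bias_vector()]), `normalized` (matrix, `NA` where a locus is
#'   filtered), `converged`, and `iterations`.
#' @export
#' @examples
#' m <- simulate_counts(generate_structure(20, "helix"),
#'                      cfg = simulation_config(20, seed = 1))
#' ice <- ice_normalize(m)
#' summary(ice$bias$b)
ice_normalize <- function(m, max_iter = 300L, tol = 1e-5,
                          filter_fraction = 0) {
  stopifnot(inherits(m, "contact_matrix"))
  if (filter_fraction < 0 || filter_fraction >= 1) {
    stop("`filter_fraction` must be in [0, 1)", call. = FALSE)
  }
  marg <- marginal_counts(m)
  filtered <- marg == 0
  if (all(filtered)) stop("no informative loci", call. = FALSE)
  if (filter_fraction > 0) {
    nz <- which(!filtered)
    k <- floor(filter_fraction * length(nz))
    if (k > 0) {
      drop <- nz[order(marg[nz])][seq_len(k)]
      filtered[drop] <- TRUE
    }
    if (all(filtered)) stop("no informative loci", call. = FALSE)
  }
  keep <- which(!filtered)
  cm <- m$counts[keep, keep, drop = FALSE]
  b <- rep(1, length(keep))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    s <- rowSums(sweep(cm / b, 2L, b, "/"))
    rel <- s / mean(s)
    if (max(abs(rel - 1)) < tol) {
      converged <- TRUE
      break
    }
    b <- b * rel
  }
  if (!converged) {
    warning(sprintf("ICE did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  b <- b / mean(b)
  bias <- rep(NA_real_, m$n)
  bias[keep] <- b
  bv <- bias_vector(bias, filtered)
  list2 <- list(bias = bv, normalized = normalize_counts(m, bv),
                converged = converged, iterations = iter)
  class(list2) <- "ice_result"
  list2
}

#' @export
print.ice_result <- function(x, ...) {
  cat(sprintf("<ice_result> converged=%s after %d iterations, %d filtered loci\n",
              x$converged, x$iterations, sum(x$bias$filtered)))
  invisible(x)
}

#' Normalize raw counts by a bias vector
#'
#' Computes `c_ij / (b_i b_j)`; entries touching a filtered locus are `NA`.
#'
#' @param m A [contact_matrix()].
#' @param bias A [bias_vector()] of matching length.
#' @return A symmetric numeric matrix of normalized counts.
#' @export
normalize_counts <- function(m, bias) {
  stopifnot(inherits(m, "contact_matrix"), inherits(bias, "bias_vector"))
  if (bias$n != m$n) stop("bias length does not match matrix size", call. = FALSE)
  b <- bias$b
  if (any(!bias$filtered & b <= 0)) {
    stop("bias must be positive on unfiltered loci", call. = FALSE)
  }
  out <- m$counts / outer(b, b)
  out
}

#' Read / write a bias vector
#'
#' One `index<TAB>bias` line per locus, 0-based; filtered loci carry `NA`.
#'
#' @param path File path.
#' @return [read_bias()] returns a [bias_vector()].
#' @export
read_bias <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = c("integer", "character"))
  b <- rep(NA_real_, nrow(tab))
  b[tab[[1]] + 1L] <- suppressWarnings(as.numeric(tab[[2]]))
  bias_vector(b)
}

#' @rdname read_bias
#' @param bias A [bias_vector()].
#' @export
write_bias <- function(bias, path) {
  stopifnot(inherits(bias, "bias_vector"))
  val <- ifelse(is.na(bias$b), "NA", sprintf("%.15g", bias$b))
  writeLines(sprintf("%d\t%s", seq_len(bias$n) - 1L, val), path)
  invisible(path)
}
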