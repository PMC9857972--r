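#' Contact-count matrix
#'
#' Constructs a `contact_matrix`, the container for a square symmetric Hi-C
#' contact-count matrix with per-bin annotations. Entry `counts[i, j]` holds
#' the number of times loci `i` and `j` were observed in contact. The diagonal
#' (self-contacts) carries no distance information under a power-law decay and
#' is always zeroed on construction; a warning is emitted if nonzero diagonal
#' entries were present.
#'
#' @param counts Square numeric matrix of non-negative integral counts.
#' @param chrom Character vector of per-bin chromosome labels (default: one
#'   chromosome `"chr1"`).
#' @param bin_index Integer vector of 0-based bin indices within each
#'   chromosome (default: consecutive within chromosome).
#' @param resolution Positive integer, base pairs per bin (informational).
#'
#' @return An object of class `contact_matrix` with fields `counts`, `chrom`,
#'   `bin_index`, `resolution` and `n` (number of beads/bins).
#' @export
#' @examples
#' m <- contact_matrix(matrix(c(0, 4, 4, 0), 2, 2))
#' m$counts
contact_matrix <- function(counts, chrom = NULL, bin_index = NULL,
                           resolution = 1L) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("`counts` must be a square matrix", call. = FALSE)
  }
  n <- nrow(counts)
  if (any(!is.finite(counts))) {
    stop("`counts` contains non-finite values", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("contact counts must be non-negative", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("contact counts must be integral", call. = FALSE)
  }
  counts <- round(counts)
  asym <- abs(counts - t(counts)) > 0
  if (any(asym)) {
    bad <- which(asym, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "count matrix is not symmetric: entry (%d, %d) = %g but (%d, %d) = %g",
      bad[1] - 1L, bad[2] - 1L, counts[bad[1], bad[2]],
      bad[2] - 1L, bad[1] - 1L, counts[bad[2], bad[1]]
    ), call. = FALSE)
  }
  if (any(diag(counts) != 0)) {
    warning("nonzero diagonal entries found; zeroing self-contacts",
            call. = FALSE)
    diag(counts) <- 0
  }
  if (is.null(chrom)) chrom <- rep("chr1", n)
  chrom <- as.character(chrom)
  if (length(chrom) != n) stop("`chrom` must have one entry per bin", call. = FALSE)
  if (is.null(bin_index)) {
    bin_index <- unlist(lapply(unname(split(seq_len(n), factor(chrom, unique(chrom)))),
                               function(ix) seq_along(ix) - 1L),
                        use.names = FALSE)
  }
  bin_index <- as.integer(bin_index)
  if (length(bin_index) != n) stop("`bin_index` must have one entry per bin", call. = FALSE)
  resolution <- as.integer(resolution)
  if (length(resolution) != 1L || is.na(resolution) || resolution < 1L) {
    stop("`resolution` must be a positive integer", call. = FALSE)
  }
  dimnames(counts) <- NULL
  structure(
    list(n = n, counts = counts, chrom = chrom, bin_index = bin_index,
         resolution = resolution),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins, %d chromosome(s), resolution %d bp\n",
              x$n, length(unique(x$chrom)), x$resolution))
  cat(sprintf("  total counts: %s, nonzero upper-triangle pairs: %d\n",
              format(sum(x$counts) / 2), sum(x$counts[upper.tri(x$counts)] > 0)))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
#' @importFrom tibble as_tibble tibble
as_tibble.contact_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$counts) & x$counts > 0, arr.ind = TRUE)
  tibble::tibble(
    i = ut[, 1] - 1L, j = ut[, 2] - 1L,
    count = x$counts[ut],
    chrom_i = x$chrom[ut[, 1]], chrom_j = x$chrom[ut[, 2]]
  )
}

#' Per-bin marginal (total) counts
#'
#' @param m A [contact_matrix()].
#' @return Numeric vector of row sums of the count matrix.
#' @export
marginal_counts <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  rowSums(m$counts)
}

#' 3D bead structure
#'
#' Constructs a `structure3d`: 3D coordinates for `n` beads with a validity
#' mask. Invalid beads (e.g. unmappable bins or bins with no contacts) carry
#' `NA` coordinates and are excluded from every distance computation.
#'
#' @param coords Numeric matrix with one row per bead and columns x, y, z.
#' @param valid Logical vector; `FALSE` marks beads without coordinates.
#'   Defaults to rows with all-finite coordinates.
#' @param chrom,bin_index Per-bead annotations as in [contact_matrix()].
#'
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(coords, valid = NULL, chrom = NULL, bin_index = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("`coords` must have 3 columns (x, y, z)", call. = FALSE)
  n <- nrow(coords)
  if (is.null(valid)) valid <- apply(is.finite(coords), 1L, all)
  valid <- as.logical(valid)
  if (length(valid) != n) stop("`valid` must have one entry per bead", call. = FALSE)
  if (any(!apply(is.finite(coords[valid, , drop = FALSE]), 1L, all))) {
    stop("valid beads must have finite coordinates", call. = FALSE)
  }
  coords[!valid, ] <- NA_real_
  if (is.null(chrom)) chrom <- rep("chr1", n)
  chrom <- as.character(chrom)
  if (is.null(bin_index)) {
    bin_index <- unlist(lapply(unname(split(seq_len(n), factor(chrom, unique(chrom)))),
                               function(ix) seq_along(ix) - 1L),
                        use.names = FALSE)
  }
  bin_index <- as.integer(bin_index)
  if (length(chrom) != n || length(bin_index) != n) {
    stop("annotations must have one entry per bead", call. = FALSE)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(n = n, coords = coords, valid = valid, chrom = chrom,
         bin_index = bin_index),
    class = "structure3d"
  )
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d beads (%d valid), %d chromosome(s)\n",
              x$n, sum(x$valid), length(unique(x$chrom))))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.structure3d <- function(x, ...) {
  s <- x
  tibble::tibble(
    chrom = s$chrom, bin = s$bin_index,
    x = s$coords[, 1], y = s$coords[, 2], z = s$coords[, 3],
    valid = s$valid
  )
}

#' Pairwise Euclidean distances between beads
#'
#' @param s A [structure3d()].
#' @return An `n`-by-`n` symmetric matrix of distances; `NA` for pairs
#'   involving an invalid bead.
#' @export
pairwise_distances <- function(s) {
  stopifnot(inherits(s, "structure3d"))
  d <- as.matrix(stats::dist(s$coords))
  dimnames(d) <- NULL
  d
}

parse_count_token <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    stop(sprintf("non-numeric %s in '%s'", what, path), call. = FALSE)
  }
  v
}

#' Read a contact-count matrix from text
#'
#' Two plain-text layouts are supported: `dense`, a whitespace-delimited
#' n-by-n matrix, and `coo`, a triplet file with one `i j count` line per bin
#' pair (0-based global bin indices, tab or space separated, `#` comments).
#' In `coo` files pairs may be given for `i <= j` only and are mirrored;
#' if both orientations are present their values must agree. A `# n=<n>`
#' comment (as written by [write_counts()]) fixes the matrix dimension;
#' otherwise it is inferred from the largest index.
#'
#' @param path File to read.
#' @param format `"dense"` or `"coo"`.
#' @param n Number of bins (optional for `coo`; ignored for `dense`).
#' @param chrom,bin_index,resolution Optional per-bin annotations passed to
#'   [contact_matrix()]; a single chromosome is assumed when absent.
#'
#' @return A [contact_matrix()].
#' @export
read_counts <- function(path, format = c("dense", "coo"), n = NULL,
                        chrom = NULL, bin_index = NULL, resolution = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (format == "dense") {
    mat <- as.matrix(utils::read.table(path, header = FALSE,
                                       colClasses = "numeric"))
    dimnames(mat) <- NULL
  } else {
    lines <- readLines(path)
    meta <- grep("^#\\s*n\\s*=", lines, value = TRUE)
    if (is.null(n) && length(meta)) {
      n <- as.integer(sub("^#\\s*n\\s*=\\s*", "", meta[1]))
    }
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines)) {
      parts <- strsplit(lines, "[ \t]+")
      bad <- which(lengths(parts) != 3L)
      if (length(bad)) {
        stop(sprintf("malformed triplet line %d in '%s'", bad[1], path),
             call. = FALSE)
      }
      tri <- matrix(parse_count_token(unlist(parts), "triplet entry", path),
                    ncol = 3L, byrow = TRUE)
    } else {
      tri <- matrix(numeric(0), ncol = 3L)
    }
    if (is.null(n)) {
      if (!nrow(tri)) stop("empty COO file and no `n` given", call. = FALSE)
      n <- as.integer(max(tri[, 1:2]) + 1)
    }
    if (nrow(tri) && any(tri[, 1:2] < 0 | tri[, 1:2] > n - 1)) {
      stop(sprintf("bin index out of range [0, %d] in '%s'", n - 1, path),
           call. = FALSE)
    }
    if (nrow(tri) && any(abs(tri[, 1:2] - round(tri[, 1:2])) > 0)) {
      stop("bin indices must be integers", call. = FALSE)
    }
    mat <- matrix(0, n, n)
    for (k in seq_len(nrow(tri))) {
      i <- tri[k, 1] + 1L; j <- tri[k, 2] + 1L; v <- tri[k, 3]
      if (mat[i, j] != 0 && mat[i, j] != v) {
        stop(sprintf(
          "conflicting duplicate entries for pair (%d, %d): %g vs %g",
          i - 1L, j - 1L, mat[i, j], v), call. = FALSE)
      }
      mat[i, j] <- v
      mat[j, i] <- v
    }
  }
  contact_matrix(mat, chrom = chrom, bin_index = bin_index,
                 resolution = resolution)
}

#' Write a contact-count matrix to text
#'
#' The `coo` format writes a `# n=<n>` header so the dimension survives a
#' round trip, then one `i j count` line per nonzero upper-triangle pair
#' (`i < j`, 0-based).
#'
#' @param m A [contact_matrix()].
#' @param path File to write.
#' @param format `"dense"` or `"coo"`.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(m, path, format = c("dense", "coo")) {
  stopifnot(inherits(m, "contact_matrix"))
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(m$counts, path, row.names = FALSE, col.names = FALSE)
  } else {
    ut <- which(upper.tri(m$counts) & m$counts > 0, arr.ind = TRUE)
    lines <- c(
      sprintf("# n=%d", m$n),
      sprintf("%d\t%d\t%d", ut[, 1] - 1L, ut[, 2] - 1L,
              as.integer(m$counts[ut]))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a 3D structure from text
#'
#' One bead per line: `chrom bin x y z`, whitespace separated; missing beads
#' carry the literal token `NA` in the coordinate columns.
#'
#' @param path File to read.
#' @return A [structure3d()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- trimws(readLines(path))
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  parts <- strsplit(lines[keep], "[ \t]+")
  bad <- which(lengths(parts) != 5L)
  if (length(bad)) {
    stop(sprintf("malformed structure line %d in '%s': expected 5 fields",
                 keep[bad[1]], path), call. = FALSE)
  }
  fields <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  xyz <- fields[, 3:5, drop = FALSE]
  is_na <- xyz == "NA"
  coords <- suppressWarnings(matrix(as.numeric(xyz), ncol = 3L))
  badnum <- which(is.na(coords) & !is_na, arr.ind = TRUE)
  if (nrow(badnum <- as.matrix(badnum))) {
    stop(sprintf("malformed coordinate on line %d in '%s'",
                 keep[badnum[1, 1]], path), call. = FALSE)
  }
  valid <- rowSums(is_na) == 0
  if (any(rowSums(is_na) %in% c(1L, 2L))) {
    stop("beads must have either all three coordinates or all NA", call. = FALSE)
  }
  structure3d(coords, valid = valid, chrom = fields[, 1],
              bin_index = as.integer(fields[, 2]))
}

#' Write a 3D structure to text
#'
#' @param s A [structure3d()].
#' @param path File to write.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure3d"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.15g", v))
  lines <- sprintf("%s\t%d\t%s\t%s\t%s", s$chrom, s$bin_index,
                   fmt(s$coords[, 1]), fmt(s$coords[, 2]), fmt(s$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}
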