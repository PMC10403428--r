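#' Intra-chromosomal contact map
#'
#' The basic container of the package: a dense symmetric non-negative
#' matrix of interaction frequencies for one chromosome at a fixed bin
#' resolution. Entry `matrix[i, j]` counts read pairs linking genomic
#' bins `i` and `j` (0-based bins over half-open genomic intervals, as
#' in the cooler convention). Raw maps hold integer counts
#' (`is_normalized = FALSE`); after [apply_scale()] entries lie in
#' \[0, 1\] and `is_normalized` is `TRUE`.
#'
#' @param matrix numeric `n_bins x n_bins` symmetric non-negative matrix.
#' @param chrom chromosome identifier string.
#' @param resolution_bp bin width in base pairs (positive integer).
#' @param is_normalized logical; `TRUE` when entries are \[0, 1\]-scaled.
#'
#' @return An object of class `ContactMap`: a list with fields `chrom`,
#'   `resolution_bp`, `n_bins`, `matrix`, `is_normalized`.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 2] <- m[2, 1] <- 5
#' cm <- contact_map(m, chrom = "chrS", resolution_bp = 40000L)
#' cm$n_bins
#' @export
contact_map <- function(matrix, chrom = "chr1", resolution_bp = 40000L,
                        is_normalized = FALSE) {
  obj <- structure(
    list(chrom = as.character(chrom),
         resolution_bp = as.integer(resolution_bp),
         n_bins = nrow(matrix),
         matrix = matrix,
         is_normalized = isTRUE(is_normalized)),
    class = "ContactMap")
  validate_contact_map(obj)
  obj
}

#' Validate a ContactMap
#'
#' Checks the class invariants: square matrix matching `n_bins`,
#' symmetry within relative tolerance 1e-9, and non-negative entries.
#'
#' @param x object to validate.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_contact_map <- function(x) {
  if (!inherits(x, "ContactMap")) stop("not a ContactMap")
  m <- x$matrix
  if (!is.matrix(m) || !is.numeric(m)) stop("ContactMap$matrix must be a numeric matrix")
  if (nrow(m) != ncol(m)) stop("ContactMap$matrix must be square")
  if (nrow(m) != x$n_bins) stop("matrix dimension does not equal n_bins")
  if (x$resolution_bp <= 0L) stop("resolution_bp must be positive")
  if (any(m < 0)) stop("ContactMap entries must be non-negative")
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) > 1e-9 * scale) stop("ContactMap matrix is not symmetric")
  invisible(x)
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap: %s, %d bins @ %d bp, %s, total (upper tri) %.6g\n",
              x$chrom, x$n_bins, x$resolution_bp,
              if (x$is_normalized) "normalized [0,1]" else "raw counts",
              sum(x$matrix[upper.tri(x$matrix, diag = TRUE)])))
  invisible(x)
}

# Mirror the upper triangle (including diagonal) onto the lower one.
mirror_upper <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Sum over the upper triangle including the diagonal.
upper_tri_sum <- function(m) sum(m[upper.tri(m, diag = TRUE)])
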