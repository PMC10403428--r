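#' Randomly down-sample a raw contact map
#'
#' Simulates sequencing a fraction `ratio` of the original library:
#' each upper-triangle count `c` is replaced by a
#' `Binomial(c, ratio)` draw (equivalent to keeping every read pair
#' independently with probability `ratio`), then mirrored. `ratio = 1`
#' returns the input unchanged.
#'
#' @param map a raw-count [contact_map()] (`is_normalized = FALSE`).
#' @param ratio retention probability in `(0, 1]`.
#' @param seed integer RNG seed; fixed seeds give identical output.
#' @return A raw-count `ContactMap` with `sum(lr) <= sum(hr)`.
#' @examples
#' m <- contact_map(matrix(10, 3, 3))
#' lr <- downsample(m, 0.5, seed = 1)
#' @export
downsample <- function(map, ratio, seed = 1L) {
  validate_contact_map(map)
  if (map$is_normalized) stop("downsample expects raw counts, not a normalized map")
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1)
    stop("ratio must lie in (0, 1]")
  if (ratio == 1) return(map)
  n <- map$n_bins
  ut <- upper.tri(map$matrix, diag = TRUE)
  counts <- map$matrix[ut]
  if (any(counts != round(counts))) stop("downsample expects integer counts")
  thinned <- withr_seed(seed, stats::rbinom(length(counts), size = counts, prob = ratio))
  m <- matrix(0, n, n)
  m[ut] <- thinned
  m <- mirror_upper(m)
  contact_map(m, chrom = map$chrom, resolution_bp = map$resolution_bp)
}

#' Fit the clip-and-scale normalization record
#'
#' The networks consume values in \[0, 1\]; raw counts are clipped at a
#' high percentile of the non-zero entries and divided by that cap. This
#' fits the cap: the `cap_percentile`-th percentile (R's default
#' interpolation rule, `quantile(type = 7)`) of non-zero entries, never
#' below 1. An all-zero map falls back to cap 1 with a warning.
#'
#' @param map a raw-count [contact_map()], or a list of them (the cap is
#'   then fitted on the pooled non-zero entries, giving a shared scale
#'   for a training set).
#' @param cap_percentile percentile in (0, 100\]; default 99.9.
#' @return An object of class `ScaleRecord`: list with `cap` and `method`.
#' @seealso [apply_scale()], [invert_scale()]
#' @export
fit_scale <- function(map, cap_percentile = 99.9) {
  maps <- if (inherits(map, "ContactMap")) list(map) else map
  vals <- unlist(lapply(maps, function(cm) {
    validate_contact_map(cm)
    if (cm$is_normalized) stop("fit_scale expects raw-count maps")
    v <- cm$matrix[upper.tri(cm$matrix, diag = TRUE)]
    v[v > 0]
  }))
  if (length(vals) == 0L) {
    warning("all-zero map(s); normalization cap defaults to 1")
    cap <- 1
  } else {
    cap <- max(1, unname(stats::quantile(vals, cap_percentile / 100, type = 7)))
  }
  structure(list(cap = cap, method = "clip_percentile",
                 cap_percentile = cap_percentile),
            class = "ScaleRecord")
}

#' Normalize a raw map to network range
#'
#' Clips entries at `scale$cap` and divides by the cap, giving values in
#' \[0, 1\] with `is_normalized = TRUE`. Applying it to an already
#' normalized map is an error.
#'
#' @param map a raw-count [contact_map()].
#' @param scale a `ScaleRecord` from [fit_scale()].
#' @return A normalized `ContactMap`.
#' @export
apply_scale <- function(map, scale) {
  validate_contact_map(map)
  if (map$is_normalized) stop("map is already normalized (double application)")
  if (!inherits(scale, "ScaleRecord")) stop("scale must be a ScaleRecord")
  m <- pmin(map$matrix, scale$cap) / scale$cap
  out <- contact_map(m, chrom = map$chrom, resolution_bp = map$resolution_bp,
                     is_normalized = TRUE)
  out
}

#' Undo the clip-and-scale normalization
#'
#' Multiplies by the cap and clamps negative entries (which network
#' output may contain) to zero. Exactly inverts [apply_scale()] for
#' entries at or below the cap.
#'
#' @param map a normalized `ContactMap` (small negative entries
#'   tolerated).
#' @param scale the `ScaleRecord` used for normalization.
#' @return A raw-scale `ContactMap` (`is_normalized = FALSE`).
#' @export
invert_scale <- function(map, scale) {
  if (!inherits(map, "ContactMap")) stop("not a ContactMap")
  if (!map$is_normalized) stop("map is not normalized (double inversion)")
  if (!inherits(scale, "ScaleRecord")) stop("scale must be a ScaleRecord")
  m <- pmax(map$matrix * scale$cap, 0)
  contact_map(m, chrom = map$chrom, resolution_bp = map$resolution_bp,
              is_normalized = FALSE)
}

#' Crop a contact map into square patches
#'
#' Tiles the matrix with `patch_size x patch_size` sub-matrices anchored
#' at multiples of `stride` (row-major order), zero-padding tiles that
#' extend past the matrix edge. With `band_bins` set, only tiles whose
#' anchors satisfy `|row0 - col0| <= band_bins` are kept (a diagonal
#' band).
#'
#' @param map a normalized [contact_map()].
#' @param patch_size tile side length in bins (default 40).
#' @param stride anchor spacing in bins (default `patch_size`,
#'   non-overlapping).
#' @param band_bins optional diagonal band half-width in bins.
#' @return An object of class `PatchSet`: list with `patch_size`,
#'   `stride`, `source_n_bins`, `anchors` (0-based `row0`, `col0`),
#'   `tiles` (array `patch_size x patch_size x n_tiles`), and map
#'   metadata.
#' @seealso [assemble_patches()]
#' @export
crop_patches <- function(map, patch_size = 40L, stride = patch_size,
                         band_bins = NULL) {
  if (!inherits(map, "ContactMap")) stop("not a ContactMap")
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (patch_size <= 0L) stop("patch_size must be positive")
  if (stride <= 0L) stop("stride must be positive")
  n <- map$n_bins
  last <- stride * max(0L, as.integer(ceiling(max(0L, n - patch_size) / stride)))
  anchors0 <- seq(0L, last, by = stride)
  grid <- expand.grid(col0 = anchors0, row0 = anchors0)[, c("row0", "col0")]
  grid <- grid[order(grid$row0, grid$col0), , drop = FALSE]  # row-major
  if (!is.null(band_bins))
    grid <- grid[abs(grid$row0 - grid$col0) <= band_bins, , drop = FALSE]
  nt <- nrow(grid)
  tiles <- array(0, c(patch_size, patch_size, nt))
  for (k in seq_len(nt)) {
    r0 <- grid$row0[k]; c0 <- grid$col0[k]
    rr <- (r0 + 1L):min(r0 + patch_size, n)
    cc <- (c0 + 1L):min(c0 + patch_size, n)
    tiles[seq_along(rr), seq_along(cc), k] <- map$matrix[rr, cc]
  }
  structure(list(patch_size = patch_size, stride = stride,
                 source_n_bins = n,
                 anchors = data.frame(row0 = grid$row0, col0 = grid$col0),
                 tiles = tiles,
                 chrom = map$chrom, resolution_bp = map$resolution_bp,
                 is_normalized = map$is_normalized),
            class = "PatchSet")
}

#' Reassemble a full contact map from patches
#'
#' Inverse of [crop_patches()]: tiles are placed back at their anchors,
#' overlapping contributions are averaged per cell, edge padding is
#' trimmed to `source_n_bins`, and the result is symmetrized by
#' averaging with its transpose. At `stride == patch_size` the
#' crop/assemble round trip is the exact identity for symmetric input.
#'
#' @param patches a `PatchSet` whose tiles (possibly network output)
#'   cover the source matrix.
#' @return A `ContactMap` with the patch set's metadata. Tiny negative
#'   values produced by a network are preserved here; [invert_scale()]
#'   clamps them.
#' @export
assemble_patches <- function(patches) {
  if (!inherits(patches, "PatchSet")) stop("not a PatchSet")
  n <- patches$source_n_bins
  ps <- patches$patch_size
  full <- n + ps  # generous canvas; trimmed below
  acc <- matrix(0, full, full)
  cnt <- matrix(0, full, full)
  for (k in seq_len(nrow(patches$anchors))) {
    r0 <- patches$anchors$row0[k]; c0 <- patches$anchors$col0[k]
    rr <- (r0 + 1L):(r0 + ps); cc <- (c0 + 1L):(c0 + ps)
    acc[rr, cc] <- acc[rr, cc] + patches$tiles[, , k]
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  acc <- acc[1:n, 1:n, drop = FALSE]
  cnt <- cnt[1:n, 1:n, drop = FALSE]
  if (any(cnt == 0)) {
    bad <- which(cnt == 0, arr.ind = TRUE)[1L, ]
    stop("patch set does not cover the matrix; first uncovered cell (0-based): (",
         bad[1L] - 1L, ", ", bad[2L] - 1L, ")")
  }
  m <- acc / cnt
  m <- (m + t(m)) / 2
  structure(list(chrom = patches$chrom, resolution_bp = patches$resolution_bp,
                 n_bins = n, matrix = m,
                 is_normalized = patches$is_normalized),
            class = "ContactMap")
}
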