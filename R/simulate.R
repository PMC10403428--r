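#' Configuration of the synthetic single-cell Hi-C generator
#'
#' Describes an idealised intra-chromosomal contact propensity surface:
#' power-law distance decay, block-enriched TADs delimited by
#' `tad_boundaries`, and point loops with a one-bin halo. Reads are then
#' drawn from this surface by multinomial sampling ([sample_reads()]),
#' which reproduces the integer counts and extreme sparsity of
#' single-cell Hi-C maps.
#'
#' Defaults model roughly 8 Mb of chromosome at 40 kb resolution at
#' single-cell coverage: 200 bins, decay exponent 1, and 2e5 read pairs.
#'
#' @param n_bins number of bins (positive integer).
#' @param decay_exponent positive real; contact propensity decays as
#'   `(|i - j| + 1)^-decay_exponent`.
#' @param tad_boundaries strictly increasing integer vector of 0-based
#'   boundary bins in `(0, n_bins)`; they partition `[0, n_bins)` into
#'   TAD blocks.
#' @param tad_enrichment multiplier `>= 1` applied within TAD blocks.
#' @param loops list of `c(bin_i, bin_j, strength)` triples with
#'   `0 <= bin_i < bin_j < n_bins` and `strength >= 1`.
#' @param read_depth total read pairs to sample (non-negative integer).
#' @param seed integer RNG seed used by [sample_reads()].
#' @param include_diagonal keep the main diagonal in the sampling
#'   support (self-ligation counts); set `FALSE` to exclude it.
#'
#' @return An object of class `SyntheticConfig`.
#' @examples
#' cfg <- synthetic_config(n_bins = 40, tad_boundaries = 20,
#'                         tad_enrichment = 3)
#' @export
synthetic_config <- function(n_bins = 200L, decay_exponent = 1.0,
                             tad_boundaries = integer(0), tad_enrichment = 3,
                             loops = list(), read_depth = 2e5L, seed = 1L,
                             include_diagonal = TRUE) {
  n_bins <- as.integer(n_bins)
  tad_boundaries <- as.integer(tad_boundaries)
  if (n_bins < 1L) stop("n_bins must be a positive integer")
  if (decay_exponent <= 0) stop("decay_exponent must be positive")
  if (length(tad_boundaries)) {
    if (any(diff(tad_boundaries) <= 0L))
      stop("tad_boundaries must be strictly increasing")
    if (any(tad_boundaries <= 0L | tad_boundaries >= n_bins))
      stop("tad_boundaries must lie strictly inside (0, n_bins)")
  }
  if (tad_enrichment < 1) stop("tad_enrichment must be >= 1")
  for (lp in loops) {
    if (length(lp) != 3L) stop("loops entries must be (bin_i, bin_j, strength)")
    if (!(lp[1] >= 0 && lp[1] < lp[2] && lp[2] < n_bins))
      stop("loops must satisfy 0 <= bin_i < bin_j < n_bins")
    if (lp[3] < 1) stop("loops strength must be >= 1")
  }
  if (read_depth < 0) stop("read_depth must be non-negative")
  structure(list(n_bins = n_bins, decay_exponent = decay_exponent,
                 tad_boundaries = tad_boundaries,
                 tad_enrichment = tad_enrichment, loops = loops,
                 read_depth = as.numeric(read_depth), seed = as.integer(seed),
                 include_diagonal = isTRUE(include_diagonal)),
            class = "SyntheticConfig")
}

#' Expected contact propensity surface for a synthetic configuration
#'
#' Deterministically builds the symmetric, strictly positive intensity
#' matrix implied by a [synthetic_config()]: a power-law decay baseline
#' `(|i - j| + 1)^-d`, multiplied by `tad_enrichment` where both bins
#' fall in the same TAD block, multiplied by the loop strength at loop
#' anchors (the enhancement over baseline halves at Chebyshev distance
#' one from the anchor). The result is normalised so the upper triangle
#' (diagonal included) sums to one. No random numbers are used.
#'
#' @param config a `SyntheticConfig`.
#' @return An object of class `IntensityMap`: list with `n_bins` and the
#'   `intensity` matrix.
#' @examples
#' im <- simulate_intensity(synthetic_config(n_bins = 20))
#' sum(im$intensity[upper.tri(im$intensity, diag = TRUE)])
#' @export
simulate_intensity <- function(config) {
  if (!inherits(config, "SyntheticConfig")) stop("config must be a SyntheticConfig")
  n <- config$n_bins
  idx <- seq_len(n) - 1L
  dist <- abs(outer(idx, idx, "-"))
  intensity <- (dist + 1)^(-config$decay_exponent)

  # TAD blocks: bins between consecutive boundaries share a block.
  if (config$tad_enrichment > 1) {
    block <- findInterval(idx, config$tad_boundaries)
    same <- outer(block, block, "==")
    intensity[same] <- intensity[same] * config$tad_enrichment
  }

  # Loops: strength at the anchor, excess halved at the 1-bin halo.
  for (lp in config$loops) {
    i0 <- as.integer(lp[1]); j0 <- as.integer(lp[2]); s <- lp[3]
    for (di in -1:1) for (dj in -1:1) {
      i <- i0 + di; j <- j0 + dj
      if (i < 0 || i >= n || j < 0 || j >= n) next
      cheb <- max(abs(di), abs(dj))
      mult <- 1 + (s - 1) / 2^cheb
      intensity[i + 1L, j + 1L] <- intensity[i + 1L, j + 1L] * mult
      intensity[j + 1L, i + 1L] <- intensity[i + 1L, j + 1L]
    }
  }

  if (!config$include_diagonal) diag(intensity) <- 0
  intensity <- (intensity + t(intensity)) / 2
  ut <- upper_tri_sum(intensity)
  intensity <- intensity / ut
  structure(list(n_bins = n, intensity = intensity), class = "IntensityMap")
}

#' Draw an integer single-cell contact map from an intensity surface
#'
#' Assigns `read_depth` read pairs to upper-triangle cells (diagonal
#' included) by multinomial sampling with probabilities proportional to
#' the intensity, then mirrors counts to the lower triangle (the
#' diagonal is not doubled). The upper-triangle sum of the result equals
#' `read_depth` exactly.
#'
#' @param intensity an `IntensityMap` from [simulate_intensity()].
#' @param read_depth non-negative integer number of read pairs.
#' @param seed integer RNG seed; fixed seeds give identical maps.
#' @param chrom,resolution_bp metadata for the returned [contact_map()].
#' @return A raw-count `ContactMap`.
#' @examples
#' im <- simulate_intensity(synthetic_config(n_bins = 20))
#' cm <- sample_reads(im, 1000, seed = 7)
#' sum(cm$matrix[upper.tri(cm$matrix, diag = TRUE)])
#' @export
sample_reads <- function(intensity, read_depth, seed,
                         chrom = "chrS", resolution_bp = 40000L) {
  if (!inherits(intensity, "IntensityMap")) stop("intensity must be an IntensityMap")
  if (read_depth < 0) stop("read_depth must be non-negative")
  n <- intensity$n_bins
  ut <- upper.tri(intensity$intensity, diag = TRUE)
  p <- intensity$intensity[ut]
  m <- matrix(0, n, n)
  if (read_depth > 0) {
    counts <- withr_seed(seed, stats::rmultinom(1L, size = read_depth, prob = p))
    m[ut] <- counts
    m <- mirror_upper(m)
  }
  contact_map(m, chrom = chrom, resolution_bp = resolution_bp)
}

#' Generate a matched high/low-resolution training pair
#'
#' Samples the high-coverage ("HR") map from the configured intensity
#' surface, then binomially thins it to the requested ratio to produce
#' the low-coverage ("LR") companion, mimicking random read
#' down-sampling of a sequencing library.
#'
#' @param config a `SyntheticConfig`.
#' @param ratio retention ratio in `(0, 1]` passed to [downsample()].
#' @param chrom,resolution_bp metadata for both maps.
#' @return `list(hr = ContactMap, lr = ContactMap)`.
#' @examples
#' pr <- make_pair(synthetic_config(n_bins = 30, read_depth = 5000), 0.1)
#' sum(pr$lr$matrix) <= sum(pr$hr$matrix)
#' @export
make_pair <- function(config, ratio, chrom = "chrS", resolution_bp = 40000L) {
  hr <- sample_reads(simulate_intensity(config), config$read_depth,
                     seed = config$seed, chrom = chrom,
                     resolution_bp = resolution_bp)
  lr <- downsample(hr, ratio, seed = config$seed + 1L)
  list(hr = hr, lr = lr)
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's
# RNG stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
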