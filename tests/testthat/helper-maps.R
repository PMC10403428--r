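# Shared fixture builders: everything is generated in code at test time.

# Random symmetric integer contact map (counts up to `max_count`).
random_count_map <- function(n, seed, max_count = 20L, chrom = "chrT") {
  set.seed(seed)
  m <- matrix(0L, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- rpois(sum(ut), lambda = max_count / 4)
  m <- m + t(m) - diag(diag(m))
  contact_map(m, chrom = chrom, resolution_bp = 40000L)
}

# Random normalized map with entries in [0, 1].
random_norm_map <- function(n, seed, chrom = "chrT") {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- runif(sum(ut))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_map(m, chrom = chrom, resolution_bp = 40000L, is_normalized = TRUE)
}

# Tiny network configs used across tests (fast on one CPU).
tiny_gcfg <- function(...) generator_config(feature_channels = 4L,
                                            n_res_blocks = 2L, ...)
tiny_dcfg <- function(...) discriminator_config(stem_channels = 4L, ...)

# Small random patch batch [H, W, C, N].
random_batch <- function(h, n, seed, c = 1L) {
  set.seed(seed)
  array(runif(h * h * c * n), c(h, h, c, n))
}

# Absolute-or-relative closeness for gradient checks.
expect_close <- function(actual, expected, tol = 1e-5) {
  expect_lt(abs(actual - expected), tol * max(1, abs(expected)))
}
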