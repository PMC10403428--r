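test_that("downsample thins counts binomially and respects its contracts", {
  cm <- random_count_map(30, seed = 1)
  expect_identical(downsample(cm, 1.0, seed = 1), cm)       # ratio 1 identity
  zero <- contact_map(matrix(0, 10, 10))
  expect_true(all(downsample(zero, 0.3, seed = 1)$matrix == 0))

  lr <- downsample(cm, 0.4, seed = 2)
  expect_identical(lr$matrix, downsample(cm, 0.4, seed = 2)$matrix)
  expect_identical(lr$matrix, t(lr$matrix))
  expect_true(all(lr$matrix == round(lr$matrix)))
  expect_lte(sum(lr$matrix), sum(cm$matrix))                # mass-decreasing

  # single-cell binomial oracle: count 1e6 at ratio 0.45
  big <- contact_map(matrix(1e6, 1, 1))
  out <- downsample(big, 0.45, seed = 3)$matrix[1, 1]
  expect_lt(abs(out - 450000), 5 * sqrt(1e6 * 0.45 * 0.55))

  norm <- random_norm_map(10, seed = 4)
  expect_error(downsample(norm, 0.5, 1), "raw")
  expect_error(downsample(cm, 0, 1), "ratio")
  expect_error(downsample(cm, 1.2, 1), "ratio")
})

test_that("fit_scale uses the documented percentile rule", {
  n <- 45L  # 45*46/2 = 1035 upper-tri cells >= 1000 values
  set.seed(20)
  m <- matrix(0, n, n)
  ut_idx <- which(upper.tri(m, diag = TRUE))
  m[sample(ut_idx, 1000)] <- sample(1:1000)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  cm <- contact_map(m)
  sc <- fit_scale(cm, 99.9)
  # sort-based oracle: type-7 interpolated 99.9th percentile of 1..1000
  v <- sort(cm$matrix[upper.tri(cm$matrix, diag = TRUE)])
  v <- v[v > 0]
  h <- (length(v) - 1) * 0.999 + 1
  oracle <- v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
  expect_equal(sc$cap, oracle)
  expect_equal(oracle, 999.001)

  flat <- contact_map(matrix(5, 8, 8))
  expect_equal(fit_scale(flat)$cap, 5)
  expect_warning(sc0 <- fit_scale(contact_map(matrix(0, 5, 5))), "all-zero")
  expect_equal(sc0$cap, 1)
})

test_that("apply_scale clips and invert_scale clamps and round-trips", {
  m <- matrix(c(0, 250, 250, 50), 2, 2)
  cm <- contact_map(m)
  sc <- structure(list(cap = 100, method = "clip_percentile"),
                  class = "ScaleRecord")
  nm <- apply_scale(cm, sc)
  expect_true(nm$is_normalized)
  expect_equal(nm$matrix[1, 2], 1.0)           # 250 clipped at cap
  expect_equal(nm$matrix[2, 2], 0.5)
  expect_error(apply_scale(nm, sc), "normalized")

  # round trip below cap
  cm2 <- random_count_map(20, seed = 5)
  sc2 <- fit_scale(cm2, 100)                    # cap = max, nothing clipped
  rt <- invert_scale(apply_scale(cm2, sc2), sc2)
  expect_equal(rt$matrix, cm2$matrix)
  expect_false(rt$is_normalized)
  expect_error(invert_scale(rt, sc2), "not normalized")

  # network output below zero clamps to 0
  neg <- structure(list(chrom = "c", resolution_bp = 40000L, n_bins = 2L,
                        matrix = matrix(c(-0.02, 0.1, 0.1, 0.3), 2, 2),
                        is_normalized = TRUE), class = "ContactMap")
  expect_equal(invert_scale(neg, sc)$matrix[1, 1], 0)
})

test_that("crop_patches tiles, pads, and honours the diagonal band", {
  nm <- random_norm_map(80, seed = 6)
  ps <- crop_patches(nm, 40, 40)
  expect_equal(nrow(ps$anchors), 4L)
  expect_equal(ps$anchors$row0, c(0L, 0L, 40L, 40L))
  expect_equal(ps$anchors$col0, c(0L, 40L, 0L, 40L))
  expect_equal(ps$tiles[, , 1], nm$matrix[1:40, 1:40])
  expect_true(all(ps$tiles >= 0 & ps$tiles <= 1))

  nm50 <- random_norm_map(50, seed = 7)
  ps50 <- crop_patches(nm50, 40, 40)
  t4 <- ps50$tiles[, , 4]                       # anchored at (40, 40)
  expect_true(all(t4[11:40, ] == 0))            # rows beyond bin 50 padded
  expect_true(all(t4[, 11:40] == 0))
  expect_equal(t4[1:10, 1:10], nm50$matrix[41:50, 41:50])

  nm120 <- random_norm_map(120, seed = 8)
  band <- crop_patches(nm120, 40, 40, band_bins = 40)
  full <- crop_patches(nm120, 40, 40)
  keep <- abs(full$anchors$row0 - full$anchors$col0) <= 40  # enumeration oracle
  expect_equal(band$anchors, full$anchors[keep, ],
               ignore_attr = TRUE)
  expect_true(all(abs(band$anchors$row0 - band$anchors$col0) <= 40))

  expect_error(crop_patches(nm, 0), "patch_size")
  expect_error(crop_patches(nm, 40, 0), "stride")
})

test_that("assemble_patches inverts cropping, averages overlaps, symmetrizes", {
  nm <- random_norm_map(100, seed = 9)
  expect_equal(assemble_patches(crop_patches(nm, 40, 40))$matrix, nm$matrix)
  # overlapping stride: still the identity for a symmetric source
  expect_equal(assemble_patches(crop_patches(nm, 40, 20))$matrix, nm$matrix)

  # two overlapping tiles disagreeing at a cell average to the midpoint
  ps <- crop_patches(random_norm_map(40, seed = 10), 40, 40)
  ps$anchors <- data.frame(row0 = c(0L, 0L), col0 = c(0L, 0L))
  ps$tiles <- array(c(matrix(0.2, 40, 40), matrix(0.4, 40, 40)), c(40, 40, 2))
  out <- assemble_patches(ps)
  expect_equal(out$matrix[5, 7], 0.3)

  # asymmetric predicted tiles come back symmetric
  ps2 <- crop_patches(random_norm_map(60, seed = 11), 40, 40)
  set.seed(12)
  ps2$tiles <- array(runif(length(ps2$tiles)), dim(ps2$tiles))
  out2 <- assemble_patches(ps2)
  expect_lt(max(abs(out2$matrix - t(out2$matrix))), 1e-9)

  # a gap in coverage is a hard error naming the first uncovered cell
  ps3 <- crop_patches(random_norm_map(80, seed = 13), 40, 40)
  drop <- !(ps3$anchors$row0 == 40 & ps3$anchors$col0 == 40)
  ps3$anchors <- ps3$anchors[drop, ]
  ps3$tiles <- ps3$tiles[, , drop, drop = FALSE]
  expect_error(assemble_patches(ps3), "uncovered")
})
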