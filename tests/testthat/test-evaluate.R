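test_that("MSE and PSNR follow their closed forms", {
  x <- random_norm_map(10, seed = 1)
  expect_equal(metric_mse(x, x), 0)
  y <- x; y$matrix <- pmin(y$matrix + 0.01, 1)
  mm <- metric_mse(y, x)
  # loop oracle
  acc <- 0
  for (i in 1:10) for (j in 1:10) acc <- acc + (y$matrix[i, j] - x$matrix[i, j])^2
  expect_equal(mm, acc / 100, tolerance = 1e-12)

  flat <- contact_map(matrix(0.5, 10, 10), is_normalized = TRUE)
  off <- contact_map(matrix(0.51, 10, 10), is_normalized = TRUE)
  expect_equal(metric_psnr(off, flat), 40, tolerance = 1e-9)   # mse 1e-4
  expect_identical(metric_psnr(flat, flat), Inf)               # sentinel
  # halving the MSE raises PSNR by 10*log10(2)
  off2 <- contact_map(matrix(0.5 + 0.01 / sqrt(2), 10, 10), is_normalized = TRUE)
  expect_equal(metric_psnr(off2, flat) - metric_psnr(off, flat),
               10 * log10(2), tolerance = 1e-9)
  expect_error(metric_mse(x, random_norm_map(12, seed = 3)), "shape")
  raw <- random_count_map(10, seed = 4)
  expect_error(metric_mse(raw, raw), "normalized")
})

test_that("PSNR decreases monotonically in MSE over random pairs", {
  base <- random_norm_map(20, seed = 5)
  res <- sapply(c(0.005, 0.02, 0.08), function(s) {
    set.seed(6)
    pert <- base
    pert$matrix <- pmax(pmin(base$matrix + matrix(rnorm(400, sd = s), 20, 20), 1), 0)
    pert$matrix <- (pert$matrix + t(pert$matrix)) / 2
    c(metric_mse(pert, base), metric_psnr(pert, base))
  })
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) < 0))
})

test_that("SSIM matches the direct per-window Gaussian oracle", {
  x <- random_norm_map(40, seed = 7)
  y <- random_norm_map(40, seed = 8)
  expect_equal(metric_ssim(x, x), 1.0, tolerance = 1e-12)
  expect_equal(metric_ssim(x, y), metric_ssim(y, x), tolerance = 1e-12)
  expect_equal(metric_ssim(x, y), ssim_oracle(x$matrix, y$matrix),
               tolerance = 1e-6)
  expect_true(abs(metric_ssim(x, y)) <= 1)
  small <- random_norm_map(8, seed = 9)
  expect_error(metric_ssim(small, small), "window")
})

test_that("SNR follows the adopted Euclidean-residual convention", {
  y <- contact_map(matrix(0.5, 2, 2), is_normalized = TRUE)
  x <- contact_map(matrix(1.0, 2, 2), is_normalized = TRUE)
  expect_equal(metric_snr(x, y), 2)   # sum(y)=2, ||x-y|| = 1
  # doubling the residual halves the SNR
  y4 <- contact_map(matrix(0.25, 2, 2), is_normalized = TRUE)
  x4 <- contact_map(matrix(0.75, 2, 2), is_normalized = TRUE)
  xx <- contact_map(matrix(1.25, 2, 2), is_normalized = TRUE)
  expect_equal(metric_snr(xx, y4) / metric_snr(x4, y4), 0.5)
  expect_identical(metric_snr(y, y), Inf)
  # alternative squared-denominator convention is exposed
  expect_equal(metric_snr(x, y, squared_denominator = TRUE), 2)
})

test_that("insulation profile matches the loop oracle and finds boundaries", {
  uni <- contact_map(matrix(2, 40, 40))
  prof <- insulation_vector(uni, 5)
  expect_true(all(abs(prof$scores[prof$valid]) < 1e-12))
  expect_equal(which(prof$valid) - 1L, 5:34)    # documented valid range

  cm <- random_count_map(50, seed = 10)
  p <- insulation_vector(cm, 7)
  o <- insulation_oracle(cm$matrix, 7)
  expect_equal(p$valid, o$valid)
  expect_equal(p$scores[p$valid], o$scores[o$valid], tolerance = 1e-12)

  # noiseless planted boundary: profile minimum within 1 bin
  icfg <- synthetic_config(n_bins = 60, tad_boundaries = 30,
                           tad_enrichment = 5)
  intens <- simulate_intensity(icfg)$intensity
  im <- contact_map(intens * 1e6, is_normalized = FALSE)
  pr <- insulation_vector(im, 8)
  b <- which.min(pr$scores) - 1L
  expect_lte(abs(b - 30L), 1L)

  expect_error(insulation_vector(uni, 20), "too small")
})

test_that("insulation L2 matches its definition", {
  cm <- random_count_map(40, seed = 11)
  a <- insulation_vector(cm, 6)
  expect_equal(insulation_l2(a, a), 0)
  b <- a
  b$scores <- b$scores + 1
  k <- sum(a$valid & b$valid)
  expect_equal(insulation_l2(a, b), sqrt(k))
  cm2 <- random_count_map(40, seed = 12)
  b2 <- insulation_vector(cm2, 6)
  idx <- a$valid & b2$valid
  oracle <- sqrt(sum((a$scores[idx] - b2$scores[idx])^2))
  expect_equal(insulation_l2(a, b2), oracle, tolerance = 1e-12)
  bad <- insulation_vector(cm, 5)
  expect_error(insulation_l2(a, bad), "window")
})

test_that("random-walk concordance matches the dense linear-algebra oracle", {
  a <- random_count_map(25, seed = 13)
  b <- random_count_map(25, seed = 14)
  expect_equal(concordance_score(a, a, 3), 1.0, tolerance = 1e-12)
  expect_equal(concordance_score(a, b, 1),
               concordance_oracle(a$matrix, b$matrix, 1), tolerance = 1e-9)
  expect_equal(concordance_score(a, b, 3),
               concordance_oracle(a$matrix, b$matrix, 3), tolerance = 1e-9)
  expect_equal(concordance_score(a, b, 2), concordance_score(b, a, 2),
               tolerance = 1e-12)
  expect_lte(concordance_score(a, b, 2), 1)

  # block-diagonal maps with disjoint support have zero concordance
  m1 <- matrix(0, 10, 10); m1[1:5, 1:5] <- 1
  m2 <- matrix(0, 10, 10); m2[6:10, 6:10] <- 1
  expect_equal(concordance_score(contact_map(m1), contact_map(m2), 2), 0)

  z4 <- contact_map(matrix(0, 4, 4))
  o4 <- contact_map(diag(4))
  expect_error(concordance_score(z4, o4, 1), "all-zero")
  expect_error(concordance_score(a, b, 0), "t_steps")
})

test_that("image metrics degrade monotonically with heavier down-sampling", {
  cfg <- synthetic_config(n_bins = 120, tad_boundaries = c(40, 80),
                          read_depth = 2e5, seed = 15)
  hr <- sample_reads(simulate_intensity(cfg), cfg$read_depth, seed = 15)
  mild <- downsample(hr, 0.75, seed = 16)
  severe <- downsample(hr, 0.1, seed = 17)
  sc <- fit_scale(hr)
  hn <- apply_scale(hr, sc); mn <- apply_scale(mild, sc)
  sn <- apply_scale(severe, sc)
  expect_identical(metric_mse(hn, hn), 0)
  expect_lt(metric_mse(mn, hn), metric_mse(sn, hn))
  expect_gt(metric_psnr(mn, hn), metric_psnr(sn, hn))
  expect_gt(metric_ssim(mn, hn), metric_ssim(sn, hn))
  expect_equal(metric_ssim(hn, hn), 1)
  expect_gt(metric_snr(mn, hn), metric_snr(sn, hn))
})

test_that("evaluate_maps produces the combined per-comparison report", {
  cfg <- synthetic_config(n_bins = 80, tad_boundaries = 40, read_depth = 5e4,
                          seed = 18)
  pr <- make_pair(cfg, 0.2)
  rep <- evaluate_maps(pr$lr, pr$hr, lr = pr$lr, window_bins = 8)
  expect_equal(rep$comparison, c("pred_vs_target", "lr_vs_target"))
  expect_equal(rep[1, -1], rep[2, -1], ignore_attr = TRUE)
  expect_true(all(c("mse", "psnr", "ssim", "snr", "insulation_l2",
                    "concordance") %in% names(rep)))
})
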