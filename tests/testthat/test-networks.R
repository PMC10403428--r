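test_that("generator parameter count matches the closed-form convolution sum", {
  conv_params <- function(k, cin, cout) k * k * cin * cout + cout
  # reduced config, counted exactly
  g <- build_generator(generator_config(feature_channels = 8L,
                                        n_res_blocks = 3L), seed = 1)
  expected <- conv_params(3, 1, 8) + 3 * 2 * conv_params(3, 8, 8) +
    conv_params(3, 8, 8) + conv_params(3, 8, 1)
  expect_equal(n_parameters(g), expected)
  # full-size default config: stem + 32 paired 256-channel blocks + post + head
  gd <- build_generator(generator_config(), seed = 1)
  expected_full <- conv_params(3, 1, 256) +
    32 * 2 * conv_params(3, 256, 256) +
    conv_params(3, 256, 256) + conv_params(3, 256, 1)
  expect_equal(n_parameters(gd), expected_full)
})

test_that("generator forward is shape-preserving, finite and deterministic", {
  g <- build_generator(tiny_gcfg(), seed = 3)
  x <- random_batch(40, 2, seed = 4)
  y <- generator_forward(g, x)
  expect_equal(dim(y), c(40, 40, 1, 2))
  expect_identical(y, generator_forward(g, x))
  expect_true(all(is.finite(generator_forward(g, array(0, c(40, 40, 1, 1))))))
  # identical seeds give identical weights
  expect_identical(build_generator(tiny_gcfg(), seed = 3)$params, g$params)
  expect_error(generator_forward(g, array(0, c(40, 40, 2, 1))), "channels")
})

test_that("res_scale = 0 reduces every residual block to the identity", {
  cfg <- generator_config(feature_channels = 4L, n_res_blocks = 3L,
                          res_scale = 0)
  g <- build_generator(cfg, seed = 5)
  x <- random_batch(16, 1, seed = 6)
  y <- generator_forward(g, x)
  # manual stem -> post (+ global skip) -> head composition
  s0 <- schicenh:::conv_fwd(x, g$params$stem, pad = 1L)
  z <- schicenh:::conv_fwd(s0, g$params$post, pad = 1L) + s0
  manual <- schicenh:::conv_fwd(z, g$params$head, pad = 1L)
  expect_equal(y, manual, tolerance = 1e-12)
})

test_that("generator output has no cross-batch coupling", {
  g <- build_generator(tiny_gcfg(), seed = 7)
  batch <- random_batch(40, 8, seed = 8)
  alone <- generator_forward(g, batch[, , , 3, drop = FALSE])
  together <- generator_forward(g, batch)[, , , 3, drop = FALSE]
  expect_equal(alone, together, tolerance = 1e-12)
})

test_that("generator contains no batch normalization; discriminator does", {
  gl <- network_layers(build_generator(tiny_gcfg(), seed = 1))
  expect_false(any(gl$type == "batch_norm"))
  expect_true(all(c("conv", "relu", "scale", "add") %in% gl$type))
  dl <- network_layers(build_discriminator(tiny_dcfg(), seed = 1))
  expect_equal(sum(dl$type == "batch_norm"), 7L)
})

test_that("zero input yields a constant interior (translation consistency)", {
  g <- build_generator(tiny_gcfg(), seed = 9)
  y <- generator_forward(g, array(0, c(40, 40, 1, 1)))[, , 1, 1]
  interior <- y[8:33, 8:33]  # beyond the receptive-field border
  expect_lt(max(interior) - min(interior), 1e-9)
})

test_that("discriminator follows the documented 7-block architecture", {
  cfg <- discriminator_config()
  expect_equal(cfg$kernel_pattern, c(4L, 3L, 4L, 3L, 4L, 3L, 3L))
  expect_equal(cfg$downsample_blocks, c(1L, 3L, 5L))
  d <- build_discriminator(cfg, seed = 1)
  widths <- vapply(d$params$blocks, function(b) dim(b$conv$w)[4L], integer(1L))
  expect_equal(widths, c(64L, 128L, 128L, 256L, 256L, 512L, 512L))
  kerns <- vapply(d$params$blocks, function(b) dim(b$conv$w)[1L], integer(1L))
  expect_equal(kerns, cfg$kernel_pattern)
  expect_equal(dim(d$params$stem$w)[4L], 64L)
})

test_that("discriminator emits reproducible per-patch probabilities in (0,1)", {
  d <- build_discriminator(tiny_dcfg(), seed = 2)
  x <- random_batch(40, 5, seed = 10)
  p <- discriminator_forward(d, x)
  expect_length(p, 5L)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, discriminator_forward(d, x))
  # works on smaller patches too (any H = W >= 8)
  p8 <- discriminator_forward(d, random_batch(8, 2, seed = 11))
  expect_true(all(p8 > 0 & p8 < 1))
})

test_that("probabilities respond monotonically to an additive logit shift", {
  d <- build_discriminator(tiny_dcfg(), seed = 3)
  x <- random_batch(40, 4, seed = 12)
  p0 <- discriminator_forward(d, x)
  d_up <- d
  d_up$params$head$b <- d$params$head$b + 1
  expect_true(all(discriminator_forward(d_up, x) > p0))
  d_down <- d
  d_down$params$head$b <- d$params$head$b - 1
  expect_true(all(discriminator_forward(d_down, x) < p0))
})

test_that("generator backprop matches finite differences", {
  cfg <- generator_config(feature_channels = 3L, n_res_blocks = 2L)
  g <- build_generator(cfg, seed = 13)
  x <- random_batch(8, 2, seed = 14)
  set.seed(15)
  gy <- array(rnorm(length(x)), dim(x))
  fwd <- schicenh:::gen_fwd(g, x, cache = TRUE)
  bk <- schicenh:::gen_bwd(g, fwd, gy)
  eps <- 1e-6
  # input gradient at a few positions
  for (i in c(1L, 37L, 100L)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (sum(schicenh:::gen_fwd(g, xp) * gy) -
           sum(schicenh:::gen_fwd(g, xm) * gy)) / (2 * eps)
    expect_close(bk$gx[i], fd, 1e-5)
  }
  # weight gradients in distinct layers
  probe <- list(c("stem", "w", 5L), c("post", "w", 11L), c("head", "b", 1L))
  for (pr in probe) {
    gp <- g; gm <- g
    gp$params[[pr[[1]]]][[pr[[2]]]][as.integer(pr[[3]])] <-
      gp$params[[pr[[1]]]][[pr[[2]]]][as.integer(pr[[3]])] + eps
    gm$params[[pr[[1]]]][[pr[[2]]]][as.integer(pr[[3]])] <-
      gm$params[[pr[[1]]]][[pr[[2]]]][as.integer(pr[[3]])] - eps
    fd <- (sum(schicenh:::gen_fwd(gp, x) * gy) -
           sum(schicenh:::gen_fwd(gm, x) * gy)) / (2 * eps)
    expect_close(bk$grads[[pr[[1]]]][[pr[[2]]]][as.integer(pr[[3]])], fd, 1e-5)
  }
  # a residual-block weight
  i <- 7L
  gp <- g; gp$params$blocks[[1]]$c1$w[i] <- gp$params$blocks[[1]]$c1$w[i] + eps
  gm <- g; gm$params$blocks[[1]]$c1$w[i] <- gm$params$blocks[[1]]$c1$w[i] - eps
  fd <- (sum(schicenh:::gen_fwd(gp, x) * gy) -
         sum(schicenh:::gen_fwd(gm, x) * gy)) / (2 * eps)
  expect_close(bk$grads$blocks[[1]]$c1$w[i], fd, 1e-5)
})

test_that("discriminator backprop matches finite differences", {
  d <- build_discriminator(tiny_dcfg(), seed = 16)
  x <- random_batch(16, 2, seed = 17)
  set.seed(18)
  dp <- rnorm(2)
  fwd <- schicenh:::disc_fwd(d, x, cache = TRUE)
  bk <- schicenh:::disc_bwd(d, fwd, dp, need_gx = TRUE)
  eps <- 1e-6
  obj <- function(dd, xx) sum(schicenh:::disc_fwd(dd, xx) * dp)
  for (i in c(2L, 50L)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (obj(d, xp) - obj(d, xm)) / (2 * eps)
    expect_close(bk$gx[i], fd, 1e-4)
  }
  # conv weight, batch-norm gamma and beta inside a block
  i <- 3L
  dp1 <- d; dp1$params$blocks[[2]]$conv$w[i] <- dp1$params$blocks[[2]]$conv$w[i] + eps
  dm1 <- d; dm1$params$blocks[[2]]$conv$w[i] <- dm1$params$blocks[[2]]$conv$w[i] - eps
  fd <- (obj(dp1, x) - obj(dm1, x)) / (2 * eps)
  expect_close(bk$grads$blocks[[2]]$conv$w[i], fd, 1e-4)
  dp2 <- d; dp2$params$blocks[[3]]$gamma[2] <- dp2$params$blocks[[3]]$gamma[2] + eps
  dm2 <- d; dm2$params$blocks[[3]]$gamma[2] <- dm2$params$blocks[[3]]$gamma[2] - eps
  fd <- (obj(dp2, x) - obj(dm2, x)) / (2 * eps)
  expect_close(bk$grads$blocks[[3]]$gamma[2], fd, 1e-4)
  dp3 <- d; dp3$params$blocks[[1]]$beta[1] <- dp3$params$blocks[[1]]$beta[1] + eps
  dm3 <- d; dm3$params$blocks[[1]]$beta[1] <- dm3$params$blocks[[1]]$beta[1] - eps
  fd <- (obj(dp3, x) - obj(dm3, x)) / (2 * eps)
  expect_close(bk$grads$blocks[[1]]$beta[1], fd, 1e-4)
})
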