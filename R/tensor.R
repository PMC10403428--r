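# Internal tensor utilities for the conv nets. Activations are R arrays
# [H, W, C, N]; conv weights [K, K, C_in, C_out]. The conv kernels live
# in src/conv.cpp; everything elementwise or per-channel stays in R.

# He-normal initialisation for a conv layer (draws from the current RNG).
init_conv <- function(k, c_in, c_out, gain = 1) {
  sd <- gain * sqrt(2 / (k * k * c_in))
  list(w = array(stats::rnorm(k * k * c_in * c_out, sd = sd),
                 c(k, k, c_in, c_out)),
       b = numeric(c_out))
}

conv_fwd <- function(x, layer, stride = 1L, pad = 1L) {
  .conv2d_fwd(x, layer$w, layer$b, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, layer, gy, stride = 1L, pad = 1L, need_gx = TRUE) {
  .conv2d_bwd(x, layer$w, gy, as.integer(stride), as.integer(pad), need_gx)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, gy) gy * (x > 0)

leaky_relu_fwd <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}
leaky_relu_bwd <- function(x, gy, slope) {
  neg <- x < 0
  gy[neg] <- slope * gy[neg]
  gy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Batch normalization over (H, W, N) per channel, biased variance,
# eps 1e-5. Returns the output plus the cache needed for backward.
bn_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  C <- d[3L]
  xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = C)  # (H*W*N) x C
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, invstd, "*")
  ym <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  y <- aperm(array(ym, c(d[1L], d[2L], d[4L], C)), c(1L, 2L, 4L, 3L))
  list(y = y, xhat = xhat, invstd = invstd, dims = d)
}

bn_bwd <- function(cache, gamma, gy) {
  d <- cache$dims
  C <- d[3L]
  m <- d[1L] * d[2L] * d[4L]
  gym <- matrix(aperm(gy, c(1L, 2L, 4L, 3L)), ncol = C)
  xhat <- cache$xhat
  ggamma <- colSums(gym * xhat)
  gbeta <- colSums(gym)
  gxhat <- sweep(gym, 2L, gamma, "*")
  gxm <- sweep(gxhat - matrix(colMeans(gxhat), m, C, byrow = TRUE) -
                 xhat * matrix(colMeans(gxhat * xhat), m, C, byrow = TRUE),
               2L, cache$invstd, "*")
  gx <- aperm(array(gxm, c(d[1L], d[2L], d[4L], C)), c(1L, 2L, 4L, 3L))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# Convert a PatchSet tile stack (ps x ps x n) to a network batch
# [H, W, 1, N] and back.
tiles_to_batch <- function(tiles) {
  d <- dim(tiles)
  array(tiles, c(d[1L], d[2L], 1L, d[3L]))
}
batch_to_tiles <- function(batch) {
  d <- dim(batch)
  array(batch, c(d[1L], d[2L], d[4L]))
}

# Recursively apply f to matching leaves of two parameter trees.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) tree_map(f, x))
    names(out) <- names(a)
    out
  } else f(a)
}

tree_sum <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(x) tree_sum(f, x), numeric(1L)))
  else f(a)
}

# Adam optimizer over a parameter tree.
adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
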