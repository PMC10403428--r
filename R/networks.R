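#' Generator architecture configuration
#'
#' The generator is a shape-preserving residual network: a 3x3 stem
#' convolution lifting the single input channel to `feature_channels`,
#' `n_res_blocks` residual blocks, a post-residual 3x3 convolution
#' (optionally joined to the stem output by a global skip connection),
#' and a 3x3 head convolution back to the input channel count. Each
#' residual block is conv3x3 -> ReLU -> conv3x3 -> multiply by
#' `res_scale` -> add the block input; there is deliberately no batch
#' normalization anywhere in the generator, and the residual scaling
#' factor (default 0.1) stabilises training of the deep stack.
#'
#' @param in_channels input/output channels (1 for contact maps).
#' @param feature_channels width of the residual trunk (default 256).
#' @param n_res_blocks number of residual blocks (default 32).
#' @param res_scale residual scaling factor in (0, 1\] (default 0.1).
#' @param kernel convolution kernel size (default 3).
#' @param global_skip add the stem output after the post-residual
#'   convolution (default `TRUE`).
#' @return An object of class `GeneratorConfig`.
#' @export
generator_config <- function(in_channels = 1L, feature_channels = 256L,
                             n_res_blocks = 32L, res_scale = 0.1,
                             kernel = 3L, global_skip = TRUE) {
  if (n_res_blocks < 1L) stop("n_res_blocks must be >= 1")
  if (!(res_scale >= 0 && res_scale <= 1)) stop("res_scale must lie in [0, 1]")
  structure(list(in_channels = as.integer(in_channels),
                 feature_channels = as.integer(feature_channels),
                 n_res_blocks = as.integer(n_res_blocks),
                 res_scale = res_scale, kernel = as.integer(kernel),
                 global_skip = isTRUE(global_skip)),
            class = "GeneratorConfig")
}

#' Discriminator architecture configuration
#'
#' A 3x3 stem convolution with leaky ReLU, followed by seven
#' convolutional blocks (each conv -> batch normalization -> leaky
#' ReLU) with kernel pattern 4,3,4,3,4,3,3; the 4x4 blocks (1, 3, 5)
#' use stride 2, and the channel width doubles entering blocks 2, 4
#' and 6, giving widths 64,128,128,256,256,512,512 from a 64-channel
#' stem. A 3x3 head convolution and a sigmoid produce a per-patch
#' realism probability (the sigmoid map is spatially averaged).
#'
#' @param stem_channels stem width (default 64).
#' @param leaky_slope negative slope of the leaky ReLU (default 0.2).
#' @param in_channels input channels (default 1).
#' @return An object of class `DiscriminatorConfig`. The block count
#'   (7), kernel pattern and stride/doubling schedule are fixed.
#' @export
discriminator_config <- function(stem_channels = 64L, leaky_slope = 0.2,
                                 in_channels = 1L) {
  structure(list(stem_channels = as.integer(stem_channels),
                 leaky_slope = leaky_slope,
                 in_channels = as.integer(in_channels),
                 n_blocks = 7L,
                 kernel_pattern = c(4L, 3L, 4L, 3L, 4L, 3L, 3L),
                 downsample_blocks = c(1L, 3L, 5L),
                 double_blocks = c(2L, 4L, 6L)),
            class = "DiscriminatorConfig")
}

#' Build a generator with deterministic initialisation
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `Generator` holding `cfg` and the
#'   parameter tree.
#' @examples
#' g <- build_generator(generator_config(feature_channels = 8,
#'                                       n_res_blocks = 2), seed = 1)
#' n_parameters(g)
#' @export
build_generator <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "GeneratorConfig")) stop("cfg must be a GeneratorConfig")
  k <- cfg$kernel; f <- cfg$feature_channels
  params <- withr_seed(seed, {
    list(stem = init_conv(k, cfg$in_channels, f),
         blocks = lapply(seq_len(cfg$n_res_blocks), function(i)
           list(c1 = init_conv(k, f, f), c2 = init_conv(k, f, f))),
         post = init_conv(k, f, f),
         head = init_conv(k, f, cfg$in_channels))
  })
  structure(list(cfg = cfg, params = params), class = "Generator")
}

# Generator forward pass. With cache = TRUE returns everything needed
# for backprop; pad keeps spatial size for odd/even kernels alike.
gen_fwd <- function(gen, x, cache = FALSE) {
  cfg <- gen$cfg; p <- gen$params
  pad <- cfg$kernel %/% 2L
  s0 <- conv_fwd(x, p$stem, pad = pad)
  r <- s0
  caches <- if (cache) vector("list", cfg$n_res_blocks) else NULL
  for (i in seq_len(cfg$n_res_blocks)) {
    a <- conv_fwd(r, p$blocks[[i]]$c1, pad = pad)
    h <- relu_fwd(a)
    cc <- conv_fwd(h, p$blocks[[i]]$c2, pad = pad)
    if (cache) caches[[i]] <- list(input = r, a = a, h = h)
    r <- r + cfg$res_scale * cc
  }
  post <- conv_fwd(r, p$post, pad = pad)
  z <- if (cfg$global_skip) post + s0 else post
  y <- conv_fwd(z, p$head, pad = pad)
  if (!cache) return(y)
  list(y = y, x = x, s0 = s0, r = r, z = z, blocks = caches)
}

# Backward pass matching gen_fwd(cache = TRUE).
gen_bwd <- function(gen, cache, gy) {
  cfg <- gen$cfg; p <- gen$params
  pad <- cfg$kernel %/% 2L
  g <- conv_bwd(cache$z, p$head, gy, pad = pad)
  grads <- list(stem = NULL, blocks = vector("list", cfg$n_res_blocks),
                post = NULL, head = list(w = g$gw, b = g$gb))
  gz <- g$gx
  gs0 <- if (cfg$global_skip) gz else 0
  g <- conv_bwd(cache$r, p$post, gz, pad = pad)
  grads$post <- list(w = g$gw, b = g$gb)
  gr <- g$gx
  for (i in rev(seq_len(cfg$n_res_blocks))) {
    bc <- cache$blocks[[i]]
    gcc <- cfg$res_scale * gr
    g2 <- conv_bwd(bc$h, p$blocks[[i]]$c2, gcc, pad = pad)
    ga <- relu_bwd(bc$a, g2$gx)
    g1 <- conv_bwd(bc$input, p$blocks[[i]]$c1, ga, pad = pad)
    grads$blocks[[i]] <- list(c1 = list(w = g1$gw, b = g1$gb),
                              c2 = list(w = g2$gw, b = g2$gb))
    gr <- gr + g1$gx
  }
  gs0 <- gs0 + gr
  g <- conv_bwd(cache$x, p$stem, gs0, pad = pad)
  grads$stem <- list(w = g$gw, b = g$gb)
  list(gx = g$gx, grads = grads)
}

#' Run the generator on a patch batch
#'
#' Deterministic shape-preserving forward pass. Accepts a 4-D array
#' `[H, W, C, N]` (a "patch batch"); `H` and `W` must match and `C`
#' must equal the configured input channels.
#'
#' @param gen a `Generator` from [build_generator()], or an
#'   [identity_generator()].
#' @param batch numeric array `[H, W, C, N]` of normalized patches.
#' @return Array of the same shape.
#' @export
generator_forward <- function(gen, batch) {
  if (inherits(gen, "IdentityGenerator")) return(batch)
  if (!inherits(gen, "Generator")) stop("gen must be a Generator")
  d <- dim(batch)
  if (length(d) != 4L) stop("batch must be a 4-D [H, W, C, N] array")
  if (d[1L] != d[2L])
    stop("patches must be square; got ", d[1L], " x ", d[2L])
  if (d[3L] != gen$cfg$in_channels)
    stop("batch has ", d[3L], " channels; generator expects ",
         gen$cfg$in_channels)
  if (!all(is.finite(batch))) stop("batch contains non-finite values")
  gen_fwd(gen, batch, cache = FALSE)
}

#' A pass-through generator for pipeline testing
#'
#' A stand-in whose forward pass returns its input unchanged; useful
#' for verifying that the enhancement pipeline (normalize, crop,
#' assemble, invert) is the identity when the network does nothing.
#' @return An object of classes `IdentityGenerator` and `Generator`.
#' @export
identity_generator <- function() {
  structure(list(cfg = list(in_channels = 1L), params = list()),
            class = c("IdentityGenerator", "Generator"))
}

#' Build a discriminator with deterministic initialisation
#'
#' @param cfg a [discriminator_config()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `Discriminator`.
#' @export
build_discriminator <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "DiscriminatorConfig")) stop("cfg must be a DiscriminatorConfig")
  widths <- disc_widths(cfg)
  params <- withr_seed(seed, {
    blocks <- lapply(seq_len(cfg$n_blocks), function(i) {
      c_in <- if (i == 1L) cfg$stem_channels else widths[i - 1L]
      list(conv = init_conv(cfg$kernel_pattern[i], c_in, widths[i]),
           gamma = rep(1, widths[i]), beta = numeric(widths[i]))
    })
    list(stem = init_conv(3L, cfg$in_channels, cfg$stem_channels),
         blocks = blocks,
         head = init_conv(3L, widths[cfg$n_blocks], 1L))
  })
  structure(list(cfg = cfg, params = params), class = "Discriminator")
}

# Channel widths after each of the seven blocks.
disc_widths <- function(cfg) {
  w <- integer(cfg$n_blocks)
  cur <- cfg$stem_channels
  for (i in seq_len(cfg$n_blocks)) {
    if (i %in% cfg$double_blocks) cur <- cur * 2L
    w[i] <- cur
  }
  w
}

# Discriminator forward. Returns per-patch probabilities in (0, 1);
# with cache = TRUE also everything needed for backprop.
disc_fwd <- function(disc, x, cache = FALSE) {
  cfg <- disc$cfg; p <- disc$params
  s_pre <- conv_fwd(x, p$stem, pad = 1L)
  h <- leaky_relu_fwd(s_pre, cfg$leaky_slope)
  caches <- if (cache) vector("list", cfg$n_blocks) else NULL
  stem_cache <- if (cache) list(x = x, pre = s_pre) else NULL
  for (i in seq_len(cfg$n_blocks)) {
    k <- cfg$kernel_pattern[i]
    stride <- if (i %in% cfg$downsample_blocks) 2L else 1L
    pre <- conv_fwd(h, p$blocks[[i]]$conv, stride = stride, pad = 1L)
    bn <- bn_fwd(pre, p$blocks[[i]]$gamma, p$blocks[[i]]$beta)
    out <- leaky_relu_fwd(bn$y, cfg$leaky_slope)
    if (cache)
      caches[[i]] <- list(input = h, stride = stride, bn = bn, bn_y = bn$y)
    h <- out
  }
  logits <- conv_fwd(h, p$head, pad = 1L)
  sg <- sigmoid(logits)
  d <- dim(sg)
  probs <- apply(sg, 4L, mean)
  if (!cache) return(probs)
  list(probs = probs, x = x, stem = stem_cache, blocks = caches,
       head_in = h, logits = logits, sg = sg)
}

# Discriminator backward from d(loss)/d(probs); returns parameter
# gradients and optionally the gradient on the input batch.
disc_bwd <- function(disc, cache, dprobs, need_gx = FALSE) {
  cfg <- disc$cfg; p <- disc$params
  sg <- cache$sg
  d <- dim(sg)
  npix <- d[1L] * d[2L] * d[3L]
  dsig <- array(rep(dprobs / npix, each = npix), d)
  dlogits <- dsig * sg * (1 - sg)
  g <- conv_bwd(cache$head_in, p$head, dlogits, pad = 1L)
  grads <- list(stem = NULL, blocks = vector("list", cfg$n_blocks),
                head = list(w = g$gw, b = g$gb))
  gh <- g$gx
  for (i in rev(seq_len(cfg$n_blocks))) {
    bc <- cache$blocks[[i]]
    gout <- leaky_relu_bwd(bc$bn_y, gh, cfg$leaky_slope)
    gb <- bn_bwd(bc$bn, p$blocks[[i]]$gamma, gout)
    gc <- conv_bwd(bc$input, p$blocks[[i]]$conv, gb$gx,
                   stride = bc$stride, pad = 1L)
    grads$blocks[[i]] <- list(conv = list(w = gc$gw, b = gc$gb),
                              gamma = gb$ggamma, beta = gb$gbeta)
    gh <- gc$gx
  }
  gpre <- leaky_relu_bwd(cache$stem$pre, gh, cfg$leaky_slope)
  g <- conv_bwd(cache$stem$x, p$stem, gpre, pad = 1L, need_gx = need_gx)
  grads$stem <- list(w = g$gw, b = g$gb)
  list(gx = if (need_gx) g$gx else NULL, grads = grads)
}

#' Run the discriminator on a patch batch
#'
#' @param disc a `Discriminator` from [build_discriminator()].
#' @param batch numeric array `[H, W, C, N]`.
#' @return Numeric vector of `N` per-patch probabilities, each strictly
#'   in (0, 1).
#' @export
discriminator_forward <- function(disc, batch) {
  if (!inherits(disc, "Discriminator")) stop("disc must be a Discriminator")
  d <- dim(batch)
  if (length(d) != 4L) stop("batch must be a 4-D [H, W, C, N] array")
  if (d[3L] != disc$cfg$in_channels)
    stop("batch has ", d[3L], " channels; discriminator expects ",
         disc$cfg$in_channels)
  disc_fwd(disc, batch, cache = FALSE)
}

#' Count trainable parameters of a network
#'
#' @param net a `Generator` or `Discriminator`.
#' @return Integer-valued scalar: total number of weights, biases and
#'   batch-norm parameters.
#' @export
n_parameters <- function(net) {
  tree_sum(length, net$params)
}

#' List the layers of a network
#'
#' Introspection helper used to assert architectural contracts (e.g.
#' that the generator contains no batch-normalization layers).
#'
#' @param net a `Generator` or `Discriminator`.
#' @return `data.frame` with columns `name` and `type` (one of
#'   `"conv"`, `"relu"`, `"leaky_relu"`, `"scale"`, `"add"`,
#'   `"batch_norm"`, `"sigmoid"`, `"spatial_mean"`).
#' @export
network_layers <- function(net) {
  if (inherits(net, "Generator") && !inherits(net, "IdentityGenerator")) {
    cfg <- net$cfg
    rows <- list(c("stem", "conv"))
    for (i in seq_len(cfg$n_res_blocks)) {
      b <- paste0("block", i, ".")
      rows <- c(rows, list(c(paste0(b, "conv1"), "conv"),
                           c(paste0(b, "relu"), "relu"),
                           c(paste0(b, "conv2"), "conv"),
                           c(paste0(b, "scale"), "scale"),
                           c(paste0(b, "add"), "add")))
    }
    rows <- c(rows, list(c("post", "conv")))
    if (cfg$global_skip) rows <- c(rows, list(c("global_skip", "add")))
    rows <- c(rows, list(c("head", "conv")))
  } else if (inherits(net, "Discriminator")) {
    cfg <- net$cfg
    rows <- list(c("stem", "conv"), c("stem.lrelu", "leaky_relu"))
    for (i in seq_len(cfg$n_blocks)) {
      b <- paste0("block", i, ".")
      rows <- c(rows, list(c(paste0(b, "conv"), "conv"),
                           c(paste0(b, "bn"), "batch_norm"),
                           c(paste0(b, "lrelu"), "leaky_relu")))
    }
    rows <- c(rows, list(c("head", "conv"), c("head.sigmoid", "sigmoid"),
                         c("head.mean", "spatial_mean")))
  } else stop("unsupported network")
  do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[1L], type = r[2L], stringsAsFactors = FALSE)))
}
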