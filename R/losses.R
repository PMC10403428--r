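#' Generator loss weights
#'
#' Scalar weights of the four-term generator loss
#' `L_G = l_MSE + alpha * l_VGG + beta * l_TV + gamma * l_AD`, plus the
#' internal total-variation weight `psi`. The pixel MSE term always has
#' weight one; `alpha`, `beta`, `gamma` lie in \[0, 1\]. Defaults are
#' the conventional magnitudes used by SRGAN-family enhancers for the
#' same three auxiliary terms.
#'
#' @param alpha weight of the perceptual (feature) loss.
#' @param beta weight of the total-variation loss.
#' @param gamma weight of the adversarial loss.
#' @param psi internal scalar of the TV loss (see [loss_tv()]).
#' @return An object of class `LossWeights`.
#' @export
loss_weights <- function(alpha = 0.006, beta = 2e-8, gamma = 0.001, psi = 1) {
  for (v in c(alpha, beta, gamma, psi))
    if (!is.finite(v) || v < 0) stop("loss weights must be non-negative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, psi = psi),
            class = "LossWeights")
}

#' Pixel mean-squared-error loss
#'
#' Mean over all elements of the squared difference between generated
#' and target patch batches.
#'
#' @param pred,target numeric arrays of identical shape.
#' @return Non-negative scalar; zero iff the batches are equal.
#' @export
loss_mse <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop("shape mismatch: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(target), collapse = "x"))
  mean((pred - target)^2)
}

#' Perceptual feature loss
#'
#' Mean squared difference between the feature representations of the
#' generated and target batches under a fixed feature extractor. With
#' the identity extractor this reduces exactly to [loss_mse()]. The
#' package default extractor is a fixed-seed random-convolution
#' feature map ([feature_extractor_random()]).
#'
#' @param extractor a feature extractor (see
#'   [feature_extractor_random()], [feature_extractor_identity()]).
#' @param pred,target numeric arrays `[H, W, C, N]` of identical shape.
#' @return Non-negative scalar; zero when `pred == target`.
#' @export
loss_perceptual <- function(extractor, pred, target) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  fp <- extractor_forward(extractor, pred)
  ft <- extractor_forward(extractor, target)
  mean((fp - ft)^2)
}

#' Total-variation loss
#'
#' Penalises squared first differences along rows (`hTV`) and columns
#' (`wTV`) of each patch:
#' `hTV = sum(dv^2) / (C * (H - 1) * W)`,
#' `wTV = sum(dh^2) / (C * H * (W - 1))`,
#' `l_TV = 2 * psi * (hTV + wTV) / F`, where `F` is the batch count and
#' the sums run over the whole batch. Invariant to adding a constant.
#'
#' @param pred numeric array `[H, W, C, N]` with `H, W >= 2`.
#' @param psi non-negative scalar weight.
#' @return Non-negative scalar.
#' @export
loss_tv <- function(pred, psi = 1) {
  d <- dim(pred)
  if (length(d) != 4L) stop("pred must be a 4-D [H, W, C, N] array")
  H <- d[1L]; W <- d[2L]; C <- d[3L]; F <- d[4L]
  if (H < 2L || W < 2L) stop("TV loss needs H >= 2 and W >= 2")
  dv <- pred[2:H, , , , drop = FALSE] - pred[1:(H - 1L), , , , drop = FALSE]
  dh <- pred[, 2:W, , , drop = FALSE] - pred[, 1:(W - 1L), , , drop = FALSE]
  htv <- sum(dv^2) / (C * (H - 1L) * W)
  wtv <- sum(dh^2) / (C * H * (W - 1L))
  2 * psi * (htv + wtv) / F
}

# Gradient of loss_tv with respect to pred.
loss_tv_grad <- function(pred, psi = 1) {
  d <- dim(pred)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; F <- d[4L]
  g <- array(0, d)
  dv <- pred[2:H, , , , drop = FALSE] - pred[1:(H - 1L), , , , drop = FALSE]
  dh <- pred[, 2:W, , , drop = FALSE] - pred[, 1:(W - 1L), , , drop = FALSE]
  cv <- 2 * psi / (F * C * (H - 1L) * W)
  ch <- 2 * psi / (F * C * H * (W - 1L))
  g[2:H, , , ] <- g[2:H, , , , drop = FALSE] + 2 * cv * dv
  g[1:(H - 1L), , , ] <- g[1:(H - 1L), , , , drop = FALSE] - 2 * cv * dv
  g[, 2:W, , ] <- g[, 2:W, , , drop = FALSE] + 2 * ch * dh
  g[, 1:(W - 1L), , ] <- g[, 1:(W - 1L), , , drop = FALSE] - 2 * ch * dh
  g
}

#' Adversarial loss of the generator
#'
#' One minus the mean probability that the discriminator assigns to
#' the generated patches being real: `l_AD = 1 - sum(D(Yhat_i)) / N`.
#'
#' @param probs numeric vector of discriminator probabilities in (0, 1).
#' @return Scalar in \[0, 1\].
#' @export
loss_adversarial <- function(probs) {
  if (length(probs) == 0L) stop("probs must be non-empty")
  1 - mean(probs)
}

#' Combine the four generator loss terms
#'
#' `L_G = mse + alpha * vgg + beta * tv + gamma * ad`.
#'
#' @param mse,vgg,tv,ad scalar component losses computed on one batch.
#' @param w a [loss_weights()] object.
#' @return Scalar total generator loss.
#' @export
generator_loss <- function(mse, vgg, tv, ad, w) {
  if (!inherits(w, "LossWeights")) stop("w must be a LossWeights")
  mse + w$alpha * vgg + w$beta * tv + w$gamma * ad
}

#' Discriminator binary cross-entropy loss
#'
#' `L_D = BCE(probs_real, 1) + BCE(probs_fake, 0)`, each term the mean
#' over its batch, with probabilities clipped to
#' `[1e-7, 1 - 1e-7]` before taking logarithms.
#'
#' @param probs_real,probs_fake numeric vectors of probabilities.
#' @param eps clipping epsilon (default 1e-7).
#' @return Non-negative scalar.
#' @export
discriminator_loss <- function(probs_real, probs_fake, eps = 1e-7) {
  if (length(probs_real) == 0L || length(probs_fake) == 0L)
    stop("probability vectors must be non-empty")
  pr <- pmin(pmax(probs_real, eps), 1 - eps)
  pf <- pmin(pmax(probs_fake, eps), 1 - eps)
  -mean(log(pr)) - mean(log(1 - pf))
}

#' Identity feature extractor
#'
#' Maps a batch to itself, reducing [loss_perceptual()] to
#' [loss_mse()]; mainly a reference point for tests and ablations.
#' @return An object of class `FeatureExtractor`.
#' @export
feature_extractor_identity <- function() {
  structure(list(type = "identity"), class = "FeatureExtractor")
}

#' Random-convolution feature extractor
#'
#' A fixed, untrained stack of 3x3 convolutions with ReLU between them
#' whose weights are drawn once from `seed`. Random convolutional
#' features are a standard training-free stand-in for learned
#' perceptual features: the loss still compares multi-scale local
#' structure rather than raw pixels, and the extractor is fully
#' deterministic and self-contained.
#'
#' @param seed integer seed fixing the weights.
#' @param in_channels input channels (default 1).
#' @param channels feature width per layer (default 8).
#' @param n_layers number of conv layers (default 2).
#' @return An object of class `FeatureExtractor`.
#' @export
feature_extractor_random <- function(seed = 1L, in_channels = 1L,
                                     channels = 8L, n_layers = 2L) {
  layers <- withr_seed(seed, {
    lapply(seq_len(n_layers), function(i)
      init_conv(3L, if (i == 1L) in_channels else channels, channels))
  })
  structure(list(type = "random_conv", layers = layers),
            class = "FeatureExtractor")
}

# Forward pass of a feature extractor; cache = TRUE keeps pre-ReLU
# activations for backprop through the (frozen) extractor.
extractor_forward <- function(ex, x, cache = FALSE) {
  if (!inherits(ex, "FeatureExtractor")) stop("not a FeatureExtractor")
  if (ex$type == "identity")
    return(if (cache) list(f = x, caches = NULL) else x)
  caches <- if (cache) list() else NULL
  h <- x
  nl <- length(ex$layers)
  for (i in seq_len(nl)) {
    pre <- conv_fwd(h, ex$layers[[i]], pad = 1L)
    if (cache) caches[[i]] <- list(input = h, pre = pre)
    h <- if (i < nl) relu_fwd(pre) else pre
  }
  if (cache) list(f = h, caches = caches) else h
}

# Gradient of a scalar loss on the features back to the extractor input.
extractor_backward <- function(ex, fwd, gfeat) {
  if (ex$type == "identity") return(gfeat)
  nl <- length(ex$layers)
  g <- gfeat
  for (i in rev(seq_len(nl))) {
    if (i < nl) g <- relu_bwd(fwd$caches[[i]]$pre, g)
    g <- conv_bwd(fwd$caches[[i]]$input, ex$layers[[i]], g, pad = 1L)$gx
  }
  g
}
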