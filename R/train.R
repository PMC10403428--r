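#' Training configuration
#'
#' Hyper-parameters of the adversarial training loop. Per step, one
#' discriminator update (binary cross-entropy on real vs generated
#' patches) is followed by one generator update (four-term loss); both
#' use Adam.
#'
#' @param ratio down-sampling ratio the model is trained for.
#' @param batch_size patches per step (default 64).
#' @param epochs passes over the training patches.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param adam_betas Adam `(beta1, beta2)` (default 0.9, 0.999).
#' @param seed master seed: fixes weight initialisation, patch
#'   shuffling and everything else in the run.
#' @param patch_size side length of training patches (default 40).
#' @param selection_metric validation criterion for model selection;
#'   `"ssim"` (default) or `"psnr"`.
#' @param drop_empty_patches drop patch pairs whose target tile is all
#'   zero (default `FALSE`: single-cell maps are mostly zeros and
#'   filtering would bias training toward dense regions).
#' @param train_discriminator set `FALSE` (typically with
#'   `gamma = 0`) to reduce training to supervised regression.
#' @return An object of class `TrainConfig`.
#' @export
train_config <- function(ratio = 0.1, batch_size = 64L, epochs = 5L,
                         learning_rate = 1e-4, adam_betas = c(0.9, 0.999),
                         seed = 1L, patch_size = 40L,
                         selection_metric = c("ssim", "psnr"),
                         drop_empty_patches = FALSE,
                         train_discriminator = TRUE) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(ratio = ratio, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 adam_betas = adam_betas, seed = as.integer(seed),
                 patch_size = as.integer(patch_size),
                 selection_metric = match.arg(selection_metric),
                 drop_empty_patches = isTRUE(drop_empty_patches),
                 train_discriminator = isTRUE(train_discriminator)),
            class = "TrainConfig")
}

# Stack every patch of a list of normalized maps into one [H,W,1,P]
# array (paired hr/lr tiles kept aligned by identical cropping).
pairs_to_patches <- function(pairs, patch_size, drop_empty) {
  xs <- list(); ys <- list()
  for (pr in pairs) {
    ph <- crop_patches(pr$hr, patch_size = patch_size)
    pl <- crop_patches(pr$lr, patch_size = patch_size)
    keep <- seq_len(dim(ph$tiles)[3L])
    if (drop_empty)
      keep <- keep[apply(ph$tiles, 3L, function(t) any(t != 0))]
    xs[[length(xs) + 1L]] <- pl$tiles[, , keep, drop = FALSE]
    ys[[length(ys) + 1L]] <- ph$tiles[, , keep, drop = FALSE]
  }
  bind3 <- function(lst) {
    nt <- sum(vapply(lst, function(a) dim(a)[3L], integer(1L)))
    out <- array(0, c(patch_size, patch_size, nt))
    at <- 0L
    for (a in lst) {
      k <- dim(a)[3L]
      if (k > 0L) out[, , (at + 1L):(at + k)] <- a
      at <- at + k
    }
    out
  }
  list(x = tiles_to_batch(bind3(xs)), y = tiles_to_batch(bind3(ys)))
}

#' Train the enhancement model
#'
#' Adversarial training on matched (high-coverage, down-sampled) map
#' pairs. All maps must be normalized with one shared [fit_scale()]
#' record, which is stored in the returned checkpoint so inference can
#' invert it. Per step the discriminator is updated on a real batch
#' and a generated batch, then the generator is updated with the
#' four-term loss ([generator_loss()]). Validation metrics are
#' computed each epoch on the assembled enhanced validation maps, and
#' the returned checkpoint holds the epoch with the best
#' `selection_metric`. Fully reproducible for a fixed
#' `tcfg$seed`.
#'
#' @param train_pairs,val_pairs lists of `list(hr =, lr =)` pairs of
#'   normalized [contact_map()]s.
#' @param gcfg a [generator_config()].
#' @param dcfg a [discriminator_config()].
#' @param weights a [loss_weights()].
#' @param tcfg a [train_config()].
#' @param scale the shared `ScaleRecord` the maps were normalized with.
#' @param extractor perceptual feature extractor; default
#'   [feature_extractor_random()] seeded from `tcfg$seed`.
#' @param max_steps optional hard cap on generator update steps.
#' @param verbose print per-epoch progress.
#' @return An object of class `Checkpoint`: generator and
#'   discriminator (weights + configs), `weights`, `tcfg`, `scale`,
#'   `extractor`, per-epoch `history` (data.frame), and `best_epoch`.
#' @export
train_model <- function(train_pairs, val_pairs, gcfg, dcfg, weights, tcfg,
                        scale, extractor = NULL, max_steps = Inf,
                        verbose = FALSE) {
  if (length(train_pairs) == 0L) stop("empty training set")
  for (pr in c(train_pairs, val_pairs))
    if (!pr$hr$is_normalized || !pr$lr$is_normalized)
      stop("train_model expects maps normalized with a shared ScaleRecord")
  if (!inherits(scale, "ScaleRecord")) stop("scale must be a ScaleRecord")
  if (is.null(extractor))
    extractor <- feature_extractor_random(seed = tcfg$seed + 2L)

  set.seed(tcfg$seed)
  gen <- build_generator(gcfg, seed = tcfg$seed)
  disc <- build_discriminator(dcfg, seed = tcfg$seed + 1L)
  opt_g <- adam_init(gen$params)
  opt_d <- adam_init(disc$params)

  dat <- pairs_to_patches(train_pairs, tcfg$patch_size,
                          tcfg$drop_empty_patches)
  P <- dim(dat$x)[4L]
  bs <- min(tcfg$batch_size, P)
  numel_batch <- function(n) tcfg$patch_size^2 * n

  history <- NULL
  best <- list(metric = -Inf, epoch = NA_integer_, params = NULL)
  step <- 0L
  eps <- 1e-7
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample.int(P)
    nb <- floor(P / bs)
    ep <- c(d_loss = 0, g_loss = 0, mse = 0, vgg = 0, tv = 0, ad = 0)
    nsteps_ep <- 0L
    for (b in seq_len(nb)) {
      if (step >= max_steps) break
      idx <- ord[((b - 1L) * bs + 1L):(b * bs)]
      x <- dat$x[, , , idx, drop = FALSE]
      y <- dat$y[, , , idx, drop = FALSE]

      d_loss <- NA_real_
      if (tcfg$train_discriminator) {
        fake <- gen_fwd(gen, x, cache = FALSE)
        fr <- disc_fwd(disc, y, cache = TRUE)
        ff <- disc_fwd(disc, fake, cache = TRUE)
        d_loss <- discriminator_loss(fr$probs, ff$probs, eps = eps)
        if (!is.finite(d_loss))
          stop("discriminator loss diverged (non-finite) at step ", step + 1L)
        pr <- pmin(pmax(fr$probs, eps), 1 - eps)
        pf <- pmin(pmax(ff$probs, eps), 1 - eps)
        n <- length(idx)
        dp_real <- ifelse(fr$probs > eps & fr$probs < 1 - eps,
                          -1 / (n * pr), 0)
        dp_fake <- ifelse(ff$probs > eps & ff$probs < 1 - eps,
                          1 / (n * (1 - pf)), 0)
        gr <- disc_bwd(disc, fr, dp_real)$grads
        gf <- disc_bwd(disc, ff, dp_fake)$grads
        gd <- tree_map2(`+`, gr, gf)
        st <- adam_step(disc$params, gd, opt_d, tcfg$learning_rate,
                        tcfg$adam_betas)
        disc$params <- st$params; opt_d <- st$state
      }

      fwd <- gen_fwd(gen, x, cache = TRUE)
      fake <- fwd$y
      mse <- loss_mse(fake, y)
      g_fake <- 2 * (fake - y) / length(fake)

      exf <- extractor_forward(extractor, fake, cache = TRUE)
      ext <- extractor_forward(extractor, y, cache = FALSE)
      vgg <- mean((exf$f - ext)^2)
      if (weights$alpha > 0) {
        gfeat <- 2 * (exf$f - ext) / length(exf$f)
        g_fake <- g_fake + weights$alpha *
          extractor_backward(extractor, exf, gfeat)
      }

      tv <- loss_tv(fake, weights$psi)
      if (weights$beta > 0)
        g_fake <- g_fake + weights$beta * loss_tv_grad(fake, weights$psi)

      ad <- NA_real_
      if (weights$gamma > 0 && tcfg$train_discriminator) {
        fd <- disc_fwd(disc, fake, cache = TRUE)
        ad <- loss_adversarial(fd$probs)
        dp <- rep(-1 / length(fd$probs), length(fd$probs))
        g_fake <- g_fake + weights$gamma *
          disc_bwd(disc, fd, dp, need_gx = TRUE)$gx
      } else ad <- 0
      g_loss <- generator_loss(mse, vgg, tv, ad, weights)
      if (!is.finite(g_loss))
        stop("generator loss diverged (non-finite) at step ", step + 1L,
             " (mse=", mse, ", vgg=", vgg, ", tv=", tv, ", ad=", ad, ")")

      gg <- gen_bwd(gen, fwd, g_fake)$grads
      st <- adam_step(gen$params, gg, opt_g, tcfg$learning_rate,
                      tcfg$adam_betas)
      gen$params <- st$params; opt_g <- st$state

      step <- step + 1L
      nsteps_ep <- nsteps_ep + 1L
      ep <- ep + c(ifelse(is.na(d_loss), 0, d_loss), g_loss, mse, vgg, tv, ad)
    }
    if (nsteps_ep == 0L) break
    ep <- ep / nsteps_ep

    val <- validate_generator(gen, val_pairs, tcfg$patch_size)
    metric <- if (tcfg$selection_metric == "ssim") val["ssim"] else val["psnr"]
    if (is.finite(metric) && metric > best$metric)
      best <- list(metric = metric, epoch = epoch, params = gen$params)
    history <- rbind(history, data.frame(
      epoch = epoch, steps = step, d_loss = ep["d_loss"],
      g_loss = ep["g_loss"], mse = ep["mse"], vgg = ep["vgg"],
      tv = ep["tv"], ad = ep["ad"],
      val_ssim = unname(val["ssim"]), val_psnr = unname(val["psnr"]),
      row.names = NULL))
    if (verbose)
      message(sprintf("epoch %d: g_loss %.5f mse %.5f val_ssim %.4f",
                      epoch, ep["g_loss"], ep["mse"], val["ssim"]))
    if (step >= max_steps) break
  }
  if (!is.null(best$params)) gen$params <- best$params

  structure(list(generator = gen, discriminator = disc,
                 gcfg = gcfg, dcfg = dcfg, weights = weights, tcfg = tcfg,
                 scale = scale, extractor = extractor,
                 history = history,
                 best_epoch = best$epoch),
            class = "Checkpoint")
}

# Mean validation SSIM/PSNR of assembled enhanced maps (normalized
# domain, negatives clamped).
validate_generator <- function(gen, val_pairs, patch_size) {
  if (length(val_pairs) == 0L) return(c(ssim = NA_real_, psnr = NA_real_))
  ss <- ps <- numeric(0)
  for (pr in val_pairs) {
    enh <- enhance_normalized(gen, pr$lr, patch_size)
    ss <- c(ss, metric_ssim(enh, pr$hr))
    ps <- c(ps, metric_psnr(enh, pr$hr))
  }
  c(ssim = mean(ss), psnr = mean(ps))
}

# Patch-wise generator inference on a normalized map; returns the
# assembled normalized ContactMap with negatives clamped to 0.
enhance_normalized <- function(gen, lr_norm, patch_size, stride = patch_size,
                               chunk = 64L) {
  ps <- crop_patches(lr_norm, patch_size = patch_size, stride = stride)
  nt <- dim(ps$tiles)[3L]
  out <- ps$tiles
  at <- 1L
  while (at <= nt) {
    hi <- min(at + chunk - 1L, nt)
    batch <- tiles_to_batch(ps$tiles[, , at:hi, drop = FALSE])
    out[, , at:hi] <- batch_to_tiles(generator_forward(gen, batch))
    at <- hi + 1L
  }
  ps$tiles <- out
  m <- assemble_patches(ps)
  m$matrix <- pmax(m$matrix, 0)
  m
}

#' Enhance a raw low-coverage map with a trained checkpoint
#'
#' Full inference pipeline: normalize with the checkpoint's stored
#' scale, crop into patches (zero-padding the edges), run the
#' generator patch-wise, assemble the full matrix (averaging overlaps,
#' trimming the padding, symmetrizing), and invert the normalization
#' (clamping negatives to zero). Output has the same `n_bins` and
#' resolution as the input.
#'
#' @param ckpt a `Checkpoint` from [train_model()] (or any list with
#'   `generator`, `tcfg`, `scale`).
#' @param lr_map raw-count low-coverage [contact_map()].
#' @param stride inference patch stride; default the training patch
#'   size (non-overlapping). Smaller strides average overlapping
#'   predictions.
#' @return A raw-scale `ContactMap`, symmetric and non-negative.
#' @export
enhance_map <- function(ckpt, lr_map, stride = NULL) {
  if (!inherits(ckpt, "Checkpoint")) stop("ckpt must be a Checkpoint")
  validate_contact_map(lr_map)
  if (lr_map$is_normalized) stop("enhance_map expects a raw-count map")
  ps <- ckpt$tcfg$patch_size
  if (is.null(stride)) stride <- ps
  lrn <- apply_scale(lr_map, ckpt$scale)
  enh <- enhance_normalized(ckpt$generator, lrn, ps, stride = stride)
  invert_scale(enh, ckpt$scale)
}

#' Save or load a training checkpoint
#'
#' Single-file serialized container recording the generator and
#' discriminator weights plus every configuration and normalization
#' record needed to reproduce inference.
#'
#' @param ckpt a `Checkpoint`.
#' @param path file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `Checkpoint`.
#' @export
save_checkpoint <- function(ckpt, path) {
  if (!inherits(ckpt, "Checkpoint")) stop("ckpt must be a Checkpoint")
  tmp <- paste0(path, ".tmp")
  saveRDS(ckpt, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "Checkpoint")) stop(path, " does not hold a Checkpoint")
  ckpt
}

#' Write the per-epoch training history as TSV
#'
#' @param ckpt a `Checkpoint`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(ckpt, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(ckpt$history, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
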