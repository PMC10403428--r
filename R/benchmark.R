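#' Synthetic end-to-end enhancement benchmark
#'
#' Runs the whole pipeline under the package's reference synthetic
#' conditions: simulate single-cell-like maps (200 bins at 40 kb,
#' power-law decay 1.0, four planted TADs with enrichment 3, two
#' loops, 2e5 read pairs), down-sample to `ratio`, train a reduced
#' model (2 residual blocks, 16 feature channels, 16-channel
#' discriminator stem, batch 16), and score the held-out test maps:
#' SSIM, PSNR, insulation-L2 and random-walk concordance of the
#' enhanced maps against the originals, next to the same scores for
#' the unenhanced down-sampled maps. An enhancement method is doing
#' its job when the enhanced column beats the down-sampled baseline
#' on every metric.
#'
#' All randomness (map sampling, down-sampling, weight initialisation,
#' batch order) derives from `seed`.
#'
#' @param seed master integer seed.
#' @param n_train,n_val,n_test number of synthetic cells for training,
#'   validation (model selection) and held-out testing.
#' @param ratio down-sampling ratio (default 0.1).
#' @param epochs training epochs of the reduced model.
#' @param max_steps cap on generator update steps (default 500).
#' @param n_bins,read_depth synthetic map size and coverage.
#' @param window_bins insulation window for the TAD comparison.
#' @param verbose print per-epoch progress.
#' @return A list with `summary` (data.frame: metric, enhanced, lr),
#'   `checkpoint`, and `per_map` (data.frame of per-test-map scores).
#' @examples
#' \donttest{
#' bench <- synthetic_benchmark(seed = 1, n_train = 4, n_val = 1,
#'                              n_test = 2, epochs = 1, max_steps = 20)
#' bench$summary
#' }
#' @export
synthetic_benchmark <- function(seed = 1L, n_train = 30L, n_val = 4L,
                                n_test = 10L, ratio = 0.1, epochs = 10L,
                                max_steps = 500L, n_bins = 200L,
                                read_depth = 2e5, window_bins = 10L,
                                verbose = FALSE) {
  seed <- as.integer(seed)
  boundaries <- c(40L, 80L, 120L, 160L) * (n_bins %/% 200L)
  if (n_bins < 200L) boundaries <- as.integer(n_bins * c(0.2, 0.4, 0.6, 0.8))
  loops <- list(c(30, 70, 5), c(110, 150, 5))
  loops <- Filter(function(lp) lp[2] < n_bins, loops)
  cell_cfg <- function(s) synthetic_config(
    n_bins = n_bins, decay_exponent = 1.0, tad_boundaries = boundaries,
    tad_enrichment = 3, loops = loops, read_depth = read_depth, seed = s)

  total <- n_train + n_val + n_test
  pairs <- lapply(seq_len(total), function(i)
    make_pair(cell_cfg(seed * 1000L + i), ratio))
  tr_raw <- pairs[seq_len(n_train)]
  va_raw <- pairs[n_train + seq_len(n_val)]
  te_raw <- pairs[n_train + n_val + seq_len(n_test)]

  scale <- fit_scale(lapply(tr_raw, function(p) p$hr))
  norm <- function(p) list(hr = apply_scale(p$hr, scale),
                           lr = apply_scale(p$lr, scale))
  ckpt <- train_model(
    lapply(tr_raw, norm), lapply(va_raw, norm),
    gcfg = generator_config(feature_channels = 16L, n_res_blocks = 2L),
    dcfg = discriminator_config(stem_channels = 16L),
    weights = loss_weights(),
    tcfg = train_config(ratio = ratio, batch_size = 16L, epochs = epochs,
                        learning_rate = 1e-3, seed = seed),
    scale = scale, max_steps = max_steps, verbose = verbose)

  per_map <- NULL
  for (i in seq_along(te_raw)) {
    hr <- te_raw[[i]]$hr; lr <- te_raw[[i]]$lr
    enh <- enhance_map(ckpt, lr)
    hn <- apply_scale(hr, scale)
    en <- apply_scale(enh, scale)
    ln <- apply_scale(lr, scale)
    ins_h <- insulation_vector(hr, window_bins)
    per_map <- rbind(per_map, data.frame(
      map = i,
      ssim_enhanced = metric_ssim(en, hn),
      ssim_lr = metric_ssim(ln, hn),
      psnr_enhanced = metric_psnr(en, hn),
      psnr_lr = metric_psnr(ln, hn),
      insulation_l2_enhanced =
        insulation_l2(insulation_vector(enh, window_bins), ins_h),
      insulation_l2_lr =
        insulation_l2(insulation_vector(lr, window_bins), ins_h),
      concordance_enhanced = concordance_score(enh, hr),
      concordance_lr = concordance_score(lr, hr)))
  }
  summary <- data.frame(
    metric = c("ssim", "psnr", "insulation_l2", "concordance"),
    enhanced = c(mean(per_map$ssim_enhanced), mean(per_map$psnr_enhanced),
                 mean(per_map$insulation_l2_enhanced),
                 mean(per_map$concordance_enhanced)),
    lr = c(mean(per_map$ssim_lr), mean(per_map$psnr_lr),
           mean(per_map$insulation_l2_lr), mean(per_map$concordance_lr)))
  list(summary = summary, checkpoint = ckpt, per_map = per_map)
}
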