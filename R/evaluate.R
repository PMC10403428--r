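#' Image-metric configuration
#'
#' Parameters of the SSIM/PSNR computations: the SSIM regularisers
#' `c1 = (0.01)^2` and `c2 = (0.03)^2`, the Gaussian window (side 11,
#' sigma 1.5 — the standard reference parameters), and the PSNR peak
#' (1 for \[0, 1\]-scaled maps, so `PSNR = -10 * log10(MSE)`).
#'
#' @param c1,c2 positive SSIM stabilising constants.
#' @param ssim_window odd window side length in bins.
#' @param gaussian_sigma Gaussian window standard deviation.
#' @param psnr_peak peak signal value.
#' @return An object of class `MetricConfig`.
#' @export
metric_config <- function(c1 = 0.01^2, c2 = 0.03^2, ssim_window = 11L,
                          gaussian_sigma = 1.5, psnr_peak = 1) {
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive")
  ssim_window <- as.integer(ssim_window)
  if (ssim_window %% 2L != 1L) stop("ssim_window must be odd")
  structure(list(c1 = c1, c2 = c2, ssim_window = ssim_window,
                 gaussian_sigma = gaussian_sigma, psnr_peak = psnr_peak),
            class = "MetricConfig")
}

metric_matrices <- function(x, y, require_normalized = TRUE) {
  for (m in list(x, y)) if (!inherits(m, "ContactMap")) stop("not a ContactMap")
  if (x$n_bins != y$n_bins)
    stop("shape mismatch: ", x$n_bins, " vs ", y$n_bins, " bins")
  if (require_normalized && (!x$is_normalized || !y$is_normalized))
    stop("image metrics require [0,1]-normalized maps (see apply_scale)")
  list(x = x$matrix, y = y$matrix)
}

#' Mean squared error between two normalized maps
#'
#' @param x,y normalized [contact_map()]s of equal size.
#' @return Non-negative scalar: elementwise mean squared difference
#'   over the full matrix.
#' @export
metric_mse <- function(x, y) {
  m <- metric_matrices(x, y)
  mean((m$x - m$y)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `PSNR = 10 * log10(peak^2 / MSE)`; with the default peak of 1 on
#' normalized maps this is `-10 * log10(MSE)`. Identical maps give
#' `Inf` (the "infinite PSNR" sentinel).
#'
#' @param x,y normalized [contact_map()]s of equal size.
#' @param cfg a [metric_config()].
#' @return PSNR in decibels, or `Inf` when `x == y`.
#' @export
metric_psnr <- function(x, y, cfg = metric_config()) {
  mse <- metric_mse(x, y)
  if (mse == 0) return(Inf)
  10 * log10(cfg$psnr_peak^2 / mse)
}

# 2-D Gaussian window, normalised to sum 1.
gaussian_kernel <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 'valid' convolution of a matrix with a kernel via the conv engine.
filter_valid <- function(m, kern) {
  x <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  w <- array(kern, c(nrow(kern), ncol(kern), 1L, 1L))
  y <- .conv2d_fwd(x, w, 0, 1L, 0L)
  matrix(y, dim(y)[1L], dim(y)[2L])
}

#' Structural similarity index between two normalized maps
#'
#' Gaussian-weighted local means, variances and covariance are computed
#' with a moving window; the SSIM map
#' `(2*mux*muy + C1) * (2*sxy + C2) /
#'  ((mux^2 + muy^2 + C1) * (sx^2 + sy^2 + C2))`
#' is averaged over all valid window positions. Symmetric in `x` and
#' `y`; equals 1 iff the maps are identical.
#'
#' @param x,y normalized [contact_map()]s, at least as large as the
#'   window.
#' @param cfg a [metric_config()].
#' @return Scalar in \[-1, 1\].
#' @export
metric_ssim <- function(x, y, cfg = metric_config()) {
  m <- metric_matrices(x, y)
  if (x$n_bins < cfg$ssim_window)
    stop("map (", x$n_bins, " bins) smaller than SSIM window (",
         cfg$ssim_window, ")")
  k <- gaussian_kernel(cfg$ssim_window, cfg$gaussian_sigma)
  mux <- filter_valid(m$x, k)
  muy <- filter_valid(m$y, k)
  sxx <- filter_valid(m$x^2, k) - mux^2
  syy <- filter_valid(m$y^2, k) - muy^2
  sxy <- filter_valid(m$x * m$y, k) - mux * muy
  num <- (2 * mux * muy + cfg$c1) * (2 * sxy + cfg$c2)
  den <- (mux^2 + muy^2 + cfg$c1) * (sxx + syy + cfg$c2)
  mean(num / den)
}

#' Signal-to-noise ratio of an enhanced map against its target
#'
#' Ratio of the total clean signal in the target to the Euclidean norm
#' of the residual: `SNR = sum(y) / sqrt(sum((x - y)^2))`. Larger is
#' better; identical maps give `Inf`. Set `squared_denominator = TRUE`
#' for the alternative convention dividing by the summed squared
#' residual itself.
#'
#' @param x the noisy or enhanced [contact_map()].
#' @param y the target [contact_map()].
#' @param squared_denominator use the squared-residual denominator.
#' @return Non-negative scalar, or `Inf` when `x == y`.
#' @export
metric_snr <- function(x, y, squared_denominator = FALSE) {
  m <- metric_matrices(x, y, require_normalized = FALSE)
  ss <- sum((m$x - m$y)^2)
  if (ss == 0) return(Inf)
  den <- if (squared_denominator) ss else sqrt(ss)
  sum(m$y) / den
}

#' All four image metrics at once
#'
#' @param x enhanced or degraded map; `y` the target; both normalized.
#' @param y target [contact_map()].
#' @param cfg a [metric_config()].
#' @return An object of class `MetricsReport`: list with `mse`, `psnr`,
#'   `ssim`, `snr`.
#' @export
metrics_report <- function(x, y, cfg = metric_config()) {
  structure(list(mse = metric_mse(x, y),
                 psnr = metric_psnr(x, y, cfg),
                 ssim = metric_ssim(x, y, cfg),
                 snr = metric_snr(x, y)),
            class = "MetricsReport")
}

#' Insulation score profile of a contact map
#'
#' Slides a `window_bins x window_bins` window along the diagonal: the
#' raw score at bin `i` (0-based) is the mean of the sub-matrix
#' spanning rows `[i - window_bins, i)` and columns
#' `(i, i + window_bins]` — the contact density crossing bin `i`. Raw
#' scores are normalised as `log2(raw / mean(raw over valid bins))`;
#' local minima of the profile mark TAD boundaries. Bins within
#' `window_bins` of either end, or whose window is empty (raw 0), are
#' marked invalid.
#'
#' @param map a [contact_map()] (raw or normalized).
#' @param window_bins window size in bins (default 10, i.e. 400 kb at
#'   40 kb resolution).
#' @return An object of class `InsulationProfile`: list with
#'   `window_bins`, `scores` (length `n_bins`, `NA` where invalid) and
#'   logical `valid`.
#' @export
insulation_vector <- function(map, window_bins = 10L) {
  if (!inherits(map, "ContactMap")) stop("not a ContactMap")
  w <- as.integer(window_bins)
  if (w < 1L) stop("window_bins must be >= 1")
  n <- map$n_bins
  if (n <= 2L * w)
    stop("map too small for window: need n_bins > ", 2L * w)
  m <- map$matrix
  raw <- rep(NA_real_, n)
  for (i0 in w:(n - w - 1L)) {
    rows <- (i0 - w + 1L):i0
    cols <- (i0 + 2L):(i0 + w + 1L)
    raw[i0 + 1L] <- mean(m[rows, cols])
  }
  valid <- !is.na(raw) & raw > 0
  scores <- rep(NA_real_, n)
  if (any(valid)) {
    mu <- mean(raw[valid])
    scores[valid] <- log2(raw[valid] / mu)
  }
  structure(list(window_bins = w, scores = scores, valid = valid),
            class = "InsulationProfile")
}

#' L2 dissimilarity between two insulation profiles
#'
#' Euclidean norm of the difference of the normalised scores over bins
#' valid in both profiles. Smaller values indicate better agreement of
#' TAD structure.
#'
#' @param a,b `InsulationProfile`s with matching window and length.
#' @return Non-negative scalar.
#' @export
insulation_l2 <- function(a, b) {
  for (p in list(a, b)) if (!inherits(p, "InsulationProfile"))
    stop("not an InsulationProfile")
  if (a$window_bins != b$window_bins) stop("window size mismatch")
  if (length(a$scores) != length(b$scores)) stop("profile length mismatch")
  idx <- a$valid & b$valid
  sqrt(sum((a$scores[idx] - b$scores[idx])^2))
}

#' Random-walk concordance between two contact maps
#'
#' A GenomeDISCO-style reproducibility score: each map is
#' row-normalised to a transition matrix (all-zero rows stay zero),
#' raised to the `t_steps`-th power (a `t_steps`-step random-walk
#' smoothing), re-normalised to unit total mass, and compared by L1
#' distance: `score = 1 - 0.5 * sum(|A - B|)`. The score is symmetric,
#' at most 1, equals 1 iff the smoothed maps coincide, and 0 for maps
#' with disjoint support. It follows the random-walk idea of the
#' published tool but is not bit-compatible with it.
#'
#' @param a,b [contact_map()]s of equal size, not all-zero.
#' @param t_steps number of random-walk steps (default 3).
#' @return Scalar in \[0, 1\] (up to symmetrisation round-off).
#' @export
concordance_score <- function(a, b, t_steps = 3L) {
  m <- metric_matrices(a, b, require_normalized = FALSE)
  t_steps <- as.integer(t_steps)
  if (t_steps < 1L) stop("t_steps must be >= 1")
  smooth <- function(mm) {
    rs <- rowSums(mm)
    if (all(rs == 0)) stop("all-zero map has no random-walk representation")
    p <- mm / ifelse(rs == 0, 1, rs)
    pt <- p
    if (t_steps > 1L) for (k in 2:t_steps) pt <- pt %*% p
    pt / sum(pt)
  }
  1 - 0.5 * sum(abs(smooth(m$x) - smooth(m$y)))
}

#' Full evaluation report for an enhanced map
#'
#' Computes the image metrics, insulation L2 and concordance of a
#' predicted map against the target, and (optionally) of the
#' unenhanced low-coverage map against the same target as a baseline.
#' Raw-count inputs are normalized with a shared cap fitted on the
#' target.
#'
#' @param pred enhanced [contact_map()] (raw counts).
#' @param target original high-coverage map (raw counts).
#' @param lr optional unenhanced low-coverage map (raw counts).
#' @param window_bins insulation window (default 10).
#' @param t_steps random-walk steps for the concordance (default 3).
#' @param cfg a [metric_config()].
#' @return `data.frame` with one row per comparison (`pred_vs_target`,
#'   `lr_vs_target`) and columns `mse`, `psnr`, `ssim`, `snr`,
#'   `insulation_l2`, `concordance`.
#' @export
evaluate_maps <- function(pred, target, lr = NULL, window_bins = 10L,
                          t_steps = 3L, cfg = metric_config()) {
  scale <- fit_scale(target)
  tn <- apply_scale(target, scale)
  ins_t <- insulation_vector(target, window_bins)
  one <- function(m, label) {
    mn <- if (m$is_normalized) m else apply_scale(m, scale)
    data.frame(comparison = label,
               mse = metric_mse(mn, tn),
               psnr = metric_psnr(mn, tn, cfg),
               ssim = metric_ssim(mn, tn, cfg),
               snr = metric_snr(mn, tn),
               insulation_l2 = insulation_l2(insulation_vector(m, window_bins),
                                             ins_t),
               concordance = concordance_score(m, target, t_steps))
  }
  out <- one(pred, "pred_vs_target")
  if (!is.null(lr)) out <- rbind(out, one(lr, "lr_vs_target"))
  out
}
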