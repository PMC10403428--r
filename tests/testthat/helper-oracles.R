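# Independent brute-force reference implementations (oracles) used by
# the unit and acceptance tests; deliberately written as direct loops,
# independent of the package's computational route.

ssim_oracle <- function(X, Y, win = 11L, sigma = 1.5, c1 = 1e-4, c2 = 9e-4) {
  r <- (win - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  n <- nrow(X)
  vals <- c()
  for (i in 1:(n - win + 1)) for (j in 1:(n - win + 1)) {
    wx <- X[i:(i + win - 1), j:(j + win - 1)]
    wy <- Y[i:(i + win - 1), j:(j + win - 1)]
    mx <- sum(k * wx); my <- sum(k * wy)
    sx <- sum(k * wx^2) - mx^2; sy <- sum(k * wy^2) - my^2
    sxy <- sum(k * wx * wy) - mx * my
    vals <- c(vals, (2 * mx * my + c1) * (2 * sxy + c2) /
                ((mx^2 + my^2 + c1) * (sx + sy + c2)))
  }
  mean(vals)
}

insulation_oracle <- function(M, w) {
  n <- nrow(M)
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {   # 1-based centre bin
    s <- 0
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) s <- s + M[a, b]
    raw[i] <- s / (w * w)
  }
  valid <- !is.na(raw) & raw > 0
  sc <- rep(NA_real_, n)
  sc[valid] <- log2(raw[valid] / mean(raw[valid]))
  list(scores = sc, valid = valid)
}

concordance_oracle <- function(A, B, t) {
  sm <- function(M) {
    P <- M
    for (i in seq_len(nrow(M))) {
      rs <- sum(M[i, ])
      if (rs > 0) P[i, ] <- M[i, ] / rs
    }
    Pt <- diag(nrow(M))
    for (s in seq_len(t)) Pt <- Pt %*% P
    Pt / sum(Pt)
  }
  1 - 0.5 * sum(abs(sm(A) - sm(B)))
}

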