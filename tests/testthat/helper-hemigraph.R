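# Shared test utilities: small data generators and independent oracles.

# Random labelled window array with the full 19-channel montage.
random_windows <- function(n, t_len = 64, seed = 1) {
  set.seed(seed)
  x <- array(rnorm(19 * t_len * n), c(19, t_len, n))
  y <- factor(rep(c("HC", "MDD"), length.out = n), levels = c("HC", "MDD"))
  list(x = x, y = y)
}

# Periodogram band power of one channel (independent spectral oracle).
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(sp[f >= lo & f <= hi & f <= fs / 2])
}

# Brute-force cosine Top-K adjacency: explicit normalisation, full sort,
# independent of the package implementation.
brute_adjacency <- function(x, k) {
  n <- nrow(x)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ni <- sqrt(sum(x[i, ]^2)); nj <- sqrt(sum(x[j, ]^2))
    s[i, j] <- if (ni > 1e-12 && nj > 1e-12)
      sum(x[i, ] * x[j, ]) / (ni * nj) else 0
  }
  s[s < 0] <- 0
  diag(s) <- 0
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(-s[i, ], seq_len(n))
    kept <- 0
    for (j in ord) {
      if (s[i, j] <= 0 || kept >= k) break
      a[i, j] <- s[i, j]
      kept <- kept + 1
    }
  }
  pmax(a, t(a))
}

# Dense polynomial-in-matrix Chebyshev oracle via explicit matrix powers.
brute_cheb <- function(x, laplacian, coeffs, order) {
  lt <- laplacian - diag(nrow(laplacian))
  n <- nrow(lt)
  Ts <- list(diag(n), lt)
  if (order >= 3)
    for (p in 3:order)
      Ts[[p]] <- 2 * lt %*% Ts[[p - 1]] - Ts[[p - 2]]
  out <- 0
  for (p in seq_len(order)) out <- out + Ts[[p]] %*% x %*% coeffs[, , p]
  out
}

# Tiny in-memory synthetic cohort ready for windowing.
tiny_cohort <- function(n_pairs = 2, duration = 10, effect = 1, snr = 1,
                        seed = 5) {
  generate_cohort(synth_spec(n_pairs = n_pairs, duration = duration,
                             asymmetry_effect = effect, snr = snr,
                             seed = seed))
}
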