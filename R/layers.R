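# Internal differentiable layer primitives. Each *_fwd returns list(y, cache);
# each *_bwd consumes the upstream gradient and the cache. Batches of windows
# are arrays (C x T x B); feature matrices put samples in rows.

.elu_fwd <- function(x) {
  neg <- x <= 0
  y <- x
  y[neg] <- exp(x[neg]) - 1
  list(y = y, cache = list(y = y, neg = neg))
}
.elu_bwd <- function(dy, cache) {
  d <- dy
  d[cache$neg] <- dy[cache$neg] * (cache$y[cache$neg] + 1)
  d
}

.relu_fwd <- function(x) {
  y <- pmax(x, 0)
  list(y = y, cache = y > 0)
}
.relu_bwd <- function(dy, cache) dy * cache

# Batch normalization per channel over (time x batch). x is C x M (M = T*B).
.bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                    momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(x)
    v <- rowMeans(x^2) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * invstd
  y <- gamma * xhat + beta
  list(y = y, run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    training = training))
}

.bn_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  m <- ncol(xhat)
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  if (cache$training) {
    dx <- (cache$gamma * cache$invstd / m) *
      (m * dy - dbeta - xhat * dgamma)
  } else {
    dx <- dy * cache$gamma * cache$invstd
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Layer normalization over the feature axis. x is n x F (each row one
# feature vector); gamma/beta length F.
.ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans(x^2) - mu^2
  invstd <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * invstd
  y <- sweep(xhat, 2, gamma, `*`)
  y <- sweep(y, 2, beta, `+`)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma))
}

.ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  f <- ncol(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, `*`)
  dx <- cache$invstd / f *
    (f * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Column-wise softmax (over rows, per column).
.softmax_cols <- function(s) {
  s <- sweep(s, 2, apply(s, 2, max))
  e <- exp(s)
  sweep(e, 2, colSums(e), `/`)
}

# Backward of column-wise softmax: ds = p * (dp - colsum(p * dp))
.softmax_cols_bwd <- function(dp, p) {
  p * sweep(dp, 2, colSums(p * dp))
}

# Row-wise softmax (per sample in rows).
.softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}
.softmax_rows_bwd <- function(dp, p) {
  p * (dp - rowSums(p * dp))
}

.dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0)
    return(list(y = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, cache = mask)
}
.dropout_bwd <- function(dy, cache) if (is.null(cache)) dy else dy * cache

# Softmax cross-entropy on logits (B x 2); y integer class index (1-based).
.ce_loss <- function(logits, y) {
  p <- .softmax_rows(logits)
  b <- nrow(logits)
  idx <- cbind(seq_len(b), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / b, prob = p)
}
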