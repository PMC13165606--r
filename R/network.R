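# Full network: multi-scale temporal filter bank -> per-region cosine Top-K
# graphs -> per-node temporal embedding with time attention -> two residual
# Chebyshev graph-convolution blocks -> node pooling -> region-attention
# fusion -> layer norm -> linear classifier. Forward/backward are written
# out by hand; gradients are exercised by finite-difference tests.

.unif_init <- function(dims, fan_in) {
  a <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -a, a), dim = dims)
}

# Build parameter and buffer trees for a given configuration.
.init_network <- function(cfg) {
  C <- cfg$n_channels
  kset <- vapply(cfg$scales, kernel_length, 0, fs = cfg$sampling_rate)
  mstf <- lapply(kset, function(k) list(
    w = .unif_init(c(C, k), k),
    gamma = rep(1, C), beta = rep(0, C)))
  mstf_buf <- lapply(kset, function(k) list(
    run_mean = rep(0, C), run_var = rep(1, C)))

  C1 <- cfg$c1; C2 <- cfg$c2; T1 <- cfg$t1; ke <- cfg$embed_kernel
  regions <- lapply(cfg$region_sizes, function(N) {
    cheb <- lapply(seq_len(cfg$cheb_layers), function(l) list(
      theta = .unif_init(c(T1, T1, cfg$cheb_order), T1 * cfg$cheb_order),
      ln_g = rep(1, T1), ln_b = rep(0, T1)))
    list(w1 = .unif_init(c(C1, ke, N), ke),
         b1 = array(0, c(C1, N)),
         w2 = .unif_init(c(C2, C1 * ke, N), C1 * ke),
         b2 = array(0, c(C2, N)),
         u = .unif_init(c(C2, N), C2),
         bu = rep(0, N),
         wl = .unif_init(c(T1, C2), C2),
         bl = rep(0, T1),
         cheb = cheb)
  })
  R <- length(cfg$region_sizes)
  D <- if (cfg$fusion == "concat_mlp") R * T1 else T1
  # scoring and classifier heads start at zero: fusion begins as an even
  # average and logits at zero, which stabilises the first optimizer steps
  fusion <- list(ws = rep(0, T1), bs = 0,
                 ln_g = rep(1, D), ln_b = rep(0, D),
                 wc = array(0, c(2, D)), bc = rep(0, 2))
  list(params = list(mstf = mstf, regions = regions, fusion = fusion),
       buffers = list(mstf = mstf_buf),
       kernels = kset)
}

# Chebyshev basis matrices T_0..T_{order-1} of the scaled Laplacian.
.cheb_basis <- function(lt, order) {
  n <- nrow(lt)
  Ts <- vector("list", order)
  Ts[[1]] <- diag(n)
  if (order >= 2) Ts[[2]] <- lt
  if (order >= 3)
    for (p in 3:order) Ts[[p]] <- 2 * (lt %*% Ts[[p - 1]]) - Ts[[p - 2]]
  Ts
}

# Node-wise temporal embedding for one region (heavy lifting in C++; the
# backward pass recomputes the activations from the cached region input).
.node_embed_fwd <- function(xi, rp, cfg) {
  cpp_embed_fwd(xi, rp$w1, rp$b1, rp$w2, rp$b2, rp$u, rp$bu, rp$wl, rp$bl,
                cfg$embed_kernel, single = isTRUE(cfg$single))
}

# One residual Chebyshev block layer on concatenated node rows.
# xcat is (B*N) x T1 with node index fastest; Tb[[b]] are basis matrices.
.cheb_layer_fwd <- function(xcat, Tb, lp, cfg, training, N, B) {
  order <- cfg$cheb_order
  Zs <- vector("list", order)
  Zs[[1]] <- xcat
  for (p in seq_len(order)[-1]) {
    z <- matrix(0, nrow(xcat), ncol(xcat))
    for (b in seq_len(B)) {
      rows <- ((b - 1) * N + 1):(b * N)
      z[rows, ] <- Tb[[b]][[p]] %*% xcat[rows, , drop = FALSE]
    }
    Zs[[p]] <- z
  }
  cpre <- matrix(0, nrow(xcat), ncol(xcat))
  for (p in seq_len(order)) cpre <- cpre + Zs[[p]] %*% lp$theta[, , p]
  act <- pmax(cpre, 0)
  dp <- .dropout_fwd(act, cfg$dropout, training)
  ln <- .ln_fwd(xcat + dp$y, lp$ln_g, lp$ln_b)
  list(y = ln$y,
       cache = list(Zs = Zs, relu_mask = cpre > 0, drop = dp$cache,
                    ln = ln$cache, xin = xcat))
}

.cheb_layer_bwd <- function(dy, cache, Tb, lp, cfg, N, B) {
  order <- cfg$cheb_order
  lnb <- .ln_bwd(dy, cache$ln)
  dres <- lnb$dx
  dxin <- dres
  dact <- .dropout_bwd(dres, cache$drop)
  dc <- dact * cache$relu_mask
  dtheta <- array(0, dim(lp$theta))
  for (p in seq_len(order)) {
    dtheta[, , p] <- crossprod(cache$Zs[[p]], dc)
    g <- dc %*% t(lp$theta[, , p])
    if (p == 1) {
      dxin <- dxin + g
    } else {
      for (b in seq_len(B)) {
        rows <- ((b - 1) * N + 1):(b * N)
        dxin[rows, ] <- dxin[rows, ] + Tb[[b]][[p]] %*% g[rows, , drop = FALSE]
      }
    }
  }
  list(dx = dxin, dtheta = dtheta, dln_g = lnb$dgamma, dln_b = lnb$dbeta)
}

# Full forward pass. x: (C x T x B). Returns logits (B x 2), cache, and
# updated batch-norm buffers. `graphs` optionally supplies precomputed
# per-region Chebyshev bases (list over regions of lists over samples),
# bypassing adjacency construction; the graphs are a non-differentiable
# function of the filtered signal either way.
.network_fwd <- function(params, buffers, x, cfg, training = FALSE,
                         graphs = NULL) {
  d <- dim(x); C <- d[1]; T <- d[2]; B <- d[3]
  M <- length(params$mstf)
  x1m <- 0
  mstf_cache <- vector("list", M)
  for (m in seq_len(M)) {
    pm <- params$mstf[[m]]
    z <- cpp_dwconv_fwd(x, pm$w)
    zm <- matrix(z, C, T * B)
    bn <- .bn_fwd(zm, pm$gamma, pm$beta, buffers$mstf[[m]]$run_mean,
                  buffers$mstf[[m]]$run_var, training)
    if (training) {
      buffers$mstf[[m]]$run_mean <- bn$run_mean
      buffers$mstf[[m]]$run_var <- bn$run_var
    }
    el <- .elu_fwd(bn$y)
    x1m <- x1m + el$y
    mstf_cache[[m]] <- list(bn = bn$cache, elu = el$cache)
  }
  x1m <- x1m / M
  x1 <- array(x1m, c(C, T, B))

  nR <- length(cfg$region_index)
  region_cache <- vector("list", nR)
  pooled <- vector("list", nR)
  for (r in seq_len(nR)) {
    idx <- cfg$region_index[[r]]
    N <- length(idx)
    xi <- x1[idx, , , drop = FALSE]
    dim(xi) <- c(N, T, B)
    if (is.null(graphs)) {
      Tb <- vector("list", B)
      for (b in seq_len(B)) {
        a <- build_adjacency(matrix(xi[, , b], N, T), cfg$top_k,
                             cfg$symmetrize)
        lt <- normalized_laplacian(a) - diag(N)
        Tb[[b]] <- .cheb_basis(lt, cfg$cheb_order)
      }
    } else Tb <- graphs[[r]]
    emb <- .node_embed_fwd(xi, params$regions[[r]], cfg)
    xcat <- matrix(aperm(emb$E, c(1, 3, 2)), N * B, cfg$t1)
    layer_caches <- vector("list", cfg$cheb_layers)
    h <- xcat
    for (l in seq_len(cfg$cheb_layers)) {
      lf <- .cheb_layer_fwd(h, Tb, params$regions[[r]]$cheb[[l]], cfg,
                            training, N, B)
      h <- lf$y
      layer_caches[[l]] <- lf$cache
    }
    xout <- array(h, c(N, B, cfg$t1))
    pooled[[r]] <- colMeans(xout)                 # mean over nodes -> B x T1
    dim(pooled[[r]]) <- c(B, cfg$t1)
    region_cache[[r]] <- list(xi = xi, Tb = Tb, S = emb$S, H5 = emb$H5,
                              layers = layer_caches, N = N)
  }

  fp <- params$fusion
  fus <- .fusion_fwd(pooled, fp, cfg$fusion)
  ln <- .ln_fwd(fus$y, fp$ln_g, fp$ln_b)
  logits <- ln$y %*% t(fp$wc)
  logits <- sweep(logits, 2, fp$bc, `+`)
  list(logits = logits, buffers = buffers,
       cache = list(x = x, x1m = x1m, mstf = mstf_cache,
                    regions = region_cache, pooled = pooled,
                    fusion = fus$cache, ln_in = fus$y, ln = ln$cache,
                    ln_y = ln$y, T = T, B = B))
}

.fusion_fwd <- function(pooled, fp, strategy) {
  R <- length(pooled)
  B <- nrow(pooled[[1]])
  if (strategy == "attn") {
    sc <- vapply(pooled, function(p) as.vector(p %*% fp$ws) + fp$bs,
                 numeric(B))
    dim(sc) <- c(B, R)
    w <- .softmax_rows(sc)
    y <- 0
    for (r in seq_len(R)) y <- y + w[, r] * pooled[[r]]
    list(y = y, cache = list(strategy = strategy, w = w, pooled = pooled))
  } else if (strategy == "avg") {
    y <- Reduce(`+`, pooled) / R
    list(y = y, cache = list(strategy = strategy, R = R))
  } else if (strategy == "max") {
    y <- pooled[[1]]
    amax <- matrix(1L, nrow(y), ncol(y))
    if (R > 1) for (r in 2:R) {
      upd <- pooled[[r]] > y
      amax[upd] <- r
      y[upd] <- pooled[[r]][upd]
    }
    list(y = y, cache = list(strategy = strategy, amax = amax))
  } else if (strategy == "concat_mlp") {
    list(y = do.call(cbind, pooled),
         cache = list(strategy = strategy, R = R, t1 = ncol(pooled[[1]])))
  } else stop("unknown fusion strategy: ", strategy)
}

.fusion_bwd <- function(dy, cache, fp) {
  st <- cache$strategy
  if (st == "attn") {
    w <- cache$w; pooled <- cache$pooled; R <- ncol(w)
    dpooled <- vector("list", R)
    dw <- matrix(0, nrow(w), R)
    for (r in seq_len(R)) {
      dpooled[[r]] <- w[, r] * dy
      dw[, r] <- rowSums(dy * pooled[[r]])
    }
    dsc <- .softmax_rows_bwd(dw, w)
    dws <- 0; dbs <- 0
    for (r in seq_len(R)) {
      dpooled[[r]] <- dpooled[[r]] + outer(dsc[, r], fp$ws)
      dws <- dws + as.vector(crossprod(pooled[[r]], dsc[, r]))
      dbs <- dbs + sum(dsc[, r])
    }
    list(dpooled = dpooled, dws = dws, dbs = dbs)
  } else if (st == "avg") {
    list(dpooled = replicate(cache$R, dy / cache$R, simplify = FALSE),
         dws = 0, dbs = 0)
  } else if (st == "max") {
    R <- max(cache$amax)
    list(dpooled = lapply(seq_len(R), function(r) dy * (cache$amax == r)),
         dws = 0, dbs = 0)
  } else {
    t1 <- cache$t1
    list(dpooled = lapply(seq_len(cache$R), function(r)
      dy[, ((r - 1) * t1 + 1):(r * t1), drop = FALSE]),
         dws = 0, dbs = 0)
  }
}

# Backward through one region's node embedding (C++, recomputes
# activations from the cached region input).
.node_embed_bwd <- function(dE, rc, rp, cfg) {
  bw <- cpp_embed_bwd(rc$xi, rp$w1, rp$b1, rp$w2, rp$b2, rp$u, rp$bu,
                      rp$wl, rc$S, rc$H5, dE, cfg$embed_kernel,
                      single = isTRUE(cfg$single))
  list(grads = list(w1 = bw$dw1, b1 = bw$db1, w2 = bw$dw2, b2 = bw$db2,
                    u = bw$du, bu = as.vector(bw$dbu), wl = bw$dwl,
                    bl = as.vector(bw$dbl)),
       dxi = bw$dxi)
}

# Full backward pass; returns the gradient tree.
.network_bwd <- function(params, cache, dlogits, cfg) {
  T <- cache$T; B <- cache$B
  C <- dim(cache$x)[1]
  M <- length(params$mstf)
  fp <- params$fusion
  g_fus <- list(ws = 0, bs = 0, ln_g = 0, ln_b = 0, wc = 0, bc = 0)

  g_fus$wc <- crossprod(dlogits, cache$ln_y)
  g_fus$bc <- colSums(dlogits)
  dlny <- dlogits %*% fp$wc
  lnb <- .ln_bwd(dlny, cache$ln)
  g_fus$ln_g <- lnb$dgamma; g_fus$ln_b <- lnb$dbeta
  fb <- .fusion_bwd(lnb$dx, cache$fusion, fp)
  g_fus$ws <- fb$dws; g_fus$bs <- fb$dbs

  dx1m <- matrix(0, C, T * B)
  g_regions <- vector("list", length(cfg$region_index))
  for (r in seq_along(cfg$region_index)) {
    rc <- cache$regions[[r]]
    rp <- params$regions[[r]]
    N <- rc$N
    dpool <- fb$dpooled[[r]]                     # B x T1
    dxcat <- (1 / N) * dpool[rep(seq_len(B), each = N), , drop = FALSE]
    g_cheb <- vector("list", cfg$cheb_layers)
    for (l in rev(seq_len(cfg$cheb_layers))) {
      lb <- .cheb_layer_bwd(dxcat, rc$layers[[l]], rc$Tb,
                            rp$cheb[[l]], cfg, N, B)
      dxcat <- lb$dx
      g_cheb[[l]] <- list(theta = lb$dtheta, ln_g = lb$dln_g,
                          ln_b = lb$dln_b)
    }
    dE <- aperm(array(dxcat, c(N, B, cfg$t1)), c(1, 3, 2))
    nb <- .node_embed_bwd(dE, rc, rp, cfg)
    g <- nb$grads
    g$cheb <- g_cheb
    g_regions[[r]] <- g
    idx <- cfg$region_index[[r]]
    dxi_m <- matrix(nb$dxi, N, T * B)
    dx1m[idx, ] <- dx1m[idx, ] + dxi_m
  }

  g_mstf <- vector("list", M)
  for (m in seq_len(M)) {
    mc <- cache$mstf[[m]]
    de <- dx1m / M
    dbn <- .elu_bwd(de, mc$elu)
    bnb <- .bn_bwd(dbn, mc$bn)
    dz <- array(bnb$dx, c(C, T, B))
    cw <- cpp_dwconv_bwd(cache$x, params$mstf[[m]]$w, dz, need_dx = FALSE)
    g_mstf[[m]] <- list(w = cw$dw, gamma = bnb$dgamma, beta = bnb$dbeta)
  }
  list(mstf = g_mstf, regions = g_regions, fusion = g_fus)
}

# ---- Adam over the parameter tree ------------------------------------------

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- .tree_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

.adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- state$m; vh <- state$v
  upd <- .tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    mh, vh)
  params <- .tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
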