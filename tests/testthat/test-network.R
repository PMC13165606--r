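# Whole-model checks: analytic gradients against finite differences, the
# hemispheric permutation property of the region pipeline, and determinism
# of the fitting procedure.

small_cfg <- function(...) {
  cfg <- hemigraph_config(scales = 0.1, precision = "double", seed = 3, ...)
  cfg <- hemigraph:::.resolve_config(cfg)
  cfg$t1 <- 12; cfg$c1 <- 4; cfg$c2 <- 6
  cfg
}

test_that("analytic gradients match finite differences everywhere", {
  cfg <- small_cfg()
  set.seed(11)
  net <- hemigraph:::.init_network(cfg)
  # non-degenerate heads so their gradients are informative
  net$params$fusion$wc <- hemigraph:::.unif_init(c(2, cfg$t1), cfg$t1)
  net$params$fusion$ws <- hemigraph:::.unif_init(cfg$t1, cfg$t1)
  B <- 3; tl <- 64
  x <- array(rnorm(19 * tl * B), c(19, tl, B))
  y <- c(1L, 2L, 2L)
  fw <- hemigraph:::.network_fwd(net$params, net$buffers, x, cfg)
  graphs <- lapply(fw$cache$regions, function(rc) rc$Tb)
  ce <- hemigraph:::.ce_loss(fw$logits, y)
  gr <- hemigraph:::.network_bwd(net$params, fw$cache, ce$dlogits, cfg)
  loss_at <- function(params) {
    f <- hemigraph:::.network_fwd(params, net$buffers, x, cfg,
                                  graphs = graphs)
    hemigraph:::.ce_loss(f$logits, y)$loss
  }
  # central differences cross ReLU kinks occasionally, so compare with a
  # scaled tolerance rather than exact equality
  check <- function(get, set, gval, n = 4, eps = 1e-5) {
    arr <- get(net$params)
    idx <- sample(length(arr), min(n, length(arr)))
    for (i in idx) {
      a1 <- arr; a1[i] <- a1[i] + eps
      a2 <- arr; a2[i] <- a2[i] - eps
      num <- (loss_at(set(net$params, a1)) - loss_at(set(net$params, a2))) /
        (2 * eps)
      expect_lt(abs(gval[i] - num) / max(1e-3, abs(num) + abs(gval[i])),
                2e-3)
    }
  }
  set.seed(12)
  check(function(p) p$mstf[[1]]$w, function(p, a) { p$mstf[[1]]$w <- a; p },
        gr$mstf[[1]]$w)
  check(function(p) p$mstf[[1]]$gamma,
        function(p, a) { p$mstf[[1]]$gamma <- a; p }, gr$mstf[[1]]$gamma)
  check(function(p) p$mstf[[1]]$beta,
        function(p, a) { p$mstf[[1]]$beta <- a; p }, gr$mstf[[1]]$beta)
  for (r in 1:2) {
    for (nm in c("w1", "b1", "w2", "b2", "u", "bu", "wl", "bl")) {
      check(function(p) p$regions[[r]][[nm]],
            function(p, a) { p$regions[[r]][[nm]] <- a; p },
            gr$regions[[r]][[nm]])
    }
    for (l in 1:2) {
      check(function(p) p$regions[[r]]$cheb[[l]]$theta,
            function(p, a) { p$regions[[r]]$cheb[[l]]$theta <- a; p },
            gr$regions[[r]]$cheb[[l]]$theta)
      check(function(p) p$regions[[r]]$cheb[[l]]$ln_g,
            function(p, a) { p$regions[[r]]$cheb[[l]]$ln_g <- a; p },
            gr$regions[[r]]$cheb[[l]]$ln_g)
    }
  }
  for (nm in c("ws", "bs", "ln_g", "ln_b", "wc", "bc")) {
    check(function(p) p$fusion[[nm]],
          function(p, a) { p$fusion[[nm]] <- a; p }, gr$fusion[[nm]])
  }
})

# One region of the graph pipeline: adjacency, embedding, Chebyshev block,
# node pooling — run in double precision.
region_embedding <- function(xi_mat, rp, cfg) {
  N <- nrow(xi_mat)
  xi <- array(xi_mat, c(N, ncol(xi_mat), 1))
  lt <- normalized_laplacian(build_adjacency(xi_mat, cfg$top_k)) - diag(N)
  Tb <- list(hemigraph:::.cheb_basis(lt, cfg$cheb_order))
  emb <- hemigraph:::.node_embed_fwd(xi, rp, cfg)
  h <- matrix(emb$E[, , 1], N, cfg$t1)
  for (l in seq_along(rp$cheb))
    h <- hemigraph:::.cheb_layer_fwd(h, Tb, rp$cheb[[l]], cfg, FALSE, N, 1)$y
  colMeans(h)
}

test_that("hemisphere channel permutation leaves the region embedding fixed", {
  cfg <- hemigraph:::.resolve_config(
    hemigraph_config(precision = "double", seed = 5))
  set.seed(21)
  net <- hemigraph:::.init_network(cfg)
  rp <- net$params$regions[[1]]
  xi <- matrix(rnorm(11 * 512), 11, 512)
  base <- region_embedding(xi, rp, cfg)
  for (s in 1:5) {
    set.seed(30 + s)
    perm <- sample(11)
    rp2 <- rp
    rp2$w1 <- rp$w1[, , perm, drop = FALSE]
    rp2$b1 <- rp$b1[, perm, drop = FALSE]
    rp2$w2 <- rp$w2[, , perm, drop = FALSE]
    rp2$b2 <- rp$b2[, perm, drop = FALSE]
    rp2$u <- rp$u[, perm, drop = FALSE]
    rp2$bu <- rp$bu[perm]
    out <- region_embedding(xi[perm, ], rp2, cfg)
    expect_equal(out, base, tolerance = 1e-6)
  }
})

test_that("fitting is deterministic given the seed", {
  d <- random_windows(12, t_len = 64, seed = 31)
  cfg <- hemigraph_config(scales = 0.1, max_epochs = 2, batch_size = 4,
                          seed = 17)
  f1 <- hemigraph(d$x, d$y, cfg)
  f2 <- hemigraph(d$x, d$y, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})

test_that("predictions come back as classes, probabilities or scores", {
  d <- random_windows(8, t_len = 64, seed = 32)
  cfg <- hemigraph_config(scales = 0.1, max_epochs = 1, batch_size = 4,
                          seed = 2)
  fit <- hemigraph(d$x, d$y, cfg)
  cl <- predict(fit, d$x)
  expect_s3_class(cl, "factor")
  expect_equal(levels(cl), c("HC", "MDD"))
  pr <- predict(fit, d$x, type = "prob")
  expect_equal(dim(pr), c(8L, 2L))
  expect_equal(rowSums(pr), rep(1, 8), tolerance = 1e-9)
  sc <- predict(fit, d$x, type = "score")
  expect_true(all(is.finite(sc)))
})

test_that("training with validation tracks history and restores a checkpoint", {
  d <- random_windows(16, t_len = 64, seed = 33)
  v <- random_windows(8, t_len = 64, seed = 34)
  cfg <- hemigraph_config(scales = 0.1, max_epochs = 3, batch_size = 8,
                          seed = 4)
  fit <- hemigraph(d$x, d$y, cfg, validation = v$x, val_y = v$y)
  expect_equal(nrow(fit$history), fit$epochs_run)
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_true(fit$best_epoch >= 1 && fit$best_epoch <= fit$epochs_run)
  expect_lte(fit$epochs_run, 3)
})
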