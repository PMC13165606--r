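test_that("node embedding produces N x T1 features with normalized attention", {
  set.seed(1)
  p <- node_embed_params(11)
  x <- matrix(rnorm(11 * 64), 11, 64)
  e <- node_temporal_embedding(x, p)
  expect_equal(dim(e), c(11L, 64L))
  attn <- attr(e, "attention")
  expect_equal(dim(attn), c(11L, 64L))
  expect_equal(rowSums(attn), rep(1, 11), tolerance = 1e-8)
  expect_true(all(attn >= 0))
})

test_that("constant-in-time input gives uniform attention and a time mean", {
  set.seed(2)
  p <- node_embed_params(3, c1 = 4, c2 = 6, t1 = 8)
  x <- matrix(rep(rnorm(3), 32), 3, 32)           # constant along time
  e <- node_temporal_embedding(x, p)
  attn <- attr(e, "attention")
  # interior time steps (beyond both conv receptive fields) see identical
  # inputs -> attention is uniform there within each node
  inner <- attn[, 7:26]
  for (j in 1:3)
    expect_equal(max(inner[j, ]) / min(inner[j, ]), 1, tolerance = 1e-9)
  expect_equal(max(attn) / min(attn), 1, tolerance = 0.35)
})

test_that("embedding respects the kernel-extent precondition", {
  p <- node_embed_params(2, c1 = 2, c2 = 2, t1 = 4, kernel = 7)
  expect_error(node_temporal_embedding(matrix(rnorm(10), 2, 5), p),
               "kernel")
})

test_that("Chebyshev block with zero coefficients is a pure LN residual", {
  set.seed(3)
  p <- cheb_block_params(t1 = 8, layers = 2)
  for (l in 1:2) p$layers[[l]]$theta[] <- 0
  x <- matrix(rnorm(5 * 8), 5, 8)
  l <- normalized_laplacian(build_adjacency(matrix(rnorm(5 * 12), 5), 3))
  out <- cheb_block(x, l, p)
  ln <- function(m) t(apply(m, 1, function(r)
    (r - mean(r)) / sqrt(mean(r^2) - mean(r)^2 + 1e-5)))
  expect_equal(out, ln(ln(x)), tolerance = 1e-7)
})

test_that("Chebyshev block keeps the embedding width and dropout is train-only", {
  set.seed(4)
  p <- cheb_block_params(t1 = 64, layers = 2, dropout = 0.2)
  x <- matrix(rnorm(11 * 64), 11, 64)
  l <- normalized_laplacian(build_adjacency(matrix(rnorm(11 * 32), 11), 10))
  out <- cheb_block(x, l, p)
  expect_equal(dim(out), c(11L, 64L))
  # eval mode is deterministic
  expect_equal(out, cheb_block(x, l, p))
  # dropout-free training equals evaluation
  p0 <- p; p0$dropout <- 0
  expect_equal(cheb_block(x, l, p0, training = TRUE), cheb_block(x, l, p0))
  # with dropout active, training differs from evaluation
  set.seed(9)
  expect_false(isTRUE(all.equal(cheb_block(x, l, p, training = TRUE), out)))
})

test_that("region pooling is the node mean and permutation invariant", {
  row <- rnorm(6)
  expect_equal(region_pool(rbind(row, row, row)), row)
  expect_equal(region_pool(rbind(rep(0, 4), rep(2, 4))), rep(1, 4))
  set.seed(5)
  x <- matrix(rnorm(9 * 7), 9, 7)
  expect_equal(region_pool(x), region_pool(x[sample(9), ]))
})

test_that("attention fusion weights are a proper convex combination", {
  set.seed(6)
  fp <- fusion_params(t2 = 16, strategy = "attn")
  e <- rnorm(16)
  out <- fuse_regions(rbind(e, e), fp)
  expect_equal(attr(out, "weights"), c(0.5, 0.5))
  expect_equal(as.vector(out), e)

  for (i in 1:25) {
    emb <- matrix(rnorm(2 * 16), 2, 16)
    f <- fuse_regions(emb, fp)
    w <- attr(f, "weights")
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
    expect_true(all(f >= pmin(emb[1, ], emb[2, ]) - 1e-12))
    expect_true(all(f <= pmax(emb[1, ], emb[2, ]) + 1e-12))
  }
})

test_that("fixed fusion rules behave and attn reduces to avg at zero scores", {
  set.seed(7)
  emb <- matrix(rnorm(2 * 8), 2, 8)
  avg <- fusion_params(t2 = 8, strategy = "avg")
  expect_equal(as.vector(fuse_regions(rbind(rep(0, 8), rep(2, 8)), avg)),
               rep(1, 8))
  expect_equal(fuse_regions(emb, avg), fuse_regions(emb[2:1, ], avg))

  mx <- fusion_params(t2 = 8, strategy = "max")
  expect_equal(as.vector(fuse_regions(emb, mx)), pmax(emb[1, ], emb[2, ]))
  expect_equal(fuse_regions(emb, mx), fuse_regions(emb[2:1, ], mx))

  cc <- fusion_params(t2 = 8, strategy = "concat_mlp")
  expect_length(fuse_regions(emb, cc), 16)

  at <- fusion_params(t2 = 8, strategy = "attn")
  at$ws[] <- 0; at$bs <- 0
  expect_equal(as.vector(fuse_regions(emb, at)),
               as.vector(fuse_regions(emb, avg)))
})

test_that("the classifier head is linear on a layer-normalized vector", {
  fp <- fusion_params(t2 = 8)
  fp$wc[] <- 0; fp$bc[] <- 0
  expect_equal(unname(classify_fused(rnorm(8), fp)), c(0, 0))

  set.seed(8)
  fp2 <- fusion_params(t2 = 8)
  draws <- replicate(1000, classify_fused(rnorm(8), fp2))
  expect_true(all(is.finite(draws)))

  # argmax invariant to adding a constant to both scores
  sc <- classify_fused(rnorm(8), fp2)
  expect_equal(which.max(sc), which.max(sc + 13.7))

  expect_error(classify_fused(rnorm(5), fp2), "width")
})
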