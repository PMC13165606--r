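test_that("row normalization hits unit norms and guards zero rows", {
  expect_equal(l2_normalize_rows(matrix(c(3, 4), 1)), matrix(c(0.6, 0.8), 1))
  z <- matrix(0, 2, 3)
  expect_equal(l2_normalize_rows(z), z)
  set.seed(1)
  x <- matrix(rnorm(40), 8, 5)
  x[4, ] <- 0
  nrms <- sqrt(rowSums(l2_normalize_rows(x)^2))
  expect_true(all(abs(nrms - 1) < 1e-6 | nrms == 0))
  expect_equal(nrms[4], 0)
})

test_that("adjacency construction matches hand-worked examples", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  a <- build_adjacency(rbind(e1, e1, e2), k = 1)
  expect_equal(unname(a), rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))

  # identical rows, k = N-1: complete graph with unit weights
  x <- matrix(rep(rnorm(6), each = 11), 11, 6)
  a <- build_adjacency(x, k = 10)
  expect_equal(unname(a), matrix(1, 11, 11) - diag(11), tolerance = 1e-12)

  # orthogonal rows: empty graph
  a0 <- build_adjacency(diag(4), k = 3)
  expect_equal(a0, matrix(0, 4, 4))
})

test_that("adjacency equals a brute-force cosine Top-K enumeration", {
  for (s in 1:120) {
    set.seed(s)
    n <- sample(2:6, 1)
    tl <- sample(3:8, 1)
    k <- sample(1:5, 1)
    x <- matrix(rnorm(n * tl), n, tl)
    if (s %% 7 == 0) x[1, ] <- 0          # degenerate zero row sometimes
    expect_equal(build_adjacency(x, k), brute_adjacency(x, k),
                 tolerance = 1e-12)
  }
})

test_that("normalized Laplacian matches closed forms and conventions", {
  a3 <- matrix(1, 3, 3) - diag(3)
  l3 <- normalized_laplacian(a3)
  expect_equal(l3, diag(3) - (matrix(1, 3, 3) - diag(3)) / 2)
  expect_equal(sort(eigen(l3, symmetric = TRUE)$values), c(0, 1.5, 1.5),
               tolerance = 1e-12)

  expect_equal(normalized_laplacian(matrix(0, 4, 4)), diag(4))

  expect_error(normalized_laplacian(matrix(c(0, 1, 0, 0), 2, 2)),
               "symmetric")
})

test_that("Laplacian spectra stay inside [0, 2] on random Top-K graphs", {
  for (s in 1:200) {
    set.seed(1000 + s)
    n <- sample(3:11, 1)
    x <- matrix(rnorm(n * 16), n, 16)
    l <- normalized_laplacian(build_adjacency(x, k = sample(1:10, 1)))
    ev <- eigen(l, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_lt(max(ev), 2 + 1e-8)
  }
})

test_that("Chebyshev convolution reduces correctly in closed-form cases", {
  set.seed(2)
  n <- 5; f <- 3
  x <- matrix(rnorm(n * f), n, f)
  coeffs <- array(rnorm(f * f * 3), c(f, f, 3))

  # only the zeroth coefficient: graph-independent linear map
  c0 <- coeffs; c0[, , 2:3] <- 0
  l <- normalized_laplacian(build_adjacency(matrix(rnorm(n * 8), n), 3))
  expect_equal(cheb_conv(x, l, c0, 3), x %*% coeffs[, , 1])

  # empty graph: L = I, scaled operator 0, T2 = -I
  li <- diag(n)
  expect_equal(cheb_conv(x, li, coeffs, 3),
               x %*% (coeffs[, , 1] - coeffs[, , 3]))

  expect_error(cheb_conv(x, li, coeffs, 0), "order")
})

test_that("Chebyshev convolution matches the dense polynomial oracle", {
  for (s in 1:120) {
    set.seed(2000 + s)
    n <- sample(3:8, 1)
    f <- sample(2:5, 1)
    ord <- sample(1:4, 1)
    x <- matrix(rnorm(n * f), n, f)
    l <- normalized_laplacian(build_adjacency(matrix(rnorm(n * 10), n),
                                              k = sample(2:6, 1)))
    coeffs <- array(rnorm(f * f * ord), c(f, f, ord))
    expect_equal(cheb_conv(x, l, coeffs, ord), brute_cheb(x, l, coeffs, ord),
                 tolerance = 1e-10)
  }
})

test_that("region graphs bundle a symmetric adjacency with its Laplacian", {
  set.seed(3)
  x <- matrix(rnorm(11 * 64), 11, 64)
  g <- region_graph(x, k = 10)
  expect_s3_class(g, "region_graph")
  expect_equal(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))
  expect_true(all(g$adjacency >= 0))
  expect_equal(g$laplacian, normalized_laplacian(g$adjacency))

  # mean symmetrization never exceeds max symmetrization
  gm <- region_graph(x, k = 3, symmetrize = "mean")
  gx <- region_graph(x, k = 3, symmetrize = "max")
  expect_true(all(gm$adjacency <= gx$adjacency + 1e-15))
})
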