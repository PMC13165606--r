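#' L2-normalize matrix rows
#'
#' Scales each row to unit Euclidean norm; all-zero rows are left at zero
#' (epsilon-guarded), so cosine similarities involving them are zero.
#'
#' @param x Numeric matrix.
#' @param eps Rows with norm below `eps` are treated as zero.
#' @return Matrix of the same shape.
#' @export
l2_normalize_rows <- function(x, eps = 1e-12) {
  nrm <- sqrt(rowSums(x^2))
  scale <- ifelse(nrm > eps, 1 / nrm, 0)
  x * scale
}

#' Sparse cosine Top-K functional-connectivity adjacency
#'
#' Builds the within-region graph from a window's channel time series:
#' pairwise cosine similarity between L2-normalized rows, negative values
#' suppressed, self-similarity excluded, and per node only the `k` largest
#' positive similarities retained (fewer if fewer are positive; ties broken
#' toward the lower column index). The row-wise selection is symmetrized by
#' the element-wise maximum so every retained edge survives.
#'
#' @param x_region Channels x time matrix for one region's window.
#' @param k Number of neighbours retained per node (default 10).
#' @param symmetrize `"max"` (default) or `"mean"` combination of the
#'   asymmetric row-wise selection.
#' @return Nonnegative symmetric adjacency matrix with zero diagonal.
#' @export
build_adjacency <- function(x_region, k = 10, symmetrize = c("max", "mean")) {
  symmetrize <- match.arg(symmetrize)
  n <- nrow(x_region)
  if (n < 2) stop("need at least 2 nodes to build a graph")
  xn <- l2_normalize_rows(x_region)
  s <- tcrossprod(xn)
  s[s < 0] <- 0
  diag(s) <- 0
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- s[i, ]
    pos <- which(row > 0)
    if (!length(pos)) next
    keep <- pos[order(-row[pos], pos)][seq_len(min(k, length(pos)))]
    a[i, keep] <- row[keep]
  }
  if (symmetrize == "max") pmax(a, t(a)) else (a + t(a)) / 2
}

#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^{-1/2} A D^{-1/2}` with `D` the degree (row-sum) matrix.
#' Isolated nodes (zero degree) use the convention `D^{-1/2} = 0`, which
#' leaves an identity row/column. The spectrum lies in `[0, 2]`.
#'
#' @param adjacency Symmetric nonnegative matrix with zero diagonal.
#' @param tol Symmetry tolerance.
#' @return Symmetric Laplacian matrix.
#' @export
normalized_laplacian <- function(adjacency, tol = 1e-8) {
  if (max(abs(adjacency - t(adjacency))) > tol)
    stop("adjacency must be symmetric")
  d <- rowSums(adjacency)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  l <- diag(nrow(adjacency)) - (dinv %o% dinv) * adjacency
  (l + t(l)) / 2
}

#' Chebyshev spectral graph convolution
#'
#' Filters node features with a low-order Chebyshev polynomial in the scaled
#' Laplacian `Lt = L - I` (taking `lambda_max = 2`, a valid bound for any
#' normalized Laplacian): `y = sum_p T_p(Lt) x Theta_p` with the recurrence
#' `T_0 = I`, `T_1 = Lt`, `T_p = 2 Lt T_{p-1} - T_{p-2}`. Order `p` reaches a
#' `(p-1)`-hop neighbourhood.
#'
#' @param x Node feature matrix (N x F).
#' @param laplacian Normalized Laplacian (N x N), see
#'   [normalized_laplacian()].
#' @param coeffs Coefficient array (F x F' x order) or list of `order`
#'   matrices (F x F').
#' @param order Polynomial order (number of terms, >= 1).
#' @return Filtered features (N x F').
#' @export
cheb_conv <- function(x, laplacian, coeffs, order = 3) {
  if (order < 1) stop("order must be >= 1")
  if (is.array(coeffs) && length(dim(coeffs)) == 3)
    coeffs <- lapply(seq_len(dim(coeffs)[3]), function(p) coeffs[, , p])
  if (length(coeffs) < order) stop("need ", order, " coefficient matrices")
  lt <- laplacian - diag(nrow(laplacian))
  z_prev2 <- x
  out <- z_prev2 %*% coeffs[[1]]
  if (order >= 2) {
    z_prev1 <- lt %*% x
    out <- out + z_prev1 %*% coeffs[[2]]
    if (order >= 3) {
      for (p in 3:order) {
        z <- 2 * (lt %*% z_prev1) - z_prev2
        out <- out + z %*% coeffs[[p]]
        z_prev2 <- z_prev1
        z_prev1 <- z
      }
    }
  }
  out
}

#' Per-window region graph
#'
#' Convenience wrapper bundling the Top-K adjacency and its normalized
#' Laplacian for one region's window slice.
#'
#' @param x_region Channels x time matrix.
#' @param k Top-K neighbour count.
#' @param node_labels Optional electrode labels.
#' @param symmetrize Passed to [build_adjacency()].
#' @return Object of class `region_graph`: `node_labels`, `adjacency`,
#'   `laplacian`.
#' @export
region_graph <- function(x_region, k = 10, node_labels = rownames(x_region),
                         symmetrize = "max") {
  a <- build_adjacency(x_region, k, symmetrize)
  structure(list(node_labels = node_labels, adjacency = a,
                 laplacian = normalized_laplacian(a)),
            class = "region_graph")
}
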