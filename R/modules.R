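#' Odd temporal kernel length for a given time scale
#'
#' Converts a temporal receptive field in seconds to a convolution kernel
#' length in samples: `floor(alpha * fs)`, incremented to the next integer if
#' even, so that symmetric "same" padding is exact. At 256 Hz the scales
#' 0.4 / 0.2 / 0.1 s give 103 / 51 / 25 samples.
#'
#' @param alpha Temporal window in seconds.
#' @param fs Sampling rate in Hz.
#' @return Odd integer kernel length.
#' @examples
#' kernel_length(0.4, 256)
#' @export
kernel_length <- function(alpha, fs) {
  if (alpha <= 0 || fs <= 0) stop("alpha and fs must be positive")
  k <- floor(alpha * fs)
  if (k < 1) stop("kernel shorter than one sample")
  if (k %% 2 == 0) k <- k + 1
  as.integer(k)
}

#' Parameters for the multi-scale temporal filter bank
#'
#' One depthwise (per-channel) 1-D convolution branch per temporal scale,
#' each followed by per-channel batch normalization and an ELU activation;
#' branch outputs are mean-fused. Weights are drawn from the current RNG;
#' batch-norm scale/offset start at 1/0 with unit running variance.
#'
#' @param n_channels Number of EEG channels.
#' @param scales Temporal scales in seconds (1 to 3 supported).
#' @param sampling_rate Hz.
#' @return List of parameters with class `mstf_params`.
#' @export
mstf_params <- function(n_channels = 19, scales = c(0.4, 0.2, 0.1),
                        sampling_rate = 256) {
  stopifnot(length(scales) >= 1)
  kset <- vapply(scales, kernel_length, 0L, fs = sampling_rate)
  branches <- lapply(kset, function(k) list(
    w = .unif_init(c(n_channels, k), k),
    gamma = rep(1, n_channels), beta = rep(0, n_channels),
    run_mean = rep(0, n_channels), run_var = rep(1, n_channels)))
  structure(list(branches = branches, scales = scales, kernels = kset,
                 sampling_rate = sampling_rate),
            class = "mstf_params")
}

#' Multi-scale temporal filtering
#'
#' Applies every branch's depthwise convolution + batch norm + ELU to the
#' input and averages the branch outputs. Channels never mix: branch
#' filtering is per channel (one group per channel) with same padding.
#'
#' @param x Channels x time matrix, or a channels x time x batch array.
#' @param params An `mstf_params` object.
#' @param training Use batch statistics (`TRUE`) or running statistics
#'   (`FALSE`, default) in batch normalization.
#' @return Filtered signal, same shape as `x`.
#' @export
mstf_forward <- function(x, params, training = FALSE) {
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(dim(x), 1))
  d <- dim(x)
  out <- 0
  for (br in params$branches) {
    z <- cpp_dwconv_fwd(x, br$w)
    zm <- matrix(z, d[1], d[2] * d[3])
    bn <- .bn_fwd(zm, br$gamma, br$beta, br$run_mean, br$run_var, training)
    out <- out + .elu_fwd(bn$y)$y
  }
  out <- array(out / length(params$branches), d)
  if (was_mat) out <- out[, , 1]
  out
}

#' Parameters for the node-wise temporal embedding
#'
#' Per-node grouped temporal convolutions (widths `c1` then `c2`, time
#' extent `kernel`), time-attention pooling, and a shared linear projection
#' to length `t1`.
#'
#' @param n_nodes Nodes (electrodes) in the region.
#' @param c1,c2 Convolution widths.
#' @param t1 Embedding length.
#' @param kernel Temporal kernel extent.
#' @return List of parameters with class `node_embed_params`.
#' @export
node_embed_params <- function(n_nodes = 11, c1 = 16, c2 = 32, t1 = 64,
                              kernel = 7) {
  list(w1 = .unif_init(c(c1, kernel, n_nodes), kernel),
       b1 = array(0, c(c1, n_nodes)),
       w2 = .unif_init(c(c2, c1 * kernel, n_nodes), c1 * kernel),
       b2 = array(0, c(c2, n_nodes)),
       u = .unif_init(c(c2, n_nodes), c2),
       bu = rep(0, n_nodes),
       wl = .unif_init(c(t1, c2), c2),
       bl = rep(0, t1),
       c1 = c1, c2 = c2, t1 = t1, kernel = kernel)
}

#' Node-wise temporal embedding with time attention
#'
#' Encodes each node's time series into a fixed-length vector: two per-node
#' ReLU temporal convolutions, softmax attention over time steps, an
#' attention-weighted sum over time, and a linear projection.
#'
#' @param x_region Nodes x time matrix.
#' @param params A `node_embed_params` object.
#' @return Nodes x `t1` embedding matrix; the per-node attention weights
#'   (rows summing to 1) are attached as attribute `"attention"`.
#' @export
node_temporal_embedding <- function(x_region, params) {
  n <- nrow(x_region); tl <- ncol(x_region)
  if (tl < params$kernel) stop("time axis shorter than the kernel extent")
  xi <- array(x_region, c(n, tl, 1))
  cfg <- list(c1 = params$c1, c2 = params$c2, t1 = params$t1,
              embed_kernel = params$kernel, single = FALSE)
  emb <- .node_embed_fwd(xi, params, cfg)
  out <- matrix(emb$E[, , 1], n, params$t1)
  rownames(out) <- rownames(x_region)
  attn <- t(matrix(emb$S[, 1, ], tl, n))
  attr(out, "attention") <- attn
  out
}

#' Parameters for the residual Chebyshev convolution block
#'
#' @param t1 Feature width (input and output; the residual forces equality).
#' @param order Chebyshev polynomial order.
#' @param layers Number of stacked residual layers.
#' @param dropout Dropout rate applied to the activation inside the residual
#'   branch during training.
#' @return List of parameters with class `cheb_block_params`.
#' @export
cheb_block_params <- function(t1 = 64, order = 3, layers = 2, dropout = 0.2) {
  if (order < 1) stop("order must be >= 1")
  lay <- lapply(seq_len(layers), function(l) list(
    theta = .unif_init(c(t1, t1, order), t1 * order),
    ln_g = rep(1, t1), ln_b = rep(0, t1)))
  list(layers = lay, order = order, dropout = dropout, t1 = t1)
}

#' Residual Chebyshev graph-convolution block
#'
#' Applies `layers` repetitions of
#' `x <- LN(x + Dropout(ReLU(ChebConv(x))))` on one region graph.
#'
#' @param x Nodes x features matrix (features = `t1`).
#' @param laplacian Normalized Laplacian of the region graph.
#' @param params A `cheb_block_params` object.
#' @param training Enables dropout.
#' @return Nodes x features matrix.
#' @export
cheb_block <- function(x, laplacian, params, training = FALSE) {
  n <- nrow(x)
  lt <- laplacian - diag(n)
  Tb <- list(.cheb_basis(lt, params$order))
  cfg <- list(cheb_order = params$order, dropout = params$dropout)
  h <- x
  for (lp in params$layers)
    h <- .cheb_layer_fwd(h, Tb, lp, cfg, training, n, 1)$y
  h
}

#' Mean pooling over region nodes
#'
#' @param x Nodes x features matrix.
#' @return Numeric vector of length `ncol(x)` (the region embedding).
#' @export
region_pool <- function(x) colMeans(x)

#' Parameters for region fusion and classification
#'
#' @param t2 Region-embedding width.
#' @param n_regions Number of regions being fused.
#' @param strategy `"attn"`, `"avg"`, `"max"` or `"concat_mlp"`.
#' @return List of parameters with class `fusion_params`.
#' @export
fusion_params <- function(t2 = 64, n_regions = 2,
                          strategy = c("attn", "avg", "max", "concat_mlp")) {
  strategy <- match.arg(strategy)
  d <- if (strategy == "concat_mlp") n_regions * t2 else t2
  list(ws = .unif_init(t2, t2), bs = 0,
       ln_g = rep(1, d), ln_b = rep(0, d),
       wc = .unif_init(c(2, d), d), bc = rep(0, 2),
       strategy = strategy, t2 = t2)
}

#' Fuse region embeddings
#'
#' Attention fusion scores each region embedding with a shared linear map,
#' softmaxes the scores into weights, and returns the weighted sum; `avg`,
#' `max` and `concat_mlp` are fixed alternatives.
#'
#' @param region_embeddings Regions x features matrix (one row per region),
#'   or a list of equal-length vectors.
#' @param params A `fusion_params` object.
#' @return Fused feature vector (length `t2`, or `R * t2` for
#'   `concat_mlp`); for `"attn"` the weights are attached as attribute
#'   `"weights"`.
#' @export
fuse_regions <- function(region_embeddings, params) {
  if (is.list(region_embeddings))
    region_embeddings <- do.call(rbind, region_embeddings)
  pooled <- lapply(seq_len(nrow(region_embeddings)), function(r)
    matrix(region_embeddings[r, ], 1))
  fw <- .fusion_fwd(pooled, params, params$strategy)
  out <- as.vector(fw$y)
  if (params$strategy == "attn") attr(out, "weights") <- as.vector(fw$cache$w)
  out
}

#' Classify a fused embedding
#'
#' Layer-normalizes the fused vector and maps it linearly to two unnormalized
#' class scores; the depressed class (MDD) is the positive class, score
#' index 2.
#'
#' @param fused Fused feature vector.
#' @param params A `fusion_params` object.
#' @return Numeric vector of 2 class scores, named `HC` and `MDD`.
#' @export
classify_fused <- function(fused, params) {
  if (length(fused) != ncol(params$wc))
    stop("fused width ", length(fused), " does not match classifier width ",
         ncol(params$wc))
  ln <- .ln_fwd(matrix(fused, 1), params$ln_g, params$ln_b)
  sc <- as.vector(ln$y %*% t(params$wc)) + params$bc
  names(sc) <- c("HC", "MDD")
  sc
}
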