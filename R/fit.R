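#' Model and training configuration
#'
#' Collects every architectural and optimization hyperparameter. Defaults
#' follow the reference configuration: three temporal scales (0.4/0.2/0.1 s),
#' hemispheric two-region partition, cosine Top-10 graphs, order-3 Chebyshev
#' convolution in two residual layers with dropout 0.2, node embedding widths
#' 16/32 with embedding length 64, attention fusion, Adam (lr 0.001) with
#' cosine annealing (T_max 50, eta_min 1e-6), batch size 64, at most 50
#' epochs, early stopping after 10 epochs without validation-loss
#' improvement, 20% validation fraction.
#'
#' @param scales Temporal scales in seconds (subsets of the default support
#'   the scale ablations).
#' @param sampling_rate Hz.
#' @param partition Partition strategy, see [build_partition()].
#' @param top_k Neighbours kept per node in the region graphs.
#' @param symmetrize Adjacency symmetrization, `"max"` or `"mean"`.
#' @param cheb_order Chebyshev polynomial order.
#' @param cheb_layers Stacked residual Chebyshev layers.
#' @param dropout Dropout rate inside the residual branch.
#' @param c1,c2 Node-embedding convolution widths.
#' @param t1 Node/region embedding length.
#' @param embed_kernel Temporal extent of the embedding convolutions.
#' @param fusion Region fusion strategy, see [fuse_regions()].
#' @param lr Initial Adam learning rate.
#' @param t_max,eta_min Cosine annealing schedule parameters.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param val_fraction Fraction of training windows held out for validation.
#' @param precision `"single"` (default) runs the embedding convolutions in
#'   single precision, the customary arithmetic for network training;
#'   `"double"` is available when exact accumulation matters (e.g. numerical
#'   verification).
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and splits.
#' @return Object of class `hemigraph_config`.
#' @export
hemigraph_config <- function(scales = c(0.4, 0.2, 0.1), sampling_rate = 256,
                             partition = "two_region", top_k = 10,
                             symmetrize = "max", cheb_order = 3,
                             cheb_layers = 2, dropout = 0.2,
                             c1 = 16, c2 = 32, t1 = 64, embed_kernel = 7,
                             fusion = "attn", lr = 0.001, t_max = 50,
                             eta_min = 1e-6, max_epochs = 50,
                             batch_size = 64, patience = 10,
                             val_fraction = 0.2,
                             precision = c("single", "double"), seed = 1) {
  precision <- match.arg(precision)
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  if (!fusion %in% c("attn", "avg", "max", "concat_mlp"))
    stop("unknown fusion strategy: ", fusion)
  structure(as.list(environment()), class = "hemigraph_config")
}

# Resolve montage/partition-dependent fields into an internal config.
.resolve_config <- function(config, montage = standard_1020_montage(
                              config$sampling_rate)) {
  partition <- build_partition(montage, config$partition)
  idx <- channel_indices(partition, montage)
  cfg <- unclass(config)
  cfg$single <- identical(cfg$precision, "single") || is.null(cfg$precision)
  cfg$n_channels <- length(montage$channel_names)
  cfg$region_index <- idx
  cfg$region_sizes <- lengths(idx)
  cfg$montage <- montage
  cfg$partition_obj <- partition
  cfg
}

.windows_xy <- function(data, y = NULL) {
  if (inherits(data, "eeg_windows")) {
    x <- data$x
    y <- factor(data$info$group, levels = c("HC", "MDD"))
  } else {
    x <- data
    if (is.null(y)) stop("y labels required when x is a plain array")
    y <- factor(y, levels = c("HC", "MDD"))
  }
  if (anyNA(y)) stop("labels must be 'HC' or 'MDD'")
  list(x = x, y = as.integer(y))
}

#' Fit the hemispheric-partition EEG graph network
#'
#' Trains the classifier on labeled EEG windows with Adam, cosine learning
#' rate annealing and cross-entropy loss. If `validation` windows are given,
#' each epoch is scored on them, the checkpoint with the best validation
#' accuracy (ties broken by lower validation loss) is restored at the end,
#' and training stops early when the validation loss has not improved for
#' `config$patience` epochs.
#'
#' @param x Training data: an `eeg_windows` object (labels taken from its
#'   `info$group`), or a channels x time x windows array.
#' @param y Class labels (`"HC"`/`"MDD"`) when `x` is a plain array.
#' @param config A [hemigraph_config()].
#' @param validation Optional validation data (same forms as `x`).
#' @param val_y Labels for an array-form `validation`.
#' @param verbose Print per-epoch progress.
#' @return Object of class `hemigraph` with elements `params`, `buffers`,
#'   `config`, `history` (per-epoch data frame), `best_epoch`, `epochs_run`.
#' @seealso [predict.hemigraph()], [run_lopo()]
#' @export
hemigraph <- function(x, y = NULL, config = hemigraph_config(),
                      validation = NULL, val_y = NULL, verbose = FALSE) {
  tr <- .windows_xy(x, y)
  va <- if (!is.null(validation)) .windows_xy(validation, val_y)
  cfg <- .resolve_config(config)
  set.seed(cfg$seed)
  net <- .init_network(cfg)
  params <- net$params
  buffers <- net$buffers
  opt <- .adam_init(params)
  n <- dim(tr$x)[3]
  nb <- max(1L, ceiling(n / cfg$batch_size))
  best <- list(acc = -Inf, loss = Inf, params = params, buffers = buffers,
               epoch = 0L)
  stall <- 0L
  best_val_loss <- Inf
  hist <- list()
  epochs_run <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- cfg$eta_min + 0.5 * (cfg$lr - cfg$eta_min) *
      (1 + cos(pi * (epoch - 1) / cfg$t_max))
    ord <- sample.int(n)
    tot_loss <- 0
    for (ib in seq_len(nb)) {
      sel <- ord[((ib - 1) * cfg$batch_size + 1):min(ib * cfg$batch_size, n)]
      xb <- tr$x[, , sel, drop = FALSE]
      fw <- .network_fwd(params, buffers, xb, cfg, training = TRUE)
      buffers <- fw$buffers
      ce <- .ce_loss(fw$logits, tr$y[sel])
      if (!is.finite(ce$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      grads <- .network_bwd(params, fw$cache, ce$dlogits, cfg)
      st <- .adam_step(params, grads, opt, lr)
      params <- st$params
      opt <- st$state
      tot_loss <- tot_loss + ce$loss * length(sel)
    }
    epochs_run <- epoch
    row <- data.frame(epoch = epoch, lr = lr, train_loss = tot_loss / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(va)) {
      ev <- .evaluate_batches(params, buffers, va$x, va$y, cfg)
      row$val_loss <- ev$loss
      row$val_acc <- ev$acc
      if (ev$acc > best$acc ||
          (ev$acc == best$acc && ev$loss < best$loss)) {
        best <- list(acc = ev$acc, loss = ev$loss, params = params,
                     buffers = buffers, epoch = epoch)
      }
      if (ev$loss < best_val_loss - 1e-12) {
        best_val_loss <- ev$loss
        stall <- 0L
      } else stall <- stall + 1L
    }
    hist[[epoch]] <- row
    if (verbose)
      cat(sprintf("epoch %2d  lr %.5f  train loss %.4f  val loss %s  val acc %s\n",
                  epoch, lr, row$train_loss,
                  ifelse(is.na(row$val_loss), "-", sprintf("%.4f", row$val_loss)),
                  ifelse(is.na(row$val_acc), "-", sprintf("%.3f", row$val_acc))))
    if (!is.null(va) && stall >= cfg$patience) break
  }
  if (!is.null(va) && best$epoch > 0) {
    params <- best$params
    buffers <- best$buffers
  }
  structure(list(params = params, buffers = buffers, config = config,
                 cfg = cfg, history = do.call(rbind, hist),
                 best_epoch = if (!is.null(va)) best$epoch else epochs_run,
                 epochs_run = epochs_run,
                 classes = c("HC", "MDD")),
            class = "hemigraph")
}

.evaluate_batches <- function(params, buffers, x, y, cfg, batch_size = 128) {
  n <- dim(x)[3]
  nb <- ceiling(n / batch_size)
  loss <- 0; correct <- 0
  probs <- matrix(0, n, 2)
  for (ib in seq_len(nb)) {
    sel <- ((ib - 1) * batch_size + 1):min(ib * batch_size, n)
    fw <- .network_fwd(params, buffers, x[, , sel, drop = FALSE], cfg,
                       training = FALSE)
    ce <- .ce_loss(fw$logits, y[sel])
    loss <- loss + ce$loss * length(sel)
    pred <- max.col(ce$prob, ties.method = "first")
    correct <- correct + sum(pred == y[sel])
    probs[sel, ] <- ce$prob
  }
  list(loss = loss / n, acc = correct / n, probs = probs)
}

#' Predict from a fitted hemigraph model
#'
#' @param object A fitted `hemigraph` model.
#' @param newdata An `eeg_windows` object or channels x time x windows array.
#' @param type `"class"` (factor HC/MDD), `"prob"` (matrix of class
#'   probabilities) or `"score"` (unnormalized logits).
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return Predictions in the form selected by `type`.
#' @export
predict.hemigraph <- function(object, newdata, type = c("class", "prob",
                                                        "score"),
                              batch_size = 128, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "eeg_windows")) newdata$x else newdata
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  cfg <- object$cfg
  n <- dim(x)[3]
  nb <- ceiling(n / batch_size)
  out <- matrix(0, n, 2, dimnames = list(NULL, object$classes))
  for (ib in seq_len(nb)) {
    sel <- ((ib - 1) * batch_size + 1):min(ib * batch_size, n)
    fw <- .network_fwd(object$params, object$buffers,
                       x[, , sel, drop = FALSE], cfg, training = FALSE)
    out[sel, ] <- if (type == "score") fw$logits else .softmax_rows(fw$logits)
  }
  if (type == "class")
    factor(object$classes[max.col(out, ties.method = "first")],
           levels = object$classes)
  else out
}

#' @export
print.hemigraph <- function(x, ...) {
  cat("Hemispheric-partition EEG graph network\n")
  cat(sprintf("  partition: %s | scales: %s s | top-k: %d | fusion: %s\n",
              x$config$partition,
              paste(x$config$scales, collapse = "/"),
              x$config$top_k, x$config$fusion))
  cat(sprintf("  trained %d epoch(s); selected checkpoint: epoch %d\n",
              x$epochs_run, x$best_epoch))
  h <- x$history
  if (!all(is.na(h$val_acc)))
    cat(sprintf("  best validation accuracy: %.3f\n",
                max(h$val_acc, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.hemigraph <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.hemigraph <- function(object, ...) object$params

#' @export
plot.hemigraph <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "Training history", ...)
  if (!all(is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", legend = c("train", "validation"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
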