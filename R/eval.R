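#' Leave-one-pair-out fold construction
#'
#' Matches each depressed subject with a control subject (a seeded random
#' matching, recorded in the output) and builds one fold per pair: the
#' fold's test set is every window of that pair; everything else is the
#' training pool. No subject ever appears on both sides of a fold.
#'
#' @param subjects Data frame with columns `subject_id` and `group`
#'   (`"MDD"`/`"HC"`), one row per subject.
#' @param seed Seed for the matching.
#' @return List of folds; each fold is a list with `pair`
#'   (named character vector: mdd, hc), `test_subjects`, `train_subjects`.
#' @export
make_lopo_folds <- function(subjects, seed = 1) {
  subjects <- unique(subjects[, c("subject_id", "group")])
  mdd <- subjects$subject_id[subjects$group == "MDD"]
  hc <- subjects$subject_id[subjects$group == "HC"]
  if (length(mdd) != length(hc))
    stop("leave-one-pair-out needs equal group sizes (", length(mdd),
         " MDD vs ", length(hc), " HC)")
  if (!length(mdd)) stop("no subjects")
  set.seed(seed)
  hc_perm <- sample(hc)
  lapply(seq_along(mdd), function(i) {
    test <- c(mdd = mdd[i], hc = hc_perm[i])
    list(pair = test,
         test_subjects = unname(test),
         train_subjects = setdiff(subjects$subject_id, test))
  })
}

#' Stratified train/validation split of windows
#'
#' Window-level random split, stratified by class so the validation fraction
#' holds within each group.
#'
#' @param windows An `eeg_windows` object.
#' @param val_fraction Fraction assigned to validation.
#' @param seed Seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
split_train_val <- function(windows, val_fraction = 0.2, seed = 1) {
  info <- windows$info
  if (nrow(info) < 2) stop("need at least 2 windows to split")
  set.seed(seed)
  val <- integer(0)
  for (g in unique(info$group)) {
    idx <- which(info$group == g)
    n_val <- round(val_fraction * length(idx))
    if (n_val > 0) val <- c(val, sample(idx, n_val))
  }
  val <- sort(val)
  list(train = setdiff(seq_len(nrow(info)), val), val = val)
}

.subset_windows <- function(windows, idx) {
  structure(list(x = windows$x[, , idx, drop = FALSE],
                 info = windows$info[idx, , drop = FALSE],
                 sampling_rate = windows$sampling_rate,
                 montage = windows$montage),
            class = "eeg_windows")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall of the depressed class) and specificity as
#' percentages, and the F-measure `2 TP / (FP + FN + 2 TP)` as a fraction.
#' A zero denominator yields `NA` rather than an error.
#'
#' @param tp,tn,fp,fn Confusion counts (MDD is the positive class).
#' @return Named list: `accuracy`, `sensitivity`, `specificity`,
#'   `f_measure`.
#' @examples
#' compute_metrics(4606, 4357, 503, 254)
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  if (sum(counts) == 0) stop("confusion counts are all zero")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  list(accuracy = 100 * sdiv(tp + tn, tp + tn + fp + fn),
       sensitivity = 100 * sdiv(tp, tp + fn),
       specificity = 100 * sdiv(tn, tn + fp),
       f_measure = sdiv(2 * tp, fp + fn + 2 * tp))
}

#' One-sided paired t-test on fold-wise values
#'
#' Tests whether `a` exceeds `b` on average across paired folds (upper-tail
#' alternative on the paired differences). Zero-variance differences are
#' degenerate for the t statistic; they are flagged and resolved by the sign
#' of the mean difference (p -> 0 for a positive shift, 1 for negative,
#' 0.5 for identical vectors).
#'
#' @param a,b Equal-length numeric vectors (e.g. per-fold accuracies).
#' @return List with `statistic`, `p_value`, `df`, `degenerate`.
#' @export
paired_onesided_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 paired values")
  d <- a - b
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, mean(abs(d)))) {
    md <- mean(d)
    p <- if (md > 0) 0 else if (md < 0) 1 else 0.5
    return(list(statistic = if (md == 0) 0 else sign(md) * Inf,
                p_value = p, df = length(a) - 1, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

.confusion <- function(pred, truth) {
  c(tp = sum(pred == "MDD" & truth == "MDD"),
    tn = sum(pred == "HC" & truth == "HC"),
    fp = sum(pred == "MDD" & truth == "HC"),
    fn = sum(pred == "HC" & truth == "MDD"))
}

#' Train and evaluate one leave-one-pair-out fold
#'
#' Splits the fold's training pool into train/validation windows (stratified
#' by class), fits the model, and scores every window of the held-out pair.
#'
#' @param windows Pooled `eeg_windows` for the whole cohort.
#' @param fold One fold from [make_lopo_folds()].
#' @param config A [hemigraph_config()]; its `seed` drives the split,
#'   initialization and training.
#' @param keep_model Keep the fitted model in the result.
#' @param verbose Print training progress.
#' @return List with `pair`, `confusion`, `metrics`, `n_test`, and
#'   optionally `model`.
#' @export
train_fold <- function(windows, fold, config = hemigraph_config(),
                       keep_model = FALSE, verbose = FALSE) {
  test_idx <- which(windows$info$subject_id %in% fold$test_subjects)
  pool_idx <- which(windows$info$subject_id %in% fold$train_subjects)
  if (!length(test_idx) || !length(pool_idx)) stop("empty fold")
  stopifnot(length(intersect(test_idx, pool_idx)) == 0)
  pool <- .subset_windows(windows, pool_idx)
  sp <- split_train_val(pool, config$val_fraction, seed = config$seed)
  fit <- hemigraph(.subset_windows(pool, sp$train),
                   config = config,
                   validation = .subset_windows(pool, sp$val),
                   verbose = verbose)
  test <- .subset_windows(windows, test_idx)
  pred <- predict(fit, test, type = "class")
  conf <- .confusion(pred, test$info$group)
  res <- list(pair = fold$pair, confusion = conf,
              metrics = compute_metrics(conf[["tp"]], conf[["tn"]],
                                        conf[["fp"]], conf[["fn"]]),
              n_test = length(test_idx))
  if (keep_model) res$model <- fit
  res
}

#' Run the full leave-one-pair-out experiment
#'
#' The cross-subject evaluation protocol: recordings are filtered,
#' trimmed to the centered analysis segment and cut into 2 s windows; MDD/HC
#' subjects are matched into pairs; one model is trained per fold on all
#' other pairs (with a stratified window-level validation split and
#' checkpoint selection) and tested on every window of the held-out pair.
#' All randomness derives from `config$seed`, so a rerun with the same
#' inputs reproduces the summary exactly.
#'
#' @param data A cohort as returned by [generate_cohort()] (list with
#'   `recordings`), a list of `eeg_recording` objects, or a manifest data
#'   frame / CSV path pointing at recordings on disk.
#' @param config A [hemigraph_config()].
#' @param filter Apply [bandpass_notch()] to each recording.
#' @param segment_seconds Centered segment length in seconds.
#' @param window_seconds Window length in seconds.
#' @param verbose Print per-fold progress.
#' @return Object of class `hemigraph_eval`: `folds` (per-fold metric data
#'   frame), `fold_results`, `aggregate` (summed confusion + pooled
#'   metrics), `mean`, `sd`, `config`, `n_windows`.
#' @export
run_lopo <- function(data, config = hemigraph_config(), filter = TRUE,
                     segment_seconds = 180, window_seconds = 2,
                     verbose = FALSE) {
  recordings <- if (is.character(data)) load_cohort(read_manifest(data))
    else if (is.data.frame(data)) load_cohort(data)
    else if (!is.null(data$recordings)) data$recordings
    else data
  windows <- prepare_windows(recordings, filter = filter,
                             segment_seconds = segment_seconds,
                             window_seconds = window_seconds)
  subjects <- unique(windows$info[, c("subject_id", "group")])
  folds <- make_lopo_folds(subjects, seed = config$seed)
  results <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    fcfg <- config
    fcfg$seed <- config$seed + 7919L * i
    results[[i]] <- train_fold(windows, folds[[i]], fcfg)
    if (verbose) {
      m <- results[[i]]$metrics
      cat(sprintf("fold %d (%s vs %s): acc %.2f%%  sens %.2f%%  spec %.2f%%\n",
                  i, folds[[i]]$pair["mdd"], folds[[i]]$pair["hc"],
                  m$accuracy, m$sensitivity, m$specificity))
    }
  }
  fold_df <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(fold = i, mdd = r$pair[["mdd"]], hc = r$pair[["hc"]],
               tp = r$confusion[["tp"]], tn = r$confusion[["tn"]],
               fp = r$confusion[["fp"]], fn = r$confusion[["fn"]],
               accuracy = r$metrics$accuracy,
               sensitivity = r$metrics$sensitivity,
               specificity = r$metrics$specificity,
               f_measure = r$metrics$f_measure,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  agg <- as.integer(colSums(fold_df[, c("tp", "tn", "fp", "fn")]))
  names(agg) <- c("tp", "tn", "fp", "fn")
  metric_cols <- c("accuracy", "sensitivity", "specificity", "f_measure")
  structure(list(folds = fold_df, fold_results = results,
                 aggregate = c(as.list(agg),
                               compute_metrics(agg[["tp"]], agg[["tn"]],
                                               agg[["fp"]], agg[["fn"]])),
                 mean = colMeans(fold_df[, metric_cols]),
                 sd = apply(fold_df[, metric_cols], 2, stats::sd),
                 config = config,
                 n_windows = dim(windows$x)[3]),
            class = "hemigraph_eval")
}

#' @export
print.hemigraph_eval <- function(x, ...) {
  cat("Leave-one-pair-out evaluation:", nrow(x$folds), "folds,",
      x$n_windows, "windows\n")
  cat(sprintf("  accuracy    %6.2f +/- %5.2f %%\n", x$mean["accuracy"],
              x$sd["accuracy"]))
  cat(sprintf("  sensitivity %6.2f +/- %5.2f %%\n", x$mean["sensitivity"],
              x$sd["sensitivity"]))
  cat(sprintf("  specificity %6.2f +/- %5.2f %%\n", x$mean["specificity"],
              x$sd["specificity"]))
  cat(sprintf("  F-measure   %6.4f +/- %5.4f\n", x$mean["f_measure"],
              x$sd["f_measure"]))
  cat(sprintf("  pooled confusion: TP %d  TN %d  FP %d  FN %d\n",
              x$aggregate$tp, x$aggregate$tn, x$aggregate$fp,
              x$aggregate$fn))
  invisible(x)
}

#' @export
summary.hemigraph_eval <- function(object, ...) {
  print(object)
  cat("\nPer-fold results:\n")
  print(object$folds, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
plot.hemigraph_eval <- function(x, ...) {
  graphics::barplot(x$folds$accuracy, names.arg = x$folds$fold,
                    xlab = "fold", ylab = "accuracy (%)", ylim = c(0, 100),
                    main = "Per-fold test accuracy", ...)
  graphics::abline(h = x$mean["accuracy"], lty = 2)
  invisible(x)
}
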