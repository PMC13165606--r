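test_that("leave-one-pair-out folds pair the groups and partition the data", {
  subj <- data.frame(subject_id = c("M1", "M2", "M3", "H1", "H2", "H3"),
                     group = c("MDD", "MDD", "MDD", "HC", "HC", "HC"))
  folds <- make_lopo_folds(subj, seed = 3)
  expect_length(folds, 3)
  tests <- lapply(folds, `[[`, "test_subjects")
  expect_setequal(unlist(tests), subj$subject_id)       # disjoint cover
  expect_equal(sum(lengths(tests)), 6)
  for (f in folds) {
    expect_length(intersect(f$test_subjects, f$train_subjects), 0)
    expect_true(startsWith(f$pair[["mdd"]], "M"))
    expect_true(startsWith(f$pair[["hc"]], "H"))
  }
  expect_identical(make_lopo_folds(subj, seed = 3), folds)  # seeded matching

  expect_error(make_lopo_folds(subj[-1, ], seed = 1), "equal")
})

test_that("train/validation split is stratified, sized and seeded", {
  w <- list(info = data.frame(group = rep(c("HC", "MDD"), each = 50)))
  class(w) <- "eeg_windows"
  sp <- split_train_val(w, 0.2, seed = 5)
  expect_length(sp$val, 20)
  expect_length(sp$train, 80)
  expect_length(intersect(sp$train, sp$val), 0)
  tab <- table(w$info$group[sp$val])
  expect_true(all(abs(tab - 10) <= 1))
  expect_identical(split_train_val(w, 0.2, seed = 5), sp)
  expect_false(identical(split_train_val(w, 0.2, seed = 6), sp))
})

test_that("metrics reproduce the aggregated-confusion arithmetic", {
  m <- compute_metrics(4606, 4357, 503, 254)
  expect_equal(round(m$accuracy, 2), 92.21)
  expect_equal(round(m$sensitivity, 2), 94.77)
  expect_equal(round(m$specificity, 2), 89.65)
  expect_equal(m$f_measure, 9212 / 9969, tolerance = 1e-12)

  perfect <- compute_metrics(1, 1, 0, 0)
  expect_equal(unlist(perfect), c(accuracy = 100, sensitivity = 100,
                                  specificity = 100, f_measure = 1))

  # accuracy identity from class-conditional rates
  set.seed(9)
  for (i in 1:20) {
    cts <- as.list(rpois(4, 30))
    names(cts) <- c("tp", "tn", "fp", "fn")
    m <- do.call(compute_metrics, cts)
    p <- cts$tp + cts$fn; n <- cts$tn + cts$fp
    if (p > 0 && n > 0)
      expect_equal(m$accuracy, (m$sensitivity * p + m$specificity * n) /
                     (p + n), tolerance = 1e-10)
  }

  expect_true(is.na(compute_metrics(0, 5, 2, 0)$sensitivity))
  expect_error(compute_metrics(-1, 1, 1, 1), "nonnegative")
})

test_that("one-sided paired t-test matches a closed-form oracle", {
  r <- paired_onesided_ttest(1:5, 1:5)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 0.5)
  expect_equal(r$statistic, 0)

  r2 <- paired_onesided_ttest(2:6, 1:5)    # constant +1 shift
  expect_true(r2$degenerate)
  expect_equal(r2$p_value, 0)

  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    r3 <- paired_onesided_ttest(a, b)
    d <- a - b
    tstat <- mean(d) / (sd(d) / sqrt(10))
    expect_false(r3$degenerate)
    expect_equal(r3$statistic, tstat, tolerance = 1e-12)
    expect_equal(r3$p_value, 1 - pt(tstat, df = 9), tolerance = 1e-10)
  }

  expect_error(paired_onesided_ttest(1:3, 1:4), "equal length")
})

test_that("fold training never leaks the held-out pair and counts windows", {
  coh <- tiny_cohort(n_pairs = 2, duration = 10, effect = 1, seed = 13)
  w <- prepare_windows(coh$recordings, filter = FALSE, segment_seconds = 8)
  # 4 subjects x 2 conditions x 4 windows
  expect_equal(dim(w$x)[3], 32)
  folds <- make_lopo_folds(unique(w$info[, c("subject_id", "group")]),
                           seed = 1)
  cfg <- hemigraph_config(scales = 0.1, max_epochs = 1, batch_size = 8,
                          seed = 1)
  res <- train_fold(w, folds[[1]], cfg)
  expect_equal(res$n_test, 16)                  # 2 subjects x 2 x 4
  expect_equal(sum(res$confusion), 16)
  expect_equal(res$confusion[["tp"]] + res$confusion[["fn"]], 8)
  expect_equal(res$confusion[["tn"]] + res$confusion[["fp"]], 8)
})

test_that("the full protocol aggregates folds consistently and reruns identically", {
  coh <- tiny_cohort(n_pairs = 2, duration = 10, effect = 4, seed = 19)
  cfg <- hemigraph_config(scales = 0.1, max_epochs = 2, batch_size = 16,
                          seed = 7)
  ev <- run_lopo(coh, cfg, filter = FALSE, segment_seconds = 8)
  expect_s3_class(ev, "hemigraph_eval")
  expect_equal(nrow(ev$folds), 2)
  expect_equal(ev$n_windows, 32)
  expect_equal(sum(ev$folds$tp + ev$folds$tn + ev$folds$fp + ev$folds$fn),
               32)
  expect_equal(ev$aggregate$tp, sum(ev$folds$tp))
  # equal-size folds: pooled accuracy equals the fold mean
  expect_equal(ev$aggregate$accuracy, mean(ev$folds$accuracy),
               tolerance = 1e-10)
  # no subject appears in two test sets
  expect_false(any(duplicated(c(ev$folds$mdd, ev$folds$hc))))

  ev2 <- run_lopo(coh, cfg, filter = FALSE, segment_seconds = 8)
  expect_identical(ev$folds, ev2$folds)
  expect_identical(ev$aggregate, ev2$aggregate)
})
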