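test_that("confusion counts follow the >= threshold rule", {
  expect_equal(confusion(c(0.9, 0.1), c(1, 0)), list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  # ties predicted positive
  expect_equal(confusion(c(0.5, 0.5), c(1, 0))[c("TP", "FP")], list(TP = 1L, FP = 1L))
  expect_error(confusion(c(0.1, 0.2), 1), "differ in length")

  set.seed(81)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    s <- round(runif(n), 2)
    y <- sample(0:1, n, replace = TRUE)
    thr <- runif(1)
    expect_equal(confusion(s, y, thr), brute_confusion(s, y, thr))
  }
})

test_that("threshold metrics match hand arithmetic and stay consistent", {
  m <- classification_metrics(list(TP = 4, FP = 1, TN = 5, FN = 0))
  expect_equal(m$acc, 0.9)
  expect_equal(m$sens, 1)
  expect_equal(m$spec, 5 / 6)
  expect_equal(m$f_measure, 8 / 9)

  m2 <- classification_metrics(list(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(unlist(m2), c(acc = 0.5, sens = 0.5, spec = 0.5, f_measure = 0.5))

  m3 <- classification_metrics(list(TP = 7, FP = 0, TN = 3, FN = 0))
  expect_equal(unlist(m3), c(acc = 1, sens = 1, spec = 1, f_measure = 1))

  # undefined ratios surface as NaN, total-zero errors out
  expect_true(is.nan(classification_metrics(list(TP = 0, FP = 0, TN = 5, FN = 0))$sens))
  expect_error(classification_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)), "no evaluated")

  # accuracy decomposes over prevalence exactly
  set.seed(82)
  for (rep in 1:50) {
    counts <- as.list(setNames(sample(0:30, 4, replace = TRUE), c("TP", "FP", "TN", "FN")))
    if (counts$TP + counts$FN == 0 || counts$TN + counts$FP == 0) next
    m <- classification_metrics(counts)
    P <- counts$TP + counts$FN
    N <- counts$TN + counts$FP
    expect_equal(m$acc, (m$sens * P + m$spec * N) / (P + N), tolerance = 1e-14)
  }
})

test_that("PR curve and AP match the exhaustive enumeration oracle", {
  sep <- pr_curve_and_ap(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$ap, 1)
  flat <- pr_curve_and_ap(rep(0.4, 10), rep(c(1, 0), 5))
  expect_equal(flat$ap, 0.5)
  expect_error(pr_curve_and_ap(c(0.2, 0.4), c(0, 0)), "positive")

  set.seed(83)
  for (rep in 1:50) {
    n <- sample(4:50, 1)
    s <- round(runif(n), 1) # force ties
    y <- sample(0:1, n, replace = TRUE)
    if (sum(y) == 0) y[1] <- 1
    got <- pr_curve_and_ap(s, y)
    expect_equal(got$ap, enum_ap(s, y), tolerance = 1e-12)
    expect_gte(got$ap, 0)
    expect_lte(got$ap, 1)
  }
})

test_that("ROC sweep equals the all-pairs Mann-Whitney statistic", {
  sep <- roc_curve_and_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  expect_error(roc_curve_and_auc(c(0.2, 0.4), c(1, 1)), "both classes")

  set.seed(84)
  for (rep in 1:50) {
    n <- sample(4:50, 1)
    s <- round(runif(n), 1)
    y <- sample(0:1, n, replace = TRUE)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[1] <- 0
    got <- roc_curve_and_auc(s, y)
    expect_equal(got$auc, mw_auc(s, y), tolerance = 1e-12)
  }

  # independent scores: AUC concentrates at 1/2
  set.seed(85)
  s <- runif(2000)
  y <- sample(0:1, 2000, replace = TRUE)
  expect_lt(abs(roc_curve_and_auc(s, y)$auc - 0.5), 0.05)
})

test_that("AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(86)
  s <- round(runif(80), 2)
  y <- sample(0:1, 80, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_curve_and_auc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("stratified folds are balanced, exhaustive and reproducible", {
  ds <- tiny_dataset(50, 50, seed = 10)
  ds <- stratified_kfold(ds, k = 5, seed = 3)
  folds <- split(ds$pairs$label, ds$fold_of[ds$pairs$pair_id])
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(f, 20L)
    expect_equal(sum(f == 1), 10L)
  }

  # 101 pairs: remainder goes to the first fold
  ds101 <- tiny_dataset(51, 50, seed = 11)
  ds101 <- stratified_kfold(ds101, k = 5, seed = 4)
  sizes <- as.integer(table(ds101$fold_of))
  expect_equal(sort(sizes, decreasing = TRUE), c(21L, 20L, 20L, 20L, 20L))

  ds_b <- stratified_kfold(tiny_dataset(51, 50, seed = 11), k = 5, seed = 4)
  expect_identical(ds101$fold_of, ds_b$fold_of)

  expect_error(stratified_kfold(tiny_dataset(3, 50, seed = 12), k = 5), "fewer than k")
})

test_that("cross-validation produces per-fold reports and an exact mean", {
  ds <- tiny_dataset(20, 20, seed = 13)
  oh <- one_hot_table()
  ctor <- function(dim, hidden1, hidden2, linear1, seed) {
    init_site_model(model_config(dim = dim, hidden1 = 3, hidden2 = 2, linear1 = 2),
                    seed = seed)
  }
  cfg <- train_config(epochs = 2, seed = 1)
  cv <- cross_validate(ds, ctor, list(mi2vec = oh, m2vec = oh), cfg, k = 2, seed = 5)
  expect_length(cv$folds, 2L)
  accs <- vapply(cv$folds, function(r) r$acc, numeric(1))
  expect_equal(cv$mean[["acc"]], mean(accs), tolerance = 1e-15)

  cv2 <- cross_validate(ds, ctor, list(mi2vec = oh, m2vec = oh), cfg, k = 2, seed = 5)
  expect_identical(cv$mean, cv2$mean)
})

test_that("the paired t-test follows the textbook formula and its degenerate rules", {
  a <- c(0.9, 0.8, 0.85, 0.95, 0.9)
  expect_warning(same <- students_t_test(a, a), "zero variance")
  expect_equal(same$p_value, 1)

  d <- c(1, 1, 1, 1, 2)
  r <- students_t_test(d, rep(0, 5))
  s_d <- sd(d)
  expect_equal(r$t, mean(d) / (s_d / sqrt(5)), tolerance = 1e-14)
  expect_equal(r$t, 6, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(6, df = 4, lower.tail = FALSE), tolerance = 1e-14)

  expect_warning(diff0 <- students_t_test(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  expect_equal(diff0$p_value, 0)

  set.seed(87)
  for (rep in 1:20) {
    x <- rnorm(6)
    y <- rnorm(6)
    ref <- t.test(x, y, paired = TRUE)
    got <- students_t_test(x, y, paired = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    ref2 <- t.test(x, y, paired = FALSE, var.equal = FALSE)
    got2 <- students_t_test(x, y, paired = FALSE)
    expect_equal(got2$t, unname(ref2$statistic), tolerance = 1e-12)
    expect_equal(got2$p_value, ref2$p.value, tolerance = 1e-12)
  }
})

test_that("null p values are approximately uniform (paired test)", {
  set.seed(88)
  ps <- replicate(200, {
    x <- rnorm(10)
    y <- rnorm(10)
    students_t_test(x, y)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("raising the threshold never increases TP or FP", {
  set.seed(89)
  s <- runif(60)
  y <- sample(0:1, 60, replace = TRUE)
  thr <- sort(runif(12))
  prev <- NULL
  for (t in thr) {
    cc <- confusion(s, y, t)
    if (!is.null(prev)) {
      expect_lte(cc$TP, prev$TP)
      expect_lte(cc$FP, prev$FP)
    }
    prev <- cc
  }
})

test_that("evaluation reports serialise to JSON with curve exports", {
  set.seed(90)
  s <- runif(40)
  y <- sample(0:1, 40, replace = TRUE)
  rep_ <- evaluate_scores(s, y)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$counts$TP + rep_$counts$FP + rep_$counts$TN + rep_$counts$FN, 40)
  f <- tempfile(fileext = ".json")
  write_eval_report(rep_, f, digest = "d1")
  back <- jsonlite::fromJSON(f)
  expect_equal(back$acc, rep_$acc)
  expect_equal(back$config_digest, "d1")
  pr_f <- tempfile()
  roc_f <- tempfile()
  write_curves(s, y, pr_f, roc_f)
  expect_true(file.exists(pr_f) && file.exists(roc_f))
  roc_tab <- read.delim(roc_f, comment.char = "#")
  expect_named(roc_tab, c("threshold", "fpr", "tpr"))
})
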