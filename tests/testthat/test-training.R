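test_that("weighted cross-entropy matches hand values and is numerically stable", {
  expect_equal(weighted_cross_entropy(c(0, 0), 1L, c(1, 1)), log(2), tolerance = 1e-15)
  expect_equal(weighted_cross_entropy(c(0, 0), 1L, c(1, 2)), 2 * log(2), tolerance = 1e-15)
  l <- weighted_cross_entropy(c(50, -50), 0L, c(1, 1))
  expect_true(is.finite(l))
  expect_lt(l, 1e-20)
  expect_gte(l, 0)
  expect_error(weighted_cross_entropy(c(Inf, 0), 1L), "non-finite")

  # weights (1,1) equals the unweighted cross-entropy exactly
  set.seed(61)
  for (rep in 1:25) {
    z <- rnorm(2, sd = 5)
    y <- sample(0:1, 1)
    plain <- -log(exp(z[y + 1]) / sum(exp(z)))
    expect_equal(weighted_cross_entropy(z, y, c(1, 1)), plain, tolerance = 1e-9)
  }
})

test_that("inverse-frequency class weights follow N/(2*Nc)", {
  ds_bal <- tiny_dataset(25, 25, seed = 1)
  expect_equal(auto_class_weights(ds_bal), c(1, 1))

  ds_skew <- tiny_dataset(25, 75, seed = 2)
  expect_equal(auto_class_weights(ds_skew), c(100 / 150, 100 / 50), tolerance = 1e-12)

  # at the published corpus class balance the weights are within 2% of 1
  n_pos <- 33142
  n_neg <- 32284
  w <- c((n_pos + n_neg) / (2 * n_neg), (n_pos + n_neg) / (2 * n_pos))
  expect_true(all(abs(w - 1) < 0.02))

  ds_one <- tiny_dataset(10, 0, seed = 3)
  expect_error(auto_class_weights(ds_one), "both classes")
})

test_that("training is deterministic given dataset, config and seed", {
  ds <- tiny_dataset(30, 30, seed = 4)
  oh <- one_hot_table()
  tabs <- list(mi2vec = oh, m2vec = oh)
  model <- init_site_model(
    model_config(dim = 4, hidden1 = 5, hidden2 = 3, linear1 = 3), seed = 9
  )
  cfg <- train_config(epochs = 5, seed = 21)
  f1 <- train_model(ds, model, tabs, cfg)
  f2 <- train_model(ds, model, tabs, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$history$train_acc, f2$history$train_acc)
  expect_identical(mirsite:::flatten_params(f1$model$params),
                   mirsite:::flatten_params(f2$model$params))
  expect_equal(nrow(f1$history), 5L)
  expect_true(all(is.finite(f1$history$loss)))
})

test_that("training reduces the loss and improves training accuracy on the fixture", {
  ds <- tiny_dataset(100, 100, seed = 6)
  oh <- one_hot_table()
  model <- init_site_model(
    model_config(dim = 4, hidden1 = 8, hidden2 = 4, linear1 = 4), seed = 2
  )
  fit <- train_model(ds, model, list(mi2vec = oh, m2vec = oh),
                     train_config(epochs = 15, seed = 2))
  h <- fit$history
  expect_gt(head(h$loss, 1), tail(h$loss, 1))
  expect_gt(tail(h$train_acc, 1), head(h$train_acc, 1))
})

test_that("one optimiser step on a frozen batch reduces that batch's loss", {
  set.seed(71)
  for (rep in 1:20) {
    cfg <- model_config(dim = 3, hidden1 = 3, hidden2 = 2, linear1 = 2)
    m <- init_site_model(cfg, seed = rep)
    n <- 5
    Xa <- array(rnorm(30 * 3 * n), c(30, 3, n))
    Xb <- array(rnorm(30 * 3 * n), c(30, 3, n))
    y <- c(sample(0:1, n - 2, replace = TRUE), 0L, 1L)
    w <- c(1, 1)
    before <- mirsite:::cpp_model_loss_grad(Xa, Xb, y, w, m$params, cfg)
    shuffles <- matrix(0:(n - 1), n, 1)
    fit <- mirsite:::cpp_model_train(
      Xa, Xb, y, m$params, cfg,
      list(lr = 1e-4, batch = n, epochs = 1L, adam = TRUE,
           beta1 = 0.9, beta2 = 0.999, eps = 1e-8, weights = w, clip = 0),
      shuffles, NULL, NULL, NULL
    )
    after <- mirsite:::cpp_model_loss_grad(Xa, Xb, y, w, fit$params, cfg)
    expect_lt(after$loss, before$loss)
  }
})

test_that("an aggressive learning rate is allowed but warned about", {
  ds <- tiny_dataset(8, 8, seed = 7)
  oh <- one_hot_table()
  model <- init_site_model(model_config(dim = 4, hidden1 = 3, hidden2 = 2, linear1 = 2),
                           seed = 1)
  expect_warning(
    train_model(ds, model, list(mi2vec = oh, m2vec = oh),
                train_config(learning_rate = 0.01, epochs = 1, seed = 1)),
    "0.01"
  )
  expect_error(
    train_model(subset_pairs(ds, integer(0)), model, list(mi2vec = oh, m2vec = oh),
                train_config(epochs = 1)),
    "empty"
  )
})

test_that("validation tracking records per-epoch accuracy and the best checkpoint", {
  ds <- tiny_dataset(40, 40, seed = 8)
  val <- tiny_dataset(10, 10, seed = 9)
  oh <- one_hot_table()
  model <- init_site_model(model_config(dim = 4, hidden1 = 5, hidden2 = 3, linear1 = 3),
                           seed = 3)
  out <- withr::local_tempdir()
  fit <- train_model(ds, model, list(mi2vec = oh, m2vec = oh),
                     train_config(epochs = 4, seed = 5), validation = val,
                     out_dir = out)
  expect_true(all(is.finite(fit$history$val_acc)))
  expect_true(file.exists(file.path(out, "final.ckpt")))
  expect_true(file.exists(file.path(out, "best.ckpt")))
  expect_true(file.exists(file.path(out, "history.tsv")))
  # the written history excludes wall time but keeps the metrics
  hdr <- strsplit(readLines(file.path(out, "history.tsv"))[1], "\t")[[1]]
  expect_setequal(hdr, c("epoch", "loss", "train_acc", "val_acc"))
})
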