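zero_cell <- function(type, hidden, input) {
  p <- rand_cell(type, hidden, input)
  lapply(p, function(x) x * 0)
}

zero_model <- function(cfg, seed = 1) {
  m <- init_site_model(cfg, seed = seed)
  m$params <- rapply(m$params, function(x) x * 0, how = "replace")
  m
}

test_that("the LSTM cell reproduces the hand-computed gate arithmetic", {
  p0 <- zero_cell("lstm", 3, 2)
  st <- lstm_cell_step(c(0.3, -0.7), list(h = numeric(3), c = numeric(3)), p0)
  expect_equal(st$h, numeric(3))
  expect_equal(st$c, numeric(3))

  v <- c(0.5, -1.2, 2)
  st2 <- lstm_cell_step(c(0.3, -0.7), list(h = numeric(3), c = v), p0)
  expect_equal(st2$c, 0.5 * v, tolerance = 1e-15)
  expect_equal(st2$h, 0.5 * tanh(0.5 * v), tolerance = 1e-15)

  p1 <- zero_cell("lstm", 1, 1)
  p1$b_f <- 10
  st3 <- lstm_cell_step(0, list(h = 0, c = 1), p1)
  f10 <- 1 / (1 + exp(-10))
  expect_equal(st3$c, f10, tolerance = 1e-12)
  expect_gt(st3$c, 0.9999)
  expect_equal(st3$h, 0.5 * tanh(f10), tolerance = 1e-12)

  expect_error(lstm_cell_step(c(1, 2, 3), list(h = numeric(3), c = numeric(3)), p0),
               "expects input")
})

test_that("vectorised cell steps agree with scalar oracles (all cell types)", {
  set.seed(52)
  for (rep in 1:40) {
    h <- sample(1:4, 1)
    d <- sample(1:4, 1)
    T_ <- sample(2:8, 1)
    X <- matrix(rnorm(T_ * d), T_, d)
    for (type in c("lstm", "gru", "rnn")) {
      p <- rand_cell(type, h, d)
      want <- scalar_run(X, p, type)
      got <- mirsite:::cpp_cell_forward(X, p, type, FALSE)
      expect_lt(max(abs(want - got)), 1e-12)
    }
    # the R-level LSTM runner matches too
    p <- rand_cell("lstm", h, d)
    expect_lt(max(abs(mirsite:::lstm_run(X, p) - scalar_run(X, p, "lstm"))), 1e-12)
  }
})

test_that("bidirectional composition aligns positions and swaps on reversal", {
  set.seed(53)
  d <- 3
  h <- 4
  fwd <- rand_cell("lstm", h, d)
  bwd <- rand_cell("lstm", h, d)

  # palindromic input with tied parameters: mirror symmetry
  half <- matrix(rnorm(4 * d), 4, d)
  X <- rbind(half, half[4:1, ])
  B <- bilstm_forward(X, fwd, fwd)
  L <- nrow(X)
  for (t in seq_len(L)) {
    expect_equal(B[t, 1:h], B[L + 1 - t, h + 1:h], tolerance = 1e-12)
  }

  # zero parameters: zero fixed point
  z <- zero_cell("lstm", h, d)
  expect_equal(bilstm_forward(X, z, z), matrix(0, L, 2 * h))

  # length-1 input: both directions see the same single step
  X1 <- matrix(rnorm(d), 1, d)
  B1 <- bilstm_forward(X1, fwd, fwd)
  expect_equal(B1[1, 1:h], B1[1, h + 1:h], tolerance = 1e-14)

  # reversing the input swaps the role of the two halves exactly
  Y <- matrix(rnorm(6 * d), 6, d)
  Bf <- bilstm_forward(Y, fwd, bwd)
  Br <- bilstm_forward(Y[6:1, , drop = FALSE], bwd, fwd)
  expect_equal(Bf[, 1:h], Br[6:1, h + 1:h], tolerance = 1e-14)
  expect_equal(Bf[, h + 1:h], Br[6:1, 1:h], tolerance = 1e-14)

  # C++ bidirectional layer equals the R composition
  got <- mirsite:::cpp_cell_forward(Y, list(fwd = fwd, bwd = bwd), "lstm", TRUE)
  expect_lt(max(abs(got - bilstm_forward(Y, fwd, bwd))), 1e-12)

  expect_error(bilstm_forward(matrix(0, 0, d), fwd, bwd), "empty")
})

test_that("the stacked two-branch classifier behaves per contract", {
  cfg <- model_config(dim = 5, hidden1 = 6, hidden2 = 4, linear1 = 3)
  mz <- zero_model(cfg)
  enc_a <- matrix(rnorm(150), 30, 5)
  enc_b <- matrix(rnorm(150), 30, 5)
  out <- stacked_forward(enc_a, enc_b, mz)
  expect_equal(out$logits, c(0, 0))
  expect_equal(out$probs, c(0.5, 0.5))

  set.seed(54)
  m <- init_site_model(cfg, seed = 17)
  out2 <- stacked_forward(enc_a, enc_b, m)
  expect_lt(abs(sum(out2$probs) - 1), 1e-9)
  # distinct branch parameters: swapping the inputs changes the logits
  out_swapped <- stacked_forward(enc_b, enc_a, m)
  expect_false(isTRUE(all.equal(out2$logits, out_swapped$logits)))

  expect_error(stacked_forward(enc_a[, 1:3], enc_b, m), "input width")
})

test_that("architecture variants change cells and widths as declared", {
  # identity configuration reproduces the default model exactly
  ctor <- make_variant(c("BiLSTM", "BiLSTM"))
  m1 <- ctor(dim = 5, hidden1 = 6, hidden2 = 4, linear1 = 3, seed = 11)
  m2 <- init_site_model(model_config(dim = 5, hidden1 = 6, hidden2 = 4, linear1 = 3),
                        seed = 11)
  expect_identical(m1$params, m2$params)
  enc_a <- matrix(rnorm(150), 30, 5)
  enc_b <- matrix(rnorm(150), 30, 5)
  expect_identical(stacked_forward(enc_a, enc_b, m1), stacked_forward(enc_a, enc_b, m2))

  # unidirectional first layer halves the layer-1 output width
  mu <- make_variant(c("LSTM", "LSTM"))(dim = 5, hidden1 = 6, hidden2 = 4,
                                        linear1 = 3, seed = 1)
  expect_null(mu$params$mi_l1_bwd)
  expect_equal(ncol(mu$params$l2_fwd$W_f), 4 + 6) # hidden2 + hidden1 (not 2*hidden1)
  expect_equal(ncol(mu$params$lin1_W), 4) # unidirectional layer-2 summary
  out <- stacked_forward(enc_a, enc_b, mu)
  expect_lt(abs(sum(out$probs) - 1), 1e-9)

  # vanilla RNN stack, zero parameters: uniform softmax
  mr <- make_variant(c("RNN", "RNN"))(dim = 5, hidden1 = 6, hidden2 = 4,
                                      linear1 = 3, seed = 1)
  mr$params <- rapply(mr$params, function(x) x * 0, how = "replace")
  expect_equal(stacked_forward(enc_a, enc_b, mr)$probs, c(0.5, 0.5))

  # GRU forward path agrees with the scalar oracle through cpp_cell_forward
  mg <- make_variant(c("GRU", "GRU"))(dim = 5, hidden1 = 6, hidden2 = 4,
                                      linear1 = 3, seed = 2)
  expect_lt(abs(sum(stacked_forward(enc_a, enc_b, mg)$probs) - 1), 1e-9)

  expect_error(make_variant(c("BiLSTM", "Transformer")), "unknown architecture")
})

test_that("weight sharing ties the two branch parameter sets", {
  cfg <- model_config(dim = 4, hidden1 = 5, hidden2 = 3, linear1 = 3,
                      share_branches = TRUE)
  m <- init_site_model(cfg, seed = 3)
  expect_null(m$params$cts_l1_fwd)
  set.seed(99)
  enc_a <- matrix(rnorm(120), 30, 4)
  enc_b <- matrix(rnorm(120), 30, 4)
  # with shared branches, swapping inputs flips which rows feed layer 2,
  # but identical inputs give identical results trivially; check shape + norm
  out <- stacked_forward(enc_a, enc_b, m)
  expect_lt(abs(sum(out$probs) - 1), 1e-9)
  # gradient flows into the shared component from both branches
  g <- mirsite:::cpp_model_loss_grad(
    array(enc_a, c(30, 4, 1)), array(enc_b, c(30, 4, 1)),
    0L, c(1, 1), m$params, m$config
  )
  expect_true(max(abs(g$grads$mi_l1_fwd$W_f)) > 0)
})

test_that("the CNN1d baseline is a working classifier head", {
  cfg <- cnn1d_config(dim = 4, filters = c(6L, 8L))
  mz <- zero_model(cfg)
  enc_a <- matrix(rnorm(120), 30, 4)
  enc_b <- matrix(rnorm(120), 30, 4)
  expect_equal(cnn1d_forward(enc_a, enc_b, mz)$probs, c(0.5, 0.5))
  m <- init_site_model(cfg, seed = 5)
  out <- cnn1d_forward(enc_a, enc_b, m)
  expect_lt(abs(sum(out$probs) - 1), 1e-9)
  expect_length(out$logits, 2L)
})

test_that("checkpoints round-trip bit-exactly and preserve predictions", {
  for (cfg in list(
    model_config(dim = 4, hidden1 = 5, hidden2 = 3, linear1 = 3),
    model_config(dim = 4, hidden1 = 5, hidden2 = 3, linear1 = 3,
                 arch = c("GRU", "LSTM")),
    cnn1d_config(dim = 4, filters = c(5L, 6L))
  )) {
    m <- init_site_model(cfg, seed = 23)
    f <- tempfile(fileext = ".ckpt")
    write_checkpoint(m, f, digest = "deadbeef")
    back <- read_checkpoint(f)
    expect_identical(back$params, m$params)
    expect_equal(unclass(back$config), unclass(m$config))
    enc_a <- matrix(rnorm(120), 30, 4)
    enc_b <- matrix(rnorm(120), 30, 4)
    fwd <- if (cfg$kind == "cnn1d") cnn1d_forward else stacked_forward
    expect_identical(fwd(enc_a, enc_b, back), fwd(enc_a, enc_b, m))
  }
})
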