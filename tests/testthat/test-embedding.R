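test_that("skip-gram pair enumeration matches exhaustive window logic", {
  expect_equal(nrow(skipgram_pairs(c(1L, 2L, 3L, 4L), window = 5L)), 12L)
  expect_equal(
    skipgram_pairs(c(2L, 4L), window = 1L),
    matrix(c(2L, 4L, 4L, 2L), ncol = 2, byrow = TRUE,
           dimnames = list(NULL, c("center", "context")))
  )
  expect_equal(nrow(skipgram_pairs(3L, window = 5L)), 0L)

  set.seed(21)
  for (rep in 1:20) {
    sen <- sample(1:4, sample(2:15, 1), replace = TRUE)
    w <- sample(1:6, 1)
    got <- skipgram_pairs(sen, w)
    want <- do.call(rbind, lapply(seq_along(sen), function(n) {
      do.call(rbind, lapply((-w):w, function(m) {
        j <- n + m
        if (m != 0 && j >= 1 && j <= length(sen)) c(sen[n], sen[j])
      }))
    }))
    expect_equal(unname(got), unname(want))
  }
})

test_that("negative-sampling loss and gradients match hand values and finite differences", {
  zero_tab <- table_from_matrix(matrix(0, 4, 3), output = matrix(0, 4, 3))
  r <- skipgram_loss_and_grads(1L, 2L, zero_tab, negatives = 3L)
  expect_equal(r$loss, 2 * log(2), tolerance = 1e-12)

  expect_error(skipgram_loss_and_grads(1L, 2L, zero_tab, negatives = c(2L, 3L)),
               "exclude")

  set.seed(31)
  for (rep in 1:100) {
    d <- sample(2:6, 1)
    tab <- table_from_matrix(matrix(rnorm(4 * d, sd = 0.7), 4, d),
                             output = matrix(rnorm(4 * d, sd = 0.7), 4, d))
    cen <- sample(1:4, 1)
    ctx <- sample(1:4, 1)
    negs <- sample(setdiff(1:4, ctx), sample(1:3, 1), replace = TRUE)
    got <- skipgram_loss_and_grads(cen, ctx, tab, negs)
    # finite differences on the centre input vector
    f_cen <- function(v) {
      t2 <- tab
      t2$input_vectors[cen, ] <- v
      skipgram_loss_and_grads(cen, ctx, t2, negs)$loss
    }
    fd <- fd_grad(f_cen, tab$input_vectors[cen, ])
    expect_lt(max(abs(fd - got$grad_center)) / max(abs(fd) + abs(got$grad_center), 1e-8), 1e-5)
    # and on the context output vector
    f_ctx <- function(v) {
      t2 <- tab
      t2$output_vectors[ctx, ] <- v
      skipgram_loss_and_grads(cen, ctx, t2, negs)$loss
    }
    fd2 <- fd_grad(f_ctx, tab$output_vectors[ctx, ])
    expect_lt(max(abs(fd2 - got$grad_context)) / max(abs(fd2) + abs(got$grad_context), 1e-8), 1e-5)
  }
})

test_that("the exact 4-way softmax of the skip-gram model is normalised", {
  set.seed(41)
  for (rep in 1:100) {
    d <- sample(2:8, 1)
    tab <- table_from_matrix(matrix(rnorm(4 * d, sd = 2), 4, d),
                             output = matrix(rnorm(4 * d, sd = 2), 4, d))
    for (cen in 1:4) {
      p <- skipgram_softmax(tab, cen)
      expect_lt(abs(sum(p) - 1), 1e-12)
      expect_true(all(p >= 0))
    }
  }
})

test_that("skip-gram training is deterministic, shaped, and PAD-inert", {
  corpus <- build_corpus(tiny_dataset(40, 40, seed = 5)$pairs$mirna_seq)
  cfg <- skipgram_config(dim = 20, epochs = 3, seed = 99)
  t1 <- suppressWarnings(train_skipgram(corpus, cfg))
  t2 <- suppressWarnings(train_skipgram(corpus, cfg))
  expect_identical(t1$input_vectors, t2$input_vectors)
  expect_identical(t1$output_vectors, t2$output_vectors)
  expect_identical(attr(t1, "epoch_loss"), attr(t2, "epoch_loss"))

  t4 <- suppressWarnings(train_skipgram(corpus, skipgram_config(dim = 4, epochs = 2, seed = 1)))
  expect_equal(dim(t4$input_vectors), c(4L, 4L))
  expect_equal(rownames(t4$input_vectors), c("A", "C", "G", "U"))
  expect_identical(t4$pad_vector, numeric(4))
  expect_error(train_skipgram(list(), skipgram_config()), "empty corpus")
})

test_that("training objective descends on a corpus with co-occurrence structure", {
  corpus <- structured_corpus(n_sent = 60, len = 22, seed = 2)
  tab <- train_skipgram(corpus, skipgram_config(dim = 10, epochs = 10, seed = 7))
  losses <- attr(tab, "epoch_loss")
  expect_length(losses, 10L)
  expect_lt(losses[10], losses[1])
  # the learned geometry reflects the structure: within-group cosine
  # similarity (A~G, C~U) exceeds between-group
  M <- cosine_similarity_matrix(tab)
  expect_gt(min(M["A", "G"], M["C", "U"]),
            max(M["A", "C"], M["A", "U"], M["G", "C"], M["G", "U"]))
})

test_that("different seeds give different tables with correlated geometry", {
  corpus <- structured_corpus(n_sent = 60, len = 22, seed = 3)
  ta <- suppressWarnings(train_skipgram(corpus, skipgram_config(dim = 10, epochs = 10, seed = 1)))
  tb <- suppressWarnings(train_skipgram(corpus, skipgram_config(dim = 10, epochs = 10, seed = 2)))
  expect_false(identical(ta$input_vectors, tb$input_vectors))
  off <- function(M) M[upper.tri(M)]
  rho <- suppressWarnings(cor(off(cosine_similarity_matrix(ta)),
                              off(cosine_similarity_matrix(tb)),
                              method = "spearman"))
  expect_gt(rho, 0)
})

test_that("one-hot table is the orthonormal basis and encodes as basis rows", {
  oh <- one_hot_table()
  expect_equal(oh$dim, 4L)
  expect_equal(sum(oh$input_vectors["A", ] * oh$input_vectors["C", ]), 0)
  expect_equal(sqrt(sum(oh$input_vectors["G", ]^2)), 1)
  enc <- encode_sequence(pad_to_length(normalize_and_tokenize("ACGU"), 4), oh)
  expect_equal(enc, diag(4), ignore_attr = TRUE)
})

test_that("encode_sequence produces padded_length x dim matrices with zero PAD rows", {
  mir22 <- pad_to_length(normalize_and_tokenize(strrep("GU", 11)))
  set.seed(8)
  tab50 <- table_from_matrix(matrix(rnorm(200), 4, 50))
  enc <- encode_sequence(mir22, tab50)
  expect_equal(dim(enc), c(30L, 50L))
  expect_true(all(enc[23:30, ] == 0))
  expect_equal(enc[1, ], tab50$input_vectors["G", ], ignore_attr = TRUE)

  oh_enc <- encode_sequence(mir22, one_hot_table())
  expect_equal(unname(rowSums(oh_enc)), c(rep(1, 22), rep(0, 8)))
})

test_that("cosine similarity matrix is symmetric with unit diagonal", {
  tab <- table_from_matrix(rbind(
    A = c(1, 0), C = c(0, 1), G = c(1, 1) / sqrt(2), U = c(-1, 0)
  ))
  M <- cosine_similarity_matrix(tab)
  expect_equal(M["A", "A"], 1)
  expect_equal(M, t(M))
  expect_equal(M["A", "G"], sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(cosine_similarity_matrix(tab, distance = TRUE)["A", "G"],
               1 - sqrt(2) / 2, tolerance = 1e-12)
  expect_true(all(M >= -1 - 1e-12 & M <= 1 + 1e-12))
  expect_equal(unname(diag(cosine_similarity_matrix(one_hot_table()))), rep(1, 4))
  expect_equal(sum(abs(cosine_similarity_matrix(one_hot_table())) > 1e-12), 4L)

  bad <- table_from_matrix(rbind(A = c(1, 0), C = c(0, 0), G = c(1, 1), U = c(0, 1)))
  expect_error(cosine_similarity_matrix(bad), "token C")
})

test_that("embedding tables round-trip through the TSV format bit-exactly", {
  corpus <- structured_corpus(20, 15, seed = 4)
  tab <- suppressWarnings(train_skipgram(corpus, skipgram_config(dim = 7, epochs = 2, seed = 3), "mRNA"))
  f <- tempfile(fileext = ".tsv")
  write_embedding_table(tab, f, digest = "abc123")
  back <- read_embedding_table(f)
  expect_identical(back$input_vectors, tab$input_vectors)
  expect_identical(back$output_vectors, tab$output_vectors)
  expect_identical(back$molecule, "mRNA")
  expect_identical(back$dim, 7L)
})

test_that("corpus building drops unusable records with a warning", {
  expect_warning(sent <- build_corpus(c("ACGT", "NNN", "GG")), "dropping 1")
  expect_length(sent, 2L)
  expect_equal(sent[[1]], c(1L, 2L, 3L, 4L))
  expect_error(build_corpus(character(0)), "empty corpus")
})
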