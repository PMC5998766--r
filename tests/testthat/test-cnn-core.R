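# the network core against naive loop oracles

test_that("embedding rows are gathered concatenations of table rows", {
  set.seed(1)
  tm <- tiny_model()
  enc <- random_encoded()
  W_e <- tm$params$W_e; W_d1 <- tm$params$W_d1; W_d2 <- tm$params$W_d2
  X <- ddi_embed(enc, W_e, W_d1, W_d2)
  expect_equal(dim(X), c(8L, 6L + 2L * 2L))
  # per-cell gather loop
  for (i in seq_len(nrow(X))) {
    row <- c(W_e[enc$word_ids[i], ], W_d1[enc$pos1_ids[i] + 1L, ],
             W_d2[enc$pos2_ids[i] + 1L, ])
    expect_equal(unname(X[i, ]), unname(row))
  }
  expect_true(all(ddi_embed(enc, W_e * 0, W_d1 * 0, W_d2 * 0) == 0))
})

test_that("convolution matches the triple-loop oracle", {
  set.seed(2)
  for (rep in 1:10) {
    X <- matrix(rnorm(24), 6, 4)
    w <- sample(2:4, 1)
    m <- sample(2:5, 1)
    W <- matrix(rnorm(w * 4 * m), w * 4, m)
    b <- rnorm(m)
    expect_lt(max(abs(ddi_convolve(X, W, b) - oracle_conv(X, W, b))),
              1e-10)
  }
  # zero filters and bias give a zero block; w = n gives a single score row
  X <- matrix(rnorm(24), 6, 4)
  expect_true(all(ddi_convolve(X, matrix(0, 8, 3), numeric(3)) == 0))
  expect_equal(nrow(ddi_convolve(X, matrix(rnorm(24), 24, 2), c(0, 0))), 1L)
})

test_that("the stacked feature matrix zero-fills each block to n rows", {
  set.seed(3)
  X <- matrix(rnorm(10 * 6), 10, 6)
  filters <- list(`2` = list(W = matrix(rnorm(12 * 3), 12, 3), b = rnorm(3)),
                  `4` = list(W = matrix(rnorm(24 * 3), 24, 3), b = rnorm(3)))
  fm <- ddi_feature_matrix(X, filters)
  S <- ddi_fm_matrix(fm)
  expect_equal(dim(S), c(10L * 2L, 3L))
  expect_equal(fm$valid, c(9L, 7L))
  expect_true(all(S[10, ] == 0))            # beyond block 1's valid rows
  expect_true(all(S[(10 + 8):20, ] == 0))   # beyond block 2's valid rows
  expect_equal(S[1:9, ], fm$blocks[[1]], ignore_attr = TRUE)
})

test_that("pooling operators match brute-force oracles", {
  set.seed(4)
  for (rep in 1:100) {
    n <- sample(6:12, 1)
    m <- sample(2:5, 1)
    widths <- sort(sample(2:5, 2))
    fm <- random_fm(n, m, widths)
    rows <- sample(c("all", "valid"), 1)
    expect_lt(max(abs(ddi_pool_max(fm, rows) - oracle_pool_max(fm, rows))),
              1e-10)
    expect_lt(max(abs(ddi_pool_avg(fm, rows) - oracle_pool_avg(fm, rows))),
              1e-10)
    wa <- lapply(widths, function(w) rnorm(m))
    z <- ddi_pool_attentive(fm, wa, rows)
    expect_lt(max(abs(as.numeric(z) - oracle_pool_attentive(fm, wa, rows))),
              1e-10)
    alpha <- attr(z, "alpha")
    for (a in alpha) {
      expect_true(all(a >= 0))
      expect_equal(sum(a), 1)
    }
  }
})

test_that("single-valid-row attention degenerates to tanh of the row", {
  fm <- random_fm(n = 5, m = 3, widths = 5)  # w = n: one valid row
  z <- ddi_pool_attentive(fm, list(rnorm(3)), rows = "valid")
  expect_equal(unname(attr(z, "alpha")[[1]]), 1)
  expect_equal(as.numeric(z), as.numeric(tanh(fm$blocks[[1]][1, ])),
               tolerance = 1e-12)
})

test_that("pooling is permutation-equivariant across filters", {
  set.seed(5)
  fm <- random_fm(n = 9, m = 4, widths = c(2, 3))
  perm <- sample(4)
  fmp <- fm
  fmp$blocks <- lapply(fm$blocks, function(H) H[, perm, drop = FALSE])
  pz <- function(z) matrix(z, ncol = 4, byrow = TRUE)[, perm]
  expect_equal(ddi_pool_max(fmp), as.numeric(t(pz(ddi_pool_max(fm)))))
  expect_equal(ddi_pool_avg(fmp), as.numeric(t(pz(ddi_pool_avg(fm)))))
})

test_that("combined pooling concatenates the two branch outputs", {
  set.seed(6)
  fa <- random_fm(n = 8, m = 3, widths = c(2, 3))
  fb <- random_fm(n = 8, m = 3, widths = c(2, 3))
  wa <- list(rnorm(3), rnorm(3))
  z <- ddi_pool_combined(fa, fb, wa)
  expect_length(z, 12L)  # 2 * m * k with m = 3, k = 2
  expect_equal(z[1:6], ddi_pool_max(fa))
  expect_equal(z[7:12], as.numeric(ddi_pool_attentive(fb, wa)))
  # zero attentive branch -> second half exactly 0
  fb0 <- fb
  fb0$blocks <- lapply(fb$blocks, function(H) H * 0)
  expect_true(all(ddi_pool_combined(fa, fb0, wa)[7:12] == 0))
})

test_that("softmax scorer normalises, shifts and matches log-sum-exp", {
  z <- rnorm(6)
  u <- ddi_classify(z, matrix(0, 6, 5), numeric(5))
  expect_equal(unname(u), rep(0.2, 5))
  set.seed(7)
  W <- matrix(rnorm(30), 6, 5)
  d <- rnorm(5)
  p1 <- ddi_classify(z, W, d)
  expect_equal(sum(p1), 1)
  expect_true(all(p1 > 0))
  expect_equal(unname(p1), unname(ddi_classify(z, W, d + 3.7)),
               tolerance = 1e-12)
  o <- drop(t(W) %*% z) + d
  expect_lt(max(abs(p1 - oracle_softmax(o))), 1e-12)
  # inverted dropout: full mask at p reproduces scaled activations
  mask <- rep(1, 6)
  pm <- ddi_classify(z, W, d, dropout_mask = mask, p = 0.5)
  expect_equal(unname(pm), unname(ddi_classify(2 * z, W, d)))
})

test_that("end-to-end forward matches a fully naive implementation", {
  set.seed(8)
  naive_forward <- function(enc, params, cfg) {
    X <- matrix(0, cfg$n, cfg$D)
    for (i in seq_len(cfg$n))
      X[i, ] <- c(params$W_e[enc$word_ids[i], ],
                  params$W_d1[enc$pos1_ids[i] + 1, ],
                  params$W_d2[enc$pos2_ids[i] + 1, ])
    fms <- lapply(params$F, function(fb) {
      blocks <- lapply(names(fb), function(wn)
        oracle_conv(X, fb[[wn]]$W, fb[[wn]]$b))
      names(blocks) <- names(fb)
      structure(list(blocks = blocks, widths = as.integer(names(fb)),
                     valid = cfg$n - as.integer(names(fb)) + 1L,
                     n = cfg$n, m = cfg$m), class = "ddi_fm")
    })
    z <- switch(cfg$pooling,
      max = oracle_pool_max(fms[[1]]),
      avg = oracle_pool_avg(fms[[1]]),
      attentive = oracle_pool_attentive(fms[[1]], params$w_alpha),
      combined = c(oracle_pool_max(fms[[1]]),
                   oracle_pool_attentive(fms[[2]], params$w_alpha)))
    o <- numeric(5)
    for (r in 1:5) o[r] <- sum(z * params$W_s[, r]) + params$d[r]
    oracle_softmax(o)
  }
  for (pool in c("max", "avg", "attentive", "combined")) {
    tm <- tiny_model(pooling = pool, m = 2L)
    enc <- random_encoded()
    fw <- ddipool:::cnn_forward(enc, tm$params, tm$cfg, NULL)
    expect_lt(max(abs(fw$probs - naive_forward(enc, tm$params, tm$cfg))),
              1e-8)
  }
})

test_that("max pooling is pad-invariant, average pooling is not", {
  # The padding mechanism: with the pad token's word vector, the pad
  # position rows and all filter biases at zero, every window fully inside
  # the pad region scores ReLU(0) = 0. Growing the padded length then
  # leaves the max-pooled vector unchanged while the average-pooled vector
  # shifts. Position tables are indexed by signed distance so the real
  # tokens embed identically at every padded length.
  set.seed(9)
  n_long <- 16L
  m_e <- 5L; m_d <- 2L; m <- 3L; widths <- c(2L, 3L)
  V <- 10L
  W_e <- matrix(runif(V * m_e, -0.25, 0.25), V, m_e)
  W_e[1, ] <- 0  # pad word vector
  dist_tab1 <- matrix(runif((4 * n_long) * m_d, -0.25, 0.25), 4 * n_long)
  dist_tab2 <- matrix(runif((4 * n_long) * m_d, -0.25, 0.25), 4 * n_long)
  filters <- lapply(widths, function(w)
    list(W = matrix(rnorm(w * (m_e + 2 * m_d) * m, sd = 0.3),
                    w * (m_e + 2 * m_d), m),
         b = numeric(m)))
  names(filters) <- widths
  forward_z <- function(word_ids, p1, p2, n) {
    len <- length(word_ids)
    # distance-indexed position tables, pad rows zero
    W_d <- function(tab, p) {
      out <- matrix(0, 2 * n, m_d)
      for (code in 1:(2 * n - 1))
        out[code + 1, ] <- tab[(code - n) + 2 * n_long, ]
      out
    }
    enc <- structure(list(
      word_ids = c(word_ids, rep(1L, n - len)),
      pos1_ids = c(ddi_regroup(seq_len(len) - p1, n), rep(0L, n - len)),
      pos2_ids = c(ddi_regroup(seq_len(len) - p2, n), rep(0L, n - len)),
      label_id = 1L, p1 = p1, p2 = p2, pad_start = len + 1L,
      sentence_id = "s", pair_id = "p"), class = "ddi_encoded")
    X <- ddi_embed(enc, W_e, W_d(dist_tab1, p1), W_d(dist_tab2, p2))
    fm <- ddi_feature_matrix(X, filters)
    list(zmax = ddi_pool_max(fm, "all"), zavg = ddi_pool_avg(fm, "all"))
  }
  n_diff <- 0L
  for (rep in 1:50) {
    len <- sample(4:8, 1)
    word_ids <- sample(2:V, len, replace = TRUE)
    p1 <- sample(len - 1L, 1L)
    p2 <- p1 + 1L
    short <- forward_z(word_ids, p1, p2, n = len + 2L)
    long <- forward_z(word_ids, p1, p2, n = n_long)
    expect_equal(short$zmax, long$zmax, tolerance = 1e-12)
    if (max(abs(short$zavg - long$zavg)) > 1e-8) n_diff <- n_diff + 1L
  }
  expect_equal(n_diff, 50L)
})
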