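test_that("gru_step matches hand-evaluated gate equations", {
  # scalar case: all weights 1, biases 0, f = 1, h = 0
  p <- gru_params(1, 1)
  for (nm in c("U_z", "U_r", "U_c", "W_z", "W_r", "W_c")) p[[nm]][] <- 1
  h <- gru_step(1, 0, p)
  sig1 <- 1 / (1 + exp(-1))
  expect_equal(as.numeric(h), (1 - sig1) * tanh(1), tolerance = 1e-12)
  expect_equal(as.numeric(h), 0.2048242, tolerance = 1e-6)

  # all-zero parameters: z = r = 0.5, c = 0, h_t = h/2
  p0 <- gru_params(2, 3)
  h0 <- gru_step(c(1, -1), c(2, 4, -6), p0)
  expect_equal(as.numeric(h0), c(1, 2, -3))
  expect_equal(attr(h0, "z"), rep(0.5, 3), ignore_attr = TRUE)

  # saturated update gate copies the previous state
  psat <- gru_params(2, 3)
  psat$b_z[] <- 20
  hs <- gru_step(c(5, -3), c(0.3, -0.7, 1.1), psat)
  expect_equal(as.numeric(hs), c(0.3, -0.7, 1.1), tolerance = 1e-6)

  expect_error(gru_step(c(1, 2, 3), c(0, 0, 0), p0), "shape mismatch")
})

test_that("gru_step agrees with an independent loop oracle on random small cases", {
  set.seed(21)
  for (trial in 1:20) {
    d_in <- sample(1:4, 1); d_h <- sample(1:4, 1)
    p <- gru_params(d_in, d_h, seed = trial)
    f <- rnorm(d_in); h <- rnorm(d_h)
    expect_equal(as.numeric(gru_step(f, h, p)),
                 oracle_gru_step(f, h, p), tolerance = 1e-10)
    # gates are open: z, r in (0,1); h_t between c and h elementwise
    out <- gru_step(f, h, p)
    z <- attr(out, "z"); r <- attr(out, "r"); cc <- attr(out, "c")
    expect_true(all(z > 0 & z < 1))
    expect_true(all(r > 0 & r < 1))
    expect_true(all(as.numeric(out) >= pmin(cc, h) - 1e-12 &
                    as.numeric(out) <= pmax(cc, h) + 1e-12))
  }
})

test_that("bigru output is a palindromic swap for shared parameters", {
  p <- gru_params(2, 3, seed = 5)
  seq_pal <- rbind(c(1, -0.5), c(0.3, 2), c(1, -0.5))
  H <- bigru_forward(seq_pal, p, p)
  d_h <- 3
  for (t in 1:3) {
    expect_equal(H[t, 1:d_h], H[4 - t, d_h + 1:d_h], tolerance = 1e-12)
  }
  # length-1 sequence: both directions see the same single input
  H1 <- bigru_forward(matrix(c(1, 2), 1), p, p)
  expect_equal(dim(H1), c(1L, 6L))
  expect_equal(H1[1, 1:3], H1[1, 4:6])
  # all-zero params from zero state give zero output
  H0 <- bigru_forward(seq_pal, gru_params(2, 3), gru_params(2, 3))
  expect_equal(max(abs(H0)), 0)
  expect_error(bigru_forward(matrix(0, 0, 2), p, p), "non-empty")
})

test_that("self_attention matches hand-computed softmax values and the loop oracle", {
  # 2 positions, 1-D, identity projections, H = [1, 2], d = 1
  a <- attention_params(1, 1)
  H <- matrix(c(1, 2), 2, 1)
  out <- self_attention(H, a)
  w <- exp(c(1, 2)) / sum(exp(c(1, 2)))
  expect_equal(out[1, 1], w[1] * 1 + w[2] * 2, tolerance = 1e-12)
  expect_equal(out[1, 1], 1.7311, tolerance = 1e-4)
  expect_equal(attr(out, "weights")[1, ], c(0.2689, 0.7311), tolerance = 1e-4)

  # single position: weight exactly 1, output = its value projection
  o1 <- self_attention(matrix(c(3, -1), 1, 2), attention_params(2, 2, seed = 1))
  expect_equal(attr(o1, "weights")[1, 1], 1)

  # identical positions: uniform weights, output = any V row
  a2 <- attention_params(3, 2, seed = 2)
  Hrep <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE)
  o2 <- self_attention(Hrep, a2)
  expect_equal(attr(o2, "weights"), matrix(0.25, 4, 4), ignore_attr = TRUE)
  expect_equal(o2[1, ], (matrix(c(1, 2, 3), 1) %*% a2$W_v)[1, ], tolerance = 1e-12)

  # random cases vs the dense loop oracle; rows sum to 1
  set.seed(31)
  for (trial in 1:10) {
    n <- sample(2:4, 1); m <- sample(1:4, 1); d <- sample(1:3, 1)
    ap <- attention_params(m, d, seed = trial + 100)
    Hr <- matrix(rnorm(n * m), n, m)
    got <- self_attention(Hr, ap)
    expect_equal(unclass(got), oracle_attention(Hr, ap$W_q, ap$W_k, ap$W_v, d),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(rowSums(attr(got, "weights")), rep(1, n), tolerance = 1e-9)
  }
})

test_that("the batched forward pass agrees with the exported per-sequence ops", {
  fx <- small_fixture(n_active = 12, n_inactive = 6)
  cfg <- tiny_bgatt_config(epochs = 0)
  model <- train_bgatt(fx$fused, fx$labels, config = cfg)
  X <- fx$fused$matrix
  emb <- extract_embeddings(model, X)
  # rebuild one compound's embedding with the public single-sequence ops
  i <- 3
  tokens <- do.call(rbind, lapply(seq_along(model$token_ranges), function(t) {
    r <- model$token_ranges[[t]]
    X[i, (r[["start"]] + 1):r[["end"]], drop = FALSE] %*% model$proj[[t]]
  }))
  H <- bigru_forward(tokens, model$fwd, model$bwd)
  att <- self_attention(H, model$att)
  expect_equal(colMeans(att), emb[i, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("embedding geometry: width 2*d_h regardless of input count", {
  fx <- small_fixture(n_active = 10, n_inactive = 5)
  model <- train_bgatt(fx$fused, fx$labels, config = tiny_bgatt_config(epochs = 0))
  expect_equal(ncol(extract_embeddings(model, fx$fused)), 16)
  e0 <- extract_embeddings(model, fx$fused$matrix[integer(0), , drop = FALSE])
  expect_equal(dim(e0), c(0L, 16L))
  # identical input rows -> identical embeddings; repeat -> bitwise identical
  X2 <- fx$fused$matrix[c(1, 1), ]
  e2 <- extract_embeddings(model, X2)
  expect_identical(e2[1, ], e2[2, ])
  expect_identical(extract_embeddings(model, fx$fused), extract_embeddings(model, fx$fused))
  expect_error(extract_embeddings(model, fx$fused$matrix[, 1:10]), "width")
})

test_that("training is deterministic, learns separable data, and zero epochs = init", {
  fx <- small_fixture(n_active = 60, n_inactive = 30, seed = 13,
                      density_active = 0.15, density_inactive = 0.75, noise = 0.01)
  cfg <- tiny_bgatt_config(epochs = 30)
  m1 <- train_bgatt(fx$fused, fx$labels, config = cfg, positive = "inactive")
  m2 <- train_bgatt(fx$fused, fx$labels, config = cfg, positive = "inactive")
  expect_identical(m1$fwd, m2$fwd)
  expect_identical(m1$head, m2$head)
  expect_identical(m1$history, m2$history)

  # training BACC on linearly separable planted signal
  final_bacc <- m1$history$bacc[nrow(m1$history)]
  expect_gte(final_bacc, 0.95)
  # loss decreased
  expect_lt(m1$history$loss[nrow(m1$history)], m1$history$loss[1])

  m0 <- train_bgatt(fx$fused, fx$labels, config = tiny_bgatt_config(epochs = 0))
  init <- bgatt_init(fx$fused$view_offsets, ncol(fx$fused$matrix),
                     tiny_bgatt_config(epochs = 0))
  expect_equal(m0$head, init$head)
  expect_equal(m0$fwd, init$fwd)
})

test_that("fixed-width chunk tokenization works without view offsets", {
  fx <- small_fixture(n_active = 20, n_inactive = 10)
  cfg <- tiny_bgatt_config(epochs = 2, chunk_size = 40)
  m <- train_bgatt(fx$fused$matrix, fx$labels, config = cfg)
  # 130 fused columns at chunk 40 -> tokens of width 40/40/40/10
  expect_length(m$proj, 4)
  expect_equal(nrow(m$proj[[4]]), 10)
  expect_equal(dim(extract_embeddings(m, fx$fused$matrix)), c(30L, 16L))
  expect_error(train_bgatt(fx$fused$matrix, fx$labels, config = tiny_bgatt_config()),
               "view_offsets")
})

test_that("model checkpoints round-trip through JSON", {
  fx <- small_fixture(n_active = 15, n_inactive = 8)
  m <- train_bgatt(fx$fused, fx$labels, config = tiny_bgatt_config(epochs = 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_bgatt(m, path)
  m2 <- load_bgatt(path)
  expect_equal(extract_embeddings(m2, fx$fused), extract_embeddings(m, fx$fused),
               tolerance = 1e-12)
  expect_equal(predict_bgatt(m2, fx$fused), predict_bgatt(m, fx$fused),
               tolerance = 1e-12)
})
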