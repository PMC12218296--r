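test_that("SMOTE points lie on segments between minority neighbours", {
  # two points, k = 1: every synthetic point must lie on the segment
  m <- rbind(c(0, 0, 0), c(1, 2, 3))
  s <- smote_oversample(m, 20, k = 1, seed = 4)
  lam <- s[, 1] / 1
  expect_true(all(lam >= 0 & lam <= 1))
  expect_equal(s[, 2], 2 * lam)
  expect_equal(s[, 3], 3 * lam)

  expect_equal(nrow(smote_oversample(m, 0, k = 1)), 0)
  expect_error(smote_oversample(m, 5, k = 5, seed = 1), "smaller k")
})

test_that("SMOTE parents match a brute-force k-NN oracle", {
  set.seed(7)
  m <- matrix(rnorm(30), 10, 3)
  s <- smote_oversample(m, 5, k = 3, seed = 7)
  parents <- attr(s, "parents")
  # oracle: exhaustive pairwise distances
  for (i in seq_len(nrow(s))) {
    b <- parents[i, "base"]; nb <- parents[i, "neighbour"]
    d_all <- sqrt(colSums((t(m) - m[b, ])^2))
    d_all[b] <- Inf
    expect_lte(d_all[nb], sort(d_all)[3])
    # interpolation consistency: synthetic = base + lambda (nn - base)
    diff_nn <- m[nb, ] - m[b, ]
    lam <- (s[i, ] - m[b, ]) / ifelse(diff_nn == 0, 1, diff_nn)
    lam <- lam[diff_nn != 0]
    expect_equal(max(lam) - min(lam), 0, tolerance = 1e-12)
    expect_true(all(lam >= 0 & lam <= 1))
  }
})

test_that("balanced datasets hit the proportional target sizes exactly", {
  set.seed(1)
  n_maj <- 1054; n_min <- 214
  X <- matrix(rnorm((n_maj + n_min) * 4), ncol = 4)
  y <- c(rep("active", n_maj), rep("inactive", n_min))
  sizes <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    b <- build_balanced(X, y, p = p, seed = 3)
    expect_equal(sum(b$labels == "active"), sum(b$labels == "inactive"))
    expect_equal(sum(b$synthetic), b$counts$per_class - n_min)
    # synthetic rows only ever carry the minority label
    expect_true(all(b$labels[b$synthetic] == "inactive"))
    b$counts$per_class
  }, numeric(1))
  expect_equal(sizes, c(214, 424, 634, 844, 1054))
  # monotone in p
  expect_true(all(diff(sizes) > 0))
  expect_error(build_balanced(X, y, p = 1.2), "\\[0, 1\\]")
  expect_error(build_balanced(X, rep("a", nrow(X)), p = 0.5), "two classes")
})

test_that("p = 0 is pure undersampling with no synthetic rows", {
  fx <- small_fixture(n_active = 60, n_inactive = 12)
  b <- build_balanced(fx$fused$matrix, fx$labels, p = 0, seed = 2)
  expect_equal(nrow(b$features), 24)
  expect_equal(sum(b$synthetic), 0)
  # every row is one of the original rows
  orig <- apply(fx$fused$matrix, 1, paste, collapse = "")
  bal <- apply(b$features, 1, paste, collapse = "")
  expect_true(all(bal %in% orig))
})

test_that("balancing is deterministic under a fixed seed", {
  fx <- small_fixture(n_active = 40, n_inactive = 10)
  b1 <- build_balanced(fx$fused$matrix, fx$labels, p = 0.5, seed = 5)
  b2 <- build_balanced(fx$fused$matrix, fx$labels, p = 0.5, seed = 5)
  expect_identical(b1$features, b2$features)
  expect_identical(b1$labels, b2$labels)
  b3 <- build_balanced(fx$fused$matrix, fx$labels, p = 0.5, seed = 6)
  expect_false(identical(b1$features, b3$features))
})

test_that("fold-wise balancing keeps validation folds synthetic-free and partitioned", {
  fx <- small_fixture(n_active = 100, n_inactive = 25, seed = 8)
  for (p in c(0, 0.5, 1)) {
    folds <- foldwise_balance(fx$fused$matrix, fx$labels, folds = 5, p = p, seed = 9)
    val_idx <- sort(unlist(lapply(folds, function(f) f$validation$indices)))
    expect_equal(val_idx, seq_along(fx$labels))  # exact partition
    for (f in folds) {
      expect_equal(sum(f$train$labels == "active"), sum(f$train$labels == "inactive"))
      # validation rows are verbatim original rows (no SMOTE interpolation)
      expect_identical(f$validation$features,
                       fx$fused$matrix[f$validation$indices, , drop = FALSE])
    }
  }
  expect_error(foldwise_balance(fx$fused$matrix, fx$labels, folds = 1, p = 0),
               "folds")
})

test_that("balanced CSV + sidecar round-trips counts and mask", {
  dir <- withr::local_tempdir()
  fx <- small_fixture(n_active = 30, n_inactive = 10, seed = 4)
  b <- build_balanced(fx$fused$matrix, fx$labels, p = 1, seed = 1)
  path <- file.path(dir, "bal.csv")
  write_balanced(b, path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$p, 1)
  expect_equal(side$counts$per_class, 30)
  expect_equal(sum(side$synthetic_mask), sum(b$synthetic))
})
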