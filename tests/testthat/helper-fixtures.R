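# Shared test fixtures, all generated in code.

# reduced view geometry for fast end-to-end tests (same five views,
# narrower; fused width 130)
small_widths <- function() c(AP2D = 20, CDKExt = 25, KR = 35, Morgan = 25, RDKIT = 25)

small_fixture <- function(n_active = 150, n_inactive = 30, seed = 11, ...) {
  generate_fingerprints(fixture_config(
    n_active = n_active, n_inactive = n_inactive, widths = small_widths(),
    signal_bits = 15, seed = seed, ...))
}

as_fused <- function(matrix, offsets) {
  structure(list(matrix = matrix, view_offsets = offsets), class = "grq_fused")
}

tiny_bgatt_config <- function(...) {
  args <- utils::modifyList(
    list(d_model = 16, d_h = 8, d_att = 8, epochs = 10, batch_size = 16, seed = 3),
    list(...))
  do.call(bgatt_config, args)
}

# independent scalar/loop GRU oracle: plain arithmetic, no matrix ops
oracle_gru_step <- function(f, h, p) {
  sig <- function(x) 1 / (1 + exp(-x))
  d_h <- length(h)
  z <- r <- cc <- ht <- numeric(d_h)
  for (j in seq_len(d_h)) {
    az <- p$b_z[j]; ar <- p$b_r[j]; ac <- p$b_c[j]
    for (i in seq_along(f)) {
      az <- az + f[i] * p$U_z[i, j]
      ar <- ar + f[i] * p$U_r[i, j]
      ac <- ac + f[i] * p$U_c[i, j]
    }
    for (i in seq_len(d_h)) {
      az <- az + h[i] * p$W_z[i, j]
      ar <- ar + h[i] * p$W_r[i, j]
    }
    z[j] <- sig(az); r[j] <- sig(ar)
  }
  for (j in seq_len(d_h)) {
    hw <- 0
    for (i in seq_len(d_h)) hw <- hw + h[i] * p$W_c[i, j]
    ac <- p$b_c[j]
    for (i in seq_along(f)) ac <- ac + f[i] * p$U_c[i, j]
    cc[j] <- tanh(ac + r[j] * hw)
    ht[j] <- (1 - z[j]) * cc[j] + z[j] * h[j]
  }
  ht
}

# dense loop-based attention oracle
oracle_attention <- function(H, W_q, W_k, W_v, d) {
  Q <- H %*% W_q; K <- H %*% W_k; V <- H %*% W_v
  n <- nrow(H)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}
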