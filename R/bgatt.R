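# BiGRU + self-attention embedding network.
#
# Each compound's fused fingerprint vector is mapped to a short token
# sequence (by default one token per descriptor view, linearly projected to a
# common width), run through a bidirectional GRU, re-weighted by scaled
# dot-product self-attention over the sequence positions, mean-pooled, and
# read out by a sigmoid head. The mean-pooled attention output (width 2*d_h;
# 4000 under the default d_h = 2000) is the feature embedding consumed by
# PCA + classifier downstream. No autograd framework is used: gradients
# (BPTT through both GRU directions, the softmax-attention Jacobian and the
# linear projections) are implemented directly with matrix algebra.
#
# Convention: vectors are rows, so a GRU gate is sigma(f %*% U + h %*% W + b)
# with U of shape d_in x d_h and W of shape d_h x d_h.

.rep_row <- function(b, n) matrix(b, nrow = n, ncol = length(b), byrow = TRUE)

.softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# orthogonal-ish init for square recurrent matrices, scaled Gaussian otherwise
.init_mat <- function(nr, nc, orthogonal = FALSE) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (orthogonal && nr == nc) qr.Q(qr(m)) else m * sqrt(1 / nr)
}

#' Construct GRU gate parameters
#'
#' @param d_in input width; `d_h` hidden width.
#' @param d_h hidden width.
#' @param seed integer RNG seed; omit for the all-zero parameter set.
#' @return list of class `grq_gru_params` with input-to-gate matrices `U_z`,
#'   `U_r`, `U_c` (`d_in x d_h`), recurrent matrices `W_z`, `W_r`, `W_c`
#'   (`d_h x d_h`) and biases `b_z`, `b_r`, `b_c`.
#' @export
gru_params <- function(d_in, d_h, seed = NULL) {
  if (is.null(seed)) {
    z <- function(nr, nc) matrix(0, nr, nc)
    p <- list(U_z = z(d_in, d_h), U_r = z(d_in, d_h), U_c = z(d_in, d_h),
              W_z = z(d_h, d_h), W_r = z(d_h, d_h), W_c = z(d_h, d_h),
              b_z = numeric(d_h), b_r = numeric(d_h), b_c = numeric(d_h))
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    p <- list(U_z = .init_mat(d_in, d_h), U_r = .init_mat(d_in, d_h),
              U_c = .init_mat(d_in, d_h),
              W_z = .init_mat(d_h, d_h, TRUE), W_r = .init_mat(d_h, d_h, TRUE),
              W_c = .init_mat(d_h, d_h, TRUE),
              b_z = numeric(d_h), b_r = numeric(d_h), b_c = numeric(d_h))
  }
  class(p) <- "grq_gru_params"
  p
}

# batched GRU step: F n x d_in, H_prev n x d_h -> list(H, cache)
.gru_step_batch <- function(F_t, H_prev, p) {
  n <- nrow(F_t)
  Z <- stats::plogis(F_t %*% p$U_z + H_prev %*% p$W_z + .rep_row(p$b_z, n))
  R <- stats::plogis(F_t %*% p$U_r + H_prev %*% p$W_r + .rep_row(p$b_r, n))
  Hc <- H_prev %*% p$W_c
  C <- tanh(F_t %*% p$U_c + R * Hc + .rep_row(p$b_c, n))
  H <- (1 - Z) * C + Z * H_prev
  list(H = H, cache = list(F_t = F_t, H_prev = H_prev, Z = Z, R = R, C = C, Hc = Hc))
}

# backward through one GRU step; accumulates into grad (same shape as params)
.gru_step_backward <- function(dH, cache, p, grad) {
  with(cache, {
    dZ <- dH * (H_prev - C)
    dC <- dH * (1 - Z)
    dHp <- dH * Z
    dAc <- dC * (1 - C^2)
    grad$U_c <- grad$U_c + crossprod(F_t, dAc)
    grad$b_c <- grad$b_c + colSums(dAc)
    dF <- dAc %*% t(p$U_c)
    dR <- dAc * Hc
    dHc <- dAc * R
    grad$W_c <- grad$W_c + crossprod(H_prev, dHc)
    dHp <- dHp + dHc %*% t(p$W_c)
    dAr <- dR * R * (1 - R)
    grad$U_r <- grad$U_r + crossprod(F_t, dAr)
    grad$W_r <- grad$W_r + crossprod(H_prev, dAr)
    grad$b_r <- grad$b_r + colSums(dAr)
    dF <- dF + dAr %*% t(p$U_r)
    dHp <- dHp + dAr %*% t(p$W_r)
    dAz <- dZ * Z * (1 - Z)
    grad$U_z <- grad$U_z + crossprod(F_t, dAz)
    grad$W_z <- grad$W_z + crossprod(H_prev, dAz)
    grad$b_z <- grad$b_z + colSums(dAz)
    dF <- dF + dAz %*% t(p$U_z)
    dHp <- dHp + dAz %*% t(p$W_z)
    list(dF = dF, dH_prev = dHp, grad = grad)
  })
}

#' One GRU step on a single input vector
#'
#' Computes the update gate `z = sigma(f U_z + h W_z + b_z)`, reset gate
#' `r = sigma(f U_r + h W_r + b_r)`, candidate state
#' `c = tanh(f U_c + r * (h W_c) + b_c)` and new hidden state
#' `h_t = (1 - z) * c + z * h_prev` (elementwise; vectors are rows).
#'
#' @param f_t input vector of length `d_in`.
#' @param h_prev hidden state vector of length `d_h`.
#' @param params a [gru_params()] object.
#' @return hidden state vector of length `d_h`, with gates `z`, `r` and
#'   candidate `c` attached as attributes.
#' @export
gru_step <- function(f_t, h_prev, params) {
  if (length(f_t) != nrow(params$U_z) || length(h_prev) != nrow(params$W_z)) {
    stop(sprintf("shape mismatch: f_t has length %d (expect %d), h_prev %d (expect %d)",
                 length(f_t), nrow(params$U_z), length(h_prev), nrow(params$W_z)))
  }
  st <- .gru_step_batch(matrix(f_t, 1), matrix(h_prev, 1), params)
  out <- drop(st$H)
  attr(out, "z") <- drop(st$cache$Z)
  attr(out, "r") <- drop(st$cache$R)
  attr(out, "c") <- drop(st$cache$C)
  out
}

#' Bidirectional GRU over a sequence
#'
#' Runs a forward GRU over positions `1..d` and a backward GRU over `d..1`,
#' both from zero initial state, and concatenates the two hidden states at
#' each position.
#'
#' @param sequence a `d x d_in` matrix (one input vector per row) or a list
#'   of input vectors.
#' @param fwd,bwd [gru_params()] for the two directions.
#' @return `d x (2 * d_h)` matrix; columns `1:d_h` are the forward states,
#'   the rest the backward states.
#' @export
bigru_forward <- function(sequence, fwd, bwd) {
  if (is.list(sequence)) sequence <- do.call(rbind, sequence)
  sequence <- as.matrix(sequence)
  d <- nrow(sequence)
  if (d == 0) stop("sequence must be non-empty")
  d_h <- nrow(fwd$W_z)
  hf <- matrix(0, d, d_h); hb <- matrix(0, d, d_h)
  h <- matrix(0, 1, d_h)
  for (t in seq_len(d)) {
    h <- .gru_step_batch(sequence[t, , drop = FALSE], h, fwd)$H
    hf[t, ] <- h
  }
  h <- matrix(0, 1, nrow(bwd$W_z))
  for (t in rev(seq_len(d))) {
    h <- .gru_step_batch(sequence[t, , drop = FALSE], h, bwd)$H
    hb[t, ] <- h
  }
  cbind(hf, hb)
}

#' Construct self-attention parameters
#'
#' @param d_in width of the attended vectors.
#' @param d_att query/key dimensionality (the softmax scaling is
#'   `1 / sqrt(d_att)`).
#' @param seed integer RNG seed; omit for identity-like initialization.
#' @return list of class `grq_att_params` with `W_q`, `W_k` (`d_in x d_att`)
#'   and `W_v` (`d_in x d_in`).
#' @export
attention_params <- function(d_in, d_att = d_in, seed = NULL) {
  if (d_att <= 0) stop("d_att must be positive")
  if (is.null(seed)) {
    p <- list(W_q = diag(1, d_in, d_att), W_k = diag(1, d_in, d_att),
              W_v = diag(1, d_in, d_in))
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    p <- list(W_q = .init_mat(d_in, d_att), W_k = .init_mat(d_in, d_att),
              W_v = .init_mat(d_in, d_in))
  }
  p$d_att <- d_att
  class(p) <- "grq_att_params"
  p
}

#' Scaled dot-product self-attention over one sequence
#'
#' `Q = H W_q`, `K = H W_k`, `V = H W_v`;
#' `output = softmax(Q K^T / sqrt(d)) V` with row-wise softmax.
#'
#' @param H `d x d_in` matrix of sequence vectors (rows).
#' @param params an [attention_params()] object.
#' @return `d x d_in` matrix of attended vectors; the `d x d` attention
#'   weight matrix (rows sum to 1) is attached as attribute `"weights"`.
#' @export
self_attention <- function(H, params) {
  H <- as.matrix(H)
  if (nrow(H) == 0) stop("H must be non-empty")
  if (ncol(H) != nrow(params$W_q)) {
    stop(sprintf("H has width %d but attention expects %d", ncol(H), nrow(params$W_q)))
  }
  Q <- H %*% params$W_q; K <- H %*% params$W_k; V <- H %*% params$W_v
  A <- .softmax_rows(Q %*% t(K) / sqrt(params$d_att))
  out <- A %*% V
  attr(out, "weights") <- A
  out
}

# ---- full model ------------------------------------------------------------

#' Default network configuration
#'
#' @param d_model token projection width.
#' @param d_h GRU hidden width per direction (embedding width is `2 * d_h`;
#'   the default 2000 gives the 4000-wide embedding).
#' @param d_att attention query/key width.
#' @param epochs,learning_rate,batch_size Adam training schedule.
#' @param weight_decay decoupled (AdamW-style) L2 decay applied at each step.
#' @param input_dropout probability of zeroing each input feature during a
#'   training step (inverted dropout; inference uses the full input). For
#'   sparse binary fingerprints this is random bit masking, the main
#'   regularizer against memorizing idiosyncratic bits of the few real
#'   minority examples.
#' @param label_smoothing epsilon for smoothed binary cross-entropy targets
#'   (`y' = y(1 - eps) + eps/2`). Bounds the optimal logits near
#'   `log((1-eps/2)/(eps/2))`, which keeps the sigmoid and tanh units out of
#'   saturation and the embedding from collapsing onto the decision axis.
#' @param patience,min_delta early stopping on a training-loss plateau.
#' @param chunk_size `NULL` for one token per descriptor view (default), or
#'   an integer to tokenize the fused vector into fixed-width chunks instead.
#' @param seed integer seed controlling initialization and batch order.
#' @return named list of configuration values.
#' @export
bgatt_config <- function(d_model = 512, d_h = 2000, d_att = 64,
                         epochs = 50, learning_rate = 1e-3, batch_size = 32,
                         weight_decay = 0.05, input_dropout = 0.2,
                         label_smoothing = 0,
                         patience = 10, min_delta = 1e-5,
                         chunk_size = NULL, seed = 1) {
  list(d_model = d_model, d_h = d_h, d_att = d_att, epochs = epochs,
       learning_rate = learning_rate, batch_size = batch_size,
       weight_decay = weight_decay, input_dropout = input_dropout,
       label_smoothing = label_smoothing,
       patience = patience, min_delta = min_delta,
       chunk_size = chunk_size, seed = seed)
}

# token column ranges: per-view offsets or fixed-width chunks
.token_ranges <- function(view_offsets, total_width, chunk_size = NULL) {
  if (is.null(chunk_size)) {
    lapply(view_offsets, function(o) c(start = o[["start"]], end = o[["end"]]))
  } else {
    starts <- seq(0L, total_width - 1L, by = chunk_size)
    rngs <- lapply(starts, function(s) c(start = s, end = min(s + chunk_size, total_width)))
    names(rngs) <- paste0("chunk", seq_along(rngs))
    rngs
  }
}

#' Initialize the BiGRU-attention model
#'
#' @param view_offsets named list of half-open 0-based column ranges (as in a
#'   `grq_fused` object) describing how the fused matrix splits into views.
#' @param total_width number of fused columns.
#' @param config a [bgatt_config()].
#' @return object of class `grq_bgatt`: per-token projection matrices,
#'   forward/backward [gru_params()], [attention_params()], sigmoid head, and
#'   the config.
#' @export
bgatt_init <- function(view_offsets, total_width, config = bgatt_config()) {
  ranges <- .token_ranges(view_offsets, total_width, config$chunk_size)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  proj <- lapply(ranges, function(r) .init_mat(r[["end"]] - r[["start"]], config$d_model))
  m <- 2L * config$d_h
  model <- list(
    proj = proj, token_ranges = ranges, total_width = total_width,
    fwd = gru_params(config$d_model, config$d_h, seed = config$seed + 1L),
    bwd = gru_params(config$d_model, config$d_h, seed = config$seed + 2L),
    att = attention_params(m, config$d_att, seed = config$seed + 3L),
    head = list(w = matrix(stats::rnorm(m) * sqrt(1 / m), m, 1), b = 0),
    config = config)
  class(model) <- "grq_bgatt"
  model
}

#' @export
print.grq_bgatt <- function(x, ...) {
  cat(sprintf("BiGRU-attention embedding model: %d tokens -> d_model %d -> d_h %d (embedding width %d)\n",
              length(x$proj), x$config$d_model, x$config$d_h, 2 * x$config$d_h))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                nrow(x$history), x$history$loss[nrow(x$history)]))
  }
  invisible(x)
}

# full forward pass on a batch; X n x total_width
# returns list(prob, emb, cache) -- cache only when keep_cache
.bgatt_forward <- function(model, X, keep_cache = FALSE) {
  n <- nrow(X)
  Tn <- length(model$token_ranges)
  m <- 2L * model$config$d_h
  d_h <- model$config$d_h

  tokens <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    r <- model$token_ranges[[t]]
    tokens[[t]] <- X[, (r[["start"]] + 1L):r[["end"]], drop = FALSE] %*% model$proj[[t]]
  }

  # BiGRU
  fcache <- vector("list", Tn); bcache <- vector("list", Tn)
  Hf <- vector("list", Tn); Hb <- vector("list", Tn)
  h <- matrix(0, n, d_h)
  for (t in seq_len(Tn)) {
    st <- .gru_step_batch(tokens[[t]], h, model$fwd)
    h <- st$H; Hf[[t]] <- h; fcache[[t]] <- st$cache
  }
  h <- matrix(0, n, d_h)
  for (t in rev(seq_len(Tn))) {
    st <- .gru_step_batch(tokens[[t]], h, model$bwd)
    h <- st$H; Hb[[t]] <- h; bcache[[t]] <- st$cache
  }
  H <- lapply(seq_len(Tn), function(t) cbind(Hf[[t]], Hb[[t]]))

  # batched self-attention over the Tn positions
  p <- model$att
  Q <- lapply(H, function(h) h %*% p$W_q)
  K <- lapply(H, function(h) h %*% p$W_k)
  V <- lapply(H, function(h) h %*% p$W_v)
  scl <- 1 / sqrt(p$d_att)
  A <- vector("list", Tn)   # A[[t]]: n x Tn attention rows for position t
  O <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    S <- vapply(seq_len(Tn), function(tp) rowSums(Q[[t]] * K[[tp]]) * scl, numeric(n))
    S <- matrix(S, n, Tn)
    At <- .softmax_rows(S)
    Ot <- matrix(0, n, m)
    for (tp in seq_len(Tn)) Ot <- Ot + At[, tp] * V[[tp]]
    A[[t]] <- At; O[[t]] <- Ot
  }

  emb <- Reduce(`+`, O) / Tn
  logit <- drop(emb %*% model$head$w) + model$head$b
  prob <- stats::plogis(logit)

  cache <- if (keep_cache) {
    list(X = X, tokens = tokens, fcache = fcache, bcache = bcache,
         H = H, Q = Q, K = K, V = V, A = A, O = O, emb = emb, prob = prob)
  }
  list(prob = prob, emb = emb, cache = cache)
}

# backward pass; y in {0,1}; returns gradient list matching model params
.bgatt_backward <- function(model, cache, y) {
  n <- length(y)
  Tn <- length(model$token_ranges)
  d_h <- model$config$d_h
  m <- 2L * d_h
  p <- model$att
  scl <- 1 / sqrt(p$d_att)

  grad <- list(
    proj = lapply(model$proj, function(P) P * 0),
    fwd = gru_params(model$config$d_model, d_h),
    bwd = gru_params(model$config$d_model, d_h),
    att = list(W_q = p$W_q * 0, W_k = p$W_k * 0, W_v = p$W_v * 0),
    head = list(w = model$head$w * 0, b = 0))

  dlogit <- (cache$prob - y) / n
  grad$head$w <- crossprod(cache$emb, dlogit)
  grad$head$b <- sum(dlogit)
  dEmb <- dlogit %*% t(model$head$w)        # n x m
  dO <- lapply(seq_len(Tn), function(t) dEmb / Tn)

  dH <- lapply(seq_len(Tn), function(t) matrix(0, n, m))
  dQ <- lapply(seq_len(Tn), function(t) matrix(0, n, p$d_att))
  dK <- lapply(seq_len(Tn), function(t) matrix(0, n, p$d_att))
  dV <- lapply(seq_len(Tn), function(t) matrix(0, n, m))

  for (t in seq_len(Tn)) {
    At <- cache$A[[t]]
    dAt <- vapply(seq_len(Tn), function(tp) rowSums(dO[[t]] * cache$V[[tp]]), numeric(n))
    dAt <- matrix(dAt, n, Tn)
    for (tp in seq_len(Tn)) dV[[tp]] <- dV[[tp]] + At[, tp] * dO[[t]]
    dS <- At * (dAt - rowSums(dAt * At))    # softmax Jacobian, row-wise
    for (tp in seq_len(Tn)) {
      dQ[[t]] <- dQ[[t]] + dS[, tp] * cache$K[[tp]] * scl
      dK[[tp]] <- dK[[tp]] + dS[, tp] * cache$Q[[t]] * scl
    }
  }
  for (t in seq_len(Tn)) {
    grad$att$W_q <- grad$att$W_q + crossprod(cache$H[[t]], dQ[[t]])
    grad$att$W_k <- grad$att$W_k + crossprod(cache$H[[t]], dK[[t]])
    grad$att$W_v <- grad$att$W_v + crossprod(cache$H[[t]], dV[[t]])
    dH[[t]] <- dQ[[t]] %*% t(p$W_q) + dK[[t]] %*% t(p$W_k) + dV[[t]] %*% t(p$W_v)
  }

  dTok <- lapply(seq_len(Tn), function(t) matrix(0, n, model$config$d_model))

  # forward direction: chain runs 1 -> Tn, so backprop Tn -> 1
  dh <- matrix(0, n, d_h)
  for (t in rev(seq_len(Tn))) {
    dh <- dh + dH[[t]][, seq_len(d_h), drop = FALSE]
    st <- .gru_step_backward(dh, cache$fcache[[t]], model$fwd, grad$fwd)
    grad$fwd <- st$grad
    dTok[[t]] <- dTok[[t]] + st$dF
    dh <- st$dH_prev
  }
  # backward direction: chain runs Tn -> 1, so backprop 1 -> Tn
  dh <- matrix(0, n, d_h)
  for (t in seq_len(Tn)) {
    dh <- dh + dH[[t]][, d_h + seq_len(d_h), drop = FALSE]
    st <- .gru_step_backward(dh, cache$bcache[[t]], model$bwd, grad$bwd)
    grad$bwd <- st$grad
    dTok[[t]] <- dTok[[t]] + st$dF
    dh <- st$dH_prev
  }

  for (t in seq_len(Tn)) {
    r <- model$token_ranges[[t]]
    Xv <- cache$X[, (r[["start"]] + 1L):r[["end"]], drop = FALSE]
    grad$proj[[t]] <- crossprod(Xv, dTok[[t]])
  }
  grad
}

# recursive Adam update over nested parameter lists
.adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, t_step = 1, weight_decay = 0) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        if (!is.numeric(p[[k]]) && !is.list(p[[k]])) next
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mhat <- m2 / (1 - beta1^t_step)
      vhat <- v2 / (1 - beta2^t_step)
      # decoupled (AdamW-style) weight decay
      p2 <- p - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p)
      list(p = p2, m = m2, v = v2)
    }
  }
  walk(params, grads, state$m, state$v)
}

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like) else p * 0
}

.trainable <- function(model) {
  list(proj = model$proj, fwd = unclass(model$fwd)[1:9], bwd = unclass(model$bwd)[1:9],
       att = model$att[c("W_q", "W_k", "W_v")], head = model$head)
}

.restore_trainable <- function(model, tp) {
  model$proj <- tp$proj
  model$fwd[1:9] <- tp$fwd; model$bwd[1:9] <- tp$bwd
  model$att[c("W_q", "W_k", "W_v")] <- tp$att
  model$head <- tp$head
  model
}

#' Train the BiGRU-attention network
#'
#' Trains all parameters (view projections, both GRU directions, attention,
#' head) end-to-end on binary cross-entropy with Adam, mini-batches shuffled
#' deterministically per epoch, and optional early stopping when the training
#' loss plateaus. The positive class for the head is the first level of
#' `factor(labels)` unless `positive` is given.
#'
#' @param features numeric matrix (`n x total_width`) or a `grq_fused`.
#' @param labels binary labels.
#' @param view_offsets column ranges of the descriptor views (taken from
#'   `features` when it is a `grq_fused`).
#' @param config a [bgatt_config()].
#' @param positive label value treated as the positive class (score 1).
#' @return a trained `grq_bgatt`; element `history` is a data.frame with
#'   per-epoch `loss` and training `bacc`.
#' @export
train_bgatt <- function(features, labels, view_offsets = NULL,
                        config = bgatt_config(), positive = NULL) {
  if (inherits(features, "grq_fused")) {
    view_offsets <- features$view_offsets
    features <- features$matrix
  }
  X <- as.matrix(features)
  if (is.null(view_offsets) && is.null(config$chunk_size)) {
    stop("view_offsets required (or set chunk_size in the config)")
  }
  if (length(labels) != nrow(X)) stop("labels length must match feature rows")
  lev <- if (is.null(positive)) sort(unique(as.character(labels)))[1] else positive
  y <- as.numeric(as.character(labels) == lev)
  if (length(unique(y)) < 2) stop("labels must contain two classes")

  model <- bgatt_init(view_offsets %||% list(), ncol(X), config)
  model$positive <- lev
  if (config$epochs == 0) {
    model$history <- data.frame(epoch = integer(0), loss = numeric(0), bacc = numeric(0))
    return(model)
  }

  state <- list(m = .zeros_like(.trainable(model)), v = .zeros_like(.trainable(model)))
  n <- nrow(X)
  t_step <- 0
  best_loss <- Inf; stale <- 0
  history <- vector("list", config$epochs)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  for (epoch in seq_len(config$epochs)) {
    set.seed(config$seed + 1000L + epoch)
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      drop_p <- config$input_dropout %||% 0
      if (drop_p > 0) {
        mask <- matrix(stats::runif(length(Xb)) >= drop_p, nrow(Xb), ncol(Xb))
        Xb <- Xb * mask / (1 - drop_p)
      }
      fw <- .bgatt_forward(model, Xb, keep_cache = TRUE)
      ls <- config$label_smoothing %||% 0
      yb <- y[idx] * (1 - ls) + ls / 2
      eps <- 1e-12
      loss <- -mean(yb * log(fw$prob + eps) + (1 - yb) * log(1 - fw$prob + eps))
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d (lr %g); try a smaller learning rate",
                     epoch, config$learning_rate))
      }
      epoch_loss <- epoch_loss + loss * length(idx)
      grad <- .bgatt_backward(model, fw$cache, yb)
      t_step <- t_step + 1
      upd <- .adam_update(.trainable(model), grad, state,
                          lr = config$learning_rate, t_step = t_step,
                          weight_decay = config$weight_decay %||% 0)
      model <- .restore_trainable(model, upd$p)
      state <- list(m = upd$m, v = upd$v)
    }
    epoch_loss <- epoch_loss / n
    pr <- .bgatt_forward(model, X)$prob
    cm <- confusion(y, as.numeric(pr >= 0.5), positive = 1)
    bacc <- metrics_from_cm(cm)$bacc
    history[[epoch]] <- data.frame(epoch = epoch, loss = epoch_loss, bacc = bacc)
    if (epoch_loss < best_loss - config$min_delta) {
      best_loss <- epoch_loss; stale <- 0
    } else {
      stale <- stale + 1
      if (stale >= config$patience) break
    }
  }
  model$history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  model
}

#' Extract feature embeddings from a trained model
#'
#' Forward pass without the classification head: token projections, BiGRU,
#' self-attention, mean-pool. Inference is deterministic and performs no
#' parameter updates.
#'
#' @param model a `grq_bgatt`.
#' @param features matrix or `grq_fused` with the model's training width.
#' @return `n x (2 * d_h)` embedding matrix.
#' @export
extract_embeddings <- function(model, features) {
  if (inherits(features, "grq_fused")) features <- features$matrix
  X <- as.matrix(features)
  if (ncol(X) != model$total_width) {
    stop(sprintf("features have width %d but the model was built for %d",
                 ncol(X), model$total_width))
  }
  if (nrow(X) == 0) return(matrix(0, 0, 2L * model$config$d_h))
  .bgatt_forward(model, X)$emb
}

#' Predict class probabilities with the network head
#'
#' @param model trained `grq_bgatt`.
#' @param features matrix or `grq_fused`.
#' @return numeric vector of probabilities of the model's positive class.
#' @export
predict_bgatt <- function(model, features) {
  if (inherits(features, "grq_fused")) features <- features$matrix
  X <- as.matrix(features)
  if (nrow(X) == 0) return(numeric(0))
  .bgatt_forward(model, X)$prob
}

#' Save / load a model as JSON
#'
#' Checkpoints are a versioned JSON container of all parameter arrays plus
#' the config, portable across sessions.
#'
#' @param model a `grq_bgatt`.
#' @param path file path.
#' @return `load_bgatt` returns the restored model.
#' @export
save_bgatt <- function(model, path) {
  ser <- list(format = "grq_bgatt", version = 1L,
              config = model$config, positive = model$positive,
              total_width = model$total_width,
              token_ranges = lapply(model$token_ranges, as.list),
              proj = lapply(model$proj, unclass),
              fwd = lapply(unclass(model$fwd)[1:9], unclass),
              bwd = lapply(unclass(model$bwd)[1:9], unclass),
              att = lapply(model$att[c("W_q", "W_k", "W_v")], unclass),
              d_att = model$att$d_att,
              head = list(w = as.numeric(model$head$w), b = model$head$b))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_bgatt
#' @export
load_bgatt <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$format, "grq_bgatt")) stop(path, " is not a model checkpoint")
  cfg <- ser$config
  cfg$chunk_size <- if (length(cfg$chunk_size)) cfg$chunk_size else NULL
  ranges <- lapply(ser$token_ranges, function(r) c(start = r$start, end = r$end))
  model <- bgatt_init(ranges, ser$total_width, do.call(bgatt_config, cfg))
  model$token_ranges <- ranges
  model$proj <- lapply(seq_along(model$proj), function(i) as.matrix(ser$proj[[i]]))
  names(model$proj) <- names(ranges)
  for (nm in names(ser$fwd)) model$fwd[[nm]] <- if (grepl("^b_", nm)) as.numeric(ser$fwd[[nm]]) else as.matrix(ser$fwd[[nm]])
  for (nm in names(ser$bwd)) model$bwd[[nm]] <- if (grepl("^b_", nm)) as.numeric(ser$bwd[[nm]]) else as.matrix(ser$bwd[[nm]])
  for (nm in c("W_q", "W_k", "W_v")) model$att[[nm]] <- as.matrix(ser$att[[nm]])
  model$head <- list(w = matrix(ser$head$w, ncol = 1), b = ser$head$b)
  model$positive <- ser$positive
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
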