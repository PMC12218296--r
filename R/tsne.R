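# Exact (O(n^2)) t-SNE for qualitative visualization of feature
# representations. Standard formulation: per-point Gaussian input affinities
# calibrated by binary search to the requested perplexity, symmetrized and
# normalized; Student-t (df = 1) low-dimensional kernel; gradient descent on
# the KL divergence with momentum and the usual early-exaggeration phase.

.tsne_p_matrix <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) { p <- rep(1e-12, length(di)); sumP <- sum(p) }
      H <- log(sumP) + beta * sum(di * p) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sumP
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Two-dimensional t-SNE embedding
#'
#' @param X numeric matrix (rows = compounds). Requires
#'   `nrow(X) > 3 * perplexity`.
#' @param perplexity effective neighbourhood size (default 30).
#' @param max_iter gradient-descent iterations.
#' @param seed integer RNG seed (initial layout).
#' @param learning_rate step size; `"auto"` uses `max(n / 12, 50)`.
#' @return `n x 2` coordinate matrix.
#' @export
tsne_embed <- function(X, perplexity = 30, max_iter = 500, seed = 1,
                       learning_rate = "auto") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= 3 * perplexity) {
    stop(sprintf("need more than 3 * perplexity = %g rows, have %d", 3 * perplexity, n))
  }
  eta <- if (identical(learning_rate, "auto")) max(n / 12, 50) else learning_rate
  P <- .tsne_p_matrix(X, perplexity)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  momentum <- 0.5

  for (iter in seq_len(max_iter)) {
    Pit <- if (iter <= 100) P * 4 else P    # early exaggeration
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 250) momentum <- 0.8
  }
  Y
}

#' t-SNE scatter of a feature representation
#'
#' Embeds the rows in 2-D with [tsne_embed()] and draws a class-colored
#' scatter (active compounds green, inactive red, matching the conventional
#' chemical-space plots).
#'
#' @param features numeric matrix or `grq_fused`.
#' @param labels class labels, `"active"`/`"inactive"` (others plotted grey).
#' @param perplexity,seed,max_iter passed to [tsne_embed()].
#' @param file optional PNG path; when given the plot is written there.
#' @param main plot title.
#' @return invisibly, a data.frame with columns `x`, `y`, `label`.
#' @export
tsne_plot <- function(features, labels, perplexity = 30, seed = 1,
                      max_iter = 500, file = NULL, main = "t-SNE") {
  if (inherits(features, "grq_fused")) features <- features$matrix
  Y <- tsne_embed(features, perplexity = perplexity, seed = seed,
                  max_iter = max_iter)
  cols <- ifelse(labels == "active", "forestgreen",
                 ifelse(labels == "inactive", "firebrick", "grey50"))
  draw <- function() {
    graphics::plot(Y, col = cols, pch = 19, cex = 0.6,
                   xlab = "t-SNE 1", ylab = "t-SNE 2", main = main)
    graphics::legend("topright", legend = c("active", "inactive"),
                     col = c("forestgreen", "firebrick"), pch = 19, bty = "n")
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    draw()
    grDevices::dev.off()
  } else {
    draw()
  }
  invisible(data.frame(x = Y[, 1], y = Y[, 2], label = labels))
}
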