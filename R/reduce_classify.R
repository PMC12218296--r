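#' Fit PCA keeping components up to an explained-variance threshold
#'
#' Fits PCA on training rows only (the transform is centered by the training
#' mean; no scaling) and keeps the smallest number of leading components
#' whose cumulative explained-variance ratio reaches the threshold.
#'
#' @param x numeric matrix of training embeddings (rows >= 2).
#' @param variance_threshold value in `(0, 1]` (default 0.95).
#' @return object of class `grq_pca` with `mean`, `rotation`
#'   (`width x k`), `explained` (per-component variance ratios) and `k`.
#' @export
fit_pca <- function(x, variance_threshold = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to fit PCA")
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 || variance_threshold > 1) {
    stop("variance_threshold must be in (0, 1]")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  # drop numerically-null trailing components so rank-deficient data reports
  # its true rank at threshold 1
  nz <- ratio > .Machine$double.eps * length(ratio)
  cum <- cumsum(ratio)
  k <- which(cum >= variance_threshold - 1e-12)[1]
  if (is.na(k)) k <- sum(nz)
  k <- min(k, sum(nz))
  structure(list(mean = pc$center, rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = ratio, k = k,
                 variance_threshold = variance_threshold, width = ncol(x)),
            class = "grq_pca")
}

#' @export
print.grq_pca <- function(x, ...) {
  cat(sprintf("PCA: %d components explain %.1f%% of variance (threshold %.0f%%, input width %d)\n",
              x$k, 100 * sum(x$explained[seq_len(x$k)]), 100 * x$variance_threshold, x$width))
  invisible(x)
}

#' Project data with a fitted PCA transform
#'
#' Test rows use the training-fitted mean and rotation unchanged.
#'
#' @param transform a `grq_pca`.
#' @param x matrix with the training width.
#' @return `n x k` score matrix.
#' @export
apply_pca <- function(transform, x) {
  x <- as.matrix(x)
  if (ncol(x) != transform$width) {
    stop(sprintf("x has width %d but the transform was fitted on width %d",
                 ncol(x), transform$width))
  }
  sweep(x, 2, transform$mean) %*% transform$rotation
}

# ---- classifier registry ---------------------------------------------------

.CLASSIFIERS <- c("ET", "MLP", "ADA", "RF", "SVM", "XGB", "DT", "KNN",
                  "LDA", "PLS", "LR")

#' Supported classifier names and default hyperparameter grids
#'
#' Eleven classifiers share one grid-search protocol: ET (extremely
#' randomized trees, via ranger with random split points), RF, SVM (RBF),
#' XGB, DT, KNN, LDA, PLS (PLS-DA: SIMPLS regression on 0/1 with a 0.5
#' cutoff), LR, MLP (single hidden layer) and ADA (SAMME AdaBoost over
#' depth-1 rpart stumps). LGBM is not available in this implementation.
#'
#' @return named list of default grids (each a named list of value vectors).
#' @export
default_grids <- function() {
  list(
    ET = list(num_trees = c(100, 250, 500)),
    RF = list(num_trees = c(100, 250, 500)),
    SVM = list(cost = c(0.1, 1, 10), gamma = c(NA, 0.01)),  # NA = 1/ncol heuristic
    XGB = list(nrounds = c(100, 250), max_depth = c(3, 6), eta = 0.1),
    DT = list(cp = c(0.01, 0.001)),
    KNN = list(k = c(3, 5, 7)),
    LDA = list(),
    PLS = list(ncomp = c(2, 5, 10)),
    LR = list(),
    MLP = list(size = c(16, 32), decay = c(0, 1e-3)),
    ADA = list(n_rounds = c(50, 100)))
}

#' Define a classifier specification
#'
#' @param name one of `"ET"`, `"MLP"`, `"ADA"`, `"RF"`, `"SVM"`, `"XGB"`,
#'   `"DT"`, `"KNN"`, `"LDA"`, `"PLS"`, `"LR"`.
#' @param grid hyperparameter grid (named list of value vectors); defaults to
#'   [default_grids()] for the name. A single-point grid skips the search.
#' @param seed integer seed shared by the model and the CV folds.
#' @return object of class `grq_clf_spec`.
#' @export
classifier_spec <- function(name, grid = NULL, seed = 1) {
  if (!name %in% .CLASSIFIERS) {
    stop("unknown classifier '", name, "'; supported: ",
         paste(.CLASSIFIERS, collapse = ", "),
         if (name == "LGBM") " (LGBM is not available in this implementation)")
  }
  structure(list(name = name, grid = grid %||% default_grids()[[name]], seed = seed),
            class = "grq_clf_spec")
}

# expand a named list of value vectors into a data.frame of combinations
.expand_grid <- function(grid) {
  if (length(grid) == 0) return(data.frame(row.names = 1))
  do.call(expand.grid, c(grid, list(stringsAsFactors = FALSE)))
}

# ---- hand-written learners (no installed package provides them) -----------

# SAMME AdaBoost over rpart stumps; y in {0,1}
.ada_fit <- function(X, y, n_rounds = 50, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(y = factor(y), X)
  stumps <- list(); alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- as.numeric(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y)) / sum(w)
    if (err <= 1e-10) { stumps[[r]] <- fit; alphas[r] <- 10; break }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[r]] <- fit; alphas[r] <- alpha
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  if (!length(stumps)) {  # nothing better than chance: constant model
    stumps <- list(NULL); alphas <- 0
  }
  list(stumps = stumps, alphas = alphas)
}

.ada_score <- function(fit, X) {
  df <- data.frame(X)
  f <- rep(0, nrow(df))
  for (r in seq_along(fit$stumps)) {
    if (is.null(fit$stumps[[r]])) next
    pred <- as.numeric(as.character(predict(fit$stumps[[r]], df, type = "class")))
    f <- f + fit$alphas[r] * (2 * pred - 1)
  }
  stats::plogis(2 * f)  # margin -> probability squashing
}

# SIMPLS partial least squares regression on y in {0,1}
.pls_fit <- function(X, y, ncomp = 2) {
  X <- as.matrix(X)
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx); yc <- y - my
  p <- ncol(Xc)
  ncomp <- min(ncomp, p, nrow(X) - 1)
  S <- crossprod(Xc, yc)          # p x 1
  R <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    r <- S                         # dominant direction of X'y residual
    t_sc <- Xc %*% r
    t_sc <- t_sc - mean(t_sc)
    normt <- sqrt(sum(t_sc^2))
    if (normt < 1e-12) { ncomp <- a - 1L; break }
    t_sc <- t_sc / normt; r <- r / normt
    P[, a] <- crossprod(Xc, t_sc)
    q[a] <- crossprod(yc, t_sc)
    v <- P[, a]
    if (a > 1) v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], P[, a])
    v <- v / sqrt(sum(v^2))
    V[, a] <- v
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
  }
  if (ncomp == 0) return(list(coef = rep(0, p), mx = mx, my = my))
  keep <- seq_len(ncomp)
  coef <- R[, keep, drop = FALSE] %*% q[keep]
  list(coef = drop(coef), mx = mx, my = my)
}

.pls_score <- function(fit, X) {
  raw <- drop(sweep(as.matrix(X), 2, fit$mx) %*% fit$coef) + fit$my
  pmin(pmax(raw, 0), 1)
}

# ---- fit / score dispatch --------------------------------------------------

# y01: numeric 0/1 with 1 = positive class
.fit_one <- function(name, X, y01, pars, seed) {
  X <- as.matrix(X)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(y = factor(y01, levels = c(0, 1)), X)
  switch(name,
    ET = ranger::ranger(x = X, y = df$y, num.trees = pars$num_trees %||% 250,
                        splitrule = "extratrees", num.random.splits = 1,
                        replace = FALSE, sample.fraction = 1,
                        probability = TRUE, seed = seed, num.threads = 1),
    RF = ranger::ranger(x = X, y = df$y, num.trees = pars$num_trees %||% 250,
                        probability = TRUE, seed = seed, num.threads = 1),
    SVM = {
      gamma <- pars$gamma
      if (is.null(gamma) || is.na(gamma)) gamma <- 1 / ncol(X)
      e1071::svm(X, df$y, kernel = "radial", cost = pars$cost %||% 1,
                 gamma = gamma, probability = TRUE)
    },
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y01)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = pars$max_depth %||% 6,
                      learning_rate = pars$eta %||% 0.1,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = pars$nrounds %||% 100, verbose = 0)
    },
    DT = rpart::rpart(y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(cp = pars$cp %||% 0.01, xval = 0)),
    KNN = list(X = X, y = y01, k = pars$k %||% 5),
    LDA = MASS::lda(X, grouping = df$y),
    PLS = .pls_fit(X, y01, ncomp = pars$ncomp %||% 2),
    LR = suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial())),
    MLP = {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      nnet::nnet(X, y01, size = pars$size %||% 16, decay = pars$decay %||% 0,
                 maxit = 200, entropy = TRUE, trace = FALSE, MaxNWts = 1e6)
    },
    ADA = .ada_fit(X, y01, n_rounds = pars$n_rounds %||% 50, seed = seed),
    stop("unknown classifier '", name, "'"))
}

.score_one <- function(name, fit, X) {
  X <- as.matrix(X)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(X)
  switch(name,
    ET = ,
    RF = predict(fit, X, num.threads = 1)$predictions[, "1"],
    SVM = {
      pr <- predict(fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    XGB = predict(fit, X),
    DT = predict(fit, df, type = "prob")[, "1"],
    KNN = {
      pr <- class::knn(fit$X, X, cl = factor(fit$y, levels = c(0, 1)),
                       k = fit$k, prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "1", p_win, 1 - p_win)
    },
    LDA = predict(fit, X)$posterior[, "1"],
    PLS = .pls_score(fit, X),
    LR = unname(predict(fit, df, type = "response")),
    MLP = drop(predict(fit, X)),
    ADA = .ada_score(fit, X),
    stop("unknown classifier '", name, "'"))
}

#' Train a classifier with grid-search cross-validation
#'
#' For every hyperparameter combination in the spec's grid, runs stratified
#' k-fold cross-validation with fold assignments shared across combinations
#' (and across classifiers using the same `fold_seed`), scores each
#' combination by the chosen metric (AUPR by default), then refits the best
#' combination on all rows. A single-point grid skips the search.
#'
#' @param spec a [classifier_spec()].
#' @param X numeric feature matrix.
#' @param y labels with exactly two classes.
#' @param positive the positive class for scoring (default: minority class).
#' @param folds CV folds for the grid search (default 10).
#' @param metric selection metric, `"aupr"`, `"auc"` or `"bacc"`.
#' @param fold_seed seed for the shared fold assignment (default `spec$seed`).
#' @return object of class `grq_classifier` with the fitted model, chosen
#'   parameters and the grid-search table.
#' @export
train_classifier <- function(spec, X, y, positive = NULL, folds = 10,
                             metric = c("aupr", "auc", "bacc"), fold_seed = NULL) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  tab <- table(y)
  if (length(tab) != 2) stop("y must contain exactly two classes")
  if (is.null(positive)) positive <- names(tab)[which.min(tab)]
  y01 <- as.numeric(y == positive)
  combos <- .expand_grid(spec$grid)
  search <- NULL

  if (nrow(combos) > 1) {
    fold_id <- stratified_folds(y, folds, seed = fold_seed %||% spec$seed)
    scores <- vapply(seq_len(nrow(combos)), function(i) {
      pars <- as.list(combos[i, , drop = FALSE])
      cvs <- rep(NA_real_, length(y))
      for (f in sort(unique(fold_id))) {
        val <- fold_id == f
        fit <- .fit_one(spec$name, X[!val, , drop = FALSE], y01[!val], pars, spec$seed)
        cvs[val] <- .score_one(spec$name, fit, X[val, , drop = FALSE])
      }
      m <- score_metrics(cvs, y01, positive = 1)
      m[[metric]]
    }, numeric(1))
    search <- cbind(combos, metric = scores)
    best <- as.list(combos[which.max(scores), , drop = FALSE])
  } else {
    best <- if (nrow(combos)) as.list(combos[1, , drop = FALSE]) else list()
  }

  fit <- .fit_one(spec$name, X, y01, best, spec$seed)
  structure(list(name = spec$name, fit = fit, chosen = best, positive = positive,
                 search = search, width = ncol(X), seed = spec$seed),
            class = "grq_classifier")
}

#' Predict positive-class probabilities
#'
#' @param model a `grq_classifier` from [train_classifier()].
#' @param X feature matrix with the training width.
#' @return numeric scores in `[0, 1]`; hard labels are `score >= 0.5`.
#' @export
predict_scores <- function(model, X) {
  if (!inherits(model, "grq_classifier")) stop("model must come from train_classifier()")
  X <- as.matrix(X)
  if (nrow(X) == 0) return(numeric(0))
  if (ncol(X) != model$width) {
    stop(sprintf("X has width %d but the model was trained on width %d",
                 ncol(X), model$width))
  }
  as.numeric(.score_one(model$name, model$fit, X))
}

#' @export
print.grq_classifier <- function(x, ...) {
  cat(sprintf("%s classifier (positive = %s, %d features)\n", x$name, x$positive, x$width))
  if (length(x$chosen)) {
    cat("  parameters:", paste(names(x$chosen), unlist(x$chosen), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
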