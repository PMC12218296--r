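#' SMOTE oversampling of a minority class
#'
#' Generates `n_new` synthetic minority rows. Each synthetic row is
#' `x_i + lambda * (x_nn - x_i)` where `x_i` is a uniformly drawn minority
#' row, `x_nn` one of its `k` nearest minority neighbours under Euclidean
#' distance, and `lambda ~ Uniform(0, 1)`. Synthetic fingerprint values are
#' left continuous in `[0, 1]`; they are not re-binarized.
#'
#' @param minority numeric matrix of minority-class rows.
#' @param n_new number of synthetic rows to generate.
#' @param k number of nearest neighbours considered (default 5).
#' @param seed integer RNG seed.
#' @return `n_new x ncol(minority)` matrix (0 rows when `n_new = 0`).
#' @export
smote_oversample <- function(minority, n_new, k = 5, seed = 1) {
  minority <- as.matrix(minority)
  if (n_new == 0) return(minority[integer(0), , drop = FALSE])
  if (k < 1) stop("k must be >= 1")
  if (nrow(minority) < k + 1) {
    stop(sprintf("need at least k+1 = %d minority rows for k = %d neighbours (have %d); use a smaller k",
                 k + 1, k, nrow(minority)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # k nearest minority neighbours of every minority row (self excluded)
  d <- as.matrix(stats::dist(minority))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1) matrix(nn, ncol = 1) else t(nn)

  base_idx <- sample.int(nrow(minority), n_new, replace = TRUE)
  nn_pick <- nn[cbind(base_idx, sample.int(k, n_new, replace = TRUE))]
  lambda <- stats::runif(n_new)
  xi <- minority[base_idx, , drop = FALSE]
  xn <- minority[nn_pick, , drop = FALSE]
  out <- xi + lambda * (xn - xi)
  attr(out, "parents") <- cbind(base = base_idx, neighbour = nn_pick)
  out
}

#' Build a 1:1 balanced dataset at SMOTE proportion p
#'
#' The per-class target size is `round(n_min + p * (n_maj - n_min))`:
#' at `p = 0` the majority is undersampled all the way down to the minority
#' count (pure random undersampling, RUS); at `p = 1` the minority is
#' oversampled all the way up to the majority count (pure SMOTE); in between
#' the two meet proportionally. SMOTE supplies `target - n_min` synthetic
#' minority rows and the majority class is undersampled uniformly without
#' replacement to the same target, so the output is always balanced 1:1.
#'
#' @param features numeric matrix, one row per compound.
#' @param labels vector with exactly two distinct values; the rarer one is
#'   the minority class.
#' @param p SMOTE proportion in `[0, 1]`.
#' @param k SMOTE neighbour count.
#' @param seed integer RNG seed (drives SMOTE, undersampling and the final
#'   shuffle).
#' @return object of class `grq_balanced`: list with `features`, `labels`,
#'   `synthetic` (logical mask, TRUE for SMOTE-generated rows), `p`, `seed`,
#'   and `counts`.
#' @export
build_balanced <- function(features, labels, p, k = 5, seed = 1) {
  features <- as.matrix(features)
  if (length(labels) != nrow(features)) stop("labels length must match feature rows")
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single value in [0, 1]")
  }
  tab <- table(labels)
  if (length(tab) != 2) stop("labels must contain exactly two classes, got ", length(tab))
  minority_class <- names(tab)[which.min(tab)]
  majority_class <- setdiff(names(tab), minority_class)
  n_min <- min(tab); n_maj <- max(tab)
  target <- as.integer(round(n_min + p * (n_maj - n_min)))

  min_idx <- which(labels == minority_class)
  maj_idx <- which(labels == majority_class)
  n_new <- target - n_min

  synth <- smote_oversample(features[min_idx, , drop = FALSE], n_new, k = k, seed = seed)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)
  maj_keep <- sample(maj_idx, target)

  X <- rbind(features[min_idx, , drop = FALSE], synth,
             features[maj_keep, , drop = FALSE])
  y <- c(rep(minority_class, n_min + n_new), rep(majority_class, target))
  is_synth <- c(rep(FALSE, n_min), rep(TRUE, n_new), rep(FALSE, target))

  perm <- sample.int(nrow(X))
  out <- list(
    features = X[perm, , drop = FALSE],
    labels = y[perm],
    synthetic = is_synth[perm],
    p = p, seed = seed,
    counts = list(minority_class = minority_class, majority_class = majority_class,
                  per_class = target, n_synthetic = n_new,
                  n_min_original = as.integer(n_min), n_maj_original = as.integer(n_maj)))
  class(out) <- "grq_balanced"
  out
}

#' @export
print.grq_balanced <- function(x, ...) {
  cat(sprintf("Balanced dataset: %d rows (%d per class), p = %g, %d synthetic minority rows\n",
              nrow(x$features), x$counts$per_class, x$p, x$counts$n_synthetic))
  invisible(x)
}

#' Stratified fold assignment
#'
#' @param labels class labels.
#' @param folds number of folds.
#' @param seed integer RNG seed.
#' @return integer vector of fold ids in `1:folds`.
#' @export
stratified_folds <- function(labels, folds, seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

#' Leakage-safe fold-wise balancing
#'
#' Assigns stratified cross-validation folds, then applies [build_balanced()]
#' to the training portion of each fold only. Validation folds are left
#' untouched, so no SMOTE-generated row can ever leak into a validation
#' partition.
#'
#' @inheritParams build_balanced
#' @param folds number of folds (>= 2).
#' @return list of length `folds`; each element has `train` (a
#'   `grq_balanced`), `validation` (list with `features`, `labels`,
#'   `indices`), and `fold`.
#' @export
foldwise_balance <- function(features, labels, folds, p, k = 5, seed = 1) {
  features <- as.matrix(features)
  fold_id <- stratified_folds(labels, folds, seed = seed)
  lapply(seq_len(folds), function(f) {
    val <- fold_id == f
    tr_lab <- labels[!val]
    if (length(unique(tr_lab)) < 2 || length(unique(labels[val])) < 2) {
      stop("fold ", f, " has a single class; use fewer folds or more data")
    }
    list(
      fold = f,
      train = build_balanced(features[!val, , drop = FALSE], tr_lab,
                             p = p, k = k, seed = seed + f),
      validation = list(features = features[val, , drop = FALSE],
                        labels = labels[val], indices = which(val)))
  })
}

#' Serialize a balanced dataset to CSV plus a JSON sidecar
#'
#' @param balanced a `grq_balanced`.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @export
write_balanced <- function(balanced, path) {
  df <- data.frame(label = balanced$labels, synthetic = balanced$synthetic,
                   balanced$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(p = balanced$p, seed = balanced$seed, counts = balanced$counts,
         synthetic_mask = balanced$synthetic),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
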