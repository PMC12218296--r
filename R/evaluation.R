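#' Pipeline configuration
#'
#' Bundles every stage toggle and seed for the end-to-end pipeline:
#' balancing (SMOTE proportion `p`, neighbour count `k`), the
#' BiGRU-attention embedding, the PCA threshold and the final classifier.
#'
#' @param p SMOTE proportion in `[0, 1]` (default 0.75, the best-performing
#'   proportion).
#' @param k SMOTE neighbour count.
#' @param use_aug,use_bgatt stage toggles (both on = complete model; both off
#'   = raw fused features straight to PCA + classifier).
#' @param cv_mode `"safe"` balances inside each CV training fold only
#'   (leakage-free, default); `"paper"` balances once before folding, so
#'   synthetic rows can appear in validation folds.
#' @param variance_threshold PCA explained-variance threshold.
#' @param classifier a [classifier_spec()]; default ET with a single-point
#'   grid (250 trees).
#' @param bgatt a [bgatt_config()].
#' @param positive positive class for metrics; `NULL` = minority class.
#' @param seed master seed; stage seeds are derived from it.
#' @return named list of class `grq_pipe_config`.
#' @export
pipeline_config <- function(p = 0.75, k = 5, use_aug = TRUE, use_bgatt = TRUE,
                            cv_mode = c("safe", "paper"),
                            variance_threshold = 0.95,
                            classifier = classifier_spec("ET", grid = list(num_trees = 250)),
                            bgatt = bgatt_config(),
                            positive = NULL, seed = 1) {
  cv_mode <- match.arg(cv_mode)
  structure(list(p = p, k = k, use_aug = use_aug, use_bgatt = use_bgatt,
                 cv_mode = cv_mode, variance_threshold = variance_threshold,
                 classifier = classifier, bgatt = bgatt, positive = positive,
                 seed = seed),
            class = "grq_pipe_config")
}

#' Fit the full pipeline on a training set
#'
#' Depending on the toggles: balance the classes (SMOTE + RUS), train the
#' BiGRU-attention network on the (balanced) training rows and embed them,
#' fit PCA on the training embeddings, and train the classifier on the PCA
#' scores. Nothing in the fit touches rows outside `features`.
#'
#' @param features training matrix or `grq_fused`.
#' @param labels training labels (two classes).
#' @param config a [pipeline_config()].
#' @return object of class `grq_pipeline` with all fitted stages.
#' @export
fit_pipeline <- function(features, labels, config = pipeline_config()) {
  view_offsets <- NULL
  if (inherits(features, "grq_fused")) {
    view_offsets <- features$view_offsets
    features <- features$matrix
  }
  features <- as.matrix(features)
  tab <- table(labels)
  positive <- config$positive %||% names(tab)[which.min(tab)]

  if (config$use_aug) {
    bal <- build_balanced(features, labels, p = config$p, k = config$k,
                          seed = config$seed)
    Xtr <- bal$features; ytr <- bal$labels
  } else {
    bal <- NULL
    Xtr <- features; ytr <- as.character(labels)
  }

  # PCA operates on the learned embedding; without the network the fused
  # fingerprints go to the classifier directly (the "Fusion -> classifier"
  # baseline), since an explained-variance cut on raw near-independent bits
  # discards the planted signal along with the noise.
  if (config$use_bgatt) {
    bcfg <- config$bgatt
    bcfg$seed <- config$seed + 10L
    net <- train_bgatt(Xtr, ytr, view_offsets = view_offsets, config = bcfg,
                       positive = positive)
    Etr <- extract_embeddings(net, Xtr)
    pca <- fit_pca(Etr, variance_threshold = config$variance_threshold)
    Ztr <- apply_pca(pca, Etr)
  } else {
    net <- NULL
    pca <- NULL
    Ztr <- Xtr
  }
  spec <- config$classifier
  spec$seed <- config$seed + 20L
  clf <- train_classifier(spec, Ztr, ytr, positive = positive,
                          fold_seed = config$seed + 30L)

  structure(list(config = config, positive = positive, balanced = bal,
                 net = net, pca = pca, classifier = clf,
                 view_offsets = view_offsets, width = ncol(features)),
            class = "grq_pipeline")
}

#' Score new compounds with a fitted pipeline
#'
#' @param pipeline a `grq_pipeline`.
#' @param features matrix or `grq_fused` with the training width.
#' @return numeric positive-class probabilities.
#' @export
predict_pipeline <- function(pipeline, features) {
  if (inherits(features, "grq_fused")) features <- features$matrix
  features <- as.matrix(features)
  if (ncol(features) != pipeline$width) {
    stop(sprintf("features have width %d, pipeline expects %d",
                 ncol(features), pipeline$width))
  }
  Z <- if (!is.null(pipeline$net)) {
    apply_pca(pipeline$pca, extract_embeddings(pipeline$net, features))
  } else {
    features
  }
  predict_scores(pipeline$classifier, Z)
}

#' Evaluate a fitted pipeline on an independent test set
#'
#' @inheritParams predict_pipeline
#' @param labels test labels.
#' @return a `grq_metrics` report (`mode = "independent"`).
#' @export
evaluate_pipeline <- function(pipeline, features, labels) {
  scores <- predict_pipeline(pipeline, features)
  score_metrics(scores, labels, positive = pipeline$positive, mode = "independent")
}

# macro-average a list of grq_metrics into one cv_mean report
.average_metrics <- function(reports) {
  keys <- c("sn", "sp", "bacc", "mcc", "f1", "acc", "auc", "aupr")
  avg <- lapply(keys, function(k) mean(vapply(reports, function(r) r[[k]], numeric(1))))
  names(avg) <- keys
  cm_tot <- confusion_from_counts(
    tp = sum(vapply(reports, function(r) r$cm$tp, numeric(1))),
    fn = sum(vapply(reports, function(r) r$cm$fn, numeric(1))),
    tn = sum(vapply(reports, function(r) r$cm$tn, numeric(1))),
    fp = sum(vapply(reports, function(r) r$cm$fp, numeric(1))),
    positive = reports[[1]]$positive)
  out <- c(avg, list(cm = cm_tot, positive = reports[[1]]$positive, mode = "cv_mean",
                     folds = lapply(reports, function(r) unclass(r)[keys])))
  class(out) <- "grq_metrics"
  out
}

#' Cross-validated evaluation of the pipeline
#'
#' Stratified k-fold cross-validation of the configured pipeline. In
#' `"safe"` mode each fold's training portion is balanced independently and
#' validation folds contain only real rows (no SMOTE leakage); in `"paper"`
#' mode the data are balanced once up front and the folds partition the
#' balanced rows. Fold metrics are macro-averaged.
#'
#' @param features matrix or `grq_fused`.
#' @param labels class labels.
#' @param config a [pipeline_config()].
#' @param folds number of folds (default 10).
#' @return a `grq_metrics` with `mode = "cv_mean"`; per-fold values in
#'   `$folds`.
#' @export
run_cv <- function(features, labels, config = pipeline_config(), folds = 10) {
  view_offsets <- NULL
  if (inherits(features, "grq_fused")) {
    view_offsets <- features$view_offsets
    features <- features$matrix
  }
  features <- as.matrix(features)
  labels <- as.character(labels)

  if (config$cv_mode == "paper" && config$use_aug) {
    bal <- build_balanced(features, labels, p = config$p, k = config$k,
                          seed = config$seed)
    features <- bal$features
    labels <- bal$labels
    inner <- config; inner$use_aug <- FALSE   # already balanced
  } else {
    inner <- config
  }

  fold_id <- stratified_folds(labels, folds, seed = config$seed + 100L)
  reports <- lapply(seq_len(folds), function(f) {
    val <- fold_id == f
    if (length(unique(labels[val])) < 2 || length(unique(labels[!val])) < 2) {
      stop("fold ", f, " has a single class; use fewer folds or more data")
    }
    fcfg <- inner; fcfg$seed <- inner$seed + f
    Xtr <- features[!val, , drop = FALSE]
    if (!is.null(view_offsets)) {
      Xtr <- structure(list(matrix = Xtr, view_offsets = view_offsets),
                       class = "grq_fused")
    }
    pipe <- fit_pipeline(Xtr, labels[!val], fcfg)
    evaluate_pipeline(pipe, features[val, , drop = FALSE], labels[val])
  })
  .average_metrics(reports)
}

#' Ablation experiment over the augmentation and embedding stages
#'
#' Runs the four stage combinations — baseline (neither), augmentation only,
#' embedding only, and the complete model — each trained on the training set
#' and evaluated on the independent test set (and optionally by
#' cross-validation).
#'
#' @param train_features,train_labels training data (matrix or `grq_fused`).
#' @param test_features,test_labels independent test data.
#' @param config a [pipeline_config()]; its `use_aug`/`use_bgatt` toggles are
#'   overridden per strategy.
#' @param include_cv also run [run_cv()] per strategy (slower).
#' @param folds CV folds when `include_cv = TRUE`.
#' @return list with `reports` (per-strategy independent-test
#'   `grq_metrics`), optional `cv_reports`, and `table` (a data.frame in the
#'   strategy x metric layout of published ablation tables).
#' @export
run_ablation <- function(train_features, train_labels, test_features, test_labels,
                         config = pipeline_config(), include_cv = FALSE, folds = 10) {
  strategies <- list(
    "-AUG-BGATT" = c(FALSE, FALSE),
    "+AUG-BGATT" = c(TRUE, FALSE),
    "-AUG+BGATT" = c(FALSE, TRUE),
    "+AUG+BGATT" = c(TRUE, TRUE))
  reports <- list(); cv_reports <- list(); pipes <- list()
  for (nm in names(strategies)) {
    cfg <- config
    cfg$use_aug <- strategies[[nm]][1]
    cfg$use_bgatt <- strategies[[nm]][2]
    pipe <- fit_pipeline(train_features, train_labels, cfg)
    pipes[[nm]] <- pipe
    reports[[nm]] <- evaluate_pipeline(pipe, test_features, test_labels)
    if (include_cv) cv_reports[[nm]] <- run_cv(train_features, train_labels, cfg, folds)
  }
  out <- list(reports = reports, table = metrics_table(reports), pipelines = pipes)
  if (include_cv) {
    out$cv_reports <- cv_reports
    out$cv_table <- metrics_table(cv_reports)
  }
  out
}
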