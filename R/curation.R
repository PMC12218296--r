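#' Convert an IC50 in nanomolar to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar half-maximal
#' inhibitory concentration, so an IC50 of 1000 nM (1 uM, 1e-6 M) maps to
#' pIC50 = 6. For an input in nM the identity is `pIC50 = 9 - log10(IC50)`.
#'
#' @param ic50_nM positive numeric vector of IC50 values in nanomolar.
#' @return numeric vector of pIC50 values (unitless).
#' @examples
#' ic50_to_pic50(c(1, 1000, 10000))  # 9, 6, 5
#' @export
ic50_to_pic50 <- function(ic50_nM) {
  if (!is.numeric(ic50_nM)) stop("ic50_nM must be numeric")
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("ic50_nM must be finite and strictly positive")
  }
  9 - log10(ic50_nM)
}

#' Label compounds by potency
#'
#' Compounds with pIC50 above 6 (IC50 below 1 uM) are labeled `active`,
#' those below 5 (IC50 above 10 uM) `inactive`, and the band in between
#' `intermediate`. Intermediates are excluded from all downstream modeling
#' by [curate_bioactivity()].
#'
#' @param pic50 finite numeric vector.
#' @return character vector in `c("active", "inactive", "intermediate")`.
#' @export
label_compound <- function(pic50) {
  if (any(!is.finite(pic50))) stop("pic50 must be finite")
  ifelse(pic50 > 6, "active", ifelse(pic50 < 5, "inactive", "intermediate"))
}

#' Filter a raw bioactivity table
#'
#' Applies the curation rules for an IC50 bioactivity extract:
#' \enumerate{
#'   \item keep only rows whose relation symbol is exactly `"="` (censored
#'     measurements `<`, `>`, `<=`, `>=` are discarded);
#'   \item drop rows with missing or non-positive IC50;
#'   \item drop exact duplicate `(compound_id, ic50_nM)` pairs;
#'   \item for compounds with replicate measurements, drop the compound when
#'     the standard deviation of its replicate pIC50 values exceeds
#'     `sd_cutoff` (default 2), otherwise collapse the replicates with
#'     `aggregate_fun` (default mean) of the pIC50 values.
#' }
#'
#' @param rows data.frame with columns `compound_id`, `smiles`, `relation`,
#'   `ic50_nM` (extra columns are carried through from the first row per
#'   compound).
#' @param sd_cutoff maximum allowed replicate pIC50 standard deviation.
#' @param aggregate_fun statistic used to collapse replicate pIC50 values,
#'   `"mean"` or `"median"`.
#' @return data.frame with one row per surviving compound, keeping the raw
#'   schema (`compound_id`, `smiles`, `relation`, `ic50_nM`) plus the
#'   aggregated `pic50`, so filtering is idempotent; attribute
#'   `"curation_report"` holds per-step drop counts.
#' @export
filter_rows <- function(rows, sd_cutoff = 2, aggregate_fun = c("mean", "median")) {
  aggregate_fun <- match.arg(aggregate_fun)
  if (!is.data.frame(rows) || nrow(rows) == 0) stop("rows must be a non-empty data.frame")
  needed <- c("compound_id", "smiles", "relation", "ic50_nM")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))

  n0 <- nrow(rows)
  keep <- !is.na(rows$relation) & rows$relation == "="
  n_relation <- sum(!keep)
  rows <- rows[keep, , drop = FALSE]

  keep <- !is.na(rows$ic50_nM) & is.finite(rows$ic50_nM) & rows$ic50_nM > 0
  n_missing <- sum(!keep)
  rows <- rows[keep, , drop = FALSE]

  dup <- duplicated(rows[, c("compound_id", "ic50_nM")])
  n_dup <- sum(dup)
  rows <- rows[!dup, , drop = FALSE]

  if (nrow(rows) == 0) {
    stop(sprintf(
      "all %d rows filtered out (relation: %d, missing/invalid IC50: %d, duplicates: %d)",
      n0, n_relation, n_missing, n_dup))
  }

  rows$pic50 <- ic50_to_pic50(rows$ic50_nM)
  agg <- if (aggregate_fun == "mean") mean else stats::median
  split_rows <- split(rows, rows$compound_id)
  sds <- vapply(split_rows, function(d) {
    if (nrow(d) < 2) 0 else stats::sd(d$pic50)
  }, numeric(1))
  n_noisy <- sum(sds > sd_cutoff)
  kept <- split_rows[sds <= sd_cutoff]
  out <- do.call(rbind, lapply(kept, function(d) {
    pic50 <- agg(d$pic50)
    data.frame(compound_id = d$compound_id[1], smiles = d$smiles[1],
               relation = "=", ic50_nM = 10^(9 - pic50), pic50 = pic50,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out) || nrow(out) == 0) {
    stop(sprintf("all compounds dropped by replicate SD filter (cutoff %g)", sd_cutoff))
  }
  rownames(out) <- NULL
  attr(out, "curation_report") <- list(
    n_input = n0,
    dropped_relation = n_relation,
    dropped_missing_ic50 = n_missing,
    dropped_duplicate = n_dup,
    dropped_replicate_sd = n_noisy,
    n_output = nrow(out))
  out
}

#' Curate a raw bioactivity table into labeled compound records
#'
#' Runs [filter_rows()], converts to pIC50, attaches activity labels and
#' removes intermediate compounds (5 <= pIC50 <= 6).
#'
#' @inheritParams filter_rows
#' @param drop_intermediate drop the intermediate potency band (default TRUE).
#' @return data.frame with columns `compound_id`, `smiles`, `pic50`, `label`;
#'   attribute `"curation_report"` extends the [filter_rows()] report with the
#'   intermediate count and final class counts.
#' @export
curate_bioactivity <- function(rows, sd_cutoff = 2,
                               aggregate_fun = c("mean", "median"),
                               drop_intermediate = TRUE) {
  recs <- filter_rows(rows, sd_cutoff = sd_cutoff, aggregate_fun = aggregate_fun)
  report <- attr(recs, "curation_report")
  recs$label <- label_compound(recs$pic50)
  n_inter <- sum(recs$label == "intermediate")
  if (drop_intermediate) recs <- recs[recs$label != "intermediate", , drop = FALSE]
  rownames(recs) <- NULL
  report$dropped_intermediate <- n_inter
  report$n_active <- sum(recs$label == "active")
  report$n_inactive <- sum(recs$label == "inactive")
  attr(recs, "curation_report") <- report
  recs
}

#' Split curated compounds into training and independent test sets
#'
#' Samples the requested number of active and inactive compounds uniformly
#' without replacement into the independent test set; the remainder forms the
#' training set. Deterministic for a fixed seed.
#'
#' @param records curated data.frame with a `label` column containing only
#'   `"active"` and `"inactive"`.
#' @param n_test_active,n_test_inactive per-class test-set sizes.
#' @param seed integer RNG seed.
#' @return list of class `grq_split` with elements `train`, `test` (both
#'   data.frames), `seed`, and `counts` (per-side class counts).
#' @export
split_train_test <- function(records, n_test_active, n_test_inactive, seed) {
  if (any(records$label == "intermediate")) {
    stop("records must not contain intermediate compounds")
  }
  idx_act <- which(records$label == "active")
  idx_ina <- which(records$label == "inactive")
  if (n_test_active > length(idx_act) || n_test_inactive > length(idx_ina)) {
    stop(sprintf("requested test counts (%d active, %d inactive) exceed availability (%d, %d)",
                 n_test_active, n_test_inactive, length(idx_act), length(idx_ina)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  test_idx <- c(
    if (n_test_active > 0) sample(idx_act, n_test_active) else integer(0),
    if (n_test_inactive > 0) sample(idx_ina, n_test_inactive) else integer(0))
  test <- records[sort(test_idx), , drop = FALSE]
  train <- records[setdiff(seq_len(nrow(records)), test_idx), , drop = FALSE]
  rownames(test) <- rownames(train) <- NULL
  out <- list(
    train = train, test = test, seed = seed,
    counts = list(
      train_active = sum(train$label == "active"),
      train_inactive = sum(train$label == "inactive"),
      test_active = sum(test$label == "active"),
      test_inactive = sum(test$label == "inactive")))
  class(out) <- "grq_split"
  out
}

#' @export
print.grq_split <- function(x, ...) {
  cat("Train/test split (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  train: %d active / %d inactive\n",
              x$counts$train_active, x$counts$train_inactive))
  cat(sprintf("  test:  %d active / %d inactive\n",
              x$counts$test_active, x$counts$test_inactive))
  invisible(x)
}

#' Read a raw bioactivity CSV
#'
#' @param path CSV file with a header.
#' @param columns named character vector mapping the required names
#'   (`compound_id`, `smiles`, `relation`, `ic50_nM`) to the file's column
#'   names; defaults to `id, smiles, relation, ic50_nM`.
#' @return data.frame with the standard column names.
#' @export
read_bioactivity_csv <- function(path,
                                 columns = c(compound_id = "id", smiles = "smiles",
                                             relation = "relation", ic50_nM = "ic50_nM")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols)) stop("columns not found in ", path, ": ",
                                 paste(missing_cols, collapse = ", "))
  out <- raw[, unname(columns), drop = FALSE]
  names(out) <- names(columns)
  out$ic50_nM <- as.numeric(out$ic50_nM)
  out
}

#' Write a curated split to CSV plus a JSON curation report
#'
#' @param split a `grq_split` from [split_train_test()].
#' @param dir output directory (created if needed).
#' @param report optional curation report list to serialize alongside.
#' @return invisibly, the paths written.
#' @export
write_split <- function(split, dir, report = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(train = file.path(dir, "train.csv"), test = file.path(dir, "test.csv"))
  utils::write.csv(split$train[, c("compound_id", "smiles", "pic50", "label")],
                   paths["train"], row.names = FALSE)
  utils::write.csv(split$test[, c("compound_id", "smiles", "pic50", "label")],
                   paths["test"], row.names = FALSE)
  info <- c(list(seed = split$seed), split$counts, if (!is.null(report)) report)
  report_path <- file.path(dir, "curation_report.json")
  jsonlite::write_json(info, report_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, report = report_path))
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
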