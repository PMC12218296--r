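# The five fingerprint views and their fixed widths. The fused representation
# concatenates them in this order, giving 780+1024+4857+2048+2048 = 10757 columns.
.VIEW_WIDTHS <- c(AP2D = 780L, CDKExt = 1024L, KR = 4857L,
                  Morgan = 2048L, RDKIT = 2048L)

#' Fingerprint view names and widths
#'
#' The pipeline represents each compound by five fingerprint views: 2D atom
#' pairs (AP2D, 780 bits), the extended CDK fingerprint (CDKExt, 1024 bits),
#' Klekota-Roth substructure keys (KR, 4857 bits), Morgan circular
#' fingerprints (2048 bits) and RDKit topological fingerprints (2048 bits).
#'
#' @return named integer vector of per-view widths.
#' @export
view_widths <- function() .VIEW_WIDTHS

#' Construct a FeatureView
#'
#' @param name one of `names(view_widths())`.
#' @param matrix numeric matrix, one row per compound, `view_widths()[name]`
#'   columns, non-negative and free of missing values.
#' @param widths named widths to validate against (override for non-default
#'   view geometries, e.g. reduced synthetic fixtures).
#' @return object of class `grq_view`.
#' @export
feature_view <- function(name, matrix, widths = view_widths()) {
  if (!name %in% names(widths)) {
    stop("unknown view '", name, "'; available: ", paste(names(widths), collapse = ", "))
  }
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != widths[[name]]) {
    stop(sprintf("view %s must have %d columns, got %d", name, widths[[name]], ncol(matrix)))
  }
  if (anyNA(matrix)) stop("view matrix must not contain missing values")
  if (any(matrix < 0)) stop("view matrix must be non-negative")
  structure(list(name = name, matrix = matrix, d_view = ncol(matrix)),
            class = "grq_view")
}

#' Compute one fingerprint view for a list of SMILES
#'
#' Fingerprint computation is delegated to a pluggable provider. A provider is
#' either a function `f(smiles, view, widths)` returning a numeric matrix with
#' one row per SMILES, or a named list of such functions keyed by view name.
#' The package ships a file-backed provider ([file_provider()]) for
#' precomputed PADEL-style CSV matrices and a seeded synthetic provider
#' ([synthetic_provider()]); external tools (PADEL, RDKit) can be wrapped as
#' provider functions. Rows whose fingerprints a provider reports as
#' unparseable (all-NA rows) are dropped; the caller is told which, so the
#' drop can be applied consistently across views.
#'
#' @param smiles_list character vector of SMILES (or compound keys understood
#'   by the provider).
#' @param view view name.
#' @param provider provider function or named list of provider functions.
#' @param widths view geometry (default [view_widths()]).
#' @return a `grq_view`; attribute `"dropped"` lists indices of dropped rows.
#' @export
compute_view <- function(smiles_list, view, provider, widths = view_widths()) {
  if (!view %in% names(widths)) {
    stop("provider has no view '", view, "'; available: ",
         paste(names(widths), collapse = ", "))
  }
  f <- if (is.function(provider)) provider else provider[[view]]
  if (is.null(f)) {
    stop("provider has no view '", view, "'; available: ",
         paste(names(provider), collapse = ", "))
  }
  m <- f(smiles_list, view, widths)
  m <- as.matrix(m)
  if (nrow(m) != length(smiles_list)) {
    stop("provider returned ", nrow(m), " rows for ", length(smiles_list), " SMILES")
  }
  bad <- which(apply(m, 1, function(r) all(is.na(r))))
  if (length(bad)) m <- m[-bad, , drop = FALSE]
  v <- feature_view(view, m, widths = widths)
  attr(v, "dropped") <- bad
  v
}

#' File-backed fingerprint provider
#'
#' Reads precomputed per-view fingerprint matrices from CSV files whose first
#' column is the compound id and remaining columns are the bits/counts.
#'
#' @param paths named character vector mapping view names to CSV paths.
#' @return provider function for [compute_view()]; compounds are matched by
#'   id, so `smiles_list` should carry the ids used in the files.
#' @export
file_provider <- function(paths) {
  force(paths)
  function(ids, view, widths) {
    if (!view %in% names(paths)) {
      stop("provider has no view '", view, "'; available: ",
           paste(names(paths), collapse = ", "))
    }
    tab <- utils::read.csv(paths[[view]], stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
    hit <- match(as.character(ids), rownames(m))
    out <- matrix(NA_real_, length(ids), ncol(m))
    ok <- !is.na(hit)
    out[ok, ] <- m[hit[ok], , drop = FALSE]
    out
  }
}

#' Fuse fingerprint views into one wide matrix
#'
#' Column-wise concatenation of the five views in the fixed order
#' AP2D, CDKExt, KR, Morgan, RDKIT. With the default widths the fused matrix
#' has 10,757 columns. Per-view half-open column ranges are recorded so each
#' view can be sliced back out exactly.
#'
#' @param views list of `grq_view` objects, one per view name, in the fixed
#'   order above.
#' @param widths expected view geometry.
#' @return object of class `grq_fused` with elements `matrix` and
#'   `view_offsets` (named list of `c(start, end)` half-open 0-based ranges).
#' @export
fuse_views <- function(views, widths = view_widths()) {
  expected <- names(widths)
  got <- vapply(views, function(v) v$name, character(1))
  if (length(got) != length(expected) || any(got != expected)) {
    stop("views must be exactly ", paste(expected, collapse = ", "),
         " in that order; got ", paste(got, collapse = ", "))
  }
  n <- unique(vapply(views, function(v) nrow(v$matrix), integer(1)))
  if (length(n) != 1) stop("views disagree on row count: ", paste(n, collapse = ", "))
  mat <- do.call(cbind, lapply(views, function(v) v$matrix))
  offsets <- list()
  at <- 0L
  for (v in views) {
    offsets[[v$name]] <- c(start = at, end = at + v$d_view)
    at <- at + v$d_view
  }
  colnames(mat) <- NULL
  structure(list(matrix = mat, view_offsets = offsets), class = "grq_fused")
}

#' Slice one view back out of a fused matrix
#'
#' @param fused a `grq_fused` (or any matrix paired with `view_offsets`).
#' @param name view name.
#' @return the view's columns.
#' @export
slice_view <- function(fused, name) {
  off <- fused$view_offsets[[name]]
  if (is.null(off)) stop("no view '", name, "' in fused matrix")
  fused$matrix[, (off[["start"]] + 1L):off[["end"]], drop = FALSE]
}

#' Write a fused (or per-view) matrix as an id + bits CSV
#'
#' @param matrix numeric matrix.
#' @param ids compound ids, one per row.
#' @param path output CSV path.
#' @export
write_fingerprint_csv <- function(matrix, ids, path) {
  stopifnot(length(ids) == nrow(matrix))
  df <- data.frame(id = ids, matrix, check.names = FALSE)
  names(df) <- c("id", paste0("bit", seq_len(ncol(matrix))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
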