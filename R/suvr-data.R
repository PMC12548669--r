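#' SUVR dataset container
#'
#' Bundles a subjects-by-regions matrix of standardized uptake value ratios
#' (SUVR) with subject identifiers, volume-of-interest (VOI) names, a group
#' label and optional per-subject covariates. This is the input type consumed
#' by every network-construction function in the package.
#'
#' @param values numeric N x d matrix of SUVR values (dimensionless ratios,
#'   e.g. pons-referenced uptake); rows are subjects, columns are VOIs.
#' @param group single character label for the diagnostic group
#'   (e.g. \code{"CU"}, \code{"MCI"}, \code{"AD"}).
#' @param subject_ids character vector of N unique subject identifiers;
#'   defaults to the rownames of \code{values} or \code{"sub_<i>"}.
#' @param voi_names character vector of d unique VOI names; defaults to the
#'   colnames of \code{values} or \code{"VOI_<j>"}.
#' @param covariates optional numeric N x c matrix of subject covariates
#'   (e.g. age in years, sex coded 0/1); used by
#'   \code{\link{residualize_covariates}}.
#'
#' @return An object of class \code{"suvr_dataset"}: a list with elements
#'   \code{values}, \code{group}, \code{subject_ids}, \code{voi_names} and
#'   \code{covariates}.
#'
#' @details Validation is strict: at least 2 subjects and 2 VOIs, no missing
#'   or non-finite entries, all SUVR values strictly positive, and unique
#'   subject/VOI labels. Datasets violating any of these are rejected with a
#'   message naming the offending rows/columns; imputation is deliberately
#'   out of scope.
#'
#' @examples
#' x <- suvr_dataset(matrix(rexp(20) + 0.5, 5, 4), group = "CU")
#' x
#' @export
suvr_dataset <- function(values, group = "group", subject_ids = NULL,
                         voi_names = NULL, covariates = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  n <- nrow(values)
  d <- ncol(values)
  if (n < 2L || d < 2L)
    stop("need at least 2 subjects and 2 VOIs (got ", n, " x ", d, ")")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("missing or non-finite SUVR values at (row, column): ",
         paste(sprintf("(%d, %d)", bad[, 1L], bad[, 2L])[seq_len(min(5L, nrow(bad)))],
               collapse = ", "),
         if (nrow(bad) > 5L) sprintf(" and %d more", nrow(bad) - 5L))
  }
  if (any(values <= 0))
    stop("SUVR values must be strictly positive; ",
         sum(values <= 0), " non-positive entries found")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- sprintf("sub_%03d", seq_len(n))
  }
  if (is.null(voi_names)) {
    voi_names <- colnames(values)
    if (is.null(voi_names)) voi_names <- sprintf("VOI_%02d", seq_len(d))
  }
  subject_ids <- as.character(subject_ids)
  voi_names <- as.character(voi_names)
  if (length(subject_ids) != n) stop("subject_ids length != number of rows")
  if (length(voi_names) != d) stop("voi_names length != number of columns")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject_ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyDuplicated(voi_names))
    stop("duplicate voi_names: ",
         paste(unique(voi_names[duplicated(voi_names)]), collapse = ", "))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.numeric(covariates) || nrow(covariates) != n)
      stop("covariates must be a numeric matrix with one row per subject")
    if (anyNA(covariates)) stop("covariates contain missing values")
  }
  dimnames(values) <- list(subject_ids, voi_names)
  structure(
    list(values = values, group = as.character(group)[1L],
         subject_ids = subject_ids, voi_names = voi_names,
         covariates = covariates),
    class = "suvr_dataset")
}

#' @export
print.suvr_dataset <- function(x, ...) {
  cat(sprintf("SUVR dataset: %d subjects x %d VOIs, group '%s'%s\n",
              nrow(x$values), ncol(x$values), x$group,
              if (is.null(x$covariates)) ""
              else sprintf(", %d covariate(s)", ncol(x$covariates))))
  invisible(x)
}

#' @export
dim.suvr_dataset <- function(x) dim(x$values)

#' Read a SUVR table from delimited text
#'
#' Parses a CSV of SUVR values: header row of VOI names, one subject per row,
#' first column holding the subject identifier. Covariate columns can be
#' split off by name.
#'
#' @param path path to a CSV file.
#' @param group group label attached to the returned dataset.
#' @param covariate_cols optional character vector of column names to treat
#'   as covariates rather than VOIs.
#' @param voi_list optional path to a text file with one VOI name per line;
#'   when given, only these columns are kept (in the listed order).
#'
#' @return A validated \code{\link{suvr_dataset}}.
#' @seealso \code{\link{write_suvr_table}}
#' @export
read_suvr_table <- function(path, group = "group", covariate_cols = NULL,
                            voi_list = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("expected at least 3 columns (subject id + 2 VOIs) in ", path)
  subject_ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  covariates <- NULL
  if (!is.null(covariate_cols)) {
    miss <- setdiff(covariate_cols, names(df))
    if (length(miss) > 0L)
      stop("covariate columns not found: ", paste(miss, collapse = ", "))
    covariates <- as.matrix(df[, covariate_cols, drop = FALSE])
    df <- df[, setdiff(names(df), covariate_cols), drop = FALSE]
  }
  if (!is.null(voi_list)) {
    vois <- readLines(voi_list)
    vois <- vois[nzchar(trimws(vois))]
    miss <- setdiff(vois, names(df))
    if (length(miss) > 0L)
      stop("VOIs listed but absent from table: ", paste(miss, collapse = ", "))
    df <- df[, vois, drop = FALSE]
  }
  nonnum <- names(df)[!vapply(df, is.numeric, logical(1L))]
  if (length(nonnum) > 0L)
    stop("non-numeric SUVR columns: ", paste(nonnum, collapse = ", "))
  values <- as.matrix(df)
  rownames(values) <- subject_ids
  suvr_dataset(values, group = group, subject_ids = subject_ids,
               voi_names = colnames(values), covariates = covariates)
}

#' Write a SUVR dataset to CSV
#'
#' Inverse of \code{\link{read_suvr_table}}: subject identifiers in the first
#' column, VOI names in the header, covariates (if any) as trailing columns.
#'
#' @param x a \code{\link{suvr_dataset}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_suvr_table <- function(x, path) {
  stopifnot(inherits(x, "suvr_dataset"))
  df <- data.frame(subject_id = x$subject_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$covariates)) {
    cov <- as.data.frame(x$covariates)
    if (is.null(colnames(x$covariates)))
      names(cov) <- sprintf("cov_%d", seq_len(ncol(cov)))
    df <- cbind(df, cov)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Weighted network container
#'
#' A weighted undirected network over VOIs: a symmetric d x d matrix of
#' intersubject Pearson correlation weights in [-1, 1] with a companion
#' symmetric matrix of p-values. Self-correlations are not edges: the
#' diagonal is stored as 0 so that graph measures (density, degree) are
#' computed without self-loops.
#'
#' @param weights symmetric numeric d x d matrix with zero diagonal.
#' @param pvalues symmetric numeric d x d matrix of edge p-values in [0, 1].
#' @param voi_names d VOI labels.
#' @param alpha optional significance level if the network has been
#'   FDR-corrected.
#' @param correction character tag recording the corrections applied
#'   (\code{"none"}, \code{"fdr"} or \code{"fdr+pmap"}).
#' @param theta optional probability-map threshold applied (see
#'   \code{\link{apply_pmap_threshold}}).
#' @return An object of class \code{"mbn_network"}.
#' @export
mbn_network <- function(weights, pvalues = NULL, voi_names = NULL,
                        alpha = NULL, correction = "none", theta = NULL) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("`weights` must be a square matrix")
  d <- nrow(weights)
  if (d < 2L) stop("network needs at least 2 nodes")
  if (max(abs(weights - t(weights))) > 1e-8) stop("`weights` must be symmetric")
  if (any(abs(diag(weights)) > 0)) stop("diagonal of `weights` must be 0")
  if (any(abs(weights) > 1 + 1e-12)) stop("weights must lie in [-1, 1]")
  if (is.null(pvalues)) {
    pvalues <- matrix(NA_real_, d, d)
  } else {
    if (!all(dim(pvalues) == d)) stop("pvalues dimension mismatch")
    if (!all(is.na(pvalues)) &&
        max(abs(pvalues - t(pvalues)), na.rm = TRUE) > 1e-8)
      stop("`pvalues` must be symmetric")
  }
  if (is.null(voi_names)) {
    voi_names <- colnames(weights)
    if (is.null(voi_names)) voi_names <- sprintf("VOI_%02d", seq_len(d))
  }
  dimnames(weights) <- list(voi_names, voi_names)
  dimnames(pvalues) <- list(voi_names, voi_names)
  structure(
    list(weights = weights, pvalues = pvalues, voi_names = voi_names,
         alpha = alpha, correction = correction, theta = theta),
    class = "mbn_network")
}

#' @export
print.mbn_network <- function(x, ...) {
  d <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("MBN: %d VOIs, %d edges (density %.3f), correction: %s%s\n",
              d, ne, ne / (d * (d - 1) / 2), x$correction,
              if (is.null(x$alpha)) "" else sprintf(" (alpha = %g)", x$alpha)))
  invisible(x)
}

#' Write a network and its metadata
#'
#' Writes the weight matrix as a labeled CSV, the p-value matrix as a second
#' CSV (suffix \code{_pvalues}), and a JSON sidecar (suffix \code{.meta.json})
#' recording the correction applied, alpha, theta and any seed, so a network
#' written to disk is fully auditable. \code{\link{read_network}} inverts it.
#'
#' @param net an \code{\link{mbn_network}}.
#' @param path output CSV path for the weight matrix.
#' @param seed optional integer seed to record in the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path, seed = NULL) {
  stopifnot(inherits(net, "mbn_network"))
  .write_square(net$weights, path)
  .write_square(net$pvalues, .sidecar_path(path, "_pvalues.csv"))
  meta <- list(voi_count = nrow(net$weights),
               correction = net$correction,
               alpha = net$alpha, theta = net$theta, seed = seed)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1L))],
                       .sidecar_path(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network written by \code{\link{write_network}}
#'
#' @param path path to the weight-matrix CSV.
#' @return An \code{\link{mbn_network}} with metadata restored from the
#'   JSON sidecar.
#' @export
read_network <- function(path) {
  w <- .read_square(path)
  pv_path <- .sidecar_path(path, "_pvalues.csv")
  pv <- if (file.exists(pv_path)) .read_square(pv_path) else NULL
  meta_path <- .sidecar_path(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  mbn_network(w, pvalues = pv, voi_names = colnames(w),
              alpha = meta$alpha, theta = meta$theta,
              correction = if (is.null(meta$correction)) "none" else meta$correction)
}

.sidecar_path <- function(path, suffix) {
  sub("\\.csv$", "", path, ignore.case = TRUE) |> paste0(suffix)
}

.write_square <- function(m, path) {
  df <- data.frame(voi = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

.read_square <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  m
}
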