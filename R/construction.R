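#' Intersubject Pearson correlation network
#'
#' Computes the weighted adjacency matrix of a metabolic brain network: the
#' Pearson correlation between every pair of VOI columns across subjects,
#'
#' \deqn{r_{pq} = \frac{\sum_i (y_{ip} - \bar y_p)(y_{iq} - \bar y_q)}
#'   {\sqrt{\sum_i (y_{ip} - \bar y_p)^2}\sqrt{\sum_i (y_{iq} - \bar y_q)^2}},}
#'
#' together with two-sided p-values from the exact t transform
#' \eqn{t = r\sqrt{(N-2)/(1-r^2)}} on \eqn{N - 2} degrees of freedom.
#' Negative correlations are retained as signed weights; the diagonal is 0.
#'
#' @param x a \code{\link{suvr_dataset}} with at least 3 subjects.
#' @return An uncorrected \code{\link{mbn_network}}.
#' @export
pearson_adjacency <- function(x) {
  stopifnot(inherits(x, "suvr_dataset"))
  v <- x$values
  n <- nrow(v)
  if (n < 3L) stop("need at least 3 subjects for correlation p-values")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance VOI column(s): ",
         paste(x$voi_names[sds == 0], collapse = ", "))
  r <- stats::cor(v)
  # exact t transform; clamp r^2 away from 1 to keep t finite for
  # perfectly collinear columns (p -> 0 there anyway)
  r2 <- pmin(r^2, 1 - 1e-15)
  tval <- abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(tval, df = n - 2, lower.tail = FALSE)
  diag(r) <- 0
  diag(p) <- 0
  r[abs(r) > 1] <- sign(r[abs(r) > 1])  # guard fp overshoot
  mbn_network(r, pvalues = p, voi_names = x$voi_names, correction = "none")
}

#' Benjamini-Hochberg FDR correction of network edges
#'
#' Applies the Benjamini-Hochberg step-up procedure to the d(d-1)/2
#' upper-triangle p-values (each edge counted once) and zeroes the weights of
#' edges that do not survive at level \code{alpha}.
#'
#' @param net an \code{\link{mbn_network}} with populated p-values.
#' @param alpha significance level in (0, 1).
#' @return The corrected \code{\link{mbn_network}}, with \code{alpha}
#'   recorded and \code{correction = "fdr"}.
#' @export
fdr_correct <- function(net, alpha) {
  stopifnot(inherits(net, "mbn_network"), alpha > 0, alpha < 1)
  if (anyNA(net$pvalues)) stop("network has no p-values to correct")
  d <- nrow(net$weights)
  ut <- upper.tri(net$weights)
  padj <- stats::p.adjust(net$pvalues[ut], method = "BH")
  w <- net$weights
  keep <- padj <= alpha
  wu <- w[ut]
  wu[!keep] <- 0
  w[ut] <- wu
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  mbn_network(w, pvalues = net$pvalues, voi_names = net$voi_names,
              alpha = alpha, correction = "fdr")
}

#' Multiple-sampling network ensemble
#'
#' Builds the collection \eqn{\Phi = \{M^1, \dots, M^n\}} of FDR-corrected
#' correlation networks, one per random sample of the subjects. In
#' \code{"bootstrap"} mode each sample draws N rows with replacement (the
#' sample may duplicate subjects); in \code{"subsample"} mode each sample
#' draws \code{round(fraction * N)} rows without replacement.
#'
#' Degenerate draws whose resampled columns have zero variance (possible only
#' for tiny N) are redrawn up to 100 times, preserving the ensemble size
#' without biasing typical draws; the redraw count is recorded.
#'
#' @param x a \code{\link{suvr_dataset}}.
#' @param n ensemble size (number of sampled networks).
#' @param alpha FDR level applied to every member.
#' @param mode \code{"bootstrap"} (default) or \code{"subsample"}.
#' @param fraction subsample fraction in (0, 1); default 0.8. Ignored in
#'   bootstrap mode.
#' @param seed integer seed; fixed seed gives an identical ensemble.
#' @return An object of class \code{"mbn_ensemble"}: list with
#'   \code{networks}, \code{sample_indices}, \code{mode}, \code{fraction},
#'   \code{alpha}, \code{seed}, \code{redraws}.
#' @export
build_ensemble <- function(x, n, alpha, mode = c("bootstrap", "subsample"),
                           fraction = 0.8, seed = NULL) {
  stopifnot(inherits(x, "suvr_dataset"), n >= 1)
  mode <- match.arg(mode)
  N <- nrow(x$values)
  if (mode == "subsample") {
    if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
    m <- max(3L, round(fraction * N))
  } else {
    m <- N
  }
  .with_seed(seed, {
    networks <- vector("list", n)
    indices <- vector("list", n)
    redraws <- 0L
    for (k in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(100L)) {
        idx <- if (mode == "bootstrap") sample.int(N, N, replace = TRUE)
               else sample.int(N, m)
        sub <- x$values[idx, , drop = FALSE]
        if (all(.col_sds(sub) > 0)) { ok <- TRUE; break }
        redraws <- redraws + 1L
      }
      if (!ok) stop("could not draw a sample without zero-variance columns ",
                    "after 100 attempts (dataset nearly degenerate)")
      y <- suvr_dataset(sub, group = x$group,
                        subject_ids = sprintf("draw_%d", seq_along(idx)),
                        voi_names = x$voi_names)
      networks[[k]] <- fdr_correct(pearson_adjacency(y), alpha)
      indices[[k]] <- idx
    }
    structure(
      list(networks = networks, sample_indices = indices, mode = mode,
           fraction = if (mode == "subsample") fraction else NULL,
           alpha = alpha, seed = seed, redraws = redraws,
           voi_names = x$voi_names, data = x),
      class = "mbn_ensemble")
  })
}

# column SDs without the matrixStats dependency
.col_sds <- function(m) {
  mu <- colMeans(m)
  sqrt(colSums(sweep(m, 2L, mu)^2) / (nrow(m) - 1L))
}

#' @export
print.mbn_ensemble <- function(x, ...) {
  cat(sprintf("MBN ensemble: n = %d networks, %d VOIs, %s sampling, alpha = %g\n",
              length(x$networks), length(x$voi_names), x$mode, x$alpha))
  invisible(x)
}

#' @export
length.mbn_ensemble <- function(x) length(x$networks)

#' Select the representative network of an ensemble
#'
#' Chooses one member of the ensemble as the group representative network.
#' Under the \code{"mean"} criterion the representative is
#' \deqn{M = \arg\min_{1 \le k \le n} \| M^k - \bar M \|_F,}
#' the member closest in Frobenius norm to the elementwise mean matrix
#' \eqn{\bar M}; \code{"median"} replaces \eqn{\bar M} with the elementwise
#' median matrix. The \code{"mode"} criterion returns the maximum-density
#' member in matrix space, with density estimated for each member as the
#' negative mean Frobenius distance to its \eqn{\lceil\sqrt n\rceil} nearest
#' ensemble neighbours (a k-nearest-neighbour density surrogate). Ties are
#' broken by the lowest ensemble index. The result is always an actual
#' ensemble member, never a synthetic average.
#'
#' @param ens an \code{\link{mbn_ensemble}}.
#' @param criterion \code{"mean"} (default), \code{"median"} or \code{"mode"}.
#' @return The selected \code{\link{mbn_network}}, with attribute
#'   \code{"index"} giving its position in the ensemble.
#' @export
select_representative <- function(ens, criterion = c("mean", "median", "mode")) {
  stopifnot(inherits(ens, "mbn_ensemble"))
  criterion <- match.arg(criterion)
  n <- length(ens$networks)
  if (n == 0L) stop("empty ensemble")
  W <- t(vapply(ens$networks, function(m) as.vector(m$weights),
                numeric(length(ens$networks[[1L]]$weights))))
  idx <- switch(criterion,
    mean = {
      target <- colMeans(W)
      which.min(sqrt(rowSums(sweep(W, 2L, target)^2)))
    },
    median = {
      target <- apply(W, 2L, stats::median)
      which.min(sqrt(rowSums(sweep(W, 2L, target)^2)))
    },
    mode = {
      if (n == 1L) 1L else {
        sq <- rowSums(W^2)
        D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(W), 0)
        D <- sqrt(D2)
        k <- min(ceiling(sqrt(n)), n - 1L)
        knn_mean <- vapply(seq_len(n), function(i) {
          mean(sort(D[i, -i])[seq_len(k)])
        }, numeric(1L))
        which.min(knn_mean)  # max density = min mean kNN distance
      }
    })
  rep <- ens$networks[[idx]]
  attr(rep, "index") <- as.integer(idx)
  rep
}

#' Edge probability map of an ensemble
#'
#' For every VOI pair (p, q), the fraction of ensemble networks in which the
#' (FDR-corrected) edge is nonzero:
#' \deqn{\dot P_{pq} = \frac1n \sum_{k=1}^n \hat B(r^k_{pq} \ne 0),}
#' where \eqn{\hat B} is the 0/1 indicator. Entries are exact multiples of
#' 1/n.
#'
#' @param ens an \code{\link{mbn_ensemble}} of FDR-corrected networks.
#' @return An object of class \code{"mbn_pmap"}: list with \code{probs}
#'   (d x d matrix in [0, 1]), \code{n} and \code{voi_names}.
#' @export
compute_pmap <- function(ens) {
  stopifnot(inherits(ens, "mbn_ensemble"))
  n <- length(ens$networks)
  if (n == 0L) stop("empty ensemble")
  counts <- Reduce(`+`, lapply(ens$networks, function(m) (m$weights != 0) * 1L))
  probs <- counts / n
  diag(probs) <- 0
  dimnames(probs) <- list(ens$voi_names, ens$voi_names)
  structure(list(probs = probs, n = n, voi_names = ens$voi_names),
            class = "mbn_pmap")
}

#' @export
print.mbn_pmap <- function(x, ...) {
  cat(sprintf("Edge probability map over n = %d networks, %d VOIs; mean edge prob %.3f\n",
              x$n, nrow(x$probs), mean(.upper_vals(x$probs))))
  invisible(x)
}

#' Threshold a network with an edge probability map
#'
#' Second-stage, occurrence-based thresholding: an edge of the representative
#' network is retained only if its probability-map entry exceeds \code{theta}
#' strictly (\eqn{\dot T_{pq} = \hat B(\dot P_{pq} > \theta)}; the corrected
#' network is the Hadamard product \eqn{M \odot \dot T}). The conventional
#' choice is \code{theta = 1 - alpha}. Combined with the FDR stage this is the
#' "FDR + Pmap" correction, which is never less conservative than FDR alone.
#'
#' @param net an \code{\link{mbn_network}} (typically FDR-corrected).
#' @param pmap an \code{\link{mbn_pmap}} of the same dimension.
#' @param theta probability threshold in [0, 1]; edges with map entry exactly
#'   equal to \code{theta} are removed.
#' @return The thresholded \code{\link{mbn_network}} with
#'   \code{correction = "fdr+pmap"} and \code{theta} recorded.
#' @export
apply_pmap_threshold <- function(net, pmap, theta) {
  stopifnot(inherits(net, "mbn_network"), inherits(pmap, "mbn_pmap"))
  if (!all(dim(net$weights) == dim(pmap$probs)))
    stop("network and probability map dimensions differ")
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  keep <- pmap$probs > theta
  w <- net$weights * keep
  diag(w) <- 0
  mbn_network(w, pvalues = net$pvalues, voi_names = net$voi_names,
              alpha = net$alpha, correction = "fdr+pmap", theta = theta)
}

#' Conventional (single-pass) metabolic brain network
#'
#' The baseline construction used for comparison with the multiple-sampling
#' scheme: one intersubject Pearson correlation matrix computed on the full
#' dataset, followed by Benjamini-Hochberg FDR correction. No resampling, no
#' probability map.
#'
#' @param x a \code{\link{suvr_dataset}}.
#' @param alpha FDR level.
#' @return An FDR-corrected \code{\link{mbn_network}}.
#' @export
conventional_mbn <- function(x, alpha) {
  fdr_correct(pearson_adjacency(x), alpha)
}

#' Residualize SUVR values on covariates
#'
#' Replaces each VOI column by the residuals of an ordinary least-squares fit
#' on the dataset's covariates (plus intercept), with the column mean added
#' back so values remain on the SUVR scale. Used to correct networks for
#' nuisance covariates such as age and sex before correlation.
#'
#' @param x a \code{\link{suvr_dataset}} with covariates.
#' @return A \code{\link{suvr_dataset}} with adjusted values (covariates
#'   retained for bookkeeping).
#' @export
residualize_covariates <- function(x) {
  stopifnot(inherits(x, "suvr_dataset"))
  if (is.null(x$covariates)) stop("dataset has no covariates")
  X <- cbind(1, x$covariates)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X))
    stop("covariate matrix is rank-deficient (constant or collinear columns)")
  fitted <- X %*% qr.coef(qr_X, x$values)
  resid <- x$values - fitted
  adj <- sweep(resid, 2L, colMeans(x$values), "+")
  suvr_dataset(adj, group = x$group, subject_ids = x$subject_ids,
               voi_names = x$voi_names, covariates = x$covariates)
}
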