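#' Degree distribution of a network
#'
#' Normalized histogram of binary node degrees (counts of surviving incident
#' edges) over the integer bins 0, 1, ..., d-1. The binning is fixed by the
#' node count, so histograms from different runs on the same VOI set are
#' directly comparable.
#'
#' @param net an \code{\link{mbn_network}}.
#' @return A \code{"distribution_histogram"}: list with \code{bins} (degree
#'   values), \code{probabilities} (summing to 1) and \code{kind = "degree"}.
#' @export
degree_distribution <- function(net) {
  stopifnot(inherits(net, "mbn_network"))
  w <- net$weights
  d <- nrow(w)
  deg <- rowSums(w != 0)
  counts <- tabulate(deg + 1L, nbins = d)
  structure(list(bins = 0:(d - 1L), probabilities = counts / d,
                 kind = "degree"),
            class = "distribution_histogram")
}

#' Weight distribution of a network
#'
#' Normalized histogram of the surviving (nonzero, upper-triangle) edge
#' weights over 100 equal-width bins spanning [-1, 1].
#'
#' @param net an \code{\link{mbn_network}} with at least one surviving edge.
#' @return A \code{"distribution_histogram"} with 100 bins and
#'   \code{kind = "weight"}.
#' @export
weight_distribution <- function(net) {
  stopifnot(inherits(net, "mbn_network"))
  w <- .upper_vals(net$weights)
  w <- w[w != 0]
  if (length(w) == 0L) stop("network has no surviving edges")
  edges <- seq(-1, 1, length.out = 101L)
  counts <- graphics::hist(w, breaks = edges, plot = FALSE)$counts
  structure(list(bins = edges, probabilities = counts / length(w),
                 kind = "weight"),
            class = "distribution_histogram")
}

#' @export
print.distribution_histogram <- function(x, ...) {
  cat(sprintf("%s distribution: %d bins, entropy %.3f\n", x$kind,
              length(x$probabilities),
              -sum(ifelse(x$probabilities > 0,
                          x$probabilities * log(x$probabilities), 0))))
  invisible(x)
}

#' Bhattacharyya distance between two histograms
#'
#' \eqn{d_B(p, q) = -\ln \sum_i \sqrt{p_i q_i}}. Zero if and only if the
#' histograms are identical; histograms with disjoint support (Bhattacharyya
#' coefficient 0) are reported as the finite sentinel 700 (about
#' \eqn{-\ln} of the smallest positive double), keeping convergence traces
#' plottable.
#'
#' @param p,q \code{"distribution_histogram"} objects with identical binning.
#' @return Nonnegative scalar.
#' @export
bhattacharyya_distance <- function(p, q) {
  stopifnot(inherits(p, "distribution_histogram"),
            inherits(q, "distribution_histogram"))
  if (!identical(p$kind, q$kind) ||
      length(p$probabilities) != length(q$probabilities) ||
      !isTRUE(all.equal(p$bins, q$bins)))
    stop("histograms are not on the same binning")
  bc <- sum(sqrt(p$probabilities * q$probabilities))
  if (bc <= 0) return(700)
  max(0, -log(bc))
}

#' Tune the ensemble size by degree-distribution convergence
#'
#' For each grid value k, builds representative networks from two independent
#' ensembles of sizes k and k + \code{step} (fresh seeds derived from the
#' master seed) and computes the Bhattacharyya distance between their degree
#' distributions. As n grows the degree distribution stabilizes and the trace
#' decays towards zero; the selected ensemble size is the k minimizing the
#' distance (ties broken by the smallest k).
#'
#' @param x a \code{\link{suvr_dataset}}.
#' @param k_grid ascending integer grid of candidate ensemble sizes; the
#'   default, \code{seq(100, 9900, by = 100)}, spans the full operating range
#'   and can be shortened for quick runs.
#' @param step offset between the two compared ensemble sizes (default 100).
#' @param alpha FDR level (default 0.0001).
#' @param criterion representative-selection criterion.
#' @param mode sampling mode passed to \code{\link{build_ensemble}}.
#' @param seed master seed.
#' @return An object of class \code{"mbn_tuning"}: list with \code{trace}
#'   (data frame of k and dB), \code{best_k} and the call parameters.
#' @export
tune_n <- function(x, k_grid = seq(100L, 9900L, by = 100L), step = 100L,
                   alpha = 1e-4, criterion = "mean",
                   mode = c("bootstrap", "subsample"), seed = NULL) {
  stopifnot(inherits(x, "suvr_dataset"))
  mode <- match.arg(mode)
  if (length(k_grid) == 0L) stop("empty tuning grid")
  if (is.unsorted(k_grid)) stop("k_grid must be ascending")
  db <- vapply(seq_along(k_grid), function(i) {
    k <- k_grid[i]
    ens1 <- build_ensemble(x, n = k, alpha = alpha, mode = mode,
                           seed = .derive_seed(seed, 2L * i))
    ens2 <- build_ensemble(x, n = k + step, alpha = alpha, mode = mode,
                           seed = .derive_seed(seed, 2L * i + 1L))
    d1 <- degree_distribution(select_representative(ens1, criterion))
    d2 <- degree_distribution(select_representative(ens2, criterion))
    bhattacharyya_distance(d1, d2)
  }, numeric(1L))
  best <- k_grid[which.min(db)]
  structure(
    list(trace = data.frame(k = k_grid, dB = db), best_k = best,
         step = step, alpha = alpha, criterion = criterion, mode = mode,
         seed = seed),
    class = "mbn_tuning")
}

#' @export
print.mbn_tuning <- function(x, ...) {
  cat(sprintf("Ensemble-size tuning over k in [%d, %d]: best k = %d (dB = %.4g)\n",
              min(x$trace$k), max(x$trace$k), x$best_k, min(x$trace$dB)))
  invisible(x)
}

#' @export
plot.mbn_tuning <- function(x, ...) {
  plot(x$trace$k, x$trace$dB, type = "b", pch = 16,
       xlab = "ensemble size k", ylab = "Bhattacharyya distance dB",
       main = "Degree-distribution convergence", ...)
  graphics::abline(v = x$best_k, lty = 2)
  invisible(x)
}
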