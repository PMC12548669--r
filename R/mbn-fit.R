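#' Fit a group metabolic brain network
#'
#' The package's main entry point: estimates a group-representative metabolic
#' brain network from a subjects-by-VOIs SUVR table. With
#' \code{method = "bootstrap"} or \code{"subsample"} the multiple-sampling
#' scheme is used — an ensemble of \code{n} resampled Pearson correlation
#' networks is built, each FDR-corrected at \code{alpha}, one member is
#' selected as the representative (closest to the ensemble mean/median, or
#' the maximum-density member), and, when \code{pmap = TRUE}, edges that do
#' not recur in more than \code{theta = 1 - alpha} of the ensemble are
#' additionally removed (the "FDR + Pmap" correction). With
#' \code{method = "conventional"} a single correlation network is computed on
#' the full dataset and FDR-corrected, with no resampling.
#'
#' @param x a \code{\link{suvr_dataset}} (or numeric subjects-by-VOIs matrix).
#' @param method \code{"bootstrap"} (default), \code{"subsample"} or
#'   \code{"conventional"}.
#' @param n ensemble size for the multiple-sampling methods; 9300 by default
#'   (a typical converged value for large cohorts — use \code{\link{tune_n}}
#'   to calibrate for a given dataset, and much smaller values for quick
#'   exploration).
#' @param alpha FDR level; default 0.0001.
#' @param criterion representative-selection criterion
#'   (\code{"mean"}, \code{"median"}, \code{"mode"}).
#' @param pmap logical: apply the probability-map threshold on top of FDR
#'   (multiple-sampling methods only).
#' @param theta probability-map threshold; defaults to \code{1 - alpha}.
#' @param fraction subsample fraction for \code{method = "subsample"}.
#' @param residualize logical: regress covariates out of every VOI column
#'   first (requires covariates in \code{x}).
#' @param seed integer seed making the fit fully reproducible.
#'
#' @return An object of class \code{"mbn"} with components \code{network}
#'   (the corrected representative \code{\link{mbn_network}}),
#'   \code{ensemble}, \code{pmap}, \code{rep_index}, \code{features}
#'   (lazily computed by \code{summary}), and \code{call}.
#'
#' @examples
#' spec <- cohort_spec(n_subjects = c(CU = 60, MCI = 60, AD = 60),
#'                     d = 20, n_blocks = 4)
#' cohort <- generate_cohort(spec, seed = 7)
#' fit <- mbn(cohort$CU, method = "bootstrap", n = 50, alpha = 0.01, seed = 7)
#' fit
#' summary(fit)
#' @seealso \code{\link{run_attack_experiment}} for stability evaluation,
#'   \code{\link{tune_n}} for choosing \code{n}.
#' @export
mbn <- function(x, method = c("bootstrap", "subsample", "conventional"),
                n = 9300L, alpha = 1e-4,
                criterion = c("mean", "median", "mode"),
                pmap = TRUE, theta = NULL, fraction = 0.8,
                residualize = FALSE, seed = NULL) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  if (!inherits(x, "suvr_dataset")) x <- suvr_dataset(as.matrix(x))
  if (residualize) x <- residualize_covariates(x)
  if (is.null(theta)) theta <- 1 - alpha
  cl <- match.call()

  if (method == "conventional") {
    net <- conventional_mbn(x, alpha)
    ens <- NULL; pm <- NULL; rep_index <- NULL
  } else {
    ens <- build_ensemble(x, n = n, alpha = alpha,
                          mode = if (method == "bootstrap") "bootstrap"
                                 else "subsample",
                          fraction = fraction, seed = seed)
    net <- select_representative(ens, criterion)
    rep_index <- attr(net, "index")
    pm <- compute_pmap(ens)
    if (pmap) net <- apply_pmap_threshold(net, pm, theta)
  }
  structure(
    list(network = net, ensemble = ens, pmap = pm, rep_index = rep_index,
         method = method, alpha = alpha, theta = if (method != "conventional")
           theta else NULL,
         criterion = if (method == "conventional") NULL else criterion,
         data = x, seed = seed, call = cl),
    class = "mbn")
}

#' @export
print.mbn <- function(x, ...) {
  cat("Metabolic brain network fit\n")
  cat(sprintf("  method: %s%s, alpha = %g%s\n", x$method,
              if (is.null(x$ensemble)) ""
              else sprintf(" (n = %d, criterion = %s)",
                           length(x$ensemble), x$criterion),
              x$alpha,
              if (is.null(x$theta)) "" else sprintf(", theta = %g", x$theta)))
  cat("  ")
  print(x$network)
  invisible(x)
}

#' @export
summary.mbn <- function(object, ...) {
  feats <- suppressWarnings(graph_features(object$network))
  out <- list(fit = object, features = feats)
  class(out) <- "summary.mbn"
  out
}

#' @export
print.summary.mbn <- function(x, ...) {
  print(x$fit)
  cat("  graph features:\n")
  f <- unclass(x$features)[seq_len(6L)]
  for (nm in names(f)) cat(sprintf("    %-3s = %.4f\n", nm, f[[nm]]))
  invisible(x)
}

#' Extract the adjacency matrix of a fitted network
#'
#' @param object an \code{"mbn"} fit.
#' @param ... unused.
#' @return The corrected d x d weight matrix.
#' @export
coef.mbn <- function(object, ...) object$network$weights

#' Plot a fitted metabolic brain network
#'
#' Displays the corrected adjacency matrix as a signed heat map (blue
#' negative, red positive), VOIs in table order.
#'
#' @param x an \code{"mbn"} fit.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.mbn <- function(x, ...) {
  w <- x$network$weights
  d <- nrow(w)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(seq_len(d), seq_len(d), t(w[d:1, ]), zlim = c(-1, 1),
                  col = pal, xlab = "VOI", ylab = "VOI",
                  main = sprintf("MBN (%s, alpha = %g)", x$method, x$alpha),
                  ...)
  invisible(x)
}
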