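#' Random undersampling of imbalanced groups
#'
#' Removes subjects at random (without replacement) from the larger groups
#' until every group matches the smallest group's size. The smallest group is
#' returned unchanged; no synthetic values are ever introduced.
#'
#' @param groups named list of \code{\link{suvr_dataset}} objects.
#' @param seed integer seed.
#' @return Named list of equally sized \code{\link{suvr_dataset}} objects.
#' @export
undersample_groups <- function(groups, seed = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- vapply(groups, function(g) nrow(g$values), integer(1L))
  if (any(sizes == 0L)) stop("empty group")
  target <- min(sizes)
  .with_seed(seed, {
    lapply(groups, function(g) {
      n <- nrow(g$values)
      if (n == target) return(g)
      keep <- sort(sample.int(n, target))
      suvr_dataset(g$values[keep, , drop = FALSE], group = g$group,
                   subject_ids = g$subject_ids[keep],
                   voi_names = g$voi_names,
                   covariates = if (is.null(g$covariates)) NULL
                                else g$covariates[keep, , drop = FALSE])
    })
  })
}

#' ADASYN oversampling of minority groups
#'
#' Adaptive synthetic oversampling: each minority group is grown to the
#' majority group's size by interpolated synthetic subjects. For each
#' minority point \eqn{x_i}, the fraction of other-group points among its k
#' nearest neighbours (over all groups) sets how many synthetic points are
#' generated around it — points near group boundaries receive more. Each
#' synthetic point is \eqn{x_i + \lambda (x_{z} - x_i)} with
#' \eqn{\lambda \sim U(0,1)} and \eqn{x_z} a random same-group point among
#' the k nearest minority neighbours of \eqn{x_i}, so every synthetic row
#' lies on a segment between two original same-group rows.
#'
#' @param groups named list of \code{\link{suvr_dataset}} objects.
#' @param k_neighbors neighbourhood size (default 5).
#' @param seed integer seed.
#' @return Named list of \code{\link{suvr_dataset}} objects, all at the
#'   majority size; each carries a logical attribute \code{"synthetic"}
#'   flagging generated rows.
#' @export
adasyn_oversample <- function(groups, k_neighbors = 5L, seed = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- vapply(groups, function(g) nrow(g$values), integer(1L))
  majority <- max(sizes)
  small <- sizes < majority
  if (any(sizes[small] <= k_neighbors))
    stop("minority group smaller than k_neighbors + 1")
  all_values <- do.call(rbind, lapply(groups, function(g) g$values))
  all_group <- rep(names(groups), sizes)
  .with_seed(seed, {
    out <- groups
    for (gname in names(groups)[small]) {
      g <- groups[[gname]]
      G <- majority - nrow(g$values)
      if (G == 0L) next
      minority <- g$values
      n_min <- nrow(minority)
      # adaptive allocation: other-class fraction among kNN in the full data
      r <- vapply(seq_len(n_min), function(i) {
        dists <- sqrt(colSums((t(all_values) - minority[i, ])^2))
        self <- which(all_group == gname)[i]
        ord <- order(dists)
        nn <- ord[ord != self][seq_len(k_neighbors)]
        mean(all_group[nn] != gname)
      }, numeric(1L))
      if (sum(r) == 0) r <- rep(1, n_min)  # interior minority: uniform budget
      rhat <- r / sum(r)
      gi <- .apportion(rhat * G)
      # same-group kNN used for interpolation partners
      dmin <- as.matrix(stats::dist(minority))
      syn <- matrix(NA_real_, G, ncol(minority))
      pos <- 0L
      for (i in seq_len(n_min)) {
        if (gi[i] == 0L) next
        nn_i <- order(dmin[i, ])[-1L][seq_len(min(k_neighbors, n_min - 1L))]
        for (s in seq_len(gi[i])) {
          z <- nn_i[sample.int(length(nn_i), 1L)]
          lambda <- stats::runif(1L)
          pos <- pos + 1L
          syn[pos, ] <- minority[i, ] + lambda * (minority[z, ] - minority[i, ])
        }
      }
      values <- rbind(minority, syn)
      ids <- c(g$subject_ids, sprintf("syn_%s_%04d", gname, seq_len(G)))
      rownames(values) <- ids
      res <- suvr_dataset(values, group = g$group, subject_ids = ids,
                          voi_names = g$voi_names)
      attr(res, "synthetic") <- c(rep(FALSE, n_min), rep(TRUE, G))
      out[[gname]] <- res
    }
    for (gname in names(groups)[!small]) {
      attr(out[[gname]], "synthetic") <-
        rep(FALSE, nrow(out[[gname]]$values))
    }
    out
  })
}

# Integer apportionment preserving the exact total: floor everything, then
# hand out the remainder by largest fractional part (ties by index).
.apportion <- function(x) {
  base <- floor(x)
  rem <- round(sum(x)) - sum(base)
  if (rem > 0L) {
    extra <- order(x - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}
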