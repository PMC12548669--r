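#' Specification of a synthetic SUVR cohort
#'
#' Describes a group-structured multivariate-normal generative model for SUVR
#' data: VOIs are partitioned into blocks ("modules") with a block-constant
#' correlation structure (within-block correlation \code{rho_in}, between-block
#' \code{rho_out}), and each group can shift the mean SUVR of each block to
#' mimic group-wise hypo-/hypermetabolism. Values are centred near a positive
#' SUVR baseline so generated tables look like pons-referenced uptake ratios.
#'
#' @param n_subjects named integer vector of subjects per group. The default
#'   mirrors a typical imbalanced Alzheimer's-continuum cohort (352 CU,
#'   641 MCI, 234 AD).
#' @param d number of VOIs (default 72).
#' @param n_blocks number of correlation blocks the VOIs are split into
#'   (nearly equal sizes).
#' @param rho_in within-block correlation, in [0, 1).
#' @param rho_out between-block correlation, with
#'   \code{0 <= rho_out <= rho_in < 1} (guarantees a positive semi-definite
#'   correlation matrix by construction).
#' @param group_effects optional named list: for each group, a numeric vector
#'   of per-block mean SUVR offsets. Groups not listed get zero offset. The
#'   default imposes a graded hypometabolism on the first half of the blocks
#'   (0 for the first group, -0.04 for the second, -0.08 for the third),
#'   echoing the reduced uptake seen along the disease continuum.
#' @param baseline mean SUVR level (default 1.2).
#' @param noise_sd marginal SUVR standard deviation (default 0.1).
#'
#' @return An object of class \code{"cohort_spec"}.
#' @seealso \code{\link{generate_cohort}}
#' @export
cohort_spec <- function(n_subjects = c(CU = 352L, MCI = 641L, AD = 234L),
                        d = 72L, n_blocks = 6L, rho_in = 0.6, rho_out = 0.2,
                        group_effects = NULL, baseline = 1.2, noise_sd = 0.1) {
  if (is.null(names(n_subjects)) || any(!nzchar(names(n_subjects))))
    stop("`n_subjects` must be a named vector of group sizes")
  if (any(n_subjects < 2L)) stop("every group needs at least 2 subjects")
  if (d < 2L) stop("need d >= 2 VOIs")
  if (n_blocks < 1L || n_blocks > d) stop("n_blocks must be in [1, d]")
  if (!(rho_out >= 0 && rho_out <= rho_in && rho_in < 1))
    stop("need 0 <= rho_out <= rho_in < 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  blocks <- sort(rep_len(seq_len(n_blocks), d))
  groups <- names(n_subjects)
  if (is.null(group_effects)) {
    affected <- seq_len(max(1L, n_blocks %/% 2L))
    group_effects <- lapply(seq_along(groups), function(g) {
      eff <- numeric(n_blocks)
      eff[affected] <- -0.04 * (g - 1L)
      eff
    })
    names(group_effects) <- groups
  }
  for (g in groups) {
    if (is.null(group_effects[[g]])) group_effects[[g]] <- numeric(n_blocks)
    if (length(group_effects[[g]]) != n_blocks)
      stop("group_effects[['", g, "']] must have one offset per block")
  }
  structure(
    list(n_subjects = n_subjects, d = as.integer(d), blocks = blocks,
         rho_in = rho_in, rho_out = rho_out,
         group_effects = group_effects[groups],
         baseline = baseline, noise_sd = noise_sd),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: %s; d = %d VOIs in %d blocks (rho_in = %g, rho_out = %g)\n",
    paste(sprintf("%s = %d", names(x$n_subjects), x$n_subjects), collapse = ", "),
    x$d, max(x$blocks), x$rho_in, x$rho_out))
  invisible(x)
}

# Block-constant correlation matrix implied by a cohort_spec.
.spec_correlation <- function(spec) {
  same <- outer(spec$blocks, spec$blocks, "==")
  R <- ifelse(same, spec$rho_in, spec$rho_out)
  diag(R) <- 1
  R
}

#' Generate a synthetic multi-group SUVR cohort
#'
#' Draws each group from a multivariate normal with the block-constant
#' correlation matrix implied by the cohort spec, marginal standard deviation
#' \code{noise_sd}, and group/block mean offsets added to the SUVR baseline.
#' Because the generative family is Gaussian, the Pearson-correlation
#' networks downstream are exactly parameterized by the cohort spec, which makes
#' parameter-recovery checks possible.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @param covariates logical; if \code{TRUE}, attach synthetic age (years,
#'   normal around 73) and sex (0/1) covariates to each dataset.
#' @return Named list of \code{\link{suvr_dataset}}, one per group.
#' @export
generate_cohort <- function(spec, seed = NULL, covariates = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  R <- .spec_correlation(spec)
  Lc <- tryCatch(chol(R), error = function(e)
    stop("implied correlation matrix is not positive definite: ",
         conditionMessage(e)))
  .with_seed(seed, {
    out <- lapply(names(spec$n_subjects), function(g) {
      n <- spec$n_subjects[[g]]
      z <- matrix(stats::rnorm(n * spec$d), n, spec$d) %*% Lc
      mu <- spec$baseline + spec$group_effects[[g]][spec$blocks]
      values <- sweep(z * spec$noise_sd, 2L, mu, "+")
      cov <- NULL
      if (covariates) {
        cov <- cbind(age = stats::rnorm(n, 73, 6),
                     sex = stats::rbinom(n, 1L, 0.5))
      }
      suvr_dataset(values, group = g,
                   subject_ids = sprintf("%s_%04d", g, seq_len(n)),
                   voi_names = sprintf("VOI_%02d", seq_len(spec$d)),
                   covariates = cov)
    })
    names(out) <- names(spec$n_subjects)
    out
  })
}

#' Append cross-group outlier rows to a dataset
#'
#' Implements the contamination primitive of the outlier-attack model: rows
#' drawn without replacement from donor datasets (other diagnostic groups)
#' are appended to the target, giving a perturbed dataset with N + L rows.
#' With two donors the L rows are split as evenly as possible between them
#' (half/half); an odd L is resolved by a seeded coin flip for the extra row.
#' Inputs are never mutated.
#'
#' @param target a \code{\link{suvr_dataset}}.
#' @param donors list of donor \code{\link{suvr_dataset}} objects sharing the
#'   target's VOIs.
#' @param L number of outlier rows to append (\code{L >= 0}).
#' @param seed integer seed for donor-row selection.
#' @return A \code{\link{suvr_dataset}} with \code{N + L} rows; the attribute
#'   \code{"outlier_source"} records, for every row, the group it came from
#'   (the target's own group for original rows).
#' @export
inject_outliers <- function(target, donors, L, seed = NULL) {
  stopifnot(inherits(target, "suvr_dataset"), L >= 0)
  if (!is.list(donors) || length(donors) == 0L)
    stop("need at least one donor dataset")
  donors <- lapply(donors, function(d) {
    stopifnot(inherits(d, "suvr_dataset"))
    if (!identical(d$voi_names, target$voi_names))
      stop("donor VOIs do not match target VOIs")
    d
  })
  src <- rep(target$group, nrow(target$values))
  if (L == 0L) {
    out <- target
    attr(out, "outlier_source") <- src
    return(out)
  }
  .with_seed(seed, {
    counts <- .split_outliers(L, length(donors))
    if (any(counts > vapply(donors, function(d) nrow(d$values), integer(1L))))
      stop("requested more outliers than available donor rows")
    picked <- mapply(function(d, k) {
      idx <- sample.int(nrow(d$values), k)
      list(values = d$values[idx, , drop = FALSE], group = rep(d$group, k))
    }, donors, counts, SIMPLIFY = FALSE)
    extra <- do.call(rbind, lapply(picked, `[[`, "values"))
    extra_src <- unlist(lapply(picked, `[[`, "group"))
    values <- rbind(target$values, extra)
    ids <- c(target$subject_ids,
             sprintf("out_%s_%03d", extra_src, seq_len(L)))
    rownames(values) <- ids
    out <- suvr_dataset(values, group = target$group, subject_ids = ids,
                        voi_names = target$voi_names)
    attr(out, "outlier_source") <- c(src, extra_src)
    out
  })
}

# Even split of L outliers across donors; for two donors this is the
# half-and-half allocation, with an odd remainder assigned by coin flip.
.split_outliers <- function(L, n_donors) {
  base <- L %/% n_donors
  counts <- rep(base, n_donors)
  rem <- L - base * n_donors
  if (rem > 0L) {
    lucky <- sample.int(n_donors, rem)
    counts[lucky] <- counts[lucky] + 1L
  }
  counts
}
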