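#' Graph-theoretic feature vector of a network
#'
#' Computes the six global measures used to compare a network with its
#' perturbed version in feature space:
#' \describe{
#'   \item{ge}{global efficiency: mean over ordered node pairs of the inverse
#'     weighted shortest-path length, with edge length \eqn{1/|w|}
#'     (disconnected pairs contribute 0).}
#'   \item{ac}{degree assortativity: Pearson correlation of the binary
#'     degrees at the two endpoints of each edge; reported as 0 (with a
#'     warning) when undefined, e.g. on regular graphs.}
#'   \item{ad}{average binary degree (surviving edges per node).}
#'   \item{as}{average strength: mean over nodes of the summed absolute
#'     weights of incident edges.}
#'   \item{d}{density: fraction of the d(d-1)/2 possible edges present.}
#'   \item{acc}{average binary clustering coefficient (local triangle
#'     density, zero for nodes of degree < 2).}
#' }
#' Measures follow the standard complex-network definitions; clustering and
#' degree use the binarized nonzero-edge graph, while efficiency and strength
#' use absolute weights (signed correlations enter through their magnitude).
#'
#' @param net an \code{\link{mbn_network}} (or a bare symmetric matrix).
#' @return Named numeric vector of class \code{"graph_features"} with
#'   components \code{ge, ac, ad, as, d, acc} and attribute
#'   \code{"ac_defined"}.
#' @export
graph_features <- function(net) {
  w <- if (inherits(net, "mbn_network")) net$weights else as.matrix(net)
  d <- nrow(w)
  if (d < 2L) stop("need at least 2 nodes")
  diag(w) <- 0
  A <- (w != 0) * 1
  deg <- rowSums(A)
  n_edges <- sum(A) / 2
  dens <- n_edges / (d * (d - 1) / 2)
  ad <- mean(deg)
  strength <- rowSums(abs(w))
  as_ <- mean(strength)
  ac_defined <- TRUE
  if (n_edges == 0) {
    ge <- 0; acc <- 0; ac <- 0; ac_defined <- FALSE
  } else {
    g <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    # shortest paths on lengths 1/|w|: strong correlations = short edges
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
    sp <- igraph::distances(g, weights = igraph::E(g)$weight)
    inv <- 1 / sp
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    ge <- sum(inv) / (d * (d - 1))
    gb <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                              diag = FALSE)
    cc <- igraph::transitivity(gb, type = "local", isolates = "zero")
    acc <- mean(cc)
    ac <- igraph::assortativity_degree(gb)
    if (!is.finite(ac)) {
      warning("assortativity undefined (zero degree variance); reported as 0")
      ac <- 0
      ac_defined <- FALSE
    }
  }
  structure(c(ge = ge, ac = ac, ad = ad, as = as_, d = dens, acc = acc),
            class = "graph_features", ac_defined = ac_defined)
}

#' @export
print.graph_features <- function(x, ...) {
  print(round(unclass(x)[seq_len(6L)], 4), ...)
  invisible(x)
}

#' Distance between two networks in matrix space
#'
#' \code{"frobenius"} is \eqn{\|M - \tilde M\|_F}. \code{"hausdorff"} treats
#' each matrix as the set of its row vectors \eqn{\{m_1, \dots, m_d\}}
#' (rows equal columns by symmetry) and computes
#' \deqn{d_H(M, \tilde M) = \max\{h(M, \tilde M),\; h(\tilde M, M)\},\quad
#'   h(M, \tilde M) = \max_i \min_j \|m_i - \tilde m_j\|_2.}
#' Both are nonnegative and zero on identical inputs; the Hausdorff distance
#' is zero whenever the two row sets coincide, so it is invariant to
#' simultaneous row/column permutations.
#'
#' @param m,m2 \code{\link{mbn_network}} objects or symmetric matrices of
#'   equal dimension.
#' @param metric \code{"frobenius"} or \code{"hausdorff"}.
#' @return Nonnegative scalar distance.
#' @export
matrix_distance <- function(m, m2, metric = c("frobenius", "hausdorff")) {
  metric <- match.arg(metric)
  A <- if (inherits(m, "mbn_network")) m$weights else as.matrix(m)
  B <- if (inherits(m2, "mbn_network")) m2$weights else as.matrix(m2)
  if (!all(dim(A) == dim(B))) stop("network dimensions differ")
  if (metric == "frobenius") return(sqrt(sum((A - B)^2)))
  # cross Euclidean distances between row vectors of A and B, computed by
  # explicit differencing (exact zeros for matching rows)
  d <- nrow(A)
  D <- vapply(seq_len(d), function(i) {
    sqrt(rowSums(sweep(B, 2L, A[i, ])^2))
  }, numeric(d))  # D[j, i] = ||a_i - b_j||
  max(max(apply(D, 2L, min)), max(apply(D, 1L, min)))
}

#' Distance between two graph-feature vectors
#'
#' \code{"euclidean"} is \eqn{\|f - \tilde f\|_2};
#' \code{"canberra"} is \eqn{\sum_i |f_i - \tilde f_i| / (|f_i| + |\tilde f_i|)},
#' with 0/0 terms contributing 0.
#'
#' @param f,f2 \code{\link{graph_features}} vectors (or plain numeric vectors
#'   of equal length).
#' @param metric \code{"euclidean"} or \code{"canberra"}.
#' @return Nonnegative scalar distance.
#' @export
feature_distance <- function(f, f2, metric = c("euclidean", "canberra")) {
  metric <- match.arg(metric)
  a <- as.numeric(f)
  b <- as.numeric(f2)
  if (length(a) != length(b)) stop("feature vectors differ in length")
  if (metric == "euclidean") return(sqrt(sum((a - b)^2)))
  den <- abs(a) + abs(b)
  num <- abs(a - b)
  terms <- ifelse(den == 0, 0, num / den)
  sum(terms)
}

#' Outlier attack on a dataset
#'
#' Contaminates a group's dataset with rows from the two other diagnostic
#' groups: \code{L = round(p_o/100 * N)} donor rows (at least 1 when
#' \code{p_o > 0}) are appended, half from each donor (odd L resolved by a
#' seeded coin flip), giving a perturbed dataset of N + L rows.
#'
#' @param target the \code{\link{suvr_dataset}} under attack.
#' @param donor_a,donor_b donor datasets from the two comparison groups.
#' @param p_o percentage of outliers (0 to < 100), e.g. 2, 5 or 8.
#' @param seed integer seed.
#' @return Perturbed \code{\link{suvr_dataset}} with attribute
#'   \code{"outlier_source"}.
#' @export
attack_dataset <- function(target, donor_a, donor_b, p_o, seed = NULL) {
  stopifnot(p_o >= 0, p_o < 100)
  N <- nrow(target$values)
  L <- round(p_o / 100 * N)
  if (p_o > 0 && L < 1L) L <- 1L
  inject_outliers(target, list(donor_a, donor_b), L, seed = seed)
}

#' Recompute a network after an outlier attack
#'
#' For the multiple-sampling methods the outlier rows are appended to the
#' representative network's own source sample \eqn{Y^q} (recovered through the
#' ensemble's recorded sample indices) and the Pearson + FDR construction is
#' rerun at the same alpha — no new ensemble and no probability-map stage, so
#' both methods are compared at the same correction depth. For the
#' conventional method the same outlier rows are appended to the original
#' dataset X and the single-pass construction is rerun.
#'
#' @param object an \code{\link{mbn_ensemble}} (multiple-sampling path) or a
#'   \code{\link{suvr_dataset}} (conventional path).
#' @param outlier_values numeric matrix of outlier rows (columns = VOIs); may
#'   have zero rows.
#' @param alpha FDR level (defaults to the ensemble's alpha when available).
#' @param rep_index for the ensemble path, the index of the representative
#'   member whose source sample is perturbed (the \code{"index"} attribute of
#'   \code{\link{select_representative}}).
#' @return The perturbed FDR-corrected \code{\link{mbn_network}}.
#' @export
perturbed_network <- function(object, outlier_values, alpha = NULL,
                              rep_index = NULL) {
  if (inherits(object, "mbn_ensemble")) {
    if (is.null(rep_index)) stop("rep_index required for the ensemble path")
    if (is.null(alpha)) alpha <- object$alpha
    idx <- object$sample_indices[[rep_index]]
    if (is.null(idx)) stop("ensemble carries no sample provenance")
    base <- object$data$values[idx, , drop = FALSE]
  } else if (inherits(object, "suvr_dataset")) {
    if (is.null(alpha)) stop("alpha required for the conventional path")
    base <- object$values
  } else {
    stop("object must be an mbn_ensemble or a suvr_dataset")
  }
  outlier_values <- as.matrix(outlier_values)
  if (nrow(outlier_values) > 0 && ncol(outlier_values) != ncol(base))
    stop("outlier rows have wrong VOI dimension")
  values <- rbind(base, outlier_values)
  rownames(values) <- sprintf("row_%04d", seq_len(nrow(values)))
  y <- suvr_dataset(values, group = "perturbed",
                    voi_names = colnames(base))
  conventional_mbn(y, alpha)
}

#' Run an outlier-attack stability experiment
#'
#' Builds the unperturbed network for the chosen construction method once,
#' then performs \code{q_attacks} independent outlier attacks; each attack
#' recomputes the network from the contaminated data and records the four
#' stability distances between the original and perturbed networks:
#' Frobenius (dF) and Hausdorff (dH) in matrix space, Euclidean (dE) and
#' Canberra (dC) over the six graph features. Lower values mean a more stable
#' network. For the multiple-sampling methods the unperturbed reference is
#' the FDR+Pmap-corrected representative (the group network as the scheme
#' defines it, with \code{theta = 1 - alpha}); each attack appends the
#' outlier rows to the representative's source sample, reruns Pearson + FDR
#' at the same alpha, and masks the result with the same probability-map
#' threshold matrix, so a zero-outlier attack reproduces the reference
#' exactly. For the conventional method attacks append the same rows to the
#' full dataset and rerun the single-pass FDR construction.
#'
#' @param target the \code{\link{suvr_dataset}} under attack.
#' @param donor_a,donor_b donor datasets for the cross-group outliers.
#' @param method \code{"ms_bootstrap"}, \code{"ms_subsample"} or
#'   \code{"conventional"}.
#' @param p_o outlier percentage (default 2).
#' @param q_attacks number of attacks (default 256).
#' @param n ensemble size for the multiple-sampling methods.
#' @param alpha FDR level (default 0.0001).
#' @param criterion representative-selection criterion.
#' @param fraction subsample fraction for \code{"ms_subsample"}.
#' @param ns optional reduced target size: the target is first subsampled
#'   (without replacement) to \code{ns} rows, for size-sweep experiments.
#' @param seed master seed; attack k uses a seed derived from it.
#' @return A \code{"stability_report"}: list with \code{records} (data frame
#'   of dF, dH, dE, dC per attack), \code{summary} (mean and sd per metric),
#'   and \code{config}.
#' @export
run_attack_experiment <- function(target, donor_a, donor_b,
                                  method = c("ms_bootstrap", "ms_subsample",
                                             "conventional"),
                                  p_o = 2, q_attacks = 256L, n = 9300L,
                                  alpha = 1e-4,
                                  criterion = c("mean", "median", "mode"),
                                  fraction = 0.8, ns = NULL, seed = NULL) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  stopifnot(inherits(target, "suvr_dataset"), q_attacks >= 1)
  if (!is.null(ns)) {
    if (ns > nrow(target$values)) stop("ns exceeds target size")
    keep <- .with_seed(.derive_seed(seed, 777L),
                       sample.int(nrow(target$values), ns))
    target <- suvr_dataset(target$values[keep, , drop = FALSE],
                           group = target$group,
                           subject_ids = target$subject_ids[keep],
                           voi_names = target$voi_names)
  }
  N <- nrow(target$values)
  L <- round(p_o / 100 * N)
  if (p_o > 0 && L < 1L) L <- 1L

  if (method == "conventional") {
    reference <- conventional_mbn(target, alpha)
    ens <- NULL
    rep_index <- NULL
    pmask <- NULL
  } else {
    mode <- if (method == "ms_bootstrap") "bootstrap" else "subsample"
    ens <- build_ensemble(target, n = n, alpha = alpha, mode = mode,
                          fraction = fraction,
                          seed = .derive_seed(seed, 1L))
    rep_net <- select_representative(ens, criterion)
    rep_index <- attr(rep_net, "index")
    # the group network is defined through FDR + Pmap; perturbed versions are
    # masked by the same threshold matrix, so the comparison is between the
    # network as defined and its recomputation under contamination
    pm <- compute_pmap(ens)
    theta <- 1 - alpha
    reference <- apply_pmap_threshold(rep_net, pm, theta)
    pmask <- pm$probs > theta
  }
  f_ref <- suppressWarnings(graph_features(reference))

  records <- vector("list", q_attacks)
  for (q in seq_len(q_attacks)) {
    attacked <- attack_dataset(target, donor_a, donor_b, p_o,
                               seed = .derive_seed(seed, 1000L + q))
    out_rows <- attacked$values[-seq_len(N), , drop = FALSE]
    pert <- if (method == "conventional") {
      perturbed_network(target, out_rows, alpha = alpha)
    } else {
      raw <- perturbed_network(ens, out_rows, alpha = alpha,
                               rep_index = rep_index)
      w <- raw$weights * pmask
      diag(w) <- 0
      mbn_network(w, pvalues = raw$pvalues, voi_names = raw$voi_names,
                  alpha = alpha, correction = "fdr+pmap",
                  theta = 1 - alpha)
    }
    f_pert <- suppressWarnings(graph_features(pert))
    records[[q]] <- data.frame(
      attack = q,
      dF = matrix_distance(reference, pert, "frobenius"),
      dH = matrix_distance(reference, pert, "hausdorff"),
      dE = feature_distance(f_ref, f_pert, "euclidean"),
      dC = feature_distance(f_ref, f_pert, "canberra"))
  }
  records <- do.call(rbind, records)
  metrics <- c("dF", "dH", "dE", "dC")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(records[metrics], mean, numeric(1L)),
    sd = vapply(records[metrics], stats::sd, numeric(1L)),
    row.names = NULL)
  structure(
    list(records = records, summary = summ,
         config = list(method = method, p_o = p_o, q_attacks = q_attacks,
                       n = if (method == "conventional") NA_integer_ else n,
                       alpha = alpha, criterion = criterion, ns = ns,
                       L = L, N = N, seed = seed)),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Stability report: %s, P_o = %g%% (L = %d of N = %d), %d attacks\n",
              cfg$method, cfg$p_o, cfg$L, cfg$N, cfg$q_attacks))
  print(transform(x$summary, mean = signif(mean, 4), sd = signif(sd, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Write the per-attack records of a stability report
#'
#' One row per attack and metric (long format), so downstream statistical
#' comparisons (e.g. ANOVA over methods and groups) can be run in any stats
#' environment.
#'
#' @param report a \code{"stability_report"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_stability_report <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  rec <- report$records
  long <- do.call(rbind, lapply(c("dF", "dH", "dE", "dC"), function(m) {
    data.frame(attack = rec$attack, metric = m, value = rec[[m]],
               method = report$config$method, p_o = report$config$p_o)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
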