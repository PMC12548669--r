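# Network construction: correlation adjacency, FDR, ensembles,
# representative selection, probability maps

test_that("pearson adjacency matches the direct sum-formula oracle", {
  p <- c(1, 2, 3, 4, 5)
  q <- c(2, 1, 4, 3, 6)
  x <- suvr_dataset(cbind(a = p, b = q, c = c(5, 3, 8, 2, 7)))
  net <- pearson_adjacency(x)
  expect_equal(net$weights["a", "b"], oracle_pearson(p, q), tolerance = 1e-12)
  expect_equal(net$weights["a", "c"],
               oracle_pearson(p, c(5, 3, 8, 2, 7)), tolerance = 1e-12)
  expect_equal(diag(net$weights), rep(0, 3), ignore_attr = TRUE)
})

test_that("perfect linear dependence gives r = +/- 1", {
  p <- c(1.3, 2.1, 0.9, 1.7)
  x <- suvr_dataset(cbind(a = p, b = 2 * p + 3, c = 10 - p))
  net <- pearson_adjacency(x)
  expect_equal(net$weights["a", "b"], 1, tolerance = 1e-12)
  expect_equal(net$weights["a", "c"], -1, tolerance = 1e-12)
  expect_lt(net$pvalues["a", "b"], 1e-10)
})

test_that("pearson p-values agree with cor.test", {
  x <- make_dataset(20, 4, seed = 3)
  net <- pearson_adjacency(x)
  for (pair in list(c(1, 2), c(2, 4), c(3, 4))) {
    ct <- stats::cor.test(x$values[, pair[1]], x$values[, pair[2]])
    expect_equal(net$pvalues[pair[1], pair[2]], ct$p.value, tolerance = 1e-9)
  }
})

test_that("zero-variance columns are rejected with the VOI named", {
  v <- make_values(10, 3)
  v[, 2] <- 1.5
  x <- suvr_dataset(v, voi_names = c("hippocampus", "pons", "thalamus"))
  expect_error(pearson_adjacency(x), "pons")
  expect_error(conventional_mbn(x, 0.05), "pons")
})

test_that("BH step-up oracle reproduces the worked 4-edge case", {
  reject <- oracle_bh(c(0.001, 0.02, 0.04, 0.2), alpha = 0.05)
  expect_identical(reject, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("fdr_correct matches brute-force BH on random and boundary cases", {
  for (seed in 1:6) {
    set.seed(seed)
    d <- sample(4:8, 1)
    w <- matrix(stats::runif(d * d, -1, 1), d)
    pv <- matrix(stats::runif(d * d)^2, d)
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
    diag(pv) <- 0
    net <- toy_network(w, pvalues = pv)
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    corrected <- fdr_correct(net, alpha)
    ut <- upper.tri(pv)
    expect_identical(corrected$weights[ut] != 0, oracle_bh(pv[ut], alpha))
    expect_equal(corrected$alpha, alpha)
  }
})

test_that("degenerate p-value extremes behave as expected", {
  d <- 5
  w <- matrix(0.5, d, d); diag(w) <- 0
  ones <- matrix(1, d, d); diag(ones) <- 0
  all_kept <- fdr_correct(toy_network(w, pvalues = ones * 0), 0.05)
  expect_true(all(all_kept$weights[upper.tri(w)] != 0))
  none_kept <- fdr_correct(toy_network(w, pvalues = ones), 0.05)
  expect_true(all(none_kept$weights[upper.tri(w)] == 0))
})

test_that("build_ensemble is deterministic and records provenance", {
  x <- make_dataset(25, 6, seed = 9)
  e1 <- build_ensemble(x, n = 10, alpha = 0.05, seed = 31)
  e2 <- build_ensemble(x, n = 10, alpha = 0.05, seed = 31)
  expect_identical(e1$sample_indices, e2$sample_indices)
  expect_equal(e1$networks[[3]]$weights, e2$networks[[3]]$weights)

  e3 <- build_ensemble(x, n = 1, alpha = 0.05, seed = 1)
  expect_length(e3$networks, 1L)
  idx <- e3$sample_indices[[1]]
  expect_length(idx, 25L)
  expect_true(all(idx >= 1 & idx <= 25))

  # member k is exactly the Pearson+FDR network of its recorded sample
  y <- suvr_dataset(x$values[e1$sample_indices[[4]], , drop = FALSE],
                    subject_ids = sprintf("r%d", 1:25))
  expect_equal(e1$networks[[4]]$weights,
               conventional_mbn(y, 0.05)$weights, tolerance = 1e-12)
})

test_that("subsample mode draws distinct rows of the requested size", {
  x <- make_dataset(40, 5, seed = 2)
  e <- build_ensemble(x, n = 5, alpha = 0.05, mode = "subsample",
                      fraction = 0.5, seed = 17)
  for (idx in e$sample_indices) {
    expect_length(idx, 20L)
    expect_false(anyDuplicated(idx) > 0)
  }
})

test_that("a constant dataset is rejected rather than resampled forever", {
  v <- matrix(rep(c(1.2, 1.3, 1.4, 1.5), each = 8), 8, 4)  # 8 identical rows
  x <- suvr_dataset(v)
  expect_error(build_ensemble(x, n = 2, alpha = 0.05, seed = 1),
               "zero-variance")
})

test_that("representative selection matches an exhaustive Frobenius scan", {
  x <- make_dataset(30, 6, seed = 12)
  ens <- build_ensemble(x, n = 5, alpha = 0.2, seed = 8)
  W <- lapply(ens$networks, function(m) m$weights)

  mbar <- Reduce(`+`, W) / length(W)
  dists <- vapply(W, function(m) sqrt(sum((m - mbar)^2)), numeric(1L))
  rep_mean <- select_representative(ens, "mean")
  expect_equal(attr(rep_mean, "index"), which.min(dists))
  expect_equal(rep_mean$weights, W[[which.min(dists)]])

  med <- apply(simplify2array(W), c(1, 2), stats::median)
  dists_med <- vapply(W, function(m) sqrt(sum((m - med)^2)), numeric(1L))
  expect_equal(attr(select_representative(ens, "median"), "index"),
               which.min(dists_med))

  # mode: brute-force kNN density over pairwise Frobenius distances
  n <- length(W)
  D <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) sqrt(sum((W[[i]] - W[[j]])^2))))
  k <- min(ceiling(sqrt(n)), n - 1L)
  knn <- vapply(seq_len(n),
                function(i) mean(sort(D[i, -i])[seq_len(k)]), numeric(1L))
  expect_equal(attr(select_representative(ens, "mode"), "index"),
               which.min(knn))

  # representative is always an ensemble member
  for (cr in c("mean", "median", "mode")) {
    rep <- select_representative(ens, cr)
    expect_true(any(vapply(W, function(m) identical(m, rep$weights),
                           logical(1L))))
  }
})

test_that("probability map entries are exact edge-occurrence fractions", {
  x <- make_dataset(20, 5, seed = 4)
  ens <- build_ensemble(x, n = 4, alpha = 0.3, seed = 3)
  pm <- compute_pmap(ens)
  counts <- Reduce(`+`, lapply(ens$networks, function(m) (m$weights != 0) * 1))
  expect_equal(pm$probs[upper.tri(counts)],
               counts[upper.tri(counts)] / 4, tolerance = 1e-15)
  # entries are exact multiples of 1/n
  expect_true(all(abs(pm$probs * 4 - round(pm$probs * 4)) < 1e-12))
  expect_equal(diag(pm$probs), rep(0, 5), ignore_attr = TRUE)
})

test_that("pmap threshold retains strictly-exceeding edges only", {
  probs <- matrix(c(0, 0.5, 0.75, 0.5, 0, 1, 0.75, 1, 0), 3)
  pm <- structure(list(probs = probs, n = 4L,
                       voi_names = c("a", "b", "c")),
                  class = "mbn_pmap")
  w <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3)
  net <- toy_network(w)

  kept0 <- apply_pmap_threshold(net, pm, theta = 0)
  expect_true(all(kept0$weights[upper.tri(w)] != 0))  # all probs > 0

  # boundary: entry exactly equal to theta is removed
  kept50 <- apply_pmap_threshold(net, pm, theta = 0.5)
  expect_equal(kept50$weights[1, 2], 0)
  expect_equal(kept50$weights[1, 3], .4)
  expect_equal(kept50$weights[2, 3], .5)

  kept1 <- apply_pmap_threshold(net, pm, theta = 1)
  expect_true(all(kept1$weights == 0))

  expect_error(apply_pmap_threshold(net, pm, theta = 1.2), "theta")
})

test_that("theta = 1 - alpha at alpha 1e-4 requires near-unanimous edges", {
  # integer arithmetic: k/n > 0.9999 with n = 9300 only for k = 9300
  n <- 9300
  expect_false(9299 / n > 0.9999)
  expect_true(9300 / n > 0.9999)
  # and at the package's reduced ensemble sizes the bound is unanimity too
  expect_false(499 / 500 > 0.9999)
})

test_that("conventional network equals ensemble member under identity draw", {
  x <- make_dataset(15, 4, seed = 6)
  conv <- conventional_mbn(x, 0.05)
  y <- suvr_dataset(x$values[seq_len(15), , drop = FALSE])
  expect_equal(conv$weights, fdr_correct(pearson_adjacency(y), 0.05)$weights)
  expect_equal(conv$correction, "fdr")
})

test_that("conventional network is invariant to subject permutation", {
  x <- make_dataset(22, 5, seed = 10)
  perm <- sample(22)
  xp <- suvr_dataset(x$values[perm, , drop = FALSE],
                     subject_ids = x$subject_ids[perm],
                     voi_names = x$voi_names)
  expect_equal(conventional_mbn(x, 0.05)$weights,
               conventional_mbn(xp, 0.05)$weights, tolerance = 1e-12)
})

test_that("covariate residualization removes the covariate signal", {
  set.seed(44)
  n <- 50
  age <- stats::rnorm(n, 73, 6)
  v <- cbind(2 * 0.01 * age + stats::rnorm(n, 1.2, 0.05),
             stats::rnorm(n, 1.2, 0.05),
             stats::rnorm(n, 1.4, 0.05))
  x <- suvr_dataset(v, covariates = cbind(age = age))
  adj <- residualize_covariates(x)
  expect_lt(abs(stats::cor(adj$values[, 1], age)), 1e-10)
  # column means preserved
  expect_equal(colMeans(adj$values), colMeans(x$values), tolerance = 1e-10)
  # covariate orthogonal to a column leaves it unchanged
  ortho <- stats::residuals(stats::lm(v[, 2] ~ age)) + mean(v[, 2])
  x2 <- suvr_dataset(cbind(a = ortho, b = v[, 3]),
                     covariates = cbind(age = age))
  adj2 <- residualize_covariates(x2)
  expect_equal(adj2$values[, "a"], x2$values[, "a"], tolerance = 1e-10)

  # rank-deficient covariates rejected
  x3 <- suvr_dataset(v, covariates = cbind(z = rep(0, n)))
  expect_error(residualize_covariates(x3), "rank-deficient")
})

test_that("FDR+Pmap never keeps an edge that FDR alone removed (property)", {
  for (seed in 1:8) {
    x <- make_dataset(20, 6, seed = 100 + seed)
    alpha <- sample(c(0.05, 0.2), 1)
    ens <- build_ensemble(x, n = 12, alpha = alpha, seed = seed)
    rep <- select_representative(ens, "mean")
    pm <- compute_pmap(ens)
    theta <- stats::runif(1)
    combined <- apply_pmap_threshold(rep, pm, theta)
    expect_true(all(which(combined$weights != 0) %in%
                    which(rep$weights != 0)))
  }
})

test_that("FDR survival is monotone in alpha", {
  x <- make_dataset(30, 8, seed = 55)
  net <- pearson_adjacency(x)
  alphas <- c(0.0001, 0.001, 0.01, 0.05, 0.2)
  survived <- lapply(alphas, function(a) which(fdr_correct(net, a)$weights != 0))
  for (i in seq_len(length(alphas) - 1L)) {
    expect_true(all(survived[[i]] %in% survived[[i + 1L]]))
  }
})

test_that("the mbn() fit wraps the pipeline end to end", {
  co <- small_cohort(n_per_group = 50, d = 12)
  fit <- mbn(co$CU, method = "bootstrap", n = 30, alpha = 0.01, seed = 2)
  expect_s3_class(fit, "mbn")
  expect_equal(fit$network$correction, "fdr+pmap")
  expect_equal(fit$network$theta, 1 - 0.01)
  expect_identical(coef(fit), fit$network$weights)
  expect_output(print(summary(fit)), "graph features")

  # reproducible under seed
  fit2 <- mbn(co$CU, method = "bootstrap", n = 30, alpha = 0.01, seed = 2)
  expect_equal(coef(fit), coef(fit2))

  conv <- mbn(co$CU, method = "conventional", alpha = 0.01)
  expect_equal(coef(conv), conventional_mbn(co$CU, 0.01)$weights)
})
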