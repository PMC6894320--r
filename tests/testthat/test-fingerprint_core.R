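test_that("subsampled replicates conserve depth and follow the multinomial mean", {
  # single support point: every draw lands on the nonzero feature
  reps <- subsample_replicates(c(a = 7, b = 0), subsample_spec(depth = 10, n_replicates = 4))
  expect_true(all(reps[, "a"] == 10L) && all(reps[, "b"] == 0L))
  # row sums equal depth for arbitrary counts
  set.seed(11)
  for (i in 1:20) {
    cnt <- rpois(8, lambda = 50) + 1
    m <- subsample_replicates(cnt, subsample_spec(depth = 1234, n_replicates = 5,
                                                  seed = i), donor_id = "dX")
    expect_true(all(rowSums(m) == 1234L))
  }
  # binomial standard-error bound on the mean fraction
  m <- subsample_replicates(c(900, 100), subsample_spec(depth = 100000,
                                                        n_replicates = 10, seed = 7))
  frac <- mean(m[, 1]) / 100000
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 100000))
  expect_error(subsample_replicates(c(0, 0), donor_id = "Dz"), "Dz")
})

test_that("each donor draws from its own seed stream", {
  counts <- rbind(D1 = c(10, 20, 30), D2 = c(5, 5, 5))
  colnames(counts) <- c("a", "b", "c")
  spec <- subsample_spec(depth = 100, n_replicates = 3, seed = 9)
  both <- build_replicate_matrix(counts, spec)
  solo <- subsample_replicates(counts["D1", ], spec, donor_id = "D1")
  expect_equal(both[1:3, ], solo)  # adding D2 never perturbs D1's replicates
  expect_identical(build_replicate_matrix(counts, spec), both)  # determinism
})

test_that("z-score normalization matches the hand-derived worked example", {
  mat <- cbind(x = c(1, 10, 100))
  out <- zscore_normalize(mat)
  expected <- c(10^(-sqrt(1.5)), 1, 10^sqrt(1.5))  # population sd of (0,1,2) logs
  expect_equal(unname(out[, 1]), expected, tolerance = 1e-9)
  expect_equal(unname(out[, 1]), c(0.0596, 1.0, 16.777), tolerance = 1e-2)
  # zero-variance column policy: all values map to 1
  expect_equal(unname(zscore_normalize(cbind(c(5, 5, 5)))[, 1]), c(1, 1, 1))
  # zeros become the pseudocount before the log transform
  m0 <- cbind(c(0, 0, 1))
  logs <- log10(ifelse(m0 == 0, 0.01, m0))
  expect_equal(unname(logs[, 1]), c(-2, -2, 0))
  out0 <- zscore_normalize(m0)
  expect_equal(unname(log10(out0[, 1])),
               unname((logs[, 1] - mean(logs)) / sqrt(mean((logs - mean(logs))^2))),
               tolerance = 1e-12)
  expect_error(zscore_normalize(cbind(c(5))), "2 rows")
})

test_that("z-score normalization agrees with an independent oracle and is unit-scaled", {
  set.seed(21)
  for (i in 1:25) {
    m <- matrix(rpois(48, lambda = 40), nrow = 6)
    m[sample(48, 5)] <- 0
    out <- zscore_normalize(m)
    expect_equal(out, oracle_zscore(m), tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(out > 0))
    lg <- log10(out)
    keep <- apply(lg, 2, function(c) diff(range(c)) > 0)
    expect_true(all(abs(colMeans(lg[, keep])) < 1e-9))
    expect_true(all(abs(sqrt(colMeans(sweep(lg[, keep], 2,
                    colMeans(lg[, keep]))^2)) - 1) < 1e-9))
  }
})

test_that("PCA reproduces the covariance eigendecomposition", {
  # rank-1 data: first component explains everything
  t_vals <- seq(0, 1, length.out = 6)
  rank1 <- outer(t_vals, c(1, -2, 0.5))
  model <- fit_pca(rank1, 2)
  expect_equal(model$explained_variance_ratio[1], 1, tolerance = 1e-9)
  # random matrices against the eigen oracle
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rnorm(40), nrow = 8)
    model <- fit_pca(m, 3)
    expect_equal(model$explained_variance_ratio, oracle_pca_ratios(m, 3),
                 tolerance = 1e-8)
    expect_true(all(diff(model$explained_variance_ratio) <= 1e-12))
    expect_lte(sum(model$explained_variance_ratio), 1 + 1e-9)
    expect_equal(model$loadings %*% t(model$loadings), diag(3),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(fit_pca(matrix(rnorm(12), 3), 4), "n_components")
  expect_warning(fit_pca(matrix(1, 4, 3), 2), "degenerate")
})

test_that("projection is centered, self-consistent, and validates features", {
  set.seed(41)
  m <- matrix(rnorm(60), nrow = 10)
  colnames(m) <- paste0("f", 1:6)
  model <- fit_pca(m, 2)
  emb <- project_embedding(model, m)
  # training scores reproduce the model's variance ratios
  total <- sum(eigen(stats::cov(m))$values)
  expect_equal(unname(apply(emb, 2, stats::var) / total),
               model$explained_variance_ratio, tolerance = 1e-8)
  # centering invariance: constant translation leaves nothing (after re-centering
  # with the stored means the shift passes through the loadings identically)
  shifted <- project_embedding(model, sweep(m, 2, rep(2, 6), `+`))
  delta <- sweep(shifted, 2, drop(rep(2, 6) %*% t(model$loadings)))
  expect_equal(delta, emb, tolerance = 1e-10, ignore_attr = TRUE)
  # a row equal to the column means maps to the origin
  at_center <- matrix(model$center, nrow = 1,
                      dimnames = list(NULL, colnames(m)))
  expect_equal(unclass(project_embedding(model, at_center)),
               matrix(0, 1, 2), tolerance = 1e-10, ignore_attr = TRUE)
  bad <- m
  colnames(bad) <- paste0("g", 1:6)
  expect_error(project_embedding(model, bad), "g1")
})

test_that("feature weights surface the varying feature with a positive top weight", {
  set.seed(51)
  m <- matrix(rnorm(40, sd = 0.01), nrow = 8, ncol = 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  m[, 3] <- rnorm(8, sd = 5)
  model <- fit_pca(m, 2)
  w <- feature_weights(model, 1)
  expect_equal(w$feature[w$PC1_rank == 1], "f3")
  expect_gte(w$PC1[w$PC1_rank == 1], 0)        # sign convention
  expect_equal(sum(w$PC1^2), 1, tolerance = 1e-8)  # unit-norm loading
  expect_error(feature_weights(model, 5), "invalid component")
})

test_that("k-means recovers separated groups with deterministic label order", {
  emb <- rbind(matrix(rnorm(6, 0, 0.1), 3, 2), matrix(rnorm(6, 10, 0.1), 3, 2))
  labels <- kmeans_cluster(emb, cluster_spec(k = 2, seed = 3))
  expect_equal(as.integer(labels), c(1L, 1L, 1L, 2L, 2L, 2L))  # centroid-ordered
  expect_identical(labels, kmeans_cluster(emb, cluster_spec(k = 2, seed = 3)))
  expect_equal(as.integer(kmeans_cluster(emb, cluster_spec(k = 1))), rep(1L, 6))
  expect_error(kmeans_cluster(emb[1:2, , drop = FALSE], cluster_spec(k = 3)),
               "clusters")
})

test_that("the fingerprint pipeline is deterministic under a fixed seed", {
  specs <- default_study_specs(delta = 1, clonotypes_per_donor = 50000L)
  study <- generate_study(specs$cohort_a, specs$cohort_b, seed = 5)
  fp1 <- fingerprint(study$counts, subsample = subsample_spec(depth = 20000, seed = 5),
                     cluster = cluster_spec(seed = 5))
  fp2 <- fingerprint(study$counts, subsample = subsample_spec(depth = 20000, seed = 5),
                     cluster = cluster_spec(seed = 5))
  expect_identical(fp1$replicates, fp2$replicates)
  expect_identical(fp1$embedding, fp2$embedding)
  expect_identical(fp1$clusters, fp2$clusters)
})

test_that("PCA models survive the JSON round trip", {
  set.seed(61)
  m <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("f", 1:5)))
  model <- fit_pca(m, 2)
  path <- tempfile(fileext = ".json")
  write_pca_model(model, path)
  back <- read_pca_model(path)
  expect_equal(back$loadings, model$loadings, tolerance = 1e-12)
  expect_equal(back$center, model$center, tolerance = 1e-12)
  expect_equal(back$explained_variance_ratio, model$explained_variance_ratio,
               tolerance = 1e-12)
  expect_equal(project_embedding(back, m), project_embedding(model, m),
               tolerance = 1e-10, ignore_attr = TRUE)
})
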