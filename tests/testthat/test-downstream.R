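test_that("head-operon correlation recovers an attention head equal to the labels", {
  set.seed(51)
  n <- 400L
  labels <- runif(n) < 0.3
  features <- matrix(rnorm(n * 6), n, 6,
                     dimnames = list(NULL, sprintf("L1H%d", 1:6)))
  features[, 3] <- as.numeric(labels)
  res <- head_operon_correlation(features, labels)
  expect_identical(res$head[1], "L1H3")
  expect_equal(res$rho[1], 1, tolerance = 1e-12)
  expect_lt(res$p_adjusted[1], 1e-10)
  # constant head: undefined correlation reported as missing
  features[, 5] <- 1
  res2 <- head_operon_correlation(features, labels)
  expect_true(is.na(res2$rho[res2$head == "L1H5"]))
  expect_error(head_operon_correlation(features, rep(TRUE, n)), "variance")
})

test_that("permuted labels yield no Bonferroni-significant heads beyond the nominal level", {
  set.seed(52)
  n <- 800L
  features <- matrix(rnorm(n * 16), n, 16)
  labels <- runif(n) < 0.25
  res <- head_operon_correlation(features, labels)
  expect_lte(sum(res$p_adjusted < 0.05, na.rm = TRUE), 1L)
  # permutation null of a single head is centered at zero
  null <- head_correlation_null(features[, 1], labels, n_perm = 400L, seed = 53L)
  expect_lt(abs(mean(null)), 0.01)
  expect_lt(stats::quantile(abs(null), 0.95), 0.1)
})

test_that("operon classifier: perfect features give AP 1, null features give prevalence", {
  set.seed(54)
  n <- 500L
  labels <- runif(n) < 0.3
  sep <- cbind(as.numeric(labels) * 2 - 1 + rnorm(n, sd = 0.05),
               matrix(rnorm(n * 3), n, 3))
  res <- train_operon_classifier(sep, labels, k = 5L, seed = 55L)
  expect_equal(res$fold_ap, rep(1, 5), tolerance = 1e-8)
  null_feats <- matrix(rnorm(n * 8), n, 8)
  res0 <- train_operon_classifier(null_feats, labels, k = 5L, seed = 56L)
  expect_lt(abs(res0$ap_mean - mean(labels)), 0.1)
  expect_error(train_operon_classifier(null_feats, rep(TRUE, n)), "single-class")
})

test_that("average precision behaves at its extremes", {
  expect_equal(average_precision(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(average_precision(c(0, 1, 2, 3), c(TRUE, TRUE, FALSE, FALSE)), 5 / 12)
  set.seed(57)
  y <- runif(2000) < 0.2
  expect_lt(abs(average_precision(rnorm(2000), y) - mean(y)), 0.05)
})

test_that("Gaussian KL matches its closed forms", {
  s <- function(mu, S) structure(list(mean = mu, covariance = rbind(S),
                                      n = Inf, dim = length(mu)),
                                 class = "gaussian_summary")
  expect_equal(as.numeric(gaussian_kl(s(0, 1), s(1, 1))), 0.5)
  expect_equal(as.numeric(gaussian_kl(s(c(0, 0), diag(2)), s(c(0, 0), diag(2)))), 0)
  set.seed(58)
  X <- matrix(rnorm(500 * 3), 500, 3)
  expect_lt(as.numeric(gaussian_kl(X, X)), 1e-8)
  expect_gte(as.numeric(gaussian_kl(X, X + 1)), 0)
})

test_that("Gaussian KL agrees with a Monte-Carlo estimate on random 5-d Gaussians", {
  set.seed(59)
  k <- 5L
  A0 <- matrix(rnorm(k * k), k)
  A1 <- matrix(rnorm(k * k), k)
  S0 <- crossprod(A0) + diag(k)
  S1 <- crossprod(A1) + diag(k)
  mu0 <- rnorm(k)
  mu1 <- rnorm(k)
  P <- structure(list(mean = mu0, covariance = S0, n = Inf, dim = k),
                 class = "gaussian_summary")
  Q <- structure(list(mean = mu1, covariance = S1, n = Inf, dim = k),
                 class = "gaussian_summary")
  closed <- as.numeric(gaussian_kl(P, Q))
  # Monte-Carlo oracle: E_P[log p - log q] over samples from P
  n_mc <- 2e5
  Z <- matrix(rnorm(n_mc * k), n_mc, k)
  X <- Z %*% chol(S0) + matrix(mu0, n_mc, k, byrow = TRUE)
  logdens <- function(X, mu, S) {
    ch <- chol(S)
    D <- forwardsolve(t(ch), t(X) - mu)
    -0.5 * colSums(D^2) - sum(log(diag(ch))) - k / 2 * log(2 * pi)
  }
  ratio <- logdens(X, mu0, S0) - logdens(X, mu1, S1)
  mc <- mean(ratio)
  se <- stats::sd(ratio) / sqrt(n_mc)
  expect_lt(abs(closed - mc), 3 * se)
})

test_that("Mahalanobis filter removes about the nominal tail of a clean sample", {
  set.seed(60)
  X <- matrix(rnorm(5000 * 4), 5000, 4)
  kept <- remove_outliers_mahalanobis(X, chi_q = 0.975)
  expect_lt(abs(attr(kept, "removed_fraction") - 0.025), 0.012)
  pp <- kl_preprocess(X, X + 0.5, n_pc = 2L)
  expect_identical(ncol(pp$X0), 2L)
  expect_identical(ncol(pp$X1), 2L)
})

test_that("KL ratio hits its fixed points and refuses a zero denominator", {
  set.seed(61)
  A <- matrix(rnorm(300 * 3), 300, 3)
  B <- matrix(rnorm(300 * 3), 300, 3) + 2
  expect_equal(kl_ratio(A, B, B), 1)
  expect_equal(kl_ratio(A, A, B), 0)
  expect_error(kl_ratio(A, B, A), "undefined")
})

test_that("context variance is zero for identical occurrences and d/2 for two point masses", {
  one_point <- list(G1 = matrix(1, 150, 4))
  rep1 <- context_variance(one_point, n_samples = 5L, sample_size = 100L, seed = 1L)
  expect_equal(rep1$per_gene$variance, 0)

  # two balanced point masses at distance d: cross pairs have frequency 1/2
  # in the limit, so the mean pairwise distance tends to d/2
  d <- 3
  X <- rbind(matrix(0, 200, 4), matrix(d / 2, 200, 4))  # distance d in L2
  dist_d <- sqrt(sum((X[1, ] - X[400, ])^2))
  rep2 <- context_variance(list(G = X), n_samples = 30L, sample_size = 100L,
                           seed = 2L)
  expect_equal(rep2$per_gene$variance, dist_d / 2, tolerance = 0.03)

  expect_message(context_variance(list(tiny = matrix(0, 5, 2))), "skipping")
  expect_error(context_variance(one_point, sample_size = 1L), "sample_size")
})

test_that("linear probe separates blobs and collapses under shuffled labels", {
  set.seed(62)
  n <- 400L
  centers <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, 2, byrow = TRUE)
  y <- rep(1:4, each = n / 4)
  X <- centers[y, ] + matrix(rnorm(n * 2, sd = 0.3), n, 2)
  tr <- seq(1, n, by = 2)
  te <- seq(2, n, by = 2)
  res <- linear_probe(X[tr, ], y[tr], X[te, ], y[te], seed = 63L)
  expect_equal(res$accuracy, 1)
  expect_gt(res$mean_ap, 0.99)
  y_shuf <- sample(y[tr])
  res0 <- linear_probe(X[tr, ], y_shuf, X[te, ], y[te], seed = 64L)
  expect_lt(abs(res0$accuracy - 0.25), 0.15)
  expect_error(linear_probe(X[tr, ], rep(1, length(tr)), X[te, ], y[te]),
               "classes")
})

test_that("per-class F1 comparison applies BH across classes", {
  set.seed(65)
  f1_a <- matrix(c(0.9, 0.5, 0.7), 3, 5) + matrix(rnorm(15, sd = 0.01), 3)
  f1_b <- f1_a
  f1_b[1, ] <- f1_b[1, ] - 0.3  # only class 1 differs
  rownames(f1_a) <- rownames(f1_b) <- c("c1", "c2", "c3")
  cmp <- compare_probe_f1(f1_a, f1_b)
  expect_lt(cmp$p_adjusted[cmp$class == "c1"], 0.01)
  expect_gt(min(cmp$p_adjusted[cmp$class != "c1"]), 0.05)
})

test_that("silhouette: separated blobs near 1, arbitrary split of one blob near 0", {
  set.seed(66)
  blob <- matrix(rnorm(200 * 2, sd = 0.1), 200, 2)
  two <- rbind(blob, blob + 50)
  g <- rep(1:2, each = 200)
  expect_gt(silhouette_score(two, g), 0.95)
  split_one <- silhouette_score(blob, sample(1:2, 200, replace = TRUE))
  expect_lt(abs(split_one), 0.1)
  # relabeling the groups changes nothing
  expect_equal(silhouette_score(two, g), silhouette_score(two, 3 - g))
  expect_error(silhouette_score(blob, rep(1, 200)), "groups")
})

test_that("paralog matching is trivially correct with a single candidate", {
  ts <- tiny_setup()
  cand <- matrix(rnorm(5), 1, 5, dimnames = list("partner", NULL))
  q <- ts$contigs[[1]]$genes[[1]]
  res <- paralog_match(ts$model, q, cand, "partner")
  expect_true(res$correct_exact)
  expect_error(paralog_match(ts$model, q, cand[0, , drop = FALSE], "x"), "empty")
})

test_that("the paralog chance null scales like nearest-candidate guessing", {
  set.seed(67)
  cand <- matrix(rnorm(20 * 6), 20, 6,
                 dimnames = list(sprintf("c%02d", 1:20), NULL))
  truth <- sample(rownames(cand), 8L, replace = TRUE)
  null <- paralog_chance_null(cand, truth, n_iter = 400L, seed = 68L)
  expect_length(null, 400L)
  expect_true(all(null >= 0 & null <= 8))
  # two flanks of roughly-1/20 guesses per query: mean lands well below 2
  expect_lt(mean(null), 2)
})

test_that("taxonomy classifier: disjoint-support classes separate, permuted labels do not", {
  catalog <- build_family_catalog(8L, 8L, noise_scale = 0.1, seed = 71L)
  spec <- list(A = c(F001 = 1, F002 = 1, F003 = 1, F004 = 1) / 4,
               B = c(F005 = 1, F006 = 1, F007 = 1, F008 = 1) / 4)
  corp <- sample_corpus(catalog, n_contigs = 80L, len_range = c(6L, 10L),
                        class_spec = spec, seed = 72L)
  emb <- t(vapply(corp$contigs,
                  function(ct) contig_embedding(NULL, ct, "context_free"),
                  numeric(8)))
  classes <- vapply(corp$contigs, function(ct) ct$contig_class, character(1))
  res <- taxonomy_classifier(emb, classes, k = 5L, seed = 73L)
  expect_gt(res$ap_mean, 0.95)
  expect_identical(sum(res$confusion), length(classes))

  perm <- sample(classes)
  res0 <- taxonomy_classifier(emb, perm, k = 5L, seed = 74L)
  expect_lt(res0$ap_mean, 0.75)

  # identical embeddings: chance-level average precision
  same <- matrix(1, length(classes), 4) + matrix(rnorm(length(classes) * 4,
                                                       sd = 1e-9), ncol = 4)
  res_same <- taxonomy_classifier(same, classes, k = 5L, seed = 75L)
  expect_lt(abs(res_same$ap_mean - 0.5), 0.12)

  expect_error(taxonomy_classifier(emb, c("A", rep("B", length(classes) - 1))),
               "smaller than k")
})
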