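# Gaussian KL divergence metrics with Mahalanobis outlier removal and PCA
# preprocessing, the KL ratio, and the context-variance statistic.

#' Gaussian summary of a sample
#'
#' @param X sample x feature matrix (or an existing summary passed through).
#' @return object of class `gaussian_summary`: `mean`, `covariance`, `n`, `dim`.
#' @export
gaussian_summary <- function(X) {
  if (inherits(X, "gaussian_summary")) return(X)
  X <- rbind(X)
  structure(list(mean = colMeans(X), covariance = stats::cov(X),
                 n = nrow(X), dim = ncol(X)),
            class = "gaussian_summary")
}

#' Closed-form KL divergence between two Gaussians
#'
#' \deqn{D_{KL}(P\|Q) = \tfrac12\left[\mathrm{tr}(\Sigma_1^{-1}\Sigma_0) - k
#'   + (\mu_1-\mu_0)^\top\Sigma_1^{-1}(\mu_1-\mu_0)
#'   + \ln(\det\Sigma_1/\det\Sigma_0)\right]}
#' with P = (mu0, Sigma0) and Q = (mu1, Sigma1). A singular `Sigma1` is
#' ridge-regularized by `epsilon * trace / k` (both covariances, so
#' `KL(P||P)` stays 0) with a warning recording the applied ridge.
#'
#' @param P,Q `gaussian_summary` objects (or sample matrices).
#' @param epsilon relative ridge used when `Sigma1` is not invertible.
#' @return nonnegative number; attribute `ridge` records any regularization.
#' @export
gaussian_kl <- function(P, Q, epsilon = 1e-6) {
  P <- gaussian_summary(P)
  Q <- gaussian_summary(Q)
  if (P$dim != Q$dim) stop_param("gaussian_kl: dimension mismatch")
  k <- P$dim
  S0 <- P$covariance
  S1 <- Q$covariance
  ridge <- 0
  ch1 <- tryCatch(chol(S1), error = function(e) NULL)
  if (is.null(ch1)) {
    ridge <- epsilon * sum(diag(S1)) / k
    if (ridge <= 0) ridge <- epsilon
    S0 <- S0 + ridge * diag(k)
    S1 <- S1 + ridge * diag(k)
    warning(sprintf("gaussian_kl: singular covariance, ridge %.3g applied", ridge))
    ch1 <- chol(S1)
  }
  ch0 <- tryCatch(chol(S0), error = function(e) NULL)
  if (is.null(ch0)) {
    r0 <- epsilon * max(sum(diag(S0)) / k, 1)
    ridge <- ridge + r0
    S0 <- S0 + r0 * diag(k)
    S1 <- S1 + r0 * diag(k)
    warning(sprintf("gaussian_kl: singular covariance, ridge %.3g applied", r0))
    ch0 <- chol(S0)
    ch1 <- chol(S1)
  }
  S1inv <- chol2inv(ch1)
  dmu <- Q$mean - P$mean
  val <- 0.5 * (sum(S1inv * S0) - k + drop(t(dmu) %*% S1inv %*% dmu) +
                  2 * sum(log(diag(ch1))) - 2 * sum(log(diag(ch0))))
  structure(max(val, 0), ridge = ridge)
}

#' KL divergence ratio
#'
#' `D_KL(B||A) / D_KL(C||A)`: below 1 means distribution B sits closer to the
#' reference A than C does (functional discrimination of B from C relative
#' to A).
#'
#' @param A,B,C `gaussian_summary` objects (or sample matrices).
#' @return nonnegative ratio.
#' @export
kl_ratio <- function(A, B, C) {
  den <- gaussian_kl(C, A)
  if (den == 0) stop_param("kl_ratio: D_KL(C||A) = 0, ratio undefined")
  as.numeric(gaussian_kl(B, A)) / as.numeric(den)
}

#' Mahalanobis outlier filter
#'
#' Drops points whose squared Mahalanobis distance from the sample mean
#' exceeds the chi-squared quantile `chi_q` at `k` degrees of freedom; on a
#' clean multivariate normal sample this removes about `1 - chi_q` of points.
#'
#' @param X sample x feature matrix.
#' @param chi_q chi-squared probability threshold (default 0.975).
#' @return the retained rows; attribute `removed_fraction`.
#' @export
remove_outliers_mahalanobis <- function(X, chi_q = 0.975) {
  X <- rbind(X)
  d2 <- stats::mahalanobis(X, colMeans(X), stats::cov(X))
  keep <- d2 <= stats::qchisq(chi_q, df = ncol(X))
  structure(X[keep, , drop = FALSE], removed_fraction = mean(!keep))
}

#' Preprocess two embedding sets for the KL comparison
#'
#' Applies the Mahalanobis filter to each set separately, then fits one PCA
#' on the pooled filtered sample and projects both sets to `n_pc` components
#' so the two distributions live in a common reduced space.
#'
#' @param X0,X1 sample x feature matrices.
#' @param n_pc retained components.
#' @param chi_q Mahalanobis threshold.
#' @return list: `X0`, `X1` (projected), `explained_variance`,
#'   `removed_fraction` (per set).
#' @export
kl_preprocess <- function(X0, X1, n_pc, chi_q = 0.975) {
  F0 <- remove_outliers_mahalanobis(X0, chi_q)
  F1 <- remove_outliers_mahalanobis(X1, chi_q)
  pooled <- rbind(F0, F1)
  if (n_pc > ncol(pooled)) stop_param("kl_preprocess: n_pc exceeds dimension")
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE, rank. = n_pc)
  list(X0 = stats::predict(pc, F0)[, seq_len(n_pc), drop = FALSE],
       X1 = stats::predict(pc, F1)[, seq_len(n_pc), drop = FALSE],
       explained_variance = sum(pc$sdev[seq_len(n_pc)]^2) / sum(pc$sdev^2),
       removed_fraction = c(attr(F0, "removed_fraction"),
                            attr(F1, "removed_fraction")))
}

#' Context variance of genes across occurrences
#'
#' For each gene (family) with at least `sample_size` occurrence embeddings,
#' draws `n_samples` independent random samples of `sample_size` occurrences
#' and averages the mean pairwise Euclidean distance within each sample.
#' Genes below the occurrence threshold are skipped with a message. The
#' distribution of the per-gene statistic is summarized by its excess
#' kurtosis and skew.
#'
#' @param embeddings named list: gene -> occurrences x feature matrix
#'   (e.g. from [collect_family_embeddings()], which already excludes
#'   contig-edge occurrences).
#' @param n_samples independent samples per gene (default 10).
#' @param sample_size occurrences per sample (default 100).
#' @param seed integer seed.
#' @return object of class `variance_report`: data.frame `per_gene`
#'   (gene, n_occurrences, variance), plus `kurtosis` and `skew`.
#' @export
context_variance <- function(embeddings, n_samples = 10L, sample_size = 100L,
                             seed = 1L) {
  if (sample_size < 2L) stop_param("context_variance: sample_size must be >= 2")
  genes <- names(embeddings)
  rows <- list()
  with_seed(seed, {
    for (g in genes) {
      X <- embeddings[[g]]
      if (nrow(X) < sample_size) {
        message("context_variance: skipping ", g, " (",
                nrow(X), " < ", sample_size, " occurrences)")
        next
      }
      v <- mean(vapply(seq_len(n_samples), function(s) {
        take <- sample.int(nrow(X), sample_size)
        mean(stats::dist(X[take, , drop = FALSE]))
      }, numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(gene = g,
                                              n_occurrences = nrow(X),
                                              variance = v)
    }
  })
  per_gene <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), n_occurrences = integer(0),
               variance = numeric(0))
  structure(list(per_gene = per_gene,
                 kurtosis = if (nrow(per_gene) > 3)
                   e1071::kurtosis(per_gene$variance) else NA_real_,
                 skew = if (nrow(per_gene) > 2)
                   e1071::skewness(per_gene$variance) else NA_real_,
                 n_samples = n_samples, sample_size = sample_size),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf("<variance_report: %d genes, %dx%d sampling, kurtosis %.3g, skew %.3g>\n",
              nrow(x$per_gene), x$n_samples, x$sample_size, x$kurtosis, x$skew))
  invisible(x)
}
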