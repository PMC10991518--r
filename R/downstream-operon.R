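# Attention-operon statistics: per-head Pearson correlation with Bonferroni
# adjustment, and a cross-validated all-heads logistic classifier.

#' Per-head correlation between adjacent-pair attention and operon labels
#'
#' Pools adjacent gene pairs over contigs and, for each layer/head, computes
#' Pearson's correlation between the symmetrized attention value at the pair
#' entry and the boolean operon label, with Bonferroni adjustment across
#' heads. Heads with constant attention get `NA` (correlation undefined).
#'
#' @param features pair x head matrix from [pair_attention_features()] (or
#'   its full list result).
#' @param labels logical operon labels (ignored when `features` is the list).
#' @return data.frame: `head` (column name), `layer`, `head_index`, `rho`,
#'   `p_value`, `p_adjusted`, sorted by |rho| descending.
#' @export
head_operon_correlation <- function(features, labels = NULL) {
  if (is.list(features) && !is.null(features$features)) {
    labels <- features$labels
    features <- features$features
  }
  if (length(unique(labels)) < 2L) stop_param("head_operon_correlation: label variance is zero")
  if (length(labels) < 2L) stop_param("head_operon_correlation: need >= 2 labeled pairs")
  y <- as.numeric(labels)
  n_heads <- ncol(features)
  rho <- rep(NA_real_, n_heads)
  pval <- rep(NA_real_, n_heads)
  for (j in seq_len(n_heads)) {
    x <- features[, j]
    if (stats::sd(x) == 0) next
    ct <- stats::cor.test(x, y, method = "pearson")
    rho[j] <- unname(ct$estimate)
    pval[j] <- ct$p.value
  }
  nm <- colnames(features) %||% sprintf("H%d", seq_len(n_heads))
  parsed <- regmatches(nm, regexec("^L([0-9]+)H([0-9]+)$", nm))
  layer <- vapply(parsed, function(m) if (length(m) == 3) as.integer(m[2]) else NA_integer_, integer(1))
  hidx <- vapply(parsed, function(m) if (length(m) == 3) as.integer(m[3]) else NA_integer_, integer(1))
  out <- data.frame(head = nm, layer = layer, head_index = hidx,
                    rho = rho, p_value = pval,
                    p_adjusted = pmin(pval * n_heads, 1),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$rho), na.last = TRUE), ]
}

#' Permutation null for a head's operon correlation
#'
#' @param x attention values of one head.
#' @param labels operon labels.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return vector of null correlations.
#' @export
head_correlation_null <- function(x, labels, n_perm = 500L, seed = 1L) {
  y <- as.numeric(labels)
  with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stats::cor(x, sample(y))
  }, numeric(1)))
}

stratified_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in levels(y)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        stop_param("stratified_folds: class '", cls, "' has fewer than ", k, " members")
      }
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold
}

#' Cross-validated operon classifier over all attention heads
#'
#' Ridge-regularized logistic regression (fixed lambda, recorded in the
#' result) on the full head-feature matrix, evaluated by stratified k-fold
#' cross-validation with per-fold average precision.
#'
#' @param features pair x head matrix (or [pair_attention_features()] list).
#' @param labels logical operon labels.
#' @param k folds (default 5).
#' @param lambda ridge penalty.
#' @param seed integer seed for fold assignment.
#' @return list: `ap_mean`, `ap_sd`, `fold_ap`, `pr_curves`, `prevalence`,
#'   `lambda`, and the final full-data `fit`.
#' @export
train_operon_classifier <- function(features, labels = NULL, k = 5L,
                                    lambda = 1e-3, seed = 1L) {
  if (is.list(features) && !is.null(features$features)) {
    labels <- features$labels
    features <- features$features
  }
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop_param("train_operon_classifier: single-class data")
  fold <- stratified_folds(labels, k, seed)
  fold_ap <- numeric(k)
  pr_curves <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- glmnet::glmnet(features[tr, , drop = FALSE], factor(labels[tr]),
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = TRUE)
    sc <- as.numeric(stats::predict(fit, features[!tr, , drop = FALSE],
                                    type = "response"))
    fold_ap[f] <- average_precision(sc, labels[!tr])
    pr_curves[[f]] <- pr_curve(sc, labels[!tr])
  }
  fit_all <- glmnet::glmnet(features, factor(labels), family = "binomial",
                            alpha = 0, lambda = lambda, standardize = TRUE)
  list(ap_mean = mean(fold_ap), ap_sd = stats::sd(fold_ap), fold_ap = fold_ap,
       pr_curves = pr_curves, prevalence = mean(labels), lambda = lambda,
       fit = fit_all)
}

#' Cross-validated contig taxonomy classifier
#'
#' Multinomial ridge logistic regression on contig embeddings with stratified
#' k-fold cross-validation, reporting micro-averaged average precision
#' (one-vs-rest probabilities of all classes pooled), per-fold PR curves and
#' a confusion matrix.
#'
#' @param embeddings contig x feature matrix.
#' @param classes per-contig class labels (>= 2 classes, each >= k members).
#' @param k folds (default 5).
#' @param lambda ridge penalty.
#' @param seed fold seed.
#' @return list: `ap_mean`, `ap_sd`, `fold_ap`, `pr_curves`, `confusion`,
#'   `accuracy`, `lambda`.
#' @export
taxonomy_classifier <- function(embeddings, classes, k = 5L, lambda = 1e-3,
                                seed = 1L) {
  classes <- as.factor(classes)
  if (nlevels(classes) < 2L) stop_param("taxonomy_classifier: need >= 2 classes")
  small <- names(which(table(classes) < k))
  if (length(small)) {
    stop_param("taxonomy_classifier: classes smaller than k folds: ",
               paste(small, collapse = ", "))
  }
  fold <- stratified_folds(classes, k, seed)
  fold_ap <- numeric(k)
  pr_curves <- vector("list", k)
  confusion <- matrix(0L, nlevels(classes), nlevels(classes),
                      dimnames = list(truth = levels(classes),
                                      predicted = levels(classes)))
  n_correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- glmnet::glmnet(embeddings[tr, , drop = FALSE], classes[tr],
                          family = "multinomial", alpha = 0, lambda = lambda,
                          standardize = TRUE)
    pr <- stats::predict(fit, embeddings[!tr, , drop = FALSE], type = "response")[, , 1]
    pr <- rbind(pr)
    truth <- classes[!tr]
    onehot <- outer(as.character(truth), colnames(pr), "==")
    fold_ap[f] <- average_precision(as.vector(pr), as.vector(onehot))
    pr_curves[[f]] <- pr_curve(as.vector(pr), as.vector(onehot))
    pred_cls <- colnames(pr)[max.col(pr, ties.method = "first")]
    for (i in seq_along(truth)) {
      confusion[as.character(truth[i]), pred_cls[i]] <-
        confusion[as.character(truth[i]), pred_cls[i]] + 1L
    }
    n_correct <- n_correct + sum(pred_cls == as.character(truth))
  }
  list(ap_mean = mean(fold_ap), ap_sd = stats::sd(fold_ap), fold_ap = fold_ap,
       pr_curves = pr_curves, confusion = confusion,
       accuracy = n_correct / length(classes), lambda = lambda)
}

#' Mean silhouette width of a grouping
#'
#' Standard silhouette with Euclidean distances.
#'
#' @param embeddings point x feature matrix.
#' @param grouping group labels (>= 2 groups, total >= 3 points).
#' @return mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(embeddings, grouping) {
  g <- as.integer(as.factor(grouping))
  if (length(unique(g)) < 2L) stop_param("silhouette_score: need >= 2 groups")
  if (nrow(embeddings) < 3L) stop_param("silhouette_score: need >= 3 points")
  sil <- cluster::silhouette(g, stats::dist(embeddings))
  mean(sil[, "sil_width"])
}
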