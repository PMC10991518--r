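#' @keywords internal
"_PACKAGE"

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed below 2^31 from a parent seed and a stream index.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483629
}

stop_param <- function(...) stop(..., call. = FALSE)

# ---- nested-list (parameter tree) helpers -----------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_sum <- function(f, tree) {
  if (is.list(tree)) sum(vapply(tree, function(x) tree_sum(f, x), numeric(1))) else f(tree)
}

# Flatten leaves into a single numeric vector (used by the gradient checker).
tree_unlist <- function(tree) unlist(tree, use.names = FALSE)

tree_relist <- function(values, skeleton) {
  pos <- 0L
  rebuild <- function(node) {
    if (is.list(node)) return(lapply(node, rebuild))
    n <- length(node)
    out <- values[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dim(out) <- dim(node)
    out
  }
  rebuild(skeleton)
}

# sklearn-style average precision: sum over ranked positives of precision@k
# weighted by recall increments.
#' Average precision of a score ranking
#'
#' Computes the area under the precision-recall curve by the step-wise
#' interpolation used throughout the package: \eqn{\sum_n (R_n - R_{n-1}) P_n}
#' over thresholds at every distinct ranked example.
#'
#' @param scores numeric vector of classifier scores (larger = more positive).
#' @param labels logical or 0/1 vector of true labels.
#' @return a single number in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels)) stop_param("average_precision: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  drecall <- diff(c(0, recall))
  sum(precision * drecall)
}

# Precision-recall curve points for plotting / reporting.
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  data.frame(
    threshold = scores[ord],
    precision = tp / seq_along(y),
    recall = tp / sum(y)
  )
}
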