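#' K-means clustering of signal matrices
#'
#' Clusters regions on their (already blurred and square-root
#' transformed) signal profiles across one or more marks/cell types.
#' Matrices sharing the same row ids are concatenated column-wise, then
#' clustered with Lloyd's algorithm from a seeded k-means++
#' initialization (Euclidean distance, at most `max_iter` iterations or
#' centroid movement below `tol`). Class labels are renumbered by
#' descending centroid mean so that numbering is reproducible rather
#' than initialization-dependent.
#'
#' @param matrices A `signal_matrix` or list of them with identical
#'   rownames (one per mark/cell type).
#' @param k Number of classes (>= 2; 4 is the conventional choice for
#'   enhancer signal, 3 for promoter methylation).
#' @param seed Integer seed for the k-means++ draw.
#' @param n_start Number of k-means++ restarts; the run with the lowest
#'   inertia is kept (default 10).
#' @param max_iter Maximum Lloyd iterations (default 300).
#' @param tol Convergence threshold on total centroid movement.
#' @return A `signal_clusters` object: `k`, `assignments` tibble
#'   (`region_id`, `class`), `centroids` matrix, `inertia`, per-iteration
#'   `inertia_trace`, `seed`, `iterations`.
#' @export
kmeans_cluster <- function(matrices, k, seed = 1L, n_start = 10L,
                           max_iter = 300L, tol = 1e-6) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  ids <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), ids)) {
      abort("all signal matrices must share identical row ids")
    }
  }
  x <- do.call(cbind, lapply(matrices, unclass))
  if (k > nrow(x)) abort("k exceeds the number of regions")
  if (k < 1) abort("k must be >= 1")

  fit <- NULL
  for (s in seq_len(max(n_start, 1L))) {
    centers <- with_local_seed(derive_seed(seed, s), kmeanspp_init(x, k))
    cand <- lloyd_kmeans(x, centers, max_iter = max_iter, tol = tol)
    if (is.null(fit) || cand$inertia < fit$inertia) fit <- cand
  }

  # deterministic labels: class 1 has the highest mean signal
  ord <- order(rowMeans(fit$centers), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  structure(
    list(
      k = as.integer(k),
      assignments = tibble(region_id = ids,
                           class = as.integer(relabel[fit$cluster])),
      centroids = fit$centers[ord, , drop = FALSE],
      inertia = fit$inertia,
      inertia_trace = fit$trace,
      iterations = fit$iterations,
      seed = as.integer(seed)
    ),
    class = "signal_clusters"
  )
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, each
# subsequent center drawn with probability proportional to squared
# distance to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
  if (k > 1) {
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1L, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ])^2))
    }
  }
  x[idx, , drop = FALSE]
}

# Lloyd's algorithm with an inertia trace; empty clusters are re-seeded
# with the point farthest from its centroid.
lloyd_kmeans <- function(x, centers, max_iter = 300L, tol = 1e-6) {
  k <- nrow(centers)
  trace <- numeric(0)
  cluster <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- cross_dist2(x, centers)
    cluster <- max.col(-d2, ties.method = "first")
    for (j in which(tabulate(cluster, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), cluster)])
      cluster[far] <- j
      d2[far, ] <- Inf
      d2[far, j] <- 0
    }
    trace <- c(trace, sum(d2[cbind(seq_len(nrow(x)), cluster)]))
    new_centers <- centers
    for (j in seq_len(k)) {
      new_centers[j, ] <- colMeans(x[cluster == j, , drop = FALSE])
    }
    moved <- sum(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (moved < tol) break
  }
  inertia <- sum(cross_dist2(x, centers)[cbind(seq_len(nrow(x)), cluster)])
  list(cluster = cluster, centers = centers, inertia = inertia,
       trace = trace, iterations = it)
}

cross_dist2 <- function(x, centers) {
  xc <- tcrossprod(x, centers)
  sweep(sweep(-2 * xc, 1, rowSums(x^2), "+"), 2, rowSums(centers^2), "+")
}

#' @export
print.signal_clusters <- function(x, ...) {
  cat(sprintf("<signal_clusters> k = %d, %d regions, inertia %.4g (%d iter)\n",
              x$k, nrow(x$assignments), x$inertia, x$iterations))
  print(count(x$assignments, .data$class))
  invisible(x)
}

#' @rdname kmeans_cluster
#' @param x A `signal_clusters` object.
#' @param ... Unused.
#' @method tidy signal_clusters
#' @export
tidy.signal_clusters <- function(x, ...) x$assignments

#' @rdname kmeans_cluster
#' @method glance signal_clusters
#' @export
glance.signal_clusters <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$assignments), inertia = x$inertia,
         iterations = x$iterations, seed = x$seed)
}

#' Agreement between cluster assignments and planted classes
#'
#' Finds the label permutation maximizing agreement (exact search over
#' all k! permutations; k is small here) and returns the matched
#' agreement fraction — the Hungarian-matched accuracy.
#'
#' @param assigned Integer vector of cluster labels.
#' @param truth Vector of planted labels (same length).
#' @return List with `agreement` (fraction) and `mapping` (named vector
#'   truth level -> cluster label).
#' @export
matched_agreement <- function(assigned, truth) {
  stopifnot(length(assigned) == length(truth))
  tl <- sort(unique(as.character(truth)))
  al <- sort(unique(assigned))
  k <- max(length(tl), length(al))
  if (k > 7) abort("matched_agreement supports up to 7 classes")
  conf <- matrix(0L, length(tl), length(al), dimnames = list(tl, al))
  tab <- table(as.character(truth), assigned)
  conf[rownames(tab), colnames(tab)] <- tab
  perms <- permutations(seq_len(ncol(conf)))
  if (nrow(conf) > ncol(conf)) abort("more truth classes than clusters")
  best <- 0L
  best_p <- perms[[1]]
  for (p in perms) {
    s <- sum(conf[cbind(seq_len(nrow(conf)), p[seq_len(nrow(conf))])])
    if (s > best) {
      best <- s
      best_p <- p
    }
  }
  list(agreement = best / length(assigned),
       mapping = setNames(al[best_p[seq_len(nrow(conf))]], tl))
}

permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
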