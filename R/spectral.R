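#' Eigendecomposition of the normalized community graph
#'
#' Full symmetric eigendecomposition with eigenvalues sorted descending and a
#' deterministic sign convention: each eigenvector is flipped so that its
#' largest-magnitude entry is positive. A dense solver is used on purpose —
#' the knee-point rule needs the whole eigenvalue curve, and the sampler
#' bounds the matrix to a few thousand rows.
#'
#' @param graph a [NormalizedGraph-class] object (or a plain symmetric
#'   matrix).
#' @param symmetryTol tolerance on `max|M - t(M)|` before refusing the input.
#' @return list with `values` (descending) and `vectors` (orthonormal
#'   columns).
#' @export
eigenDecompose <- function(graph, symmetryTol = 1e-8) {
  M <- if (is(graph, "NormalizedGraph")) graph@matrix else graph
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (max(abs(M - t(M))) > symmetryTol * max(1, max(abs(M))))
    stop("matrix is not symmetric within tolerance")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(values = e$values, vectors = V)
}

#' Knee-point estimate of the number of spectral clusters
#'
#' For a well-scaled kernel the leading eigenvalues sit on a plateau near 1
#' (one per well-connected cluster) and then decay almost linearly. The knee
#' point is the intersection of an ordinary-least-squares line through the
#' post-plateau eigenvalues with the horizontal line y = 1; its x coordinate,
#' rounded to the nearest rank, estimates k.
#'
#' The plateau is `{lambda >= 1 - plateauTol}` and always counts toward the
#' lower bound on k (eigenvalue-1 multiplicity equals the number of connected
#' components). The regression window runs from the first post-plateau rank
#' to `windowMax`, bounding the influence of the curved tail. When the window
#' is empty or the fitted slope is nonnegative (no decay), the estimate falls
#' back to the plateau length, never below 2.
#'
#' @param eigenvalues numeric vector sorted descending (>= 3 values).
#' @param plateauTol eigenvalues within this of 1 count as "close to one".
#' @param windowMax last rank included in the regression window.
#' @return list with `k` (integer), `plateau` (plateau length), `slope`,
#'   `intercept` (fitted line; `NA` when the fallback fired), `window`
#'   (ranks used) and `kRaw` (unclipped intersection).
#' @export
estimateNumClusters <- function(eigenvalues, plateauTol = 1e-3,
                                windowMax = 50L) {
  stopifnot(length(eigenvalues) >= 3L)
  if (is.unsorted(rev(eigenvalues)))
    stop("'eigenvalues' must be sorted in decreasing order")
  p <- sum(eigenvalues >= 1 - plateauTol)
  lastRank <- min(length(eigenvalues), windowMax)
  window <- if (p + 1L <= lastRank) (p + 1L):lastRank else integer()
  fallback <- list(k = max(2L, p), plateau = p, slope = NA_real_,
                   intercept = NA_real_, window = window, kRaw = NA_real_)
  if (length(window) < 2L)
    return(fallback)
  fit <- stats::lm.fit(cbind(1, window), eigenvalues[window])
  a <- fit$coefficients[[1]]
  b <- fit$coefficients[[2]]
  if (!is.finite(b) || b >= -1e-12)   # no meaningful decay
    return(fallback)
  xStar <- (1 - a) / b
  k <- min(max(as.integer(round(min(xStar, lastRank))), max(2L, p)), lastRank)
  list(k = k, plateau = p, slope = b, intercept = a, window = window,
       kRaw = xStar)
}

#' Row-normalized spectral embedding
#'
#' Takes the top-k eigenvector columns and scales each row to unit Euclidean
#' norm (all-zero rows are left at zero). Communities of the same connected
#' component then collapse onto (nearly) the same direction, which is what
#' makes plain k-means effective on the embedding.
#'
#' @param eigenvectors matrix of eigenvector columns, leading columns first.
#' @param k number of columns to keep.
#' @return numeric matrix with `k` columns and rows of norm 0 or 1.
#' @export
spectralEmbed <- function(eigenvectors, k) {
  stopifnot(k >= 1L, k <= ncol(eigenvectors))
  Y <- eigenvectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(Y^2))
  nz <- nrm > 0
  Y[nz, ] <- Y[nz, , drop = FALSE] / nrm[nz]
  Y
}

# k-means++ style seeding: first center uniform, then each next center drawn
# with probability proportional to the squared distance to the nearest
# chosen center. Never picks a duplicate of an existing center.
kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
  for (j in seq_len(k - 1L)) {
    tot <- sum(d2)
    if (tot <= 0) return(centers[seq_len(j), , drop = FALSE])
    idx <- sample.int(n, 1L, prob = d2 / tot)
    centers[j + 1L, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - rep(x[idx, ], each = n))^2))
  }
  centers
}

#' k-means clustering of the spectral embedding
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ style seeds, best
#' of `restarts` runs by total within-cluster sum of squares. If `k` exceeds
#' the number of distinct embedding rows, `k` is reduced to that number with
#' a warning.
#'
#' @param embedding numeric matrix, one row per community.
#' @param k requested number of clusters (>= 1).
#' @param seed optional RNG seed; `NULL` uses the ambient stream.
#' @param restarts independent seeded runs to take the best of.
#' @param iterMax Lloyd iteration cap per run.
#' @return integer cluster label in 1..k per row.
#' @export
kmeansCluster <- function(embedding, k, seed = NULL, restarts = 10L,
                          iterMax = 300L) {
  stopifnot(is.matrix(embedding), k >= 1L)
  if (!is.null(seed)) set.seed(seed)
  nDistinct <- nrow(unique(embedding))
  if (k > nDistinct) {
    warning(sprintf("k = %d exceeds the %d distinct embedding rows; reduced",
                    k, nDistinct))
    k <- nDistinct
  }
  if (k == 1L) return(rep(1L, nrow(embedding)))
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeansppCenters(embedding, k)
    km <- suppressWarnings(
      stats::kmeans(embedding, centers = centers,
                    iter.max = iterMax, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  labels <- as.integer(best$cluster)
  # Lloyd can leave a cluster empty; keep label ids contiguous
  match(labels, sort(unique(labels)))
}

#' Spectral clustering of a normalized community graph
#'
#' Composes [eigenDecompose()], the knee-point estimate (unless `kOverride`
#' is given), [spectralEmbed()] and [kmeansCluster()]. Graphs with fewer than
#' three communities skip the knee estimate and use `k = m'`.
#'
#' @param graph a [NormalizedGraph-class] object.
#' @param kOverride optional fixed number of clusters.
#' @param seed optional RNG seed for k-means.
#' @param restarts,iterMax k-means settings, see [kmeansCluster()].
#' @param plateauTol,windowMax knee-point settings, see
#'   [estimateNumClusters()].
#' @return a [SpectralClustering-class] object.
#' @export
spectralCluster <- function(graph, kOverride = NULL, seed = NULL,
                            restarts = 10L, iterMax = 300L,
                            plateauTol = 1e-3, windowMax = 50L) {
  stopifnot(is(graph, "NormalizedGraph"))
  if (!is.null(seed)) set.seed(seed)
  e <- eigenDecompose(graph)
  m <- length(e$values)
  if (!is.null(kOverride)) {
    k <- min(as.integer(kOverride), m)
    knee <- list(k = k, plateau = NA_integer_, slope = NA_real_,
                 intercept = NA_real_, window = integer(), kRaw = NA_real_)
  } else if (m < 3L) {
    k <- m
    knee <- list(k = k, plateau = m, slope = NA_real_,
                 intercept = NA_real_, window = integer(), kRaw = NA_real_)
  } else {
    knee <- estimateNumClusters(e$values, plateauTol = plateauTol,
                                windowMax = windowMax)
    k <- knee$k
  }
  emb <- spectralEmbed(e$vectors, k)
  labels <- kmeansCluster(emb, k, seed = NULL, restarts = restarts,
                          iterMax = iterMax)
  new("SpectralClustering",
      eigenvalues = e$values,
      eigenvectors = e$vectors,
      k = max(labels),          # may be below k via the distinct-row guard
      labels = labels,
      kneeFit = knee)
}
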