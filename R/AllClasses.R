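#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Run configuration for the clustering pipeline
#'
#' Holds the tunable parameters of a full clustering run. `m` caps the number
#' of communities built by faithful sampling (the adaptive radius loop targets
#' `m/2 <= m' <= m`); `sigma` is the heat-kernel scale in the same units as
#' the event channels; `separationFactor` is the threshold on the
#' between/within maximum-edge-weight ratio used when merging spectral
#' clusters; `kOverride`, when not `NULL`, bypasses the knee-point estimate of
#' the number of spectral clusters. All randomness (sampling pick orders,
#' k-means restarts) flows from `seed`.
#'
#' @slot m integer, maximum number of communities (>= 2).
#' @slot sigma numeric, heat-kernel scaling parameter (> 0). No default: it
#'   must be tuned per dataset.
#' @slot separationFactor numeric, merge threshold (> 0).
#' @slot kOverride integer or `NULL`, fixed number of spectral clusters.
#' @slot seed integer, master seed for the run.
#' @slot maxSamplingIterations integer, cap on radius-adjustment iterations.
#' @slot kmeansRestarts integer, number of k-means restarts.
#'
#' @seealso [runConfig()] for the validating constructor.
#' @export
setClass("RunConfig", representation(
  m = "integer",
  sigma = "numeric",
  separationFactor = "numeric",
  kOverride = "integerOrNULL",
  seed = "integer",
  maxSamplingIterations = "integer",
  kmeansRestarts = "integer"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (length(object@m) != 1L || is.na(object@m) || object@m < 2L)
    msg <- c(msg, "'m' must be a single integer >= 2")
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma <= 0)
    msg <- c(msg, "'sigma' must be a single positive number")
  if (length(object@separationFactor) != 1L ||
      !is.finite(object@separationFactor) || object@separationFactor <= 0)
    msg <- c(msg, "'separationFactor' must be a single positive number")
  if (!is.null(object@kOverride) &&
      (length(object@kOverride) != 1L || object@kOverride < 1L))
    msg <- c(msg, "'kOverride' must be NULL or a positive integer")
  if (object@maxSamplingIterations < 1L)
    msg <- c(msg, "'maxSamplingIterations' must be >= 1")
  if (object@kmeansRestarts < 1L)
    msg <- c(msg, "'kmeansRestarts' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Result of faithful sampling
#'
#' Partition of all events into communities: each community is one
#' representative event plus every event registered to it (all within L1
#' distance `h` of the representative at registration time). Community sizes
#' carry the local-density information that plain subsampling would discard.
#'
#' @slot communities list of integer vectors, event indices per community
#'   (each includes its representative).
#' @slot representatives integer vector, representative event index per
#'   community.
#' @slot membership integer vector of length n, community index per event.
#' @slot h numeric, final neighbourhood radius (L1 metric).
#' @slot hTrace numeric vector, radius used at each adjustment iteration.
#' @slot iterations integer, number of sampling passes performed.
#' @slot converged logical, whether `m/2 <= m' <= m` was reached.
#' @slot singletonFallback logical, `TRUE` when n < m/2 forced one community
#'   per event.
#' @export
setClass("FaithfulSampling", representation(
  communities = "list",
  representatives = "integer",
  membership = "integer",
  h = "numeric",
  hTrace = "numeric",
  iterations = "integer",
  converged = "logical",
  singletonFallback = "logical"
))

setValidity("FaithfulSampling", function(object) {
  msg <- character()
  n <- length(object@membership)
  sizes <- lengths(object@communities)
  if (sum(sizes) != n)
    msg <- c(msg, "community sizes must sum to the number of events")
  if (length(object@representatives) != length(object@communities))
    msg <- c(msg, "one representative per community required")
  if (any(sizes < 1L))
    msg <- c(msg, "communities must be nonempty")
  if (n > 0L && (anyNA(object@membership) ||
                 min(object@membership) < 1L ||
                 max(object@membership) > length(object@communities)))
    msg <- c(msg, "membership must map every event to a community")
  if (length(msg)) msg else TRUE
})

#' Weighted community graph
#'
#' Complete graph over communities; the weight between two communities is the
#' sum of heat-kernel similarities over all member pairs (no normalization by
#' community size: the sizes encode local density, which is the biological
#' signal being preserved). Diagonal entries apply the same sum to a community
#' against itself, including the i = j terms.
#'
#' @slot similarity symmetric numeric matrix of community similarities.
#' @slot sigma heat-kernel scale used to build the matrix.
#' @slot sizes integer vector of community sizes.
#' @export
setClass("CommunityGraph", representation(
  similarity = "matrix",
  sigma = "numeric",
  sizes = "integer"
))

setValidity("CommunityGraph", function(object) {
  S <- object@similarity
  msg <- character()
  if (nrow(S) != ncol(S)) msg <- c(msg, "similarity matrix must be square")
  if (length(object@sizes) != nrow(S))
    msg <- c(msg, "'sizes' must have one entry per community")
  if (any(!is.finite(S)) || any(S < 0))
    msg <- c(msg, "similarities must be finite and nonnegative")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    msg <- c(msg, "similarity matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Symmetrically normalized community graph
#'
#' The matrix `D^(-1/2) A D^(-1/2)` where `A` is the community similarity
#' matrix and `D` its diagonal degree matrix (row sums, diagonal included).
#' All eigenvalues lie in `[-1, 1]` and the largest equals 1 for a connected
#' graph.
#'
#' @slot matrix the normalized symmetric matrix.
#' @slot degree numeric vector of community degrees (row sums of `A`).
#' @export
setClass("NormalizedGraph", representation(
  matrix = "matrix",
  degree = "numeric"
))

setValidity("NormalizedGraph", function(object) {
  msg <- character()
  M <- object@matrix
  if (nrow(M) != ncol(M)) msg <- c(msg, "matrix must be square")
  if (length(object@degree) != nrow(M))
    msg <- c(msg, "'degree' must have one entry per community")
  if (any(object@degree <= 0))
    msg <- c(msg, "all degrees must be positive")
  if (length(msg)) msg else TRUE
})

#' Spectral clustering of the community graph
#'
#' Full eigendecomposition of the normalized community graph, the estimated
#' (or overridden) number of clusters `k`, and the k-means labels of the
#' communities in the row-normalized embedding spanned by the top-k
#' eigenvectors.
#'
#' @slot eigenvalues numeric, sorted descending.
#' @slot eigenvectors matrix with orthonormal columns aligned to eigenvalues.
#' @slot k integer, number of spectral clusters used.
#' @slot labels integer, cluster id in 1..k per community.
#' @slot kneeFit list with the knee-point regression diagnostics (`plateau`,
#'   `slope`, `intercept`, `window`, `kRaw`).
#' @export
setClass("SpectralClustering", representation(
  eigenvalues = "numeric",
  eigenvectors = "matrix",
  k = "integer",
  labels = "integer",
  kneeFit = "list"
))

setValidity("SpectralClustering", function(object) {
  msg <- character()
  m <- length(object@eigenvalues)
  if (ncol(object@eigenvectors) != m || nrow(object@eigenvectors) != m)
    msg <- c(msg, "eigenvector matrix must be m' x m'")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be sorted in decreasing order")
  if (object@k < 1L || object@k > max(1L, m))
    msg <- c(msg, "'k' must lie in 1..m'")
  if (length(object@labels) != m)
    msg <- c(msg, "one label per community required")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' Final component labeling
#'
#' Spectral clusters merged into connected components (the estimated
#' biological populations), at community and at event resolution.
#'
#' @slot componentPerCommunity integer, component id in 1..C per community.
#' @slot componentPerEvent integer, component id per event.
#' @slot mergeLog data.frame with one row per merge: the two component member
#'   sets merged (as comma-separated spectral cluster ids) and the
#'   between/within ratio that triggered the merge.
#' @export
setClass("ComponentLabeling", representation(
  componentPerCommunity = "integer",
  componentPerEvent = "integer",
  mergeLog = "data.frame"
))

setValidity("ComponentLabeling", function(object) {
  msg <- character()
  cc <- object@componentPerCommunity
  if (length(cc)) {
    ids <- sort(unique(cc))
    if (!identical(ids, seq_along(ids)))
      msg <- c(msg, "component ids must be contiguous 1..C")
  }
  if (length(object@componentPerEvent) &&
      length(cc) &&
      max(object@componentPerEvent) > max(cc))
    msg <- c(msg, "event components must reference community components")
  if (length(msg)) msg else TRUE
})

#' Full pipeline result
#'
#' Container returned by [runPipeline()]: the per-event population labels
#' together with every intermediate stage and run diagnostics.
#'
#' @slot labels integer, final component id per event (1-based, contiguous).
#' @slot sampling the [FaithfulSampling-class] stage result.
#' @slot graph the [CommunityGraph-class] similarity matrix.
#' @slot spectral the [SpectralClustering-class] stage result.
#' @slot components the [ComponentLabeling-class] merge result.
#' @slot config the [RunConfig-class] used.
#' @slot diagnostics list: `mPrime`, `hTrace`, `eigenvalues`, `k`, `kneeFit`,
#'   `componentSizes`, `mergeLog`.
#' @export
setClass("SpecGateResult", representation(
  labels = "integer",
  sampling = "FaithfulSampling",
  graph = "CommunityGraph",
  spectral = "SpectralClustering",
  components = "ComponentLabeling",
  config = "RunConfig",
  diagnostics = "list"
))

#' Gaussian-mixture benchmark specification
#'
#' Declarative description of a synthetic dataset: a list of multivariate
#' normal clusters (mean, covariance, count) plus optional uniform background
#' noise, with a seed making generation deterministic.
#'
#' @slot clusters list; each element a list with `mean` (numeric), `cov`
#'   (symmetric PSD matrix) and `count` (nonnegative integer).
#' @slot noiseCount integer, number of uniform background events.
#' @slot noiseBox `NULL` (auto: realized mixture bounding box expanded by
#'   10 percent) or a 2 x d matrix of lower/upper bounds.
#' @slot seed integer.
#' @export
setClass("MixtureSpec", representation(
  clusters = "list",
  noiseCount = "integer",
  noiseBox = "ANY",
  seed = "integer"
))

setValidity("MixtureSpec", function(object) {
  msg <- character()
  for (cl in object@clusters) {
    if (!is.list(cl) || !all(c("mean", "cov", "count") %in% names(cl))) {
      msg <- c(msg, "each cluster needs 'mean', 'cov' and 'count'")
      break
    }
    if (cl$count < 0) msg <- c(msg, "cluster counts must be >= 0")
    cv <- cl$cov
    if (!is.matrix(cv) || nrow(cv) != ncol(cv) ||
        nrow(cv) != length(cl$mean) ||
        max(abs(cv - t(cv))) > 1e-8)
      msg <- c(msg, "covariances must be symmetric and match the mean length")
    else if (min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) <
             -1e-8 * max(1, max(abs(cv))))
      msg <- c(msg, "covariances must be positive semi-definite")
  }
  if (object@noiseCount < 0L) msg <- c(msg, "'noiseCount' must be >= 0")
  if (length(msg)) msg else TRUE
})
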