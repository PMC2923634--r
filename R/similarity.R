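#' Heat-kernel similarity
#'
#' `exp(-D^2 / (2*sigma^2))` for Euclidean distance `D`: 1 at distance zero,
#' strictly decreasing, in (0, 1]. `sigma` controls how fast similarity falls
#' off — smaller values sparsify the graph and yield more spectral clusters.
#'
#' @param distance nonnegative numeric (vectorized).
#' @param sigma positive kernel scale, in the units of the event channels.
#' @return numeric similarity in (0, 1].
#' @export
heatKernel <- function(distance, sigma) {
  stopifnot(sigma > 0, all(distance >= 0))
  exp(-distance^2 / (2 * sigma^2))
}

#' Similarity between two communities
#'
#' The sum of heat-kernel similarities over all member pairs (i in c, j in
#' c'). The sum is deliberately not normalized by community size: sizes encode
#' local density, and the summed ("parallel-conductance") similarity is how
#' that density survives the sampling reduction.
#'
#' @param membersA,membersB integer event-index vectors of the two
#'   communities.
#' @param data numeric event matrix.
#' @param sigma heat-kernel scale.
#' @return nonnegative numeric similarity.
#' @export
communitySimilarity <- function(membersA, membersB, data, sigma) {
  data <- asEventMatrix(data)
  stopifnot(length(membersA) >= 1L, length(membersB) >= 1L)
  A <- data[membersA, , drop = FALSE]
  B <- data[membersB, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sum(exp(-d2 / (2 * sigma^2)))
}

#' Build the community similarity matrix
#'
#' Complete weighted graph over the communities of a [FaithfulSampling-class]
#' result. Off-diagonal entries are [communitySimilarity()] sums; diagonal
#' entries apply the same double sum to a community against itself over all
#' ordered member pairs (each i = j pair contributing 1), so `S[c,c] >= |c|`.
#'
#' Community pairs whose entire contribution is provably below `tol`
#' (representative distance minus both community radii bounds every member
#' pair from below) are set to 0; with the default `tol = 1e-12` the result
#' is exact to well beyond the precision any downstream stage uses.
#'
#' @param sampling a [FaithfulSampling-class] object.
#' @param data the event matrix the sampling was built from.
#' @param sigma heat-kernel scale.
#' @param tol absolute truncation threshold for far-apart community pairs.
#' @return a [CommunityGraph-class] object.
#' @export
buildSimilarityMatrix <- function(sampling, data, sigma, tol = 1e-12) {
  stopifnot(is(sampling, "FaithfulSampling"), sigma > 0)
  data <- asEventMatrix(data)
  S <- .similarityMatrixCpp(data, sampling@communities,
                            sampling@representatives, sigma, tol)
  new("CommunityGraph", similarity = S, sigma = sigma,
      sizes = lengths(sampling@communities))
}

#' Symmetric normalization of the community graph
#'
#' Computes `Ahat = D^(-1/2) A D^(-1/2)` where `D` is the diagonal matrix of
#' row sums of the similarity matrix `A` (diagonal entries included in the
#' degree). The spectrum of `Ahat` lies in `[-1, 1]`; its eigenvalue-1
#' multiplicity equals the number of connected components of the graph, the
#' fact underlying the knee-point cluster-count estimate.
#'
#' @param graph a [CommunityGraph-class] object.
#' @return a [NormalizedGraph-class] object.
#' @export
normalizeAdjacency <- function(graph) {
  stopifnot(is(graph, "CommunityGraph"))
  A <- graph@similarity
  degree <- rowSums(A)
  if (any(degree <= 0))
    stop("disconnected vertex: community with zero degree")
  isd <- 1 / sqrt(degree)
  Ahat <- A * tcrossprod(isd)
  Ahat <- (Ahat + t(Ahat)) / 2   # enforce exact symmetry
  new("NormalizedGraph", matrix = Ahat, degree = degree)
}
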