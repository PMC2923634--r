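#' Initial neighbourhood radius for faithful sampling
#'
#' Returns `h0 = (1/2) * (V/m)^(1/d)` where `V` is the volume of the
#' axis-aligned bounding box of the data. If events were spread uniformly
#' over the box, tiling it with boxes of side `2*h0` would yield about `m`
#' communities, so this is the natural starting point for the adjustment
#' loop. Dimensions with zero extent are replaced by a negligible extent
#' (1e-12 of the largest range) so that flat-but-informative data still has a
#' finite volume.
#'
#' @param data numeric event matrix (rows = events, columns = channels).
#' @param m target maximum number of communities (>= 2).
#' @return positive numeric radius.
#' @export
initialRadius <- function(data, m) {
  data <- asEventMatrix(data)
  stopifnot(length(m) == 1L, m >= 2)
  ranges <- apply(data, 2L, function(x) diff(range(x)))
  if (all(ranges == 0))
    stop("degenerate data: all events are identical in every channel")
  ranges[ranges == 0] <- 1e-12 * max(ranges)
  d <- ncol(data)
  0.5 * (prod(ranges) / m)^(1 / d)
}

#' One pass of faithful sampling
#'
#' Walks `pickOrder`; every event that is still unregistered when reached
#' becomes the representative of a new community containing itself and all
#' currently unregistered events within L1 (Manhattan) distance `h`.
#' Terminates with every event registered to exactly one community, so the
#' communities partition the data. Representatives end up spread nearly
#' uniformly over the occupied space while community sizes record the local
#' density.
#'
#' @param data numeric event matrix.
#' @param h positive neighbourhood radius (L1 metric).
#' @param pickOrder integer permutation of `1:nrow(data)` giving the order in
#'   which candidate representatives are considered.
#' @return list with `communities` (list of integer event-index vectors,
#'   representative included), `representatives` (integer vector) and
#'   `membership` (integer community id per event).
#' @export
faithfulSample <- function(data, h, pickOrder) {
  data <- asEventMatrix(data)
  n <- nrow(data)
  stopifnot(h > 0)
  pickOrder <- as.integer(pickOrder)
  if (length(pickOrder) != n || !identical(sort(pickOrder), seq_len(n)))
    stop("'pickOrder' must be a permutation of 1:nrow(data)")
  res <- .faithfulSampleCpp(data, h, pickOrder)
  memb <- res$membership
  list(communities = unname(split(seq_len(n), memb)),
       representatives = res$representatives,
       membership = memb)
}

#' Adaptive faithful sampling
#'
#' Repeats [faithfulSample()] with a fresh random pick order, adjusting the
#' radius by `h <- h * (m'/m)^(1/d)` after each pass until the number of
#' communities `m'` satisfies `m/2 <= m' <= m`. Since `m'` scales like
#' `h^(-d)` for fixed data, this power-law update drives `m'` toward `m`; in
#' practice a few iterations suffice.
#'
#' When `n < m/2` the loop condition is unsatisfiable (pigeonhole), so the
#' sampler short-circuits: every event becomes its own singleton community
#' and the result is flagged via the `singletonFallback` slot. Small inputs
#' thus still cluster at full resolution.
#'
#' @param data numeric event matrix.
#' @param m maximum number of communities (>= 2).
#' @param seed optional integer; when given, seeds the RNG. Leave `NULL` to
#'   draw pick orders from the ambient RNG stream (as [runPipeline()] does
#'   after seeding once).
#' @param maxIterations cap on adjustment iterations; exceeding it raises an
#'   error of class `specGateNonConvergence` carrying the radius trace in its
#'   `hTrace` field.
#' @return a [FaithfulSampling-class] object.
#' @export
adaptiveSample <- function(data, m, seed = NULL, maxIterations = 20L) {
  data <- asEventMatrix(data)
  m <- as.integer(m)
  stopifnot(m >= 2L, maxIterations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)

  if (n < m / 2) {
    return(new("FaithfulSampling",
               communities = as.list(seq_len(n)),
               representatives = seq_len(n),
               membership = seq_len(n),
               h = 0,
               hTrace = numeric(),
               iterations = 0L,
               converged = FALSE,
               singletonFallback = TRUE))
  }

  h <- initialRadius(data, m)
  d <- ncol(data)
  hTrace <- numeric()
  for (iter in seq_len(maxIterations)) {
    hTrace <- c(hTrace, h)
    fs <- faithfulSample(data, h, sample.int(n))
    mPrime <- length(fs$communities)
    if (mPrime >= m / 2 && mPrime <= m) {
      return(new("FaithfulSampling",
                 communities = fs$communities,
                 representatives = fs$representatives,
                 membership = fs$membership,
                 h = h,
                 hTrace = hTrace,
                 iterations = iter,
                 converged = TRUE,
                 singletonFallback = FALSE))
    }
    h <- h * (mPrime / m)^(1 / d)
  }
  cond <- structure(
    class = c("specGateNonConvergence", "error", "condition"),
    list(message = sprintf(
           "radius adjustment did not reach m/2 <= m' <= m in %d iterations",
           maxIterations),
         call = sys.call(-1), hTrace = hTrace))
  stop(cond)
}

#' Uniform random sample of events
#'
#' Simple random sampling without replacement — the baseline that faithful
#' sampling improves on: it can miss low-density populations entirely when
#' neighbouring populations differ greatly in density.
#'
#' @param data numeric event matrix.
#' @param count number of events to draw (1..n).
#' @param seed optional integer RNG seed.
#' @return integer vector of `count` distinct event indices.
#' @export
uniformSample <- function(data, count, seed = NULL) {
  data <- asEventMatrix(data)
  n <- nrow(data)
  if (count < 1 || count > n)
    stop("'count' must be between 1 and nrow(data)")
  if (!is.null(seed)) set.seed(seed)
  sample.int(n, count)
}

#' Extend representative labels to all events
#'
#' Gives every event the label of its Euclidean-nearest representative; ties
#' go to the representative appearing first in `representatives`. This is the
#' label-extension step of the uniform-sampling baseline.
#'
#' @param data numeric event matrix.
#' @param representatives integer vector of representative event indices.
#' @param repLabels integer labels aligned with `representatives`.
#' @return integer label per event.
#' @export
nearestRepresentativeLabels <- function(data, representatives, repLabels) {
  data <- asEventMatrix(data)
  if (length(representatives) < 1L)
    stop("'representatives' must be nonempty")
  if (length(repLabels) != length(representatives))
    stop("'repLabels' must align with 'representatives'")
  R <- data[representatives, , drop = FALSE]
  rNorm <- rowSums(R^2)
  n <- nrow(data)
  out <- integer(n)
  # chunked so the n x r cross-distance matrix never materializes in full
  chunk <- max(1L, as.integer(2e6 / length(representatives)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    E <- data[idx, , drop = FALSE]
    d2 <- outer(rowSums(E^2), rNorm, "+") - 2 * tcrossprod(E, R)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  repLabels[out]
}

# Coerce input to a validated numeric event matrix.
asEventMatrix <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data))
    stop("event data must be a numeric matrix or data frame")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("event matrix must have at least one event and one channel")
  if (!all(is.finite(data)))
    stop("event matrix contains non-finite values")
  storage.mode(data) <- "double"
  data
}
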