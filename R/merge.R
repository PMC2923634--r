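#' Within-similarity of a component
#'
#' The maximum similarity-matrix weight over the community pairs inside a
#' component (diagonal excluded). A biologically coherent population has its
#' densest communities — hence its heaviest edges — at its centre, so this
#' maximum characterizes the population core. A singleton component has no
#' internal edge; its diagonal self-similarity is used instead, the natural
#' internal-conductance analogue, keeping the merge ratio defined.
#'
#' @param component integer vector of community indices.
#' @param S community similarity matrix.
#' @return nonnegative numeric.
#' @export
withinSimilarity <- function(component, S) {
  stopifnot(length(component) >= 1L)
  if (length(component) == 1L)
    return(S[component, component])
  block <- S[component, component, drop = FALSE]
  diag(block) <- -Inf
  max(block)
}

#' Between-similarity of two components
#'
#' The maximum similarity-matrix weight over community pairs crossing the two
#' components.
#'
#' @param componentA,componentB disjoint integer vectors of community
#'   indices.
#' @param S community similarity matrix.
#' @return nonnegative numeric.
#' @export
betweenSimilarity <- function(componentA, componentB, S) {
  stopifnot(length(componentA) >= 1L, length(componentB) >= 1L,
            !any(componentA %in% componentB))
  max(S[componentA, componentB, drop = FALSE])
}

#' Merge spectral clusters into connected components
#'
#' Starts from the spectral clusters and repeatedly merges the pair of
#' components with the globally largest separation ratio
#' `between(Ci, Cj) / within(Ci)` while any ratio exceeds
#' `separationFactor` (or a within-similarity of zero makes a ratio
#' infinite). Within/between similarities are recomputed from the merged
#' components each round; the loop stops when every ratio is at or below the
#' threshold or a single component remains. Smaller separation factors merge
#' more aggressively.
#'
#' Final component ids are contiguous, ordered by each component's smallest
#' community index. Ties on the maximal ratio break on the smaller (i, j)
#' pair so the procedure is deterministic.
#'
#' @param spectralLabels integer cluster id per community.
#' @param S community similarity matrix (unnormalized weights).
#' @param separationFactor positive merge threshold.
#' @return a [ComponentLabeling-class] object with the community-level
#'   labeling and the merge log; the event-level slot is filled by
#'   [extendLabels()].
#' @export
combineComponents <- function(spectralLabels, S, separationFactor) {
  stopifnot(separationFactor > 0, length(spectralLabels) == nrow(S))
  clusterIdx <- unname(split(seq_along(spectralLabels), spectralLabels))
  k <- length(clusterIdx)

  # Max is associative, so within/between similarities of merged components
  # reduce exactly to cluster-level maxima computed once from S:
  #   crossMax[a,b] — heaviest edge between clusters a and b
  #   selfMax[a]    — heaviest internal edge of cluster a (-Inf if it holds a
  #                   single community)
  #   diagSelf[a]   — S_cc for single-community clusters (singleton fallback)
  crossMax <- matrix(-Inf, k, k)
  selfMax <- rep(-Inf, k)
  diagSelf <- rep(NA_real_, k)
  for (a in seq_len(k)) {
    ia <- clusterIdx[[a]]
    if (length(ia) == 1L) {
      diagSelf[a] <- S[ia, ia]
    } else {
      block <- S[ia, ia, drop = FALSE]
      diag(block) <- -Inf
      selfMax[a] <- max(block)
    }
    for (b in seq_len(k)) {
      if (b <= a) next
      crossMax[a, b] <- crossMax[b, a] <- max(S[ia, clusterIdx[[b]],
                                                drop = FALSE])
    }
  }
  diag(crossMax) <- selfMax
  minIdx <- vapply(clusterIdx, min, numeric(1))

  comps <- lapply(seq_len(k), identity)   # sets of spectral cluster ids
  log <- data.frame(componentA = character(), componentB = character(),
                    ratio = numeric(), stringsAsFactors = FALSE)

  withinOf <- function(set) {
    w <- max(crossMax[set, set])
    if (is.infinite(w) && w < 0) diagSelf[set[1L]] else w
  }

  while (length(comps) > 1L) {
    nc <- length(comps)
    within <- vapply(comps, withinOf, numeric(1))
    ratio <- matrix(-Inf, nc, nc)
    for (i in seq_len(nc)) {
      for (j in seq_len(nc)) {
        if (i == j) next
        btw <- max(crossMax[comps[[i]], comps[[j]], drop = FALSE])
        ratio[i, j] <- if (within[i] > 0) btw / within[i] else Inf
      }
    }
    best <- max(ratio)
    if (best <= separationFactor) break
    hits <- which(ratio == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    log <- rbind(log, data.frame(
      componentA = paste(sort(comps[[i]]), collapse = ","),
      componentB = paste(sort(comps[[j]]), collapse = ","),
      ratio = best, stringsAsFactors = FALSE))
    comps[[i]] <- c(comps[[i]], comps[[j]])
    comps[[j]] <- NULL
  }

  ord <- order(vapply(comps, function(set) min(minIdx[set]), numeric(1)))
  comps <- comps[ord]
  labels <- integer(length(spectralLabels))
  for (c in seq_along(comps))
    labels[unlist(clusterIdx[comps[[c]]])] <- c
  new("ComponentLabeling",
      componentPerCommunity = labels,
      componentPerEvent = integer(),
      mergeLog = log)
}

#' Extend community components to events
#'
#' Every event inherits the component id of the community it was registered
#' to during sampling; community membership itself is never changed by
#' merging.
#'
#' @param componentPerCommunity integer component id per community.
#' @param membership integer community index per event.
#' @return integer component id per event.
#' @export
extendLabels <- function(componentPerCommunity, membership) {
  if (anyNA(membership) || min(membership) < 1L ||
      max(membership) > length(componentPerCommunity))
    stop("'membership' must map every event to a community")
  componentPerCommunity[membership]
}
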