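#' Accessors for pipeline objects
#'
#' Small accessor functions for the S4 stage objects; prefer these over
#' direct slot access.
#'
#' @param x a stage object ([FaithfulSampling-class],
#'   [CommunityGraph-class], [SpectralClustering-class],
#'   [ComponentLabeling-class] or [SpecGateResult-class]).
#' @return The requested slot content: counts and labels as integer vectors,
#'   matrices as base matrices.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nCommunities", "FaithfulSampling",
          function(x) length(x@communities))

#' @rdname accessors
setMethod("communitySizes", "FaithfulSampling",
          function(x) lengths(x@communities))

#' @rdname accessors
setMethod("communities", "FaithfulSampling", function(x) x@communities)

#' @rdname accessors
setMethod("representatives", "FaithfulSampling",
          function(x) x@representatives)

#' @rdname accessors
setMethod("membership", "FaithfulSampling", function(x) x@membership)

#' @rdname accessors
setMethod("samplingRadius", "FaithfulSampling", function(x) x@h)

#' @rdname accessors
setMethod("similarityMatrix", "CommunityGraph", function(x) x@similarity)

#' @rdname accessors
setMethod("communitySizes", "CommunityGraph", function(x) x@sizes)

#' @rdname accessors
setMethod("graphEigenvalues", "SpectralClustering", function(x) x@eigenvalues)

#' @rdname accessors
setMethod("numClusters", "SpectralClustering", function(x) x@k)

#' @rdname accessors
setMethod("clusterLabels", "SpectralClustering", function(x) x@labels)

#' @rdname accessors
setMethod("componentCount", "ComponentLabeling",
          function(x) max(x@componentPerCommunity))

#' @rdname accessors
setMethod("mergeLog", "ComponentLabeling", function(x) x@mergeLog)

#' @rdname accessors
setMethod("eventLabels", "SpecGateResult", function(x) x@labels)

#' @rdname accessors
setMethod("componentCount", "SpecGateResult",
          function(x) componentCount(x@components))

#' @rdname accessors
setMethod("mergeLog", "SpecGateResult", function(x) mergeLog(x@components))

#' @rdname accessors
setMethod("diagnostics", "SpecGateResult", function(x) x@diagnostics)

#' @rdname accessors
setMethod("membership", "SpecGateResult", function(x) membership(x@sampling))

setMethod("show", "FaithfulSampling", function(object) {
  cat("FaithfulSampling with", nCommunities(object), "communities over",
      length(object@membership), "events\n")
  cat("  radius h =", format(object@h, digits = 4),
      "| iterations:", object@iterations,
      "| converged:", object@converged, "\n")
  if (object@singletonFallback)
    cat("  (singleton fallback: n < m/2)\n")
})

setMethod("show", "CommunityGraph", function(object) {
  cat("CommunityGraph over", nrow(object@similarity), "communities",
      "(sigma =", format(object@sigma, digits = 4), ")\n")
})

setMethod("show", "SpectralClustering", function(object) {
  cat("SpectralClustering:", length(object@eigenvalues), "communities in",
      object@k, "clusters\n")
  ev <- object@eigenvalues
  cat("  top eigenvalues:",
      paste(format(utils::head(ev, 5), digits = 4), collapse = ", "), "\n")
})

setMethod("show", "SpecGateResult", function(object) {
  nc <- componentCount(object)
  cat("SpecGateResult:", length(object@labels), "events in", nc,
      if (nc == 1L) "component\n" else "components\n")
  cat("  communities:", nCommunities(object@sampling),
      "| spectral clusters:", object@spectral@k, "\n")
  sz <- tabulate(object@labels)
  cat("  component sizes:", paste(sz, collapse = ", "), "\n")
})
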