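#' @rdname accessors
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))

#' @rdname accessors
#' @export
setGeneric("communitySizes", function(x) standardGeneric("communitySizes"))

#' @rdname accessors
#' @export
setGeneric("communities", function(x) standardGeneric("communities"))

#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("samplingRadius", function(x) standardGeneric("samplingRadius"))

#' @rdname accessors
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname accessors
#' @export
setGeneric("graphEigenvalues", function(x) standardGeneric("graphEigenvalues"))

#' @rdname accessors
#' @export
setGeneric("numClusters", function(x) standardGeneric("numClusters"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("eventLabels", function(x) standardGeneric("eventLabels"))

#' @rdname accessors
#' @export
setGeneric("componentCount", function(x) standardGeneric("componentCount"))

#' @rdname accessors
#' @export
setGeneric("mergeLog", function(x) standardGeneric("mergeLog"))

#' @rdname accessors
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))
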