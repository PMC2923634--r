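#' Create a run configuration
#'
#' Validating constructor for [RunConfig-class]. `sigma` has no default: the
#' kernel scale must be tuned per dataset (typically on one or two random
#' samples, then reused for the rest of the samples of that dataset).
#' Decreasing `sigma` or increasing `separationFactor` yields more
#' populations.
#'
#' @param sigma heat-kernel scale (> 0), in the units of the event channels.
#' @param m maximum number of communities; the sampler targets
#'   `m/2 <= m' <= m`. The default 3000 keeps the eigendecomposition fast
#'   while leaving the communities small enough that no population-level
#'   detail is lost.
#' @param separationFactor threshold on the between/within edge-weight ratio
#'   above which spectral clusters merge; 0.39 is a robust default.
#' @param kOverride optional fixed number of spectral clusters, bypassing the
#'   knee-point estimate.
#' @param seed master seed for all randomness in the run.
#' @param maxSamplingIterations cap on radius-adjustment iterations.
#' @param kmeansRestarts number of k-means restarts.
#' @return a validated [RunConfig-class] object.
#' @export
runConfig <- function(sigma, m = 3000L, separationFactor = 0.39,
                      kOverride = NULL, seed = 1L,
                      maxSamplingIterations = 20L, kmeansRestarts = 10L) {
  if (missing(sigma))
    stop("'sigma' is required and must be tuned for the dataset at hand")
  new("RunConfig",
      m = as.integer(m),
      sigma = as.numeric(sigma),
      separationFactor = as.numeric(separationFactor),
      kOverride = if (is.null(kOverride)) NULL else as.integer(kOverride),
      seed = as.integer(seed),
      maxSamplingIterations = as.integer(maxSamplingIterations),
      kmeansRestarts = as.integer(kmeansRestarts))
}

#' Run the full clustering pipeline
#'
#' Composes the five stages: adaptive faithful sampling, community
#' similarity matrix, symmetric normalization, spectral clustering with
#' knee-point cluster-count estimation, and merge of spectral clusters into
#' connected components, which are then extended to every event. Given the
#' same `data` and `config` (including the seed) the result is bit-stable.
#'
#' @param data numeric event matrix (rows = events), e.g. from
#'   [readEvents()].
#' @param config a [RunConfig-class] from [runConfig()].
#' @return a [SpecGateResult-class]; see [eventLabels()], [componentCount()]
#'   and [diagnostics()].
#' @examples
#' spec <- coreSatelliteSpec(seed = 7)
#' dat <- generateMixture(spec)
#' res <- runPipeline(dat$events, runConfig(sigma = 0.6, seed = 7))
#' componentCount(res)
#' @export
runPipeline <- function(data, config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  data <- asEventMatrix(data)
  set.seed(config@seed)

  sampling <- adaptiveSample(data, config@m,
                             maxIterations = config@maxSamplingIterations)
  graph <- buildSimilarityMatrix(sampling, data, config@sigma)
  normalized <- normalizeAdjacency(graph)
  spectral <- spectralCluster(normalized,
                              kOverride = config@kOverride,
                              restarts = config@kmeansRestarts)
  comp <- combineComponents(spectral@labels, graph@similarity,
                            config@separationFactor)
  labels <- extendLabels(comp@componentPerCommunity, sampling@membership)
  comp@componentPerEvent <- labels

  diag <- list(
    mPrime = nCommunities(sampling),
    hTrace = sampling@hTrace,
    samplingIterations = sampling@iterations,
    eigenvalues = spectral@eigenvalues,
    k = spectral@k,
    kneeFit = spectral@kneeFit,
    componentSizes = tabulate(labels),
    mergeLog = comp@mergeLog)

  new("SpecGateResult",
      labels = labels,
      sampling = sampling,
      graph = graph,
      spectral = spectral,
      components = comp,
      config = config,
      diagnostics = diag)
}

#' Write run diagnostics as JSON
#'
#' Serializes the diagnostics of a result — community count, radius trace,
#' eigenvalue curve, knee-fit line, component sizes and merge log — so a
#' clustering run can be audited without rerunning it.
#'
#' @param result a [SpecGateResult-class].
#' @param path output JSON file.
#' @export
writeDiagnostics <- function(result, path) {
  stopifnot(is(result, "SpecGateResult"))
  d <- result@diagnostics
  d$kneeFit$window <- NULL
  jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(NULL)
}
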