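# Structured run configuration (YAML). Unknown keys are rejected so typos
# fail loudly; every parsed config carries a provenance hash.

configSchema <- list(
  priors = c("n_cab_present", "n_cab_split", "n_moz_present", "n_moz_split",
             "gen_split"),
  constants = c("n_ancestral_fixed", "gen_ancestral_change", "mutation_rate",
                "generation_time_years"),
  genome = c("sequence_length", "samples_per_pop", "mutation_rate",
             "recombination_rate", "recombination_map"),
  error = c("error_rate"),
  abc = c("tolerance", "method", "hidden_units", "restarts")
)

#' Read a structured run configuration
#'
#' Parses a YAML document with optional sections \code{priors} (per
#' parameter: dist/lower/upper), \code{constants}, \code{genome},
#' \code{error} and \code{abc}; unknown sections or keys are rejected.
#' Missing entries fall back to package defaults. The parsed object
#' carries the raw document's hash for provenance logging.
#'
#' @param path path to a YAML config file.
#' @return List with \code{prior} (PriorSpec), \code{constants}
#'   (ModelConstants), \code{genome} (GenomeConfig), \code{errorRate},
#'   \code{abc} (ABCConfig) and \code{hash}.
#' @export
readRunConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  unknown <- setdiff(names(doc), names(configSchema))
  if (length(unknown))
    stop("config error: unknown section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(configSchema)) {
    bad <- setdiff(names(doc[[sec]]), configSchema[[sec]])
    if (length(bad))
      stop("config error: unknown key(s) in ", sec, ": ",
           paste(bad, collapse = ", "))
  }
  keyMap <- c(n_ancestral_fixed = "nAncestralFixed",
              gen_ancestral_change = "genAncestralChange",
              mutation_rate = "mutationRate",
              generation_time_years = "generationTimeYears")
  cargs <- list()
  for (k in names(keyMap))
    if (!is.null(doc$constants[[k]])) cargs[[keyMap[[k]]]] <- doc$constants[[k]]
  constants <- do.call(modelConstants, cargs)
  prior <- defaultPriors()
  if (!is.null(doc$priors)) {
    tb <- prior@table
    for (pn in names(doc$priors)) {
      e <- doc$priors[[pn]]
      i <- which(tb$parameter == pn)
      if (!is.null(e$dist)) tb$dist[i] <- e$dist
      if (!is.null(e$lower)) tb$lower[i] <- e$lower
      if (!is.null(e$upper)) tb$upper[i] <- e$upper
    }
    prior <- priorSpec(tb, constants)
  }
  gm <- doc$genome
  L <- if (!is.null(gm$sequence_length)) gm$sequence_length else 1e7
  rmap <- if (!is.null(gm$recombination_map)) {
    readRecombMap(gm$recombination_map)
  } else if (!is.null(gm$recombination_rate)) {
    uniformRecombMap(gm$recombination_rate, L)
  } else deskRecombMap(L)
  genome <- genomeConfig(
    sequenceLength = L,
    recombMap = rmap,
    mutationRate = if (!is.null(gm$mutation_rate)) gm$mutation_rate
                   else constants@mutationRate,
    samplesPerPop = if (!is.null(gm$samples_per_pop)) gm$samples_per_pop else 40L
  )
  ab <- doc$abc
  abc <- abcConfig(
    tolerance = if (!is.null(ab$tolerance)) ab$tolerance else 0.10,
    method = if (!is.null(ab$method)) ab$method else "neuralnet",
    hiddenUnits = if (!is.null(ab$hidden_units)) ab$hidden_units else 4L,
    restarts = if (!is.null(ab$restarts)) ab$restarts else 10L
  )
  list(
    prior = prior,
    constants = constants,
    genome = genome,
    errorRate = if (!is.null(doc$error$error_rate)) doc$error$error_rate else 0.001,
    abc = abc,
    hash = configHash(doc)
  )
}
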