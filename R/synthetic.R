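# Synthetic pseudo-observed datasets and the simulated reference table.
# Every dataset is regenerable bit-for-bit from its truth sidecar; per-row
# seeds are derived from (master seed, row index) so chunked and monolithic
# reference generation agree.

#' Generate a pseudo-observed VCF with its truth sidecar
#'
#' Composition simulate -> diploid genotypes -> genotype error -> VCF.
#' Sample columns are named \code{CAB_1..n} and \code{MOZ_1..n}; genotypes
#' at error-perturbed entries are written unphased. The sidecar (YAML)
#' records everything needed to regenerate the dataset bit-for-bit.
#'
#' @param params the true \code{SplitModelParams}.
#' @param genome a \code{GenomeConfig}.
#' @param errorRate per-genotype error probability.
#' @param seed integer seed (drives both simulation and error injection).
#' @param vcfPath output VCF path.
#' @param truthPath output sidecar path (default: vcfPath + ".truth.yaml").
#' @param constants a \code{ModelConstants}.
#' @return Invisibly, a list with the panel, genotypes and file paths.
#' @export
generatePseudoObserved <- function(params, genome = genomeConfig(),
                                   errorRate = 0.001, seed = 1L,
                                   vcfPath, truthPath = paste0(vcfPath, ".truth.yaml"),
                                   constants = modelConstants()) {
  panel <- simulatePanel(params, constants, genome, seed = seed)
  g <- panelToGenotypes(panel)
  gErr <- applyGenotypeError(g, errorRate, seed = deriveSeed(seed, 1L))
  nPer <- genome@samplesPerPop
  samples <- c(paste0("CAB_", seq_len(nPer)), paste0("MOZ_", seq_len(nPer)))
  writeVCF(gErr, panel@posBp, samples, vcfPath,
           haplotypes = panel@haplotypes, unphase = attr(gErr, "flipped"))
  truth <- list(
    params = as.list(paramsToVector(params)),
    constants = list(n_ancestral_fixed = constants@nAncestralFixed,
                     gen_ancestral_change = constants@genAncestralChange,
                     mutation_rate = constants@mutationRate,
                     generation_time_years = constants@generationTimeYears),
    genome = list(sequence_length = genome@sequenceLength,
                  samples_per_pop = genome@samplesPerPop,
                  mutation_rate = genome@mutationRate,
                  map_pos = genome@recombMap@pos,
                  map_rate_cm_mb = genome@recombMap@rateCMMb,
                  map_cm = genome@recombMap@cm),
    error_rate = errorRate,
    seed = as.integer(seed)
  )
  yaml::write_yaml(truth, truthPath)
  invisible(list(panel = panel, genotypes = gErr, vcf = vcfPath,
                 truth = truthPath))
}

#' Regenerate a pseudo-observed dataset from its truth sidecar
#'
#' @param truthPath path to a sidecar written by
#'   \code{\link{generatePseudoObserved}}.
#' @param vcfPath output VCF path.
#' @return As \code{\link{generatePseudoObserved}}, invisibly.
#' @export
regenerateFromTruth <- function(truthPath, vcfPath) {
  tr <- yaml::read_yaml(truthPath)
  params <- paramsFromVector(unlist(tr$params))
  constants <- modelConstants(tr$constants$n_ancestral_fixed,
                              tr$constants$gen_ancestral_change,
                              tr$constants$mutation_rate,
                              tr$constants$generation_time_years)
  rmap <- new("RecombMap", pos = as.numeric(tr$genome$map_pos),
              rateCMMb = as.numeric(tr$genome$map_rate_cm_mb),
              cm = as.numeric(tr$genome$map_cm))
  genome <- genomeConfig(tr$genome$sequence_length, rmap,
                         tr$genome$mutation_rate, tr$genome$samples_per_pop)
  generatePseudoObserved(params, genome, tr$error_rate, tr$seed, vcfPath,
                         truthPath = tempfile(), constants = constants)
}

#' Generate the ABC reference table
#'
#' Draws \code{nSim} parameter sets from the prior (one independent draw
#' per row from a row-derived seed), simulates each, injects genotype
#' error, computes the 46-statistic summary vector, and assembles the
#' parameters x statistics reference table. Simulation requests are
#' batched in chunks through one engine process per chunk; chunked and
#' monolithic runs produce identical tables.
#'
#' @param prior a \code{PriorSpec}.
#' @param nSim number of simulations (>= 1).
#' @param genome a \code{GenomeConfig}.
#' @param errorRate per-genotype error probability (default 0.001).
#' @param seed master integer seed.
#' @param chunkSize simulations per engine batch (default 250).
#' @param constants a \code{ModelConstants}.
#' @param statConfig optional overrides for
#'   \code{\link{computeSummaryVector}}.
#' @param progress print per-chunk progress.
#' @return A \code{ReferenceTable}.
#' @export
generateReference <- function(prior, nSim, genome = genomeConfig(),
                              errorRate = 0.001, seed = 1L, chunkSize = 250L,
                              constants = modelConstants(),
                              statConfig = list(), progress = FALSE) {
  if (nSim < 1) stop("nSim must be >= 1")
  validObject(prior); validObject(genome); validObject(constants)
  gsUpper <- priorBounds(prior)$upper[["gen_split"]]
  if (gsUpper >= constants@genAncestralChange)
    stop("config error: gen_split prior exceeds the ancestral change generation")
  pn <- paramNames()
  paramMat <- matrix(NA_real_, nSim, length(pn), dimnames = list(NULL, pn))
  statMat <- NULL
  for (start in seq(1L, nSim, by = chunkSize)) {
    rows <- start:min(start + chunkSize - 1L, nSim)
    jobs <- vector("list", length(rows))
    for (k in seq_along(rows)) {
      i <- rows[k]
      rowSeed <- deriveSeed(seed, i)
      draw <- samplePrior(prior, 1L, seed = rowSeed)
      paramMat[i, ] <- as.numeric(draw[1, pn])
      jobs[[k]] <- splitJob(as.character(i), paramsFromVector(draw),
                            constants, genome, seed = deriveSeed(rowSeed, 1L))
    }
    panels <- runSimulationBatch(jobs)
    for (k in seq_along(rows)) {
      i <- rows[k]
      panel <- rawToPanel(panels[[as.character(i)]], genome)
      g <- panelToGenotypes(panel)
      gErr <- applyGenotypeError(g, errorRate,
                                 seed = deriveSeed(deriveSeed(seed, i), 2L))
      sv <- suppressWarnings(computeSummaryVector(
        list(genotypes = gErr, posBp = panel@posBp,
             labels = individualLabels(panel)),
        map = genome@recombMap, config = statConfig))
      if (is.null(statMat))
        statMat <- matrix(NA_real_, nSim, length(sv),
                          dimnames = list(NULL, names(sv)))
      statMat[i, ] <- sv
    }
    if (progress)
      message(sprintf("reference: %d/%d simulations done", max(rows), nSim))
  }
  new("ReferenceTable", params = paramMat, stats = statMat,
      provenance = list(seed = as.integer(seed), nSim = nSim,
                        errorRate = errorRate, prior = prior,
                        registry = registryVersion,
                        hash = configHash(list(prior@table, errorRate,
                                               genome@sequenceLength,
                                               genome@samplesPerPop))))
}

#' Write a reference table as tab-separated text
#'
#' One row per simulation; the five parameter columns precede the
#' statistic columns.
#'
#' @param reference a \code{ReferenceTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReferenceTable <- function(reference, path) {
  df <- data.frame(refParams(reference), refStats(reference),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a reference table written by \code{writeReferenceTable}
#'
#' @param path path to the tab-separated table.
#' @return A \code{ReferenceTable} (provenance carries only the source
#'   path).
#' @export
readReferenceTable <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  pn <- paramNames()
  if (!all(pn %in% names(df)))
    stop("format error: reference table lacks the five parameter columns")
  new("ReferenceTable",
      params = as.matrix(df[, pn, drop = FALSE]),
      stats = as.matrix(df[, setdiff(names(df), pn), drop = FALSE]),
      provenance = list(source = path))
}
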