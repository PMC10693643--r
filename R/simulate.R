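# Bridge to the msprime coalescent engine. Simulation requests are written
# as a JSON job list, executed in one external python process (so the
# per-process start-up cost is amortised over a whole batch), and read back
# from a compact binary panel format.

pythonBinary <- function() {
  p <- getOption("splitABC.python", Sys.getenv("SPLITABC_PYTHON", "python"))
  if (!nzchar(Sys.which(p)))
    stop("simulation engine failure: python interpreter '", p, "' not found; ",
         "set options(splitABC.python=) or SPLITABC_PYTHON")
  p
}

workerScript <- function() {
  path <- system.file("python", "simulate_panels.py", package = "splitABC")
  if (!nzchar(path)) stop("simulation worker script not found in package installation")
  path
}

# Build one job entry for the clean-split model.
splitJob <- function(id, params, constants, genome, seed) {
  aCab <- growthRate(params@nCabPresent, params@nCabSplit, params@genSplit)
  aMoz <- growthRate(params@nMozPresent, params@nMozSplit, params@genSplit)
  iv <- mapToIntervals(genome@recombMap, genome@sequenceLength)
  list(
    id = as.character(id),
    seed = as.integer(seed),
    sequence_length = genome@sequenceLength,
    mutation_rate = genome@mutationRate,
    recombination = list(type = "map", positions = iv$positions, rates = iv$rates),
    demography = list(
      type = "split",
      n_cab = params@nCabPresent, alpha_cab = aCab,
      n_moz = params@nMozPresent, alpha_moz = aMoz,
      gen_split = params@genSplit,
      n_anc_merge = params@nCabSplit + params@nMozSplit,
      n_anc_fixed = constants@nAncestralFixed,
      gen_anc = constants@genAncestralChange,
      samples = c(genome@samplesPerPop, genome@samplesPerPop)
    )
  )
}

# Single-population constant-size control job (used for simulator checks).
constantJob <- function(id, n, nDiploid, sequenceLength, mutationRate,
                        recombRate, seed) {
  list(
    id = as.character(id),
    seed = as.integer(seed),
    sequence_length = sequenceLength,
    mutation_rate = mutationRate,
    recombination = list(type = "uniform", rate = recombRate),
    demography = list(type = "constant", n = n, samples = c(nDiploid))
  )
}

readPanelBin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "double", n = 2)
  nSites <- as.integer(hdr[1]); nHaps <- as.integer(hdr[2])
  pos <- readBin(con, "double", n = nSites)
  raw <- readBin(con, "integer", n = nSites * nHaps, size = 1L, signed = FALSE)
  h <- matrix(0L, nrow = nSites, ncol = nHaps)
  if (nSites > 0L) h <- t(matrix(as.integer(raw), nrow = nHaps, ncol = nSites))
  list(positions = pos, haplotypes = h)
}

# Run a batch of jobs through the worker; returns a named list of raw panels
# in job order. Fails loudly (with the worker's stderr) on engine errors.
runSimulationBatch <- function(jobs) {
  outDir <- tempfile("splitABC_sim_")
  dir.create(outDir)
  on.exit(unlink(outDir, recursive = TRUE))
  jobsPath <- file.path(outDir, "jobs.json")
  jsonlite::write_json(list(jobs = jobs), jobsPath,
                       auto_unbox = TRUE, digits = NA)
  log <- system2(pythonBinary(), c(workerScript(), jobsPath, outDir),
                 stdout = TRUE, stderr = TRUE)
  manifestPath <- file.path(outDir, "manifest.json")
  if (!file.exists(manifestPath))
    stop("simulation engine failure:\n", paste(log, collapse = "\n"))
  manifest <- jsonlite::read_json(manifestPath)
  out <- lapply(manifest, function(m) readPanelBin(file.path(outDir, m$file)))
  names(out) <- vapply(manifest, function(m) m$id, character(1))
  out[vapply(jobs, function(j) j$id, character(1))]
}

#' Simulate a phased haplotype panel under the clean-split model
#'
#' Runs the coalescent with recombination (msprime, through a bundled worker
#' script) under the backwards-in-time timeline of
#' \code{\link{buildTimeline}}, with biallelic segregating SNPs only.
#' Haplotypes are phased; the first \code{samplesPerPop} diploids carry the
#' CAB-like label, the remainder the MOZ-like label. Identical seeds produce
#' identical panels.
#'
#' @param params a \code{SplitModelParams}.
#' @param constants a \code{ModelConstants}.
#' @param genome a \code{GenomeConfig}.
#' @param seed integer seed.
#' @return A \code{HaplotypePanel}.
#' @export
simulatePanel <- function(params, constants = modelConstants(),
                          genome = genomeConfig(), seed = 1L) {
  validObject(params); validObject(constants); validObject(genome)
  if (params@genSplit >= constants@genAncestralChange)
    stop("invalid parameter: gen_split must be < genAncestralChange")
  job <- splitJob("1", params, constants, genome, seed)
  raw <- runSimulationBatch(list(job))[[1]]
  rawToPanel(raw, genome)
}

rawToPanel <- function(raw, genome) {
  nPer <- genome@samplesPerPop
  labels <- c(rep("CAB", 2L * nPer), rep("MOZ", 2L * nPer))
  nh <- ncol(raw$haplotypes)
  if (nh > 0L && nh != length(labels)) labels <- rep("POP", nh)
  if (nh == 0L) labels <- character(0)
  new("HaplotypePanel",
      haplotypes = raw$haplotypes,
      posBp = raw$positions,
      posCm = mapCM(genome@recombMap, raw$positions),
      popLabels = labels)
}

#' Simulate single-population constant-size control panels
#'
#' A batch of independent constant-size, single-population coalescent
#' replicates under a uniform recombination rate. Used for simulator
#' sanity checks against closed-form neutral expectations (Watterson's
#' segregating-site count, pairwise diversity).
#'
#' @param nReps number of replicates.
#' @param n diploid effective size.
#' @param nDiploid diploid sample size.
#' @param sequenceLength sequence length in bp.
#' @param mutationRate per-bp per-generation mutation rate.
#' @param recombRate per-bp per-generation recombination rate.
#' @param seed integer seed (per-replicate seeds derived from it).
#' @return List of \code{HaplotypePanel} objects (labels all "POP").
#' @export
simulateConstantPanels <- function(nReps, n, nDiploid, sequenceLength = 1e6,
                                   mutationRate = 1.25e-8, recombRate = 1e-8,
                                   seed = 1L) {
  jobs <- lapply(seq_len(nReps), function(i)
    constantJob(as.character(i), n, nDiploid, sequenceLength, mutationRate,
                recombRate, seed = deriveSeed(seed, i)))
  raws <- runSimulationBatch(jobs)
  genome <- genomeConfig(sequenceLength,
                         uniformRecombMap(recombRate, sequenceLength),
                         mutationRate, as.integer(nDiploid))
  lapply(raws, rawToPanel, genome = genome)
}

#' Collapse phased haplotypes into diploid genotypes
#'
#' Individual i owns haplotypes 2i-1 and 2i (1-based); genotypes are
#' derived-allele dosages in \{0, 1, 2\}.
#'
#' @param panel a \code{HaplotypePanel} (or a 0/1 sites-x-haplotypes matrix).
#' @return Integer matrix, sites x individuals.
#' @export
panelToGenotypes <- function(panel) {
  h <- if (is(panel, "HaplotypePanel")) panel@haplotypes else panel
  if (ncol(h) %% 2L != 0L)
    stop("invalid input: haplotype count must be even to form diploids")
  nInd <- ncol(h) %/% 2L
  if (nInd == 0L) return(matrix(integer(0), nrow = nrow(h), ncol = 0L))
  g <- h[, seq(1L, 2L * nInd, by = 2L), drop = FALSE] +
    h[, seq(2L, 2L * nInd, by = 2L), drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

#' Population labels per diploid individual
#' @param panel a \code{HaplotypePanel}.
#' @return Character vector, one label per individual.
#' @export
individualLabels <- function(panel) {
  stopifnot(is(panel, "HaplotypePanel"))
  panel@popLabels[seq(1L, length(panel@popLabels), by = 2L)]
}
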