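# Desk-scale reference table shared by the calibration checks in
# test-acceptance.R. Built once per test run (a few minutes of coalescent
# simulation) and cached in the session; the sizes are the package's
# desk-scale run conditions (see the methods vignette).

.refCache <- new.env(parent = emptyenv())

acceptanceReference <- function() {
  if (!is.null(.refCache$ref)) return(.refCache$ref)
  genome <- genomeConfig(sequenceLength = 5e6,
                         recombMap = deskRecombMap(5e6),
                         samplesPerPop = 20L)
  .refCache$ref <- generateReference(defaultPriors(), nSim = 800,
                                     genome = genome, errorRate = 0.001,
                                     seed = 20260929L, chunkSize = 200L)
  .refCache$ref
}
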