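#' Inject genotype errors into a diploid genotype matrix
#'
#' Each non-missing genotype is independently perturbed with probability
#' \code{errorRate}: a homozygote becomes a heterozygote (0 -> 1, 2 -> 1)
#' and a heterozygote becomes a randomly chosen homozygote (1 -> 0 or 2,
#' each with probability 1/2). Missing genotypes are untouched. The indices
#' of altered entries are attached as attribute \code{"flipped"} (a logical
#' matrix) so that callers can invalidate phase at those entries when
#' writing VCF output.
#'
#' @param genotypes integer matrix (sites x individuals) with values in
#'   \{0, 1, 2, NA\}.
#' @param errorRate per-genotype error probability in [0, 1] (default 0.001,
#'   the rate typical of low/intermediate-coverage sequencing calls).
#' @param seed integer seed.
#' @return The perturbed matrix with attribute \code{"flipped"}.
#' @export
applyGenotypeError <- function(genotypes, errorRate = 0.001, seed = 1L) {
  checkGenotypeMatrix(genotypes)
  if (is.na(errorRate) || errorRate < 0 || errorRate > 1)
    stop("errorRate must be in [0, 1]")
  out <- genotypes
  flipped <- matrix(FALSE, nrow = nrow(genotypes), ncol = ncol(genotypes))
  n <- length(genotypes)
  if (n > 0L && errorRate > 0) {
    draws <- withSeed(seed, {
      hit <- stats::runif(n) < errorRate
      homChoice <- stats::runif(n) < 0.5
      list(hit = hit, homChoice = homChoice)
    })
    hit <- draws$hit & !is.na(genotypes)
    g <- genotypes[hit]
    newg <- ifelse(g == 1L, ifelse(draws$homChoice[hit], 0L, 2L), 1L)
    out[hit] <- as.integer(newg)
    flipped[hit] <- TRUE
  }
  attr(out, "flipped") <- flipped
  out
}
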