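---
title: "Inferring a two-population clean split with ABC: model, statistics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a two-population clean split with ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference problem

splitABC estimates when two related populations — in the motivating
application, Bantu-speaking groups sampled around Cabinda/Angola
("CAB-like") and Mozambique ("MOZ-like") — separated, and how their
effective sizes changed, from diploid biallelic SNP genotypes. Because the
likelihood of whole-chromosome haplotype data under an explicit demographic
model is intractable, the package uses Approximate Bayesian Computation
(ABC): simulate many datasets from parameter values drawn from priors,
summarise every dataset (simulated and observed) by the same fixed
statistic vector, keep the simulations closest to the observation, and
correct the retained parameter values by a regression of parameters on
statistics.

# The clean-split model

Backwards in time from the present (generation 0):

* Two populations start at diploid sizes $N_{CAB}$ and $N_{MOZ}$ and change
  exponentially along their branches at rates
  $\alpha_n = \log(N_n / N'_n) / g_{split}$, so that each branch has size
  $N'_n$ exactly at the split generation $g_{split}$
  (`growthRate()`, `branchSizeAt()`).
* At $g_{split}$ the two branches merge into a single ancestral population
  in which lineages coalesce freely.
* At generation 7586 the ancestral population changes instantaneously to a
  fixed diploid size of 12,000. These two ancestral constants are fixed
  (they are standard values from a widely used composite model of human
  population history) and only the five quantities above are inferred.

A clean split — no post-split migration — is deliberately the simplest
separation model; estimates under it are usefully read as a lower bound on
the true separation time, since any unmodelled gene flow would push the
fitted split further back.

**Ancestral deme size between the split and generation 7586.** The model
fixes the ancestral size only *after* generation 7586; the size of
the merged deme between $g_{split}$ and 7586 is not stated and is not a free
parameter. This package sets it to $N'_{CAB} + N'_{MOZ}$, the total size of
the two merging branches, which makes the merge conserve the census at the
instant of joining and introduces no additional parameter. This is a design
choice a user can revisit only by editing `splitJob()`; posterior split
times are insensitive to it in the desk-scale checks because coalescence in
the merged deme is dominated by the long fixed-size epoch.

Time is measured in generations throughout; conversion to years before
present multiplies by the generation time (27 years) only at reporting
(`generationsToYearsBP()`, the `yearsBP` slot of posterior results).

# Priors

There is no canonical public prior table for the five parameters, so the
package ships defaults chosen to span the plausible range while respecting
the fixed ancestral ceiling:

| parameter | distribution | bounds |
|---|---|---|
| all four sizes | log-uniform | [100, 100 000] |
| `gen_split` | uniform | [10, 7000] |

Log-uniform size priors put equal mass on each order of magnitude, the
usual weakly-informative choice for effective sizes. The split upper bound
stays below the 7586-generation ancestral change by construction
(`priorSpec()` enforces this). Every bound and distribution kind is
overridable from the YAML run configuration (`readRunConfig()`).

# Simulation

Coalescent simulation with recombination is delegated to msprime through a
bundled worker script (one external process per batch of simulations, so
interpreter start-up is amortised). The package constructs the demography,
converts the genetic map into per-interval rates, filters the returned
variants to biallelic segregating SNPs, and assigns genetic (cM) positions
by linear interpolation on the same map used for simulation — so the cM
coordinates used by the IBD statistics are exactly consistent with the
recombination process that generated the data.

Genotype errors are injected after simulation, before any statistic is
computed: each genotype
independently with probability 0.001, homozygotes become heterozygotes and
heterozygotes become a randomly chosen homozygote
(`applyGenotypeError()`). Phase is invalidated at perturbed entries when
writing VCF. Sites rendered monomorphic by error are retained: the
segregating-sites restriction is applied to the simulated panel before
error injection, mirroring a pipeline that filters observed data before
adding simulated noise; re-filtering after injection is a defensible
alternative, so the choice is documented rather than left implicit.

# The 46 summary statistics

There is no canonical public listing of the 46 statistics. The registry
here assembles the families — classical
diversity, site-frequency, divergence, and the IBD/ROH haplotype statistics
known to carry signal about recent demography — with this fixed order
(`summaryStatNames()`):

* per population (×2): segregating sites, singletons, doubletons, π,
  Tajima's D, mean observed heterozygosity (12);
* within-population IBD count and total cM in the bins [2,4), [4,8),
  [8,∞) cM (12);
* within-population ROH count and total kb in classes < 1 Mb and ≥ 1 Mb
  (8);
* cross-population: Hudson F~ST~ (ratio-of-sums, unbiased within-population
  heterozygosity), D~xy~, shared/private/fixed site counts (6);
* between-population IBD in the same three bins (6);
* pooled segregating sites and pooled Tajima's D (2).

The registry is data-driven: an alternative listing can be swapped in
wholesale without touching the inference code. Non-finite
entries (e.g. F~ST~ on a panel with no between-population diversity) are
replaced by 0 with a warning so distances stay defined.

**IBD detection.** The external IBD caller used on the real data models
unphased genotype pairs under Hardy–Weinberg equilibrium; the package
implements the same model class directly: a per-site log~10~ likelihood
ratio of "the pair shares one haplotype IBD" against "unrelated", computed
from sample allele frequencies with the genotype error rate folded into the
emission (so opposite homozygotes are strongly negative but finite), and
maximal positive-sum run extraction per pair. Defaults: MAF > 0.01, LOD ≥ 3,
length ≥ 2 cM. Post-processing: gaps
< 0.6 cM containing at most one discordant homozygote are merged
(iterated to a fixpoint), and segments in low-SNP-density regions are
removed. The density threshold has no canonical value; the default
(50 SNPs/cM, retained at exactly the threshold) is a documented package
choice.

**ROH scanning** follows the standard PLINK procedure with the printed
parameters (50-SNP windows, threshold 0.05, min 50 SNPs, 300 kb, 50 kb/SNP
density, 1 Mb gap) and the scanning engine's documented default window
tolerances (1 heterozygote, 5 missing calls per window). kb thresholds
use floor(bp/1000).

# ABC estimation

`estimatePosterior()` composes three steps:

1. **Robust standardisation** of every statistic column by median/MAD of
   the reference table (zero-variance columns dropped; MAD-zero columns
   fall back to the SD). Median/MAD is a deliberate divergence from the
   usual mean/SD: the IBD and ROH counts are heavy-tailed and a handful of
   extreme simulations would otherwise dominate the distance.
2. **Rejection**: Euclidean distance in standardised space; the
   ⌈tolerance·n⌉ closest simulations are accepted (ties broken by row
   order). The default tolerance is 10%.
3. **Regression adjustment** on logit-transformed parameters (bounds = the
   prior bounds, boundary values nudged inward by 10⁻⁹ of the range, so
   adjusted draws always back-transform inside the prior support). The
   default engine is a single-hidden-layer feed-forward network with 4
   hidden units, sigmoidal activation, weight decay and linear
   output, fitted with Epanechnikov kernel weights
   $w_i = 1 - (d_i/d_{max})^2$ and averaged over 10 re-seeded restarts —
   single fits at this width are visibly initialisation-sensitive, and
   averaging tames that without changing the estimand. A second regression
   on log squared residuals supplies the heteroscedastic rescaling
   $\theta^* = m(s_{obs}) + (\theta_i - m(s_i))\,\sigma(s_{obs})/\sigma(s_i)$;
   the variance ratio is clamped to [1/20, 20] as a guard against exploding
   corrections where residuals are near zero. The default weight decay is
   1: at desk scale the accepted set is of order 10^2 rows against 46
   standardised predictors, and weaker decay lets both the mean and the
   variance networks interpolate the accepted rows, collapsing the
   posterior spread (interval coverage drops to ~0.4 at decay 0.01 in the
   package's own holdout checks, against 0.93-1.0 at decay 1). Large-scale
   references with thousands of accepted rows can and should lower
   `abcConfig(decay=)`. `method = "loclinear"`
   substitutes weighted linear regression; `method = "rejection"` skips
   adjustment and reports the raw accepted draws with uniform weights (so
   its summaries are exactly the accepted-sample quantiles). If a
   regression fails the parameter falls back to rejection with a warning.

Posterior medians and [2.5, 97.5] percentile intervals are weighted
quantiles over the adjusted draws; the split generation is additionally
reported in years BP.

# Validation

`holdoutValidate()` implements the accuracy/calibration protocol: rows of
the reference are treated as pseudo-observed datasets, each excluded from
the reference during its own evaluation (leave-one-out; keeping it would
plant a distance-zero self-match and flatter the estimator), and the
posterior medians are scored by MAE, MSE and RMSE against the known truths
together with the frequency at which truths fall inside the [2.5, 97.5]
interval. Medians (not means) are the point estimates being scored,
matching the median-point-estimate convention of the posterior summaries.
`compareTolerances()` replays the tolerance/method selection grid; its
"mean prediction error" is the parameter-averaged MSE scaled by the
variance of the holdout truths, so parameters on different natural scales
contribute comparably.

# Cohort statistics

Shared f2 alleles are sites whose minor-allele count across the whole
dataset is exactly 2, outside masked intervals (low-complexity and
segmental-duplication BED masks in the real-data application). When the two
minor alleles sit in two different individuals the group pair is tallied
symmetrically; a homozygous doubleton in a single individual is counted in
a separate within-individual tally rather than the matrix — a convention
that keeps the matrix a pure between-individual sharing count.
The one-tailed permutation test on mean pairwise IBD relabels individuals
(not pairs — pairs are not exchangeable units) and uses the add-one
estimator p = (1 + #{T_perm ≥ T_obs})/(1 + n_perm).

# Desk-scale conditions and what the tests do (and do not) show

The full-scale campaign — 135,000 simulations of a ~249 Mb chromosome with
40+40 diploid samples — is a cluster computation, and the real cohort
genomes are under restricted access. The package's test and acceptance runs therefore
use desk-scale conditions chosen once: a 5 Mb segment under the bundled
variable-rate map (knots every 500 kb, rates 0.4–2.8 cM/Mb, mean
≈ 1.24 cM/Mb, comparable to the chromosome-1 average), 20+20 diploids,
reference tables of 400–800 simulations, 40–50 regression-adjusted holdouts
and 250 prior-baseline holdouts, and 100–200 replicates for the closed-form
coalescent checks. Full scale is reachable through the same API
(`genomeConfig(2.49e8, readRecombMap(...), samplesPerPop = 40L)` and
`generateReference(..., nSim = 135000)`) but is flagged cluster-scale.

What the synthetic data emulate: two-population clean-split coalescent
genealogies with recombination under a variable-rate map, biallelic
segregating SNPs, phased GT fields, and genotype noise at the 0.001 error
rate. What they do not emulate: SNP ascertainment of real cohorts, phasing
and calling artefacts beyond the symmetric error model, low-complexity or
duplicated-region masking, and admixture or migration — so green tests
certify the machinery and its calibration under the model, not the
historical conclusions drawn from the restricted data.

Numerical conventions collected in one place: 0-based half-open coordinates
internally, 1-based at VCF and map boundaries; multiallelic records are
skipped on read and multi-allelic simulated sites dropped; rejection ties
broken by row order; weighted quantiles interpolate at plotting positions
$(F_i - w_i/2)/\sum w$, which reduces to the ordinary median for uniform
weights; per-row simulation seeds are integer hashes of (master seed, row
index), so chunked and monolithic reference generation agree bit-for-bit.

# Known limitations

* The 46-statistic registry and the priors encode statistic families and
  plausible ranges rather than a canonical external listing; both are
  configurable precisely because of that.
* The IBD detector is a likelihood-ratio scan of the same model class as
  the external caller, not a reimplementation of its windowed LD machinery;
  absolute segment counts can differ from the caller's even though the
  pipeline-level statistics respond to demography the same way.
* A clean split with no migration is a lower-bound model by design;
  applying the package to populations with substantial post-split gene flow
  will bias split estimates downward.
* The neural-net adjustment is averaged over restarts but remains a
  stochastic estimator; all entry points accept seeds and are reproducible
  bit-for-bit under a fixed seed.
* The local-linear adjustment estimates 47 coefficients and is therefore
  itself overfit-prone on desk-scale accepted sets; at those sizes the
  regularised neural net is the better-calibrated default, and loclinear
  is most useful at larger reference sizes or reduced statistic sets.

# A minimal session

```{r example}
library(splitABC)

genome <- genomeConfig(sequenceLength = 5e6, recombMap = deskRecombMap(5e6),
                       samplesPerPop = 20L)

# reference table: prior draws -> simulate -> error -> 46 statistics
ref <- generateReference(defaultPriors(), nSim = 400, genome = genome,
                         errorRate = 0.001, seed = 1L)

# a pseudo-observed cohort at a known truth
truth <- splitModelParams(20000, 5000, 15000, 3000, genSplit = 118)
obsRun <- generatePseudoObserved(truth, genome, errorRate = 0.001, seed = 2L,
                                 vcfPath = "observed.vcf")
rv <- readVCF("observed.vcf")
obs <- computeSummaryVector(list(genotypes = rv$genotypes, posBp = rv$posBp,
                                 labels = sub("_[0-9]+$", "", rv$samples)),
                            map = genome@recombMap)

post <- estimatePosterior(ref, obs, abcConfig(tolerance = 0.1,
                                              method = "neuralnet"))
post               # per-parameter medians and 95% intervals, split in years BP
holdoutValidate(ref, 40, abcConfig(), seed = 3L)
```
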